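#' Construct a SnpMap
#'
#' Builds the ordered autosomal SNP map used by every track. Input rows
#' may arrive in any order; they are sorted by (chromosome, position)
#' with a warning when re-ordering was needed. X/Y loci and duplicate
#' SNP ids are rejected.
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chromosome vector coercible to integer 1-22 (the strings
#'   "X"/"Y" and 23/24 are rejected; a leading "chr" prefix is allowed).
#' @param arm character vector, "p" or "q".
#' @param position integer vector of 1-based base-pair positions.
#' @return a [SnpMap-class].
#' @examples
#' SnpMap(c("s1", "s2"), c(1, 1), c("p", "q"), c(100, 5e6))
#' @export
SnpMap <- function(snp_id, chromosome, arm, position) {
  chromosome <- sub("^chr", "", as.character(chromosome))
  if (any(toupper(chromosome) %in% c("X", "Y", "23", "24")))
    stop("X/Y chromosome SNPs are excluded from the map")
  chrom <- suppressWarnings(as.integer(chromosome))
  if (anyNA(chrom))
    stop("unparseable chromosome label(s): ",
         paste(unique(chromosome[is.na(chrom)]), collapse = ", "))
  if (anyDuplicated(snp_id))
    stop("duplicate SNP id(s): ",
         paste(unique(snp_id[duplicated(snp_id)]), collapse = ", "))
  o <- order(chrom, position)
  if (is.unsorted(o, strictly = TRUE) || any(o != seq_along(o))) {
    if (!identical(o, seq_along(o)))
      warning("input loci were not sorted by (chromosome, position); sorting")
  }
  new("SnpMap",
    snpId = as.character(snp_id)[o],
    chromosome = chrom[o],
    arm = as.character(arm)[o],
    position = as.integer(position)[o])
}

#' Read a SNP map from a tab-separated file
#'
#' Expects one header line with columns snp_id, chromosome, arm,
#' position. Rows are validated and sorted via [SnpMap()].
#'
#' @param path path to the TSV file.
#' @return a [SnpMap-class].
#' @seealso [writeSnpMap()]
#' @export
readSnpMap <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("snp_id", "chromosome", "arm", "position")
  if (!all(need %in% names(df)))
    stop("SNP map must have columns ", paste(need, collapse = ", "))
  bad <- which(is.na(df$snp_id) | is.na(df$position) | !nzchar(df$snp_id))
  if (length(bad))
    stop("malformed SNP map row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "))
  SnpMap(df$snp_id, df$chromosome, df$arm, df$position)
}

#' @rdname readSnpMap
#' @param map a [SnpMap-class] to write.
#' @export
writeSnpMap <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a genotype call matrix aligned to a SNP map
#'
#' The file is a TSV whose first column is the SNP id and remaining
#' columns are samples; cells are AA/AB/BB/NC. Rows are re-ordered to
#' match \code{map}; SNPs present in the map but absent from the file
#' are filled with NC and flagged via a warning.
#'
#' @param path path to the TSV file.
#' @param map the [SnpMap-class] the matrix must align to.
#' @return character matrix (SNP x sample), rownames = SNP ids.
#' @export
readGenotypeMatrix <- function(path, map) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- df[[1L]]
  unknown <- setdiff(ids, snpIds(map))
  if (length(unknown))
    stop("genotype matrix contains SNP(s) not in the map: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  bad <- !(m %in% GENOTYPE_LEVELS)
  if (any(bad))
    stop("unknown genotype token(s): ",
         paste(unique(m[bad]), collapse = ", "))
  rownames(m) <- ids
  missing <- setdiff(snpIds(map), ids)
  if (length(missing)) {
    warning(length(missing), " map SNP(s) absent from genotype file; filled as NC")
    fill <- matrix("NC", length(missing), ncol(m),
                   dimnames = list(missing, colnames(m)))
    m <- rbind(m, fill)
  }
  m[snpIds(map), , drop = FALSE]
}

#' Read a numeric per-SNP matrix (intensity log ratios or expression)
#'
#' @param path path to a TSV whose first column is the row id.
#' @param map optional [SnpMap-class]; when given, rows are aligned to
#'   it and unknown ids rejected.
#' @return numeric matrix with rownames from the first column.
#' @export
readNumericMatrix <- function(path, map = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!is.null(map)) {
    unknown <- setdiff(ids, snpIds(map))
    if (length(unknown))
      stop("matrix contains SNP(s) not in the map: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    m <- m[snpIds(map), , drop = FALSE]
  }
  m
}

#' Write a matrix as TSV with an id column
#'
#' Inverse of [readGenotypeMatrix()] / [readNumericMatrix()]: writes
#' rownames as a first column named \code{idCol}.
#'
#' @param m matrix with rownames.
#' @param path output path.
#' @param idCol name for the id column.
#' @export
writeMatrixTsv <- function(m, path, idCol = "snp_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- idCol
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene/probe-set annotation table
#'
#' Columns: probeset_id, gene_symbol, chromosome, start, end. Distinct
#' probe sets of one gene may carry distinct regions (they map to
#' different reference sequences), so probeset_id is the key.
#'
#' @param path path to the TSV file.
#' @return data.frame with the five columns, chromosome as integer.
#' @export
readGeneTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("probeset_id", "gene_symbol", "chromosome", "start", "end")
  if (!all(need %in% names(df)))
    stop("gene table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$probeset_id))
    stop("duplicate probeset_id(s) in gene table")
  df$chromosome <- as.integer(sub("^chr", "", as.character(df$chromosome)))
  if (any(df$start > df$end)) stop("gene regions must have start <= end")
  df[need]
}

#' Export six-state segments of one case as BED
#'
#' BED6: chrom (chr-prefixed), 0-based half-open interval, name =
#' "LOH|neutral"-style state label, score = number of informative SNPs,
#' strand ".". Internal coordinates are 1-based inclusive; the 0-based
#' shift happens here.
#'
#' @param segments data.frame as returned by [segmentStates()],
#'   restricted to a single case.
#' @param path output path.
#' @return the path, invisibly.
#' @seealso [readSegmentsBed()]
#' @export
writeSegmentsBed <- function(segments, path) {
  if (nrow(segments) && length(unique(segments$case_id)) > 1L)
    stop("writeSegmentsBed() writes one case per file; split by case_id")
  if (!nrow(segments)) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = paste0("chr", segments$chromosome),
    ranges = IRanges::IRanges(start = segments$start, end = segments$end),
    name = segments$state,
    score = segments$n_informative_snps)
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Import six-state segments of one case from BED
#'
#' @param path BED file written by [writeSegmentsBed()].
#' @param case_id case identifier to stamp onto the rows.
#' @return data.frame with the [segmentStates()] columns.
#' @export
readSegmentsBed <- function(path, case_id = NA_character_) {
  gr <- rtracklayer::import.bed(path)
  if (!length(gr)) {
    return(data.frame(case_id = character(), chromosome = integer(),
                      start = integer(), end = integer(),
                      state = character(), loh = logical(),
                      cn_group = character(),
                      n_informative_snps = integer(),
                      stringsAsFactors = FALSE))
  }
  state <- as.character(gr$name)
  parts <- strsplit(state, "|", fixed = TRUE)
  data.frame(
    case_id = case_id,
    chromosome = as.integer(sub("^chr", "", as.character(GenomicRanges::seqnames(gr)))),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    state = state,
    loh = vapply(parts, `[`, "", 1L) == "LOH",
    cn_group = vapply(parts, `[`, "", 2L),
    n_informative_snps = as.integer(gr$score),
    stringsAsFactors = FALSE)
}

#' Published reference-cohort LOH counts
#'
#' Per-case (30 esophageal squamous cell carcinoma trios) and per-arm
#' (39 autosomal arms) counts of informative SNPs with LOH, split by CN
#' group, from a published genome-wide 500K-array ESCC study. Two
#' per-arm cells whose printed values contradicted their own row totals
#' and fractions were restored to the internally consistent values
#' (see the package vignette). These tables feed [footerStats()] and
#' [percentCasesWithLoh()] in the reproduction tests.
#'
#' @param by "case" or "arm".
#' @return data.frame in the [tabulateLohByCn()] layout: unit_id,
#'   total, n_loss, n_neutral, n_gain plus half-up-rounded frac_
#'   columns.
#' @examples
#' footerStats(referenceCohortCounts("case"))
#' @export
referenceCohortCounts <- function(by = c("case", "arm")) {
  by <- match.arg(by)
  f <- system.file("extdata",
                   sprintf("escc_loh_by_%s.tsv", by), package = "cnnloh")
  df <- read.delim(f, stringsAsFactors = FALSE,
                   colClasses = c("character", rep("integer", 4L)))
  names(df) <- c("unit_id", "total", "n_loss", "n_neutral", "n_gain")
  addFractions(df)
}
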