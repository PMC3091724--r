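#' Informative-SNP mask from blood genotypes
#'
#' A SNP is informative for LOH exactly when the germline (blood) call
#' is heterozygous: only there can loss of one allele be observed as a
#' zygosity change.
#'
#' @param blood character vector or matrix of blood genotype calls
#'   (AA/AB/BB/NC).
#' @return logical vector/matrix of the same shape: TRUE where AB.
#' @examples
#' informativeSnps(c("AB", "AA", "BB", "NC"))
#' @export
informativeSnps <- function(blood) {
  bad <- !(blood %in% GENOTYPE_LEVELS)
  if (any(bad))
    stop("invalid genotype call(s): ", paste(unique(blood[bad]), collapse = ", "))
  out <- blood == "AB"
  if (is.matrix(blood)) dim(out) <- dim(blood)
  if (is.matrix(blood)) dimnames(out) <- dimnames(blood)
  out
}

#' Call per-SNP LOH against the matched blood reference
#'
#' Paired-zygosity rule, applied per case column: at informative SNPs
#' (blood AB), a homozygous target call (AA or BB) is LOH, a
#' heterozygous target call is RETENTION, and a NoCall is UNDEFINED.
#' Uninformative SNPs (blood homozygous or NoCall) are always
#' UNDEFINED. Opposite-homozygote pairs (blood AA, target BB) indicate
#' genotyping error; they remain UNDEFINED and are counted per case in
#' the \code{discordantHom} QC slot.
#'
#' @param blood character genotype matrix (SNP x case) for blood.
#' @param target matrix of identical shape for tumor or adjacent
#'   normal.
#' @param map the [SnpMap-class] both matrices are aligned to.
#' @return a [LohTrack-class].
#' @examples
#' map <- SnpMap("s1", 1, "p", 100)
#' callLoh(matrix("AB", 1, 1, dimnames = list("s1", "c1")),
#'         matrix("AA", 1, 1, dimnames = list("s1", "c1")), map)
#' @export
callLoh <- function(blood, target, map) {
  if (!is.matrix(blood)) blood <- as.matrix(blood)
  if (!is.matrix(target)) target <- as.matrix(target)
  if (!identical(dim(blood), dim(target)))
    stop("blood and target matrices differ in shape")
  if (nrow(blood) != length(map))
    stop("genotype matrices are not aligned to the map")
  bad <- !(blood %in% GENOTYPE_LEVELS) | !(target %in% GENOTYPE_LEVELS)
  if (any(bad)) stop("invalid genotype call(s) in input")
  informative <- blood == "AB"
  status <- matrix("UNDEFINED", nrow(blood), ncol(blood),
                   dimnames = dimnames(blood))
  status[informative & (target == "AA" | target == "BB")] <- "LOH"
  status[informative & target == "AB"] <- "RETENTION"
  discordant <- (blood == "AA" & target == "BB") |
    (blood == "BB" & target == "AA")
  new("LohTrack", map = map, status = status,
      informative = informative,
      discordantHom = as.integer(colSums(discordant)))
}
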