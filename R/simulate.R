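## Synthetic trio-cohort generator. Every stage draws from its own
## stream derived from the root seed, so stages can be re-run in
## isolation and still reproduce the full-cohort values.

stageSeed <- function(seed, stage) {
  offsets <- c(map = 1L, germline = 2L, events = 3L, tumor = 4L,
               intensity = 5L, genes = 6L, expression = 7L, null = 8L)
  (as.integer(seed) %% 100003L) * 1009L + offsets[[stage]] * 97L
}

caseLabels <- function(n) sprintf("case%02d", seq_len(n))

#' Simulate a SNP map with regular-plus-jitter spacing
#'
#' Positions sit on a regular grid at the configured mean spacing with
#' uniform jitter of up to 40% of the spacing, mimicking the
#' near-regular but irregular probe spacing of a dense SNP array. Each
#' chromosome gets at least one SNP. The p/q arm boundary is placed at
#' \code{armFraction} of each chromosome length.
#'
#' @param config a [SimConfig-class] (spacing and seed are used).
#' @param chromosomeLengths numeric vector of chromosome lengths in bp;
#'   names (default \code{seq_along}) are the chromosome numbers.
#' @param armFraction fraction of each chromosome assigned to the p arm.
#' @return a [SnpMap-class].
#' @export
simulateSnpMap <- function(config, chromosomeLengths,
                           armFraction = 0.4) {
  stopifnot(is(config, "SimConfig"), length(chromosomeLengths) >= 1L)
  if (any(chromosomeLengths <= 0)) stop("chromosome lengths must be positive")
  if (is.null(names(chromosomeLengths)))
    names(chromosomeLengths) <- seq_along(chromosomeLengths)
  set.seed(stageSeed(config@seed, "map"))
  sp <- config@snpSpacingBp
  pieces <- lapply(names(chromosomeLengths), function(chr) {
    len <- chromosomeLengths[[chr]]
    grid <- if (sp / 2 <= len) seq(sp / 2, len, by = sp) else (len + 1) / 2
    pos <- grid + runif(length(grid), -0.4 * sp, 0.4 * sp)
    pos <- sort(pmin(pmax(round(pos), 1), len))
    pos <- unique(pos)
    data.frame(
      snp_id = sprintf("chr%s_snp%05d", chr, seq_along(pos)),
      chromosome = as.integer(chr),
      arm = ifelse(pos < armFraction * len, "p", "q"),
      position = as.integer(pos), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  SnpMap(df$snp_id, df$chromosome, df$arm, df$position)
}

#' Simulate germline (blood) genotype calls
#'
#' Each SNP in each case is drawn i.i.d.: AB with probability equal to
#' the configured heterozygosity, AA/BB splitting the remainder
#' equally. A NoCall overlay replaces calls with NC at rate
#' \code{1 - callRate}.
#'
#' @param map a [SnpMap-class].
#' @param config a [SimConfig-class].
#' @return character matrix (SNP x case) over AA/AB/BB/NC.
#' @export
simulateGermline <- function(map, config) {
  stopifnot(is(map, "SnpMap"), is(config, "SimConfig"))
  set.seed(stageSeed(config@seed, "germline"))
  n <- length(map); k <- config@nCases
  h <- config@heterozygosity
  g <- matrix(
    sample(c("AA", "AB", "BB"), n * k, replace = TRUE,
           prob = c((1 - h) / 2, h, (1 - h) / 2)),
    nrow = n, dimnames = list(snpIds(map), caseLabels(k)))
  nc <- matrix(runif(n * k) > config@callRate, nrow = n)
  g[nc] <- "NC"
  g
}

#' Plant six-state somatic events and build the per-SNP truth track
#'
#' Events are intervals with an LOH flag and a true copy number; the
#' background everywhere else is retention at CN 2. The returned truth
#' track labels every SNP in every case, forming a partition (exactly
#' one true state per SNP per case).
#'
#' @param map a [SnpMap-class].
#' @param caseIds character vector of case identifiers.
#' @param events data.frame with columns case_id, chromosome, start,
#'   end, loh (logical), cn (integer 0-4). Events of one case on one
#'   chromosome must not overlap.
#' @return list with elements \code{events} (the input, with a derived
#'   \code{cn_group} column), \code{loh} (logical SNP x case matrix of
#'   true LOH) and \code{cn} (integer SNP x case matrix of true copy
#'   number).
#' @export
plantEvents <- function(map, caseIds, events) {
  stopifnot(is(map, "SnpMap"))
  n <- length(map)
  lohT <- matrix(FALSE, n, length(caseIds),
                 dimnames = list(snpIds(map), caseIds))
  cnT <- matrix(2L, n, length(caseIds),
                dimnames = list(snpIds(map), caseIds))
  if (nrow(events)) {
    stopifnot(all(c("case_id", "chromosome", "start", "end", "loh", "cn")
                  %in% names(events)),
              all(events$cn %in% 0:4),
              all(events$case_id %in% caseIds))
    for (key in split(seq_len(nrow(events)),
                      paste(events$case_id, events$chromosome))) {
      if (length(key) > 1L) {
        e <- events[key, ]
        e <- e[order(e$start), ]
        if (any(e$end[-nrow(e)] >= e$start[-1L]))
          stop("overlapping events for case ", e$case_id[1L],
               " chromosome ", e$chromosome[1L])
      }
    }
    for (i in seq_len(nrow(events))) {
      sel <- map@chromosome == events$chromosome[i] &
        map@position >= events$start[i] & map@position <= events$end[i]
      lohT[sel, events$case_id[i]] <- events$loh[i]
      cnT[sel, events$case_id[i]] <- as.integer(events$cn[i])
    }
  }
  grp <- c("loss", "loss", "neutral", "gain", "gain")
  events$cn_group <- if (nrow(events)) grp[events$cn + 1L] else character(0)
  list(events = events, loh = lohT, cn = cnT, map = map)
}

#' Generate the default planted-event roster for a cohort
#'
#' Somatic events in a tumor cohort recur: the same regions are hit in
#' many cases (in ESCC, CNNLOH recurs on every arm and reaches 96-100%
#' of cases on some arms, gain-LOH 74-82%, loss-LOH ~56%), and one
#' recurrently altered region is carried with LOH in some cases and
#' without it in others -- which is what makes LOH-conditioned
#' expression comparisons possible at all. The roster therefore draws
#' a fixed set of mutually non-overlapping candidate regions per CN
#' level (each sized to an expected
#' \code{minInformative}-\code{maxInformative} informative SNPs), and
#' each case carries each candidate independently with probability
#' \code{carryProb}; a carried CN-neutral candidate is always LOH
#' (retention at CN 2 is the background), while carried loss/gain
#' candidates are LOH with probability \code{lohGivenCarry}. The
#' probabilities are ordered like the published recurrence: CNNLOH
#' most common, loss-LOH least.
#'
#' @param map a [SnpMap-class].
#' @param config a [SimConfig-class].
#' @param minInformative,maxInformative expected informative-SNP span
#'   bounds per candidate region.
#' @param nCandidates named integer: candidate regions per CN group.
#' @param carryProb named numeric: probability a case carries a given
#'   candidate.
#' @param lohGivenCarry named numeric: probability a carried candidate
#'   is LOH positive in that case.
#' @return events data.frame suitable for [plantEvents()].
#' @export
defaultEventSpec <- function(map, config, minInformative = 25L,
                             maxInformative = 50L,
                             nCandidates = c(loss = 3L, neutral = 4L,
                                             gain = 3L),
                             carryProb = c(loss = 0.40, neutral = 0.60,
                                           gain = 0.60),
                             lohGivenCarry = c(loss = 0.55, neutral = 1,
                                               gain = 0.80)) {
  set.seed(stageSeed(config@seed, "events"))
  chroms <- unique(map@chromosome)
  chrLen <- vapply(chroms, function(c)
    max(map@position[map@chromosome == c]), 0)
  cnOf <- c(loss = 1L, neutral = 2L, gain = 3L)
  placed <- data.frame(chromosome = integer(), start = numeric(),
                       end = numeric())
  cand <- do.call(rbind, lapply(names(nCandidates), function(grp) {
    do.call(rbind, lapply(seq_len(nCandidates[[grp]]), function(j) {
      span <- round(runif(1, minInformative, maxInformative) /
                      config@heterozygosity * config@snpSpacingBp)
      clash <- TRUE
      for (try in 1:200) {
        chr <- sample(chroms, 1L)
        start <- round(runif(1, 1, max(1, chrLen[match(chr, chroms)] - span)))
        clash <- placed$chromosome == chr &
          placed$start <= start + span & placed$end >= start
        if (!any(clash)) break
      }
      if (any(clash)) stop("could not place non-overlapping candidate regions")
      placed <<- rbind(placed, data.frame(chromosome = chr, start = start,
                                          end = start + span))
      data.frame(chromosome = as.integer(chr), start = as.integer(start),
                 end = as.integer(start + span), cn = cnOf[[grp]],
                 carry = carryProb[[grp]], pLoh = lohGivenCarry[[grp]],
                 stringsAsFactors = FALSE)
    }))
  }))
  rows <- lapply(caseLabels(config@nCases), function(cs) {
    carried <- runif(nrow(cand)) < cand$carry
    loh <- runif(nrow(cand)) < cand$pLoh
    keep <- carried & (loh | cand$cn != 2L)  # retention at CN 2 = background
    if (!any(keep)) return(NULL)
    data.frame(case_id = cs,
               cand[keep, c("chromosome", "start", "end")],
               loh = loh[keep], cn = cand$cn[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate tumor and adjacent-normal genotype calls
#'
#' The tumor copies the blood calls except inside true-LOH runs, where
#' heterozygous (AB) calls collapse to a homozygote. The retained
#' allele is chosen uniformly at random once per contiguous LOH run
#' (one clonal event, one surviving haplotype), not per SNP. The
#' adjacent normal is a copy of blood. Both get independent NoCall
#' overlays at rate \code{1 - callRate}.
#'
#' @param blood character genotype matrix from [simulateGermline()].
#' @param truth truth track from [plantEvents()].
#' @param config a [SimConfig-class].
#' @return list with character matrices \code{tumor} and \code{normal}.
#' @export
simulateTumorGenotypes <- function(blood, truth, config) {
  set.seed(stageSeed(config@seed, "tumor"))
  stopifnot(identical(dim(blood), dim(truth$loh)))
  tumor <- blood
  chromKey <- truth$map@chromosome
  for (cs in colnames(blood)) {
    loh <- truth$loh[, cs]
    runId <- cumsum(c(TRUE, diff(as.integer(loh)) != 0L |
                        chromKey[-1L] != chromKey[-length(chromKey)]))
    for (r in unique(runId[loh])) {
      sel <- runId == r & loh
      retained <- sample(c("AA", "BB"), 1L)
      het <- sel & blood[, cs] == "AB"
      tumor[het, cs] <- retained
    }
  }
  overlay <- function(m) {
    nc <- matrix(runif(length(m)) > config@callRate, nrow = nrow(m))
    m[nc] <- "NC"
    m
  }
  list(tumor = overlay(tumor), normal = overlay(blood))
}

#' Simulate per-SNP intensity log2 ratios
#'
#' Tumor-vs-blood ratios are drawn Normal(log2(c/2), noise sd) where c
#' is the true copy number (c = 0 uses a floor of -3, the residual
#' signal of a homozygous deletion on an array). Adjacent-normal-vs-
#' blood ratios are drawn at c = 2.
#'
#' @param truth truth track from [plantEvents()].
#' @param config a [SimConfig-class].
#' @return list with numeric matrices \code{tumor} and \code{normal}.
#' @export
simulateIntensities <- function(truth, config) {
  set.seed(stageSeed(config@seed, "intensity"))
  cn <- truth$cn
  mu <- ifelse(cn == 0L, -3, log2(cn / 2))
  sd <- config@intensityNoiseSd
  tumor <- matrix(rnorm(length(cn), mean = as.vector(mu), sd = sd),
                  nrow = nrow(cn), dimnames = dimnames(cn))
  normal <- matrix(rnorm(length(cn), mean = 0, sd = sd),
                   nrow = nrow(cn), dimnames = dimnames(cn))
  list(tumor = tumor, normal = normal)
}

#' Simulate a gene/probe-set annotation table
#'
#' Genes are placed uniformly along the simulated chromosomes with
#' spans of 20-150 kb. A fraction of genes carry two probe sets with
#' slightly different reference regions, mirroring expression arrays
#' where probe sets of one gene can differ in location and therefore
#' in the number of SNPs they contain.
#'
#' @param config a [SimConfig-class] (seed).
#' @param chromosomeLengths as in [simulateSnpMap()].
#' @param nGenes number of genes.
#' @param twoProbesetFraction fraction of genes given a second probe set.
#' @return data.frame with columns probeset_id, gene_symbol,
#'   chromosome, start, end.
#' @export
simulateGeneTable <- function(config, chromosomeLengths, nGenes = 400L,
                              twoProbesetFraction = 0.2) {
  set.seed(stageSeed(config@seed, "genes"))
  if (is.null(names(chromosomeLengths)))
    names(chromosomeLengths) <- seq_along(chromosomeLengths)
  chrom <- sample(names(chromosomeLengths), nGenes, replace = TRUE)
  span <- round(runif(nGenes, 2e4, 1.5e5))
  start <- vapply(seq_len(nGenes), function(i) {
    round(runif(1, 1, max(1, chromosomeLengths[[chrom[i]]] - span[i])))
  }, 0)
  sym <- sprintf("GENE%04d", seq_len(nGenes))
  df <- data.frame(
    probeset_id = sprintf("%04d_at", seq_len(nGenes)),
    gene_symbol = sym,
    chromosome = as.integer(chrom),
    start = as.integer(start),
    end = as.integer(start + span),
    stringsAsFactors = FALSE)
  dup <- which(runif(nGenes) < twoProbesetFraction)
  if (length(dup)) {
    shift <- round(runif(length(dup), -1e4, 1e4))
    second <- df[dup, ]
    second$probeset_id <- sprintf("%04d_s_at", dup)
    second$start <- pmax(1L, as.integer(second$start + shift))
    second$end <- as.integer(second$end + shift)
    df <- rbind(df, second)
  }
  df <- df[order(df$chromosome, df$start), ]
  rownames(df) <- NULL
  df
}

#' Expression-effect parameters for the simulator
#'
#' @param effectLog2 mean log2 shift added to tumor expression of
#'   affected genes lying fully inside a true LOH event.
#' @param noiseSd residual sd of the per-case log2 fold change.
#' @param affectedFraction fraction of genes designated as
#'   LOH-responsive (each gets a random sign).
#' @return list of class "ExpressionEffect".
#' @export
ExpressionEffect <- function(effectLog2 = 2, noiseSd = 0.3,
                             affectedFraction = 0.3) {
  stopifnot(noiseSd > 0, affectedFraction >= 0, affectedFraction <= 1)
  structure(list(effectLog2 = effectLog2, noiseSd = noiseSd,
                 affectedFraction = affectedFraction),
            class = "ExpressionEffect")
}

#' Simulate paired normal/tumor expression matrices
#'
#' The first \code{nExpressionPairs} cases receive expression data.
#' Normal log2 values are a per-gene baseline plus noise; tumor values
#' add independent case/gene noise, plus a signed \code{effectLog2}
#' shift for designated affected genes whose region lies fully inside
#' a true LOH event of that case. The gene truth table records which
#' probe sets are affected and with which sign.
#'
#' @param genes annotation from [simulateGeneTable()].
#' @param truth truth track from [plantEvents()] (its \code{events}
#'   element is used for gene-in-event containment).
#' @param effect an [ExpressionEffect()].
#' @param config a [SimConfig-class].
#' @return list with matrices \code{normal} and \code{tumor}
#'   (probe set x expression case) and data.frame \code{genes}
#'   (probeset_id, affected, sign).
#' @export
simulateExpression <- function(genes, truth, effect, config) {
  stopifnot(inherits(effect, "ExpressionEffect"))
  set.seed(stageSeed(config@seed, "expression"))
  cases <- caseLabels(config@nCases)[seq_len(config@nExpressionPairs)]
  np <- nrow(genes)
  baseline <- rnorm(np, mean = 7, sd = 1)
  affected <- runif(np) < effect$affectedFraction
  sign <- ifelse(runif(np) < 0.5, -1, 1)
  ev <- truth$events[truth$events$loh, , drop = FALSE]
  inLoh <- matrix(FALSE, np, length(cases),
                  dimnames = list(genes$probeset_id, cases))
  for (i in seq_len(nrow(ev))) {
    if (!ev$case_id[i] %in% cases) next
    sel <- genes$chromosome == ev$chromosome[i] &
      genes$start >= ev$start[i] & genes$end <= ev$end[i]
    inLoh[sel, ev$case_id[i]] <- TRUE
  }
  normal <- matrix(baseline + rnorm(np * length(cases), sd = effect$noiseSd),
                   nrow = np, dimnames = list(genes$probeset_id, cases))
  shift <- (affected * sign * effect$effectLog2) * inLoh
  tumor <- normal + matrix(rnorm(np * length(cases), sd = effect$noiseSd),
                           nrow = np) + shift
  list(normal = normal, tumor = tumor,
       genes = data.frame(probeset_id = genes$probeset_id,
                          affected = affected, sign = as.integer(sign),
                          stringsAsFactors = FALSE))
}

#' Simulate a null expression experiment with known group structure
#'
#' Generates eligible probe sets directly: each gets a random number of
#' LOH-positive (2-8) and LOH-negative (>= 2) cases in the CN-neutral
#' class, the remainder undefined, and pure-noise log2 fold changes.
#' Used to check the type-I error of the LOH differential-expression
#' test against its binomial expectation.
#'
#' @param nProbesets number of probe sets.
#' @param nCases number of expression cases.
#' @param noiseSd sd of the null log2 fold changes.
#' @param seed integer seed.
#' @return list with \code{fc} (probe set x case log2 fold-change
#'   matrix) and \code{states} (long data.frame: case_id, probeset_id,
#'   cn_group, loh).
#' @export
simulateNullExpression <- function(nProbesets = 4572L, nCases = 17L,
                                   noiseSd = 0.3, seed = 1L) {
  set.seed(stageSeed(seed, "null"))
  cases <- caseLabels(nCases)
  ps <- sprintf("null%05d_at", seq_len(nProbesets))
  fc <- matrix(rnorm(nProbesets * nCases, sd = noiseSd),
               nrow = nProbesets, dimnames = list(ps, cases))
  nLoh <- sample(2:8, nProbesets, replace = TRUE)
  nNo <- vapply(nLoh, function(k) sample(2:(nCases - k), 1L), 0L)
  states <- do.call(rbind, lapply(seq_len(nProbesets), function(i) {
    idx <- sample(nCases, nLoh[i] + nNo[i])
    data.frame(case_id = cases[idx], probeset_id = ps[i],
               cn_group = "neutral",
               loh = rep(c(TRUE, FALSE), c(nLoh[i], nNo[i])),
               stringsAsFactors = FALSE)
  }))
  list(fc = fc, states = states)
}

#' Simulate a complete trio cohort with planted six-state events
#'
#' Runs the whole generator: SNP map, germline calls, planted events,
#' tumor/adjacent-normal genotypes, intensity log ratios, gene
#' annotation and paired expression. The default genome is a scaled-
#' down one (8 chromosomes of 12 Mb, ~16,500 SNPs at 5.8 kb spacing)
#' so that a full cohort simulates in seconds while every downstream
#' stage still sees realistic SNP densities and event sizes.
#'
#' @param config a [SimConfig-class].
#' @param chromosomeLengths chromosome lengths in bp (named by
#'   chromosome number).
#' @param events optional event roster; defaults to
#'   [defaultEventSpec()].
#' @param effect an [ExpressionEffect()] for the expression layer.
#' @param nGenes genes in the simulated annotation.
#' @param armFraction p-arm fraction of each chromosome.
#' @return list with elements config, map, genotypes (blood, tumor,
#'   normal), ratios (tumor, normal), genes, expression (normal,
#'   tumor), truth (events, loh, cn, genes).
#' @examples
#' cohort <- simulateCohort(SimConfig(nCases = 4, nExpressionPairs = 2,
#'                                    seed = 1),
#'                          chromosomeLengths = rep(6e6, 5))
#' dim(cohort$genotypes$blood)
#' @export
simulateCohort <- function(config = SimConfig(),
                           chromosomeLengths = setNames(rep(12e6, 8), 1:8),
                           events = NULL,
                           effect = ExpressionEffect(),
                           nGenes = 400L,
                           armFraction = 0.4) {
  map <- simulateSnpMap(config, chromosomeLengths, armFraction)
  blood <- simulateGermline(map, config)
  if (is.null(events)) events <- defaultEventSpec(map, config)
  truth <- plantEvents(map, caseLabels(config@nCases), events)
  gt <- simulateTumorGenotypes(blood, truth, config)
  ratios <- simulateIntensities(truth, config)
  genes <- simulateGeneTable(config, chromosomeLengths, nGenes)
  expr <- simulateExpression(genes, truth, effect, config)
  truth$genes <- expr$genes
  list(config = config, map = map,
       genotypes = list(blood = blood, tumor = gt$tumor,
                        normal = gt$normal),
       ratios = ratios, genes = genes,
       expression = list(normal = expr$normal, tumor = expr$tumor),
       truth = truth)
}

#' Write a simulated cohort to the on-disk pipeline layout
#'
#' Emits snp_map.tsv, genotypes_blood/normal/tumor.tsv,
#' logratio_tumor/normal.tsv, genes.tsv, expression_normal/tumor.tsv,
#' truth_events.tsv and truth_genes.tsv into \code{dir}.
#'
#' @param cohort result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeSnpMap(cohort$map, p("snp_map.tsv"))
  writeMatrixTsv(cohort$genotypes$blood, p("genotypes_blood.tsv"))
  writeMatrixTsv(cohort$genotypes$normal, p("genotypes_normal.tsv"))
  writeMatrixTsv(cohort$genotypes$tumor, p("genotypes_tumor.tsv"))
  writeMatrixTsv(cohort$ratios$tumor, p("logratio_tumor.tsv"))
  writeMatrixTsv(cohort$ratios$normal, p("logratio_normal.tsv"))
  write.table(cohort$genes, p("genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeMatrixTsv(cohort$expression$normal, p("expression_normal.tsv"),
                 idCol = "probeset_id")
  writeMatrixTsv(cohort$expression$tumor, p("expression_tumor.tsv"),
                 idCol = "probeset_id")
  write.table(cohort$truth$events, p("truth_events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$truth$genes, p("truth_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
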