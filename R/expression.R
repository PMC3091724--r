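#' Per-pair log2 fold changes in expression
#'
#' log2 fold change = tumor log2 value minus matched adjacent-normal
#' log2 value, per probe set and case. Inputs must share probe-set
#' rows and case columns.
#'
#' @param exprNormal,exprTumor numeric log2 expression matrices
#'   (probe set x case).
#' @return numeric matrix of log2 fold changes, same shape.
#' @examples
#' foldChanges(matrix(5, 1, 1, dimnames = list("p", "c")),
#'             matrix(6, 1, 1, dimnames = list("p", "c")))
#' @export
foldChanges <- function(exprNormal, exprTumor) {
  if (!identical(dim(exprNormal), dim(exprTumor)) ||
      !identical(colnames(exprNormal), colnames(exprTumor)) ||
      !identical(rownames(exprNormal), rownames(exprTumor)))
    stop("normal and tumor expression matrices are not matched")
  exprTumor - exprNormal
}

geneGRanges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = paste0("chr", genes$chromosome),
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    probeset_id = genes$probeset_id)
}

#' Map gene regions onto six-state segments, per case
#'
#' A probe set in a case takes the (CN group, LOH) state of the unique
#' segment that fully contains its reference region. A gene straddling
#' a segment boundary, falling into a gap between segments, or lying
#' on a chromosome without segments has an undefined state (NA) for
#' that case and is excluded from both groups downstream.
#'
#' @param genes annotation data.frame ([readGeneTable()] layout).
#' @param segments segment table from [segmentStates()] (all cases).
#' @param caseIds cases to map; defaults to the cases present in
#'   \code{segments}.
#' @return long data.frame: case_id, probeset_id, cn_group (NA when
#'   undefined), loh (NA when undefined).
#' @export
mapGenes <- function(genes, segments, caseIds = NULL) {
  if (is.null(caseIds)) caseIds <- unique(segments$case_id)
  segments <- segments[segments$case_id %in% caseIds, , drop = FALSE]
  gr <- geneGRanges(genes)
  np <- nrow(genes)
  cnGrp <- matrix(NA_character_, np, length(caseIds),
                  dimnames = list(NULL, caseIds))
  lohSt <- matrix(NA, np, length(caseIds), dimnames = list(NULL, caseIds))
  if (nrow(segments)) {
    segGr <- GenomicRanges::GRanges(
      seqnames = paste0("chr", segments$chromosome),
      ranges = IRanges::IRanges(start = segments$start,
                                end = segments$end))
    ov <- GenomicRanges::findOverlaps(gr, segGr, type = "within")
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    ## segments of one case never overlap, so (gene, case) pairs with a
    ## containing segment are unique
    idx <- cbind(q, match(segments$case_id[s], caseIds))
    cnGrp[idx] <- segments$cn_group[s]
    lohSt[idx] <- segments$loh[s]
  }
  data.frame(
    case_id = rep(caseIds, each = np),
    probeset_id = rep(genes$probeset_id, length(caseIds)),
    cn_group = as.vector(cnGrp),
    loh = as.vector(lohSt),
    stringsAsFactors = FALSE)
}

#' Eligible probe sets for the LOH differential-expression test
#'
#' A probe set is testable in a CN class when at least \code{minGroup}
#' expression cases are LOH positive and at least \code{minGroup} are
#' LOH negative with the gene in that CN class; cases with an
#' undefined gene state count in neither group.
#'
#' @param states long data.frame from [mapGenes()].
#' @param cnClass "neutral", "loss" or "gain".
#' @param minGroup minimum cases per group (default 2).
#' @return data.frame: probeset_id, n_loh, n_noloh for eligible probe
#'   sets.
#' @export
eligibleProbesets <- function(states, cnClass = c("neutral", "loss", "gain"),
                              minGroup = 2L) {
  cnClass <- match.arg(cnClass)
  inClass <- !is.na(states$cn_group) & states$cn_group == cnClass
  nLoh <- tapply(inClass & states$loh, states$probeset_id, sum)
  nNo <- tapply(inClass & !states$loh, states$probeset_id, sum)
  keep <- !is.na(nLoh) & nLoh >= minGroup & nNo >= minGroup
  data.frame(probeset_id = names(nLoh)[keep],
             n_loh = as.integer(nLoh[keep]),
             n_noloh = as.integer(nNo[keep]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Count SNP-array loci within gene regions
#'
#' Number of SNP positions of the map falling inside each probe set's
#' reference region (inclusive). Probe sets of one gene with different
#' regions get independent counts.
#'
#' @param genes annotation data.frame.
#' @param map a [SnpMap-class].
#' @return integer vector, one count per row of \code{genes}.
#' @export
countSnpsInRegion <- function(genes, map) {
  GenomicRanges::countOverlaps(geneGRanges(genes), asGRanges(map))
}

#' Expected false positives at a significance threshold
#'
#' Integer part of n tests x alpha: how many of the tested probe sets
#' would be called significant by chance alone.
#'
#' @param nTested number of tests.
#' @param alpha significance level in (0,1).
#' @return integer.
#' @examples
#' expectedFalsePositives(4572, 0.01)
#' @export
expectedFalsePositives <- function(nTested, alpha) {
  stopifnot(nTested >= 0, alpha > 0, alpha < 1)
  as.integer(floor(nTested * alpha))
}

#' Two-fold expression-difference rule
#'
#' TRUE when the LOH group's tumor/normal fold change is at least
#' two-fold in either direction (>= 2 or <= 0.5).
#'
#' @param meanFcLoh linear tumor/normal fold change of the LOH group.
#' @return logical of the same length.
#' @export
twofoldFilter <- function(meanFcLoh) {
  meanFcLoh >= 2 | meanFcLoh <= 0.5
}

#' LOH-conditioned differential expression within one CN class
#'
#' For every eligible probe set, an unpaired two-sample t-test
#' (pooled-variance by default; Welch optional) compares the log2
#' fold changes of LOH-positive versus LOH-negative cases. The
#' reported t statistic is positive when the LOH group's fold change
#' is the lower one. Group fold changes are the anti-logged group
#' means (2^mean log2fc). Probe sets with zero pooled variance are
#' untestable: they get NA statistics and never count as significant.
#' Raw p-values at \code{alpha} define significance (no multiplicity
#' correction); a BH-adjusted column is attached for information only.
#'
#' @param fc log2 fold-change matrix from [foldChanges()].
#' @param states long gene-state table from [mapGenes()] (or any table
#'   with case_id, probeset_id, cn_group, loh).
#' @param cnClass CN class to test within: "neutral" tests CNNLOH.
#' @param genes optional annotation (adds gene_symbol).
#' @param map optional [SnpMap-class] (adds snp_count per probe set).
#' @param alpha raw significance level (default 0.01).
#' @param minGroup minimum cases per group (default 2).
#' @param varEqual pooled-variance t (TRUE, default) or Welch.
#' @return data.frame with one row per eligible probe set:
#'   probeset_id, gene_symbol, cn_class, n_loh, n_noloh, mean_fc_loh,
#'   mean_fc_noloh, t_statistic, p_value, direction, twofold,
#'   significant, untestable, snp_count, fdr.
#' @export
lohDifferentialExpression <- function(fc, states,
                                      cnClass = c("neutral", "loss", "gain"),
                                      genes = NULL, map = NULL,
                                      alpha = 0.01, minGroup = 2L,
                                      varEqual = TRUE) {
  cnClass <- match.arg(cnClass)
  elig <- eligibleProbesets(states, cnClass, minGroup)
  inClass <- !is.na(states$cn_group) & states$cn_group == cnClass
  statesClass <- states[inClass, , drop = FALSE]
  byPs <- split(seq_len(nrow(statesClass)), statesClass$probeset_id)
  res <- lapply(seq_len(nrow(elig)), function(i) {
    ps <- elig$probeset_id[i]
    rows <- statesClass[byPs[[ps]], ]
    x <- fc[ps, rows$case_id[rows$loh]]
    y <- fc[ps, rows$case_id[!rows$loh]]
    n1 <- length(x); n2 <- length(y)
    v1 <- stats::var(x); v2 <- stats::var(y)
    if (varEqual) {
      sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      dfree <- n1 + n2 - 2
    } else {
      se <- sqrt(v1 / n1 + v2 / n2)
      dfree <- (v1 / n1 + v2 / n2)^2 /
        ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    }
    untestable <- !is.finite(se) || se == 0
    tstat <- if (untestable) NA_real_ else (mean(y) - mean(x)) / se
    pval <- if (untestable) NA_real_ else 2 * pt(-abs(tstat), dfree)
    data.frame(
      probeset_id = ps,
      cn_class = cnClass,
      n_loh = n1, n_noloh = n2,
      mean_fc_loh = 2^mean(x),
      mean_fc_noloh = 2^mean(y),
      t_statistic = tstat,
      p_value = pval,
      direction = ifelse(mean(x) < mean(y), "lower_in_LOH",
                         "higher_in_LOH"),
      untestable = untestable,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(probeset_id = character(), cn_class = character(),
                      n_loh = integer(), n_noloh = integer(),
                      mean_fc_loh = numeric(), mean_fc_noloh = numeric(),
                      t_statistic = numeric(), p_value = numeric(),
                      direction = character(), untestable = logical(),
                      stringsAsFactors = FALSE)
  out$twofold <- twofoldFilter(out$mean_fc_loh)
  out$significant <- !out$untestable & !is.na(out$p_value) &
    out$p_value < alpha
  out$gene_symbol <- if (!is.null(genes))
    genes$gene_symbol[match(out$probeset_id, genes$probeset_id)]
  else NA_character_
  out$snp_count <- if (!is.null(genes) && !is.null(map)) {
    cnt <- countSnpsInRegion(genes, map)
    cnt[match(out$probeset_id, genes$probeset_id)]
  } else NA_integer_
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("probeset_id", "gene_symbol", "cn_class", "n_loh", "n_noloh",
          "mean_fc_loh", "mean_fc_noloh", "t_statistic", "p_value",
          "direction", "twofold", "significant", "untestable",
          "snp_count", "fdr")]
}
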