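#' Round half-up to a fixed number of decimals
#'
#' Display rounding used throughout the summary tables (base R's
#' \code{round} is round-half-even; the published tables use half-up).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

unroundedFractions <- function(rows) {
  tot <- rows$total
  f <- function(n) ifelse(tot == 0L, 0, n / tot)
  data.frame(loss = f(rows$n_loss), neutral = f(rows$n_neutral),
             gain = f(rows$n_gain))
}

addFractions <- function(rows) {
  fr <- unroundedFractions(rows)
  rows$frac_loss <- roundHalfUp(fr$loss)
  rows$frac_neutral <- roundHalfUp(fr$neutral)
  rows$frac_gain <- roundHalfUp(fr$gain)
  rows
}

countsByGroup <- function(track, lohPositive, by) {
  stopifnot(is(track, "SixStateTrack"))
  by <- match.arg(by, c("case", "arm"))
  prefix <- if (lohPositive) "LOH|" else "noLOH|"
  keep <- !is.na(track@state) & startsWith(track@state, prefix)
  grp <- sub("^.*\\|", "", track@state)
  if (by == "case") {
    units <- colnames(track@state)
    unitOf <- matrix(rep(units, each = nrow(track@state)),
                     nrow = nrow(track@state))
  } else {
    armLab <- paste0(track@map@chromosome, track@map@arm)
    units <- unique(armLab[order(track@map@chromosome, track@map@arm)])
    unitOf <- matrix(rep(armLab, ncol(track@state)),
                     nrow = nrow(track@state))
  }
  u <- factor(unitOf[keep], levels = units)
  g <- factor(grp[keep], levels = CN_GROUPS)
  tab <- table(u, g)
  rows <- data.frame(
    unit_id = units,
    total = as.integer(rowSums(tab)),
    n_loss = as.integer(tab[, "loss"]),
    n_neutral = as.integer(tab[, "neutral"]),
    n_gain = as.integer(tab[, "gain"]),
    stringsAsFactors = FALSE)
  stopifnot(all(rows$n_loss + rows$n_neutral + rows$n_gain == rows$total))
  addFractions(rows)
}

#' Tabulate LOH-positive SNPs by CN group, per case or per arm
#'
#' Counts defined LOH-positive SNPs in each unit (case, or chromosome
#' arm pooled over all cases) split by CN group, with display
#' fractions rounded half-up to two decimals. Row conservation
#' (loss + neutral + gain = total) is asserted on every output.
#'
#' @param track a [SixStateTrack-class] for the cohort.
#' @param by "case" (one row per case) or "arm" (pooled across cases,
#'   one row per chromosome arm present in the map).
#' @return data.frame: unit_id, total, n_loss, n_neutral, n_gain,
#'   frac_loss, frac_neutral, frac_gain.
#' @seealso [footerStats()], [percentCasesWithLoh()]
#' @export
tabulateLohByCn <- function(track, by = c("case", "arm")) {
  countsByGroup(track, lohPositive = TRUE, by = by)
}

#' Tabulate LOH-negative (retention) SNPs by CN group
#'
#' Same layout as [tabulateLohByCn()] but over defined LOH-negative
#' SNPs: the CN-state distribution outside LOH.
#'
#' @inheritParams tabulateLohByCn
#' @return data.frame as in [tabulateLohByCn()].
#' @export
tabulateNoLohCn <- function(track, by = c("case", "arm")) {
  countsByGroup(track, lohPositive = FALSE, by = by)
}

#' Footer statistics for a per-case or per-arm summary table
#'
#' For each CN group: the number of units whose displayed (half-up,
#' two-decimal) fraction is 0.00; the range and median of the
#' unrounded per-unit fractions (units with zero total contribute
#' fraction 0 unless excluded); and the global average, i.e. the
#' pooled count ratio sum(group counts) / sum(totals).
#'
#' @param rows table from [tabulateLohByCn()], [tabulateNoLohCn()] or
#'   [referenceCohortCounts()].
#' @param excludeZeroTotal drop zero-total units from range/median.
#' @return data.frame with one row per CN group: group,
#'   n_zero_fraction, min, max, median, global_average.
#' @examples
#' footerStats(referenceCohortCounts("case"))
#' @export
footerStats <- function(rows, excludeZeroTotal = FALSE) {
  stopifnot(nrow(rows) >= 1L)
  fr <- unroundedFractions(rows)
  if (excludeZeroTotal) fr <- fr[rows$total > 0L, , drop = FALSE]
  pooled <- colSums(rows[, c("n_loss", "n_neutral", "n_gain")]) /
    sum(rows$total)
  data.frame(
    group = CN_GROUPS,
    n_zero_fraction = vapply(fr, function(f)
      sum(roundHalfUp(f) == 0), 0L),
    min = vapply(fr, min, 0),
    max = vapply(fr, max, 0),
    median = vapply(fr, median, 0),
    global_average = as.numeric(pooled),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Percentage of cases showing LOH in a CN group
#'
#' 100 x (1 - zero-fraction units / all units), rounded half-up to a
#' whole percent. Under \code{"exact_zero"} a unit counts as zero when
#' its group count is exactly 0; under \code{"rounded_zero"} when its
#' fraction displays as 0.00.
#'
#' @param rows per-case table ([tabulateLohByCn()] layout).
#' @param group "loss", "neutral" or "gain".
#' @param zeroRule "exact_zero" or "rounded_zero".
#' @return whole-number percentage.
#' @examples
#' percentCasesWithLoh(referenceCohortCounts("case"), "neutral")
#' @export
percentCasesWithLoh <- function(rows, group = c("loss", "neutral", "gain"),
                                zeroRule = c("exact_zero", "rounded_zero")) {
  group <- match.arg(group)
  zeroRule <- match.arg(zeroRule)
  if (!nrow(rows)) stop("empty summary table")
  cnt <- rows[[paste0("n_", group)]]
  isZero <- if (zeroRule == "exact_zero") {
    cnt == 0L
  } else {
    roundHalfUp(unroundedFractions(rows)[[group]]) == 0
  }
  roundHalfUp(100 * (1 - sum(isZero) / nrow(rows)), 0L)
}

#' Copy-number call concordance between two tracks
#'
#' Used to compare blood-derived and adjacent-normal-derived CN calls:
#' the percentage of per-SNP state calls that are identical, and the
#' percentage of diploid (state 2) calls in each track.
#'
#' @param cnA,cnB [CnTrack-class] objects over the same map and cases.
#' @return data.frame with percent_identical, percent_neutral_a,
#'   percent_neutral_b.
#' @export
cnConcordance <- function(cnA, cnB) {
  stopifnot(is(cnA, "CnTrack"), is(cnB, "CnTrack"))
  if (!identical(dim(cnA@state), dim(cnB@state)) ||
      !identical(as.data.frame(cnA@map), as.data.frame(cnB@map)))
    stop("CN tracks are not aligned")
  data.frame(
    percent_identical = 100 * mean(cnA@state == cnB@state),
    percent_neutral_a = 100 * mean(cnA@state == 2L),
    percent_neutral_b = 100 * mean(cnB@state == 2L))
}
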