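## Copy-number calling: boxcar smoothing of intensity log2 ratios over
## a fixed base-pair window, then nearest-center classification onto
## the five CN states 0..4 (2 = diploid).

#' Default CN state centers
#'
#' Expected log2(c/2) for copy numbers 1..4 plus a floor of -3 for
#' state 0 (log2 of a true zero is undefined; -3 corresponds to ~12%
#' residual signal, a typical array floor for homozygous deletions).
#'
#' @return named numeric vector of length 5 (names "0".."4").
#' @export
defaultStateCenters <- function() {
  c("0" = -3, "1" = -1, "2" = 0, "3" = 0.585, "4" = 1)
}

#' Smooth per-SNP log2 ratios with a centered base-pair window
#'
#' Each SNP's value becomes the mean of the raw ratios of all SNPs
#' within +/- windowBp/2 of it on the same chromosome (the window
#' never crosses a chromosome boundary). A single SNP on a chromosome
#' keeps its raw value.
#'
#' @param ratios numeric vector or matrix (SNP x case) aligned to
#'   \code{map}.
#' @param map a [SnpMap-class].
#' @param windowBp full window width in base pairs (default 100 kb).
#' @return smoothed values, same shape as \code{ratios}.
#' @export
smoothRatios <- function(ratios, map, windowBp = 1e5) {
  vec <- !is.matrix(ratios)
  if (vec) ratios <- matrix(ratios, ncol = 1L)
  if (nrow(ratios) != length(map))
    stop("ratios are not aligned to the map")
  out <- ratios
  half <- windowBp / 2
  for (chr in unique(map@chromosome)) {
    sel <- which(map@chromosome == chr)
    pos <- map@position[sel]
    lo <- findInterval(pos - half, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + half, pos)
    cs <- apply(ratios[sel, , drop = FALSE], 2L, cumsum)
    cs <- rbind(0, matrix(cs, ncol = ncol(ratios)))
    out[sel, ] <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1L)
  }
  if (vec) out[, 1L] else out
}

#' Assign CN states by nearest state center
#'
#' Each smoothed value is assigned the state (0-4) whose center is
#' nearest; exact midpoint ties break toward the diploid state 2.
#'
#' @param smoothed numeric vector or matrix of smoothed log2 ratios.
#' @param stateCenters strictly increasing numeric vector of five
#'   centers (see [defaultStateCenters()]).
#' @return integer states, same shape as \code{smoothed}.
#' @examples
#' assignStates(c(0, -1.02, 0.8))
#' @export
assignStates <- function(smoothed, stateCenters = defaultStateCenters()) {
  if (length(stateCenters) != 5L || is.unsorted(stateCenters, strictly = TRUE))
    stop("stateCenters must be five strictly increasing values")
  if (any(!is.finite(smoothed))) {
    bad <- which(!is.finite(smoothed))
    stop("non-finite smoothed ratio at position(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  mid <- (stateCenters[-1L] + stateCenters[-5L]) / 2
  st <- findInterval(as.vector(smoothed), mid)
  ## exact midpoint: take whichever neighbouring state is closer to 2
  for (k in seq_along(mid)) {
    tie <- as.vector(smoothed) == mid[k]
    if (any(tie)) st[tie] <- if (abs(k - 2L) < abs(k - 1L - 2L)) k else k - 1L
  }
  st <- as.integer(st)
  if (is.matrix(smoothed)) {
    dim(st) <- dim(smoothed)
    dimnames(st) <- dimnames(smoothed)
  }
  st
}

#' Group a CN state as loss, neutral or gain
#'
#' States 0-1 are loss, 2 neutral, 3-4 gain.
#'
#' @param state integer vector/matrix of CN states.
#' @return character of the same shape: "loss"/"neutral"/"gain".
#' @export
cnGroup <- function(state) {
  out <- ifelse(state <= 1L, "loss", ifelse(state == 2L, "neutral", "gain"))
  if (is.matrix(state)) {
    dim(out) <- dim(state)
    dimnames(out) <- dimnames(state)
  }
  out
}

#' Call per-SNP copy-number states from raw log2 ratios
#'
#' Composition of [smoothRatios()] and [assignStates()].
#'
#' @param ratios numeric matrix (SNP x case) of raw log2 ratios.
#' @param map a [SnpMap-class].
#' @param windowBp full smoothing window in bp.
#' @param stateCenters five state centers.
#' @return a [CnTrack-class].
#' @export
callCn <- function(ratios, map, windowBp = 1e5,
                   stateCenters = defaultStateCenters()) {
  if (!is.matrix(ratios)) ratios <- matrix(ratios, ncol = 1L)
  sm <- smoothRatios(ratios, map, windowBp)
  st <- assignStates(sm, stateCenters)
  new("CnTrack", map = map, smoothed = sm, state = st)
}
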