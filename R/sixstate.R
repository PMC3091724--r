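#' Combine LOH and CN tracks into the six-state classification
#'
#' At every informative SNP with a defined LOH call, the state is the
#' cross of LOH status (positive/negative) and CN group
#' (loss/neutral/gain), giving six combinations; "LOH|neutral" is
#' CNNLOH. Uninformative SNPs and NoCalls have an undefined LOH/CN
#' state and carry NA.
#'
#' @param loh a [LohTrack-class].
#' @param cn a [CnTrack-class] over the same map and cases.
#' @return a [SixStateTrack-class].
#' @examples
#' map <- SnpMap(c("s1", "s2"), c(1, 1), c("p", "p"), c(100, 200))
#' loh <- callLoh(matrix(c("AB", "AA"), 2, dimnames = list(snpIds(map), "c1")),
#'                matrix(c("AA", "AA"), 2, dimnames = list(snpIds(map), "c1")),
#'                map)
#' cn <- callCn(matrix(0, 2, 1, dimnames = list(snpIds(map), "c1")), map)
#' sixState(combineStates(loh, cn))
#' @export
combineStates <- function(loh, cn) {
  stopifnot(is(loh, "LohTrack"), is(cn, "CnTrack"))
  if (!identical(as.data.frame(loh@map), as.data.frame(cn@map)) ||
      !identical(dim(loh@status), dim(cn@state)))
    stop("LOH and CN tracks are not aligned")
  defined <- loh@status != "UNDEFINED"
  state <- matrix(NA_character_, nrow(loh@status), ncol(loh@status),
                  dimnames = dimnames(loh@status))
  state[defined] <- paste0(
    ifelse(loh@status[defined] == "LOH", "LOH", "noLOH"),
    "|", cnGroup(cn@state[defined]))
  new("SixStateTrack", map = loh@map, state = state)
}

#' Build contiguous six-state segments over informative SNPs
#'
#' A segment is a maximal run of consecutive defined (informative,
#' LOH-called) SNPs on one chromosome sharing the same six-state
#' label; its endpoints are the positions of the run's first and last
#' informative SNP. Undefined SNPs lying between two same-state
#' defined SNPs are interstitial and by default do not break a run
#' (set \code{breakOnUndefined = TRUE} for the stricter reading where
#' any undefined SNP splits segments).
#'
#' @param track a [SixStateTrack-class].
#' @param minSnps drop segments with fewer informative SNPs.
#' @param breakOnUndefined should undefined SNPs split runs?
#' @return data.frame with columns case_id, chromosome, start, end,
#'   state, loh, cn_group, n_informative_snps.
#' @export
segmentStates <- function(track, minSnps = 1L, breakOnUndefined = FALSE) {
  stopifnot(is(track, "SixStateTrack"))
  map <- track@map
  segs <- lapply(colnames(track@state), function(cs) {
    st <- track@state[, cs]
    idx <- which(!is.na(st))
    if (!length(idx)) return(NULL)
    chrom <- map@chromosome[idx]
    val <- st[idx]
    newSeg <- c(TRUE, val[-1L] != val[-length(val)] |
                  chrom[-1L] != chrom[-length(chrom)])
    if (breakOnUndefined && length(idx) > 1L)
      newSeg <- newSeg | c(TRUE, diff(idx) > 1L)
    segId <- cumsum(newSeg)
    first <- idx[!duplicated(segId)]
    last <- idx[!duplicated(segId, fromLast = TRUE)]
    data.frame(
      case_id = cs,
      chromosome = map@chromosome[first],
      start = map@position[first],
      end = map@position[last],
      state = val[!duplicated(segId)],
      n_informative_snps = as.integer(tabulate(segId)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  if (is.null(out))
    out <- data.frame(case_id = character(), chromosome = integer(),
                      start = integer(), end = integer(),
                      state = character(),
                      n_informative_snps = integer(),
                      stringsAsFactors = FALSE)
  parts <- strsplit(out$state, "|", fixed = TRUE)
  out$loh <- vapply(parts, `[`, "", 1L) == "LOH"
  out$cn_group <- vapply(parts, `[`, "", 2L)
  out <- out[out$n_informative_snps >= minSnps, ]
  rownames(out) <- NULL
  out[, c("case_id", "chromosome", "start", "end", "state", "loh",
          "cn_group", "n_informative_snps")]
}
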