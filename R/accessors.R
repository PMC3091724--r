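#' @name accessors
#' @title Accessors for cnnloh data classes
#'
#' @description Slot access for [SnpMap-class], [LohTrack-class],
#' [CnTrack-class], [SixStateTrack-class] and [SimConfig-class] objects.
#' \code{snpMap()} returns the coordinate system a track is aligned to;
#' \code{lohStatus()}, \code{cnState()}, \code{smoothedRatios()},
#' \code{sixState()} and \code{informativeMask()} return the SNP x case
#' matrices; \code{caseIds()} returns the case columns.
#'
#' @param x an object of one of the classes above.
#' @return The slot contents (vector or matrix); see Description.
NULL

#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))
#' @rdname accessors
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))
#' @rdname accessors
#' @export
setGeneric("caseIds", function(x) standardGeneric("caseIds"))
#' @rdname accessors
#' @export
setGeneric("lohStatus", function(x) standardGeneric("lohStatus"))
#' @rdname accessors
#' @export
setGeneric("informativeMask", function(x) standardGeneric("informativeMask"))
#' @rdname accessors
#' @export
setGeneric("cnState", function(x) standardGeneric("cnState"))
#' @rdname accessors
#' @export
setGeneric("smoothedRatios", function(x) standardGeneric("smoothedRatios"))
#' @rdname accessors
#' @export
setGeneric("sixState", function(x) standardGeneric("sixState"))
#' @rdname accessors
#' @export
setGeneric("heterozygosity", function(x) standardGeneric("heterozygosity"))

#' @rdname accessors
#' @export
setMethod("snpIds", "SnpMap", function(x) x@snpId)
#' @rdname accessors
#' @export
setMethod("snpMap", "LohTrack", function(x) x@map)
#' @rdname accessors
#' @export
setMethod("snpMap", "CnTrack", function(x) x@map)
#' @rdname accessors
#' @export
setMethod("snpMap", "SixStateTrack", function(x) x@map)
#' @rdname accessors
#' @export
setMethod("caseIds", "LohTrack", function(x) colnames(x@status))
#' @rdname accessors
#' @export
setMethod("caseIds", "CnTrack", function(x) colnames(x@state))
#' @rdname accessors
#' @export
setMethod("caseIds", "SixStateTrack", function(x) colnames(x@state))
#' @rdname accessors
#' @export
setMethod("lohStatus", "LohTrack", function(x) x@status)
#' @rdname accessors
#' @export
setMethod("informativeMask", "LohTrack", function(x) x@informative)
#' @rdname accessors
#' @export
setMethod("cnState", "CnTrack", function(x) x@state)
#' @rdname accessors
#' @export
setMethod("smoothedRatios", "CnTrack", function(x) x@smoothed)
#' @rdname accessors
#' @export
setMethod("sixState", "SixStateTrack", function(x) x@state)
#' @rdname accessors
#' @export
setMethod("heterozygosity", "SimConfig", function(x) x@heterozygosity)

#' @rdname accessors
#' @export
setMethod("length", "SnpMap", function(x) length(x@snpId))

#' Coerce a SnpMap to a data.frame
#'
#' @param x a [SnpMap-class].
#' @param ... ignored.
#' @return data.frame with columns snp_id, chromosome, arm, position.
#' @export
setMethod("as.data.frame", "SnpMap", function(x, ...) {
  data.frame(snp_id = x@snpId, chromosome = x@chromosome,
             arm = x@arm, position = x@position,
             stringsAsFactors = FALSE)
})

#' Coerce a SnpMap to a GRanges of SNP positions
#'
#' Chromosomes are rendered as "chr1".."chr22"; each SNP is a width-1
#' range carrying snp_id and arm metadata.
#'
#' @param x a [SnpMap-class].
#' @return a [GenomicRanges::GRanges-class].
#' @export
asGRanges <- function(x) {
  stopifnot(is(x, "SnpMap"))
  GenomicRanges::GRanges(
    seqnames = paste0("chr", x@chromosome),
    ranges = IRanges::IRanges(start = x@position, width = 1L),
    snp_id = x@snpId, arm = x@arm)
}

setMethod("show", "SnpMap", function(object) {
  cat(sprintf("SnpMap with %d SNPs on %d chromosome(s)\n",
              length(object), length(unique(object@chromosome))))
  if (length(object)) {
    cat(sprintf("  chromosomes: %s\n",
                paste(sort(unique(object@chromosome)), collapse = ", ")))
    cat(sprintf("  first: %s (chr%d%s:%d)\n", object@snpId[1],
                object@chromosome[1], object@arm[1], object@position[1]))
  }
})

setMethod("show", "LohTrack", function(object) {
  cat(sprintf("LohTrack: %d SNPs x %d case(s)\n",
              nrow(object@status), ncol(object@status)))
  tab <- table(factor(object@status, levels = LOH_LEVELS))
  cat(sprintf("  LOH: %d  RETENTION: %d  UNDEFINED: %d\n",
              tab["LOH"], tab["RETENTION"], tab["UNDEFINED"]))
})

setMethod("show", "CnTrack", function(object) {
  cat(sprintf("CnTrack: %d SNPs x %d case(s)\n",
              nrow(object@state), ncol(object@state)))
  tab <- table(factor(object@state, levels = 0:4))
  cat("  state counts:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = " "), "\n")
})

setMethod("show", "SixStateTrack", function(object) {
  cat(sprintf("SixStateTrack: %d SNPs x %d case(s), %d defined calls\n",
              nrow(object@state), ncol(object@state),
              sum(!is.na(object@state))))
  tab <- table(factor(object@state, levels = SIX_STATES))
  for (s in SIX_STATES) cat(sprintf("  %-13s %d\n", s, tab[s]))
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:\n")
  cat(sprintf("  cases: %d (%d with expression pairs)\n",
              object@nCases, object@nExpressionPairs))
  cat(sprintf("  heterozygosity: %.2f  call rate: %.2f\n",
              object@heterozygosity, object@callRate))
  cat(sprintf("  SNP spacing: %d bp  intensity noise sd: %.3f  seed: %d\n",
              object@snpSpacingBp, object@intensityNoiseSd, object@seed))
})
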