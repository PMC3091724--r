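#' @import methods
#' @importFrom stats rnorm runif median pt setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

## Call alphabet used throughout; "NC" is the NoCall token in genotype files.
GENOTYPE_LEVELS <- c("AA", "AB", "BB", "NC")
LOH_LEVELS <- c("LOH", "RETENTION", "UNDEFINED")
CN_GROUPS <- c("loss", "neutral", "gain")

#' Ordered autosomal SNP map
#'
#' Holds the SNP coordinate system shared by every track in the package:
#' SNP identifiers, autosome (1-22), chromosome arm (p/q) and 1-based
#' base-pair position. Loci are stored sorted by (chromosome, position);
#' X/Y loci are rejected so that zygosity-based LOH calls are not
#' confounded by sex chromosomes.
#'
#' @slot snpId character vector of unique SNP identifiers.
#' @slot chromosome integer vector, values in 1:22.
#' @slot arm character vector, "p" or "q".
#' @slot position integer vector of 1-based positions, strictly
#'   increasing within a chromosome; all p-arm positions precede all
#'   q-arm positions.
#'
#' @seealso [SnpMap()], [readSnpMap()], [simulateSnpMap()]
#' @export
setClass("SnpMap",
  representation(
    snpId = "character",
    chromosome = "integer",
    arm = "character",
    position = "integer"
  )
)

setValidity("SnpMap", function(object) {
  n <- length(object@snpId)
  if (length(object@chromosome) != n || length(object@arm) != n ||
      length(object@position) != n)
    return("slot lengths differ")
  if (anyDuplicated(object@snpId))
    return("duplicate SNP identifiers")
  if (n == 0L) return(TRUE)
  if (!all(object@chromosome %in% 1:22))
    return("chromosomes must be autosomes 1-22 (X/Y are excluded)")
  if (!all(object@arm %in% c("p", "q")))
    return("arm must be 'p' or 'q'")
  if (any(object@position < 0L))
    return("positions must be non-negative")
  if (is.unsorted(order(object@chromosome, object@position), strictly = FALSE) ||
      any(diff(object@position)[diff(object@chromosome) == 0L] <= 0L))
    return("positions must be strictly increasing within each chromosome")
  for (chr in unique(object@chromosome)) {
    sel <- object@chromosome == chr
    a <- object@arm[sel]; p <- object@position[sel]
    if (any(a == "p") && any(a == "q") &&
        max(p[a == "p"]) >= min(p[a == "q"]))
      return(sprintf("chromosome %d: p-arm positions must all precede q-arm positions", chr))
  }
  TRUE
})

#' Per-SNP LOH track for a cohort
#'
#' Result of comparing each target (tumor or adjacent-normal) genotype
#' column against the matched blood reference. A SNP is informative in a
#' case when the blood call is heterozygous (AB); only there can LOH or
#' retention be observed. Everywhere else the status is UNDEFINED.
#'
#' @slot map the [SnpMap-class] the track is aligned to.
#' @slot status character matrix (SNP x case) with values "LOH",
#'   "RETENTION" or "UNDEFINED".
#' @slot informative logical matrix (SNP x case): blood call was AB.
#' @slot discordantHom integer vector per case: count of loci where blood
#'   and target carry opposite homozygous calls (a genotyping-error
#'   signature; such loci stay UNDEFINED and are only surfaced here).
#' @seealso [callLoh()]
#' @export
setClass("LohTrack",
  representation(
    map = "SnpMap",
    status = "matrix",
    informative = "matrix",
    discordantHom = "integer"
  )
)

setValidity("LohTrack", function(object) {
  if (nrow(object@status) != length(object@map))
    return("status rows must match map length")
  if (!identical(dim(object@status), dim(object@informative)))
    return("status and informative dimensions differ")
  if (!all(object@status %in% LOH_LEVELS))
    return("status values must be LOH/RETENTION/UNDEFINED")
  if (any(object@status != "UNDEFINED" & !object@informative))
    return("LOH/RETENTION may only occur at informative SNPs")
  TRUE
})

#' Per-SNP copy-number track for a cohort
#'
#' Window-smoothed intensity log2 ratios and the five-level CN state
#' (0-4) assigned to each SNP: 2 is diploid/neutral, 0-1 loss, 3-4 gain.
#'
#' @slot map the [SnpMap-class] the track is aligned to.
#' @slot smoothed numeric matrix (SNP x case) of smoothed log2 ratios.
#' @slot state integer matrix (SNP x case), values 0-4.
#' @seealso [callCn()], [smoothRatios()], [assignStates()]
#' @export
setClass("CnTrack",
  representation(
    map = "SnpMap",
    smoothed = "matrix",
    state = "matrix"
  )
)

setValidity("CnTrack", function(object) {
  if (nrow(object@state) != length(object@map))
    return("state rows must match map length")
  if (!identical(dim(object@state), dim(object@smoothed)))
    return("smoothed and state dimensions differ")
  if (!all(object@state %in% 0:4))
    return("CN states must lie in 0..4")
  TRUE
})

#' Combined six-state LOH-by-CN track
#'
#' The cross of LOH status (positive/negative) with CN group
#' (loss/neutral/gain) at every informative SNP with a defined LOH call.
#' Uninformative or uncalled SNPs carry NA ("undefined LOH/CN state").
#' States are encoded "LOH|neutral", "noLOH|gain", etc.; "LOH|neutral"
#' is copy-number-neutral LOH (CNNLOH).
#'
#' @slot map the [SnpMap-class] the track is aligned to.
#' @slot state character matrix (SNP x case); NA where undefined.
#' @seealso [combineStates()], [segmentStates()]
#' @export
setClass("SixStateTrack",
  representation(
    map = "SnpMap",
    state = "matrix"
  )
)

SIX_STATES <- as.vector(outer(c("LOH", "noLOH"), CN_GROUPS, paste, sep = "|"))

setValidity("SixStateTrack", function(object) {
  if (nrow(object@state) != length(object@map))
    return("state rows must match map length")
  ok <- is.na(object@state) | object@state %in% SIX_STATES
  if (!all(ok))
    return("states must be one of the six LOH|CN combinations or NA")
  TRUE
})

#' Simulation configuration for a synthetic trio cohort
#'
#' Defaults emulate a 500K-style SNP-array study design: 30 trio cases,
#' 17 of which carry paired expression profiles, mean heterozygosity
#' 27%, genotype call rate 96%, mean probe spacing 5.8 kb, and per-SNP
#' intensity log2-ratio noise of 0.15 sd.
#'
#' @slot nCases integer, number of trio cases.
#' @slot nExpressionPairs integer, cases with paired expression data
#'   (must not exceed \code{nCases}).
#' @slot heterozygosity numeric in (0,1): germline AB probability.
#' @slot callRate numeric in (0,1): probability a genotype is called.
#' @slot snpSpacingBp integer, mean distance between adjacent SNPs.
#' @slot intensityNoiseSd numeric > 0, per-SNP log2-ratio noise sd.
#' @slot seed integer root seed; every stage derives its own stream
#'   from it, so equal seeds give byte-identical cohorts.
#' @seealso [SimConfig()], [simulateCohort()]
#' @export
setClass("SimConfig",
  representation(
    nCases = "integer",
    nExpressionPairs = "integer",
    heterozygosity = "numeric",
    callRate = "numeric",
    snpSpacingBp = "integer",
    intensityNoiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  if (object@nCases < 1L) return("nCases must be >= 1")
  if (object@nExpressionPairs > object@nCases)
    return("nExpressionPairs must not exceed nCases")
  if (object@heterozygosity < 0 || object@heterozygosity >= 1)
    return("heterozygosity must lie in [0,1)")
  if (object@callRate <= 0 || object@callRate > 1)
    return("callRate must lie in (0,1]")
  if (object@snpSpacingBp < 1L) return("snpSpacingBp must be positive")
  if (object@intensityNoiseSd <= 0) return("intensityNoiseSd must be positive")
  TRUE
})

#' @describeIn SimConfig-class Constructor with study-design defaults.
#' @param nCases,nExpressionPairs,heterozygosity,callRate,snpSpacingBp,intensityNoiseSd,seed
#'   see the corresponding slots.
#' @return A \code{SimConfig} object.
#' @examples
#' cfg <- SimConfig(seed = 7)
#' heterozygosity(cfg)
#' @export
SimConfig <- function(nCases = 30L, nExpressionPairs = 17L,
                      heterozygosity = 0.27, callRate = 0.96,
                      snpSpacingBp = 5800L, intensityNoiseSd = 0.15,
                      seed = 1L) {
  new("SimConfig",
    nCases = as.integer(nCases),
    nExpressionPairs = as.integer(nExpressionPairs),
    heterozygosity = as.numeric(heterozygosity),
    callRate = as.numeric(callRate),
    snpSpacingBp = as.integer(snpSpacingBp),
    intensityNoiseSd = as.numeric(intensityNoiseSd),
    seed = as.integer(seed))
}
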