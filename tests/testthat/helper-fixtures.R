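## Shared fixture builders. Everything is generated in code; expensive
## cohorts are memoised so several test files can reuse one simulation.

.fixtureCache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- force(expr)
  .fixtureCache[[key]]
}

## Evenly spaced single-chromosome map.
evenMap <- function(n, spacing = 5800L, chromosome = 1L,
                    armBoundary = NULL) {
  pos <- spacing * seq_len(n)
  if (is.null(armBoundary)) armBoundary <- max(pos) * 0.4
  SnpMap(sprintf("s%04d", seq_len(n)), rep(chromosome, n),
         ifelse(pos < armBoundary, "p", "q"), pos)
}

## SixStateTrack built directly from a per-SNP state vector/matrix
## (NA = undefined), bypassing the callers.
trackFromStates <- function(states, map, caseIds = NULL) {
  if (!is.matrix(states)) states <- matrix(states, ncol = 1L)
  if (is.null(colnames(states)))
    colnames(states) <- if (is.null(caseIds))
      sprintf("case%02d", seq_len(ncol(states))) else caseIds
  rownames(states) <- snpIds(map)
  new("SixStateTrack", map = map, state = states)
}

## Default full-size cohort (30 cases) and its called tracks; used by
## the recovery, concordance and acceptance tests.
defaultRun <- function(seed = 20240501L) {
  memo(paste0("run", seed), {
    cfg <- SimConfig(seed = seed)
    cohort <- simulateCohort(cfg)
    loh <- callLoh(cohort$genotypes$blood, cohort$genotypes$tumor,
                   cohort$map)
    cn <- callCn(cohort$ratios$tumor, cohort$map)
    six <- combineStates(loh, cn)
    list(config = cfg, cohort = cohort, loh = loh, cn = cn, six = six,
         segments = segmentStates(six))
  })
}

## Per-SNP true six-state labels for the SNPs inside one planted event.
truthStateOf <- function(event) {
  grp <- c("loss", "loss", "neutral", "gain", "gain")[event$cn + 1L]
  paste0(ifelse(event$loh, "LOH", "noLOH"), "|", grp)
}

## Recovery and boundary statistics of called six-states against the
## planted truth, over events with at least minInf defined informative
## SNPs. Returns per-event data.frame plus SNP-level totals.
recoveryStats <- function(run, minInf = 20L) {
  map <- run$cohort$map
  six <- sixState(run$six)
  ev <- run$cohort$truth$events
  perEvent <- lapply(seq_len(nrow(ev)), function(i) {
    e <- ev[i, ]
    inside <- map@chromosome == e$chromosome &
      map@position >= e$start & map@position <= e$end
    st <- six[, e$case_id]
    defined <- !is.na(st)
    snps <- which(inside & defined)
    if (length(snps) < minInf) return(NULL)
    want <- truthStateOf(e)
    ## boundary error in defined-SNP units: offset between the truth
    ## run edges and the best matching called segment's edges
    defIdx <- which(defined)
    segs <- run$segments
    segs <- segs[segs$case_id == e$case_id &
                   segs$chromosome == e$chromosome &
                   segs$state == want &
                   segs$start <= e$end & segs$end >= e$start, ,
                 drop = FALSE]
    if (nrow(segs)) {
      ovl <- pmin(segs$end, e$end) - pmax(segs$start, e$start)
      best <- segs[which.max(ovl), ]
      startErr <- abs(match(snps[1L], defIdx) -
                        match(which(map@position == best$start &
                                      map@chromosome == e$chromosome),
                              defIdx))
      endErr <- abs(match(snps[length(snps)], defIdx) -
                      match(which(map@position == best$end &
                                    map@chromosome == e$chromosome),
                            defIdx))
      bErr <- max(startErr, endErr)
    } else bErr <- Inf
    data.frame(nSnps = length(snps),
               nCorrect = sum(st[snps] == want),
               boundaryErr = bErr)
  })
  perEvent <- do.call(rbind, perEvent)
  list(events = perEvent,
       snpRecovery = sum(perEvent$nCorrect) / sum(perEvent$nSnps),
       boundaryWithin2 = mean(perEvent$boundaryErr <= 2))
}

## Naive one-SNP-at-a-time LOH reference caller (test oracle).
naiveLohCall <- function(bloodCall, targetCall) {
  if (bloodCall != "AB") return("UNDEFINED")
  switch(targetCall,
         AA = "LOH", BB = "LOH", AB = "RETENTION", NC = "UNDEFINED")
}
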