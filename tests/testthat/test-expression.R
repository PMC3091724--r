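test_that("fold changes are tumor minus normal on the log2 scale", {
  n <- matrix(c(5, 7), 2, 1, dimnames = list(c("a", "b"), "c1"))
  t <- matrix(c(6, 6), 2, 1, dimnames = list(c("a", "b"), "c1"))
  fc <- foldChanges(n, t)
  expect_equal(unname(fc[, 1]), c(1, -1))
  expect_equal(2^fc["a", 1], 2)    # linear fold 2
  expect_equal(2^fc["b", 1], 0.5)  # linear fold 0.5
  expect_equal(foldChanges(n, n), n * 0)
  colnames(t) <- "c2"
  expect_error(foldChanges(n, t), "matched")
})

test_that("genes take the state of the unique containing segment", {
  genes <- data.frame(
    probeset_id = c("in_at", "straddle_at", "nowhere_at"),
    gene_symbol = c("G1", "G2", "G3"),
    chromosome = c(1L, 1L, 9L),
    start = c(1200L, 4500L, 100L),
    end = c(3800L, 6500L, 900L), stringsAsFactors = FALSE)
  segs <- data.frame(
    case_id = "c1", chromosome = 1L,
    start = c(1000L, 5000L), end = c(4999L, 9000L),
    state = c("LOH|neutral", "noLOH|neutral"),
    loh = c(TRUE, FALSE), cn_group = c("neutral", "neutral"),
    n_informative_snps = c(10L, 10L), stringsAsFactors = FALSE)
  st <- mapGenes(genes, segs)
  expect_identical(st$cn_group[st$probeset_id == "in_at"], "neutral")
  expect_true(st$loh[st$probeset_id == "in_at"])
  expect_true(is.na(st$cn_group[st$probeset_id == "straddle_at"]))
  expect_true(is.na(st$cn_group[st$probeset_id == "nowhere_at"]))

  ## a case with no segments at all is all-undefined
  st2 <- mapGenes(genes, segs, caseIds = c("c1", "c2"))
  expect_true(all(is.na(st2$cn_group[st2$case_id == "c2"])))
})

test_that("eligibility needs >= 2 LOH and >= 2 non-LOH cases in the class", {
  mkStates <- function(nLoh, nNo, cls = "neutral", ps = "p_at") {
    k <- nLoh + nNo
    data.frame(case_id = sprintf("c%02d", seq_len(k)), probeset_id = ps,
               cn_group = cls, loh = rep(c(TRUE, FALSE), c(nLoh, nNo)),
               stringsAsFactors = FALSE)
  }
  expect_identical(eligibleProbesets(mkStates(2, 13), "neutral")$n_noloh, 13L)
  expect_identical(nrow(eligibleProbesets(mkStates(1, 16), "neutral")), 0L)
  ## eligible in neutral but not in gain
  st <- mkStates(3, 3)
  expect_identical(nrow(eligibleProbesets(st, "gain")), 0L)
  expect_identical(nrow(eligibleProbesets(st, "neutral")), 1L)
  ## undefined cases are excluded from both groups
  st$cn_group[1:2] <- NA
  expect_identical(nrow(eligibleProbesets(st, "neutral")), 0L)
})

test_that("the pooled t-test matches stats::t.test and flags zero variance", {
  set.seed(101)
  cases <- sprintf("c%02d", 1:10)
  states <- data.frame(case_id = cases, probeset_id = "p_at",
                       cn_group = "neutral",
                       loh = rep(c(TRUE, FALSE), c(4, 6)),
                       stringsAsFactors = FALSE)
  for (rep in 1:10) {
    fc <- matrix(rnorm(10), 1, dimnames = list("p_at", cases))
    res <- lohDifferentialExpression(fc, states, "neutral")
    oracle <- t.test(fc[1, 5:10], fc[1, 1:4], var.equal = TRUE)
    expect_equal(res$t_statistic, unname(oracle$statistic))
    expect_equal(res$p_value, oracle$p.value)
    expect_equal(res$mean_fc_loh, 2^mean(fc[1, 1:4]))
    expect_identical(res$direction,
                     ifelse(mean(fc[1, 1:4]) < mean(fc[1, 5:10]),
                            "lower_in_LOH", "higher_in_LOH"))
  }

  ## strong depletion in the LOH group: tiny p, positive t, lower_in_LOH
  fc <- matrix(c(-2, -2, 0, 0, 0) + rnorm(5, sd = 0.01), 1,
               dimnames = list("p_at", sprintf("c%02d", 1:5)))
  st5 <- data.frame(case_id = sprintf("c%02d", 1:5), probeset_id = "p_at",
                    cn_group = "neutral", loh = c(TRUE, TRUE, FALSE,
                                                  FALSE, FALSE))
  res <- lohDifferentialExpression(fc, st5, "neutral")
  expect_lt(res$p_value, 1e-6)
  expect_gt(res$t_statistic, 0)
  expect_identical(res$direction, "lower_in_LOH")

  ## zero pooled variance is untestable, never significant
  fcZ <- matrix(1, 1, 5, dimnames = dimnames(fc))
  resZ <- lohDifferentialExpression(fcZ, st5, "neutral")
  expect_true(resZ$untestable)
  expect_true(is.na(resZ$p_value))
  expect_false(resZ$significant)
})

test_that("direction and two-fold calls agree with a brute-force pass", {
  set.seed(113)
  cases <- sprintf("c%02d", 1:17)
  nPs <- 60
  ps <- sprintf("bf%02d_at", 1:nPs)
  fc <- matrix(rnorm(nPs * 17, sd = 1.2), nPs,
               dimnames = list(ps, cases))
  states <- do.call(rbind, lapply(ps, function(p) {
    nL <- sample(2:6, 1)
    data.frame(case_id = cases, probeset_id = p, cn_group = "neutral",
               loh = seq_along(cases) <= nL, stringsAsFactors = FALSE)
  }))
  res <- lohDifferentialExpression(fc, states, "neutral")
  for (i in seq_len(nrow(res))) {
    p <- res$probeset_id[i]
    lohCases <- states$case_id[states$probeset_id == p & states$loh]
    noCases <- states$case_id[states$probeset_id == p & !states$loh]
    mL <- mean(fc[p, lohCases]); mN <- mean(fc[p, noCases])
    expect_identical(res$direction[i],
                     if (mL < mN) "lower_in_LOH" else "higher_in_LOH")
    expect_identical(res$twofold[i], 2^mL >= 2 || 2^mL <= 0.5)
  }
})

test_that("the two-fold rule is on the LOH group's fold change", {
  expect_true(twofoldFilter(0.404))
  expect_true(twofoldFilter(2.208))
  expect_false(twofoldFilter(0.51))
  expect_false(twofoldFilter(1.9))
})

test_that("expected false positives is the integer part of n x alpha", {
  expect_identical(expectedFalsePositives(4572, 0.01), 45L)
  expect_identical(expectedFalsePositives(100, 0.05), 5L)
  expect_identical(expectedFalsePositives(0, 0.01), 0L)
})

test_that("SNP counting per probe-set region is independent per probe set", {
  map <- SnpMap(c("a", "b", "c"), c(1, 1, 1), c("p", "p", "p"),
                c(100, 200, 300))
  genes <- data.frame(probeset_id = c("x_at", "x_s_at", "y_at"),
                      gene_symbol = c("G", "G", "H"),
                      chromosome = 1L,
                      start = c(50L, 150L, 400L),
                      end = c(250L, 350L, 500L), stringsAsFactors = FALSE)
  expect_identical(countSnpsInRegion(genes, map), c(2L, 2L, 0L))
  genes2 <- genes; genes2$end[2] <- 250L
  expect_identical(countSnpsInRegion(genes2, map), c(2L, 1L, 0L))
})

test_that("null fold changes yield the binomial false-positive count", {
  null <- simulateNullExpression(nProbesets = 4572L, seed = 77)
  res <- lohDifferentialExpression(null$fc, null$states, "neutral")
  expect_identical(nrow(res), 4572L)
  nSig <- sum(res$significant)
  bounds <- qbinom(c(0.005, 0.995), 4572L, 0.01)
  expect_gte(nSig, bounds[1])
  expect_lte(nSig, bounds[2])
})

test_that("a planted 2-fold effect is recovered with >= 90% power", {
  set.seed(131)
  cases <- sprintf("c%02d", 1:17)
  nPs <- 200
  ps <- sprintf("pw%03d_at", 1:nPs)
  sign <- ifelse(runif(nPs) < 0.5, -1, 1)
  fc <- matrix(rnorm(nPs * 17, sd = 0.3), nPs,
               dimnames = list(ps, cases))
  fc[, 1:3] <- fc[, 1:3] + sign * 2     # effect in the 3 LOH cases
  states <- do.call(rbind, lapply(ps, function(p)
    data.frame(case_id = cases, probeset_id = p, cn_group = "neutral",
               loh = seq_along(cases) <= 3, stringsAsFactors = FALSE)))
  res <- lohDifferentialExpression(fc, states, "neutral")
  hit <- res$significant &
    res$direction == ifelse(sign[match(res$probeset_id, ps)] < 0,
                            "lower_in_LOH", "higher_in_LOH")
  expect_gte(mean(hit), 0.90)
})

test_that("probe sets sharing a gene symbol are tested independently end to end", {
  run <- defaultRun()
  cohort <- run$cohort
  fc <- foldChanges(cohort$expression$normal, cohort$expression$tumor)
  states <- mapGenes(cohort$genes, run$segments,
                     caseIds = colnames(fc))
  res <- lohDifferentialExpression(fc, states, "neutral",
                                   genes = cohort$genes, map = cohort$map)
  expect_identical(anyDuplicated(res$probeset_id), 0L)
  ## planted CNNLOH expression effects are recovered through the full
  ## genomic pipeline (genotypes -> segments -> mapping -> t-test)
  tg <- cohort$truth$genes
  m <- merge(res, tg, by = "probeset_id")
  aff <- m[m$affected, ]
  expect_gte(nrow(aff), 3L)
  expect_true(all(aff$significant))
  expect_identical(aff$direction,
                   ifelse(aff$sign < 0, "lower_in_LOH", "higher_in_LOH"))
})
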