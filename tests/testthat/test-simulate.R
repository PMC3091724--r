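test_that("simulated SNP maps hit the spacing target and are deterministic", {
  cfg <- SimConfig(seed = 11)
  map <- simulateSnpMap(cfg, c("1" = 58000))
  expect_true(abs(length(map) - 10L) <= 1L)
  expect_true(all(diff(map@position) > 0))

  map2 <- simulateSnpMap(cfg, c("1" = 58000))
  expect_identical(as.data.frame(map), as.data.frame(map2))

  tiny <- simulateSnpMap(cfg, c("1" = 1000))  # spacing > chromosome
  expect_gte(length(tiny), 1L)

  expect_error(simulateSnpMap(cfg, c("1" = 0)), "positive")
})

test_that("germline calls match the configured heterozygosity and call rate", {
  cfg <- SimConfig(nCases = 1L, nExpressionPairs = 1L, seed = 5)
  map <- simulateSnpMap(cfg, c("1" = 5800 * 10000))
  g <- simulateGermline(map, cfg)
  called <- g != "NC"
  expect_equal(mean(g[called] == "AB"), 0.27, tolerance = 0.02 / 0.27)
  expect_equal(mean(called), 0.96, tolerance = 0.01)

  cfgAll <- SimConfig(nCases = 1L, nExpressionPairs = 1L, callRate = 1,
                      seed = 5)
  expect_false(any(simulateGermline(map, cfgAll) == "NC"))

  cfgHom <- SimConfig(nCases = 1L, nExpressionPairs = 1L,
                      heterozygosity = 0, seed = 5)
  expect_false(any(simulateGermline(map, cfgHom) == "AB"))
})

test_that("planted events label the truth track and reject overlaps", {
  map <- evenMap(60)
  cases <- c("c1", "c2")
  ev <- data.frame(case_id = "c1", chromosome = 1L,
                   start = map@position[10], end = map@position[50],
                   loh = TRUE, cn = 2L, stringsAsFactors = FALSE)
  truth <- plantEvents(map, cases, ev)
  expect_true(all(truth$loh[10:50, "c1"]))
  expect_false(any(truth$loh[-(10:50), "c1"]))
  expect_false(any(truth$loh[, "c2"]))
  expect_true(all(truth$cn == 2L))
  expect_identical(truth$events$cn_group, "neutral")

  none <- plantEvents(map, cases, ev[0, ])
  expect_false(any(none$loh))

  six <- data.frame(case_id = "c1", chromosome = 1L,
                    start = map@position[c(1, 11, 21, 31, 41)],
                    end = map@position[c(9, 19, 29, 39, 49)],
                    loh = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                    cn = c(1L, 2L, 3L, 1L, 4L), stringsAsFactors = FALSE)
  t6 <- plantEvents(map, cases, six)
  labels <- paste0(ifelse(t6$loh[, "c1"], "LOH", "noLOH"), "|",
                   cnGroup(t6$cn[, "c1"]))
  expect_setequal(unique(labels), c("LOH|loss", "LOH|neutral", "LOH|gain",
                                    "noLOH|loss", "noLOH|gain",
                                    "noLOH|neutral"))

  bad <- rbind(ev, within(ev, { start <- map@position[40]
                                end <- map@position[55] }))
  expect_error(plantEvents(map, cases, bad), "overlap")
})

test_that("tumor genotypes collapse heterozygotes only inside LOH, one allele per run", {
  cfg <- SimConfig(nCases = 2L, nExpressionPairs = 1L, callRate = 1,
                   seed = 9)
  map <- evenMap(200)
  blood <- simulateGermline(map, cfg)
  ev <- data.frame(case_id = "case01", chromosome = 1L,
                   start = map@position[20], end = map@position[120],
                   loh = TRUE, cn = 2L, stringsAsFactors = FALSE)
  truth <- plantEvents(map, c("case01", "case02"), ev)
  gt <- simulateTumorGenotypes(blood, truth, cfg)

  insideHet <- truth$loh[, "case01"] & blood[, "case01"] == "AB"
  expect_false(any(gt$tumor[insideHet, "case01"] == "AB"))
  retained <- unique(gt$tumor[insideHet, "case01"])
  expect_length(retained, 1L)  # one clonal event, one surviving allele
  expect_true(retained %in% c("AA", "BB"))

  insideHom <- truth$loh[, "case01"] & blood[, "case01"] != "AB"
  expect_identical(gt$tumor[insideHom, "case01"], blood[insideHom, "case01"])
  outside <- !truth$loh[, "case01"]
  expect_identical(gt$tumor[outside, "case01"], blood[outside, "case01"])
  expect_identical(gt$normal, blood)  # call rate 1: copy of blood
})

test_that("intensity ratios center on log2(c/2) with a floor for c = 0", {
  cfg <- SimConfig(nCases = 4L, nExpressionPairs = 1L,
                   intensityNoiseSd = 1e-6, seed = 13)
  map <- evenMap(40)
  ev <- data.frame(case_id = c("case01", "case02", "case03"),
                   chromosome = 1L,
                   start = map@position[1], end = map@position[40],
                   loh = FALSE, cn = c(1L, 3L, 0L),
                   stringsAsFactors = FALSE)
  truth <- plantEvents(map, sprintf("case%02d", 1:4), ev)
  r <- simulateIntensities(truth, cfg)
  expect_equal(mean(r$tumor[, "case01"]), -1, tolerance = 1e-4)
  expect_equal(mean(r$tumor[, "case02"]), log2(3 / 2), tolerance = 1e-4)
  expect_equal(mean(r$tumor[, "case03"]), -3, tolerance = 1e-4)
  expect_equal(mean(r$tumor[, "case04"]), 0, tolerance = 1e-4)
  expect_equal(mean(r$normal), 0, tolerance = 1e-4)
})

test_that("identical seeds reproduce the whole cohort exactly", {
  cfg <- SimConfig(nCases = 3L, nExpressionPairs = 2L, seed = 42)
  lens <- c("1" = 3e6, "2" = 3e6, "3" = 3e6, "4" = 3e6, "5" = 3e6)
  a <- simulateCohort(cfg, chromosomeLengths = lens, nGenes = 50L)
  b <- simulateCohort(cfg, chromosomeLengths = lens, nGenes = 50L)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$ratios, b$ratios)
  expect_identical(a$expression, b$expression)
  expect_identical(a$truth$events, b$truth$events)

  c2 <- simulateCohort(SimConfig(nCases = 3L, nExpressionPairs = 2L,
                                 seed = 43),
                       chromosomeLengths = lens, nGenes = 50L)
  expect_false(identical(a$genotypes$blood, c2$genotypes$blood))
})

test_that("the truth track is a partition: one state per SNP per case", {
  run <- defaultRun()
  truth <- run$cohort$truth
  expect_identical(dim(truth$loh), dim(truth$cn))
  expect_true(all(truth$cn %in% 0:4))
  expect_false(anyNA(truth$loh))
})

test_that("cohort layout round-trips through writeCohort/loadCohort", {
  cfg <- SimConfig(nCases = 3L, nExpressionPairs = 2L, seed = 8)
  cohort <- simulateCohort(cfg, chromosomeLengths = rep(3e6, 5),
                           nGenes = 40L)
  d <- withr::local_tempdir()
  writeCohort(cohort, d)
  back <- loadCohort(d)
  expect_identical(back$genotypes$blood, cohort$genotypes$blood)
  expect_identical(back$genotypes$tumor, cohort$genotypes$tumor)
  expect_equal(back$ratios$tumor, cohort$ratios$tumor, tolerance = 1e-12)
  expect_identical(back$genes$probeset_id, cohort$genes$probeset_id)
  expect_equal(back$expression$normal, cohort$expression$normal,
               tolerance = 1e-12)
})
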