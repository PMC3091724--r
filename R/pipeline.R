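#' Per-chromosome LOH plot colored by CN group
#'
#' One horizontal row per case; a marker at each defined LOH-positive
#' SNP position, colored black for CNNLOH, blue for LOH with CN loss,
#' red for LOH with CN gain (retention SNPs are not drawn). The x axis
#' is position in Mb.
#'
#' @param track a [SixStateTrack-class].
#' @param chromosome chromosome number to draw.
#' @param file optional PNG path; when NULL, draws on the active
#'   device.
#' @param width,height device size in pixels when \code{file} is used.
#' @return invisibly, the marker table actually drawn: data.frame
#'   case_id, position, cn_group, color.
#' @export
plotChromosome <- function(track, chromosome, file = NULL,
                           width = 900, height = 600) {
  stopifnot(is(track, "SixStateTrack"))
  map <- track@map
  sel <- which(map@chromosome == chromosome)
  cases <- colnames(track@state)
  pal <- c(neutral = "black", loss = "blue", gain = "red")
  rows <- lapply(seq_along(cases), function(i) {
    st <- track@state[sel, cases[i]]
    lohIdx <- which(!is.na(st) & startsWith(st, "LOH|"))
    if (!length(lohIdx)) return(NULL)
    grp <- sub("^LOH\\|", "", st[lohIdx])
    data.frame(case_id = cases[i], position = map@position[sel][lohIdx],
               cn_group = grp, color = unname(pal[grp]),
               stringsAsFactors = FALSE)
  })
  markers <- do.call(rbind, rows)
  if (is.null(markers)) {
    warning("no LOH markers on chromosome ", chromosome, "; empty plot")
    markers <- data.frame(case_id = character(), position = integer(),
                          cn_group = character(), color = character(),
                          stringsAsFactors = FALSE)
  }
  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  xmax <- if (length(sel)) max(map@position[sel]) / 1e6 else 1
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0.5, length(cases) + 0.5),
                 xlab = sprintf("Chromosome %s position (Mb)", chromosome),
                 ylab = "Case", yaxt = "n",
                 main = sprintf("LOH by CN group, chromosome %s", chromosome))
  graphics::axis(2, at = seq_along(cases), labels = cases, las = 2,
                 cex.axis = 0.6)
  if (nrow(markers)) {
    y <- match(markers$case_id, cases)
    graphics::points(markers$position / 1e6, y, pch = 15, cex = 0.3,
                     col = markers$color)
  }
  graphics::legend("topright", legend = c("CNNLOH", "LOH + CN loss",
                                          "LOH + CN gain"),
                   col = pal[c("neutral", "loss", "gain")], pch = 15,
                   cex = 0.7, bg = "white")
  invisible(markers)
}

#' Run the full trio-cohort pipeline
#'
#' Executes simulate (or load) -> LOH calling -> CN calling ->
#' six-state combination and segmentation -> per-case and per-arm
#' summary tables -> blood-vs-adjacent CN concordance -> LOH
#' differential expression per CN class -> per-chromosome figure, and
#' writes every product plus a manifest (parameters, seed, package
#' version, md5 checksum per output file) into \code{outDir}.
#'
#' @param config a [SimConfig-class]; used to simulate inputs when
#'   \code{inputDir} is NULL.
#' @param outDir output directory.
#' @param inputDir optional directory in the [writeCohort()] layout to
#'   load instead of simulating. Expression files are optional: when
#'   absent the expression stage is skipped with a warning.
#' @param windowBp CN smoothing window (bp).
#' @param alpha raw significance level for the expression test.
#' @param minGroup minimum cases per LOH group.
#' @param foldThreshold reported two-fold cutoff (display only; the
#'   rule itself is >= foldThreshold or <= 1/foldThreshold).
#' @param zeroRule zero-fraction rule for percent-of-cases summaries.
#' @param plotChrom chromosome to draw (default: first in the map).
#' @return invisibly, a list with the in-memory products: cohort,
#'   lohTumor, cnTumor, cnBlood, cnNormal, sixTrack, segments,
#'   tables (case/arm/noloh), concordance, expression results, paths.
#' @export
runPipeline <- function(config = SimConfig(), outDir, inputDir = NULL,
                        windowBp = 1e5, alpha = 0.01, minGroup = 2L,
                        foldThreshold = 2, zeroRule = "exact_zero",
                        plotChrom = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(inputDir)) {
    cohort <- simulateCohort(config)
    writeCohort(cohort, file.path(outDir, "inputs"))
  } else {
    cohort <- loadCohort(inputDir)
  }
  map <- cohort$map
  loh <- callLoh(cohort$genotypes$blood, cohort$genotypes$tumor, map)
  cn <- callCn(cohort$ratios$tumor, map, windowBp)
  cnNormal <- callCn(cohort$ratios$normal, map, windowBp)
  ## blood vs itself is diploid by definition; concordance compares the
  ## adjacent-normal track against an all-neutral blood reference
  blood0 <- new("CnTrack", map = map,
                smoothed = cohort$ratios$normal * 0,
                state = matrix(2L, nrow(cohort$ratios$normal),
                               ncol(cohort$ratios$normal),
                               dimnames = dimnames(cohort$ratios$normal)))
  six <- combineStates(loh, cn)
  segs <- segmentStates(six)
  p <- function(f) file.path(outDir, f)
  writeMatrixTsv(lohStatus(loh), p("loh_track.tsv"))
  writeMatrixTsv(cnState(cn), p("cn_state.tsv"))
  writeMatrixTsv(sixState(six), p("sixstate.tsv"))
  bedDir <- p("segments")
  dir.create(bedDir, showWarnings = FALSE)
  for (cs in unique(segs$case_id))
    writeSegmentsBed(segs[segs$case_id == cs, ],
                     file.path(bedDir, paste0(cs, ".bed")))
  tabCase <- tabulateLohByCn(six, "case")
  tabArm <- tabulateLohByCn(six, "arm")
  noCase <- tabulateNoLohCn(six, "case")
  noArm <- tabulateNoLohCn(six, "arm")
  conc <- cnConcordance(blood0, cnNormal)
  wt <- function(df, f) write.table(df, p(f), sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  wt(tabCase, "table_case.tsv"); wt(tabArm, "table_arm.tsv")
  wt(noCase, "noloh_case.tsv"); wt(noArm, "noloh_arm.tsv")
  wt(conc, "concordance.tsv")
  wt(footerStats(tabCase), "table_case_footer.tsv")
  wt(footerStats(tabArm), "table_arm_footer.tsv")
  exprResults <- NULL
  if (!is.null(cohort$expression)) {
    fc <- foldChanges(cohort$expression$normal, cohort$expression$tumor)
    exprCases <- colnames(fc)
    states <- mapGenes(cohort$genes, segs, caseIds = exprCases)
    exprResults <- do.call(rbind, lapply(CN_GROUPS, function(cls)
      lohDifferentialExpression(fc, states, cls, genes = cohort$genes,
                                map = map, alpha = alpha,
                                minGroup = minGroup)))
    wt(exprResults, "expression_results.tsv")
  } else {
    warning("expression inputs missing; skipping expression stage")
  }
  if (is.null(plotChrom)) {
    ## default to the chromosome with the heaviest LOH burden
    isLoh <- !is.na(sixState(six)) & startsWith(sixState(six), "LOH|")
    byChrom <- tapply(rowSums(isLoh), map@chromosome, sum)
    plotChrom <- as.integer(names(byChrom)[which.max(byChrom)])
  }
  plotChromosome(six, plotChrom, file = p("loh_plot.png"))
  outputs <- list.files(outDir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[!grepl("manifest.txt$|\\.png$", outputs)]
  manifest <- c(
    sprintf("cnnloh_version\t%s", as.character(packageVersion("cnnloh"))),
    sprintf("seed\t%d", config@seed),
    sprintf("window_bp\t%g", windowBp),
    sprintf("alpha\t%g", alpha),
    sprintf("min_group\t%d", as.integer(minGroup)),
    sprintf("fold_threshold\t%g", foldThreshold),
    sprintf("zero_rule\t%s", zeroRule),
    sprintf("md5\t%s\t%s",
            substring(outputs, nchar(outDir) + 2L),
            unname(tools::md5sum(outputs))))
  writeLines(manifest, p("manifest.txt"))
  invisible(list(cohort = cohort, loh = loh, cn = cn,
                 cnNormal = cnNormal, six = six, segments = segs,
                 tables = list(case = tabCase, arm = tabArm,
                               nolohCase = noCase, nolohArm = noArm),
                 concordance = conc, expression = exprResults,
                 outDir = outDir))
}

#' Load a cohort from the on-disk layout written by writeCohort()
#'
#' Expression and truth files are optional; absent layers load as
#' NULL.
#'
#' @param dir input directory.
#' @return cohort list as produced by [simulateCohort()] (without
#'   config).
#' @export
loadCohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  map <- readSnpMap(p("snp_map.tsv"))
  cohort <- list(
    map = map,
    genotypes = list(
      blood = readGenotypeMatrix(p("genotypes_blood.tsv"), map),
      tumor = readGenotypeMatrix(p("genotypes_tumor.tsv"), map),
      normal = readGenotypeMatrix(p("genotypes_normal.tsv"), map)),
    ratios = list(
      tumor = readNumericMatrix(p("logratio_tumor.tsv"), map),
      normal = readNumericMatrix(p("logratio_normal.tsv"), map)),
    genes = if (file.exists(p("genes.tsv"))) readGeneTable(p("genes.tsv")),
    expression = NULL, truth = NULL)
  if (file.exists(p("expression_normal.tsv")) &&
      file.exists(p("expression_tumor.tsv"))) {
    cohort$expression <- list(
      normal = readNumericMatrix(p("expression_normal.tsv")),
      tumor = readNumericMatrix(p("expression_tumor.tsv")))
  }
  if (file.exists(p("truth_events.tsv")))
    cohort$truth <- list(events = read.delim(p("truth_events.tsv"),
                                             stringsAsFactors = FALSE))
  cohort
}
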