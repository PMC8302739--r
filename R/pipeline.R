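#' Assemble and validate a pipeline run configuration
#'
#' A run configuration names the input files (summary statistics, genotypes,
#' sample metadata, optionally a population panel), the models to build, the
#' clumping parameters, the standardisation mode, the extremes cutoff and the
#' output directory. \code{readRunConfig} loads the same structure from a
#' YAML file; arguments passed directly override file values.
#'
#' @param statsFile summary-statistics TSV path.
#' @param genotypeFile genotype file path.
#' @param genotypeFormat \code{"dosage"} or \code{"vcf"}.
#' @param sampleFile optional sample-metadata TSV path.
#' @param populationFile optional population genotype file (population mode).
#' @param populationFormat format of the population genotype file.
#' @param models character vector of model names (see \code{\link{modelSpec}}).
#' @param pT optional p-value threshold override applied to every model.
#' @param r2Max,windowKb clumping parameters.
#' @param apoeStart,apoeEnd,apoeChrom APOE region override.
#' @param standardization \code{"in_sample"} or \code{"population"}.
#' @param nPcs number of principal components for adjustment.
#' @param cutoff extremes cutoff in SD units.
#' @param outDir output directory.
#' @param seed integer seed recorded in the manifest.
#' @return A validated list of class \code{"RunConfig"}.
#' @export
runConfig <- function(statsFile = NULL, genotypeFile = NULL,
                      genotypeFormat = "dosage", sampleFile = NULL,
                      populationFile = NULL, populationFormat = "dosage",
                      models = c("PRS.full", "PRS.no.APOE", "PRS.AD"),
                      pT = NULL, r2Max = 0.1, windowKb = 1000,
                      apoeChrom = "19", apoeStart = 44400000,
                      apoeEnd = 46500000,
                      standardization = c("in_sample", "population"),
                      nPcs = 10, cutoff = 2, outDir = "prs_output", seed = 1) {
  standardization <- match.arg(standardization)
  known <- c("ORS.full", "ORS.no.APOE", "PRS.full", "PRS.no.APOE", "PRS.AD")
  bad <- setdiff(models, known)
  if (length(bad))
    stop("unknown model name(s): ", paste(bad, collapse = ", "))
  for (p in c(statsFile, genotypeFile, sampleFile, populationFile)) {
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  }
  if (standardization == "population" && is.null(populationFile))
    stop("population standardisation needs populationFile")
  structure(list(statsFile = statsFile, genotypeFile = genotypeFile,
                 genotypeFormat = genotypeFormat, sampleFile = sampleFile,
                 populationFile = populationFile,
                 populationFormat = populationFormat, models = models,
                 pT = pT, r2Max = r2Max, windowKb = windowKb,
                 apoeChrom = apoeChrom, apoeStart = apoeStart,
                 apoeEnd = apoeEnd, standardization = standardization,
                 nPcs = nPcs, cutoff = cutoff, outDir = outDir,
                 seed = as.integer(seed)), class = "RunConfig")
}

#' @rdname runConfig
#' @param path YAML config file.
#' @param ... overrides passed to \code{runConfig} (flags win over the file).
#' @export
readRunConfig <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(runConfig, vals)
}

.config_region <- function(config) {
  GenomicRanges::GRanges(config$apoeChrom,
                         IRanges::IRanges(config$apoeStart, config$apoeEnd))
}

.write_manifest <- function(config, outDir, extra = list()) {
  inputs <- Filter(Negate(is.null),
                   list(stats = config$statsFile, genotypes = config$genotypeFile,
                        samples = config$sampleFile,
                        population = config$populationFile))
  checksums <- if (length(inputs)) {
    as.list(tools::md5sum(unlist(inputs)))
  } else {
    list()
  }
  manifest <- c(list(package = "ctprs",
                     version = as.character(utils::packageVersion("ctprs")),
                     seed = config$seed,
                     config = unclass(config),
                     input_md5 = checksums), extra)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

.load_inputs <- function(config) {
  stats <- readSummaryStats(config$statsFile)
  samples <- if (!is.null(config$sampleFile)) readSampleInfo(config$sampleFile)
  panel <- readGenotypePanel(config$genotypeFile,
                             format = config$genotypeFormat,
                             samples = samples)
  h <- harmonizePanel(panel, stats)
  list(panel = h$panel, stats = h$stats, samples = samples,
       harmonizeLog = attr(h, "harmonizeLog"))
}

#' Build and write every configured score model
#'
#' Loads and harmonises the inputs, builds each configured model
#' (\code{\link{buildModel}}), standardises per the configured mode, and
#' writes per-model score TSVs at the raw and standardized stages, a clump
#' report, and a machine-readable manifest (config echo, package version,
#' seed, input checksums).
#'
#' @param config a \code{\link{runConfig}}.
#' @return Invisibly, a named list of per-model lists with \code{raw} and
#'   \code{standardized} \code{ScoreSet}s.
#' @export
runScore <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  inp <- .load_inputs(config)
  clump <- clumpSpec(config$r2Max, config$windowKb)
  region <- .config_region(config)
  popPanel <- if (config$standardization == "population") {
    readGenotypePanel(config$populationFile, format = config$populationFormat)
  }
  out <- list()
  for (name in config$models) {
    model <- modelSpec(name, pT = config$pT)
    raw <- buildModel(inp$panel, inp$stats, model, clump = clump,
                      region = region, samples = inp$samples)
    message(sprintf("runScore: %s built from %d SNPs", name, nSnps(raw)))
    if (config$standardization == "population") {
      std <- standardizeAgainstPopulation(inp$panel, popPanel, inp$stats,
                                          model, clump = clump,
                                          region = region, k = config$nPcs,
                                          samples = inp$samples)$study
    } else {
      adj <- residualizeScores(raw, genotypePCs(inp$panel, k = config$nPcs))
      std <- standardizeInSample(adj)$scores
    }
    writeScoreSet(raw, file.path(config$outDir,
                                 sprintf("scores_%s_raw.tsv", name)))
    writeScoreSet(std, file.path(config$outDir,
                                 sprintf("scores_%s_standardized.tsv", name)))
    report <- attr(raw, "clumpReport")
    if (!is.null(report))
      utils::write.table(report,
                         file.path(config$outDir,
                                   sprintf("clump_report_%s.tsv", name)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    out[[name]] <- list(raw = raw, standardized = std)
  }
  .write_manifest(config, config$outDir,
                  extra = list(harmonize = as.list(inp$harmonizeLog),
                               n_snps = lapply(out, function(m) nSnps(m$raw))))
  invisible(out)
}

#' Extreme-tail classification report
#'
#' Standardises every configured model per the configured mode, classifies
#' samples into the +/- cutoff tails, and writes per-model tail tables
#' (counts, odds ratio with CI, AUC) plus a per-sample tail file. When a
#' model yields no extremes, the odds-ratio computation is skipped with a
#' notice and the zero table is still reported.
#'
#' @param config a \code{\link{runConfig}}; \code{sampleFile} must provide
#'   case/control status.
#' @return Invisibly, a list with \code{report} (data.frame) and \code{tails}
#'   (named list of per-sample tail factors).
#' @export
runExtremes <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.null(config$sampleFile))
    stop("runExtremes needs sampleFile with case/control status")
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  scores <- runScore(config)
  samples <- readSampleInfo(config$sampleFile)
  rows <- list(); tailsOut <- list(); perSample <- list()
  for (name in names(scores)) {
    std <- scores[[name]]$standardized
    status <- samples$status[match(sampleIds(std), samples$id)]
    known <- status %in% c("case", "control")
    tails <- classifyExtremes(std, cutoff = config$cutoff)
    tt <- tailTable(tails[known], status[known])
    cnt <- tailCounts(tt)
    hasExtremes <- sum(cnt) > 0
    haveBoth <- (cnt["a"] + cnt["c"]) >= 1 && (cnt["b"] + cnt["d"]) >= 1
    if (!hasExtremes || !haveBoth) {
      message(sprintf("runExtremes: %s has no usable extremes; OR skipped",
                      name))
      est <- list(oddsRatio = NA_real_, ciLow = NA_real_, ciHigh = NA_real_,
                  haldaneApplied = FALSE)
    } else {
      est <- oddsRatioCI(tt)
    }
    extremeAuc <- if (hasExtremes &&
                      length(unique(status[known][tails[known] != "neither"])) == 2) {
      aucPercent(scoreValues(std)[known][tails[known] != "neither"],
                 status[known][tails[known] != "neither"])
    } else {
      NA_real_
    }
    rows[[name]] <- data.frame(
      model = name, standardization = config$standardization,
      pos_cases = cnt[["a"]], pos_controls = cnt[["b"]],
      neg_cases = cnt[["c"]], neg_controls = cnt[["d"]],
      odds_ratio = est$oddsRatio, ci_low = est$ciLow, ci_high = est$ciHigh,
      haldane = est$haldaneApplied, auc_extremes = extremeAuc)
    tailsOut[[name]] <- tails
    perSample[[name]] <- data.frame(sample = names(tails), model = name,
                                    tail = as.character(tails))
  }
  report <- do.call(rbind, rows)
  utils::write.table(report, file.path(config$outDir, "extremes_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, perSample),
                     file.path(config$outDir, "extremes_per_sample.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(report = report, tails = tailsOut))
}

#' Run the simulation study
#'
#' For each seed, simulates the default (or supplied) cohort, builds ORS.full,
#' PRS.full and PRS.AD from the truth summary statistics, and records their
#' AUCs against the labelled case/control status (putative cases analysed as
#' controls). Also emits the analytic checks that anchor the design: the
#' hidden-case fraction implied by the penetrance model, the case/control
#' frequencies solved from the whole-sample frequency and odds ratio, and the
#' pooled true-case frequency.
#'
#' @param cfg a \code{\link{cohortConfig}} (its seed is replaced per run).
#' @param seeds integer vector of simulation seeds.
#' @param outDir optional output directory for the per-seed AUC table and the
#'   analytic-check JSON.
#' @param writeGenotypes also write each cohort's genotype files (large; off
#'   by default).
#' @return A list: \code{aucs} (per-seed data.frame with columns seed,
#'   ORS.full, PRS.full, PRS.AD), \code{analytic} (named list), and
#'   \code{means}.
#' @export
runSimulation <- function(cfg = cohortConfig(), seeds = 1:10, outDir = NULL,
                          writeGenotypes = FALSE) {
  stopifnot(inherits(cfg, "CohortConfig"))
  rows <- list()
  for (s in seeds) {
    cfg$seed <- as.integer(s)
    cohort <- simulateCohort(cfg)
    if (writeGenotypes && !is.null(outDir))
      writeCohort(cohort, file.path(outDir, sprintf("cohort_seed%d", s)))
    aucs <- paradoxAUCs(cohort)
    rows[[length(rows) + 1L]] <- data.frame(seed = s, t(aucs))
    rm(cohort)
    gc(FALSE)  # the full-size cohort is large; collect before the next draw
  }
  aucs <- do.call(rbind, rows)
  solved <- solveCaseControlFreqs(0.216, 3.326, 0.34)
  analytic <- list(
    hidden_case_fraction = hiddenCaseFraction(0.142, 0.91, 0.47, 0.20),
    solved_f_case = unname(solved["fCase"]),
    solved_f_control = unname(solved["fControl"]),
    pooled_true_case_freq = pooledFreq(c(10000, 2800), c(0.355, 0.36)))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(aucs, file.path(outDir, "paradox_aucs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(analytic, file.path(outDir, "analytic_checks.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(aucs = aucs, analytic = analytic,
       means = colMeans(aucs[, -1, drop = FALSE]))
}

#' AUCs of the three simulation-study models on one cohort
#'
#' Builds ORS.full (68 clumped SNPs at pT <= 1e-5, e4-like SNP included),
#' PRS.full (all SNPs at pT <= 0.1) and PRS.AD (PRS.no.APOE plus the weighted
#' e4 term) from the cohort's truth summary statistics and returns their AUCs
#' for labelled case/control status.
#'
#' @param cohort a \code{"SimulatedCohort"}.
#' @return Named numeric vector of AUC percentages.
#' @export
paradoxAUCs <- function(cohort) {
  stopifnot(inherits(cohort, "SimulatedCohort"))
  panel <- cohort$panel
  stats <- cohort$truthStats
  status <- cohort$status
  out <- vapply(c("ORS.full", "PRS.full", "PRS.AD"), function(name) {
    sc <- buildModel(panel, stats, modelSpec(name))
    a <- aucPercent(sc, status)
    gc(FALSE)
    a
  }, numeric(1))
  out
}
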