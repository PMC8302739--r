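mk_panel <- function(d, prefix = "v") {
  GenotypePanel(d, data.frame(
    id = paste0(prefix, seq_len(nrow(d))), chrom = "1",
    pos = seq_len(nrow(d)) * 1e4, effectAllele = "A", otherAllele = "G"),
    samplesInRows = FALSE)
}

test_that("principal components capture structure deterministically", {
  # rank-1 dosage matrix: PC1 carries all the variance
  v <- c(0, 1, 2, 1, 0, 2, 1, 0)
  p1 <- genotypePCs(mk_panel(rbind(v, v, v)), k = 2)
  expect_gt(p1$sdev[1], 0)
  expect_lt(p1$sdev[2] / p1$sdev[1], 1e-8)

  # two allele-frequency-separated subpopulations split cleanly on PC1
  set.seed(21)
  nv <- 80
  fA <- runif(nv, 0.05, 0.25); fB <- runif(nv, 0.6, 0.9)
  d <- cbind(matrix(rbinom(nv * 30, 2, fA), nv),
             matrix(rbinom(nv * 30, 2, fB), nv))
  pcs <- genotypePCs(mk_panel(d), k = 2)
  a <- pcs$coordinates[1:30, 1]; b <- pcs$coordinates[31:60, 1]
  expect_true(max(a) < min(b) || max(b) < min(a))

  # k = 0 gives an empty set and identity adjustment
  p0 <- genotypePCs(mk_panel(rbind(v, v)), k = 0)
  expect_equal(p0$k, 0L)
  sc <- ScoreSet(sprintf("sample_%04d", 1:8), seq(-1, 2.5, 0.5))
  expect_equal(scoreValues(residualizeScores(sc, p0)), scoreValues(sc))
  expect_equal(scoreStage(residualizeScores(sc, p0)), "pc_adjusted")

  # constant variants are dropped with a warning, not propagated
  dc <- rbind(v, rep(1, 8))
  expect_warning(genotypePCs(mk_panel(dc), k = 1), "constant")
})

test_that("PC adjustment residualises exactly and never inflates variance", {
  set.seed(33)
  d <- matrix(rbinom(50 * 40, 2, 0.4), 50)
  panel <- mk_panel(d)
  pcs <- genotypePCs(panel, k = 4)
  # score equal to PC1 residualises to zero
  s1 <- ScoreSet(pcs$sampleIds, pcs$coordinates[, 1])
  expect_lt(max(abs(scoreValues(residualizeScores(s1, pcs)))), 1e-10)
  # random scores: residuals orthogonal to every component
  s2 <- ScoreSet(pcs$sampleIds, rnorm(40))
  r <- residualizeScores(s2, pcs)
  orth <- crossprod(pcs$coordinates, scoreValues(r))
  expect_lt(max(abs(orth)), 1e-8)
  expect_lte(var(scoreValues(r)), var(scoreValues(s2)))
  # mismatched samples are an error
  s3 <- ScoreSet(paste0("zz", 1:40), rnorm(40))
  expect_error(residualizeScores(s3, pcs), "missing")
})

test_that("in-sample standardisation is exact and idempotent", {
  s <- ScoreSet(c("a", "b"), c(1, 3))
  z <- standardizeInSample(s)
  expect_equal(unname(scoreValues(z$scores)), c(-1, 1) / sqrt(2))
  expect_equal(z$ref$mean, 2)
  expect_equal(z$ref$sd, sqrt(2))

  set.seed(5)
  s2 <- ScoreSet(sprintf("s%02d", 1:25), rnorm(25, 10, 4))
  z2 <- standardizeInSample(s2)$scores
  expect_equal(mean(scoreValues(z2)), 0)
  expect_equal(sd(scoreValues(z2)), 1)
  z3 <- standardizeInSample(z2)$scores
  expect_equal(scoreValues(z3), scoreValues(z2))
  expect_equal(scoreStage(z2), "standardized")
  expect_error(standardizeInSample(ScoreSet(c("a", "b"), c(1, 1))),
               "constant")
})

test_that("standardisation references round-trip through JSON", {
  s <- ScoreSet(sprintf("s%d", 1:4), c(0, 1, 2, 3))
  ref <- standardizeInSample(s)$ref
  path <- withr::local_tempfile(fileext = ".json")
  writeStandardizationRef(ref, path, modelLabel = "PRS.full")
  back <- readStandardizationRef(path)
  expect_equal(back$mean, ref$mean)
  expect_equal(back$sd, ref$sd)
  expect_equal(back$source, "in_sample")
  expect_equal(attr(back, "model"), "PRS.full")
  zs <- standardizeWithReference(s, back)
  expect_equal(scoreValues(zs), scoreValues(standardizeInSample(s)$scores))
})

test_that("population referencing matches in-sample when panels coincide", {
  cfg <- cohortConfig(nCase = 60, nControl = 60, nPoly = 40, seed = 3)
  cohort <- simulateCohort(cfg)
  pop <- simulatePopulationPanel(cfg, 120, seed = 3)
  # population drawn identical to itself: standardise pop against pop copy
  colnames2 <- sub("^pop_", "study_", colnames(pop))
  cd <- as.data.frame(SummarizedExperiment::colData(pop))
  d2 <- dosageMatrix(pop)
  colnames(d2) <- colnames2
  popStudy <- GenotypePanel(d2, variantInfo(pop),
                            samples = cbind(id = colnames2, cd),
                            samplesInRows = FALSE)
  st <- standardizeAgainstPopulation(popStudy, pop, cohort$truthStats,
                                     modelSpec("PRS.full"), k = 2)
  # the population subsample is standardized exactly
  expect_lt(abs(mean(scoreValues(st$population))), 1e-10)
  expect_lt(abs(sd(scoreValues(st$population)) - 1), 1e-10)
  # identical genotypes -> study z equals population z (same PCs, same model)
  expect_equal(unname(scoreValues(st$study)),
               unname(scoreValues(st$population)), tolerance = 1e-8)
  # and equals plain in-sample standardisation of the same scores
  inSample <- standardizeInSample(
    residualizeScores(buildModel(pop, cohort$truthStats, modelSpec("PRS.full")),
                      genotypePCs(pop, k = 2)))$scores
  expect_equal(unname(scoreValues(st$study)),
               unname(scoreValues(inSample)), tolerance = 1e-6)
})

test_that("a constant score shift moves population-referenced z by c/sd", {
  s <- ScoreSet(sprintf("s%d", 1:6), c(1, 2, 3, 4, 5, 6))
  ref <- structure(list(mean = 2, sd = 4, source = "population", nRef = 100L),
                   class = "StandardizationRef")
  z1 <- scoreValues(standardizeWithReference(s, ref))
  sShift <- ScoreSet(sampleIds(s), scoreValues(s) + 10)
  z2 <- scoreValues(standardizeWithReference(sShift, ref))
  expect_equal(z2 - z1, setNames(rep(10 / 4, 6), sampleIds(s)))
})

test_that("case-enriched cohorts gain extremes under population referencing", {
  # lighter twin of the acceptance property: a few seeds only
  hits <- 0L
  for (seed in 1:4) {
    cfg <- cohortConfig(nCase = 150, nControl = 150, nPoly = 60, seed = seed)
    cohort <- simulateCohort(cfg)
    pop <- simulatePopulationPanel(cfg, 400)
    st <- standardizeAgainstPopulation(cohort$panel, pop, cohort$truthStats,
                                       modelSpec("PRS.full"), k = 0)
    nPop <- sum(abs(scoreValues(st$study)) > 2)
    inS <- standardizeInSample(
      residualizeScores(buildModel(cohort$panel, cohort$truthStats,
                                   modelSpec("PRS.full")),
                        genotypePCs(cohort$panel, k = 0)))$scores
    nIn <- sum(abs(scoreValues(inS)) > 2)
    hits <- hits + (nPop >= nIn)
  }
  expect_equal(hits, 4L)
})
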