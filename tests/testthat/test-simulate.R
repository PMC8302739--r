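test_that("hidden-case fraction follows the Hardy-Weinberg penetrance mix", {
  # literature penetrances at the control e4 frequency give about 28%
  expect_equal(round(100 * hiddenCaseFraction(0.142, 0.91, 0.47, 0.20)), 28)
  # equal penetrances collapse to that penetrance for any frequency
  for (f in c(0, 0.1, 0.5, 1))
    expect_equal(hiddenCaseFraction(f, 0.3, 0.3, 0.3), 0.3)
  # f = 0 leaves only non-carriers
  expect_equal(hiddenCaseFraction(0, 0.91, 0.47, 0.20), 0.20)
  # monotone non-decreasing in every penetrance, and in f when ordered
  base <- hiddenCaseFraction(0.2, 0.9, 0.5, 0.2)
  expect_gte(hiddenCaseFraction(0.2, 0.95, 0.5, 0.2), base)
  expect_gte(hiddenCaseFraction(0.2, 0.9, 0.55, 0.2), base)
  expect_gte(hiddenCaseFraction(0.2, 0.9, 0.5, 0.25), base)
  fs <- seq(0.05, 0.95, 0.05)
  expect_true(all(diff(hiddenCaseFraction(fs, 0.9, 0.5, 0.2)) >= 0))
})

test_that("the case/control frequency solver inverts the mixture system", {
  # no association: both groups at the mixture frequency
  out <- solveCaseControlFreqs(0.3, 1, 0.4)
  expect_equal(unname(out), c(0.3, 0.3), tolerance = 1e-9)
  # round trip: forward-computing mixture and OR recovers the inputs
  set.seed(17)
  for (i in 1:20) {
    fAll <- runif(1, 0.05, 0.6); or <- exp(runif(1, -1.5, 1.5))
    prop <- runif(1, 0.1, 0.9)
    f <- solveCaseControlFreqs(fAll, or, prop)
    expect_equal(prop * f[["fCase"]] + (1 - prop) * f[["fControl"]], fAll,
                 tolerance = 1e-8)
    odds <- function(p) p / (1 - p)
    expect_equal(odds(f[["fCase"]]) / odds(f[["fControl"]]), or,
                 tolerance = 1e-8)
  }
})

test_that("pooled frequencies are size-weighted means", {
  expect_equal(pooledFreq(c(10000, 2800), c(0.355, 0.36)), 4558 / 12800)
  expect_equal(pooledFreq(c(5, 50), c(0.2, 0.2)), 0.2)
  expect_equal(pooledFreq(7, 0.31), 0.31)
  expect_error(pooledFreq(numeric(0), numeric(0)), "empty")
  expect_error(pooledFreq(c(1, -1), c(0.2, 0.3)))
})

test_that("simulated cohorts honour configuration and are reproducible", {
  cfg <- cohortConfig(nCase = 3000, nControl = 3000, nPoly = 50, seed = 99)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(dosageMatrix(a$panel), dosageMatrix(b$panel))
  expect_identical(a$status, b$status)
  # different seeds change genotypes but not the variant layout
  c2 <- simulateCohort(cohortConfig(nCase = 3000, nControl = 3000,
                                    nPoly = 50, seed = 100))
  expect_false(identical(dosageMatrix(a$panel), dosageMatrix(c2$panel)))
  expect_equal(variantInfo(a$panel)[, c("id", "chrom", "pos")],
               variantInfo(c2$panel)[, c("id", "chrom", "pos")])

  # putative flags mark labelled controls only, at the configured rate
  expect_true(all(a$status[a$putative] == "control"))
  expect_equal(sum(a$putative), round(0.28 * 3000))

  # e4-like allele frequency in labelled cases within 3 Monte-Carlo SDs
  e4 <- dosageMatrix(a$panel)["e4_snp", a$status == "case"]
  mcsd <- sqrt(0.355 * 0.645 / (2 * 3000))
  expect_lt(abs(mean(e4) / 2 - 0.355), 3 * mcsd)
  # pooled labelled-case + putative frequency near the pooled target
  pooled <- pooledFreq(c(3000, sum(a$putative)), c(0.355, 0.36))
  e4t <- dosageMatrix(a$panel)["e4_snp", a$status == "case" | a$putative]
  n <- length(e4t)
  expect_lt(abs(mean(e4t) / 2 - pooled), 3 * sqrt(pooled * (1 - pooled) / (2 * n)))

  # sample metadata mirrors the e4 dosage as rs429358 genotype strings
  cd <- as.data.frame(SummarizedExperiment::colData(a$panel))
  dos <- dosageMatrix(a$panel)["e4_snp", ]
  expect_equal(unname(vapply(cd$rs429358, function(g)
    nchar(gsub("T", "", g)), numeric(1))), unname(dos))
  expect_true(all(cd$rs7412 == "CC"))

  # truth stats partition at the model thresholds: 68 strong, rest weak
  v <- variantInfo(a$truthStats)
  expect_equal(sum(v$pValue <= 1e-5), 68L)
  expect_equal(sum(v$pValue <= 0.1), nrow(v))
})

test_that("a null configuration yields chance-level prediction", {
  cfg <- cohortConfig(nCase = 5000, nControl = 5000, hiddenFraction = 0,
                      fCaseE4 = 0.142, fPutativeE4 = 0.142,
                      oligoSnps = within(syntheticOligoTable(), beta <- 0),
                      nPoly = 50, orMaxCase = 1, orMaxPutative = 1, seed = 12)
  cohort <- simulateCohort(cfg)
  aucs <- paradoxAUCs(cohort)
  expect_true(all(abs(aucs - 50) < 2))
})

test_that("allele frequencies converge to the configured values with n", {
  freqErr <- function(n, seed) {
    cfg <- cohortConfig(nCase = n, nControl = n, nPoly = 20, seed = seed)
    cohort <- simulateCohort(cfg)
    d <- dosageMatrix(cohort$panel)[, cohort$status == "case" &
                                      !cohort$putative, drop = FALSE]
    v <- variantInfo(cohort$truthStats)
    oligo <- startsWith(rownames(d), "oligo_")
    odds <- function(p) p / (1 - p)
    target <- local({
      f0 <- cohortConfig()$oligoSnps$freq
      o <- exp(cohortConfig()$oligoSnps$beta) * odds(f0)
      o / (1 + o)
    })
    mean(abs(rowMeans(d[oligo, ]) / 2 - target))
  }
  expect_lt(freqErr(4000, 2), freqErr(250, 2))
})

test_that("LD fixtures realise their target r-squared", {
  reals <- vapply(1:6, function(seed) {
    fx <- makeLdFixture(seed, 700, data.frame(size = 5, r2 = 0.6, maf = 0.3))
    d <- dosageMatrix(fx$panel)
    cors <- cor(t(d))
    mean(cors[upper.tri(cors)]^2)
  }, numeric(1))
  expect_true(all(abs(reals - 0.6) < 0.15))
  # r2 target 0 produces (near-)independent SNPs
  fx0 <- makeLdFixture(2, 700, data.frame(size = 5, r2 = 0, maf = 0.3))
  c0 <- cor(t(dosageMatrix(fx0$panel)))
  expect_lt(max(c0[upper.tri(c0)]^2), 0.05)
  expect_error(makeLdFixture(1, 100, data.frame(size = 3, r2 = 1.2, maf = 0.3)),
               "infeasible")
})

test_that("simulated cohorts round-trip through the plain-text writers", {
  cfg <- cohortConfig(nCase = 25, nControl = 25, nPoly = 10, seed = 4)
  cohort <- simulateCohort(cfg)
  dir <- withr::local_tempdir()
  paths <- writeCohort(cohort, dir)
  samples <- readSampleInfo(paths[["samples"]])
  panel <- readGenotypePanel(paths[["dosages"]], format = "dosage",
                             samples = samples)
  stats <- readSummaryStats(paths[["stats"]])
  expect_equal(dosageMatrix(panel), dosageMatrix(cohort$panel) + 0)
  expect_equal(variantInfo(stats)$beta, variantInfo(cohort$truthStats)$beta)
  expect_equal(sum(samples$status == "case"), 25L)
})
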