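test_that("AUC equals brute-force pairwise concordance", {
  # perfect separation and all-ties
  expect_equal(aucPercent(c(3, 4, 5, 1, 2), c(T, T, T, F, F)), 100)
  expect_equal(aucPercent(rep(1, 6), c(T, T, T, F, F, F)), 50)
  # 6-sample toy set with a tie across groups
  v <- c(0.3, 0.7, 0.5, 0.5, 0.1, 0.6)
  y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(aucPercent(v, y), oracle_auc(v, y))
  # random vectors across several seeds
  for (seed in 1:5) {
    set.seed(seed)
    v <- sample(seq(0, 1, 0.05), 30, replace = TRUE)
    y <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(y)) < 2) next
    expect_equal(aucPercent(v, y), oracle_auc(v, y))
    expect_equal(aucPercent(v, y) + aucPercent(-v, y), 100)
  }
  expect_error(aucPercent(1:3, c(TRUE, TRUE, TRUE)), "control")
  # status strings work and ScoreSets are accepted
  s <- ScoreSet(c("a", "b"), c(2, 1))
  expect_equal(aucPercent(s, c("case", "control")), 100)
})

test_that("logistic fits recover the 2x2 odds ratio and handle degeneracy", {
  # single binary predictor: coefficient equals log OR of the table
  x <- rep(c(1, 0, 1, 0), c(30, 20, 10, 40))
  y <- rep(c(TRUE, TRUE, FALSE, FALSE), c(30, 20, 10, 40))
  fit <- fitLogistic(y, x)
  expect_equal(unname(fit$coefficients[2]),
               log((30 * 40) / (20 * 10)), tolerance = 1e-6)
  expect_false(fit$separation)
  expect_true(fit$r2 > 0 && fit$r2 < 1)

  # null predictor: Nagelkerke R2 near zero at n = 5000
  set.seed(8)
  xn <- rnorm(5000); yn <- sample(c(TRUE, FALSE), 5000, replace = TRUE)
  expect_lt(fitLogistic(yn, xn)$r2, 0.01)

  # duplicated predictor columns: same fitted values as a single column
  f1 <- fitLogistic(y, list(a = x))
  f2 <- fitLogistic(y, list(a = x, b = x))
  expect_equal(f2$fitted, f1$fitted, tolerance = 1e-8)

  # complete separation: flagged, penalized fallback still orders correctly
  xs <- c(rnorm(30, 5), rnorm(30, -5)); ys <- rep(c(TRUE, FALSE), each = 30)
  expect_warning(fs <- fitLogistic(ys, xs), "separation")
  expect_true(fs$separation)
  expect_true(all(fs$fitted[1:30] > 0.5) && all(fs$fitted[31:60] < 0.5))
})

test_that("extreme classification uses strict +/- cutoff inequalities", {
  z <- ScoreSet(c("a", "b", "c", "d", "e"), c(2.5, 2.0, -3.1, -2.0, 0),
                stage = "standardized", reference = "in_sample")
  tails <- classifyExtremes(z)
  expect_equal(as.character(tails),
               c("positive", "neither", "negative", "neither", "neither"))
  expect_equal(names(tails), c("a", "b", "c", "d", "e"))
  # raw scores are refused; cutoff 0 puts every nonzero score in a tail
  raw <- ScoreSet(c("a", "b"), c(1, 2))
  expect_error(classifyExtremes(raw), "standardized")
  expect_equal(sum(classifyExtremes(z, cutoff = 0) != "neither"), 4L)
})

test_that("tail tables count the four cells and ignore sample order", {
  tails <- factor(c("positive", "positive", "negative", "neither", "neither"),
                  levels = c("positive", "negative", "neither"))
  status <- c("case", "case", "control", "case", "control")
  tt <- tailTable(tails, status)
  expect_equal(tailCounts(tt), c(a = 2L, b = 0L, c = 0L, d = 1L))
  perm <- c(3, 5, 1, 4, 2)
  expect_equal(tailCounts(tailTable(tails[perm], status[perm])),
               tailCounts(tt))
  empty <- tailTable(factor(rep("neither", 3),
                            levels = levels(tails)), rep("case", 3))
  expect_equal(sum(tailCounts(empty)), 0L)
})

test_that("odds ratios reproduce the published extreme-tail statistics", {
  # (a, b, c, d) -> printed OR at the tables' precision
  printed <- list(list(c(18, 2, 1, 1), 9), list(c(33, 5, 2, 3), 9.9),
                  list(c(11, 2, 3, 11), 20), list(c(19, 3, 3, 15), 32),
                  list(c(21, 1, 0, 3), 100), list(c(33, 3, 0, 6), 124),
                  list(c(4, 1, 0, 6), 39))
  for (ps in printed) {
    est <- oddsRatioCI(do.call(TailTable, as.list(ps[[1]])))
    expect_equal(printedPrecision(est$oddsRatio, "or"), ps[[2]],
                 info = paste(ps[[1]], collapse = ","))
    expect_equal(est$haldaneApplied, any(ps[[1]] == 0))
  }
  # upper CI bound of the (11,2,3,11) table prints as 145
  est <- oddsRatioCI(TailTable(11, 2, 3, 11))
  expect_equal(round(est$ciHigh), 145)
  expect_true(est$ciLow <= est$oddsRatio && est$oddsRatio <= est$ciHigh)
})

test_that("odds-ratio machinery satisfies its symmetry properties", {
  est <- oddsRatioCI(TailTable(1, 1, 1, 1))
  expect_equal(est$oddsRatio, 1)
  expect_false(est$haldaneApplied)
  # swapping the tails reciprocates the OR
  e1 <- oddsRatioCI(TailTable(12, 3, 2, 9))
  e2 <- oddsRatioCI(TailTable(2, 9, 12, 3))
  expect_equal(e1$oddsRatio, 1 / e2$oddsRatio)
  # scaling all cells leaves the OR unchanged and narrows the CI
  e4 <- oddsRatioCI(TailTable(48, 12, 8, 36))
  expect_equal(e4$oddsRatio, e1$oddsRatio)
  expect_lt(e4$ciHigh / e4$ciLow, e1$ciHigh / e1$ciLow)
  expect_error(oddsRatioCI(TailTable(0, 1, 0, 1)), "cases")
  expect_error(oddsRatioCI(TailTable(1, 0, 1, 0)), "controls")
})

test_that("extreme-tail overlap counts shared assignments per method pair", {
  mk <- function(x, ids) factor(stats::setNames(x, ids),
                                levels = c("positive", "negative", "neither"))
  ids <- sprintf("s%02d", 1:10)
  a <- mk(c("positive", "positive", "negative", rep("neither", 7)), ids)
  b <- mk(c("positive", "neither", "negative", "positive", rep("neither", 6)), ids)
  c3 <- mk(c(rep("neither", 8), "positive", "negative"), ids)
  ov <- overlapExtremes(list(A = a, B = b, C = c3))
  pick <- function(m1, m2, tail)
    ov$overlap[ov$methodA == m1 & ov$methodB == m2 & ov$tail == tail]
  expect_equal(pick("A", "B", "positive"), 1L)  # s01 only
  expect_equal(pick("A", "B", "negative"), 1L)  # s03
  expect_equal(pick("A", "C", "positive"), 0L)  # disjoint
  expect_equal(pick("B", "C", "negative"), 0L)
  # identical assignments overlap at the full tail sizes
  self <- overlapExtremes(list(A = a, A2 = a))
  expect_equal(self$overlap, c(2L, 1L))
  expect_error(overlapExtremes(list(A = a)), "two methods")
  noNames <- mk(rep("neither", 3), NULL)
  expect_error(overlapExtremes(list(A = a, B = noNames)), "named")
})

test_that("age-group summaries bin by the study's age bands", {
  # constant dosage 1 everywhere: single cell with allele frequency 0.5
  out <- ageGroupSummary(rep(1, 4), rep(70, 4),
                         rep("case", 4), asFrequency = TRUE)
  expect_equal(nrow(out), 1L)
  expect_equal(out$bin, "65-75")
  expect_equal(out$mean, 0.5)
  # boundary age 65 falls in the 65-75 bin; 85 in the open-ended last bin
  out2 <- ageGroupSummary(c(1, 1, 2), c(65, 85, 90), rep("control", 3),
                          asFrequency = TRUE)
  expect_equal(out2$bin[out2$n == 1], "65-75")
  expect_equal(out2$mean[out2$bin == "85+"], 0.75)
  # under-55 samples are excluded
  out3 <- ageGroupSummary(c(1, 1), c(40, 60), c("case", "case"))
  expect_equal(sum(out3$n), 1L)
})

test_that("declining simulated e4 frequency shows up in the age summary", {
  # built-in trend: case e4 dosage drawn with decreasing frequency by age bin
  set.seed(14)
  wins <- 0L
  for (rep in 1:10) {
    ages <- sample(c(60, 70, 80, 90), 600, replace = TRUE)
    f <- c(`60` = 0.45, `70` = 0.35, `80` = 0.25, `90` = 0.15)[as.character(ages)]
    dos <- rbinom(600, 2, f)
    out <- ageGroupSummary(dos, ages, rep("case", 600), asFrequency = TRUE)
    wins <- wins + all(diff(out$mean[order(out$bin)]) < 0)
  }
  expect_gte(wins, 6L)  # majority of replicates show the monotone decline
})
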