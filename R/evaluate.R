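.status_logical <- function(status) {
  if (is.logical(status)) return(status)
  s <- as.character(status)
  bad <- !s %in% c("case", "control")
  if (any(bad)) stop("status must be 'case' or 'control' (got: ",
                     paste(unique(s[bad]), collapse = ", "), ")")
  s == "case"
}

.score_vector <- function(x) {
  if (is(x, "ScoreSet")) scoreValues(x) else as.numeric(x)
}

#' Area under the ROC curve, in percent
#'
#' Rank-based (Mann-Whitney concordance) AUC: the probability that a random
#' case outscores a random control, tied pairs counting one half. Reported as
#' a percentage.
#'
#' @param scores a \code{\linkS4class{ScoreSet}} or numeric vector.
#' @param status case/control labels ("case"/"control", or logical with
#'   \code{TRUE} = case), aligned with the scores.
#' @return AUC in [0, 100].
#' @export
aucPercent <- function(scores, status) {
  v <- .score_vector(scores)
  y <- .status_logical(status)
  if (length(v) != length(y)) stop("scores and status lengths differ")
  nCase <- sum(y); nCtl <- sum(!y)
  if (nCase == 0 || nCtl == 0) stop("need at least one case and one control")
  r <- rank(v)
  100 * (sum(r[y]) - nCase * (nCase + 1) / 2) / (nCase * nCtl)
}

.nagelkerke <- function(devNull, devFit, n) {
  cox <- 1 - exp((devFit - devNull) / n)
  denom <- 1 - exp(-devNull / n)
  if (denom == 0) return(0)
  cox / denom
}

#' Logistic model fit with Nagelkerke pseudo-R-squared
#'
#' Maximum-likelihood logistic regression of case/control status on one or
#' more score predictors (the two-predictor APOE + PRS.no.APOE formulation is
#' the motivating multi-predictor case). Collinear predictors are handled by
#' the usual rank-deficiency dropping. Complete or quasi-complete separation
#' is detected; when flagged, coefficients and fitted probabilities come from
#' a lightly ridge-penalised fallback fit and a warning is raised.
#'
#' @param status case/control labels or logical (TRUE = case).
#' @param predictors a \code{ScoreSet}, numeric vector, or (possibly named)
#'   list of them, all aligned with \code{status}.
#' @return A list: \code{coefficients}, \code{fitted} (probabilities),
#'   \code{r2} (Nagelkerke), \code{separation} flag, and the underlying
#'   \code{model} object.
#' @export
fitLogistic <- function(status, predictors) {
  y <- .status_logical(status)
  if (is(predictors, "ScoreSet") || is.numeric(predictors))
    predictors <- list(score = predictors)
  X <- do.call(cbind, lapply(predictors, .score_vector))
  if (is.null(colnames(X)) || any(colnames(X) == ""))
    colnames(X) <- paste0("score", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop("predictors and status lengths differ")
  df <- data.frame(.y = y, X, check.names = TRUE)

  sepWarn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sepWarn <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)
  separation <- sepWarn || any(abs(co[!is.na(co)]) > 25)

  if (!separation) {
    r2 <- .nagelkerke(fit$null.deviance, fit$deviance, length(y))
    return(list(coefficients = co, fitted = as.numeric(stats::fitted(fit)),
                r2 = r2, separation = FALSE, model = fit))
  }

  warning("separation detected; reporting penalized (ridge) fallback fit")
  Xm <- as.matrix(X)
  if (ncol(Xm) < 2) Xm <- cbind(Xm, .pad = 0)  # glmnet needs >= 2 columns
  pen <- glmnet::glmnet(Xm, factor(y), family = "binomial", alpha = 0,
                        lambda = 1e-3)
  eta <- as.numeric(stats::predict(pen, newx = Xm))
  p <- 1 / (1 + exp(-eta))
  eps <- 1e-12
  dev <- -2 * sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  pbar <- mean(y)
  devNull <- -2 * sum(y * log(pbar) + (1 - y) * log(1 - pbar))
  cf <- as.numeric(stats::coef(pen))
  names(cf) <- c("(Intercept)", colnames(Xm))
  cf <- cf[names(cf) != ".pad"]
  list(coefficients = cf, fitted = p,
       r2 = .nagelkerke(devNull, dev, length(y)),
       separation = TRUE, model = pen)
}

#' Classify samples into score-distribution extremes
#'
#' A sample is a positive extreme when its z-score strictly exceeds
#' \code{cutoff}, a negative extreme when it is strictly below
#' \code{-cutoff}, and neither otherwise ("exceeding" +/-2 SD is read as a
#' strict inequality, so z exactly at the cutoff is not an extreme).
#'
#' @param scores a standardized \code{\linkS4class{ScoreSet}} (or a numeric
#'   vector of z-scores).
#' @param cutoff tail cutoff in SD units, default 2.
#' @return A factor with levels positive/negative/neither, named by sample.
#' @export
classifyExtremes <- function(scores, cutoff = 2) {
  if (is(scores, "ScoreSet") && scores@stage != "standardized")
    stop("scores must be standardized (stage = 'standardized')")
  z <- .score_vector(scores)
  out <- ifelse(z > cutoff, "positive", ifelse(z < -cutoff, "negative", "neither"))
  factor(stats::setNames(out, names(z)),
         levels = c("positive", "negative", "neither"))
}

#' Tabulate cases and controls in the score tails
#'
#' @param tails factor from \code{\link{classifyExtremes}}.
#' @param status case/control labels aligned with \code{tails}.
#' @return A \code{\linkS4class{TailTable}} with \code{a} positive-tail cases,
#'   \code{b} positive-tail controls, \code{c} negative-tail cases, \code{d}
#'   negative-tail controls ("neither" samples excluded).
#' @export
tailTable <- function(tails, status) {
  y <- .status_logical(status)
  if (length(tails) != length(y)) stop("tails and status lengths differ")
  TailTable(a = sum(tails == "positive" & y),
            b = sum(tails == "positive" & !y),
            c = sum(tails == "negative" & y),
            d = sum(tails == "negative" & !y))
}

#' Odds ratio of the tail table, with Haldane correction
#'
#' OR = (a d) / (b c) with a 95 percent Woolf (log-normal) confidence
#' interval \code{exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))}. When any
#' cell is zero, the Haldane correction adds 0.5 to all four cells before both
#' the OR and the interval are computed, and the \code{haldaneApplied} flag is
#' set.
#'
#' @param t a \code{\linkS4class{TailTable}}.
#' @param conf confidence level (default 0.95).
#' @return A list of class \code{"EffectEstimate"}: \code{oddsRatio},
#'   \code{ciLow}, \code{ciHigh}, \code{haldaneApplied}.
#' @export
oddsRatioCI <- function(t, conf = 0.95) {
  stopifnot(is(t, "TailTable"))
  cnt <- as.numeric(tailCounts(t))
  if (cnt[1] + cnt[3] < 1) stop("no cases in either tail")
  if (cnt[2] + cnt[4] < 1) stop("no controls in either tail")
  haldane <- any(cnt == 0)
  if (haldane) cnt <- cnt + 0.5
  or <- (cnt[1] * cnt[4]) / (cnt[2] * cnt[3])
  se <- sqrt(sum(1 / cnt))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  structure(list(oddsRatio = or, ciLow = exp(log(or) - z * se),
                 ciHigh = exp(log(or) + z * se), haldaneApplied = haldane),
            class = "EffectEstimate")
}

#' Round to the printed precision of the study tables
#'
#' Odds ratios of 10 or more are printed as integers, smaller ones to one
#' decimal; AUC percentages to one decimal; R-squared to two decimals.
#'
#' @param x numeric value(s).
#' @param what one of \code{"or"}, \code{"auc"}, \code{"r2"}.
#' @return Rounded numeric.
#' @export
printedPrecision <- function(x, what = c("or", "auc", "r2")) {
  what <- match.arg(what)
  switch(what,
         or = ifelse(x >= 10, round(x), round(x, 1)),
         auc = round(x, 1),
         r2 = round(x, 2))
}

#' Pairwise overlap of extreme-tail assignments across methods
#'
#' For every pair of methods and each tail, counts the shared samples both
#' methods assign to that tail (computed over the samples common to all
#' methods).
#'
#' @param assignments named list (>= 2 entries) of factors from
#'   \code{\link{classifyExtremes}}, each named by sample id.
#' @return data.frame with columns methodA, methodB, tail, overlap, nA, nB.
#' @export
overlapExtremes <- function(assignments) {
  if (!is.list(assignments) || length(assignments) < 2)
    stop("need at least two methods")
  if (is.null(names(assignments)))
    names(assignments) <- paste0("method", seq_along(assignments))
  idSets <- lapply(assignments, names)
  if (any(vapply(idSets, is.null, logical(1))))
    stop("each assignment must be named by sample id")
  shared <- Reduce(intersect, idSets)
  if (!length(shared)) stop("methods share no samples")
  rows <- list()
  nm <- names(assignments)
  for (i in seq_len(length(nm) - 1)) {
    for (j in (i + 1):length(nm)) {
      ai <- assignments[[i]][shared]
      aj <- assignments[[j]][shared]
      for (tail in c("positive", "negative")) {
        rows[[length(rows) + 1L]] <- data.frame(
          methodA = nm[i], methodB = nm[j], tail = tail,
          overlap = sum(ai == tail & aj == tail),
          nA = sum(ai == tail), nB = sum(aj == tail))
      }
    }
  }
  do.call(rbind, rows)
}

#' Per-age-group, per-status summary means
#'
#' Means of a per-sample quantity (a score, or an allele dosage) within age
#' bins split by case/control status. Default bins follow the study's age
#' groups 55-65, 65-75, 75-85, 85+ (left-closed, right-open, except the last
#' which is unbounded). Samples with ages below the first break are excluded;
#' empty cells are absent from the output.
#'
#' @param values numeric per-sample quantity (e.g. dosage of an allele, or a
#'   score), or a \code{ScoreSet}.
#' @param ages numeric ages in years.
#' @param status case/control labels.
#' @param breaks ascending bin edges; the last bin is unbounded above.
#' @param asFrequency if TRUE, values are allele dosages and the reported mean
#'   is mean dosage / 2, i.e. an allele frequency.
#' @return data.frame with columns bin, status, n, mean.
#' @export
ageGroupSummary <- function(values, ages, status,
                            breaks = c(55, 65, 75, 85), asFrequency = FALSE) {
  v <- .score_vector(values)
  y <- .status_logical(status)
  if (length(v) != length(ages) || length(v) != length(y))
    stop("values, ages and status lengths differ")
  edges <- c(breaks, Inf)
  labs <- c(paste0(utils::head(breaks, -1), "-", utils::tail(breaks, -1)),
            paste0(breaks[length(breaks)], "+"))
  bin <- cut(ages, breaks = edges, right = FALSE, labels = labs)
  keep <- !is.na(bin) & !is.na(v)
  if (!any(keep)) return(data.frame(bin = character(), status = character(),
                                    n = integer(), mean = numeric()))
  grp <- data.frame(bin = bin[keep],
                    status = ifelse(y[keep], "case", "control"),
                    v = v[keep])
  agg <- stats::aggregate(v ~ bin + status, data = grp,
                          FUN = function(x) c(n = length(x), mean = mean(x)))
  out <- data.frame(bin = as.character(agg$bin), status = agg$status,
                    n = as.integer(agg$v[, "n"]), mean = agg$v[, "mean"])
  if (asFrequency) out$mean <- out$mean / 2
  out[order(out$bin, out$status), , drop = FALSE]
}
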