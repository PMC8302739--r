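#' Genotype principal components
#'
#' Principal components of the per-variant centred, unit-variance-scaled
#' dosage matrix (samples as observations). Missing dosages are mean-imputed
#' per variant; constant variants are dropped with a warning before the
#' decomposition. A deterministic sign convention is applied: within each
#' component the loading of largest magnitude is made positive.
#'
#' @param panel a \code{\linkS4class{GenotypePanel}}.
#' @param k number of components (0 yields an empty set, making downstream
#'   adjustment the identity). Default 10.
#' @return A list of class \code{"PCSet"}: \code{sampleIds},
#'   \code{coordinates} (samples x k), \code{k}, \code{sdev}.
#' @export
genotypePCs <- function(panel, k = 10) {
  stopifnot(is(panel, "GenotypePanel"))
  ids <- colnames(panel)
  if (k == 0) {
    return(structure(list(sampleIds = ids,
                          coordinates = matrix(0, length(ids), 0),
                          k = 0L, sdev = numeric(0)), class = "PCSet"))
  }
  X <- t(dosageMatrix(panel))
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    nas <- which(is.na(X), arr.ind = TRUE)
    X[nas] <- mu[nas[, 2]]
  }
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    warning(sprintf("dropping %d constant variant(s) before PCA", sum(v == 0)))
    X <- X[, v > 0, drop = FALSE]
  }
  if (k > min(nrow(X), ncol(X)))
    stop("k exceeds min(sample count, variant count)")
  X <- scale(X)
  pr <- stats::prcomp(X, center = FALSE, scale. = FALSE, rank. = k)
  coords <- pr$x[, seq_len(k), drop = FALSE]
  rot <- pr$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- ids
  structure(list(sampleIds = ids, coordinates = coords, k = as.integer(k),
                 sdev = pr$sdev[seq_len(k)]), class = "PCSet")
}

#' Adjust scores for principal components
#'
#' Replaces each score with the residual of an ordinary least-squares
#' regression of score on the components plus an intercept. Residuals are
#' orthogonal to every component; with an empty component set the values pass
#' through unchanged. Samples are aligned by id.
#'
#' @param scores a raw \code{\linkS4class{ScoreSet}}.
#' @param pcs a \code{"PCSet"} from \code{\link{genotypePCs}}.
#' @return A \code{ScoreSet} with \code{stage = "pc_adjusted"}.
#' @export
residualizeScores <- function(scores, pcs) {
  stopifnot(is(scores, "ScoreSet"), inherits(pcs, "PCSet"))
  if (scores@stage != "raw")
    stop("scores must be at stage 'raw' (got '", scores@stage, "')")
  m <- match(scores@sampleIds, pcs$sampleIds)
  if (anyNA(m)) stop("sample(s) missing from PCSet: ",
                     paste(scores@sampleIds[is.na(m)], collapse = ", "))
  vals <- scores@values
  if (pcs$k > 0) {
    Z <- cbind(1, pcs$coordinates[m, , drop = FALSE])
    vals <- as.numeric(stats::lm.fit(Z, vals)$residuals)
  }
  ScoreSet(scores@sampleIds, vals, modelLabel = scores@modelLabel,
           stage = "pc_adjusted", reference = scores@reference,
           nSnps = scores@nSnps)
}

.make_ref <- function(mean, sd, source, nRef) {
  structure(list(mean = mean, sd = sd, source = source,
                 nRef = as.integer(nRef)), class = "StandardizationRef")
}

#' Standardise scores within the sample
#'
#' z = (value - sample mean) / sample SD, with the n-1 SD denominator. The
#' output has mean 0 and SD 1; re-standardising is the identity.
#'
#' @param scores a \code{\linkS4class{ScoreSet}} (raw or pc_adjusted; an
#'   already standardized input is passed through re-centred, which leaves it
#'   unchanged).
#' @return \code{list(scores =, ref =)} where \code{scores} has
#'   \code{stage = "standardized"}, \code{reference = "in_sample"} and
#'   \code{ref} is a \code{"StandardizationRef"} (mean, sd, source, nRef).
#' @export
standardizeInSample <- function(scores) {
  stopifnot(is(scores, "ScoreSet"))
  v <- scores@values
  if (length(v) < 2) stop("need at least 2 samples to standardise")
  s <- stats::sd(v)
  if (s == 0) stop("scores are constant; cannot standardise")
  ref <- .make_ref(mean(v), s, "in_sample", length(v))
  z <- (v - ref$mean) / ref$sd
  list(scores = ScoreSet(scores@sampleIds, z, modelLabel = scores@modelLabel,
                         stage = "standardized", reference = "in_sample",
                         nSnps = scores@nSnps),
       ref = ref)
}

#' Standardise scores against a stored reference
#'
#' @param scores a \code{\linkS4class{ScoreSet}}.
#' @param ref a \code{"StandardizationRef"} (e.g. from
#'   \code{\link{standardizeAgainstPopulation}} or
#'   \code{\link{readStandardizationRef}}).
#' @return A standardized \code{ScoreSet} with the reference's source.
#' @export
standardizeWithReference <- function(scores, ref) {
  stopifnot(is(scores, "ScoreSet"), inherits(ref, "StandardizationRef"))
  if (ref$sd <= 0) stop("reference sd must be positive")
  z <- (scores@values - ref$mean) / ref$sd
  ScoreSet(scores@sampleIds, z, modelLabel = scores@modelLabel,
           stage = "standardized",
           reference = if (ref$source == "population") "population" else "in_sample",
           nSnps = scores@nSnps)
}

#' Population-referenced standardisation
#'
#' Implements the population-referenced mode: the study panel is merged with a
#' population panel over their shared harmonised variants, the model score is
#' computed on the merged panel, principal components are derived on the
#' merged data and the scores PC-adjusted, and finally all scores are z-scored
#' using the mean and SD (n-1 denominator) of the population subsample only.
#'
#' @param studyPanel,populationPanel \code{\linkS4class{GenotypePanel}}s
#'   sharing harmonised variants (same ids and effect alleles).
#' @param stats \code{\linkS4class{SummaryStats}} driving the model.
#' @param model a \code{\link{modelSpec}}.
#' @param clump a \code{\link{clumpSpec}}.
#' @param region APOE region for region-excluding models.
#' @param k number of merged-data principal components (default 10).
#' @param samples optional APOE genotype table for PRS.AD covering both
#'   panels.
#' @return \code{list(study =, population =, ref =)}: standardized
#'   \code{ScoreSet}s for the study samples and the population subsample
#'   (both \code{reference = "population"}), and the
#'   \code{"StandardizationRef"} used.
#' @export
standardizeAgainstPopulation <- function(studyPanel, populationPanel, stats,
                                         model, clump = clumpSpec(),
                                         region = apoeRegion(), k = 10,
                                         samples = NULL) {
  stopifnot(is(studyPanel, "GenotypePanel"), is(populationPanel, "GenotypePanel"))
  sv <- variantInfo(studyPanel)
  pv <- variantInfo(populationPanel)
  shared <- intersect(sv$id, pv$id)
  if (!length(shared)) stop("no shared variants between study and population")
  sw <- sv[match(shared, sv$id), ]
  pw <- pv[match(shared, pv$id), ]
  aligned <- sw$effectAllele == pw$effectAllele &
    sw$otherAllele == pw$otherAllele
  shared <- shared[aligned]
  if (!length(shared))
    stop("no allele-aligned shared variants; harmonise the panels first")
  overlap <- intersect(colnames(studyPanel), colnames(populationPanel))
  if (length(overlap))
    stop("study and population share sample ids: ",
         paste(utils::head(overlap, 5), collapse = ", "))

  ds <- dosageMatrix(studyPanel)[shared, , drop = FALSE]
  dp <- dosageMatrix(populationPanel)[shared, , drop = FALSE]
  mergedSamples <- NULL
  cs <- as.data.frame(SummarizedExperiment::colData(studyPanel))
  cp <- as.data.frame(SummarizedExperiment::colData(populationPanel))
  if (model@name == "PRS.AD" && is.null(samples)) {
    need <- c("rs429358", "rs7412")
    if (!all(need %in% colnames(cs)) || !all(need %in% colnames(cp)))
      stop("PRS.AD needs rs429358/rs7412 genotypes for both panels")
    mergedSamples <- rbind(
      data.frame(id = colnames(studyPanel), cs[, need, drop = FALSE]),
      data.frame(id = colnames(populationPanel), cp[, need, drop = FALSE]))
  } else {
    mergedSamples <- samples
  }
  merged <- GenotypePanel(cbind(ds, dp),
                          sv[match(shared, sv$id), , drop = FALSE],
                          samples = mergedSamples, samplesInRows = FALSE)
  statsShared <- subsetVariants(stats, shared)
  if (nVariants(statsShared) == 0)
    stop("no shared variants present in summary statistics")

  raw <- buildModel(merged, statsShared, model, clump = clump,
                    region = region, samples = mergedSamples)
  adj <- residualizeScores(raw, genotypePCs(merged, k = k))
  isPop <- adj@sampleIds %in% colnames(populationPanel)
  popVals <- adj@values[isPop]
  s <- stats::sd(popVals)
  if (is.na(s) || s == 0) stop("population scores are constant")
  ref <- .make_ref(mean(popVals), s, "population", sum(isPop))
  z <- (adj@values - ref$mean) / ref$sd
  mk <- function(idx) ScoreSet(adj@sampleIds[idx], z[idx],
                               modelLabel = model@name,
                               stage = "standardized",
                               reference = "population", nSnps = adj@nSnps)
  list(study = mk(!isPop), population = mk(isPop), ref = ref)
}

#' Export / import a standardisation reference
#'
#' The reference (mean, sd, source, nRef, optional model label) is written as
#' a small JSON record so cohorts can later be standardised against a stored
#' population reference.
#'
#' @param ref a \code{"StandardizationRef"}.
#' @param path file path.
#' @param modelLabel optional label stored alongside.
#' @return \code{writeStandardizationRef}: \code{path} invisibly;
#'   \code{readStandardizationRef}: the reference.
#' @export
writeStandardizationRef <- function(ref, path, modelLabel = NULL) {
  stopifnot(inherits(ref, "StandardizationRef"))
  rec <- list(mean = ref$mean, sd = ref$sd, source = ref$source,
              n_ref = ref$nRef)
  if (!is.null(modelLabel)) rec$model <- modelLabel
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeStandardizationRef
#' @export
readStandardizationRef <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- .make_ref(rec$mean, rec$sd, rec$source, rec$n_ref)
  if (!is.null(rec$model)) attr(ref, "model") <- rec$model
  ref
}
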