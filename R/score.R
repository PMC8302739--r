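#' Weighted-sum risk score
#'
#' Per sample, the sum over score variants of beta times effect-allele dosage.
#' Inputs are assumed harmonised (see \code{\link{harmonizePanel}}); every
#' variant of \code{stats} must be present in \code{panel}. Missing dosages
#' are replaced by the variant's expected dosage \code{2 * eaf} (the PLINK
#' mean-imputation convention); a missing dosage at a variant without a
#' recorded frequency is an error.
#'
#' @param panel a \code{\linkS4class{GenotypePanel}}.
#' @param stats a \code{\linkS4class{SummaryStats}} carrying the weights.
#' @param modelLabel label stored in the result.
#' @return A \code{\linkS4class{ScoreSet}} with \code{stage = "raw"} and
#'   \code{nSnps} equal to the number of variants summed.
#' @export
scorePanel <- function(panel, stats, modelLabel = "score") {
  stopifnot(is(panel, "GenotypePanel"), is(stats, "SummaryStats"))
  v <- stats@variants
  d <- dosageMatrix(panel)
  rowIdx <- match(v$id, rownames(d))
  if (all(is.na(rowIdx))) stop("no overlapping variants between panel and stats")
  if (anyNA(rowIdx))
    stop("variant(s) missing from panel: ",
         paste(utils::head(v$id[is.na(rowIdx)], 5), collapse = ", "))
  nSamp <- ncol(d)
  values <- numeric(nSamp)
  chunk <- 1000L
  starts <- seq(1L, nrow(v), by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, nrow(v))
    block <- d[rowIdx[idx], , drop = FALSE]
    if (anyNA(block)) {
      nas <- which(is.na(block), arr.ind = TRUE)
      fill <- 2 * v$eaf[idx][nas[, 1]]
      if (anyNA(fill))
        stop("missing dosage without recorded eaf at variant(s): ",
             paste(unique(v$id[idx][nas[is.na(fill), 1]]), collapse = ", "))
      block[nas] <- fill
    }
    storage.mode(block) <- "double"
    values <- values + as.numeric(crossprod(block, v$beta[idx]))
  }
  ScoreSet(colnames(d), values, modelLabel = modelLabel, stage = "raw",
           reference = "none", nSnps = nrow(v))
}
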