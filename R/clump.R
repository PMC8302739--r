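#' Clumping parameters
#'
#' @param r2Max squared-correlation threshold; candidates with r-squared
#'   strictly greater than this with an index variant are removed. Default 0.1
#'   (0.01 and 0.001 are common stricter settings).
#' @param windowKb half-width of the clumping window in kilobases around the
#'   index variant. Default 1000.
#' @return A list of class \code{"ClumpSpec"}.
#' @export
clumpSpec <- function(r2Max = 0.1, windowKb = 1000) {
  if (r2Max < 0 || r2Max > 1) stop("r2Max must lie in [0, 1]")
  if (windowKb <= 0) stop("windowKb must be positive")
  structure(list(r2Max = r2Max, windowKb = windowKb), class = "ClumpSpec")
}

#' Squared dosage correlation between two variants
#'
#' Squared Pearson correlation of the two variants' dosage vectors over
#' samples with non-missing values at both sites (complete pairs). Returns 0
#' when either vector is constant over the complete pairs.
#'
#' @param panel a \code{\linkS4class{GenotypePanel}}.
#' @param i,j variant ids or row indices.
#' @return r-squared in [0, 1].
#' @export
pairwiseR2 <- function(panel, i, j) {
  stopifnot(is(panel, "GenotypePanel"))
  d <- dosageMatrix(panel)
  if (is.character(i)) i <- match(i, rownames(d))
  if (is.character(j)) j <- match(j, rownames(d))
  if (anyNA(c(i, j))) stop("variant not found in panel")
  x <- d[i, ]; y <- d[j, ]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) stop("fewer than 2 complete sample pairs")
  .r2_complete(x[ok], y[ok])
}

.r2_complete <- function(x, y) {
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 || vy == 0) return(0)
  r <- stats::cov(x, y) / sqrt(vx * vy)
  min(r * r, 1)
}

# r2 of index row against a set of candidate rows, pairwise-complete
.r2_vec <- function(x, Y) {
  apply(Y, 1L, function(y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2) return(0)
    .r2_complete(x[ok], y[ok])
  })
}

#' Greedy LD clumping
#'
#' Sorts candidate variants by ascending p-value (ties broken by chromosome
#' then position), then repeatedly takes the best remaining variant as an
#' index and removes all remaining variants on the same chromosome within
#' \code{windowKb} kilobases whose squared dosage correlation with the index
#' strictly exceeds \code{r2Max}. LD is computed on \code{panel} (supply a
#' dedicated LD reference panel there if desired).
#'
#' @param stats \code{\linkS4class{SummaryStats}} of candidate variants; every
#'   id must be present in \code{panel}.
#' @param panel \code{\linkS4class{GenotypePanel}} used for LD estimation.
#' @param spec a \code{\link{clumpSpec}}.
#' @return A \code{SummaryStats} of retained index variants (position-sorted);
#'   attribute \code{"clumpReport"} is a data.frame of (index, removed, r2).
#' @export
clumpVariants <- function(stats, panel, spec = clumpSpec()) {
  stopifnot(is(stats, "SummaryStats"), is(panel, "GenotypePanel"),
            inherits(spec, "ClumpSpec"))
  v <- stats@variants
  d <- dosageMatrix(panel)
  rowIdx <- match(v$id, rownames(d))
  if (anyNA(rowIdx))
    stop("variant(s) missing from panel: ",
         paste(utils::head(v$id[is.na(rowIdx)], 5), collapse = ", "))
  n <- nrow(v)
  if (n == 0) return(stats)
  window <- spec$windowKb * 1000

  # neighbour lists within the window, built once per chromosome
  neighbours <- vector("list", n)
  for (ch in unique(v$chrom)) {
    on <- which(v$chrom == ch)
    pos <- v$pos[on]
    op <- order(pos)
    sortedPos <- pos[op]
    lo <- findInterval(sortedPos - window, sortedPos, left.open = TRUE) + 1L
    hi <- findInterval(sortedPos + window, sortedPos)
    for (k in seq_along(on)) {
      idx <- on[op[lo[k]:hi[k]]]
      neighbours[[on[op[k]]]] <- idx[idx != on[op[k]]]
    }
  }

  ord <- order(v$pValue, v$chrom, v$pos)
  alive <- rep(TRUE, n)
  keep <- logical(n)
  reports <- list()
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    cand <- neighbours[[i]]
    cand <- cand[alive[cand]]
    if (!length(cand)) next
    r2 <- .r2_vec(d[rowIdx[i], ], d[rowIdx[cand], , drop = FALSE])
    kill <- cand[r2 > spec$r2Max]
    if (length(kill)) {
      alive[kill] <- FALSE
      reports[[length(reports) + 1L]] <-
        data.frame(index = v$id[i], removed = v$id[kill],
                   r2 = r2[r2 > spec$r2Max])
    }
  }
  out <- SummaryStats(v[keep, , drop = FALSE])
  attr(out, "clumpReport") <- if (length(reports)) {
    do.call(rbind, reports)
  } else {
    data.frame(index = character(), removed = character(), r2 = numeric())
  }
  out
}
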