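.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.is_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonise a genotype panel against summary statistics
#'
#' Restricts panel and statistics to their shared variants and orients every
#' panel dosage so it counts the statistics' effect allele:
#' \itemize{
#'   \item identical allele pairs are kept as-is;
#'   \item swapped pairs (panel effect = stats other) have dosages mapped to
#'     \code{2 - d};
#'   \item strand flips are resolved by base complement (with swap handling);
#'   \item strand-ambiguous A/T and C/G variants are removed;
#'   \item variants with irreconcilable alleles, or absent from either side,
#'     are removed.
#' }
#' All removals are counted in the \code{"harmonizeLog"} attribute of the
#' returned list. The operation is idempotent: a harmonised pair passes
#' through unchanged.
#'
#' @param panel a \code{\linkS4class{GenotypePanel}}.
#' @param stats a \code{\linkS4class{SummaryStats}}.
#' @return \code{list(panel =, stats =)} restricted to shared, aligned
#'   variants in (chrom, pos) order, with attribute \code{"harmonizeLog"}.
#' @export
harmonizePanel <- function(panel, stats) {
  stopifnot(is(panel, "GenotypePanel"), is(stats, "SummaryStats"))
  sv <- stats@variants
  pv <- variantInfo(panel)

  shared <- intersect(sv$id, pv$id)
  nUnsharedStats <- nrow(sv) - length(shared)
  nUnsharedPanel <- nrow(pv) - length(shared)

  sv <- sv[match(shared, sv$id), , drop = FALSE]
  pv <- pv[match(shared, pv$id), , drop = FALSE]

  ambiguous <- .is_ambiguous(sv$effectAllele, sv$otherAllele)
  sameOrient <- pv$effectAllele == sv$effectAllele &
    pv$otherAllele == sv$otherAllele
  swapped <- pv$effectAllele == sv$otherAllele &
    pv$otherAllele == sv$effectAllele
  pEffC <- unname(.COMPLEMENT[pv$effectAllele])
  pOthC <- unname(.COMPLEMENT[pv$otherAllele])
  flip <- pEffC == sv$effectAllele & pOthC == sv$otherAllele
  flipSwapped <- pEffC == sv$otherAllele & pOthC == sv$effectAllele

  keep <- !ambiguous & (sameOrient | swapped | flip | flipSwapped)
  mismatch <- !ambiguous & !keep
  log <- c(unshared_stats = nUnsharedStats, unshared_panel = nUnsharedPanel,
           ambiguous = sum(ambiguous), mismatch = sum(mismatch),
           swapped = sum(keep & (swapped | flipSwapped)),
           strand_flipped = sum(keep & (flip | flipSwapped)))
  if (sum(log[c("ambiguous", "mismatch")]) + nUnsharedStats + nUnsharedPanel > 0)
    message(sprintf(paste0("harmonizePanel: removed %d unshared (stats), ",
                           "%d unshared (panel), %d ambiguous, %d mismatched; ",
                           "%d dosage-complemented, %d strand-flipped"),
                    nUnsharedStats, nUnsharedPanel, log[["ambiguous"]],
                    log[["mismatch"]], log[["swapped"]],
                    log[["strand_flipped"]]))

  keepIds <- sv$id[keep]
  ord <- order(sv$chrom[keep], sv$pos[keep])
  keepIds <- keepIds[ord]

  outStats <- SummaryStats(sv[match(keepIds, sv$id), , drop = FALSE])
  dos <- dosageMatrix(panel)[match(keepIds, pv$id), , drop = FALSE]
  needFlip <- (swapped | flipSwapped)[match(keepIds, sv$id)]
  if (any(needFlip))
    dos[needFlip, ] <- 2 - dos[needFlip, , drop = FALSE]
  newVariants <- pv[match(keepIds, pv$id), , drop = FALSE]
  os <- outStats@variants
  newVariants$effectAllele <- os$effectAllele[match(keepIds, os$id)]
  newVariants$otherAllele <- os$otherAllele[match(keepIds, os$id)]
  cd <- as.data.frame(SummarizedExperiment::colData(panel))
  samples <- if (ncol(cd)) cbind(id = colnames(panel), cd) else NULL
  outPanel <- GenotypePanel(dos, newVariants, samples = samples,
                            samplesInRows = FALSE)
  out <- list(panel = outPanel, stats = outStats)
  attr(out, "harmonizeLog") <- log
  out
}
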