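.normalize_geno <- function(g) {
  g <- toupper(gsub("[/| ]", "", as.character(g)))
  bad <- !is.na(g) & (nchar(g) != 2 | grepl("[^CT]", g))
  if (any(bad))
    stop("invalid APOE SNP genotype(s): ", paste(unique(g[bad]), collapse = ", "),
         " (expected two bases from {C, T})")
  g
}

#' APOE isoform allele counts from the two coding SNPs
#'
#' Codes the epsilon-2 and epsilon-4 allele counts from unphased rs429358 and
#' rs7412 genotypes: the e4 count is the number of C alleles at rs429358 and
#' the e2 count the number of T alleles at rs7412. The ambiguous
#' rs429358-CT / rs7412-CT double heterozygote is resolved as e2/e4, i.e.
#' (1, 1) — the standard unphased convention (the rare e1 haplotype is
#' ignored). Genotype combinations implying more than two isoform alleles are
#' rejected.
#'
#' @param genoRs429358,genoRs7412 genotype strings ("CT", "C/T", ...),
#'   vectorised.
#' @return A data.frame with integer columns \code{nE2} and \code{nE4}
#'   (\code{nE2 + nE4 <= 2}).
#' @examples
#' apoeIsoformCounts("TT", "CC")  # e3/e3 -> (0, 0)
#' apoeIsoformCounts("CC", "CC")  # e4/e4 -> (0, 2)
#' @export
apoeIsoformCounts <- function(genoRs429358, genoRs7412) {
  g1 <- .normalize_geno(genoRs429358)
  g2 <- .normalize_geno(genoRs7412)
  if (length(g1) != length(g2)) stop("genotype vectors must have equal length")
  countBase <- function(g, base)
    ifelse(is.na(g), NA_integer_,
           nchar(g) - nchar(gsub(base, "", g, fixed = TRUE)))
  nE4 <- countBase(g1, "C")
  nE2 <- countBase(g2, "T")
  over <- !is.na(nE2) & !is.na(nE4) & nE2 + nE4 > 2
  if (any(over))
    stop("genotype combination implies more than two isoform alleles at ",
         sum(over), " sample(s)")
  data.frame(nE2 = as.integer(nE2), nE4 = as.integer(nE4))
}

#' APOE score contribution
#'
#' The log-odds contribution of the APOE isoforms:
#' \code{bE2 * nE2 + bE4 * nE4}, with the fixed per-allele weights
#' B(e2) = -0.47 and B(e4) = 1.12 by default.
#'
#' @param nE2,nE4 isoform allele counts (0..2), vectorised.
#' @param bE2,bE4 per-allele log-odds weights.
#' @return Numeric score contribution in log-odds units.
#' @export
apoeComponent <- function(nE2, nE4, bE2 = -0.47, bE4 = 1.12) {
  stopifnot(all(nE2 %in% 0:2 | is.na(nE2)), all(nE4 %in% 0:2 | is.na(nE4)))
  bE2 * nE2 + bE4 * nE4
}

#' Specify one of the named score models
#'
#' Defaults per model: \code{ORS.full} and \code{ORS.no.APOE} use pT <= 1e-5;
#' \code{PRS.full}, \code{PRS.no.APOE} and \code{PRS.AD} use pT <= 0.1; the
#' APOE region is excluded for \code{ORS.no.APOE}, \code{PRS.no.APOE} and
#' \code{PRS.AD}; \code{PRS.AD} adds the APOE term with weights
#' B(e2) = -0.47 and B(e4) = 1.12.
#'
#' @param name model name (one of the five above, or a custom label).
#' @param pT p-value threshold override.
#' @param excludeApoe region-exclusion override (required for custom names).
#' @param bE2,bE4 APOE weight overrides (PRS.AD).
#' @return A \code{\linkS4class{ModelSpec}}.
#' @export
modelSpec <- function(name, pT = NULL, excludeApoe = NULL,
                      bE2 = -0.47, bE4 = 1.12) {
  defaults <- list(
    ORS.full = list(pT = 1e-5, excludeApoe = FALSE),
    ORS.no.APOE = list(pT = 1e-5, excludeApoe = TRUE),
    PRS.full = list(pT = 0.1, excludeApoe = FALSE),
    PRS.no.APOE = list(pT = 0.1, excludeApoe = TRUE),
    PRS.AD = list(pT = 0.1, excludeApoe = TRUE))
  if (name %in% names(defaults)) {
    if (is.null(pT)) pT <- defaults[[name]]$pT
    if (is.null(excludeApoe)) excludeApoe <- defaults[[name]]$excludeApoe
  } else if (is.null(pT) || is.null(excludeApoe)) {
    stop("custom model '", name, "' needs explicit pT and excludeApoe")
  }
  new("ModelSpec", name = name, pT = pT, excludeApoe = excludeApoe,
      bE2 = bE2, bE4 = bE4)
}

.apoe_counts_for <- function(panel, samples) {
  if (is.null(samples)) {
    cd <- as.data.frame(SummarizedExperiment::colData(panel))
    if (!all(c("rs429358", "rs7412") %in% colnames(cd)))
      stop("PRS.AD needs rs429358/rs7412 genotypes in colData or 'samples'")
    samples <- cbind(id = colnames(panel), cd)
  }
  m <- match(colnames(panel), as.character(samples$id))
  if (anyNA(m)) stop("APOE genotypes missing for sample(s): ",
                     paste(colnames(panel)[is.na(m)], collapse = ", "))
  g1 <- samples$rs429358[m]; g2 <- samples$rs7412[m]
  miss <- is.na(g1) | is.na(g2)
  if (any(miss))
    stop("APOE genotypes missing for sample(s): ",
         paste(colnames(panel)[miss], collapse = ", "))
  apoeIsoformCounts(g1, g2)
}

#' Build a named risk-score model
#'
#' Runs the C+T pipeline for one model: optional APOE-region exclusion, greedy
#' LD clumping, p-value thresholding, then the weighted dosage sum. For
#' \code{PRS.AD} the per-sample APOE component (\code{\link{apoeComponent}}
#' from the rs429358/rs7412 genotypes) is added to the SNP score on the raw
#' log-odds scale, and \code{nSnps} counts the two APOE SNPs on top of the SNP
#' set.
#'
#' @param panel harmonised \code{\linkS4class{GenotypePanel}}.
#' @param stats harmonised \code{\linkS4class{SummaryStats}}.
#' @param model a \code{\link{modelSpec}}.
#' @param clump a \code{\link{clumpSpec}}.
#' @param region APOE region to exclude when the model requires it.
#' @param samples optional data.frame with \code{id}, \code{rs429358},
#'   \code{rs7412} (otherwise taken from the panel's colData; PRS.AD only).
#' @return A \code{\linkS4class{ScoreSet}} (stage \code{raw}).
#' @export
buildModel <- function(panel, stats, model, clump = clumpSpec(),
                       region = apoeRegion(), samples = NULL) {
  stopifnot(is(model, "ModelSpec"))
  s <- stats
  if (model@excludeApoe) s <- excludeRegion(s, region)
  s <- clumpVariants(s, panel, clump)
  report <- attr(s, "clumpReport")
  s <- thresholdByP(s, model@pT)
  out <- scorePanel(panel, s, modelLabel = model@name)
  if (model@name == "PRS.AD") {
    counts <- .apoe_counts_for(panel, samples)
    comp <- apoeComponent(counts$nE2, counts$nE4, model@bE2, model@bE4)
    out <- ScoreSet(out@sampleIds, out@values + comp,
                    modelLabel = model@name, stage = "raw",
                    reference = "none", nSnps = out@nSnps + 2L)
  }
  attr(out, "clumpReport") <- report
  out
}
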