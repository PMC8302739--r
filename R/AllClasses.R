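#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.VALID_BASES <- c("A", "C", "G", "T")

.check_variant_frame <- function(v) {
  required <- c("id", "chrom", "pos", "effectAllele", "otherAllele",
                "beta", "pValue")
  missing <- setdiff(required, colnames(v))
  if (length(missing))
    return(sprintf("missing variant columns: %s",
                   paste(missing, collapse = ", ")))
  if (anyDuplicated(v$id))
    return("variant ids must be unique")
  if (!all(v$effectAllele %in% .VALID_BASES) ||
      !all(v$otherAllele %in% .VALID_BASES))
    return("alleles must be single bases A/C/G/T")
  if (any(v$effectAllele == v$otherAllele))
    return("effect allele must differ from other allele")
  bad_p <- !is.na(v$pValue) & (v$pValue <= 0 | v$pValue > 1)
  if (any(bad_p))
    return("p-values must lie in (0, 1]")
  if ("eaf" %in% colnames(v)) {
    bad_f <- !is.na(v$eaf) & (v$eaf < 0 | v$eaf > 1)
    if (any(bad_f))
      return("effect-allele frequencies must lie in [0, 1]")
  }
  TRUE
}

#' GWAS summary statistics
#'
#' Ordered collection of biallelic variant association records: identifier,
#' chromosome, 1-based position, effect/other allele, log-odds effect size,
#' association p-value and (optionally) effect-allele frequency. Records are
#' kept sorted by (chromosome, position) and variant ids are unique.
#'
#' @slot variants a \code{data.frame} with columns \code{id}, \code{chrom},
#'   \code{pos}, \code{effectAllele}, \code{otherAllele}, \code{beta},
#'   \code{pValue}, \code{eaf}.
#' @export
setClass("SummaryStats", slots = c(variants = "data.frame"))

setValidity("SummaryStats", function(object) {
  v <- object@variants
  ok <- .check_variant_frame(v)
  if (!isTRUE(ok)) return(ok)
  if (is.unsorted(order(v$chrom, v$pos)) &&
      !identical(order(v$chrom, v$pos), seq_len(nrow(v))))
    return("variants must be sorted by (chrom, pos)")
  TRUE
})

#' Construct a SummaryStats object
#'
#' Validates, normalises and position-sorts a variant table. Alleles are
#' upper-cased; an absent \code{eaf} column is filled with \code{NA}.
#'
#' @param variants data.frame of variant records (see class docs for columns).
#' @return A \code{\linkS4class{SummaryStats}} object.
#' @examples
#' SummaryStats(data.frame(id = "rs1", chrom = "1", pos = 100,
#'   effectAllele = "A", otherAllele = "G", beta = 0.1, pValue = 1e-4))
#' @export
SummaryStats <- function(variants) {
  variants <- as.data.frame(variants)
  variants$id <- as.character(variants$id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.numeric(variants$pos)
  variants$effectAllele <- toupper(as.character(variants$effectAllele))
  variants$otherAllele <- toupper(as.character(variants$otherAllele))
  if (!"eaf" %in% colnames(variants)) variants$eaf <- NA_real_
  variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  new("SummaryStats", variants = variants)
}

#' Genotype dosage panel
#'
#' A \linkS4class{SummarizedExperiment} holding an effect-allele dosage matrix
#' (variants as rows, samples as columns, values in [0, 2] or \code{NA}) with
#' variant metadata in \code{rowData} and sample metadata in \code{colData}.
#'
#' @export
setClass("GenotypePanel", contains = "SummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  d <- SummarizedExperiment::assay(object, "dosage")
  rng <- suppressWarnings(range(d, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    return("dosages must lie in [0, 2] or be NA")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("id", "chrom", "pos", "effectAllele", "otherAllele")
  missing <- setdiff(need, colnames(rd))
  if (length(missing))
    return(sprintf("rowData lacks columns: %s", paste(missing, collapse = ", ")))
  if (anyDuplicated(rd$id)) return("variant ids must be unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    return("sample ids (colnames) must be present and unique")
  TRUE
})

#' Construct a GenotypePanel
#'
#' @param dosages numeric matrix of effect-allele dosages. By default samples
#'   are rows and variants are columns (the on-disk dosage-TSV layout); set
#'   \code{samplesInRows = FALSE} if the matrix is already variants x samples.
#' @param variants data.frame of variant metadata with columns \code{id},
#'   \code{chrom}, \code{pos}, \code{effectAllele}, \code{otherAllele}
#'   (extra columns such as \code{beta} are carried along).
#' @param samples optional data.frame of per-sample metadata with an \code{id}
#'   column (e.g. \code{status}, \code{age}, \code{rs429358}, \code{rs7412}).
#' @param samplesInRows orientation flag for \code{dosages}.
#' @return A \code{\linkS4class{GenotypePanel}}.
#' @export
GenotypePanel <- function(dosages, variants, samples = NULL,
                          samplesInRows = TRUE) {
  variants <- as.data.frame(variants)
  variants$id <- as.character(variants$id)
  variants$chrom <- as.character(variants$chrom)
  variants$effectAllele <- toupper(as.character(variants$effectAllele))
  variants$otherAllele <- toupper(as.character(variants$otherAllele))
  if (samplesInRows) dosages <- t(dosages)
  if (nrow(dosages) != nrow(variants))
    stop("dosage matrix and variant table dimensions disagree")
  if (!identical(rownames(dosages), variants$id))
    rownames(dosages) <- variants$id
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- if (!is.null(samples) &&
                             nrow(as.data.frame(samples)) == ncol(dosages)) {
      as.character(as.data.frame(samples)$id)
    } else {
      sprintf("sample_%04d", seq_len(ncol(dosages)))
    }
  }
  cd <- DataFrame(row.names = colnames(dosages))
  if (!is.null(samples)) {
    samples <- as.data.frame(samples)
    if (!"id" %in% colnames(samples)) stop("sample metadata needs an 'id' column")
    m <- match(colnames(dosages), as.character(samples$id))
    if (anyNA(m)) stop("sample metadata missing for: ",
                       paste(colnames(dosages)[is.na(m)], collapse = ", "))
    cd <- DataFrame(samples[m, setdiff(colnames(samples), "id"), drop = FALSE],
                    row.names = colnames(dosages))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosages),
    rowData = DataFrame(variants, row.names = variants$id),
    colData = cd)
  new("GenotypePanel", se)
}

#' Per-sample risk score container
#'
#' Holds one score value per sample together with the model label, the
#' processing stage (\code{raw} log-odds-weighted allele counts,
#' \code{pc_adjusted} residuals, or \code{standardized} z-scores), the
#' standardisation reference and the number of variants in the score.
#'
#' @slot sampleIds character vector of sample identifiers.
#' @slot values numeric score per sample (finite).
#' @slot modelLabel model name, e.g. \code{"PRS.AD"}.
#' @slot stage one of \code{raw}, \code{pc_adjusted}, \code{standardized}.
#' @slot reference one of \code{none}, \code{in_sample}, \code{population}.
#' @slot nSnps number of variants contributing to the score.
#' @export
setClass("ScoreSet", slots = c(sampleIds = "character", values = "numeric",
                               modelLabel = "character", stage = "character",
                               reference = "character", nSnps = "integer"))

setValidity("ScoreSet", function(object) {
  if (length(object@sampleIds) != length(object@values))
    return("sampleIds and values lengths differ")
  if (anyDuplicated(object@sampleIds)) return("sample ids must be unique")
  if (any(!is.finite(object@values))) return("score values must be finite")
  if (!object@stage %in% c("raw", "pc_adjusted", "standardized"))
    return("stage must be raw, pc_adjusted or standardized")
  if (!object@reference %in% c("none", "in_sample", "population"))
    return("reference must be none, in_sample or population")
  if (length(object@nSnps) != 1 || is.na(object@nSnps) || object@nSnps < 0)
    return("nSnps must be a single non-negative integer")
  TRUE
})

#' Construct a ScoreSet
#' @param sampleIds character sample identifiers.
#' @param values numeric scores, one per sample.
#' @param modelLabel model name carried into reports.
#' @param stage processing stage (\code{raw}, \code{pc_adjusted},
#'   \code{standardized}).
#' @param reference standardisation reference (\code{none}, \code{in_sample},
#'   \code{population}).
#' @param nSnps number of variants in the score.
#' @return A \code{\linkS4class{ScoreSet}}.
#' @export
ScoreSet <- function(sampleIds, values, modelLabel = "score", stage = "raw",
                     reference = "none", nSnps = NA_integer_) {
  if (is.na(nSnps)) nSnps <- 0L
  new("ScoreSet", sampleIds = as.character(sampleIds),
      values = as.numeric(values), modelLabel = modelLabel, stage = stage,
      reference = reference, nSnps = as.integer(nSnps))
}

#' 2x2 table of cases and controls in the score tails
#'
#' Counts of samples classified into the positive and negative extremes of a
#' standardized score distribution: \code{a} positive-tail cases, \code{b}
#' positive-tail controls, \code{c} negative-tail cases, \code{d} negative-tail
#' controls. Samples in neither tail are excluded.
#'
#' @export
setClass("TailTable", slots = c(a = "integer", b = "integer",
                                c = "integer", d = "integer"))

setValidity("TailTable", function(object) {
  cnt <- c(object@a, object@b, object@c, object@d)
  if (any(is.na(cnt)) || any(cnt < 0)) return("counts must be non-negative")
  TRUE
})

#' Construct a TailTable
#' @param a positive-tail case count.
#' @param b positive-tail control count.
#' @param c negative-tail case count.
#' @param d negative-tail control count.
#' @return A \code{\linkS4class{TailTable}}.
#' @export
TailTable <- function(a, b, c, d) {
  new("TailTable", a = as.integer(a), b = as.integer(b),
      c = as.integer(c), d = as.integer(d))
}

#' Score model specification
#'
#' The five named models: \code{ORS.full} (pT <= 1e-5), \code{ORS.no.APOE}
#' (pT <= 1e-5, APOE region excluded), \code{PRS.full} (pT <= 0.1),
#' \code{PRS.no.APOE} (pT <= 0.1, APOE region excluded) and \code{PRS.AD}
#' (PRS.no.APOE plus an APOE term with fixed per-allele log-odds weights
#' B(e2) = -0.47 and B(e4) = 1.12).
#'
#' @slot name model name.
#' @slot pT inclusion p-value threshold.
#' @slot excludeApoe whether the APOE region is removed before scoring.
#' @slot bE2,bE4 per-allele APOE isoform weights (used by PRS.AD only).
#' @export
setClass("ModelSpec", slots = c(name = "character", pT = "numeric",
                                excludeApoe = "logical",
                                bE2 = "numeric", bE4 = "numeric"))

setValidity("ModelSpec", function(object) {
  if (object@pT <= 0 || object@pT > 1) return("pT must lie in (0, 1]")
  known <- c("ORS.full", "ORS.no.APOE", "PRS.full", "PRS.no.APOE", "PRS.AD")
  if (object@name %in% known) {
    mustExclude <- object@name %in% c("ORS.no.APOE", "PRS.no.APOE", "PRS.AD")
    if (object@excludeApoe != mustExclude)
      return(sprintf("model %s must have excludeApoe = %s",
                     object@name, mustExclude))
  }
  if (!is.finite(object@bE2) || !is.finite(object@bE4))
    return("APOE weights must be finite")
  TRUE
})
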