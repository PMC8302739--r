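#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' \code{variantInfo} returns the variant metadata table; \code{nVariants} the
#' number of variants; \code{dosageMatrix} the variants x samples dosage
#' matrix; \code{sampleIds} the sample identifiers; \code{scoreValues} the
#' per-sample score values (named by sample); \code{nSnps} the number of
#' variants in a score; \code{modelLabel} and \code{scoreStage} the score's
#' label and processing stage; \code{tailCounts} the named 2x2 tail counts.
#'
#' @param x a \code{SummaryStats}, \code{GenotypePanel}, \code{ScoreSet} or
#'   \code{TailTable} as appropriate.
#' @return See description; plain base-R vectors, matrices and data frames.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname accessors
#' @export
setMethod("variantInfo", "SummaryStats", function(x) x@variants)

#' @rdname accessors
#' @export
setMethod("variantInfo", "GenotypePanel", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname accessors
#' @export
setMethod("nVariants", "SummaryStats", function(x) nrow(x@variants))

#' @rdname accessors
#' @export
setMethod("nVariants", "GenotypePanel", function(x) nrow(x))

#' @rdname accessors
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' @rdname accessors
#' @export
setMethod("dosageMatrix", "GenotypePanel", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setMethod("sampleIds", "GenotypePanel", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("sampleIds", "ScoreSet", function(x) x@sampleIds)

#' @rdname accessors
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))

#' @rdname accessors
#' @export
setMethod("scoreValues", "ScoreSet", function(x)
  stats::setNames(x@values, x@sampleIds))

#' @rdname accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname accessors
#' @export
setMethod("nSnps", "ScoreSet", function(x) x@nSnps)

#' @rdname accessors
#' @export
setGeneric("modelLabel", function(x) standardGeneric("modelLabel"))

#' @rdname accessors
#' @export
setMethod("modelLabel", "ScoreSet", function(x) x@modelLabel)

#' @rdname accessors
#' @export
setGeneric("scoreStage", function(x) standardGeneric("scoreStage"))

#' @rdname accessors
#' @export
setMethod("scoreStage", "ScoreSet", function(x) x@stage)

#' @rdname accessors
#' @export
setGeneric("tailCounts", function(x) standardGeneric("tailCounts"))

#' @rdname accessors
#' @export
setMethod("tailCounts", "TailTable", function(x)
  c(a = x@a, b = x@b, c = x@c, d = x@d))

setMethod("show", "SummaryStats", function(object) {
  v <- object@variants
  cat(sprintf("SummaryStats with %d variants on %d chromosome(s)\n",
              nrow(v), length(unique(v$chrom))))
  if (nrow(v)) {
    cat(sprintf("  p-value range: [%.3g, %.3g]\n",
                min(v$pValue), max(v$pValue)))
    print(utils::head(v, 3))
    if (nrow(v) > 3) cat(sprintf("  ... and %d more rows\n", nrow(v) - 3))
  }
})

setMethod("show", "GenotypePanel", function(object) {
  cat(sprintf("GenotypePanel: %d variants x %d samples\n",
              nrow(object), ncol(object)))
  d <- SummarizedExperiment::assay(object, "dosage")
  nm <- sum(is.na(d))
  if (nm) cat(sprintf("  missing dosages: %d (%.2f%%)\n",
                      nm, 100 * nm / length(d)))
  cd <- colnames(SummarizedExperiment::colData(object))
  if (length(cd)) cat("  sample metadata:", paste(cd, collapse = ", "), "\n")
})

setMethod("show", "ScoreSet", function(object) {
  cat(sprintf("ScoreSet '%s': %d samples, %d SNPs [stage=%s, reference=%s]\n",
              object@modelLabel, length(object@values), object@nSnps,
              object@stage, object@reference))
  if (length(object@values))
    cat(sprintf("  mean = %.4g, sd = %.4g\n",
                mean(object@values), stats::sd(object@values)))
})

setMethod("show", "TailTable", function(object) {
  m <- matrix(c(object@a, object@c, object@b, object@d), 2, 2,
              dimnames = list(c("positive", "negative"),
                              c("cases", "controls")))
  cat("TailTable (tail x status):\n")
  print(m)
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec '%s': pT <= %g, excludeApoe = %s",
              object@name, object@pT, object@excludeApoe))
  if (object@name == "PRS.AD")
    cat(sprintf(", B(e2) = %g, B(e4) = %g", object@bE2, object@bE4))
  cat("\n")
})

#' Subset summary statistics by variant id
#' @param x a SummaryStats object.
#' @param ids character vector of variant ids to keep.
#' @return A SummaryStats restricted to \code{ids} (position-sorted).
#' @export
subsetVariants <- function(x, ids) {
  stopifnot(is(x, "SummaryStats"))
  SummaryStats(x@variants[x@variants$id %in% ids, , drop = FALSE])
}
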