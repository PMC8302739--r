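#' The default APOE region
#'
#' chr19:44,400,000-46,500,000 (1-based, closed interval), the high-LD window
#' around the APOE locus that the region-excluding models remove. The bounds
#' apply to whatever genome build the inputs share; override by constructing
#' your own \code{GRanges}.
#'
#' @return A length-1 \code{GRanges}.
#' @examples apoeRegion()
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @export
apoeRegion <- function() {
  GenomicRanges::GRanges("19", IRanges::IRanges(44400000, 46500000))
}

.norm_chrom <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)

#' Remove variants inside a genomic region
#'
#' Drops every variant with the region's chromosome and a position inside the
#' closed interval \code{[start, end]}. Chromosome labels are compared after
#' stripping any "chr" prefix.
#'
#' @param stats a \code{\linkS4class{SummaryStats}}.
#' @param region a length-1 \code{GRanges}, e.g. \code{\link{apoeRegion}()}.
#' @return A filtered \code{SummaryStats}.
#' @export
excludeRegion <- function(stats, region = apoeRegion()) {
  stopifnot(is(stats, "SummaryStats"), length(region) == 1)
  chrom <- .norm_chrom(GenomicRanges::seqnames(region))
  lo <- GenomicRanges::start(region)
  hi <- GenomicRanges::end(region)
  if (lo > hi) stop("region start must not exceed end")
  v <- stats@variants
  inside <- .norm_chrom(v$chrom) == chrom & v$pos >= lo & v$pos <= hi
  SummaryStats(v[!inside, , drop = FALSE])
}

#' Filter variants by p-value threshold
#'
#' Retains exactly the records with \code{pValue <= pT} (the conventional
#' closed threshold, so a p-value equal to \code{pT} is kept).
#'
#' @param stats a \code{\linkS4class{SummaryStats}}.
#' @param pT p-value threshold in (0, 1].
#' @return A filtered \code{SummaryStats}; warns when the result is empty.
#' @export
thresholdByP <- function(stats, pT) {
  stopifnot(is(stats, "SummaryStats"))
  if (!is.numeric(pT) || length(pT) != 1 || pT <= 0 || pT > 1)
    stop("pT must be a single value in (0, 1]")
  v <- stats@variants
  out <- SummaryStats(v[v$pValue <= pT, , drop = FALSE])
  if (nVariants(out) == 0)
    warning(sprintf("no variants pass pT <= %g", pT))
  out
}
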