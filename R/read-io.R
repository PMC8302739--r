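#' Read GWAS summary statistics from a delimited text file
#'
#' Parses a tab-separated file with a header into a
#' \code{\linkS4class{SummaryStats}} object. Column names are configurable via
#' \code{columnMap}; defaults follow the common PLINK-style convention
#' (SNP, CHR, BP, A1 effect allele, A2, BETA, P, FREQ). Rows with non-ACGT or
#' multi-base alleles and rows whose numeric fields fail to parse are dropped,
#' with counts reported via \code{message} and attached as attribute
#' \code{"dropped"}. Output is sorted by (chromosome, position).
#'
#' @param path path to the TSV file.
#' @param columnMap named character vector mapping internal field names
#'   (\code{id}, \code{chrom}, \code{pos}, \code{effectAllele},
#'   \code{otherAllele}, \code{beta}, \code{pValue}, \code{eaf}) to the
#'   file's column names. \code{eaf} is optional.
#' @return A \code{SummaryStats}; attribute \code{"dropped"} holds the counts
#'   of removed rows by reason.
#' @export
readSummaryStats <- function(path,
                             columnMap = c(id = "SNP", chrom = "CHR",
                                           pos = "BP", effectAllele = "A1",
                                           otherAllele = "A2", beta = "BETA",
                                           pValue = "P", eaf = "FREQ")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  mandatory <- c("id", "chrom", "pos", "effectAllele", "otherAllele",
                 "beta", "pValue")
  missingMap <- setdiff(mandatory, names(columnMap))
  if (length(missingMap))
    stop("columnMap lacks mappings for: ", paste(missingMap, collapse = ", "))
  missingCols <- setdiff(unname(columnMap[mandatory]), colnames(raw))
  if (length(missingCols))
    stop("mandatory column(s) absent from file: ",
         paste(missingCols, collapse = ", "))

  v <- data.frame(id = raw[[columnMap[["id"]]]],
                  chrom = raw[[columnMap[["chrom"]]]],
                  pos = suppressWarnings(as.numeric(raw[[columnMap[["pos"]]]])),
                  effectAllele = toupper(raw[[columnMap[["effectAllele"]]]]),
                  otherAllele = toupper(raw[[columnMap[["otherAllele"]]]]),
                  beta = suppressWarnings(as.numeric(raw[[columnMap[["beta"]]]])),
                  pValue = suppressWarnings(as.numeric(raw[[columnMap[["pValue"]]]])),
                  stringsAsFactors = FALSE)
  if ("eaf" %in% names(columnMap) && columnMap[["eaf"]] %in% colnames(raw)) {
    v$eaf <- suppressWarnings(as.numeric(raw[[columnMap[["eaf"]]]]))
  } else {
    v$eaf <- NA_real_
  }

  badAllele <- !(v$effectAllele %in% .VALID_BASES) |
    !(v$otherAllele %in% .VALID_BASES) |
    v$effectAllele == v$otherAllele
  badNumeric <- !badAllele &
    (is.na(v$pos) | is.na(v$beta) | is.na(v$pValue) |
       v$pValue <= 0 | v$pValue > 1)
  dropped <- c(allele = sum(badAllele), numeric = sum(badNumeric))
  if (sum(dropped))
    message(sprintf("readSummaryStats: dropped %d row(s) (%d allele, %d numeric)",
                    sum(dropped), dropped[["allele"]], dropped[["numeric"]]))
  v <- v[!badAllele & !badNumeric, , drop = FALSE]
  out <- SummaryStats(v)
  attr(out, "dropped") <- dropped
  out
}

#' Write summary statistics as TSV
#' @param stats a SummaryStats object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSummaryStats <- function(stats, path) {
  stopifnot(is(stats, "SummaryStats"))
  v <- stats@variants
  out <- data.frame(SNP = v$id, CHR = v$chrom, BP = v$pos,
                    A1 = v$effectAllele, A2 = v$otherAllele,
                    BETA = v$beta, P = v$pValue, FREQ = v$eaf)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.parse_gt_dosage <- function(gt) {
  # diploid GT strings; "." anywhere -> missing; dosage = ALT allele count
  gt <- sub(":.*$", "", gt)
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) != 2 || any(a == ".") || any(is.na(a))) return(NA_real_)
    sum(a == "1")
  }, numeric(1))
}

#' Read genotypes into a GenotypePanel
#'
#' Two formats are supported. \code{"vcf"} reads a (optionally bgzipped) VCF
#' via \pkg{vcfR}; dosages count the ALT allele (the panel's effect allele),
#' missing genotypes (\code{./.}) become \code{NA}, and multi-allelic records
#' are rejected with a logged count. \code{"dosage"} reads a tab-separated
#' dosage matrix (rows = samples, columns = variants, first column the sample
#' id) together with a variant-metadata sidecar (columns \code{id},
#' \code{chrom}, \code{pos}, \code{effectAllele}, \code{otherAllele}) written
#' by \code{\link{writeGenotypePanel}}.
#'
#' @param path input file.
#' @param format \code{"vcf"} or \code{"dosage"}.
#' @param variantFile variant metadata TSV for \code{format = "dosage"};
#'   defaults to \code{paste0(path, ".variants")}.
#' @param samples optional per-sample metadata data.frame with an \code{id}
#'   column.
#' @return A \code{\linkS4class{GenotypePanel}}.
#' @export
readGenotypePanel <- function(path, format = c("dosage", "vcf"),
                              variantFile = NULL, samples = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1 | nchar(fix$ALT) != 1
    if (any(multi))
      message(sprintf("readGenotypePanel: rejected %d multi-allelic/indel record(s)",
                      sum(multi)))
    gt <- vcfR::extract.gt(vcf, element = "GT")
    keep <- which(!multi)
    if (!length(keep)) stop("no biallelic SNP records in VCF")
    dos <- t(vapply(keep, function(i) .parse_gt_dosage(gt[i, ]),
                    numeric(ncol(gt))))
    ids <- fix$ID[keep]
    ids[is.na(ids) | ids == "."] <-
      paste0(fix$CHROM[keep], ":", fix$POS[keep])[is.na(ids) | ids == "."]
    variants <- data.frame(id = ids, chrom = fix$CHROM[keep],
                           pos = as.numeric(fix$POS[keep]),
                           effectAllele = fix$ALT[keep],
                           otherAllele = fix$REF[keep],
                           stringsAsFactors = FALSE)
    colnames(dos) <- colnames(gt)
    return(GenotypePanel(dos, variants, samples = samples,
                         samplesInRows = FALSE))
  }
  if (is.null(variantFile)) variantFile <- paste0(path, ".variants")
  if (!file.exists(variantFile))
    stop("variant metadata file not found: ", variantFile,
         " (dosage matrices carry no allele information on their own)")
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  sampleIds <- as.character(tab[[1]])
  dos <- as.matrix(tab[, -1, drop = FALSE])
  mode(dos) <- "numeric"
  rownames(dos) <- sampleIds
  variants <- utils::read.delim(variantFile, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  if (!identical(as.character(variants$id), colnames(dos)))
    stop("variant metadata does not match dosage matrix columns")
  GenotypePanel(dos, variants, samples = samples, samplesInRows = TRUE)
}

#' Write a GenotypePanel as dosage TSV plus variant sidecar
#'
#' Emits \code{path} (rows = samples, columns = variants, first column
#' \code{sample}) and \code{paste0(path, ".variants")} with the variant
#' metadata, the layout \code{\link{readGenotypePanel}} reads back.
#'
#' @param panel a GenotypePanel.
#' @param path output dosage TSV path.
#' @return \code{path}, invisibly.
#' @export
writeGenotypePanel <- function(panel, path) {
  stopifnot(is(panel, "GenotypePanel"))
  d <- t(dosageMatrix(panel))
  out <- data.frame(sample = rownames(d), d, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(variantInfo(panel), paste0(path, ".variants"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' TSV with columns \code{id}, \code{status} (case/control/unknown), and
#' optionally \code{age}, \code{rs429358}, \code{rs7412}.
#'
#' @param path input TSV.
#' @return data.frame of sample metadata.
#' @export
readSampleInfo <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  s <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("id", "status") %in% colnames(s)))
    stop("sample metadata needs 'id' and 'status' columns")
  bad <- !s$status %in% c("case", "control", "unknown")
  if (any(bad)) stop("invalid status values: ",
                     paste(unique(s$status[bad]), collapse = ", "))
  s$id <- as.character(s$id)
  s
}

#' Write a ScoreSet as TSV
#'
#' Columns: sample, model, n_snps, stage, reference, value.
#'
#' @param scores a ScoreSet.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeScoreSet <- function(scores, path) {
  stopifnot(is(scores, "ScoreSet"))
  out <- data.frame(sample = scores@sampleIds, model = scores@modelLabel,
                    n_snps = scores@nSnps, stage = scores@stage,
                    reference = scores@reference, value = scores@values)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score file into a ScoreSet
#'
#' Accepts either the full layout written by \code{\link{writeScoreSet}} or a
#' minimal two-column file (sample id, value), e.g. scores produced by an
#' external PRS tool that are to be compared via \code{\link{overlapExtremes}}.
#'
#' @param path input TSV.
#' @param modelLabel label to use when the file does not carry one.
#' @param stage stage to assume for minimal two-column files.
#' @return A \code{\linkS4class{ScoreSet}}.
#' @export
readScoreSet <- function(path, modelLabel = "external", stage = "raw") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (all(c("sample", "model", "n_snps", "stage", "reference", "value")
          %in% colnames(tab))) {
    return(ScoreSet(tab$sample, tab$value, modelLabel = tab$model[1],
                    stage = tab$stage[1], reference = tab$reference[1],
                    nSnps = tab$n_snps[1]))
  }
  if (ncol(tab) < 2) stop("score file needs at least (sample, value) columns")
  ScoreSet(tab[[1]], tab[[2]], modelLabel = modelLabel, stage = stage)
}
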