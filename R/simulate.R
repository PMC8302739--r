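#' Expected fraction of hidden (putative) cases among controls
#'
#' Under Hardy-Weinberg genotype proportions at the control e4 allele
#' frequency \code{fE4}, the expected lifetime-risk mixture
#' \code{f^2 penHom + 2 f (1-f) penHet + (1-f)^2 penNon}: the proportion of
#' control-labelled individuals who will eventually develop disease. With the
#' literature penetrances (0.91 homozygote, 0.47 heterozygote, 0.20
#' non-carrier) and f = 0.142 this is about 0.28.
#'
#' @param fE4 e4 allele frequency among controls, in [0, 1].
#' @param penHom,penHet,penNon lifetime risks by e4 genotype, each in [0, 1].
#' @return Expected hidden-case proportion in [0, 1]; vectorised in its
#'   arguments.
#' @examples hiddenCaseFraction(0.142, 0.91, 0.47, 0.20)
#' @export
hiddenCaseFraction <- function(fE4, penHom = 0.91, penHet = 0.47,
                               penNon = 0.20) {
  stopifnot(all(fE4 >= 0 & fE4 <= 1),
            all(c(penHom, penHet, penNon) >= 0),
            all(c(penHom, penHet, penNon) <= 1))
  fE4^2 * penHom + 2 * fE4 * (1 - fE4) * penHet + (1 - fE4)^2 * penNon
}

.odds <- function(f) f / (1 - f)

.shift_freq_by_or <- function(f, or) {
  o <- or * .odds(f)
  o / (1 + o)
}

#' Solve case/control allele frequencies from mixture frequency and odds ratio
#'
#' Finds the unique \code{(fCase, fControl)} satisfying the two-equation
#' system: the mixture constraint
#' \code{caseProp * fCase + (1 - caseProp) * fControl = fAll} and the allelic
#' odds-ratio constraint \code{odds(fCase) / odds(fControl) = orAllelic}.
#' Solved by root-finding on \code{fControl} in (0, 1) to a residual below
#' 1e-10. With the reported whole-sample e4 frequency 0.216, OR 3.326 and
#' case proportion 0.34 this yields approximately 0.356 and 0.142.
#'
#' @param fAll overall allele frequency, in (0, 1).
#' @param orAllelic allelic odds ratio, positive.
#' @param caseProp proportion of cases in the mixture, in (0, 1).
#' @return Named numeric vector \code{c(fCase =, fControl =)}.
#' @examples solveCaseControlFreqs(0.216, 3.326, 0.34)
#' @export
solveCaseControlFreqs <- function(fAll, orAllelic, caseProp) {
  stopifnot(fAll > 0, fAll < 1, orAllelic > 0, caseProp > 0, caseProp < 1)
  g <- function(f0)
    caseProp * .shift_freq_by_or(f0, orAllelic) + (1 - caseProp) * f0 - fAll
  eps <- 1e-12
  if (g(eps) * g(1 - eps) > 0) stop("no root in (0, 1)")
  root <- stats::uniroot(g, c(eps, 1 - eps), tol = 1e-14)
  f0 <- root$root
  f1 <- .shift_freq_by_or(f0, orAllelic)
  if (abs(g(f0)) > 1e-10) stop("solver residual exceeds 1e-10")
  c(fCase = f1, fControl = f0)
}

#' Sample-size-weighted pooled allele frequency
#'
#' \code{sum(n_i f_i) / sum(n_i)} over groups.
#'
#' @param n group sizes (positive).
#' @param f group allele frequencies.
#' @return Pooled frequency.
#' @examples pooledFreq(c(10000, 2800), c(0.355, 0.36))
#' @export
pooledFreq <- function(n, f) {
  if (!length(n)) stop("empty group list")
  if (length(n) != length(f)) stop("n and f lengths differ")
  stopifnot(all(n > 0))
  sum(n * f) / sum(n)
}

#' Synthetic stand-in for the 67 oligogenic hit SNPs
#'
#' A deterministic table of 67 (frequency, beta) pairs emulating the
#' strongly-associated (pT <= 1e-5) non-APOE GWAS hits: frequencies spread
#' over [0.05, 0.45], |beta| over [0.05, 0.25] with mixed signs, and synthetic
#' p-values all at or below 1e-6. It is a synthetic stand-in, not the real
#' effect-size table (which sits behind a controlled-access accession); supply
#' your own table via \code{\link{cohortConfig}} to use real weights.
#'
#' @return data.frame with columns freq, beta, pValue.
#' @export
syntheticOligoTable <- function() {
  i <- 1:67
  freq <- 0.05 + 0.40 * ((i * 29) %% 67) / 66
  beta <- (0.25 - 0.20 * (i - 1) / 66) * ifelse(i %% 3 == 0, -1, 1)
  pValue <- 10^(-seq(30, 6, length.out = 67))
  data.frame(freq = freq, beta = beta, pValue = pValue)
}

#' Configuration of the simulated case-control cohort
#'
#' Defaults reproduce the study's simulation design: 10,000 cases and 10,000
#' controls of which 28 percent are hidden (putative) cases; an e4-like
#' large-effect SNP with allele frequency 0.355 in labelled cases, 0.36 in
#' putative controls and 0.142 in the remaining controls; 67 oligogenic SNPs
#' with supplied effect sizes; and 10,000 weak polygenic SNPs with minor
#' allele frequencies uniform on (0.01, 0.45) and reported odds ratios
#' decreasing linearly from 1.005 to 1 (cases) and 1.003 to 1 (putative
#' controls).
#'
#' \code{riskMinorProp} is the probability that a weak SNP's true risk
#' direction matches its reported minor-allele odds ratio (70 percent of weak
#' SNPs have a minor risk allele; for the remaining 30 percent the major
#' allele carries the risk while the reported effect stays attached to the
#' minor allele, so the scored weight opposes the true direction).
#'
#' @param nCase,nControl labelled cohort sizes.
#' @param hiddenFraction proportion of controls that are putative cases.
#' @param fCaseE4,fPutativeE4,fRestControlE4 e4-like SNP allele frequencies by
#'   subgroup.
#' @param oligoSnps data.frame of (freq, beta) for the oligogenic SNPs
#'   (optional pValue column; defaults to \code{\link{syntheticOligoTable}}).
#' @param nPoly number of weak polygenic SNPs.
#' @param mafLow,mafHigh bounds of the polygenic MAF distribution.
#' @param riskMinorProp probability that the minor (reported effect) allele is
#'   the true risk allele.
#' @param orMaxCase,orMaxPutative upper ends of the linear per-SNP OR grids.
#' @param seed integer seed; one RNG stream, documented draw order (variant
#'   frequencies and signs first, then e4, oligogenic and polygenic genotypes
#'   by group).
#' @return A list of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(nCase = 10000, nControl = 10000,
                         hiddenFraction = 0.28, fCaseE4 = 0.355,
                         fPutativeE4 = 0.36, fRestControlE4 = 0.142,
                         oligoSnps = syntheticOligoTable(), nPoly = 10000,
                         mafLow = 0.01, mafHigh = 0.45, riskMinorProp = 0.70,
                         orMaxCase = 1.005, orMaxPutative = 1.003, seed = 1) {
  freqs <- c(fCaseE4, fPutativeE4, fRestControlE4, oligoSnps$freq)
  if (any(freqs <= 0 | freqs >= 1)) stop("frequencies must lie in (0, 1)")
  if (hiddenFraction < 0 || hiddenFraction >= 1)
    stop("hiddenFraction must lie in [0, 1)")
  if (orMaxCase < 1 || orMaxPutative < 1) stop("or_max must be >= 1")
  if (nCase < 1 || nControl < 1) stop("cohort sizes must be positive")
  if (mafLow <= 0 || mafHigh >= 1 || mafLow >= mafHigh)
    stop("require 0 < mafLow < mafHigh < 1")
  if (!all(c("freq", "beta") %in% colnames(oligoSnps)))
    stop("oligoSnps needs freq and beta columns")
  structure(list(nCase = nCase, nControl = nControl,
                 hiddenFraction = hiddenFraction, fCaseE4 = fCaseE4,
                 fPutativeE4 = fPutativeE4, fRestControlE4 = fRestControlE4,
                 oligoSnps = oligoSnps, nPoly = nPoly, mafLow = mafLow,
                 mafHigh = mafHigh, riskMinorProp = riskMinorProp,
                 orMaxCase = orMaxCase, orMaxPutative = orMaxPutative,
                 seed = as.integer(seed)), class = "CohortConfig")
}

# Variant-level layout and group frequencies. Consumes the RNG stream seeded
# with cfg$seed; genotype draws continue on the same stream afterwards.
.cohort_variants <- function(cfg) {
  nOligo <- nrow(cfg$oligoSnps)
  autosomes <- as.character(c(1:18, 20:22))  # APOE-region chromosome reserved
  oligoChrom <- rep_len(autosomes, nOligo)
  oligoPos <- 1e6 + 3e6 * (seq_len(nOligo) %/% length(autosomes))
  polyChrom <- rep_len(autosomes, cfg$nPoly)
  polyPos <- 2e8 + 3e6 * (seq_len(cfg$nPoly) %/% length(autosomes))

  maf <- stats::runif(cfg$nPoly, cfg$mafLow, cfg$mafHigh)
  alignSign <- sample(c(1, -1), cfg$nPoly, replace = TRUE,
                      prob = c(cfg$riskMinorProp, 1 - cfg$riskMinorProp))
  betaRep <- log(seq(cfg$orMaxCase, 1, length.out = cfg$nPoly))
  betaPut <- log(seq(cfg$orMaxPutative, 1, length.out = cfg$nPoly))

  oligoBeta <- cfg$oligoSnps$beta
  oligoFreq <- cfg$oligoSnps$freq
  oligoP <- if ("pValue" %in% colnames(cfg$oligoSnps)) {
    cfg$oligoSnps$pValue
  } else {
    10^(-seq(30, 6, length.out = nOligo))
  }

  e4Beta <- log(3.326)
  nPut <- round(cfg$hiddenFraction * cfg$nControl)
  nRest <- cfg$nControl - nPut
  fCase <- c(cfg$fCaseE4, .shift_freq_by_or(oligoFreq, exp(oligoBeta)),
             .shift_freq_by_or(maf, exp(alignSign * betaRep)))
  fPut <- c(cfg$fPutativeE4, oligoFreq,
            .shift_freq_by_or(maf, exp(alignSign * betaPut)))
  fRest <- c(cfg$fRestControlE4, oligoFreq, maf)
  wAll <- c(cfg$nCase, nPut, nRest) / (cfg$nCase + cfg$nControl)
  eaf <- fCase * wAll[1] + fPut * wAll[2] + fRest * wAll[3]

  variants <- data.frame(
    id = c("e4_snp", sprintf("oligo_%03d", seq_len(nOligo)),
           sprintf("poly_%05d", seq_len(cfg$nPoly))),
    chrom = c("19", oligoChrom, polyChrom),
    pos = c(44908684, oligoPos, polyPos),
    effectAllele = "A", otherAllele = "G",
    beta = c(e4Beta, oligoBeta, betaRep),
    pValue = c(1e-50, oligoP,
               seq(2e-5, 0.099, length.out = cfg$nPoly)),
    eaf = eaf,
    stringsAsFactors = FALSE)
  list(variants = variants, fCase = fCase, fPut = fPut, fRest = fRest,
       nPut = nPut, nRest = nRest)
}

.draw_group <- function(freq, nSamples) {
  if (nSamples == 0)
    return(matrix(integer(0), nrow = length(freq), ncol = 0))
  matrix(stats::rbinom(length(freq) * nSamples, 2L, freq),
         nrow = length(freq))
}

#' Simulate the case-control cohort with hidden cases
#'
#' Draws independent per-SNP genotypes binomial(2, group frequency) for three
#' subgroups: labelled cases, putative (hidden-case) controls and remaining
#' true controls. The e4-like SNP uses the configured subgroup frequencies;
#' oligogenic SNP case frequencies are shifted from the control frequencies on
#' the odds scale by their effect sizes; weak polygenic SNPs follow the
#' reported minor-allele OR grid with the true risk direction aligned to the
#' reported one with probability \code{riskMinorProp} (see
#' \code{\link{cohortConfig}}). Putative cases are labelled as controls.
#'
#' Sample metadata carries status, the putative flag, ages consistent with the
#' design premise (cases older than the late typical onset, controls younger
#' than the early one) and rs429358/rs7412 genotype strings derived from the
#' e4-like SNP dosage (rs7412 is fixed at CC; no e2 is simulated).
#'
#' @param cfg a \code{\link{cohortConfig}}.
#' @return A list of class \code{"SimulatedCohort"}: \code{panel}
#'   (\code{\linkS4class{GenotypePanel}} with metadata in colData),
#'   \code{status}, \code{putative}, \code{truthStats} (the
#'   \code{\linkS4class{SummaryStats}} a practitioner would score with) and
#'   \code{config}.
#' @export
simulateCohort <- function(cfg) {
  stopifnot(inherits(cfg, "CohortConfig"))
  set.seed(cfg$seed)
  lay <- .cohort_variants(cfg)
  nVar <- nrow(lay$variants)
  nSamp <- cfg$nCase + cfg$nControl
  # one preallocated integer matrix, filled per subgroup in sample chunks to
  # keep transient allocations small at the default cohort size
  D <- matrix(0L, nrow = nVar, ncol = nSamp)
  groupCols <- list(seq_len(cfg$nCase),
                    cfg$nCase + seq_len(lay$nPut),
                    cfg$nCase + lay$nPut + seq_len(lay$nRest))
  groupFreq <- list(lay$fCase, lay$fPut, lay$fRest)
  chunk <- 2000L
  for (g in 1:3) {
    cols <- groupCols[[g]]
    freq <- groupFreq[[g]]
    if (!length(cols)) next
    for (s in seq(1L, length(cols), by = chunk)) {
      idx <- cols[s:min(s + chunk - 1L, length(cols))]
      D[, idx] <- stats::rbinom(nVar * length(idx), 2L, freq)
    }
  }
  status <- rep(c("case", "control"), c(cfg$nCase, cfg$nControl))
  putative <- rep(c(FALSE, TRUE, FALSE), c(cfg$nCase, lay$nPut, lay$nRest))
  e4dos <- D[1, ]
  samples <- data.frame(
    id = sprintf("sim_%05d", seq_len(nSamp)),
    status = status, putative = putative,
    age = ifelse(status == "case", 87, 55),
    rs429358 = c("TT", "CT", "CC")[e4dos + 1L],
    rs7412 = "CC",
    stringsAsFactors = FALSE)
  dimnames(D) <- list(lay$variants$id, samples$id)
  panel <- GenotypePanel(D, lay$variants[, c("id", "chrom", "pos",
                                             "effectAllele", "otherAllele")],
                         samples = samples, samplesInRows = FALSE)
  structure(list(panel = panel, status = status, putative = putative,
                 truthStats = SummaryStats(lay$variants), config = cfg),
            class = "SimulatedCohort")
}

#' Simulate a neutral population panel matching a cohort's variants
#'
#' Draws a genotype panel at the true-control allele frequencies of the same
#' variant set a \code{\link{simulateCohort}} call would produce for
#' \code{cfg} (the variant-level randomness is regenerated from
#' \code{cfg$seed}, so the panels share variants and frequencies), with
#' genotype draws seeded by \code{seed}. Serves as the population reference
#' for population-based standardisation experiments.
#'
#' @param cfg a \code{\link{cohortConfig}}.
#' @param nSamples number of population samples.
#' @param seed genotype-draw seed (default \code{cfg$seed + 1}).
#' @return A \code{\linkS4class{GenotypePanel}} with rs429358/rs7412 genotype
#'   strings in colData.
#' @export
simulatePopulationPanel <- function(cfg, nSamples, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "CohortConfig"), nSamples >= 1)
  set.seed(cfg$seed)
  lay <- .cohort_variants(cfg)
  set.seed(seed)
  D <- .draw_group(lay$fRest, nSamples)
  samples <- data.frame(
    id = sprintf("pop_%05d", seq_len(nSamples)),
    status = "unknown",
    rs429358 = c("TT", "CT", "CC")[D[1, ] + 1L],
    rs7412 = "CC", stringsAsFactors = FALSE)
  colnames(D) <- samples$id
  GenotypePanel(D, lay$variants[, c("id", "chrom", "pos", "effectAllele",
                                    "otherAllele")],
                samples = samples, samplesInRows = FALSE)
}

#' Correlated LD-block fixture panel
#'
#' Builds a genotype panel of independent LD blocks. Within a block every SNP
#' copies a latent block genotype allele-by-allele with probability
#' \code{q = r2^(1/4)} (else draws a fresh allele at the block MAF), which
#' makes the expected between-SNP dosage correlation \code{q^2} and hence the
#' expected pairwise r-squared equal to the target. Blocks are placed far
#' apart (different positions, 10 kb SNP spacing within a block) so clumping
#' windows only ever span one block. Deterministic synthetic summary
#' statistics are attached: p-values increase with SNP index within a block
#' (the first SNP of each block is the strongest), betas are 0.1.
#'
#' @param seed RNG seed.
#' @param nSamples samples to draw.
#' @param blockSpec data.frame with columns \code{size}, \code{r2}, \code{maf}
#'   (one row per block).
#' @return \code{list(panel =, stats =)}.
#' @export
makeLdFixture <- function(seed, nSamples,
                          blockSpec = data.frame(size = 5, r2 = 0.9,
                                                 maf = 0.3)) {
  stopifnot(all(c("size", "r2", "maf") %in% colnames(blockSpec)))
  if (any(blockSpec$r2 < 0 | blockSpec$r2 > 1))
    stop("infeasible r2 target (must lie in [0, 1])")
  if (any(blockSpec$maf <= 0 | blockSpec$maf >= 1))
    stop("block MAF must lie in (0, 1)")
  set.seed(seed)
  dosBlocks <- list(); varBlocks <- list()
  for (b in seq_len(nrow(blockSpec))) {
    size <- blockSpec$size[b]; maf <- blockSpec$maf[b]
    q <- blockSpec$r2[b]^(1 / 4)
    latent <- matrix(stats::rbinom(nSamples * 2L, 1L, maf), nSamples, 2)
    d <- matrix(0L, nrow = size, ncol = nSamples)
    for (s in seq_len(size)) {
      keep <- matrix(stats::runif(nSamples * 2L) < q, nSamples, 2)
      fresh <- matrix(stats::rbinom(nSamples * 2L, 1L, maf), nSamples, 2)
      alleles <- ifelse(keep, latent, fresh)
      d[s, ] <- as.integer(rowSums(alleles))
    }
    dosBlocks[[b]] <- d
    varBlocks[[b]] <- data.frame(
      id = sprintf("blk%d_snp%d", b, seq_len(size)),
      chrom = as.character(b), pos = 1e6 + 1e4 * (seq_len(size) - 1),
      effectAllele = "A", otherAllele = "G", beta = 0.1,
      pValue = 10^(-(8 - seq_len(size) + 1)), eaf = maf,
      stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, varBlocks)
  D <- do.call(rbind, dosBlocks)
  colnames(D) <- sprintf("fx_%04d", seq_len(nSamples))
  list(panel = GenotypePanel(D, variants[, 1:5], samplesInRows = FALSE),
       stats = SummaryStats(variants))
}

#' Write a simulated cohort to plain-text files
#'
#' Emits the dosage TSV + variant sidecar (via
#' \code{\link{writeGenotypePanel}}), a sample-metadata TSV and the truth
#' summary statistics, so the full pipeline can be run end-to-end on the
#' files.
#'
#' @param cohort a \code{"SimulatedCohort"}.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "SimulatedCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(dosages = file.path(dir, "cohort_dosages.tsv"),
             samples = file.path(dir, "cohort_samples.tsv"),
             stats = file.path(dir, "cohort_truth_stats.tsv"))
  writeGenotypePanel(cohort$panel, paths[["dosages"]])
  cd <- as.data.frame(SummarizedExperiment::colData(cohort$panel))
  utils::write.table(cbind(id = colnames(cohort$panel), cd),
                     paths[["samples"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeSummaryStats(cohort$truthStats, paths[["stats"]])
  invisible(paths)
}
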