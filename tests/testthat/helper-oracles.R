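# Independent reference implementations used as oracles. These deliberately
# share no code with the package: plain loops and base stats only.

# Exhaustive greedy clumping: repeatedly take the remaining variant with the
# smallest p (ties by chrom then pos), drop all remaining variants on the same
# chromosome within the window whose squared correlation exceeds r2max.
oracle_clump <- function(variants, dosage, r2max, window_bp) {
  remaining <- seq_len(nrow(variants))
  kept <- integer(0)
  while (length(remaining)) {
    o <- remaining[order(variants$pValue[remaining],
                         variants$chrom[remaining],
                         variants$pos[remaining])][1]
    kept <- c(kept, o)
    remaining <- setdiff(remaining, o)
    drop <- integer(0)
    for (j in remaining) {
      if (variants$chrom[j] == variants$chrom[o] &&
          abs(variants$pos[j] - variants$pos[o]) <= window_bp) {
        x <- dosage[o, ]; y <- dosage[j, ]
        ok <- !is.na(x) & !is.na(y)
        r2 <- if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
          0
        } else {
          stats::cor(x[ok], y[ok])^2
        }
        if (r2 > r2max) drop <- c(drop, j)
      }
    }
    remaining <- setdiff(remaining, drop)
  }
  sort(variants$id[kept])
}

# Brute-force concordance AUC: count case-control pairs where the case wins,
# ties counting one half.
oracle_auc <- function(values, is_case) {
  cases <- values[is_case]; controls <- values[!is_case]
  wins <- 0
  for (u in cases) for (v in controls)
    wins <- wins + (u > v) + 0.5 * (u == v)
  100 * wins / (length(cases) * length(controls))
}

# Random panel with partial LD and clustered positions, for clump oracle runs.
random_clump_panel <- function(seed, n_variants = 12, n_samples = 60) {
  set.seed(seed)
  chrom <- sample(c("1", "2"), n_variants, replace = TRUE)
  pos <- sample(seq(1e5, 2.5e6, by = 1e4), n_variants)
  latent <- rbinom(n_samples, 2, 0.45)
  dosage <- matrix(0L, n_variants, n_samples)
  for (i in seq_len(n_variants)) {
    mix <- runif(1) < 0.6  # some variants track the latent genotype
    dosage[i, ] <- if (mix) {
      pmin(2L, pmax(0L, latent + rbinom(n_samples, 1, 0.3) -
                      rbinom(n_samples, 1, 0.3)))
    } else {
      rbinom(n_samples, 2, runif(1, 0.1, 0.5))
    }
  }
  variants <- data.frame(id = sprintf("v%02d", seq_len(n_variants)),
                         chrom = chrom, pos = pos,
                         effectAllele = "A", otherAllele = "G",
                         beta = round(rnorm(n_variants, 0, 0.1), 3),
                         pValue = signif(runif(n_variants, 1e-8, 0.5), 3),
                         eaf = NA_real_, stringsAsFactors = FALSE)
  list(variants = variants, dosage = dosage)
}

# Small deterministic panel + stats used across tests.
tiny_fixture <- function() {
  variants <- data.frame(
    id = c("rsA", "rsB", "rsC", "rsD"),
    chrom = c("1", "1", "18", "19"),
    pos = c(1e5, 2e5, 4.5e7, 4.5e7),  # rsD sits inside the APOE region
    effectAllele = c("A", "C", "G", "T"),
    otherAllele = c("G", "T", "A", "C"),
    beta = c(0.2, -0.1, 0.05, 1.0),
    pValue = c(1e-9, 1e-6, 0.02, 1e-30),
    eaf = c(0.3, 0.4, 0.25, 0.15), stringsAsFactors = FALSE)
  dosage <- rbind(c(0, 1, 2, 1, 0, 2),
                  c(1, 1, 0, 2, 1, 0),
                  c(2, 0, 1, 1, 2, 1),
                  c(0, 2, 1, 0, 1, 2))
  samples <- data.frame(
    id = sprintf("s%d", 1:6),
    status = c("case", "case", "case", "control", "control", "control"),
    age = c(62, 68, 77, 88, 59, 71),
    rs429358 = c("TT", "CT", "CC", "TT", "CT", "TT"),
    rs7412 = c("CC", "CC", "CC", "CT", "CC", "TT"),
    stringsAsFactors = FALSE)
  list(panel = GenotypePanel(dosage, variants[, 1:5], samples = samples,
                             samplesInRows = FALSE),
       stats = SummaryStats(variants), samples = samples)
}
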