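# Shared fixture builders. Everything is generated in code at test time.

# Wrap a bare dosage matrix in a genotype_dataset with a generic map/fam.
toy_dataset <- function(geno, chr = NULL, pos = NULL) {
  geno <- as.matrix(geno)
  m <- ncol(geno); n <- nrow(geno)
  if (is.null(chr)) chr <- rep("chr01", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  map <- data.frame(snp = sprintf("snp%04d", seq_len(m)),
                    chr = chr, pos = pos, a1 = "A", a2 = "B",
                    stringsAsFactors = FALSE)
  fam <- data.frame(fid = "F1", iid = sprintf("I%03d", seq_len(n)),
                    sire = "0", dam = "0", sex = "0",
                    stringsAsFactors = FALSE)
  genotype_dataset(geno, map, fam)
}

# Random dosage matrix with per-marker frequency strictly below 0.5 so the
# minor-allele polarity is unambiguous on PLINK round trips.
random_minor_dataset <- function(n, m, miss_rate = 0, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.4)
  geno <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m, byrow = FALSE)
  # regenerate any column that drifted to >= 0.5 or went monomorphic
  for (j in seq_len(m)) {
    while (mean(geno[, j]) / 2 >= 0.5 || var(geno[, j]) == 0) {
      geno[, j] <- rbinom(n, 2L, p[j])
    }
  }
  if (miss_rate > 0) {
    geno[matrix(runif(n * m) < miss_rate, n, m)] <- NA_integer_
  }
  toy_dataset(geno, chr = rep(c("chr01", "chr02"), length.out = m))
}

# One moderate family-structured simulation reused across test files
# (computed at most once per file thanks to the local cache).
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

family_sim <- function() {
  cached("family_sim", {
    cfg <- sim_config(n_families = 120L, offspring_per_family = 8L,
                      n_snps = 2000L, n_chromosomes = 20L,
                      chrom_lengths = 40e6, h2_true = 0.5,
                      n_qtl = 300L, seed = 2024L)
    simulate_dataset(cfg)
  })
}
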