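test_that("simulation is a pure function of its configuration", {
  cfg <- sim_config(n_families = 10L, offspring_per_family = 5L,
                    n_snps = 200L, n_chromosomes = 4L,
                    chrom_lengths = 20e6, h2_true = 0.3, n_qtl = 50L,
                    seed = 7L)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$genotypes$geno, b$genotypes$geno)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth$true_breeding_values, b$truth$true_breeding_values)
})

test_that("founder allele frequencies follow the configured interval", {
  # degenerate interval: every SNP at 0.5
  cfg <- sim_config(n_families = 300L, offspring_per_family = 1L,
                    n_snps = 1000L, n_chromosomes = 5L, chrom_lengths = 30e6,
                    maf_range = c(0.5, 0.5), n_parents = 600L, seed = 5L)
  fo <- simulate_founders(cfg)
  phat <- colMeans(fo$geno) / 2
  expect_gt(mean(abs(phat - 0.5) < 0.05), 0.99)

  # uniform interval: realized frequencies look like a uniform draw
  cfg2 <- sim_config(n_families = 250L, offspring_per_family = 1L,
                     n_snps = 5000L, n_chromosomes = 5L, chrom_lengths = 30e6,
                     maf_range = c(0.05, 0.5), n_parents = 500L, seed = 6L)
  fo2 <- simulate_founders(cfg2)
  phat2 <- colMeans(fo2$geno) / 2
  set.seed(99)
  direct <- runif(5000, 0.05, 0.5)
  ks <- suppressWarnings(ks.test(phat2, direct))
  expect_gt(ks$p.value, 0.01)

  expect_error(sim_config(n_families = 2L, offspring_per_family = 2L,
                          n_snps = 10L, maf_range = c(0, 0.5)),
               "maf_range")
})

test_that("gene dropping follows the Haldane model", {
  m <- 1001L
  map <- data.frame(snp = sprintf("s%04d", 1:m), chr = "chr01",
                    pos = seq(1, 100e6 + 1, length.out = m),
                    a1 = "A", a2 = "B")
  haps <- rbind(rep(0L, m), rep(1L, m))

  # zero recombination: exact copy of one parental strand
  set.seed(1)
  for (i in 1:20) {
    g <- drop_gamete(haps, map, cm_per_mb = 0)
    expect_true(all(g == 0L) || all(g == 1L))
  }

  # 100 cM map: mean observable crossover count ~ 1 over 10,000 gametes
  set.seed(2)
  switches <- replicate(10000, sum(diff(drop_gamete(haps, map, 1)) != 0))
  expect_equal(mean(switches), 1.0, tolerance = 0.05)

  # two loci 50 cM apart: Haldane recombinant fraction (1 - exp(-1))/2
  map2 <- data.frame(snp = c("a", "b"), chr = "chr01",
                     pos = c(1, 50e6 + 1), a1 = "A", a2 = "B")
  haps2 <- rbind(c(0L, 0L), c(1L, 1L))
  set.seed(3)
  rec <- replicate(10000, {
    g <- drop_gamete(haps2, map2, 1)
    g[1] != g[2]
  })
  expect_equal(mean(rec), (1 - exp(-1)) / 2, tolerance = 0.02)

  bad_map <- data.frame(snp = c("a", "b"), chr = "chr01",
                        pos = c(10, 5), a1 = "A", a2 = "B")
  expect_error(drop_gamete(haps2, bad_map, 1), "sorted")
})

test_that("offspring genotypes are Mendelian-consistent with their parents", {
  sim <- family_sim()
  off <- sim$genotypes
  fo <- attr(off, "founders")
  stopifnot(!is.null(fo))
  fo_geno <- fo$geno
  rownames(fo_geno) <- fo$fam$iid
  sire_g <- fo_geno[off$fam$sire, , drop = FALSE]
  dam_g <- fo_geno[off$fam$dam, , drop = FALSE]
  # gamete from a parent with dosage 0 is 0, dosage 2 is 1, dosage 1 is 0 or 1
  lo <- (sire_g == 2L) + (dam_g == 2L)
  hi <- 2L - (sire_g == 0L) - (dam_g == 0L)
  expect_true(all(off$geno >= lo & off$geno <= hi))
  expect_true(all(off$geno %in% 0:2))
})

test_that("realized relationships are ~0.5 within and ~0 between families", {
  sim <- family_sim()
  G <- build_grm(sim$genotypes)$G
  fid <- sim$genotypes$fam$fid
  same_fam <- outer(fid, fid, "==")
  ut <- upper.tri(G)
  sib_mean <- mean(G[ut & same_fam])
  unrel_mean <- mean(G[ut & !same_fam])
  expect_equal(sib_mean, 0.5, tolerance = 0.02)
  expect_lt(abs(unrel_mean), 0.02)
  # bimodality: the two groups barely overlap
  expect_gt(stats::quantile(G[ut & same_fam], 0.05), 0.3)
  expect_lt(stats::quantile(G[ut & !same_fam], 0.95), 0.2)
})

test_that("zero heritability yields phenotypes independent of genotype", {
  cfg <- sim_config(n_families = 100L, offspring_per_family = 10L,
                    n_snps = 300L, n_chromosomes = 5L, chrom_lengths = 30e6,
                    h2_true = 0, n_qtl = 50L, seed = 11L)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$truth$true_breeding_values == 0))
  expect_equal(sim$truth$realized_h2, 0)
  set.seed(12)
  cors <- sapply(sample.int(300, 10), function(j) {
    cor(sim$genotypes$geno[, j], sim$phenotypes$trait)
  })
  expect_lt(mean(abs(cors)), 0.05)
})

test_that("censoring produces integer days in 1..censor_day", {
  cfg <- sim_config(n_families = 23L, offspring_per_family = 10L,
                    n_snps = 500L, n_chromosomes = 5L, chrom_lengths = 30e6,
                    h2_true = 0.49, n_qtl = 100L, censor_day = 8L,
                    trait_name = "days_to_death", seed = 13L)
  sim <- simulate_dataset(cfg)
  y <- sim$phenotypes$days_to_death
  expect_true(all(y == as.integer(y)))
  expect_true(all(y >= 1 & y <= 8))
  expect_equal(sort(unique(y)), 1:8)
  # monotone binning preserves the genetic signal
  expect_gt(cor(sim$truth$true_breeding_values, y), 0.3)
})

test_that("a planted fixed effect is recovered by the mixed model", {
  cfg <- sim_config(n_families = 80L, offspring_per_family = 10L,
                    n_snps = 1000L, n_chromosomes = 10L, chrom_lengths = 40e6,
                    h2_true = 0.3, n_qtl = 200L,
                    fixed_effects = list(list(name = "tank", n_levels = 2L,
                                              effects = c(0, 0.5))),
                    seed = 21L)
  sim <- simulate_dataset(cfg)
  grm <- build_grm(sim$genotypes)
  vc <- fit_genomic_model(grm, sim$phenotypes, "trait", "tank")
  # level shift was 0.5 phenotypic SD (SD ~ 1); levels are labelled tank1/tank2
  contrast <- vc$b[["tanktank2"]]
  expect_equal(unname(contrast), 0.5, tolerance = 0.15)
})

test_that("presets match the published population structures", {
  specs <- list(
    carp = c(fam = 195L, n = 1211L, snps = 6966L),
    oyster = c(fam = 23L, n = 718L, snps = 14028L),
    salmon = c(fam = 85L, n = 1481L, snps = 9866L),
    seabream = c(fam = 73L, n = 741L, snps = 7598L))
  h2s <- c(carp = 0.27, oyster = 0.49, salmon = 0.24, seabream = 0.20)
  for (nm in names(specs)) {
    cfg <- sim_preset(nm)
    expect_equal(cfg$n_families, unname(specs[[nm]]["fam"]))
    expect_equal(sum(cfg$offspring_per_family), unname(specs[[nm]]["n"]))
    expect_equal(cfg$n_snps, unname(specs[[nm]]["snps"]))
    expect_equal(cfg$h2_true, unname(h2s[nm]))
    expect_lte(max(cfg$offspring_per_family) -
                 min(cfg$offspring_per_family), 1L)
  }
  expect_equal(sim_preset("oyster")$censor_day, 8L)
  expect_equal(sim_preset("carp")$transform, "log")
  expect_error(make_families(sim_config(n_families = 5L,
                                        offspring_per_family = 2L,
                                        n_snps = 50L, n_qtl = 10L,
                                        n_parents = 10L),
                             founders = NULL), NA)
})

test_that("log-transformed traits are recovered exactly on the analysis scale", {
  cfg <- sim_config(n_families = 10L, offspring_per_family = 5L,
                    n_snps = 100L, n_chromosomes = 2L, chrom_lengths = 20e6,
                    h2_true = 0.3, n_qtl = 20L, transform = "log", seed = 3L)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$phenotypes$trait > 0))
  back <- analysis_phenotypes(sim$phenotypes, cfg)
  skewed <- sim$phenotypes$trait
  expect_equal(back$trait, log(skewed))
})
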