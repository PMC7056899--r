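test_that("allele frequencies match a per-marker recount", {
  expect_equal(unname(allele_frequencies(toy_dataset(matrix(1L, 5, 1)))), 0.5)
  expect_equal(unname(allele_frequencies(toy_dataset(matrix(0:2, 3, 1)))), 0.5)
  ds <- random_minor_dataset(30, 40, miss_rate = 0.1, seed = 9)
  f <- allele_frequencies(ds)
  recount <- sapply(seq_len(40), function(j) {
    v <- ds$geno[, j]
    sum(v, na.rm = TRUE) / (2 * sum(!is.na(v)))
  })
  expect_equal(unname(f), recount, tolerance = 1e-15)
  all_na <- toy_dataset(matrix(NA_integer_, 4, 2))
  expect_error(allele_frequencies(all_na), "non-missing")
})

test_that("G matches a brute-force double loop on explicit dosages", {
  geno <- matrix(c(0L, 1L, 2L,
                   2L, 1L, 0L,
                   1L, 1L, 1L,
                   0L, 2L, 2L), nrow = 3)
  p <- c(0.25, 0.4, 0.5, 0.3)
  ds <- toy_dataset(geno)
  G <- build_grm(ds, freqs = p)$G
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (k in 1:3) {
    s <- 0
    for (l in 1:4) {
      s <- s + (geno[i, l] - 2 * p[l]) * (geno[k, l] - 2 * p[l]) /
        (2 * p[l] * (1 - p[l]))
    }
    oracle[i, k] <- s / 4
  }
  expect_equal(unname(G), oracle, tolerance = 1e-12)
  expect_true(isSymmetric(G, tol = 1e-10))
})

test_that("identical genotype rows give identical relationship entries", {
  ds <- random_minor_dataset(8, 50, seed = 3)
  geno <- ds$geno
  geno[2, ] <- geno[1, ]
  poly <- apply(geno, 2, var) > 0
  G <- build_grm(toy_dataset(geno[, poly]))$G
  expect_equal(G[1, 2], G[1, 1])
  expect_equal(G[1, 2], G[2, 2])
})

test_that("unrelated HWE individuals give diag ~ 1 and off-diag ~ 0", {
  set.seed(77)
  n <- 200L; m <- 10000L
  p <- runif(m, 0.05, 0.5)
  geno <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  G <- build_grm(toy_dataset(geno,
                             chr = rep("chr01", m),
                             pos = seq_len(m)))$G
  expect_lt(abs(mean(diag(G)) - 1), 0.02)
  expect_lt(abs(mean(G[upper.tri(G)])), 0.02)
})

test_that("missing-data policies agree with their own oracles", {
  ds <- random_minor_dataset(12, 60, miss_rate = 0.1, seed = 21)
  p <- allele_frequencies(ds)
  Gp <- build_grm(ds, missing_policy = "pairwise")$G
  x <- ds$geno
  # pairwise oracle for one pair
  i <- 1; k <- 2
  shared <- which(!is.na(x[i, ]) & !is.na(x[k, ]))
  o <- mean((x[i, shared] - 2 * p[shared]) * (x[k, shared] - 2 * p[shared]) /
              (2 * p[shared] * (1 - p[shared])))
  expect_equal(Gp[i, k], o, tolerance = 1e-12)
  # mean imputation: missing entries contribute zero
  Gm <- build_grm(ds, missing_policy = "mean_impute")$G
  W <- sweep(sweep(ds$geno, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  W[is.na(W)] <- 0
  expect_equal(unname(Gm), unname(tcrossprod(W) / ncol(W)), tolerance = 1e-12)
})

test_that("inversion is exact, ridged only when singular, and audited", {
  I5 <- diag(5)
  rownames(I5) <- colnames(I5) <- letters[1:5]
  inv <- invert_grm(I5)
  expect_equal(unname(inv$Ginv), diag(5), tolerance = 1e-12)
  expect_equal(inv$ridge, 0)

  # duplicated individual: exactly singular, needs a recorded ridge
  dsd <- random_minor_dataset(8, 80, seed = 5)
  genod <- dsd$geno
  genod[2, ] <- genod[1, ]
  polyd <- apply(genod, 2, var) > 0
  G <- build_grm(toy_dataset(genod[, polyd]))$G
  expect_message(invd <- invert_grm(G), "ridge")
  expect_gt(invd$ridge, 0)
  expect_lt(invd$max_residual, 1e-6)

  # random PSD + explicit ridge: residual at 1e-8
  set.seed(6)
  A <- crossprod(matrix(rnorm(100), 10))
  r <- invert_grm(A, ridge = 1e-3)
  expect_lt(max(abs((A + diag(1e-3, 10)) %*% r$Ginv - diag(10))), 1e-8)

  expect_error(invert_grm(matrix(1:4, 2)), "symmetric")
})

test_that("panel G uses frequencies re-estimated on the panel's markers", {
  sim <- family_sim()
  ds <- sim$genotypes
  pn <- sample_panel(ds, 400, seed = 31)
  grm <- build_grm(subset_markers(ds, pn$snp_ids))
  expect_length(grm$freqs, 400)
  expect_equal(unname(grm$freqs),
               unname(allele_frequencies(subset_markers(ds, pn$snp_ids))))
})

test_that("both panel strategies yield matching full-sib relationship scale", {
  sim <- family_sim()
  ds <- sim$genotypes
  fid <- ds$fam$fid
  same <- outer(fid, fid, "==")
  ut <- upper.tri(diag(n_individuals(ds)))
  sib_mean <- function(pn) {
    G <- build_grm(subset_markers(ds, pn$snp_ids))$G
    mean(G[ut & same])
  }
  m1 <- sib_mean(sample_panel(ds, 500, "genomewide_random", seed = 41))
  m2 <- sib_mean(sample_panel(ds, 500, "within_chromosome_proportional",
                              seed = 41))
  expect_equal(m1, m2, tolerance = 0.05)
  expect_equal(m1, 0.5, tolerance = 0.05)
})

test_that("relationship matrices serialize as full and sparse text", {
  ds <- random_minor_dataset(6, 30, seed = 14)
  grm <- build_grm(ds)
  dir <- withr::local_tempdir()
  full <- write_grm(grm, file.path(dir, "g"), "full")
  tab <- read.delim(full, check.names = FALSE)
  expect_equal(as.matrix(tab[, -1]), grm$G, tolerance = 1e-12,
               ignore_attr = TRUE)
  sp <- write_grm(grm, file.path(dir, "g"), "sparse")
  tri <- read.table(sp)
  expect_equal(nrow(tri), 6 * 7 / 2)
  expect_equal(tri$V3[1], grm$G[1, 1], tolerance = 1e-12)
})
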