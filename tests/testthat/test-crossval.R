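# Small family simulation + panel shared by the CV tests.
cv_fixture <- function() {
  cached("cv_fixture", {
    cfg <- sim_config(n_families = 40L, offspring_per_family = 8L,
                      n_snps = 600L, n_chromosomes = 10L,
                      chrom_lengths = 40e6, h2_true = 0.4, n_qtl = 150L,
                      seed = 99L)
    sim <- simulate_dataset(cfg)
    list(sim = sim,
         panel = sample_panel(sim$genotypes, 300, seed = 5,
                              replicate_index = 1L),
         folds = make_folds(sim$phenotypes$id, k = 5,
                            replicate_seeds = c(11L, 12L)))
  })
}

test_that("folds partition the ids into near-equal parts", {
  f10 <- make_folds(sprintf("i%02d", 1:10), k = 5, replicate_seeds = 1L)
  expect_equal(unname(table(f10[[1]]$fold)), rep(2L, 5), ignore_attr = TRUE)
  f11 <- make_folds(sprintf("i%02d", 1:11), k = 5, replicate_seeds = 1L)
  expect_equal(sort(as.integer(table(f11[[1]]$fold)), decreasing = TRUE),
               c(3L, 2L, 2L, 2L, 2L))
  expect_error(make_folds(letters, k = 1), "at least 2")

  set.seed(8)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    k <- sample(2:min(n, 10), 1)
    ids <- sprintf("x%03d", sample(1000, n))
    fa <- make_folds(ids, k, replicate_seeds = i)[[1]]
    expect_setequal(names(fa$fold), ids)
    sizes <- table(fa$fold)
    expect_lte(max(sizes) - min(sizes), 1)
    expect_equal(sum(sizes), n)
  }
})

test_that("accuracy is r / sqrt(h2_ref), hand-checked", {
  v <- c(1.2, 0.3, -0.5, 2.0, 0.7)
  expect_equal(accuracy(v, v, 1), 1.0)
  expect_equal(accuracy(v, v, 0.25), 2.0)
  # hand Pearson: pred (1..5), obs (2,1,4,3,5): sum xy dev = 8, sds give
  # r = 8/10 = 0.8
  expect_equal(accuracy(1:5, c(2, 1, 4, 3, 5), 0.5), 0.8 / sqrt(0.5),
               tolerance = 1e-12)
  expect_error(accuracy(1:5, rep(1, 5), 0.5), "constant")
  expect_error(accuracy(1:5, c(2, 1, 4, 3, 5), 0), "h2_ref")
})

test_that("cross-validation is deterministic and within a plausible band", {
  fx <- cv_fixture()
  sim <- fx$sim
  res1 <- run_cv(sim$genotypes, sim$phenotypes, "trait",
                 panel = fx$panel, folds = fx$folds, h2_ref = 0.4)
  res2 <- run_cv(sim$genotypes, sim$phenotypes, "trait",
                 panel = fx$panel, folds = fx$folds, h2_ref = 0.4)
  expect_identical(res1, res2)
  expect_equal(nrow(res1), 10)  # 2 replicates x 5 folds
  expect_true(all(res1$converged))
  expect_true(all(abs(res1$r) <= 1))
  m <- mean(res1$accuracy)
  expect_gt(m, 0.3); expect_lt(m, 1.0)
})

test_that("validation phenotypes never leak into training", {
  fx <- cv_fixture()
  sim <- fx$sim
  folds <- fx$folds[1]
  ph <- sim$phenotypes
  val_ids <- names(folds[[1]]$fold)[folds[[1]]$fold == 1]
  ph2 <- ph
  ph2$trait[ph2$id %in% val_ids] <- ph2$trait[ph2$id %in% val_ids] + 100
  res_a <- run_cv(sim$genotypes, ph, "trait", panel = fx$panel,
                  folds = folds, h2_ref = 0.4)
  res_b <- run_cv(sim$genotypes, ph2, "trait", panel = fx$panel,
                  folds = folds, h2_ref = 0.4)
  # the fold where those individuals are the validation set: identical
  # training-side estimates
  expect_equal(res_a$h2_train[res_a$fold == 1],
               res_b$h2_train[res_b$fold == 1], tolerance = 1e-12)

  # and at the solver level: masked phenotypes cannot enter by construction
  grm <- build_grm(subset_markers(sim$genotypes, fx$panel$snp_ids))
  train_ids <- setdiff(ph$id, val_ids)
  y <- ph$trait[match(train_ids, ph$id)]
  names(y) <- train_ids
  vc <- fit_reml(y, NULL, grm$G[train_ids, train_ids])
  a1 <- solve_gblup(y, NULL, grm, vc)$a_hat
  a2 <- solve_gblup(y, NULL, grm, vc)$a_hat  # same inputs, same output
  expect_identical(a1, a2)
})

test_that("accuracy curves aggregate to the documented proportions", {
  rows <- function(density, panel, acc) {
    data.frame(density = density, panel_replicate = panel,
               cv_replicate = 1L, fold = seq_along(acc),
               n_validation = 10L, r = acc * sqrt(0.4), accuracy = acc,
               h2_train = 0.4, converged = TRUE)
  }
  tab <- rbind(rows(5000L, 1L, c(0.6, 0.6)),
               rows(1000L, 1L, c(0.52, 0.56)),
               rows(1000L, 2L, c(0.54, 0.54)))
  curve <- accuracy_curve(tab, full_density = 5000L)
  expect_equal(curve$proportion_full[curve$density == 5000], 1.0)
  expect_equal(curve$proportion_full[curve$density == 1000], 0.9)
  expect_equal(curve$range_panels[curve$density == 1000],
               abs(mean(c(0.52, 0.56)) - 0.54))
  expect_error(accuracy_curve(tab, full_density = 9999L), "full density")
})

test_that("loess smoothing reproduces constants, quadratics and an
           independent tricube implementation", {
  x <- seq(0, 1, length.out = 30)
  expect_equal(loess_smooth(x, rep(3, 30)), rep(3, 30), tolerance = 1e-10)
  yq <- 2 - 3 * x + 0.5 * x^2
  expect_lt(max(abs(loess_smooth(x, yq, span = 1) - yq)), 1e-8)
  expect_error(loess_smooth(x, yq, span = 0), "span")

  # independent local quadratic regression with tricube weights
  tricube_fit <- function(x, y, span) {
    n <- length(x); q <- floor(n * span)
    vapply(x, function(x0) {
      d <- abs(x - x0)
      dq <- sort(d)[q]
      w <- pmax(0, 1 - pmin(d / dq, 1)^3)^3
      Xl <- cbind(1, x - x0, (x - x0)^2)
      stats::lm.wfit(Xl, y, w)$coefficients[1]
    }, numeric(1))
  }
  set.seed(19)
  xs <- sort(runif(40)); ys <- sin(6 * xs) + rnorm(40, sd = 0.2)
  expect_lt(max(abs(loess_smooth(xs, ys, 0.75) -
                      tricube_fit(xs, ys, 0.75))), 1e-6)
})
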