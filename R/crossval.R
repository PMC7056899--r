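#' Random k-fold partitions of the phenotyped individuals
#'
#' Per replicate, a uniformly random permutation of the IDs is sliced into
#' `k` folds whose sizes differ by at most one (the first `n mod k` folds
#' take the extra individual).
#'
#' @param ids character vector of individual IDs.
#' @param k number of folds (default 5).
#' @param replicate_seeds integer vector, one seed per replicate.
#' @return list of `fold_assignment` objects: `replicate`, `seed`, and
#'   `fold` (named integer vector in 1..k).
#' @export
make_folds <- function(ids, k = 5L, replicate_seeds) {
  if (k < 2L) stop("k must be at least 2")
  n <- length(ids)
  if (n < k) stop("need at least k individuals")
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  lapply(seq_along(replicate_seeds), function(r) {
    fold <- with_seed(replicate_seeds[r], {
      perm <- sample(ids)
      f <- rep(seq_len(k), times = sizes)
      stats::setNames(f[match(ids, perm)], ids)
    })
    structure(list(replicate = r, seed = replicate_seeds[r], fold = fold),
              class = "fold_assignment")
  })
}

#' Genomic prediction accuracy
#'
#' Pearson correlation between predicted breeding values and observed
#' phenotypes of the validation individuals, divided by the square root of
#' the reference heritability (the full-panel, full-data estimate). Note
#' the estimator can exceed 1 when `h2_ref < r^2`.
#'
#' @param pred_ebv predicted breeding values.
#' @param observed_y observed (unmasked) phenotypes, same length >= 3.
#' @param h2_ref reference heritability in (0, 1].
#' @return the accuracy (a scalar).
#' @export
accuracy <- function(pred_ebv, observed_y, h2_ref) {
  if (length(pred_ebv) != length(observed_y)) {
    stop("prediction and observation vectors differ in length")
  }
  if (length(observed_y) < 3L) stop("need at least 3 validation individuals")
  if (h2_ref <= 0 || h2_ref > 1) stop("h2_ref must be in (0, 1]")
  if (stats::sd(observed_y) == 0) {
    stop("validation phenotypes are constant; accuracy undefined")
  }
  if (stats::sd(pred_ebv) == 0) {
    stop("predicted EBVs are constant; accuracy undefined")
  }
  stats::cor(pred_ebv, observed_y) / sqrt(h2_ref)
}

#' Cross-validated genomic prediction for one SNP panel
#'
#' For every fold of every replicate: the relationship matrix is built on
#' the panel's markers over *all* individuals (frequencies re-estimated on
#' those markers), variance components are re-estimated by REML on the
#' training subset only, GBLUP predicts breeding values with the
#' validation phenotypes masked, and accuracy is scored on the validation
#' individuals against their unmasked phenotypes. Masking is of phenotypes
#' only - validation individuals stay in G, which is what lets
#' sib information flow into their predictions.
#'
#' @param dataset QC-passing `genotype_dataset`.
#' @param phenotypes phenotype data.frame with `id` column.
#' @param trait,factors model specification.
#' @param panel an `snp_panel`.
#' @param folds list of fold assignments from [make_folds()].
#' @param h2_ref reference heritability for the accuracy denominator
#'   (from the full-panel, full-data REML fit).
#' @param grm optional pre-built `genomic_relationship` on exactly the
#'   panel's markers (built internally when omitted).
#' @param refit_each_fold re-estimate variance components per training
#'   fold (default, the faithful protocol); `FALSE` reuses `fixed_vc`.
#' @param fixed_vc `variance_components` to reuse when
#'   `refit_each_fold = FALSE`.
#' @return data.frame of class `cv_result`, one row per fold: `density`,
#'   `panel_replicate`, `cv_replicate`, `fold`, `n_validation`, `r`,
#'   `accuracy`, `h2_train`, `converged`.
#' @export
run_cv <- function(dataset, phenotypes, trait, factors = character(),
                   panel, folds, h2_ref, grm = NULL,
                   refit_each_fold = TRUE, fixed_vc = NULL) {
  stopifnot(inherits(panel, "snp_panel"))
  if (is.null(grm)) {
    grm <- build_grm(subset_markers(dataset, panel$snp_ids))
  } else if (length(grm$snp_ids) != length(panel$snp_ids) ||
             !all(grm$snp_ids == panel$snp_ids)) {
    stop("supplied grm was not built on the panel's markers")
  }
  des <- build_design(phenotypes, trait, factors)
  obs_all <- match(des$ids, rownames(grm$G))
  if (anyNA(obs_all)) stop("phenotyped individuals missing from G")
  rows <- list()
  for (fa in folds) {
    fold_of <- fa$fold[des$ids]
    for (j in sort(unique(fold_of))) {
      is_val <- fold_of == j
      y_tr <- des$y[!is_val]
      X_tr <- des$X[!is_val, , drop = FALSE]
      # a factor level can vanish from a training fold
      qrX <- qr(X_tr)
      if (qrX$rank < ncol(X_tr)) {
        X_tr <- X_tr[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
      }
      use_vc <- if (refit_each_fold) {
        G_tr <- grm$G[obs_all[!is_val], obs_all[!is_val], drop = FALSE]
        tryCatch(fit_reml(y_tr, X_tr, G_tr), error = function(e) NULL)
      } else {
        if (is.null(fixed_vc)) stop("fixed_vc required when not refitting")
        fixed_vc
      }
      row <- data.frame(density = panel$density,
                        panel_replicate = panel$replicate,
                        cv_replicate = fa$replicate,
                        fold = j,
                        n_validation = sum(is_val),
                        r = NA_real_, accuracy = NA_real_,
                        h2_train = NA_real_, converged = FALSE)
      if (!is.null(use_vc)) {
        if (use_vc$converged) {
          sol <- solve_gblup(y_tr, X_tr, grm, use_vc)
          pred <- sol$a_hat[des$ids[is_val]]
          acc <- tryCatch(accuracy(pred, des$y[is_val], h2_ref),
                          error = function(e) NA_real_)
          row$r <- if (is.na(acc)) NA_real_ else acc * sqrt(h2_ref)
          row$accuracy <- acc
          row$h2_train <- use_vc$h2
          row$converged <- TRUE
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cv_result", class(out))
  out
}

#' Aggregate cross-validation results into an accuracy curve
#'
#' Per density: the mean accuracy over all panels, CV replicates and
#' folds; the standard deviation across the per-panel mean accuracies
#' (panel-to-panel spread); the proportion of the full-panel mean
#' accuracy; and the max - min of the per-panel means.
#'
#' @param results row-bound [run_cv()] output covering the full density.
#' @param full_density the density of the full panel (number of QC-passing
#'   SNPs).
#' @return data.frame of class `accuracy_curve`: `density`, `n_folds`,
#'   `mean_accuracy`, `sd_panels`, `proportion_full`, `range_panels`.
#' @export
accuracy_curve <- function(results, full_density) {
  ok <- results[results$converged & !is.na(results$accuracy), , drop = FALSE]
  ok$panel_replicate[is.na(ok$panel_replicate)] <- 0L
  if (!any(ok$density == full_density)) {
    stop("results contain no rows at the full density ", full_density)
  }
  panel_means <- stats::aggregate(
    accuracy ~ density + panel_replicate, data = ok, FUN = mean)
  dens <- sort(unique(ok$density))
  full_mean <- mean(ok$accuracy[ok$density == full_density])
  out <- do.call(rbind, lapply(dens, function(d) {
    acc <- ok$accuracy[ok$density == d]
    pm <- panel_means$accuracy[panel_means$density == d]
    data.frame(density = d,
               n_folds = length(acc),
               mean_accuracy = mean(acc),
               sd_panels = if (length(pm) > 1) stats::sd(pm) else 0,
               proportion_full = mean(acc) / full_mean,
               range_panels = max(pm) - min(pm))
  }))
  class(out) <- c("accuracy_curve", class(out))
  out
}

#' Loess smoother for report curves
#'
#' Local quadratic regression with tricube weights at the given span,
#' evaluated at the input abscissae. Used for trend lines in reports; the
#' numeric summaries never depend on it.
#'
#' @param x,y numeric vectors (>= 5 points).
#' @param span smoothing span (default 0.75).
#' @return fitted values at `x`.
#' @export
loess_smooth <- function(x, y, span = 0.75) {
  if (span <= 0) stop("span must be positive")
  if (length(x) < 5L) stop("need at least 5 points")
  fit <- stats::loess(y ~ x, span = span, degree = 2,
                      control = stats::loess.control(surface = "direct"))
  unname(stats::predict(fit, newdata = data.frame(x = x)))
}
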