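#' Eigendecomposition of a relationship matrix for REML
#'
#' One O(n^3) symmetric eigendecomposition after which every restricted
#' likelihood evaluation costs O(n p). Small negative eigenvalues arising
#' from finite-precision arithmetic (or from low-rank panel G matrices)
#' are clipped at zero.
#'
#' @param grm a `genomic_relationship` or symmetric matrix.
#' @return list with `values`, `vectors`, `ids`.
#' @export
grm_eigen <- function(grm) {
  G <- if (inherits(grm, "genomic_relationship")) grm$G else grm
  if (!isSymmetric(unname(G), tol = 1e-8)) stop("G must be symmetric")
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  e$values[e$values < 0] <- 0
  list(values = e$values, vectors = e$vectors, ids = rownames(G))
}

# Profiled restricted log-likelihood in the eigenbasis of G.
# ys, Xs: rotated data (U'y, U'X); d: eigenvalues of G. The total variance
# sigma_t^2 = sigma_a^2 + sigma_e^2 is profiled out at fixed ratio h2.
reml_profile_ll <- function(ys, Xs, d, h2) {
  n <- length(ys)
  p <- ncol(Xs)
  lam <- h2 * d + (1 - h2)
  w <- 1 / lam
  XtWX <- crossprod(Xs, Xs * w)
  b <- solve(XtWX, crossprod(Xs, ys * w))
  r <- ys - drop(Xs %*% b)
  q <- sum(w * r^2)
  np <- n - p
  sigma_t2 <- q / np
  ll <- -0.5 * (np * log(2 * pi) + np * log(sigma_t2) + sum(log(lam)) +
                  determinant(XtWX, logarithm = TRUE)$modulus[1] + np)
  list(ll = as.numeric(ll), sigma_t2 = sigma_t2, b = drop(b))
}

check_identifiable <- function(d) {
  if (diff(range(d)) < 1e-8) {
    stop("relationship matrix is (a multiple of) the identity: additive and ",
         "residual variance are not separately identifiable")
  }
}

#' Restricted log-likelihood of the animal model at a heritability ratio
#'
#' Evaluates the REML log-likelihood of
#' `y ~ N(Xb, sigma_a^2 G + sigma_e^2 I)` with the total variance profiled
#' out at the fixed ratio `h2 = sigma_a^2 / (sigma_a^2 + sigma_e^2)`,
#' computed in the eigenbasis of G.
#'
#' @param y phenotype vector (observed individuals only).
#' @param X fixed-effect design matrix (full rank, includes intercept).
#' @param eig eigendecomposition of the matching G sub-block from
#'   [grm_eigen()].
#' @param h2 candidate ratio, strictly inside (0, 1).
#' @return the restricted log-likelihood (a scalar).
#' @export
restricted_loglik <- function(y, X, eig, h2) {
  if (h2 <= 0 || h2 >= 1) stop("h2 must be strictly inside (0, 1)")
  check_identifiable(eig$values)
  if (length(y) != nrow(X) || length(y) != length(eig$values)) {
    stop("y, X and the eigendecomposition must agree in size")
  }
  ys <- drop(crossprod(eig$vectors, y))
  Xs <- crossprod(eig$vectors, X)
  reml_profile_ll(ys, Xs, eig$values, h2)$ll
}

#' Fit the single-random-effect animal model by REML
#'
#' Maximizes the profiled restricted likelihood over
#' `h2 in [1e-6, 1 - 1e-6]` by bounded scalar optimization (golden
#' section / parabolic, tolerance 1e-8), then recovers the additive and
#' residual variances from the profiled total variance. The standard error
#' of the heritability comes from the curvature of the profile likelihood
#' at the optimum (central finite differences).
#'
#' @param y phenotype vector (>= 10 observed individuals).
#' @param X fixed-effect design matrix; `NULL` for intercept only.
#' @param grm a `genomic_relationship`, symmetric matrix, or a
#'   [grm_eigen()] result, over exactly the phenotyped individuals.
#' @param tol optimizer tolerance on h2.
#' @return object of class `variance_components`: `sigma2_a`, `sigma2_e`,
#'   `h2`, `se_h2`, `loglik`, `converged`, `boundary`, plus the fixed-effect
#'   estimates `b` at the optimum.
#' @export
fit_reml <- function(y, X = NULL, grm, tol = 1e-8) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 10L) stop("need at least 10 phenotyped individuals")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design matrix is rank deficient")
  eig <- if (is.list(grm) && !is.null(grm$vectors)) grm else grm_eigen(grm)
  check_identifiable(eig$values)
  if (length(eig$values) != n) stop("G block does not match phenotype length")
  ys <- drop(crossprod(eig$vectors, y))
  Xs <- crossprod(eig$vectors, X)
  d <- eig$values
  f <- function(h2) reml_profile_ll(ys, Xs, d, h2)$ll
  lo <- 1e-6; hi <- 1 - 1e-6
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
  h2 <- opt$maximum
  # a flat profile means the data carry no information on the ratio
  probe <- vapply(c(lo, 0.25, 0.5, 0.75, hi), f, numeric(1))
  converged <- diff(range(probe)) > 1e-10
  boundary <- (h2 - lo) < 1e-5 || (hi - h2) < 1e-5
  at_opt <- reml_profile_ll(ys, Xs, d, h2)
  sigma_t2 <- at_opt$sigma_t2
  # curvature-based SE of h2
  delta <- 1e-4
  hm <- max(lo, h2 - delta); hp <- min(hi, h2 + delta)
  d2 <- (f(hp) - 2 * f(h2) + f(hm)) / ((hp - h2) * (h2 - hm))
  se_h2 <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  structure(list(sigma2_a = h2 * sigma_t2,
                 sigma2_e = (1 - h2) * sigma_t2,
                 h2 = h2,
                 se_h2 = se_h2,
                 loglik = opt$objective,
                 converged = converged,
                 boundary = boundary,
                 b = at_opt$b),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("REML variance components: sigma2_a = %.4g, sigma2_e = %.4g\n",
              x$sigma2_a, x$sigma2_e))
  cat(sprintf("  h2 = %.4f (SE %.4f), logLik = %.4f%s%s\n",
              x$h2, x$se_h2, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]",
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Build phenotype vector and fixed-effect design for the animal model
#'
#' Reference-level (treatment) coding with an explicit intercept; the
#' intercept estimates the overall mean and each further column a level
#' contrast. Individuals missing the trait or any factor level are
#' excluded (they remain available in G for prediction).
#'
#' @param phenotypes phenotype data.frame with an `id` column.
#' @param trait trait column name.
#' @param factors character vector of fixed-effect factor column names.
#' @return list with `y` (named by id), `X`, `ids`.
#' @export
build_design <- function(phenotypes, trait, factors = character()) {
  if (!trait %in% names(phenotypes)) stop("trait column not found: ", trait)
  miss_f <- setdiff(factors, names(phenotypes))
  if (length(miss_f)) stop("factor column(s) not found: ",
                           paste(miss_f, collapse = ", "))
  ok <- !is.na(phenotypes[[trait]])
  for (fc in factors) {
    ok <- ok & !is.na(phenotypes[[fc]]) & nzchar(as.character(phenotypes[[fc]]))
  }
  df <- phenotypes[ok, , drop = FALSE]
  y <- df[[trait]]
  names(y) <- df$id
  X <- if (length(factors)) {
    fml <- stats::as.formula(paste("~", paste(factors, collapse = " + ")))
    dd <- df[factors]
    dd[] <- lapply(dd, factor)
    stats::model.matrix(fml, data = dd)
  } else {
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  }
  list(y = y, X = X, ids = df$id)
}

#' Fit heritability for one dataset / one G
#'
#' Convenience wrapper: aligns phenotypes with the relationship matrix,
#' restricts G to the phenotyped individuals, and runs [fit_reml()].
#'
#' @param grm a `genomic_relationship` over all individuals.
#' @param phenotypes phenotype data.frame with an `id` column.
#' @param trait trait column name.
#' @param factors fixed-effect factor names.
#' @return the `variance_components`, with attribute `"ids"` giving the
#'   phenotyped individuals used.
#' @export
fit_genomic_model <- function(grm, phenotypes, trait, factors = character()) {
  des <- build_design(phenotypes, trait, factors)
  obs <- match(des$ids, rownames(grm$G))
  if (anyNA(obs)) stop("phenotyped individuals missing from G: ",
                       paste(utils::head(des$ids[is.na(obs)], 5),
                             collapse = ", "))
  vc <- fit_reml(des$y, des$X, grm$G[obs, obs, drop = FALSE])
  attr(vc, "ids") <- des$ids
  vc
}

#' Heritability across a set of low-density panels
#'
#' Re-estimates the REML heritability once per panel, rebuilding G (with
#' frequencies re-estimated on the panel's markers) each time.
#'
#' @param dataset a QC-passing `genotype_dataset`.
#' @param phenotypes phenotype data.frame.
#' @param trait,factors model specification as in [fit_genomic_model()].
#' @param panels list of `snp_panel` objects.
#' @return data.frame with one row per panel: `density`, `replicate`,
#'   `h2`, `se_h2`, `sigma2_a`, `sigma2_e`, `converged`.
#' @export
estimate_h2_curve <- function(dataset, phenotypes, trait,
                              factors = character(), panels) {
  rows <- lapply(panels, function(pn) {
    sub <- subset_markers(dataset, pn$snp_ids)
    grm <- build_grm(sub)
    vc <- fit_genomic_model(grm, phenotypes, trait, factors)
    data.frame(density = pn$density,
               replicate = pn$replicate,
               h2 = vc$h2, se_h2 = vc$se_h2,
               sigma2_a = vc$sigma2_a, sigma2_e = vc$sigma2_e,
               converged = vc$converged)
  })
  out <- do.call(rbind, rows)
  n_bad <- sum(!out$converged)
  if (n_bad > 0) {
    message(n_bad, " non-converged fit(s) recorded; exclude them when ",
            "averaging")
  }
  out
}

#' Per-density mean heritability over converged panel fits
#'
#' @param curve output of [estimate_h2_curve()].
#' @return data.frame: `density`, `mean_h2`, `sd_h2`, `n_panels`.
#' @export
h2_curve_summary <- function(curve) {
  ok <- curve[curve$converged, , drop = FALSE]
  agg <- stats::aggregate(h2 ~ density, data = ok,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  data.frame(density = agg$density,
             mean_h2 = agg$h2[, "mean"],
             sd_h2 = agg$h2[, "sd"],
             n_panels = agg$h2[, "n"])
}
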