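#' Genomic best linear unbiased prediction
#'
#' Given variance components, estimates the fixed effects by generalized
#' least squares on the phenotyped block and predicts breeding values for
#' *every* individual in G via the conditional expectation
#' \deqn{\hat a = \sigma_a^2 \, G_{\cdot o} V_{oo}^{-1} (y - X\hat b),
#'   \quad V_{oo} = \sigma_a^2 G_{oo} + \sigma_e^2 I.}
#' Unphenotyped individuals (e.g. a masked validation set) borrow
#' information through their relationship rows; this is algebraically
#' equivalent to the mixed-model equations with the masked records absent.
#'
#' @param y named phenotype vector for the observed individuals (names are
#'   row names of `G`).
#' @param X fixed-effect design for the observed individuals (rows match
#'   `y`); `NULL` for intercept only.
#' @param grm a `genomic_relationship` (or matrix with row names) over all
#'   individuals, phenotyped or not.
#' @param vc `variance_components` from [fit_reml()].
#' @return object of class `gblup_solution`: `b_hat` (fixed effects,
#'   dropped-collinear columns reported as 0 with attribute `"aliased"`),
#'   `a_hat` (named breeding values for all individuals in G), `vc`.
#' @export
solve_gblup <- function(y, X = NULL, grm, vc) {
  G <- if (inherits(grm, "genomic_relationship")) grm$G else grm
  if (is.null(rownames(G))) stop("G must carry individual IDs as row names")
  if (is.null(names(y))) stop("y must be named by individual ID")
  obs <- match(names(y), rownames(G))
  if (anyNA(obs)) stop("phenotyped individuals missing from G")
  if (length(obs) == 0L) stop("no phenotyped individuals")
  n_obs <- length(obs)
  if (is.null(X)) X <- matrix(1, n_obs, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (vc$sigma2_e <= 0 && vc$sigma2_a <= 0) {
    stop("both variance components are zero")
  }
  Voo <- vc$sigma2_a * G[obs, obs, drop = FALSE] +
    diag(vc$sigma2_e, n_obs)
  ch <- tryCatch(chol(Voo), error = function(e) NULL)
  Vinv <- if (is.null(ch)) solve(Voo) else chol2inv(ch)
  # guard against a factor level absent from the observed block
  qrX <- qr(X)
  aliased <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    aliased <- colnames(X)[-keep]
    X <- X[, keep, drop = FALSE]
  }
  XtVi <- crossprod(X, Vinv)
  b_hat <- drop(solve(XtVi %*% X, XtVi %*% y))
  names(b_hat) <- colnames(X)
  resid <- y - drop(X %*% b_hat)
  alpha <- drop(Vinv %*% resid)
  a_hat <- vc$sigma2_a * drop(G[, obs, drop = FALSE] %*% alpha)
  names(a_hat) <- rownames(G)
  out <- structure(list(b_hat = b_hat, a_hat = a_hat, vc = vc),
                   class = "gblup_solution")
  attr(out, "aliased") <- aliased
  out
}

#' @export
print.gblup_solution <- function(x, ...) {
  cat(sprintf("GBLUP solution: %d breeding values, %d fixed effect(s)\n",
              length(x$a_hat), length(x$b_hat)))
  cat(sprintf("  h2 used: %.4f; EBV range [%.3f, %.3f]\n",
              x$vc$h2, min(x$a_hat), max(x$a_hat)))
  invisible(x)
}

#' Write breeding values as TSV
#'
#' @param solution a `gblup_solution`.
#' @param path output path (columns: `id`, `ebv`).
#' @return invisibly, `path`.
#' @export
write_ebv <- function(solution, path) {
  utils::write.table(
    data.frame(id = names(solution$a_hat), ebv = solution$a_hat),
    path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
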