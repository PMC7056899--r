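#' In-sample allele frequencies
#'
#' @param dataset a `genotype_dataset`.
#' @return named numeric vector: per-marker frequency of allele 1
#'   (`sum(dosage) / (2 * non-missing count)`).
#' @export
allele_frequencies <- function(dataset) {
  nn <- colSums(!is.na(dataset$geno))
  if (any(nn == 0)) {
    stop("marker(s) with no non-missing calls: ",
         paste(utils::head(dataset$map$snp[nn == 0], 5), collapse = ", "))
  }
  colSums(dataset$geno, na.rm = TRUE) / (2 * nn)
}

#' Frequency-weighted genomic relationship matrix
#'
#' The identity-by-state kinship of Astle & Balding weighted by allele
#' frequencies, multiplied by two so that the expectation is ~1 on the
#' diagonal and ~0.5 between full sibs:
#' \deqn{G_{ij} = \frac{1}{L}\sum_l \frac{(x_{il}-2p_l)(x_{jl}-2p_l)}
#'   {2 p_l (1-p_l)}}
#' with the same formula on the diagonal. Under the default
#' `"mean_impute"` policy, missing dosages are replaced by their marker
#' mean `2p` (a zero contribution after centering) and `L` is the total
#' marker count; under `"pairwise"`, each pair is averaged over the markers
#' non-missing in both individuals.
#'
#' @param dataset a `genotype_dataset` with polymorphic markers.
#' @param freqs optional allele-frequency vector matching the markers;
#'   estimated in-sample by default. When building G on a SNP panel, pass
#'   frequencies re-estimated on that panel's markers.
#' @param missing_policy `"mean_impute"` (default, positive semidefinite)
#'   or `"pairwise"` (complete-overlap averaging).
#' @return object of class `genomic_relationship`: list with the `n x n`
#'   matrix `G`, `freqs`, `snp_ids`, `missing_policy`, `ridge` (0 until
#'   [invert_grm()] regularizes).
#' @export
build_grm <- function(dataset, freqs = NULL,
                      missing_policy = c("mean_impute", "pairwise")) {
  missing_policy <- match.arg(missing_policy)
  if (is.null(freqs)) freqs <- allele_frequencies(dataset)
  m <- n_markers(dataset)
  if (length(freqs) != m) stop("freqs must match the marker count")
  if (any(freqs <= 0 | freqs >= 1)) {
    stop("monomorphic marker(s) present; run QC or drop them first")
  }
  x <- dataset$geno
  storage.mode(x) <- "double"
  W <- sweep(x, 2L, 2 * freqs)
  W <- sweep(W, 2L, sqrt(2 * freqs * (1 - freqs)), "/")
  if (missing_policy == "mean_impute") {
    W[is.na(W)] <- 0
    G <- tcrossprod(W) / m
  } else {
    obs <- !is.na(x)
    W[!obs] <- 0
    L <- tcrossprod(obs * 1)
    if (any(L == 0)) {
      stop("pair(s) of individuals with zero marker overlap under the ",
           "pairwise policy")
    }
    G <- tcrossprod(W) / L
  }
  dimnames(G) <- list(individual_ids(dataset), individual_ids(dataset))
  structure(list(G = G, freqs = freqs, snp_ids = dataset$map$snp,
                 missing_policy = missing_policy, ridge = 0),
            class = "genomic_relationship")
}

#' @export
print.genomic_relationship <- function(x, ...) {
  cat(sprintf(
    "genomic_relationship: %d individuals, %d markers (%s missing policy)\n",
    nrow(x$G), length(x$snp_ids), x$missing_policy))
  cat(sprintf("  mean diagonal %.3f, mean off-diagonal %.4f\n",
              mean(diag(x$G)),
              mean(x$G[upper.tri(x$G)])))
  invisible(x)
}

#' Invert a genomic relationship matrix
#'
#' Attempts a Cholesky-based inverse; if the matrix is numerically
#' singular (as happens with duplicated individuals or panels with fewer
#' markers than individuals), a ridge `ridge * I` is added, escalating
#' tenfold from 1e-6 until the factorization succeeds, and the ridge
#' actually used is recorded and reported.
#'
#' @param grm a `genomic_relationship`, or a symmetric matrix.
#' @param ridge initial ridge (default 0 = none before escalation).
#' @return list with `Ginv`, `ridge` (value actually added), and
#'   `max_residual` (`max |(G + ridge I) Ginv - I|`).
#' @export
invert_grm <- function(grm, ridge = 0) {
  G <- if (inherits(grm, "genomic_relationship")) grm$G else grm
  if (!isSymmetric(unname(G), tol = 1e-8)) stop("G must be symmetric")
  G <- (G + t(G)) / 2
  n <- nrow(G)
  try_inv <- function(r) {
    Gr <- G + diag(r, n)
    ch <- tryCatch(chol(Gr), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    list(inv = chol2inv(ch), Gr = Gr)
  }
  res <- try_inv(ridge)
  used <- ridge
  while (is.null(res) ||
         max(abs(res$Gr %*% res$inv - diag(n))) > 1e-6) {
    used <- if (used == 0) 1e-6 else used * 10
    if (used > 1) stop("could not invert G even with ridge 1")
    res <- try_inv(used)
  }
  if (used > ridge) {
    message("G numerically singular; ridge escalated to ", used)
  }
  dimnames(res$inv) <- dimnames(G)
  list(Ginv = res$inv, ridge = used,
       max_residual = max(abs(res$Gr %*% res$inv - diag(n))))
}

#' Write a relationship matrix as TSV (full) or sparse triplet text
#'
#' @param grm a `genomic_relationship` or matrix.
#' @param prefix output prefix. `format = "full"` writes
#'   `<prefix>.grm.tsv` with an ID header row and column;
#'   `format = "sparse"` writes the lower triangle as `(i, j, value)`
#'   in `<prefix>.grm.sparse.txt` plus `<prefix>.grm.ids.txt`.
#' @param format `"full"` or `"sparse"`.
#' @return invisibly, the main output path.
#' @export
write_grm <- function(grm, prefix, format = c("full", "sparse")) {
  format <- match.arg(format)
  G <- if (inherits(grm, "genomic_relationship")) grm$G else grm
  ids <- rownames(G) %||% as.character(seq_len(nrow(G)))
  if (format == "full") {
    path <- paste0(prefix, ".grm.tsv")
    df <- data.frame(id = ids, G, check.names = FALSE)
    colnames(df) <- c("id", ids)
    utils::write.table(df, path, quote = FALSE, sep = "\t",
                       row.names = FALSE)
  } else {
    path <- paste0(prefix, ".grm.sparse.txt")
    lt <- which(lower.tri(G, diag = TRUE), arr.ind = TRUE)
    utils::write.table(
      data.frame(i = lt[, 1], j = lt[, 2], value = G[lt]),
      path, quote = FALSE, sep = "\t", row.names = FALSE,
      col.names = FALSE)
    writeLines(ids, paste0(prefix, ".grm.ids.txt"))
  }
  invisible(path)
}
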