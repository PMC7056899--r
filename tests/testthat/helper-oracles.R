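# Independent oracles shared by the REML and acceptance tests.

# Naive dense REML: form V, invert it, evaluate the textbook restricted
# likelihood with the total variance profiled out. No code shared with the
# eigenbasis implementation.
dense_reml_ll <- function(y, X, G, h2) {
  n <- length(y); p <- ncol(X)
  Vr <- h2 * G + (1 - h2) * diag(n)
  Vri <- solve(Vr)
  b <- solve(t(X) %*% Vri %*% X, t(X) %*% Vri %*% y)
  r <- y - X %*% b
  q <- drop(t(r) %*% Vri %*% r)
  st <- q / (n - p)
  V <- st * Vr
  -0.5 * ((n - p) * log(2 * pi) +
            determinant(V, logarithm = TRUE)$modulus[1] +
            determinant(t(X) %*% solve(V) %*% X,
                        logarithm = TRUE)$modulus[1] +
            q / st)
}

# Random well-posed mixed-model instance.
random_instance <- function(n, p = 2, seed = 1) {
  set.seed(seed)
  W <- matrix(rnorm(n * 3 * n), n)
  G <- tcrossprod(W) / (3 * n)
  rownames(G) <- colnames(G) <- sprintf("I%03d", seq_len(n))
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
  L <- chol(0.4 * G + 0.6 * diag(n))
  y <- drop(X %*% rnorm(p) + t(L) %*% rnorm(n))
  names(y) <- rownames(G)
  list(y = y, X = X, G = G)
}
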