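# independent oracles used to validate the package's own implementations;
# these deliberately share no code with the package internals

# canonical multiplicative-update NMF (Lee-Seung, Frobenius loss):
# E ~ W H, returns the best squared-Frobenius objective over restarts
mu_nmf_objective <- function(E, j, n_restarts = 10L, seed = 1L,
                             max_iter = 1000L, tol = 1e-9) {
  m <- nrow(E); n <- ncol(E)
  eps <- 1e-12
  set.seed(seed)
  best <- Inf
  for (r in seq_len(n_restarts)) {
    W <- matrix(stats::runif(m * j, 0.1, 1), m, j)
    H <- matrix(stats::runif(j * n, 0.1, 1), j, n)
    obj_prev <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, E)) / (crossprod(W) %*% H + eps)
      W <- W * (E %*% t(H)) / (W %*% tcrossprod(H) + eps)
      obj <- sum((E - W %*% H)^2)
      if (is.finite(obj_prev) && (obj_prev - obj) <= tol * obj_prev) break
      obj_prev <- obj
    }
    if (obj < best) best <- obj
  }
  best
}

# textbook Pearson correlation from explicit sums
pearson_textbook <- function(x, y) {
  n <- length(x)
  xb <- sum(x) / n
  yb <- sum(y) / n
  sum((x - xb) * (y - yb)) /
    sqrt(sum((x - xb)^2) * sum((y - yb)^2))
}
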