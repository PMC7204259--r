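#' HALS configuration
#'
#' Settings for the hierarchical alternating least squares (HALS) NMF solver.
#'
#' @param max_sweeps Maximum full update sweeps per restart (default 500).
#' @param tol Relative objective-change stopping tolerance (default 1e-8).
#' @param n_restarts Random restarts; the factorization with the lowest
#'   Frobenius objective is kept (default 10).
#' @param seed Integer seed for the restart initializations.
#' @param eps Small positive floor guarding denominators.
#' @return A `hals_config` list.
#' @export
hals_config <- function(max_sweeps = 500L, tol = 1e-8, n_restarts = 10L,
                        seed = 1L, eps = 1e-12) {
  max_sweeps <- assert_count(max_sweeps, "max_sweeps")
  n_restarts <- assert_count(n_restarts, "n_restarts")
  if (!is.numeric(tol) || tol <= 0) stopf("`tol` must be > 0")
  if (!is.numeric(eps) || eps <= 0) stopf("`eps` must be > 0")
  structure(list(max_sweeps = max_sweeps, tol = tol,
                 n_restarts = n_restarts, seed = as.integer(seed),
                 eps = eps),
            class = "hals_config")
}

# one HALS run from given initial factors; exact block-coordinate updates,
# column k of S (then of M) is replaced by the projected least-squares
# minimizer, so the objective is non-increasing sweep to sweep
hals_run <- function(E, M, S, config) {
  j <- ncol(S)
  normE2 <- sum(E^2)
  obj_prev <- Inf
  history <- numeric(0)
  for (sweep in seq_len(config$max_sweeps)) {
    A <- crossprod(E, M)          # n x j, E^T M
    B <- crossprod(M)             # j x j, M^T M
    for (k in seq_len(j)) {
      if (B[k, k] <= config$eps) { S[, k] <- 0; next }
      S[, k] <- pmax(S[, k] + (A[, k] - S %*% B[, k]) / B[k, k], 0)
    }
    A2 <- E %*% S                 # m x j
    B2 <- crossprod(S)            # j x j
    for (k in seq_len(j)) {
      if (B2[k, k] <= config$eps) { M[, k] <- 0; next }
      M[, k] <- pmax(M[, k] + (A2[, k] - M %*% B2[, k]) / B2[k, k], 0)
    }
    obj <- normE2 - 2 * sum(M * A2) + sum(B2 * crossprod(M))
    obj <- max(obj, 0)
    history <- c(history, obj)
    if (is.finite(obj_prev) &&
        (obj_prev - obj) <= config$tol * max(obj_prev, config$eps)) {
      obj_prev <- obj
      break
    }
    obj_prev <- obj
  }
  list(M = M, S = S, objective = obj_prev, history = history,
       sweeps = length(history))
}

# push column scale into M, unit-norm columns of S; collapsed (all-zero)
# columns are left as zero
normalize_factor_scale <- function(M, S) {
  nrm <- sqrt(colSums(S^2))
  pos <- nrm > 0
  S[, pos] <- sweep(S[, pos, drop = FALSE], 2L, nrm[pos], "/")
  M[, pos] <- sweep(M[, pos, drop = FALSE], 2L, nrm[pos], "*")
  list(M = M, S = S)
}

#' Nonnegative matrix factorization by hierarchical alternating least squares
#'
#' Factorizes a nonnegative time x channel envelope matrix as `E ~ M S^T`
#' with nonnegative activations `M` (time x j) and synergies `S`
#' (channel x j), minimizing the Frobenius reconstruction error by
#' column-wise HALS updates with nonnegative projection. Unlike
#' multiplicative-update NMF, HALS remains usable when the requested number
#' of synergies exceeds the number of channels. The best of `n_restarts`
#' random initializations is returned; columns of `S` are scaled to unit
#' Euclidean norm with the magnitude pushed into `M`.
#'
#' @param E Nonnegative time x channel matrix.
#' @param j Number of synergies (>= 1).
#' @param config A [hals_config()].
#' @return List of class `hals_fit`: `M`, `S`, `objective` (squared Frobenius
#'   residual), `vaf`, `history` (objective per sweep of the winning
#'   restart), `sweeps`, `j`.
#' @export
hals_nmf <- function(E, j, config = hals_config()) {
  E <- as_matrix(E)
  j <- assert_count(j, "j")
  if (any(E < 0)) stopf("E must be nonnegative")
  if (all(E == 0)) stopf("degenerate input: E is identically zero")
  m <- nrow(E); n <- ncol(E)
  set.seed(config$seed)
  # init scale proportional to sqrt(mean(E)/j) keeps the whole update
  # trajectory equivariant under rescaling of E
  scale0 <- sqrt(mean(E) / j)
  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    M0 <- matrix(stats::runif(m * j), m, j) * scale0
    S0 <- matrix(stats::runif(n * j), n, j) * scale0
    fit <- hals_run(E, M0, S0, config)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  ns <- normalize_factor_scale(best$M, best$S)
  rownames(ns$S) <- colnames(E)
  colnames(ns$S) <- colnames(ns$M) <- sprintf("syn%d", seq_len(j))
  structure(list(M = ns$M, S = ns$S, objective = best$objective,
                 vaf = 1 - best$objective / sum(E^2),
                 history = best$history, sweeps = best$sweeps, j = j),
            class = "hals_fit")
}

#' @export
print.hals_fit <- function(x, ...) {
  cat(sprintf("HALS NMF fit: j = %d, VAF = %.4f (%d sweeps)\n",
              x$j, x$vaf, x$sweeps))
  invisible(x)
}

#' Variance accounted for (VAF)
#'
#' Uncentered fraction of variance explained by the reconstruction:
#' `1 - ||E - M S^T||_F^2 / ||E||_F^2`. Always <= 1; equals 1 for a perfect
#' reconstruction and 0 when `M` is zero.
#'
#' @param E Envelope matrix (time x channel).
#' @param M Activation matrix (time x j).
#' @param S Synergy matrix (channel x j) or a `synergy_set`.
#' @return Scalar VAF.
#' @export
vaf <- function(E, M, S) {
  E <- as_matrix(E); M <- as_matrix(M)
  if (inherits(S, "synergy_set")) S <- S$S
  S <- as_matrix(S)
  if (nrow(M) != nrow(E) || nrow(S) != ncol(E) || ncol(M) != ncol(S)) {
    stopf("non-conformable shapes in vaf()")
  }
  den <- sum(E^2)
  if (den == 0) stopf("degenerate input: ||E|| = 0")
  1 - sum((E - M %*% t(S))^2) / den
}

#' Project new envelopes onto a frozen synergy basis
#'
#' Nonnegative least squares for the activations: minimizes
#' `||E_new - M S^T||_F` over `M >= 0` with `S` fixed, by HALS sweeps on `M`
#' (exact block-coordinate descent on a convex problem) from a projected
#' unconstrained warm start. Deterministic.
#'
#' @param E_new Envelope matrix, channels matching the synergy set.
#' @param S Synergy matrix (channel x j) or `synergy_set`.
#' @param max_sweeps,tol Convergence controls.
#' @return Nonnegative activation matrix (time x j).
#' @export
project_activations <- function(E_new, S, max_sweeps = 500L, tol = 1e-12) {
  E_new <- as_matrix(E_new)
  if (inherits(S, "synergy_set")) S <- S$S
  S <- as_matrix(S)
  if (ncol(E_new) != nrow(S)) {
    stopf("channel mismatch: E has %d channels, synergy set has %d",
          ncol(E_new), nrow(S))
  }
  j <- ncol(S)
  StS <- crossprod(S)
  # warm start: projected unconstrained least squares
  G <- tryCatch(solve(StS + diag(1e-12, j)), error = function(e) NULL)
  if (is.null(G)) G <- MASS::ginv(StS)
  M <- pmax(E_new %*% S %*% G, 0)
  A2 <- E_new %*% S
  eps <- 1e-12
  obj_prev <- Inf
  normE2 <- sum(E_new^2)
  for (sweep in seq_len(max_sweeps)) {
    for (k in seq_len(j)) {
      if (StS[k, k] <= eps) { M[, k] <- 0; next }
      M[, k] <- pmax(M[, k] + (A2[, k] - M %*% StS[, k]) / StS[k, k], 0)
    }
    obj <- normE2 - 2 * sum(M * A2) + sum(StS * crossprod(M))
    if (is.finite(obj_prev) && (obj_prev - obj) <= tol * max(obj_prev, eps)) {
      break
    }
    obj_prev <- obj
  }
  colnames(M) <- colnames(S)
  M
}

#' Match estimated synergies to reference synergies
#'
#' Exact linear assignment maximizing total cosine similarity between
#' estimated and reference synergy columns (enumerated over permutations;
#' synergy counts here are small). Used for parameter-recovery validation.
#'
#' @param S_est,S_ref Channel x j matrices (or `synergy_set`s) with the same
#'   number of columns.
#' @return List with `perm` (column of `S_est` matched to each reference
#'   column), `cosines` (per reference column) and `mean_cosine`.
#' @export
match_synergies <- function(S_est, S_ref) {
  if (inherits(S_est, "synergy_set")) S_est <- S_est$S
  if (inherits(S_ref, "synergy_set")) S_ref <- S_ref$S
  S_est <- as_matrix(S_est); S_ref <- as_matrix(S_ref)
  j <- ncol(S_ref)
  if (ncol(S_est) != j) stopf("synergy counts differ")
  C <- matrix(0, j, j)
  for (a in seq_len(j)) for (b in seq_len(j)) {
    C[a, b] <- cosine(S_ref[, a], S_est[, b])
  }
  perms <- all_permutations(j)
  scores <- apply(perms, 1L, function(p) sum(C[cbind(seq_len(j), p)]))
  best <- perms[which.max(scores), ]
  cosines <- C[cbind(seq_len(j), best)]
  list(perm = best, cosines = cosines, mean_cosine = mean(cosines))
}
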