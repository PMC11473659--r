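# Analytic expected SFS under piecewise-constant demography.
#
# The number of ancestral lineages is a pure-death process with rate
# C(k,2)/(2*Ne) from state k. Within an epoch the scaled generator
# Q0 (rates C(k,2), time in units of 2*Ne generations) does not depend on
# Ne, so its eigendecomposition is computed once per sample size and
# cached; per-epoch occupancy times and the end-of-epoch state
# distribution are closed-form exponentials in that basis.

# eigendecomposition of the scaled death-process generator for sample
# size n, row-vector convention p'(t) = p(t) Q0:
#   Q0[k, k] = -C(k,2), Q0[k, k-1] = C(k,2), states k = 1..n
lineage_eigen <- function(n) {
  key <- paste0("eig", n)
  hit <- get0(key, envir = .glacialsfs_cache)
  if (!is.null(hit)) return(hit)
  cvec <- choose(seq_len(n), 2)               # c_k = C(k,2), c_1 = 0
  # right eigenvectors of A = t(Q0) (column convention), A upper bidiagonal:
  # A[i, i] = -c_i, A[i, i+1] = c_{i+1}; eigenvalue -c_j has v_j = 1,
  # v_i = -c_{i+1} v_{i+1} / (c_j - c_i) for i < j, v_i = 0 for i > j.
  V <- matrix(0, n, n)
  for (j in seq_len(n)) {
    V[j, j] <- 1
    if (j > 1) for (i in (j - 1):1)
      V[i, j] <- -cvec[i + 1] * V[i + 1, j] / (cvec[j] - cvec[i])
  }
  Vinv <- backsolve(V, diag(n))
  out <- list(V = V, Vinv = Vinv, d = -cvec)
  assign(key, out, envir = .glacialsfs_cache)
  out
}

# expected time (in generations) spent with k = 1..n ancestral lineages,
# integrated over the whole history of `dem`
expected_lineage_times <- function(dem, n) {
  eig <- lineage_eigen(n)
  nep <- length(dem$ne)
  t_end <- c(dem$t_start[-1], Inf)
  p <- numeric(n); p[n] <- 1                   # column-convention state vector
  Tk <- numeric(n)
  for (e in seq_len(nep)) {
    two_ne <- 2 * dem$ne[e]
    dt <- (t_end[e] - dem$t_start[e]) / two_ne  # scaled epoch length
    w <- eig$Vinv %*% p                         # coordinates in eigenbasis
    d <- eig$d
    if (is.finite(dt)) {
      g <- ifelse(d == 0, dt, (exp(d * dt) - 1) / d)
      Tk <- Tk + as.vector(eig$V %*% (g * w)) * two_ne
      p <- as.vector(eig$V %*% (exp(d * dt) * w))
      p[p < 0] <- 0
    } else {
      g <- ifelse(d == 0, 0, -1 / d)            # absorbing state untimed
      Tk <- Tk + as.vector(eig$V %*% (g * w)) * two_ne
    }
  }
  Tk[Tk < 0] <- 0
  Tk
}

# weight matrix W[i, k]: probability that a mutation falling while k
# lineages remain subtends i of the n samples, times k (branch count);
# E[xi_i] = mu * L * sum_k W[i, k] * E[T_k]
sfs_weights <- function(n) {
  key <- paste0("w", n)
  hit <- get0(key, envir = .glacialsfs_cache)
  if (!is.null(hit)) return(hit)
  W <- matrix(0, n - 1, n - 1)                 # i = 1..n-1, k = 2..n
  for (k in 2:n) {
    i <- seq_len(n - 1)
    W[, k - 1] <- k * choose(n - i - 1, k - 2) / choose(n - 1, k - 1)
  }
  assign(key, W, envir = .glacialsfs_cache)
  W
}

#' Expected folded SFS under a piecewise-constant demography
#'
#' Computes `E[xi_i] = mu * L * sum_k k * E[T_k] * C(n-i-1, k-2) / C(n-1, k-1)`
#' where `E[T_k]` is the expected time during which `k` ancestral lineages
#' remain, obtained exactly for piecewise-constant coalescence rates by
#' integrating the pure-death lineage-count process epoch by epoch
#' (closed-form exponentials in a cached eigenbasis). The unfolded
#' expectation is then folded; the monomorphic expectation is
#' `L - sum(E[xi])`.
#'
#' Under constant size the result reduces to the Watterson expectation
#' `E[xi_i] = theta * L / i` with `theta = 4 * Ne * mu`. The
#' eigendecomposition is numerically reliable for sample sizes up to a few
#' hundred; far larger `n` overflows the alternating-sign coefficients.
#'
#' @inheritParams simulate_coalescent_sfs
#' @return A [folded_sfs] holding expected (real-valued) counts.
#' @examples
#' expected_sfs(demography(1e4, 0), n = 10, mu = 1e-8, L = 1e6)
#' @export
expected_sfs <- function(dem, n, mu, L) {
  stopifnot(inherits(dem, "demography"))
  n <- as.integer(n)
  if (n < 2) stop("'n' must be >= 2")
  Tk <- expected_lineage_times(dem, n)
  xi <- mu * L * as.vector(sfs_weights(n) %*% Tk[2:n])
  eta <- fold_xi(xi, n)
  folded_sfs(eta = eta, n = n, L = L, n_mono = L - sum(eta))
}

#' Poisson composite log-likelihood of an observed folded SFS
#'
#' Treats every folded entry plus the monomorphic cell as an independent
#' Poisson count with mean given by the expected spectrum:
#' `sum(obs * log(exp) - exp - lgamma(obs + 1))`. Returns `-Inf` (with a
#' warning) when a cell with positive observed count has zero expectation.
#'
#' @param obs,exp [folded_sfs] objects on the same sample size `n`.
#' @return Log composite likelihood (numeric scalar).
#' @export
composite_loglik <- function(obs, exp) {
  stopifnot(inherits(obs, "folded_sfs"), inherits(exp, "folded_sfs"))
  if (obs$n != exp$n) stop("'obs' and 'exp' must share the sample size n")
  o <- c(obs$eta, obs$n_mono)
  e <- c(exp$eta, exp$n_mono)
  if (any(e < 0)) return(-Inf)
  bad <- e == 0 & o > 0
  if (any(bad)) {
    warning("expected count is 0 where observed > 0; returning -Inf")
    return(-Inf)
  }
  use <- e > 0
  sum(o[use] * log(e[use]) - e[use] - lgamma(o[use] + 1)) - sum(e[!use])
}
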