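#' Folded site frequency spectrum
#'
#' Container for a folded SFS: counts of polymorphic sites by minor-allele
#' count `1..floor(n/2)` together with the haploid sample size `n`, the
#' total number of surveyed sites `L` (monomorphic sites included) and the
#' monomorphic count. Entries may be non-integer after hypergeometric
#' projection or when holding analytic expectations.
#'
#' @param eta numeric vector of length `floor(n/2)`; counts by minor-allele
#'   count.
#' @param n haploid sample size (`>= 2`).
#' @param L total number of sites including monomorphic ones.
#' @param n_mono monomorphic site count; defaults to `L - sum(eta)`.
#' @return An object of class `folded_sfs`.
#' @export
folded_sfs <- function(eta, n, L, n_mono = NULL) {
  n <- as.integer(n)
  if (n < 2) stop("'n' must be >= 2")
  eta <- as.numeric(eta)
  if (length(eta) != n %/% 2)
    stop("'eta' must have length floor(n/2) = ", n %/% 2)
  if (any(eta < -1e-9)) stop("SFS entries must be non-negative")
  eta[eta < 0] <- 0
  if (is.null(n_mono)) n_mono <- L - sum(eta)
  structure(list(eta = eta, n = n, L = as.numeric(L),
                 n_mono = as.numeric(n_mono)),
            class = "folded_sfs")
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat(sprintf("Folded SFS: n = %d haploid samples, L = %g sites (%g monomorphic)\n",
              x$n, x$L, x$n_mono))
  eta <- round(x$eta, 3)
  names(eta) <- seq_along(eta)
  print(eta)
  invisible(x)
}

#' Joint folded site frequency spectrum for two populations
#'
#' Matrix of site counts over minor-configuration cells `(i, j)` with
#' `i in 0..n1` copies in population 1 and `j in 0..n2` in population 2,
#' folded jointly on the total count: the stored configuration satisfies
#' `i + j < (n1 + n2)/2`, or `i + j == (n1 + n2)/2` with `i <= n1 - i`.
#' Cell `(0, 0)` holds the monomorphic count.
#'
#' @param counts numeric matrix of dimension `(n1 + 1) x (n2 + 1)`.
#' @param n1,n2 haploid sample sizes.
#' @param L total number of surveyed sites.
#' @return An object of class `joint_sfs`.
#' @export
joint_sfs <- function(counts, n1, n2, L) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(n1 + 1, n2 + 1)))
    stop("'counts' must be (n1+1) x (n2+1)")
  if (any(counts < -1e-9)) stop("joint SFS entries must be non-negative")
  counts[counts < 0] <- 0
  dimnames(counts) <- list(0:n1, 0:n2)
  structure(list(counts = counts, n1 = as.integer(n1), n2 = as.integer(n2),
                 L = as.numeric(L)),
            class = "joint_sfs")
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat(sprintf("Joint folded SFS: n1 = %d, n2 = %d, L = %g sites\n",
              x$n1, x$n2, x$L))
  print(round(x$counts, 3))
  invisible(x)
}

# fold an unfolded vector xi_1..xi_{n-1} into eta_1..eta_{floor(n/2)}
fold_xi <- function(xi, n) {
  half <- n %/% 2
  eta <- numeric(half)
  for (i in seq_len(half))
    eta[i] <- if (i == n - i) xi[i] else xi[i] + xi[n - i]
  eta
}

# fold a joint (n1+1)x(n2+1) matrix over derived counts on the total count
fold_joint <- function(counts, n1, n2) {
  n <- n1 + n2
  out <- matrix(0, n1 + 1, n2 + 1)
  for (i in 0:n1) for (j in 0:n2) {
    ci <- counts[i + 1, j + 1]
    if (ci == 0) next
    tot <- i + j
    keep <- (2 * tot < n) || (2 * tot == n && i <= n1 - i)
    if (keep) out[i + 1, j + 1] <- out[i + 1, j + 1] + ci
    else out[n1 - i + 1, n2 - j + 1] <- out[n1 - i + 1, n2 - j + 1] + ci
  }
  out
}

#' Build a folded SFS from a genotype matrix
#'
#' Tallies minor-allele counts across the selected site classes, excludes
#' SNPs whose missing-call fraction exceeds `max_missing`, and projects
#' every remaining site down to a common haploid size `target_n` by exact
#' hypergeometric expectation (see [project_sfs]). Monomorphic sites of the
#' selected classes enter the total site count `L`.
#'
#' @param gm a [genotype_matrix].
#' @param classes character vector of site classes to keep; `NULL` keeps
#'   all sites.
#' @param max_missing maximum tolerated missing-call fraction per SNP
#'   (default 0.5; sites with strictly more are dropped).
#' @param target_n target haploid sample size; defaults to half the full
#'   haploid sample size rounded down to an even number.
#' @return A [folded_sfs] with `n = target_n`.
#' @export
build_folded_sfs <- function(gm, classes = NULL, max_missing = 0.5,
                             target_n = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_ind <- nrow(gm$genotypes)
  n_full <- 2L * n_ind
  if (is.null(target_n)) target_n <- (n_full %/% 2) %/% 2 * 2
  target_n <- as.integer(target_n)
  if (target_n < 2) stop("'target_n' must be >= 2")

  keep <- rep(TRUE, ncol(gm$genotypes))
  if (!is.null(classes)) {
    if (length(classes) == 0) stop("empty site-class selection")
    unknown <- setdiff(classes, c("4fold", "intron", "intergenic", "0fold", "other"))
    if (length(unknown))
      stop("unknown site class(es): ", paste(unknown, collapse = ", "))
    keep <- gm$site_class %in% classes
  }
  g <- gm$genotypes[, keep, drop = FALSE]

  n_called <- colSums(!is.na(g))
  miss_frac <- 1 - n_called / n_ind
  n_avail <- 2L * n_called
  if (ncol(g) && all(n_avail < target_n))
    stop("'target_n' exceeds the available haploid calls at every site")
  ok <- miss_frac <= max_missing & n_avail >= target_n
  g <- g[, ok, drop = FALSE]
  n_avail <- n_avail[ok]

  # class-matched monomorphic background; dropped SNPs leave L as well
  n_class_sites <- if (is.null(classes)) gm$L_total
                   else gm$L_total - sum(!keep)
  L <- n_class_sites - sum(!ok)

  half <- target_n %/% 2
  eta <- numeric(half)
  if (ncol(g)) {
    ac <- colSums(g, na.rm = TRUE)            # alt-allele copies
    mac <- pmin(ac, n_avail - ac)             # minor-allele copies
    for (s in which(mac > 0)) {
      eta <- eta + project_site(mac[s], n_avail[s], target_n)
    }
  }
  folded_sfs(eta = eta, n = target_n, L = L)
}

# expected folded counts (length floor(m/2)) of drawing m copies without
# replacement from a site with `a` minor alleles among `n_avail` copies
project_site <- function(a, n_avail, m) {
  j <- 0:m
  p <- stats::dhyper(j, a, n_avail - a, m)
  half <- m %/% 2
  out <- numeric(half)
  for (jj in j) {
    f <- min(jj, m - jj)
    if (f >= 1) out[f] <- out[f] + p[jj + 1]
  }
  out
}

#' Project a folded SFS to a smaller sample size
#'
#' Exact hypergeometric projection: entry `j` of the output accumulates,
#' over input entries `i`, the probability that a without-replacement draw
#' of `m` copies from a site with `i` minor alleles among `n` contains a
#' folded minor count of `j`. The projection is the expectation of random
#' downsampling, is linear in the input, and preserves the total site
#' count `L` (sites projected to monomorphism move into the monomorphic
#' cell).
#'
#' @param sfs a [folded_sfs].
#' @param m target haploid sample size, `2 <= m <= n`.
#' @return A [folded_sfs] with sample size `m`.
#' @export
project_sfs <- function(sfs, m) {
  stopifnot(inherits(sfs, "folded_sfs"))
  m <- as.integer(m)
  if (m < 2 || m > sfs$n) stop("'m' must satisfy 2 <= m <= n")
  if (m == sfs$n) return(sfs)
  half_m <- m %/% 2
  eta <- numeric(half_m)
  for (i in seq_along(sfs$eta)) {
    if (sfs$eta[i] == 0) next
    eta <- eta + sfs$eta[i] * project_site(i, sfs$n, m)
  }
  folded_sfs(eta = eta, n = m, L = sfs$L)
}

#' Per-site nucleotide diversity from a folded SFS
#'
#' Computes `pi = n/(L*(n-1)) * sum_sites (1 - sum_j p_j^2)`, the average
#' expected heterozygosity over all surveyed sites, with allele frequencies
#' `p = i/n` and `1 - i/n` taken from the folded minor-allele counts. This
#' equals the mean pairwise difference per site and is invariant under
#' hypergeometric projection.
#'
#' @param sfs a [folded_sfs] with `L > 0`.
#' @return Per-site nucleotide diversity (numeric scalar).
#' @examples
#' pi_from_sfs(folded_sfs(c(1, 0), n = 4, L = 10))  # 0.05
#' @export
pi_from_sfs <- function(sfs) {
  stopifnot(inherits(sfs, "folded_sfs"))
  if (sfs$L <= 0) stop("'L' must be positive")
  n <- sfs$n
  i <- seq_along(sfs$eta)
  sum(sfs$eta * 2 * i * (n - i) / (n * (n - 1))) / sfs$L
}

#' Nucleotide diversity averaged over stochastic downsampling replicates
#'
#' The stochastic counterpart of deterministic projection: in each
#' replicate every polymorphic site's calls are subsampled without
#' replacement to `target_n` haploid copies, the folded SFS is tallied and
#' [pi_from_sfs] evaluated; the mean over replicates is returned. Its
#' expectation equals the deterministic projection value.
#'
#' @inheritParams build_folded_sfs
#' @param n_reps number of resampling replicates (default 1000).
#' @param seed optional integer seed.
#' @return List with elements `pi_mean`, `pi_reps` (per-replicate values)
#'   and `target_n`.
#' @export
resampled_pi <- function(gm, classes = NULL, max_missing = 0.5,
                         target_n = NULL, n_reps = 1000, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!is.null(seed)) set.seed(seed)
  n_ind <- nrow(gm$genotypes)
  n_full <- 2L * n_ind
  if (is.null(target_n)) target_n <- (n_full %/% 2) %/% 2 * 2
  target_n <- as.integer(target_n)

  keep <- rep(TRUE, ncol(gm$genotypes))
  if (!is.null(classes)) keep <- gm$site_class %in% classes
  g <- gm$genotypes[, keep, drop = FALSE]
  n_called <- colSums(!is.na(g))
  miss_frac <- 1 - n_called / n_ind
  ok <- miss_frac <= max_missing & 2L * n_called >= target_n
  g <- g[, ok, drop = FALSE]
  n_avail <- 2L * n_called[ok]
  ac <- colSums(g, na.rm = TRUE)
  mac <- pmin(ac, n_avail - ac)
  n_class_sites <- if (is.null(classes)) gm$L_total
                   else gm$L_total - sum(!keep)
  L <- n_class_sites - sum(!ok)

  poly <- mac > 0
  m <- target_n
  coef <- 2 * seq_len(m %/% 2) * (m - seq_len(m %/% 2)) / (m * (m - 1))
  pi_reps <- vapply(seq_len(n_reps), function(r) {
    if (!any(poly)) return(0)
    j <- rhyper(sum(poly), mac[poly], n_avail[poly] - mac[poly], m)
    f <- pmin(j, m - j)
    f <- f[f >= 1]
    if (!length(f)) return(0)
    sum(coef[f]) / L
  }, numeric(1))
  list(pi_mean = mean(pi_reps), pi_reps = pi_reps, target_n = m)
}

#' Scaled SFS transform that is flat under the standard neutral model
#'
#' Maps folded counts to `phi_i = eta_i * i * (n - i) * (1 + [i == n-i]) / n`
#' and normalizes to sum 1. Under the standard neutral model
#' `E[eta_i] = theta * n / (i * (n - i) * (1 + [i == n-i]))`, so the
#' transformed spectrum is constant; departures (e.g. the rare-variant
#' excess left by population growth) show as deviations from a flat line.
#'
#' @param sfs a [folded_sfs] with at least one non-zero entry.
#' @return Numeric vector `phi` summing to 1.
#' @export
normalized_transform <- function(sfs) {
  stopifnot(inherits(sfs, "folded_sfs"))
  n <- sfs$n
  i <- seq_along(sfs$eta)
  w <- i * (n - i) * (1 + (i == n - i)) / n
  phi <- sfs$eta * w
  tot <- sum(phi)
  if (tot <= 0) stop("all-zero SFS cannot be normalized")
  phi / tot
}
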