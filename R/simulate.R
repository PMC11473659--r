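#' Simulate a folded SFS under a piecewise-constant demography
#'
#' Runs a single-population coalescent with time-rescaled exponential
#' waiting times across epochs and infinite-sites mutation: each of `reps`
#' independent loci carries `L / reps` sites, and branches accumulate
#' Poisson mutations at rate `mu` per site per generation. Entry
#' expectations converge (as `reps` grows) to the analytic expectation of
#' [expected_sfs].
#'
#' @param dem a [demography].
#' @param n haploid sample size (`>= 2`).
#' @param L total number of surveyed sites.
#' @param mu per-site per-generation mutation rate.
#' @param reps number of independent loci.
#' @param seed optional integer seed.
#' @param poisson logical; `TRUE` (default) draws Poisson mutation counts,
#'   `FALSE` accumulates expected counts `mu * L * branch length` given the
#'   simulated genealogies (a Rao-Blackwellised estimate with genealogy
#'   noise only).
#' @return A [folded_sfs].
#' @examples
#' simulate_coalescent_sfs(demography(1e4, 0), n = 10, L = 1e5,
#'                         mu = 1e-8, reps = 200, seed = 1)
#' @export
simulate_coalescent_sfs <- function(dem, n, L, mu, reps = 1000, seed = NULL,
                                    poisson = TRUE) {
  stopifnot(inherits(dem, "demography"))
  n <- as.integer(n)
  if (n < 2) stop("'n' must be >= 2")
  if (reps < 1) stop("'reps' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  xi <- .sim_sfs_single_cpp(dem$ne, dem$t_start, n, mu * L / reps,
                            as.integer(reps), poisson)
  eta <- fold_xi(xi, n)
  folded_sfs(eta = eta, n = n, L = L, n_mono = max(L - sum(eta), 0))
}

#' Simulate a joint folded SFS under a two-deme divergence model
#'
#' Structured coalescent for two demes exchanging migrants, merging into
#' the ancestral population at `tdiv` generations ago (see
#' [divergence_model] for the size history and migration-rate
#' conventions). Mutations are placed under the infinite-sites model and
#' tabulated by their descendant configuration, then folded jointly on the
#' total minor count.
#'
#' @param model a [divergence_model].
#' @param n1,n2 haploid sample sizes in the two demes (`>= 2`).
#' @inheritParams simulate_coalescent_sfs
#' @return A [joint_sfs].
#' @export
simulate_two_deme_sfs <- function(model, n1, n2, L, mu, reps = 1000,
                                  seed = NULL, poisson = TRUE) {
  stopifnot(inherits(model, "divergence_model"))
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 < 2 || n2 < 2) stop("'n1' and 'n2' must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  m1 <- if (model$has_migration) model$n1m21 / (2 * model$npop1) else 0
  m2 <- if (model$has_migration) model$n2m12 / (2 * model$npop2) else 0
  anc_change <- isTRUE(model$has_ancestral_change)
  counts <- .sim_sfs_two_deme_cpp(
    n1, n2, model$npop1, model$npop2,
    if (anc_change) model$ncur else model$nanc, model$nanc,
    model$tdiv, if (anc_change) model$tsep else Inf,
    m1, m2, anc_change, mu * L / reps, as.integer(reps), poisson)
  folded <- fold_joint(counts, n1, n2)
  n_seg <- sum(folded)
  folded[1, 1] <- max(L - n_seg, 0)
  joint_sfs(folded, n1 = n1, n2 = n2, L = L)
}

#' Simulate a genotype matrix with depth, quality and missingness
#'
#' Fixture generator for the QC and SFS stages: haplotypes are produced by
#' the single-population coalescent over independent loci, paired at
#' random into diploid genotypes, and dressed with a Poisson read-depth
#' model, a depth-monotone genotype quality (`GQ = min(99, round(10*DP/3))`)
#' and independent missing calls. INFO annotations are synthesized at
#' clearly passing values so the matrix survives [site_info_filter]
#' untouched unless a test perturbs it.
#'
#' @param dem a [demography].
#' @param n_ind number of diploid individuals.
#' @param L total surveyed sites (monomorphic included).
#' @param mu per-site per-generation mutation rate.
#' @param missing_rate per-call missing probability in `[0, 1)`.
#' @param dp_model mean of the Poisson read-depth distribution.
#' @param loci number of independent coalescent loci.
#' @param seed optional integer seed.
#' @param pop population label(s) for the individuals.
#' @return A [genotype_matrix].
#' @export
simulate_genotype_matrix <- function(dem, n_ind, L, mu, missing_rate = 0,
                                     dp_model = 30, loci = 100, seed = NULL,
                                     pop = "pop1") {
  stopifnot(inherits(dem, "demography"))
  if (missing_rate < 0 || missing_rate >= 1)
    stop("'missing_rate' must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n_hap <- 2L * n_ind
  carriers <- .sim_haplotypes_cpp(dem$ne, dem$t_start, n_hap,
                                  mu * L / loci, as.integer(loci))
  S <- length(carriers)
  # random pairing of haplotypes into individuals
  perm <- sample(n_hap)
  ind_of_hap <- rep(seq_len(n_ind), each = 2)[order(perm)]
  g <- matrix(0L, n_ind, S)
  for (s in seq_len(S)) {
    tab <- tabulate(ind_of_hap[carriers[[s]]], nbins = n_ind)
    g[, s] <- tab
  }
  # drop sites fixed in the sample (infinite-sites mutations on root edges
  # cannot occur, but keep the guard for safety)
  seg <- colSums(g) > 0 & colSums(g) < n_hap
  g <- g[, seg, drop = FALSE]
  S <- ncol(g)
  dp <- matrix(rpois(n_ind * S, dp_model), n_ind, S)
  gq <- pmin(99L, as.integer(round(10 * dp / 3)))
  gq <- matrix(gq, n_ind, S)
  if (missing_rate > 0) {
    miss <- matrix(runif(n_ind * S) < missing_rate, n_ind, S)
    g[miss] <- NA_integer_
  }
  positions <- sort(sample.int(max(L, S * 2), S))
  info <- data.frame(QD = rep(25, S), QUAL = rep(900, S), SOR = rep(1, S),
                     MQ = rep(60, S), MQRankSum = rep(0, S),
                     ReadPosRankSum = rep(0, S))
  genotype_matrix(genotypes = g, dp = dp, gq = gq, positions = positions,
                  info = info, site_class = rep("other", S),
                  pop = rep_len(pop, n_ind), L_total = L)
}

#' Inject collapsed-paralog artifacts into a genotype matrix
#'
#' Models the error process that HDplot targets: when two duplicated loci
#' map to a single reference position, a fixed difference between copies
#' makes nearly every individual appear heterozygous, and unequal copy
#' coverage biases the pooled allele-read ratio. A fraction `prop` of SNPs
#' is converted into such collapsed duplicates (all non-missing calls set
#' heterozygous, per-call alternate-read fraction `p_bias`); genuine
#' heterozygotes at the remaining sites receive balanced
#' `Binomial(depth, 0.5)` reads.
#'
#' @param gm a [genotype_matrix].
#' @param prop fraction of SNPs to convert, in `[0, 1]`.
#' @param depth mean read depth for the simulated allele counts.
#' @param p_bias alternate-read probability at collapsed sites (0.65
#'   reflects unequal amplification of the two copies).
#' @param seed optional integer seed.
#' @return List with elements `gm` (modified matrix), `reads` (a
#'   read-count table: data frame with columns `individual`, `site`,
#'   `reads_a`, `reads_b` for every heterozygous call) and
#'   `paralog_sites` (indices of the injected sites).
#' @export
inject_paralogs <- function(gm, prop, depth = 30, p_bias = 0.65,
                            seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (prop < 0 || prop > 1) stop("'prop' must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  g <- gm$genotypes
  S <- ncol(g)
  n_par <- round(prop * S)
  paralog_sites <- if (n_par > 0) sort(sample.int(S, n_par)) else integer(0)
  for (s in paralog_sites) {
    called <- !is.na(g[, s])
    g[called, s] <- 1L
  }
  het_idx <- which(!is.na(g) & g == 1L, arr.ind = TRUE)
  n_het <- nrow(het_idx)
  tot <- pmax(rpois(n_het, depth), 1L)
  is_par <- het_idx[, 2] %in% paralog_sites
  pr <- ifelse(is_par, p_bias, 0.5)
  ra <- rbinom(n_het, tot, pr)
  reads <- data.frame(individual = het_idx[, 1], site = het_idx[, 2],
                      reads_a = ra, reads_b = tot - ra)
  gm$genotypes <- g
  list(gm = gm, reads = reads, paralog_sites = paralog_sites)
}

#' Simulate a set of step-function Ne trajectories
#'
#' Calibration input for the synchronicity test: `k` independent
#' random-walk log-Ne step functions on a shared time grid (ordered from
#' the present into the past). Within each `shared_decreases` window every
#' trajectory is forced to decrease monotonically toward the present
#' (i.e. Ne grows with the grid index inside the window), emulating a
#' synchronous decline episode.
#'
#' @param k number of species (`>= 2`).
#' @param grid numeric vector of strictly increasing time points
#'   (present first).
#' @param shared_decreases list of `c(start, end)` index pairs into `grid`;
#'   windows must be within the grid, ordered and non-overlapping.
#' @param noise standard deviation of the per-step log-Ne increments.
#' @param drift mean per-step log-Ne growth toward the present (the
#'   default 0 gives driftless walks; positive values emulate the overall
#'   growth signal typical of inferred tree trajectories, on top of which
#'   shared decline episodes stand out).
#' @param ne0 typical present-day Ne used to anchor the walks.
#' @param seed optional integer seed.
#' @return A list of `k` `ne_trajectory` objects (see [ne_trajectory])
#'   whose step intervals are the consecutive grid cells.
#' @export
simulate_trajectory_set <- function(k, grid, shared_decreases = list(),
                                    noise = 0.05, drift = 0, ne0 = 1e5,
                                    seed = NULL) {
  if (k < 2) stop("'k' must be >= 2")
  grid <- as.numeric(grid)
  G <- length(grid)
  if (G < 3 || any(diff(grid) <= 0))
    stop("'grid' must be strictly increasing with >= 3 points")
  for (w in shared_decreases) {
    if (length(w) != 2 || w[1] < 1 || w[2] > G || w[1] >= w[2])
      stop("malformed shared-decrease window")
  }
  if (length(shared_decreases) > 1) {
    starts <- vapply(shared_decreases, `[`, numeric(1), 1)
    ends <- vapply(shared_decreases, `[`, numeric(1), 2)
    o <- order(starts)
    if (any(starts[o][-1] <= ends[o][-length(ends)]))
      stop("shared-decrease windows must not overlap")
  }
  if (!is.null(seed)) set.seed(seed)
  lne <- matrix(0, k, G)
  lne[, 1] <- log(ne0) + rnorm(k, 0, 0.5)
  steps <- matrix(rnorm(k * (G - 1), -drift, noise), k, G - 1)
  for (t in 2:G) lne[, t] <- lne[, t - 1] + steps[, t - 1]
  for (w in shared_decreases) {
    for (t in (w[1] + 1):w[2])
      lne[, t] <- lne[, t - 1] + 0.5 * abs(steps[, t - 1]) + 0.01
  }
  edges <- c(grid[1] - (grid[2] - grid[1]) / 2,
             (grid[-G] + grid[-1]) / 2,
             grid[G] + (grid[G] - grid[G - 1]) / 2)
  edges[1] <- max(edges[1], 0)
  lapply(seq_len(k), function(s) {
    ne_trajectory(steps = data.frame(t_lo = edges[-(G + 1)],
                                     t_hi = edges[-1],
                                     ne = exp(lne[s, ])),
                  species = paste0("species", s))
  })
}
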