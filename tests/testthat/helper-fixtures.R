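# Shared fixture builders (all programmatic; no data files).

# small genotype matrix with given allele-count columns
toy_gm <- function(geno, ...) {
  genotype_matrix(genotypes = geno, ...)
}

# random biallelic genotype matrix without missing data: minor allele
# counts drawn per site, genotypes assembled by random assignment of
# allele copies to individuals
random_gm <- function(n_ind, S, L = S, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_hap <- 2 * n_ind
  g <- matrix(0L, n_ind, S)
  for (s in seq_len(S)) {
    ac <- sample.int(n_hap - 1, 1)
    hap <- sample(c(rep(1L, ac), rep(0L, n_hap - ac)))
    g[, s] <- hap[seq(1, n_hap, 2)] + hap[seq(2, n_hap, 2)]
  }
  genotype_matrix(genotypes = g, L_total = L)
}

# brute-force mean pairwise difference per site across all pairs of
# allele copies (independent oracle for the SFS diversity estimator)
pi_pairwise_oracle <- function(gm) {
  g <- gm$genotypes
  n_hap <- 2 * nrow(g)
  total <- 0
  for (s in seq_len(ncol(g))) {
    ac <- sum(g[, s])
    # enumerate allele copies explicitly and count differing pairs
    copies <- c(rep(1L, ac), rep(0L, n_hap - ac))
    diffs <- 0L
    for (i in seq_len(n_hap - 1)) for (j in (i + 1):n_hap)
      diffs <- diffs + (copies[i] != copies[j])
    total <- total + diffs / choose(n_hap, 2)
  }
  total / gm$L_total
}

# exhaustive concordant/discordant Kendall tau-b oracle
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- txy <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i])
    dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) txy <- txy + 1L
    else if (dx == 0) tx <- tx + 1L
    else if (dy == 0) ty <- ty + 1L
    else if (dx == dy) conc <- conc + 1L
    else disc <- disc + 1L
  }
  n0 <- choose(n, 2)
  n1 <- tx + txy                # pairs tied in x
  n2 <- ty + txy                # pairs tied in y
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) return(NA_real_)
  (conc - disc) / den
}

# aligned trajectories straight from a matrix (rows = species)
aligned_from_matrix <- function(ne, grid = seq_len(ncol(ne))) {
  structure(list(grid = grid,
                 ne = matrix(ne, nrow = nrow(ne),
                             dimnames = list(rownames(ne), NULL))),
            class = "aligned_trajectories")
}
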