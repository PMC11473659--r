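test_that("glacial-cycle demography places ten alternating events", {
  d <- glacial_cycle_demography(gen_time_years = 1, ne_current = 1e5)
  expect_length(d$ne, 11)                      # 10 events = 11 epochs
  expect_equal(d$t_start[2], 15000)            # expansion 15 kya
  expect_equal(d$t_start[3], 120000)           # decline 120 kya
  expect_equal(diff(d$t_start[-(1:2)]), rep(120000, 8))
  expect_equal(d$t_start[11], 1.08e6, tolerance = 1e-9)   # ~1 Mya
  # Ne alternates by exactly the fold factor, high phase at both ends
  ratios <- d$ne[-1] / d$ne[-11]
  expect_true(all(ratios %in% c(1 / 10, 10)))
  expect_equal(d$ne[1], 1e5)
  expect_equal(d$ne[11], 1e5)
  # generation-time scaling: 25 y/gen -> first event at 600 generations
  d25 <- glacial_cycle_demography(25, 1e5)
  expect_equal(d25$t_start[2], 600)
  expect_error(glacial_cycle_demography(0, 1e5), "positive")
  expect_error(glacial_cycle_demography(25, 1e5, fold = 1), "fold")
})

test_that("demography constructor enforces its invariants", {
  expect_error(demography(c(1e4, 1e4), c(0, 0)), "increasing")
  expect_error(demography(c(1e4, -1), c(0, 10)), "positive")
  expect_error(demography(1e4, 5), "time 0")
  expect_error(demography(numeric(0), numeric(0)), "epoch")
})

test_that("constant-Ne simulated folded SFS matches Watterson within MC error", {
  ne <- 1e4; mu <- 1e-8; L <- 5e6; n <- 10
  batches <- 20; reps_per <- 1000
  sims <- sapply(seq_len(batches), function(b)
    simulate_coalescent_sfs(demography(ne, 0), n, L, mu,
                            reps = reps_per, seed = 100 + b)$eta)
  m <- rowMeans(sims)
  se <- apply(sims, 1, sd) / sqrt(batches)
  theta <- 4 * ne * mu
  i <- 1:(n - 1); xi <- theta * L / i
  eta_exp <- xi[1:5]; eta_exp[1:4] <- eta_exp[1:4] + rev(xi[6:9])
  expect_true(all(abs(m - eta_exp) <= 3 * se + 1e-9))
  # n = 2: E[eta1]/L = theta (mean pairwise diversity)
  s2 <- simulate_coalescent_sfs(demography(ne, 0), 2, 1e7, mu,
                                reps = 5000, seed = 3)
  expect_lt(abs(s2$eta[1] / 1e7 - theta) / theta, 0.1)
  # determinism under seed
  a <- simulate_coalescent_sfs(demography(ne, 0), 6, 1e5, mu, 100, seed = 9)
  b <- simulate_coalescent_sfs(demography(ne, 0), 6, 1e5, mu, 100, seed = 9)
  expect_identical(a$eta, b$eta)
  expect_error(simulate_coalescent_sfs(demography(ne, 0), 1, 1e5, mu), "n")
})

test_that("time rescaling leaves the expected spectrum invariant", {
  dem <- demography(c(1e4, 2e3, 5e4), c(0, 3000, 20000))
  e1 <- expected_sfs(dem, 12, mu = 1e-8, L = 1e6)
  c_factor <- 7
  dem2 <- demography(dem$ne * c_factor, dem$t_start * c_factor)
  e2 <- expected_sfs(dem2, 12, mu = 1e-8 / c_factor, L = 1e6)
  expect_equal(e1$eta, e2$eta, tolerance = 1e-10)
})

test_that("two-deme simulator obeys symmetry and limit cases", {
  # fully symmetric model: joint SFS symmetric under axis swap
  m <- divergence_model(npop1 = 1e4, npop2 = 1e4, nanc = 1e4, tdiv = 1e4,
                        n1m21 = 2, n2m12 = 2)
  j <- simulate_two_deme_sfs(m, 6, 6, L = 1e6, mu = 1e-8, reps = 8000,
                             seed = 4)
  seg <- sum(j$counts) - j$counts[1, 1]
  asym <- max(abs(j$counts[-1, -1] - t(j$counts[-1, -1])))
  expect_lt(asym / seg, 0.02)
  # tdiv = 0, no size change: marginal equals pooled single-population run
  m0 <- divergence_model(npop1 = 1e4, npop2 = 1e4, nanc = 1e4, tdiv = 0)
  j0 <- simulate_two_deme_sfs(m0, 5, 5, L = 1e6, mu = 1e-8, reps = 8000,
                              seed = 5)
  pooled <- pool_joint_sfs(j0)
  single <- simulate_coalescent_sfs(demography(1e4, 0), 10, 1e6, 1e-8,
                                    reps = 8000, seed = 6)
  expect_lt(max(abs(pooled$eta - single$eta)) / sum(single$eta), 0.03)
  # no migration, deep split: no shared polymorphism
  mdeep <- divergence_model(npop1 = 1e3, npop2 = 1e3, nanc = 1e3,
                            tdiv = 5e5)
  jd <- simulate_two_deme_sfs(mdeep, 4, 4, L = 1e5, mu = 1e-8,
                              reps = 3000, seed = 7)
  shared <- sum(jd$counts[2:4, 2:4])
  expect_lt(shared / (sum(jd$counts) - jd$counts[1, 1]), 0.02)
  expect_identical(
    simulate_two_deme_sfs(m, 4, 4, 1e5, 1e-8, 200, seed = 8)$counts,
    simulate_two_deme_sfs(m, 4, 4, 1e5, 1e-8, 200, seed = 8)$counts)
})

test_that("genotype-matrix simulator respects construction invariants", {
  dem <- demography(1e4, 0)
  gm <- simulate_genotype_matrix(dem, n_ind = 12, L = 1e5, mu = 1e-8,
                                 missing_rate = 0, loci = 60, seed = 20)
  expect_false(anyNA(gm$genotypes))
  expect_true(all(gm$genotypes %in% 0:2))
  expect_true(all(diff(gm$positions) > 0))
  expect_equal(gm$L_total, 1e5)
  # GQ synthesized monotone in DP
  expect_true(all(gm$gq == pmin(99L, as.integer(round(10 * gm$dp / 3)))))
  gm_m <- simulate_genotype_matrix(dem, 12, 1e5, 1e-8, missing_rate = 0.3,
                                   loci = 60, seed = 21)
  expect_gt(mean(is.na(gm_m$genotypes)), 0.2)
  expect_lt(mean(is.na(gm_m$genotypes)), 0.4)
  a <- simulate_genotype_matrix(dem, 8, 1e4, 1e-8, loci = 20, seed = 22)
  b <- simulate_genotype_matrix(dem, 8, 1e4, 1e-8, loci = 20, seed = 22)
  expect_identical(a$genotypes, b$genotypes)
  expect_error(simulate_genotype_matrix(dem, 8, 1e4, 1e-8,
                                        missing_rate = 1), "missing_rate")
})

test_that("simulated genotypes reproduce neutral diversity", {
  ne <- 1e4; mu <- 1e-8
  gm <- simulate_genotype_matrix(demography(ne, 0), n_ind = 20, L = 1e6,
                                 mu = mu, loci = 300, seed = 23)
  pi_hat <- pi_from_sfs(build_folded_sfs(gm, target_n = 40))
  expect_lt(abs(pi_hat - 4 * ne * mu) / (4 * ne * mu), 0.2)
})

test_that("paralog injector produces the advertised read-ratio structure", {
  gm <- simulate_genotype_matrix(demography(1e4, 0), 10, 1e5, 1e-8,
                                 loci = 80, seed = 24)
  inj <- inject_paralogs(gm, prop = 0.1, depth = 30, seed = 25)
  # injected sites: every non-missing call heterozygous
  for (s in inj$paralog_sites) {
    g <- inj$gm$genotypes[, s]
    expect_true(all(g[!is.na(g)] == 1L))
  }
  # every recorded heterozygote has >= 1 read
  expect_true(all(inj$reads$reads_a + inj$reads$reads_b >= 1))
  # non-paralog pooled reads balanced: |D| small on average
  st <- hdplot(inj$gm, inj$reads)
  nonpar <- setdiff(st$site[!is.na(st$d)], inj$paralog_sites)
  expect_lt(abs(mean(st$d[nonpar])), 2)
  expect_identical(inject_paralogs(gm, 0.1, seed = 26)$paralog_sites,
                   inject_paralogs(gm, 0.1, seed = 26)$paralog_sites)
})

test_that("single-population simulator agrees with an external coalescent oracle", {
  # msprime as the independent simulator on a two-epoch benchmark
  dem <- demography(c(2e3, 2e4), c(0, 1000))
  n <- 8; mu <- 1e-8; L <- 1e6
  py <- sprintf(paste0(
    "import msprime, numpy as np\n",
    "dem = msprime.Demography()\n",
    "dem.add_population(initial_size=2e3)\n",
    "dem.add_population_parameters_change(time=1000, initial_size=2e4)\n",
    "reps = 3000\n",
    "afs = np.zeros(%d + 1)\n",
    "for ts in msprime.sim_ancestry(samples=%d, demography=dem, ploidy=2,\n",
    "        sequence_length=1, num_replicates=reps, random_seed=42):\n",
    "    afs += ts.allele_frequency_spectrum(mode='branch',\n",
    "        polarised=True, span_normalise=False)\n",
    "xi = afs[1:%d] / reps * %g * %g\n",
    "print(' '.join(str(float(v)) for v in xi))\n"), n, n %/% 2, n, mu, L)
  out <- system2("python", c("-c", shQuote(py)), stdout = TRUE)
  xi_ms <- as.numeric(strsplit(tail(out, 1), " ")[[1]])
  eta_ms <- xi_ms[1:4]; eta_ms[1:3] <- eta_ms[1:3] + rev(xi_ms[5:7])
  ours <- expected_sfs(dem, n, mu, L)
  # 3000-replicate Monte Carlo SE is a few percent per entry
  expect_true(all(abs(eta_ms / ours$eta - 1) < 0.1))
  sim <- simulate_coalescent_sfs(dem, n, L, mu, reps = 20000, seed = 44)
  expect_true(all(abs(sim$eta / ours$eta - 1) < 0.15))
})
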