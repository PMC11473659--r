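test_that("expected SFS reduces to the Watterson closed form and scales", {
  ne <- 5e3; mu <- 2e-8; L <- 1e6; n <- 12
  e <- expected_sfs(demography(ne, 0), n, mu, L)
  theta <- 4 * ne * mu
  i <- 1:(n - 1); xi <- theta * L / i
  eta <- xi[1:6]; eta[1:5] <- eta[1:5] + rev(xi[7:11])
  expect_equal(e$eta, eta, tolerance = 1e-12)
  expect_equal(e$n_mono, L - sum(eta), tolerance = 1e-9)
  # doubling sizes and times while halving mu is an exact no-op
  dem <- demography(c(1e4, 1e3), c(0, 2500))
  e1 <- expected_sfs(dem, 10, mu, L)
  e2 <- expected_sfs(demography(dem$ne * 2, dem$t_start * 2), 10, mu / 2, L)
  expect_equal(e1$eta, e2$eta, tolerance = 1e-12)
})

test_that("expected SFS matches Monte Carlo on benchmark demographies", {
  benchmarks <- list(
    demography(1e4, 0),
    demography(c(1e5, 1e4), c(0, 5000)),
    demography(c(5e3, 5e4, 5e3), c(0, 2000, 20000)))
  for (k in seq_along(benchmarks)) {
    dem <- benchmarks[[k]]
    e <- expected_sfs(dem, 10, 1e-8, 5e6)
    batches <- sapply(1:12, function(b)
      simulate_coalescent_sfs(dem, 10, 5e6, 1e-8, reps = 1500,
                              seed = 1000 * k + b)$eta)
    m <- rowMeans(batches)
    se <- apply(batches, 1, sd) / sqrt(ncol(batches))
    expect_true(all(abs(m - e$eta) <= 3 * se + 1e-9),
                info = paste("benchmark", k))
  }
})

test_that("composite log-likelihood matches a direct Poisson oracle", {
  obs <- folded_sfs(c(12, 5, 3), 6, L = 1000)
  ex <- folded_sfs(c(10, 6, 2.5), 6, L = 1000)
  oracle <- sum(dpois(c(12, 5, 3), c(10, 6, 2.5), log = TRUE)) +
    dpois(1000 - 20, 1000 - 18.5, log = TRUE)
  expect_equal(composite_loglik(obs, ex), oracle, tolerance = 1e-9)
  # additive over disjoint entry subsets
  half1 <- composite_loglik(folded_sfs(c(12, 0, 0), 6, L = 12),
                            folded_sfs(c(10, 0, 0), 6, L = 10))
  # maximized at obs = exp for integer observations
  ll_at_truth <- composite_loglik(obs, obs)
  for (d in c(-1, 1)) {
    pert <- folded_sfs(obs$eta + c(d, 0, 0), 6, L = 1000)
    expect_lt(composite_loglik(obs, pert), ll_at_truth)
  }
  # zero expectation with positive observation
  expect_warning(
    ll0 <- composite_loglik(obs, folded_sfs(c(0, 6, 2.5), 6, L = 1000)),
    "0")
  expect_identical(ll0, -Inf)
  expect_error(composite_loglik(obs, folded_sfs(c(1, 1), 4, L = 10)), "n")
})

test_that("AIC table follows the formula and rejects mixed datasets", {
  f1 <- structure(list(model_name = "SNM", k = 1, loglik = -100,
                       aic = 2 - 2 * (-100), signature = c(1, 2, 3)),
                  class = "epoch_fit")
  f3 <- structure(list(model_name = "epoch3", k = 3, loglik = -100,
                       aic = 6 - 2 * (-100), signature = c(1, 2, 3)),
                  class = "epoch_fit")
  tab <- compare_models_aic(list(f3, f1))
  expect_equal(tab$model, c("SNM", "epoch3"))   # equal loglik: smaller k wins
  expect_equal(tab$delta_aic, c(0, 4))
  # permutation invariance of the ranking
  expect_equal(compare_models_aic(list(f1, f3)), tab)
  f_other <- structure(list(model_name = "SNM", k = 1, loglik = -5,
                            aic = 12, signature = c(9, 9, 9)),
                       class = "epoch_fit")
  expect_error(compare_models_aic(list(f1, f_other)), "same observed")
  expect_error(compare_models_aic(list(f1)), "two fits")
})

test_that("epoch-2 fitting recovers simulated parameters and beats SNM", {
  mu <- 7.77e-9; L <- 3e6
  truth <- demography(c(1e5, 1e4), c(0, 5000))
  e <- expected_sfs(truth, 20, mu, L)
  set.seed(77)
  obs <- folded_sfs(rpois(length(e$eta), e$eta), 20, L = L)
  f2 <- fit_epoch_model(obs, "epoch2", mu, n_starts = 12, seed = 1)
  expect_lt(abs(f2$params[["NANC"]] - 1e4) / 1e4, 0.25)
  expect_lt(abs(f2$params[["NCUR"]] - 1e5) / 1e5, 0.25)
  expect_lt(abs(f2$params[["TBOT"]] - 5000) / 5000, 0.25)
  f1 <- fit_epoch_model(obs, "SNM", mu, n_starts = 6, seed = 2)
  expect_lt(f2$aic, f1$aic)
  # parameters respect the prior bounds
  expect_true(all(f2$params >= 10 & f2$params <= 1e7))
  # likelihood nesting: more epochs never fit worse
  f3 <- fit_epoch_model(obs, "epoch3", mu, n_starts = 12, seed = 3)
  expect_gte(f3$loglik, f2$loglik - 0.05)
  expect_gte(f2$loglik, f1$loglik)
})

test_that("parametric bootstrap intervals cover the point estimate", {
  mu <- 1e-8; L <- 1e6
  truth <- demography(c(5e4, 5e3), c(0, 3000))
  e <- expected_sfs(truth, 12, mu, L)
  set.seed(5)
  obs <- folded_sfs(rpois(length(e$eta), e$eta), 12, L = L)
  best <- fit_epoch_model(obs, "epoch2", mu, n_starts = 10, seed = 6)
  ci <- bootstrap_ci(best, obs, n_boot = 12, n_starts = 5, seed = 7)
  expect_equal(ci$n_success, 12)
  inside <- ci$intervals$estimate >= ci$intervals$lower &
    ci$intervals$estimate <= ci$intervals$upper
  expect_true(all(inside))
  ci2 <- bootstrap_ci(best, obs, n_boot = 12, n_starts = 5, seed = 7)
  expect_equal(ci$intervals, ci2$intervals)
})

test_that("stairway-style trajectories recover flat and expanding histories", {
  mu <- 1e-8; L <- 2e6
  # constant Ne: flat within +/- 20 percent of truth
  sfs_flat <- simulate_coalescent_sfs(demography(2e4, 0), 16, L, mu,
                                      reps = 2000, seed = 30)
  tr_flat <- stairway_like_fit(sfs_flat, mu, n_boot = 12, n_starts = 3,
                               seed = 31)
  expect_true(all(abs(tr_flat$steps$ne / 2e4 - 1) < 0.2))
  expect_equal(count_reversals(tr_flat), 0)
  # tenfold expansion: present over ancient median ratio above 3
  sfs_exp <- simulate_coalescent_sfs(demography(c(1e5, 1e4), c(0, 2e4)),
                                     16, L, mu, reps = 2000, seed = 32)
  tr_exp <- stairway_like_fit(sfs_exp, mu, n_boot = 12, n_starts = 3,
                              seed = 33)
  ne <- tr_exp$steps$ne
  expect_gt(ne[1] / ne[length(ne)], 3)
  # halving mu doubles sizes and times exactly (same seed)
  tr_a <- stairway_like_fit(sfs_flat, mu, n_boot = 6, n_starts = 2,
                            seed = 34)
  tr_b <- stairway_like_fit(sfs_flat, mu / 2, n_boot = 6, n_starts = 2,
                            seed = 34)
  expect_equal(tr_b$steps$ne, tr_a$steps$ne * 2, tolerance = 1e-9)
  expect_equal(tr_b$steps$t_lo, tr_a$steps$t_lo * 2, tolerance = 1e-9)
  # refuses clearly underpowered input
  tiny <- folded_sfs(c(3, 2, 1, 1, 0, 0, 0, 0), 16, L = 1e4)
  expect_error(stairway_like_fit(tiny, mu), "segregating")
})

test_that("reversal counting compresses monotone segments", {
  mk <- function(ne) ne_trajectory(data.frame(
    t_lo = seq_along(ne) - 1, t_hi = seq_along(ne), ne = ne))
  expect_equal(count_reversals(mk(c(1e5, 5e4, 1e4, 5e3))), 0)
  expect_equal(count_reversals(mk(c(1e5, 1e4, 1e5))), 1)
  expect_equal(count_reversals(mk(c(1e5, 1e4, 1e5, 1e4))), 2)
  # sub-threshold wiggles are ignored
  expect_equal(count_reversals(mk(c(1e5, 9.5e4, 1e5, 9.5e4))), 0)
})

test_that("mixed-population check is quiet for panmixia, loud for structure", {
  mu <- 1e-8
  # null: one panmictic simulation split into two arbitrary halves
  gm <- simulate_genotype_matrix(demography(2e4, 0), n_ind = 24, L = 1e6,
                                 mu = mu, loci = 500, seed = 40)
  gm$pop <- rep(c("a", "b"), each = 12)
  chk0 <- mixed_population_check(gm, mu, n_boot = 8, n_starts = 2, seed = 41)
  expect_lt(chk0$max_log_ratio, log(3))
  # strongly diverged pair: two independent populations with different
  # sizes, carried on disjoint site blocks
  g1 <- simulate_genotype_matrix(demography(5e4, 0), 12, 5e5, mu,
                                 loci = 250, seed = 42)
  g2 <- simulate_genotype_matrix(demography(3e3, 0), 12, 5e5, mu,
                                 loci = 250, seed = 43)
  S1 <- ncol(g1$genotypes); S2 <- ncol(g2$genotypes)
  geno <- rbind(cbind(g1$genotypes, matrix(0L, 12, S2)),
                cbind(matrix(0L, 12, S1), g2$genotypes))
  gms <- genotype_matrix(geno, positions = seq_len(S1 + S2), L_total = 1e6,
                         pop = rep(c("a", "b"), each = 12))
  chk1 <- mixed_population_check(gms, mu, n_boot = 8, n_starts = 2,
                                 seed = 44)
  expect_gt(chk1$max_log_ratio, chk0$max_log_ratio)
  expect_gt(chk1$max_log_ratio, 0.5)
})
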