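test_that("geodesic distance matches the spherical closed form", {
  expect_equal(geodesic_km(10, 20, 10, 20), 0)
  # one degree of longitude at the equator: R * pi/180
  expect_equal(geodesic_km(0, 0, 0, 1), 6371.0088 * pi / 180,
               tolerance = 1e-6)
  expect_equal(geodesic_km(48.2, 16.4, 59.3, 18.1),
               geodesic_km(59.3, 18.1, 48.2, 16.4))
  expect_error(geodesic_km(95, 0, 0, 0), "range")
})

test_that("pairwise FST matches a hand-computed Weir-Cockerham oracle", {
  # one site, two populations of 4 diploids: pop1 genotypes 0,0,1,1;
  # pop2 genotypes 2,2,1,1
  g <- matrix(c(0L, 0L, 1L, 1L, 2L, 2L, 1L, 1L), 8, 1)
  gm <- toy_gm(g, pop = rep(c("a", "b"), each = 4))
  # oracle: direct evaluation of the variance components
  ni <- c(4, 4); p <- c(2/8, 6/8); het <- c(0.5, 0.5); r <- 2
  nbar <- 4; nc <- (8 - 32 / 8) / 1
  pbar <- 0.5
  s2 <- sum(ni * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- 0.5
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / 3)
  b <- (nbar / 3) * (pbar * (1 - pbar) - s2 / 2 - hbar * 7 / 16)
  cc <- hbar / 2
  expect_equal(unname(pairwise_fst(gm)["a", "b"]), a / (a + b + cc),
               tolerance = 1e-12)
})

test_that("FST hits the fixed-difference and panmictic limits", {
  # alternate alleles fixed in each population
  g <- matrix(c(rep(0L, 6), rep(2L, 6)), 12, 1)
  g <- cbind(g, g)
  gm <- toy_gm(g, pop = rep(c("a", "b"), each = 6))
  expect_equal(unname(pairwise_fst(gm)["a", "b"]), 1, tolerance = 1e-9)
  # one panmictic pool split arbitrarily -> FST ~ 0
  gm2 <- random_gm(n_ind = 40, S = 400, seed = 5)
  gm2$pop <- rep(c("a", "b"), each = 20)
  f <- pairwise_fst(gm2)["a", "b"]
  expect_lt(abs(f), 0.01)
  # diagonal zero, symmetric, negatives retained (not clamped)
  expect_equal(diag(pairwise_fst(gm2)), c(a = 0, b = 0))
})

test_that("IBD regression recovers an exact collinear slope", {
  set.seed(8)
  K <- 8
  coords <- data.frame(pop = paste0("p", 1:K),
                       lat = runif(K, 40, 60), lon = runif(K, -5, 25))
  pairs <- t(combn(K, 2))
  d <- geodesic_km(coords$lat[pairs[, 1]], coords$lon[pairs[, 1]],
                   coords$lat[pairs[, 2]], coords$lon[pairs[, 2]])
  beta <- 0.015; alpha <- -0.02
  y <- beta * log(d) + alpha
  f <- y / (1 + y)                      # invert y = f/(1-f)
  fst <- matrix(0, K, K, dimnames = list(coords$pop, coords$pop))
  fst[pairs] <- f; fst[pairs[, 2:1]] <- f
  fit <- suppressWarnings(ibd_regression(fst, coords))  # perfect-fit lm
  expect_equal(fit$beta, beta, tolerance = 1e-12)
  expect_equal(fit$alpha, alpha, tolerance = 1e-12)
  expect_equal(sum(fit$residuals), 0, tolerance = 1e-12)
  # fitted + residuals reproduce the inputs exactly
  expect_equal(unname(fitted(fit$lm) + fit$residuals),
               fit$pairs$fst / (1 - fit$pairs$fst), tolerance = 1e-12)
})

test_that("IBD slope is null under distance permutation", {
  set.seed(9)
  K <- 10
  coords <- data.frame(pop = paste0("p", 1:K),
                       lat = runif(K, 40, 60), lon = runif(K, -5, 25))
  fst <- matrix(0, K, K, dimnames = list(coords$pop, coords$pop))
  u <- runif(choose(K, 2), 0.01, 0.2)
  fst[t(combn(K, 2))] <- u
  fst[t(combn(K, 2))[, 2:1]] <- u
  betas <- replicate(100, {
    perm <- sample(K)
    co <- coords; co$lat <- co$lat[perm]; co$lon <- co$lon[perm]
    ibd_regression(fst, co)$beta
  })
  expect_lt(abs(mean(betas)), 2 * sd(betas) / sqrt(100))
})

test_that("IBD is invariant to population relabeling", {
  set.seed(10)
  K <- 6
  coords <- data.frame(pop = paste0("p", 1:K),
                       lat = runif(K, 40, 60), lon = runif(K, -5, 25))
  fst <- matrix(0, K, K, dimnames = list(coords$pop, coords$pop))
  u <- runif(choose(K, 2), 0.01, 0.2)
  fst[t(combn(K, 2))] <- u; fst[t(combn(K, 2))[, 2:1]] <- u
  f1 <- ibd_regression(fst, coords)
  perm <- sample(K)
  f2 <- ibd_regression(fst[perm, perm], coords)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-9)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-9)
})

test_that("scaled population FST agrees with direct arithmetic in all modes", {
  coords <- data.frame(pop = c("a", "b", "c"),
                       lat = c(0, 0, 1), lon = c(0, 1, 0))
  fst <- matrix(c(0, .1, .2, .1, 0, .4, .2, .4, 0), 3, 3,
                dimnames = list(coords$pop, coords$pop))
  dab <- geodesic_km(0, 0, 0, 1)
  dac <- geodesic_km(0, 0, 1, 0)
  dbc <- geodesic_km(0, 1, 1, 0)
  mor <- scaled_population_fst(fst, coords, "mean_of_ratios_km")
  expect_equal(unname(mor["a"]), mean(c(.1 / dab, .2 / dac)), tolerance = 1e-12)
  rom <- scaled_population_fst(fst, coords, "ratio_of_means_km")
  expect_equal(unname(rom["c"]), mean(c(.2, .4)) / mean(c(dac, dbc)),
               tolerance = 1e-12)
  morl <- scaled_population_fst(fst, coords, "mean_of_ratios_logkm")
  expect_equal(unname(morl["b"]), mean(c(.1 / log(dab), .4 / log(dbc))),
               tolerance = 1e-12)
  # two populations: both values equal FST/d
  co2 <- coords[1:2, ]
  both <- scaled_population_fst(fst[1:2, 1:2], co2)
  expect_equal(unname(both), rep(.1 / dab, 2), tolerance = 1e-12)
})
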