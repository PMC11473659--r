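test_that("step conversion takes midpoints and drops the most recent interval", {
  steps <- data.frame(t_lo = c(0, 10), t_hi = c(10, 30), ne = c(100, 200))
  out <- trajectory_to_steps(steps)
  expect_equal(out$time, 20)
  expect_equal(out$ne, 200)
  # three equal-Ne intervals -> two identical values at two midpoints
  st3 <- data.frame(t_lo = c(0, 10, 20), t_hi = c(10, 20, 40),
                    ne = c(5, 5, 5))
  out3 <- trajectory_to_steps(st3)
  expect_equal(out3$ne, c(5, 5))
  expect_equal(out3$time, c(15, 30))
  # single interval errors (empty after the drop)
  expect_error(trajectory_to_steps(data.frame(t_lo = 0, t_hi = 1, ne = 2)),
               "two intervals")
})

test_that("grid alignment picks nearest steps with older-midpoint ties", {
  a <- data.frame(time = c(10, 30), ne = c(1, 2))
  b <- data.frame(time = c(20, 40), ne = c(5, 6))
  al <- align_on_grid(list(a = a, b = b))
  expect_equal(al$grid, c(10, 20, 30, 40))
  # equidistant queries break toward the OLDER midpoint: species a at
  # t=20 (between 10 and 30) takes 30's value; species b at t=30
  # (between 20 and 40) takes 40's value
  expect_equal(al$ne["a", ], c(1, 2, 2, 2))
  expect_equal(al$ne["b", ], c(5, 5, 6, 6))
  # single species: identity
  al1 <- align_on_grid(list(x = a))
  expect_equal(al1$ne["x", ], a$ne)
  # idempotence: aligning already-aligned data changes nothing
  again <- align_on_grid(list(
    a = data.frame(time = al$grid, ne = al$ne["a", ]),
    b = data.frame(time = al$grid, ne = al$ne["b", ])))
  expect_equal(again$ne, al$ne)
  expect_equal(again$grid, al$grid)
})

test_that("Kendall matrix matches the enumeration oracle and rank invariance", {
  x <- c(3, 1, 4, 1, 5, 9)
  al <- aligned_from_matrix(rbind(a = x, b = x, c = rev(x)))
  tau <- kendall_matrix(al)
  expect_equal(tau["a", "b"], 1)
  expect_equal(diag(tau), c(a = 1, b = 1, c = 1))
  expect_equal(tau, t(tau))
  # exactly reversed ranks (no ties in the distinct part)
  y <- c(1, 2, 3, 4)
  al2 <- aligned_from_matrix(rbind(a = y, b = rev(y)))
  expect_equal(kendall_matrix(al2)["a", "b"], -1)
  # brute-force oracle on 4-point toy series with ties
  set.seed(12)
  for (i in 1:20) {
    u <- sample(1:3, 5, TRUE)
    v <- sample(1:3, 5, TRUE)
    al3 <- aligned_from_matrix(rbind(a = u, b = v))
    expect_equal(kendall_matrix(al3)["a", "b"], kendall_oracle(u, v))
  }
  # invariance under strictly monotone transform
  al4 <- aligned_from_matrix(rbind(a = x, b = c(2, 7, 1, 8, 2, 8)))
  expect_equal(kendall_matrix(aligned_from_matrix(
    rbind(a = exp(x), b = c(2, 7, 1, 8, 2, 8)^3)))["a", "b"],
    kendall_matrix(al4)["a", "b"])
  # constant series -> NA off-diagonal
  al5 <- aligned_from_matrix(rbind(a = rep(1, 5), b = 1:5))
  expect_true(is.na(kendall_matrix(al5)["a", "b"]))
})

test_that("smoothed Ne changes follow the sign and arithmetic conventions", {
  # constant series -> all zero
  al <- aligned_from_matrix(matrix(7, 2, 10))
  expect_true(all(delta_ne_smoothed(al, w = 3) == 0))
  # strictly increasing toward the past -> negative (growth toward present)
  al2 <- aligned_from_matrix(matrix(1:10, 1, 10, byrow = TRUE))
  expect_true(all(delta_ne_smoothed(al2, w = 4) < 0))
  # linear series with slope s on a unit grid -> every window equals -s
  s <- 2.5
  al3 <- aligned_from_matrix(matrix(5 + s * (0:19), 1, 20, byrow = TRUE))
  expect_equal(unname(delta_ne_smoothed(al3, w = 5)[1, ]),
               rep(-s, 15), tolerance = 1e-12)   # (G-1) - w + 1 windows
  expect_error(delta_ne_smoothed(al3, w = 25), "exceed")
})

test_that("randomization preserves the Delta-Ne multiset and seeds reproduce", {
  set.seed(13)
  dne <- rnorm(40)
  for (i in 1:25) {
    out <- glacialsfs:::permute_and_smooth(dne, w = 5)
    expect_equal(sort(out$perm), sort(dne))
    expect_equal(out$smoothed, glacialsfs:::roll_mean(out$perm, 5))
  }
  al <- aligned_from_matrix(matrix(exp(rnorm(3 * 60)), 3, 60))
  r1 <- synchrony_randomization(al, w = 10, n_perm = 200, seed = 3)
  r2 <- synchrony_randomization(al, w = 10, n_perm = 200, seed = 3)
  expect_identical(r1$null_95, r2$null_95)
  expect_identical(r1$p_run, r2$p_run)
})

test_that("an engineered shared decrease is detected; constants are not", {
  # growth toward the present (the typical inferred-trajectory signal)
  # with one shared decline episode covering a minority of the span
  grid <- seq_len(600)
  trajs <- simulate_trajectory_set(k = 4, grid = grid,
                                   shared_decreases = list(c(300, 400)),
                                   noise = 0.05, drift = 0.01, seed = 14)
  al <- align_on_grid(lapply(trajs, trajectory_to_steps))
  res <- synchrony_randomization(al, w = 50, n_perm = 500, seed = 15)
  expect_equal(res$observed_max_species, 4)
  expect_true(res$significant)
  # constant trajectories: degenerate null, not significant
  al0 <- aligned_from_matrix(matrix(5, 3, 80))
  res0 <- synchrony_randomization(al0, w = 20, n_perm = 200, seed = 16)
  expect_equal(res0$observed_max_species, 0)
  expect_false(res0$significant)
  expect_warning(synchrony_randomization(al0, w = 20, n_perm = 50),
                 "permutations")
})

test_that("trajectory-set generator honors windows and degenerate cases", {
  grid <- seq_len(100)
  # constant (zero-noise) walks have zero decreases anywhere
  trajs <- simulate_trajectory_set(k = 3, grid = grid, noise = 0,
                                   seed = 17)
  al <- align_on_grid(lapply(trajs, trajectory_to_steps))
  expect_true(all(abs(al$ne[, -1] - al$ne[, -ncol(al$ne)]) < 1e-12))
  # shared window forces every species to decrease toward the present
  trajs2 <- simulate_trajectory_set(k = 3, grid = grid,
                                    shared_decreases = list(c(20, 80)),
                                    noise = 0.05, seed = 18)
  ne2 <- t(vapply(trajs2, function(tr) tr$steps$ne, numeric(100)))
  expect_true(all(ne2[, 21:80] > ne2[, 20:79]))
  expect_error(simulate_trajectory_set(3, grid, list(c(50, 20))),
               "malformed")
  expect_error(simulate_trajectory_set(3, grid, list(c(10, 50), c(40, 80))),
               "overlap")
  expect_error(simulate_trajectory_set(1, grid), "k")
})
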