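#' Step-function Ne trajectory
#'
#' A succession of contiguous time intervals, each carrying a constant Ne
#' estimate, plus the scaling metadata (mutation rate, generation time)
#' used to express times in years. Optional percentile bands accompany
#' bootstrap-based estimates.
#'
#' @param steps data frame with columns `t_lo`, `t_hi` (interval bounds,
#'   generations unless `time_unit = "years"`), `ne`, and optionally
#'   `ne_lo`, `ne_hi` percentile bands. Intervals must be contiguous with
#'   increasing times and positive `ne`.
#' @param mu per-site per-generation mutation rate used for scaling
#'   (metadata; `NA` allowed).
#' @param gen_time_years generation time in years (metadata).
#' @param time_unit `"generations"` or `"years"`.
#' @param species optional label.
#' @return An object of class `ne_trajectory`.
#' @export
ne_trajectory <- function(steps, mu = NA_real_, gen_time_years = NA_real_,
                          time_unit = c("generations", "years"),
                          species = NA_character_) {
  time_unit <- match.arg(time_unit)
  stopifnot(is.data.frame(steps), all(c("t_lo", "t_hi", "ne") %in% names(steps)))
  if (nrow(steps) < 1) stop("trajectory needs at least one interval")
  if (any(steps$ne <= 0)) stop("'ne' must be positive")
  if (any(steps$t_hi <= steps$t_lo)) stop("intervals must have t_hi > t_lo")
  if (nrow(steps) > 1) {
    if (any(abs(steps$t_lo[-1] - steps$t_hi[-nrow(steps)]) >
            1e-8 * pmax(steps$t_hi[-nrow(steps)], 1)))
      stop("intervals must be contiguous and ordered from the present")
  }
  structure(list(steps = steps, mu = mu, gen_time_years = gen_time_years,
                 time_unit = time_unit, species = species),
            class = "ne_trajectory")
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat(sprintf("Ne trajectory (%d steps, time in %s%s):\n", nrow(x$steps),
              x$time_unit,
              if (!is.na(x$species)) paste0(", ", x$species) else ""))
  print(utils::head(x$steps, 10))
  if (nrow(x$steps) > 10) cat("  ...\n")
  invisible(x)
}

# Ne at arbitrary times for a step trajectory (times beyond the last
# interval take the terminal value)
trajectory_ne_at <- function(traj, t) {
  s <- traj$steps
  idx <- findInterval(t, c(s$t_lo[1], s$t_hi))
  idx[idx < 1] <- 1
  idx[idx > nrow(s)] <- nrow(s)
  s$ne[idx]
}

#' Stairway-style flexible Ne-trajectory estimation from a folded SFS
#'
#' Model-flexible trajectory inference in the spirit of SFS stairway
#' methods: for each of `n_boot` bootstrap replicates, a training spectrum
#' of `train_frac * L` sites is drawn by multinomial resampling of the
#' observed folded SFS (monomorphic cell included); piecewise-constant
#' models with 2 to `length(breakpoints) + 1` epochs and free change times
#' are fitted by Poisson composite likelihood and the per-replicate model
#' chosen by AIC. The reported trajectory is the per-time median Ne across
#' replicates with 2.5/97.5 percentile bands, on a logarithmic time grid
#' spanning the fitted change times; times are also expressed in years via
#' `gen_time_years`. The default breakpoint ladder `n/4, n/2, 3n/4, n-2`
#' controls only how many epoch-count models are tried (four, hence 2-5
#' epochs).
#'
#' Because fitting happens in mutation-scaled units, halving `mu` exactly
#' doubles every Ne and every time without changing the trajectory shape.
#'
#' @param obs a [folded_sfs]; needs `n >= 8` and at least `10 * n`
#'   segregating sites.
#' @param mu per-site per-generation mutation rate.
#' @param gen_time_years generation time in years.
#' @param breakpoints breakpoint ladder; its length sets the number of
#'   epoch-count models (default `n/4, n/2, 3n/4, n-2`).
#' @param train_frac fraction of sites per training resample (default 0.67).
#' @param n_boot number of SFS resamplings (default 200).
#' @param n_starts,maxit optimizer effort per model fit.
#' @param bounds optional prior range for sizes (diploids) and times
#'   (generations). The default (`NULL`) derives a generous mutation-free
#'   prior from the data scale (three orders of magnitude around the
#'   Watterson estimate), which keeps the whole fit independent of `mu`
#'   and makes the scaling identity exact; supplying explicit natural
#'   bounds ties the prior to `mu`.
#' @param grid_points number of points of the reporting time grid.
#' @param seed optional integer seed.
#' @return An [ne_trajectory] with columns `ne_lo`, `ne_hi` and, in
#'   `$details`, the per-replicate selected epoch counts.
#' @export
stairway_like_fit <- function(obs, mu, gen_time_years = 1,
                              breakpoints = NULL, train_frac = 0.67,
                              n_boot = 200, n_starts = 3, maxit = 400,
                              bounds = NULL, grid_points = 80,
                              seed = NULL) {
  stopifnot(inherits(obs, "folded_sfs"))
  n <- obs$n
  if (n < 8) stop("stairway-style fitting needs n >= 8")
  if (sum(obs$eta) < 10 * n)
    stop("too few segregating sites (< 10 * n) for trajectory inference")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(breakpoints))
    breakpoints <- unique(pmax(2, floor(c(n / 4, n / 2, 3 * n / 4, n - 2))))
  epoch_counts <- seq(2, length.out = length(breakpoints))
  if (is.null(bounds)) {
    # mutation-free prior around the Watterson scale of the data:
    # theta_W/4 = Ne*mu, so this brackets Ne*mu (and t*mu) by 1e3 each way
    theta_w <- sum(obs$eta) / obs$L / sum(1 / seq_len(n - 1))
    sb <- c(theta_w / 4 * 1e-3, theta_w / 4 * 1e3)
  } else {
    sb <- c(bounds[1] * mu, bounds[2] * mu)
  }

  cells <- c(obs$eta, obs$n_mono)
  prob <- cells / sum(cells)
  M_train <- round(train_frac * sum(cells))

  reps <- vector("list", n_boot)
  chosen <- integer(n_boot)
  for (b in seq_len(n_boot)) {
    cnt_train <- as.vector(rmultinom(1, M_train, prob))
    obs_train <- folded_sfs(cnt_train[-length(cnt_train)], n, L = M_train)
    best <- NULL
    for (m in epoch_counts) {
      # harder models get more optimizer effort
      f <- fit_piecewise(obs_train, m, sb, n_starts + m - 2,
                         round(maxit * (1 + (m - 2) / 2)))
      aic <- 2 * f$k - 2 * f$loglik
      if (is.null(best) || aic < best$aic) {
        best <- f
        best$aic <- aic
        best$m <- m
      }
    }
    reps[[b]] <- list(sizes = best$sizes / mu, times = best$times / mu)
    chosen[b] <- best$m
  }

  all_times <- unlist(lapply(reps, `[[`, "times"))
  if (!length(all_times)) all_times <- c(1, 1e4)
  # report only over the time span the replicates constrain
  t_lo <- max(quantile(all_times, 0.02), 1e-6)
  t_hi <- max(quantile(all_times, 0.98), t_lo * 10)
  grid <- exp(seq(log(t_lo), log(t_hi), length.out = grid_points + 1))

  ne_mat <- vapply(reps, function(r) {
    tr <- list(steps = data.frame(
      t_lo = c(0, r$times), t_hi = c(r$times, Inf), ne = r$sizes))
    trajectory_ne_at(tr, sqrt(grid[-length(grid)] * grid[-1]))
  }, numeric(grid_points))
  ne_mat <- matrix(ne_mat, nrow = grid_points)

  steps <- data.frame(
    t_lo = grid[-length(grid)], t_hi = grid[-1],
    ne = apply(ne_mat, 1, median),
    ne_lo = apply(ne_mat, 1, quantile, probs = 0.025),
    ne_hi = apply(ne_mat, 1, quantile, probs = 0.975))
  steps$t_lo_years <- steps$t_lo * gen_time_years
  steps$t_hi_years <- steps$t_hi * gen_time_years
  out <- ne_trajectory(steps, mu = mu, gen_time_years = gen_time_years,
                       time_unit = "generations")
  out$details <- list(epoch_counts = chosen, n_boot = n_boot,
                      train_frac = train_frac)
  out
}

#' Count direction reversals of a trajectory
#'
#' Compresses the log10 median-Ne sequence (present to past) into
#' monotone segments, ignoring movements smaller than `min_change` log10
#' units, and counts the direction changes. A monotone trajectory has 0
#' reversals; a single trough or peak has 1; each recovered
#' expansion-contraction cycle adds reversals.
#'
#' @param traj an [ne_trajectory].
#' @param min_change minimum cumulative |log10 Ne| movement for a segment
#'   to count (default 0.2, a 1.6-fold change: well above the wiggle of a
#'   bootstrap-median trajectory, well below the tenfold cycle amplitude
#'   of the glacial power scenarios).
#' @return Integer reversal count.
#' @export
count_reversals <- function(traj, min_change = 0.2) {
  stopifnot(inherits(traj, "ne_trajectory"))
  x <- log10(traj$steps$ne)
  # compress to turning points exceeding min_change
  dirs <- integer(0)
  anchor <- x[1]
  cur_dir <- 0L
  for (v in x[-1]) {
    d <- v - anchor
    if (abs(d) < min_change) next
    s <- sign(d)
    if (s != cur_dir) {
      dirs <- c(dirs, s)
      cur_dir <- s
    }
    anchor <- v
  }
  max(length(dirs) - 1L, 0L)
}

#' Glacial-cycle power study for trajectory inference
#'
#' For each scenario (generation time, mutation rate, current Ne, genome
#' size), builds the ten-event glacial-cycle demography
#' ([glacial_cycle_demography]), simulates a folded SFS with a sample size
#' of 20 haploid genomes, runs [stairway_like_fit], and summarizes whether
#' the inferred trajectory recovers the cycles (reversal count) along with
#' the nucleotide diversity of each simulated spectrum.
#'
#' @param scenarios data frame with columns `gen_time_years`, `mu`,
#'   `ne_current`, `L`; defaults to the full crossing of generation times
#'   (1, 15, 25, 60), mutation rates (2.7e-8, 7.7e-9), current Ne (1e3,
#'   1e5, 1e6) and genome sizes (1 Mbp, 6 Mbp) restricted by `subset`.
#' @param n haploid sample size (default 20).
#' @param reps simulated loci per spectrum.
#' @param n_boot,n_starts,maxit,breakpoints stairway effort per scenario
#'   (passed to [stairway_like_fit]).
#' @param seed integer seed; each scenario uses a deterministic substream.
#' @return List with `summary` (data frame: scenario parameters, pi,
#'   reversal count) and `trajectories` (list of [ne_trajectory]).
#' @export
power_study <- function(scenarios = NULL, n = 20, reps = 2000,
                        n_boot = 24, n_starts = 3, maxit = 400,
                        breakpoints = NULL, seed = 1) {
  if (is.null(scenarios))
    scenarios <- expand.grid(gen_time_years = c(1, 15, 25, 60),
                             mu = c(2.7e-8, 7.7e-9),
                             ne_current = c(1e3, 1e5, 1e6),
                             L = c(1e6, 6e6))
  stopifnot(all(c("gen_time_years", "mu", "ne_current", "L") %in%
                names(scenarios)))
  trajectories <- vector("list", nrow(scenarios))
  out <- scenarios
  out$pi <- NA_real_
  out$reversals <- NA_integer_
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    dem <- glacial_cycle_demography(sc$gen_time_years, sc$ne_current)
    sfs <- simulate_coalescent_sfs(dem, n = n, L = sc$L, mu = sc$mu,
                                   reps = reps, seed = seed + 1000L * i)
    out$pi[i] <- pi_from_sfs(sfs)
    traj <- stairway_like_fit(sfs, mu = sc$mu,
                              gen_time_years = sc$gen_time_years,
                              breakpoints = breakpoints, n_boot = n_boot,
                              n_starts = n_starts, maxit = maxit,
                              seed = seed + 1000L * i + 1L)
    trajectories[[i]] <- traj
    out$reversals[i] <- count_reversals(traj)
  }
  list(summary = out, trajectories = trajectories)
}

#' Pooled versus per-population trajectory robustness check
#'
#' Quantifies how unaccounted population structure distorts trajectory
#' inference: runs [stairway_like_fit] on the SFS of two populations
#' pooled (artificially mixed) and on each population separately, then
#' reports the largest absolute log-ratio between the pooled and the
#' separate median trajectories over the pooled time grid.
#'
#' @param gm a [genotype_matrix] carrying exactly two population labels.
#' @param mu per-site per-generation mutation rate.
#' @param target_n haploid size of each per-population SFS; pooled uses
#'   twice this. Defaults to half the smaller population's haploid count.
#' @param n_boot,n_starts stairway effort.
#' @param seed optional integer seed.
#' @return List with trajectories `pooled`, `pop1`, `pop2` and
#'   `max_log_ratio` (max over grid and populations of
#'   `|log(ne_pooled / ne_separate)|`).
#' @export
mixed_population_check <- function(gm, mu, target_n = NULL, n_boot = 24,
                                   n_starts = 3, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pops <- unique(gm$pop)
  if (length(pops) != 2) stop("need exactly two population labels")
  if (!is.null(seed)) set.seed(seed)
  idx1 <- gm$pop == pops[1]
  idx2 <- gm$pop == pops[2]
  if (is.null(target_n))
    target_n <- max((min(sum(idx1), sum(idx2)) %/% 2) * 2, 8)
  gm1 <- subset_gm(gm, individuals = which(idx1))
  gm2 <- subset_gm(gm, individuals = which(idx2))
  sfs_pool <- build_folded_sfs(gm, target_n = 2 * target_n)
  sfs1 <- build_folded_sfs(gm1, target_n = target_n)
  sfs2 <- build_folded_sfs(gm2, target_n = target_n)
  pooled <- stairway_like_fit(sfs_pool, mu, n_boot = n_boot,
                              n_starts = n_starts)
  t1 <- stairway_like_fit(sfs1, mu, n_boot = n_boot, n_starts = n_starts)
  t2 <- stairway_like_fit(sfs2, mu, n_boot = n_boot, n_starts = n_starts)
  # compare over the interior of both fitted spans: the extreme ends of a
  # bootstrap-median trajectory are weakly constrained (the reason the
  # synchronicity analysis drops the most recent step), so the overlap is
  # trimmed to each trajectory's 15-85 percentile time range
  core <- function(tr) {
    g <- c(tr$steps$t_lo, max(tr$steps$t_hi))
    exp(quantile(log(g), c(0.15, 0.85), names = FALSE))
  }
  ratio <- function(sep) {
    cp <- core(pooled); cs <- core(sep)
    lo <- max(cp[1], cs[1]); hi <- min(cp[2], cs[2])
    mid <- sqrt(pooled$steps$t_lo * pooled$steps$t_hi)
    mid <- mid[mid >= lo & mid <= hi]
    if (!length(mid)) return(NA_real_)
    max(abs(log(trajectory_ne_at(pooled, mid) /
                trajectory_ne_at(sep, mid))))
  }
  list(pooled = pooled, pop1 = t1, pop2 = t2,
       max_log_ratio = max(ratio(t1), ratio(t2), na.rm = TRUE))
}
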