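# Composite-likelihood fitting of piecewise-constant (epoch) models.
#
# All optimization happens on log10 parameters in mutation-scaled units
# (sizes as Ne*mu, times as t*mu): the expected SFS depends on (Ne, t, mu)
# only through these products, so the scaling identity
# (Ne, t, mu) -> (c*Ne, c*t, mu/c) holds exactly by construction and the
# likelihood surface is mu-free. Results are reported in natural units.

epoch_model_names <- c("SNM", "epoch2", "epoch3")

epoch_model_spec <- function(model_name) {
  switch(model_name,
    SNM    = list(m = 1L, params = "NCUR"),
    epoch2 = list(m = 2L, params = c("NCUR", "NANC", "TBOT")),
    epoch3 = list(m = 3L, params = c("NCUR", "NBOT", "NANC", "TBOT", "TENDBOT")),
    stop("unknown epoch model '", model_name, "'"))
}

# demography from an m-epoch parameter vector (sizes present->past, then
# m-1 change times, unsorted allowed)
piecewise_demography <- function(sizes, times) {
  if (length(times)) times <- sort(times)
  demography(ne = sizes, t_start = c(0, times))
}

# negative Poisson composite log-likelihood in scaled units, inlined for
# the optimizer hot path (identical math to composite_loglik(expected_sfs)
# up to the data-only constant sum(lgamma(obs + 1)), added back by the
# caller)
neg_cl_factory <- function(obs, m, lo, hi) {
  n <- obs$n
  L <- obs$L
  eig <- lineage_eigen(n)
  W <- sfs_weights(n)
  V <- eig$V; Vinv <- eig$Vinv; d <- eig$d
  half <- n %/% 2
  i1 <- seq_len(half)
  i2 <- n - i1
  wt2 <- as.numeric(i1 != i2)            # middle class not double-counted
  i2[i2 < 1] <- 1
  o <- c(obs$eta, obs$n_mono)
  function(par) {
    if (any(par < lo) || any(par > hi))
      return(1e10 + 1e6 * sum(pmax(lo - par, 0) + pmax(par - hi, 0)))
    v <- 10^par
    ne <- v[seq_len(m)]
    ts <- if (m > 1) sort(v[(m + 1):(2 * m - 1)]) else numeric(0)
    t_lo <- c(0, ts)
    t_hi <- c(ts, Inf)
    p <- numeric(n); p[n] <- 1
    Tk <- numeric(n)
    for (e in seq_len(m)) {
      two_ne <- 2 * ne[e]
      dt <- (t_hi[e] - t_lo[e]) / two_ne
      w <- Vinv %*% p
      if (is.finite(dt)) {
        ed <- exp(d * dt)
        g <- (ed - 1) / d; g[1] <- dt
        Tk <- Tk + as.vector(V %*% (g * w)) * two_ne
        p <- as.vector(V %*% (ed * w))
        p[p < 0] <- 0
      } else {
        g <- -1 / d; g[1] <- 0
        Tk <- Tk + as.vector(V %*% (g * w)) * two_ne
      }
    }
    xi <- L * as.vector(W %*% Tk[2:n])   # mutation-scaled units (mu = 1)
    e_all <- c(xi[i1] + wt2 * xi[i2], L - sum(xi))
    if (any(e_all <= 0) || any(!is.finite(e_all))) return(1e10)
    val <- sum(e_all) - sum(o * log(e_all))
    if (!is.finite(val)) return(1e10)
    val
  }
}

# multistart Nelder-Mead over an m-epoch model; obs in scaled units
fit_piecewise <- function(obs, m, bounds, n_starts, maxit, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  npar <- 2L * m - 1L
  lo <- rep(log10(bounds[1]), npar)
  hi <- rep(log10(bounds[2]), npar)
  fn <- neg_cl_factory(obs, m, lo, hi)
  best <- NULL
  converged <- FALSE
  for (s in seq_len(n_starts)) {
    par0 <- runif(npar, lo, hi)
    fit <- if (npar == 1L)
      optim(par0, fn, method = "Brent", lower = lo, upper = hi,
            control = list(maxit = maxit))
    else
      optim(par0, fn, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0) converged <- TRUE
  }
  v <- 10^best$par
  const <- sum(lgamma(c(obs$eta, obs$n_mono) + 1))
  list(sizes = v[seq_len(m)],
       times = if (m > 1) sort(v[(m + 1):(2 * m - 1)]) else numeric(0),
       loglik = -best$value - const, k = npar, converged = converged)
}

obs_signature <- function(obs) {
  c(n = obs$n, L = obs$L, seg = sum(obs$eta))
}

# rescale an observed SFS into mutation-scaled fitting units (identity: the
# counts do not change; only the parameter interpretation does)
scale_bounds <- function(bounds, mu) log10(c(bounds[1] * mu, bounds[2] * mu))

#' Fit an epoch model to a folded SFS by Poisson composite likelihood
#'
#' Maximizes the Poisson composite log-likelihood ([composite_loglik]) of
#' the observed folded SFS (monomorphic cell included) over the parameters
#' of one of three nested single-population models: `SNM` (constant size,
#' parameter NCUR), `epoch2` (one instantaneous change: NCUR, NANC, TBOT)
#' or `epoch3` (two changes: NCUR, NBOT, NANC, TBOT, TENDBOT). Parameters
#' carry log-uniform priors on `bounds` (default 10 to 1e7, applying to
#' sizes in diploids and times in generations); optimization is
#' derivative-free Nelder-Mead from `n_starts` log-uniform random starts,
#' keeping the best run.
#'
#' @param obs a [folded_sfs] with total site count `L` and monomorphic
#'   cell filled.
#' @param model one of `"SNM"`, `"epoch2"`, `"epoch3"`.
#' @param mu per-site per-generation mutation rate.
#' @param n_starts number of independent starts (default 100).
#' @param bounds length-2 prior range for sizes and times (default
#'   `c(10, 1e7)`).
#' @param maxit Nelder-Mead iteration cap per start.
#' @param seed optional integer seed.
#' @return An object of class `epoch_fit`: model name, named parameter
#'   vector, `loglik`, `aic`, `k`, `n_starts`, `converged`, and the data
#'   signature used by [compare_models_aic].
#' @export
fit_epoch_model <- function(obs, model = c("epoch2", "SNM", "epoch3"),
                            mu, n_starts = 100, bounds = c(10, 1e7),
                            maxit = 500, seed = NULL) {
  stopifnot(inherits(obs, "folded_sfs"))
  model <- match.arg(model)
  spec <- epoch_model_spec(model)
  sb <- 10^scale_bounds(bounds, mu)
  fit <- fit_piecewise(obs, spec$m, sb, n_starts, maxit, seed)
  sizes <- fit$sizes / mu
  times <- fit$times / mu
  params <- switch(model,
    SNM    = c(NCUR = sizes[1]),
    epoch2 = c(NCUR = sizes[1], NANC = sizes[2], TBOT = times[1]),
    epoch3 = c(NCUR = sizes[1], NBOT = sizes[2], NANC = sizes[3],
               TBOT = times[1], TENDBOT = times[2]))
  structure(list(model_name = model, params = params,
                 loglik = fit$loglik, k = fit$k,
                 aic = 2 * fit$k - 2 * fit$loglik,
                 n_starts = n_starts, converged = fit$converged,
                 mu = mu, signature = obs_signature(obs)),
            class = "epoch_fit")
}

#' @export
print.epoch_fit <- function(x, ...) {
  cat(sprintf("%s fit: loglik = %.2f, AIC = %.2f (%d starts%s)\n",
              x$model_name, x$loglik, x$aic, x$n_starts,
              if (x$converged) "" else ", no start converged"))
  print(signif(x$params, 4))
  invisible(x)
}

#' Rank epoch-model fits by AIC
#'
#' @param fits list of `epoch_fit` objects produced on the same observed
#'   SFS (checked via the stored data signature).
#' @return Data frame with columns `model`, `k`, `loglik`, `aic`,
#'   `delta_aic`, sorted by ascending AIC.
#' @export
compare_models_aic <- function(fits) {
  if (length(fits) < 2) stop("need at least two fits to compare")
  sigs <- vapply(fits, function(f) paste(f$signature, collapse = "/"),
                 character(1))
  if (length(unique(sigs)) != 1)
    stop("fits were not produced on the same observed SFS")
  tab <- data.frame(
    model = vapply(fits, function(f) f$model_name, character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)))
  tab <- tab[order(tab$aic), ]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  tab
}

# demography at the fitted parameters of an epoch_fit
demography_from_fit <- function(fit) {
  p <- fit$params
  switch(fit$model_name,
    SNM    = demography(p[["NCUR"]], 0),
    epoch2 = demography(c(p[["NCUR"]], p[["NANC"]]), c(0, p[["TBOT"]])),
    epoch3 = demography(c(p[["NCUR"]], p[["NBOT"]], p[["NANC"]]),
                        c(0, sort(c(p[["TBOT"]], p[["TENDBOT"]])))))
}

#' Parametric-bootstrap confidence intervals for an epoch fit
#'
#' Simulates `n_boot` spectra as independent Poisson draws from the
#' expected SFS at the fitted parameters, refits the same model to each,
#' and returns empirical percentile intervals per parameter. Replicates
#' whose refit fails to converge are dropped (and counted).
#'
#' @param best an `epoch_fit` (the point estimate).
#' @param obs the observed [folded_sfs] the fit was produced on.
#' @param n_boot number of bootstrap spectra (default 100).
#' @param n_starts starts per refit (default 20; bootstrap refits start
#'   near a well-identified optimum and need fewer restarts).
#' @param level interval coverage (default 0.95).
#' @param bounds,maxit passed to the refits.
#' @param seed optional integer seed.
#' @return List with `intervals` (data frame: parameter, estimate, lower,
#'   upper), `n_success`, and the bootstrap parameter draws.
#' @export
bootstrap_ci <- function(best, obs, n_boot = 100, n_starts = 20,
                         level = 0.95, bounds = c(10, 1e7), maxit = 500,
                         seed = NULL) {
  stopifnot(inherits(best, "epoch_fit"), inherits(obs, "folded_sfs"))
  if (!is.null(seed)) set.seed(seed)
  dem <- demography_from_fit(best)
  exp_sfs <- expected_sfs(dem, obs$n, best$mu, obs$L)
  draws <- matrix(NA_real_, n_boot, length(best$params),
                  dimnames = list(NULL, names(best$params)))
  ok <- logical(n_boot)
  for (b in seq_len(n_boot)) {
    eta_b <- rpois(length(exp_sfs$eta), exp_sfs$eta)
    mono_b <- rpois(1, exp_sfs$n_mono)
    obs_b <- folded_sfs(eta_b, obs$n, L = sum(eta_b) + mono_b)
    fit_b <- fit_epoch_model(obs_b, best$model_name, best$mu,
                             n_starts = n_starts, bounds = bounds,
                             maxit = maxit)
    ok[b] <- fit_b$converged
    if (ok[b]) draws[b, ] <- fit_b$params
  }
  alpha <- (1 - level) / 2
  qs <- apply(draws[ok, , drop = FALSE], 2, quantile,
              probs = c(alpha, 1 - alpha), na.rm = TRUE)
  list(intervals = data.frame(parameter = names(best$params),
                              estimate = unname(best$params),
                              lower = qs[1, ], upper = qs[2, ],
                              row.names = NULL),
       n_success = sum(ok), draws = draws[ok, , drop = FALSE])
}
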