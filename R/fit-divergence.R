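# Composite-likelihood fitting of the seven-model divergence set:
# three panmictic reference models fitted to the pooled spectrum
# (pan_snm, pan_epoch2, pan_epoch3) and four two-deme divergence models
# fitted to the joint folded spectrum, crossing migration after the split
# with an ancestral size change before it (div, div_mig, div_change,
# div_change_mig).

divergence_model_ids <- c("pan_snm", "pan_epoch2", "pan_epoch3",
                          "div", "div_mig", "div_change", "div_change_mig")

#' Pool a joint folded SFS into a single-population folded SFS
#'
#' Collapses every joint cell to its total minor count `i + j`; cell
#' `(0, 0)` becomes the monomorphic count.
#'
#' @param jsfs a [joint_sfs].
#' @return A [folded_sfs] with `n = n1 + n2`.
#' @export
pool_joint_sfs <- function(jsfs) {
  stopifnot(inherits(jsfs, "joint_sfs"))
  n <- jsfs$n1 + jsfs$n2
  half <- n %/% 2
  eta <- numeric(half)
  for (i in 0:jsfs$n1) for (j in 0:jsfs$n2) {
    tot <- i + j
    if (tot >= 1 && tot <= half)
      eta[tot] <- eta[tot] + jsfs$counts[i + 1, j + 1]
  }
  folded_sfs(eta, n = n, L = jsfs$L)
}

# Poisson composite log-likelihood over joint folded cells (stored
# configurations only) plus the monomorphic cell
composite_loglik_joint <- function(obs_counts, exp_counts) {
  o <- as.vector(obs_counts)
  e <- as.vector(exp_counts)
  use <- e > 0
  if (any(o > 0 & !use)) return(-Inf)
  sum(o[use] * log(e[use]) - e[use] - lgamma(o[use] + 1)) - sum(e[!use])
}

# model parameterization: names, and builder from a log10 parameter vector
divergence_param_spec <- function(model_id) {
  switch(model_id,
    div = list(
      params = c("NPOP1", "NPOP2", "NANC", "TDIV"),
      mig = c(FALSE, FALSE, FALSE, FALSE),
      build = function(v) divergence_model(v[1], v[2], v[3], v[4])),
    div_mig = list(
      params = c("NPOP1", "NPOP2", "NANC", "TDIV", "N1M21", "N2M12"),
      mig = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
      build = function(v) divergence_model(v[1], v[2], v[3], v[4],
                                           n1m21 = v[5], n2m12 = v[6])),
    div_change = list(
      params = c("NPOP1", "NPOP2", "NCUR", "NANC", "TDIV", "TSEP"),
      mig = rep(FALSE, 6),
      build = function(v) {
        tt <- sort(c(v[5], v[6]))
        divergence_model(v[1], v[2], v[4], tt[1], ncur = v[3],
                         tsep = tt[2] * (1 + 1e-9) + 1e-9,
                         has_ancestral_change = TRUE)
      }),
    div_change_mig = list(
      params = c("NPOP1", "NPOP2", "NCUR", "NANC", "TDIV", "TSEP",
                 "N1M21", "N2M12"),
      mig = c(rep(FALSE, 6), TRUE, TRUE),
      build = function(v) {
        tt <- sort(c(v[5], v[6]))
        divergence_model(v[1], v[2], v[4], tt[1], ncur = v[3],
                         tsep = tt[2] * (1 + 1e-9) + 1e-9,
                         n1m21 = v[7], n2m12 = v[8],
                         has_ancestral_change = TRUE)
      }),
    stop("unknown divergence model '", model_id, "'"))
}

# Method-of-moments start for divergence fits: per-deme diversity gives
# the daughter sizes, between-deme divergence the split time, and the
# island-model relation Nm = (1/FST - 1)/4 the migrant numbers.
moment_start <- function(jsfs, mu) {
  n1 <- jsfs$n1; n2 <- jsfs$n2; L <- jsfs$L
  cnt <- jsfs$counts
  i <- matrix(0:n1, n1 + 1, n2 + 1)
  j <- matrix(0:n2, n1 + 1, n2 + 1, byrow = TRUE)
  p1 <- i / n1; p2 <- j / n2
  h1 <- sum(cnt * 2 * p1 * (1 - p1) * n1 / (n1 - 1)) / L
  h2 <- sum(cnt * 2 * p2 * (1 - p2) * n2 / (n2 - 1)) / L
  hb <- sum(cnt * (p1 * (1 - p2) + p2 * (1 - p1))) / L
  hw <- (h1 + h2) / 2
  fst <- max(1 - hw / max(hb, 1e-12), 1e-3)
  N1 <- max(h1 / (4 * mu), 10)
  N2 <- max(h2 / (4 * mu), 10)
  NANC <- (N1 + N2) / 2
  TDIV <- max((hb - hw) / (2 * mu), 100)
  NM <- min(max((1 / fst - 1) / 4, 1e-3), 1e3)
  c(NPOP1 = N1, NPOP2 = N2, NANC = NANC, NCUR = NANC,
    TDIV = TDIV, TSEP = 2 * TDIV, N1M21 = NM, N2M12 = NM)
}

# Monte Carlo expected joint folded SFS under common random numbers: the
# RNG state is saved, reseeded with crn_seed for the genealogy draws, and
# restored, so every optimizer evaluation sees the same genealogical noise
expected_joint_sfs_mc <- function(model, n1, n2, L, mu, reps, crn_seed) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
  })
  sim <- simulate_two_deme_sfs(model, n1, n2, L, mu, reps = reps,
                               seed = crn_seed, poisson = FALSE)
  sim$counts
}

#' Fit one of the seven divergence-set models
#'
#' Panmictic reference models (`pan_snm`, `pan_epoch2`, `pan_epoch3`)
#' are fitted with [fit_epoch_model] to the pooled spectrum
#' ([pool_joint_sfs]). The four divergence models are fitted to the joint
#' folded SFS by Poisson composite likelihood, with expectations obtained
#' from the two-deme coalescent simulator in expectation mode under
#' common random numbers (the same genealogy stream for every optimizer
#' evaluation, taming the stochastic objective), multistart Nelder-Mead
#' on log10 parameters, log-uniform priors of `bounds` (default 10 to
#' 1e9) for sizes and times and `mig_bounds` (default 1e-4 to 1e4) for
#' effective migrant numbers. Expected cells are floored at `1e-4` so
#' the log-likelihood stays finite where the Monte Carlo expectation is
#' empty.
#'
#' @param jsfs a [joint_sfs].
#' @param model_id one of `pan_snm`, `pan_epoch2`, `pan_epoch3`, `div`,
#'   `div_mig`, `div_change`, `div_change_mig`.
#' @param mu per-site per-generation mutation rate.
#' @param bounds prior range for sizes (diploids) and times (generations).
#' @param mig_bounds prior range for effective migrant numbers (2*Ne*m).
#' @param n_starts independent optimizer starts (default 100).
#' @param reps genealogies per expectation evaluation.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param seed optional integer seed for the starts.
#' @param crn_seed seed of the common-random-number genealogy stream.
#' @param refine polish the best start with a fourfold-denser genealogy
#'   stream and a longer Nelder-Mead run (default `TRUE`).
#' @param reps_final genealogies for the final held-out likelihood used in
#'   AIC (default 2e5; the reported `loglik` comes from this fresh stream,
#'   the optimizer's own value is kept as `loglik_optim`).
#' @param init optional named parameter vector (natural units) used as an
#'   additional warm start — typically the optimum of a nested simpler
#'   model; missing parameters (e.g. migrant numbers when warm-starting
#'   from a no-migration fit) default to the geometric middle of their
#'   prior.
#' @return A `divergence_fit` (also usable by [compare_models_aic]):
#'   model id, named parameters, `loglik`, `aic`, `k`, `converged`.
#' @export
fit_divergence_model <- function(jsfs, model_id, mu, bounds = c(10, 1e9),
                                 mig_bounds = c(1e-4, 1e4), n_starts = 100,
                                 reps = 200, maxit = 150, seed = NULL,
                                 crn_seed = 1L, refine = TRUE,
                                 init = NULL, reps_final = 2e5) {
  stopifnot(inherits(jsfs, "joint_sfs"))
  model_id <- match.arg(model_id, divergence_model_ids)
  seg <- sum(jsfs$counts) - jsfs$counts[1, 1]
  if (seg == 0) stop("degenerate joint SFS: no polymorphic sites")
  shared <- sum(jsfs$counts[-1, -1])
  if (shared == 0)
    warning("no shared polymorphisms between the demes; divergence-time ",
            "information is weak")
  sig <- c(n = jsfs$n1 + jsfs$n2, L = jsfs$L, seg = seg)

  if (startsWith(model_id, "pan_")) {
    pooled <- pool_joint_sfs(jsfs)
    epoch_name <- switch(model_id, pan_snm = "SNM", pan_epoch2 = "epoch2",
                         pan_epoch3 = "epoch3")
    f <- fit_epoch_model(pooled, epoch_name, mu, n_starts = n_starts,
                         bounds = bounds, seed = seed)
    return(structure(list(model_name = model_id, params = f$params,
                          loglik = f$loglik, aic = f$aic, k = f$k,
                          n_starts = n_starts, converged = f$converged,
                          mu = mu, signature = sig),
                     class = c("divergence_fit", "epoch_fit")))
  }

  spec <- divergence_param_spec(model_id)
  npar <- length(spec$params)
  lo <- ifelse(spec$mig, log10(mig_bounds[1]), log10(bounds[1]))
  hi <- ifelse(spec$mig, log10(mig_bounds[2]), log10(bounds[2]))
  n1 <- jsfs$n1; n2 <- jsfs$n2; L <- jsfs$L
  obs <- jsfs$counts

  fn <- function(par) {
    if (any(par < lo) || any(par > hi))
      return(1e10 + 1e6 * sum(pmax(lo - par, 0) + pmax(par - hi, 0)))
    model <- spec$build(10^par)
    e <- expected_joint_sfs_mc(model, n1, n2, L, mu, reps, crn_seed)
    e[-1, -1][e[-1, -1] == 0] <- 1e-4   # keep reachable cells finite
    e[1, ][e[1, ] == 0] <- 1e-4
    e[, 1][e[, 1] == 0] <- 1e-4
    e[1, 1] <- max(L - (sum(e) - e[1, 1]), 1e-4)
    ll <- composite_loglik_joint(obs, e)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  if (!is.null(seed)) set.seed(seed)
  starts <- lapply(seq_len(n_starts), function(s) runif(npar, lo, hi))
  warm_par <- function(values) {
    par_w <- (lo + hi) / 2
    hit <- match(spec$params, names(values))
    par_w[!is.na(hit)] <- log10(values[hit[!is.na(hit)]])
    # migration parameters absent from the source enter at the quiet end
    par_w[spec$mig & is.na(hit)] <- log10(mig_bounds[1]) + 0.5
    pmin(pmax(par_w, lo), hi)
  }
  warms <- list(warm_par(moment_start(jsfs, mu)))
  if (!is.null(init)) warms <- c(list(warm_par(init)), warms)
  starts <- c(warms, starts)
  best <- NULL
  converged <- FALSE
  for (par0 in starts) {
    fit <- optim(par0, fn, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-8))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0) converged <- TRUE
  }
  if (refine) {
    # polish under a denser genealogy stream: the coarse incumbent plus
    # the dense-best warm start (whose coarse and dense values can
    # disagree) are polished and the dense-better kept, so a nested warm
    # start is never lost to stream noise
    reps <- 3L * reps
    warm_best <- warms[[which.min(vapply(warms, fn, numeric(1)))]]
    best_coarse <- best$par
    best <- NULL
    for (p0 in list(best_coarse, warm_best)) {
      fit <- optim(p0, fn, method = "Nelder-Mead",
                   control = list(maxit = round(1.5 * maxit), reltol = 1e-9))
      if (is.null(best) || fit$value < best$value) best <- fit
      if (fit$convergence == 0) converged <- TRUE
    }
  }
  params <- setNames(10^best$par, spec$params)
  if (model_id %in% c("div_change", "div_change_mig") &&
      params[["TDIV"]] > params[["TSEP"]]) {
    tt <- sort(c(params[["TDIV"]], params[["TSEP"]]))
    params[["TDIV"]] <- tt[1]; params[["TSEP"]] <- tt[2]
  }
  # score the fitted parameters on a fresh, much denser genealogy stream:
  # the optimizer inevitably overfits the noise pockets of its own stream,
  # and comparing models needs likelihood noise well below the AIC
  # penalty, which takes simulation counts on the 1e5 scale
  reps <- max(reps_final, reps)
  crn_seed <- crn_seed + 1000003L
  ll_final <- -fn(best$par)
  structure(list(model_name = model_id, params = params,
                 loglik = ll_final, aic = 2 * npar - 2 * ll_final,
                 loglik_optim = -best$value,
                 aic_optim = 2 * npar + 2 * best$value,
                 k = npar, n_starts = n_starts, converged = converged,
                 mu = mu, signature = sig),
            class = c("divergence_fit", "epoch_fit"))
}

#' Fit and rank the full seven-model divergence set
#'
#' Convenience wrapper running [fit_divergence_model] for every model id
#' and ranking the results by AIC.
#'
#' @inheritParams fit_divergence_model
#' @param models subset of model ids (default: all seven).
#' @return List with `fits` (named list) and `aic_table` (from
#'   [compare_models_aic]).
#' @export
fit_divergence_set <- function(jsfs, mu, models = divergence_model_ids,
                               bounds = c(10, 1e9),
                               mig_bounds = c(1e-4, 1e4), n_starts = 100,
                               reps = 200, maxit = 150, seed = NULL,
                               crn_seed = 1L, reps_final = 2e5) {
  # warm-start each divergence model from its nested simpler relative
  fits <- list()
  for (m in models) {
    init <- NULL
    if (m == "div_mig" && "div" %in% names(fits))
      init <- fits[["div"]]$params
    if (m == "div_change" && "div" %in% names(fits))
      init <- fits[["div"]]$params
    if (m == "div_change_mig" && "div_change" %in% names(fits))
      init <- fits[["div_change"]]$params
    fits[[m]] <- fit_divergence_model(jsfs, m, mu, bounds = bounds,
                                      mig_bounds = mig_bounds,
                                      n_starts = n_starts, reps = reps,
                                      maxit = maxit, seed = seed,
                                      crn_seed = crn_seed, init = init,
                                      reps_final = reps_final)
  }
  names(fits) <- models
  list(fits = fits, aic_table = compare_models_aic(fits))
}
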