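# Pairwise differentiation, isolation by distance, scaled FST.

# Weir & Cockerham (1984) variance components for one biallelic site over
# r populations; ni = diploid sample sizes, p = alt frequencies, het =
# observed heterozygote frequencies. Returns c(a, b, c).
wc_site_components <- function(ni, p, het) {
  r <- length(ni)
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- sum(ni * p) / (r * nbar)
  s2 <- sum(ni * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * het) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Pairwise FST matrix (Weir & Cockerham 1984)
#'
#' Multi-locus ratio-of-sums estimator: for each population pair, the
#' per-site variance components a (among populations), b (among
#' individuals within populations) and c (within individuals) are summed
#' across polymorphic sites and FST estimated as
#' `sum(a) / sum(a + b + c)`. Sites monomorphic in the pair or with a
#' population lacking calls are skipped; negative estimates are retained.
#'
#' @param gm a [genotype_matrix] carrying at least two population labels.
#' @param pops optional subset of population labels (default: all).
#' @return Symmetric FST matrix with zero diagonal, dimnames the
#'   population labels.
#' @export
pairwise_fst <- function(gm, pops = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(pops)) pops <- unique(gm$pop)
  if (length(pops) < 2) stop("need at least two populations")
  g <- gm$genotypes
  K <- length(pops)
  fst <- matrix(0, K, K, dimnames = list(pops, pops))
  idx <- lapply(pops, function(p) which(gm$pop == p))
  # per-population per-site summaries
  nmat <- hetm <- pmat <- matrix(NA_real_, K, ncol(g))
  for (k in seq_len(K)) {
    gk <- g[idx[[k]], , drop = FALSE]
    nk <- colSums(!is.na(gk))
    if (all(nk == 0)) stop("population '", pops[k],
                           "' has no non-missing calls at any site")
    nmat[k, ] <- nk
    pmat[k, ] <- ifelse(nk > 0, colSums(gk, na.rm = TRUE) / (2 * nk), NA)
    hetm[k, ] <- ifelse(nk > 0, colSums(gk == 1L, na.rm = TRUE) / nk, NA)
  }
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    num <- den <- 0
    for (s in seq_len(ncol(g))) {
      ni <- c(nmat[i, s], nmat[j, s])
      if (any(ni == 0) || any(is.na(ni))) next
      p <- c(pmat[i, s], pmat[j, s])
      if (max(p) == 0 || min(p) == 1) next     # monomorphic in the pair
      comp <- wc_site_components(ni, p, c(hetm[i, s], hetm[j, s]))
      num <- num + comp[1]
      den <- den + sum(comp)
    }
    fst[i, j] <- fst[j, i] <- if (den > 0) num / den else NA_real_
  }
  fst
}

#' Great-circle distance in kilometres
#'
#' Geodesic (great-circle) distance on a sphere of mean Earth radius
#' 6371.0088 km, via the spherical law of cosines.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @return Distance(s) in km.
#' @examples
#' geodesic_km(0, 0, 0, 1)  # ~111.195
#' @export
geodesic_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("coordinates out of range (|lat| <= 90, |lon| <= 180)")
  r_km <- 6371.0088
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distCosine(p1, p2, r = r_km * 1000) / 1000
}

#' Isolation-by-distance regression (Rousset's two-dimensional model)
#'
#' Ordinary least squares of linearized differentiation
#' `FST / (1 - FST)` on the natural logarithm of pairwise geodesic
#' distance in km, over all unordered population pairs:
#' `FST/(1-FST) = beta * ln(x) + alpha + eps`.
#'
#' @param fst symmetric pairwise FST matrix (dimnames = populations).
#' @param coords data frame with columns `pop`, `lat`, `lon` covering
#'   every population of `fst`.
#' @return An object of class `ibd_fit`: `beta`, `alpha`, `r2`,
#'   `residuals`, and `pairs` (data frame with pop1, pop2, fst,
#'   distance_km, used by the fitted model).
#' @export
ibd_regression <- function(fst, coords) {
  pops <- rownames(fst)
  if (is.null(pops)) stop("'fst' needs population dimnames")
  stopifnot(all(c("pop", "lat", "lon") %in% names(coords)))
  if (!all(pops %in% coords$pop))
    stop("coordinates missing for some populations")
  co <- coords[match(pops, coords$pop), ]
  pairs <- t(utils::combn(length(pops), 2))
  d_km <- geodesic_km(co$lat[pairs[, 1]], co$lon[pairs[, 1]],
                      co$lat[pairs[, 2]], co$lon[pairs[, 2]])
  if (any(d_km <= 0)) stop("coincident populations: log-distance undefined")
  f <- fst[pairs]
  if (any(f >= 1)) stop("FST = 1: linearized differentiation undefined")
  y <- f / (1 - f)
  x <- log(d_km)
  fit <- lm(y ~ x)
  structure(list(beta = unname(coef(fit)[2]), alpha = unname(coef(fit)[1]),
                 r2 = summary(fit)$r.squared, residuals = unname(resid(fit)),
                 pairs = data.frame(pop1 = pops[pairs[, 1]],
                                    pop2 = pops[pairs[, 2]],
                                    fst = f, distance_km = d_km),
                 lm = fit),
            class = "ibd_fit")
}

#' @export
print.ibd_fit <- function(x, ...) {
  cat(sprintf("Isolation by distance: FST/(1-FST) = %.4g * ln(km) + %.4g (R2 = %.3f, %d pairs)\n",
              x$beta, x$alpha, x$r2, nrow(x$pairs)))
  invisible(x)
}

#' Population-specific scaled differentiation
#'
#' Distance-scaled differentiation per focal population. The default mode
#' (`"mean_of_ratios_km"`) averages, over all partners q of the focal
#' population p, the ratio `FST(p,q) / d_km(p,q)` — the quantity displayed
#' against diversity in range-wide comparisons. Alternate modes divide the
#' average FST by the average distance (`"ratio_of_means_km"`) or use
#' log-distance variants of both.
#'
#' @param fst symmetric pairwise FST matrix.
#' @param coords data frame with columns `pop`, `lat`, `lon`.
#' @param mode one of `"mean_of_ratios_km"`, `"ratio_of_means_km"`,
#'   `"mean_of_ratios_logkm"`, `"ratio_of_means_logkm"`.
#' @return Named numeric vector, one value per population.
#' @export
scaled_population_fst <- function(fst, coords,
                                  mode = c("mean_of_ratios_km",
                                           "ratio_of_means_km",
                                           "mean_of_ratios_logkm",
                                           "ratio_of_means_logkm")) {
  mode <- match.arg(mode)
  pops <- rownames(fst)
  if (length(pops) < 2) stop("need at least two populations")
  co <- coords[match(pops, coords$pop), ]
  K <- length(pops)
  D <- matrix(0, K, K)
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    D[i, j] <- D[j, i] <- geodesic_km(co$lat[i], co$lon[i],
                                      co$lat[j], co$lon[j])
  }
  if (any(D[upper.tri(D)] <= 0)) stop("zero-distance population pair")
  x <- if (grepl("logkm", mode)) log(D) else D
  out <- numeric(K)
  for (k in seq_len(K)) {
    partners <- setdiff(seq_len(K), k)
    out[k] <- if (grepl("mean_of_ratios", mode))
      mean(fst[k, partners] / x[k, partners])
    else mean(fst[k, partners]) / mean(x[k, partners])
  }
  setNames(out, pops)
}
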