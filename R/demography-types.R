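#' Piecewise-constant demographic history
#'
#' A demography is an ordered sequence of epochs, each with a constant
#' diploid effective population size. Epoch boundaries are instantaneous
#' size changes; the last epoch extends infinitely far into the past.
#' Time is measured in generations before present, so the first epoch must
#' start at 0. With size `Ne`, `k` ancestral lineages coalesce at rate
#' `k(k-1)/(4*Ne)` per generation, i.e. `theta = 4*Ne*mu` for a pair.
#'
#' @param ne numeric vector of diploid effective sizes, one per epoch,
#'   ordered from the present backwards. All must be positive.
#' @param t_start numeric vector of epoch start times in generations before
#'   present; strictly increasing, first entry 0.
#' @return An object of class `demography`: a list with elements `ne` and
#'   `t_start`.
#' @examples
#' # tenfold expansion 5000 generations ago
#' demography(ne = c(1e5, 1e4), t_start = c(0, 5000))
#' @export
demography <- function(ne, t_start) {
  ne <- as.numeric(ne)
  t_start <- as.numeric(t_start)
  if (length(ne) == 0L) stop("demography needs at least one epoch")
  if (length(ne) != length(t_start))
    stop("'ne' and 't_start' must have the same length")
  if (any(!is.finite(ne)) || any(ne <= 0)) stop("all 'ne' must be positive")
  if (t_start[1] != 0) stop("first epoch must start at time 0")
  if (length(t_start) > 1 && any(diff(t_start) <= 0))
    stop("'t_start' must be strictly increasing")
  structure(list(ne = ne, t_start = t_start), class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  cat("Piecewise-constant demography (", length(x$ne), " epoch",
      if (length(x$ne) > 1) "s", "):\n", sep = "")
  t_end <- c(x$t_start[-1], Inf)
  for (i in seq_along(x$ne))
    cat(sprintf("  [%g, %g) generations: Ne = %g\n",
                x$t_start[i], t_end[i], x$ne[i]))
  invisible(x)
}

#' Two-population divergence model
#'
#' Describes an isolation-with-migration history: an ancestral population
#' splits at `tdiv` generations ago into two demes of sizes `npop1` and
#' `npop2`. Backward in time the merged ancestral population has size
#' `ncur` on `[tdiv, tsep)` and `nanc` beyond `tsep` when
#' `has_ancestral_change` is `TRUE`, or size `nanc` throughout otherwise.
#' `n1m21` and `n2m12` are effective migrant numbers (`2*Ne*m`): the
#' per-lineage backward migration rate for a lineage sitting in deme 1 is
#' `n1m21 / (2*npop1)` per generation, and symmetrically for deme 2. Both
#' must be 0 when `has_migration` is `FALSE`.
#'
#' @param npop1,npop2 diploid sizes of the two daughter populations.
#' @param nanc ancestral diploid size.
#' @param ncur ancestral size between `tdiv` and `tsep` (only used when
#'   `has_ancestral_change` is `TRUE`).
#' @param tdiv split time in generations before present.
#' @param tsep time of the ancestral size change; must exceed `tdiv`.
#' @param n1m21,n2m12 effective migrant numbers (`2*Ne*m`), `>= 0`.
#' @param has_migration,has_ancestral_change model flags.
#' @return An object of class `divergence_model`.
#' @export
divergence_model <- function(npop1, npop2, nanc, tdiv,
                             ncur = NA_real_, tsep = NA_real_,
                             n1m21 = 0, n2m12 = 0,
                             has_migration = (n1m21 > 0 || n2m12 > 0),
                             has_ancestral_change = is.finite(tsep)) {
  if (any(c(npop1, npop2, nanc) <= 0)) stop("population sizes must be positive")
  if (tdiv < 0) stop("'tdiv' must be non-negative")
  if (n1m21 < 0 || n2m12 < 0) stop("migrant numbers must be >= 0")
  if (!has_migration && (n1m21 > 0 || n2m12 > 0))
    stop("migrant numbers must be zero when 'has_migration' is FALSE")
  if (has_ancestral_change) {
    if (!is.finite(tsep) || tsep <= tdiv)
      stop("'tsep' must exceed 'tdiv' when 'has_ancestral_change' is TRUE")
    if (!is.finite(ncur) || ncur <= 0)
      stop("'ncur' must be positive when 'has_ancestral_change' is TRUE")
  }
  structure(list(npop1 = npop1, npop2 = npop2, nanc = nanc, ncur = ncur,
                 tdiv = tdiv, tsep = tsep, n1m21 = n1m21, n2m12 = n2m12,
                 has_migration = has_migration,
                 has_ancestral_change = has_ancestral_change),
            class = "divergence_model")
}

#' @export
print.divergence_model <- function(x, ...) {
  cat("Two-deme divergence model:\n")
  cat(sprintf("  NPOP1 = %g, NPOP2 = %g, TDIV = %g generations\n",
              x$npop1, x$npop2, x$tdiv))
  if (x$has_ancestral_change)
    cat(sprintf("  ancestral: NCUR = %g on [TDIV, TSEP = %g), NANC = %g beyond\n",
                x$ncur, x$tsep, x$nanc))
  else
    cat(sprintf("  ancestral: NANC = %g\n", x$nanc))
  if (x$has_migration)
    cat(sprintf("  migration: N1M21 = %g, N2M12 = %g (2*Ne*m)\n",
                x$n1m21, x$n2m12))
  else cat("  no migration after the split\n")
  invisible(x)
}

#' Glacial-cycle demography for power simulations
#'
#' Builds the cyclic demography used to probe whether SFS-based trajectory
#' inference can recover glacial-scale population-size fluctuations: ten
#' instantaneous events (five expansion/contraction cycles), the most
#' recent an expansion 15 kya, a decline 120 kya, and further alternating
#' events every 120 ky until a final decline at 1.08 Mya. Size alternates
#' between `ne_current` (the post-expansion high phase, which is also the
#' current and the most ancient size) and `ne_current / fold`.
#'
#' @param gen_time_years generation time in years; event times in
#'   generations are years divided by this value.
#' @param ne_current current (and high-phase) diploid effective size.
#' @param fold intensity of each expansion/contraction (default 10).
#' @return A [demography] with 11 epochs (10 events).
#' @examples
#' glacial_cycle_demography(gen_time_years = 25, ne_current = 1e5)
#' @export
glacial_cycle_demography <- function(gen_time_years, ne_current, fold = 10) {
  if (gen_time_years <= 0) stop("'gen_time_years' must be positive")
  if (ne_current <= 0) stop("'ne_current' must be positive")
  if (fold <= 1) stop("'fold' must exceed 1")
  event_years <- c(15e3, seq(120e3, by = 120e3, length.out = 9))
  t_start <- c(0, event_years / gen_time_years)
  # 11 epochs alternating high / low, high both at present and beyond 1 Mya
  ne <- ne_current / ifelse(seq_len(11) %% 2 == 1, 1, fold)
  demography(ne = ne, t_start = t_start)
}
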