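# Cross-species synchronicity analysis of Ne trajectories.
#
# Time runs from the present into the past everywhere: grid index 1 is the
# most recent point and Delta-Ne at index t is Ne(t) - Ne(t+1) (recent
# minus older). A "decrease" means Ne falling toward the present, i.e.
# Ne(t) < Ne(t+1), i.e. negative Delta-Ne under this indexing; the
# `direction` flag of the randomization test exposes the opposite reading.

#' Convert a step trajectory to (midpoint, Ne) pairs
#'
#' Represents every interval by its unique Ne value and the midpoint of
#' its two time points, dropping the most recent interval, which is not a
#' proper step of trajectory-estimator output.
#'
#' @param traj an [ne_trajectory] or a data frame with columns `t_lo`,
#'   `t_hi`, `ne` ordered from the present.
#' @return Data frame with columns `time` (interval midpoints, ascending)
#'   and `ne`.
#' @export
trajectory_to_steps <- function(traj) {
  steps <- if (inherits(traj, "ne_trajectory")) traj$steps else traj
  stopifnot(is.data.frame(steps), all(c("t_lo", "t_hi", "ne") %in% names(steps)))
  if (nrow(steps) < 2)
    stop("trajectory needs at least two intervals (one is dropped)")
  steps <- steps[-1, , drop = FALSE]
  data.frame(time = (steps$t_lo + steps$t_hi) / 2, ne = steps$ne)
}

#' Align species trajectories on the joint time grid
#'
#' Trajectory estimates are made at species-specific time points; this
#' builds the sorted union of all species' step midpoints and assigns to
#' every species, at every grid point, the Ne of its nearest own midpoint
#' (ties broken toward the older midpoint).
#'
#' @param step_lists named list of data frames from [trajectory_to_steps]
#'   (columns `time`, `ne`), one per species.
#' @return An object of class `aligned_trajectories`: list with `grid`
#'   (strictly increasing times) and `ne` (species x grid matrix).
#' @export
align_on_grid <- function(step_lists) {
  stopifnot(is.list(step_lists), length(step_lists) >= 1)
  if (is.null(names(step_lists)) || any(names(step_lists) == ""))
    names(step_lists) <- paste0("species", seq_along(step_lists))
  grid <- sort(unique(unlist(lapply(step_lists, `[[`, "time"))))
  ne <- matrix(NA_real_, length(step_lists), length(grid),
               dimnames = list(names(step_lists), NULL))
  for (s in seq_along(step_lists)) {
    st <- step_lists[[s]]
    o <- order(st$time)
    m <- st$time[o]
    v <- st$ne[o]
    i <- findInterval(grid, m)          # m[i] <= grid < m[i+1]
    i[i < 1] <- 1
    lower <- pmin(i, length(m))
    upper <- pmin(i + 1, length(m))
    # tie (equidistant) goes to the OLDER midpoint, hence >= on the right
    pick_upper <- (m[upper] - grid) <= (grid - m[lower])
    idx <- ifelse(pick_upper, upper, lower)
    ne[s, ] <- v[idx]
  }
  structure(list(grid = grid, ne = ne), class = "aligned_trajectories")
}

#' @export
print.aligned_trajectories <- function(x, ...) {
  cat(sprintf("Aligned trajectories: %d species x %d grid points (%g .. %g)\n",
              nrow(x$ne), length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Kendall correlation matrix between species' Ne series
#'
#' Kendall's tau-b between every pair of species' aligned Ne series;
#' symmetric with unit diagonal. Constant series have undefined rank
#' correlation and yield `NA` off-diagonal entries.
#'
#' @param aligned an `aligned_trajectories` object with >= 3 grid points.
#' @return k x k matrix of tau-b values.
#' @export
kendall_matrix <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_trajectories"))
  if (length(aligned$grid) < 3) stop("need a grid of length >= 3")
  tau <- suppressWarnings(cor(t(aligned$ne), method = "kendall"))
  diag(tau) <- 1
  tau
}

# sliding mean of width w along a vector (result length(x) - w + 1)
roll_mean <- function(x, w) {
  cs <- cumsum(c(0, x))
  (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
}

#' Sliding-window smoothed Ne changes
#'
#' Computes per-species `Delta-Ne_t = Ne(t) - Ne(t+1)` (present-to-past
#' indexing) on the joint grid and averages it over `w` consecutive time
#' points with a step-1 sliding window. Windows that would extend past the
#' series end are dropped, not partially averaged.
#'
#' @param aligned an `aligned_trajectories` object; grid length must
#'   exceed `w`.
#' @param w window width in grid points (default 250).
#' @return Species x windows matrix of smoothed changes (mu-Delta-Ne).
#' @export
delta_ne_smoothed <- function(aligned, w = 250) {
  stopifnot(inherits(aligned, "aligned_trajectories"))
  G <- length(aligned$grid)
  if (G <= w) stop("grid length must exceed the window width")
  dne <- aligned$ne[, -G, drop = FALSE] - aligned$ne[, -1, drop = FALSE]
  out <- t(apply(dne, 1, roll_mean, w = w))
  rownames(out) <- rownames(aligned$ne)
  out
}

# permute a species' Delta-Ne vector and re-smooth (factored out so tests
# can verify that every replicate preserves the Delta-Ne multiset)
permute_and_smooth <- function(dne_row, w) {
  perm <- sample(dne_row)
  list(perm = perm, smoothed = roll_mean(perm, w))
}

# longest run of TRUE in a logical vector
longest_true_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Species groups with the highest trajectory synchronicity
#'
#' Named presets for the two species groups commonly analysed together:
#' the temperate broadleaves (European beech and sessile oak) and the
#' boreal/riparian group (Norway spruce, silver birch, Scots pine, black
#' poplar).
#'
#' @return Named list of character vectors.
#' @export
synchrony_groups <- function() {
  list(temperate = c("Fagus_sylvatica", "Quercus_petraea"),
       boreal = c("Picea_abies", "Betula_pendula", "Pinus_sylvestris",
                  "Populus_nigra"))
}

#' Randomization test for synchronous Ne decreases
#'
#' Tests whether periods in which several species simultaneously decrease
#' in Ne are more synchronous than expected from each species' own change
#' distribution. Per species the Delta-Ne vector is computed on the joint
#' grid and smoothed over `w` consecutive points ([delta_ne_smoothed]);
#' at each window position the number of species decreasing is counted,
#' and two observed statistics recorded: the maximum number of species
#' decreasing simultaneously, and the longest consecutive run of windows
#' over which ALL group members decrease together. Each permutation
#' replicate shuffles every species' Delta-Ne vector independently,
#' re-smooths and recomputes both statistics; observed values are compared
#' with the 95th percentile of the null maxima, and permutation p-values
#' `p = (1 + #(null >= obs)) / (n_perm + 1)` are reported. The run-length
#' statistic drives the overall `significant` flag (the max-count
#' statistic is discrete and saturates at the group size under the null).
#'
#' @param aligned an `aligned_trajectories` object.
#' @param group species subset: a character vector of row names, indices,
#'   or a preset name from [synchrony_groups] (`"temperate"`,
#'   `"boreal"`). `NULL` uses all species.
#' @param w sliding-window width in grid points (default 250).
#' @param n_perm number of randomization replicates (default 10000;
#'   values below 100 warn).
#' @param level percentile for the null comparison (default 0.95).
#' @param direction `"toward_present"` (default) counts Ne falling toward
#'   the present (negative Delta-Ne under present-to-past indexing);
#'   `"toward_past"` counts the opposite sign.
#' @param seed optional integer seed.
#' @return An object of class `synchrony_result`.
#' @export
synchrony_randomization <- function(aligned, group = NULL, w = 250,
                                    n_perm = 10000, level = 0.95,
                                    direction = c("toward_present",
                                                  "toward_past"),
                                    seed = NULL) {
  stopifnot(inherits(aligned, "aligned_trajectories"))
  direction <- match.arg(direction)
  if (n_perm < 100) warning("fewer than 100 permutations: null percentiles ",
                            "will be unstable")
  if (!is.null(seed)) set.seed(seed)
  ne <- aligned$ne
  if (!is.null(group)) {
    if (is.character(group) && length(group) == 1 &&
        group %in% names(synchrony_groups()))
      group <- synchrony_groups()[[group]]
    if (is.character(group)) {
      missing_sp <- setdiff(group, rownames(ne))
      if (length(missing_sp))
        stop("species not in the aligned set: ",
             paste(missing_sp, collapse = ", "))
    }
    ne <- ne[group, , drop = FALSE]
  }
  k <- nrow(ne)
  G <- ncol(ne)
  if (G <= w) stop("grid length must exceed the window width")
  dne <- ne[, -G, drop = FALSE] - ne[, -1, drop = FALSE]
  dec_sign <- if (direction == "toward_present") -1 else 1

  smooth_mat <- t(apply(dne, 1, roll_mean, w = w))
  dec <- dec_sign * smooth_mat > 0
  counts <- colSums(dec)
  obs_max <- max(counts)
  obs_run <- longest_true_run(counts == k)

  null_max <- integer(n_perm)
  null_run <- integer(n_perm)
  nw <- ncol(smooth_mat)
  for (b in seq_len(n_perm)) {
    cnt <- integer(nw)
    for (s in seq_len(k)) {
      sm <- roll_mean(sample(dne[s, ]), w)
      cnt <- cnt + (dec_sign * sm > 0)
    }
    null_max[b] <- max(cnt)
    null_run[b] <- longest_true_run(cnt == k)
  }
  q_max <- quantile(null_max, level, type = 1, names = FALSE)
  q_run <- quantile(null_run, level, type = 1, names = FALSE)
  p_max <- (1 + sum(null_max >= obs_max)) / (n_perm + 1)
  p_run <- (1 + sum(null_run >= obs_run)) / (n_perm + 1)
  structure(list(observed_max_species = obs_max,
                 observed_longest_run = obs_run,
                 null_95 = c(max_species = q_max, longest_run = q_run),
                 p_max = p_max, p_run = p_run,
                 significant_max = obs_max > q_max,
                 significant_run = obs_run > q_run,
                 significant = p_run <= 1 - level,
                 n_perm = n_perm, w = w, k = k, level = level,
                 direction = direction,
                 counts = counts),
            class = "synchrony_result")
}

#' @export
print.synchrony_result <- function(x, ...) {
  cat(sprintf("Synchronicity randomization (%d species, w = %d, %d permutations):\n",
              x$k, x$w, x$n_perm))
  cat(sprintf("  max species decreasing simultaneously: %d (null 95%%: %g, p = %.4g)\n",
              x$observed_max_species, x$null_95[["max_species"]], x$p_max))
  cat(sprintf("  longest fully synchronous run: %d windows (null 95%%: %g, p = %.4g)\n",
              x$observed_longest_run, x$null_95[["longest_run"]], x$p_run))
  cat(sprintf("  significant: %s\n", x$significant))
  invisible(x)
}
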