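#' Run the filtering-to-inference pipeline
#'
#' Ties the stages together in the canonical order: variant/genotype QC
#' (INFO masks, DP/GQ masking, HDplot paralog flags, windowed paralog
#' regions) -> folded SFS construction -> diversity -> spatial
#' differentiation (pairwise FST, isolation by distance) -> demographic
#' model fits (SNM/epoch-2/epoch-3 by AIC, optional stairway-style
#' trajectory) -> optional synchronicity test on the resulting
#' trajectories. Every stage logs the thresholds it applied and the
#' number of sites it removed; all stochastic steps derive their seed
#' from `config$seed`, so a rerun with the same configuration reproduces
#' every output byte for byte.
#'
#' @param config a `pipeline_config` from [default_pipeline_config].
#' @param gm a [genotype_matrix] (or `NULL` to read `vcf_path`).
#' @param reads read-count table for HDplot (required for the QC stage
#'   unless supplied by the VCF's AD field).
#' @param vcf_path optional VCF to load when `gm` is `NULL`.
#' @param coords optional data frame (`pop`, `lat`, `lon`) enabling the
#'   spatial stage.
#' @param out_dir artifact directory (created if missing).
#' @return Invisible list of stage results; artifacts are written as TSV
#'   under `out_dir` alongside `pipeline.log`.
#' @export
run_pipeline <- function(config, gm = NULL, reads = NULL, vcf_path = NULL,
                         coords = NULL, out_dir = tempfile("glacialsfs_")) {
  stopifnot(inherits(config, "pipeline_config") || is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  fail <- function(stage, msg) stop("pipeline stage '", stage, "': ", msg,
                                    call. = FALSE)
  on_stage <- function(name) isTRUE(config$stages[[name]])
  results <- list()
  set.seed(config$seed)

  if (is.null(gm)) {
    if (is.null(vcf_path)) fail("input", "neither 'gm' nor 'vcf_path' given")
    vr <- read_vcf(vcf_path)
    gm <- vr$gm
    if (is.null(reads)) reads <- vr$reads
    note("input: read %d individuals x %d SNPs from %s (%d multiallelic dropped)",
         nrow(gm$genotypes), ncol(gm$genotypes), vcf_path,
         vr$n_multiallelic_dropped)
  } else {
    note("input: in-memory genotype matrix, %d individuals x %d SNPs",
         nrow(gm$genotypes), ncol(gm$genotypes))
  }

  if (on_stage("qc")) {
    q <- config$qc
    if (!is.null(gm$info)) {
      keep <- site_info_filter(gm$info, q$qd_min, q$qual_min, q$sor_max,
                               q$mq_min, q$mqrs_min, q$rprs_min)
      note("qc/info: thresholds QD<%g QUAL<%g SOR>%g MQ<%g MQRankSum<%g ReadPosRankSum<%g removed %d SNPs",
           q$qd_min, q$qual_min, q$sor_max, q$mq_min, q$mqrs_min,
           q$rprs_min, sum(!keep))
      if (!is.null(reads) && nrow(reads)) {
        old_idx <- which(keep)
        reads <- reads[reads$site %in% old_idx, , drop = FALSE]
        reads$site <- match(reads$site, old_idx)
      }
      gm <- subset_gm(gm, sites = which(keep))
    }
    n_before <- ncol(gm$genotypes)
    gm2 <- genotype_filter(gm, q$dp_min, q$gq_min, q$site_missing_max)
    dropped <- attr(gm2, "dropped_sites")
    note("qc/genotype: DP<%g or GQ<%g masked; >%g%% missing removed %d SNPs",
         q$dp_min, q$gq_min, 100 * q$site_missing_max, length(dropped))
    if (!is.null(reads) && nrow(reads) && length(dropped)) {
      kept_idx <- setdiff(seq_len(n_before), dropped)
      reads <- reads[reads$site %in% kept_idx, , drop = FALSE]
      reads$site <- match(reads$site, kept_idx)
    }
    gm <- gm2
    if (!is.null(reads) && nrow(reads)) {
      stats <- hdplot(gm, reads)
      flags <- flag_paralog_sites(stats, q$h_max, q$d_abs)
      pw <- paralog_window_filter(gm$positions, flags, gm$contig,
                                  q$window, q$frac)
      drop_sites <- sort(union(which(flags), pw$excluded))
      note("qc/hdplot: H>%g or |D|>%g flagged %d SNPs; %g-bp windows >%g%% paralogs excluded %d SNPs in %d regions",
           q$h_max, q$d_abs, sum(flags), q$window, 100 * q$frac,
           length(pw$excluded), nrow(pw$regions))
      if (nrow(pw$regions))
        write_bed(pw$regions, file.path(out_dir, "paralog_regions.bed"))
      if (length(drop_sites))
        gm <- subset_gm(gm, sites = setdiff(seq_len(ncol(gm$genotypes)),
                                            drop_sites))
    } else {
      note("qc/hdplot: skipped (no read counts available)")
    }
    results$gm <- gm
  }

  pops <- unique(gm$pop)
  sfs_by_pop <- NULL
  if (on_stage("sfs")) {
    if (!on_stage("qc")) note("sfs: running on unfiltered genotypes (qc stage off)")
    classes <- config$sfs$classes
    if (length(classes) == 1 && is.na(classes)) classes <- NULL
    target_n <- config$sfs$target_n
    if (length(target_n) == 1 && is.na(target_n)) target_n <- NULL
    sfs_by_pop <- lapply(pops, function(p) {
      build_folded_sfs(subset_gm(gm, individuals = which(gm$pop == p)),
                       classes = classes,
                       max_missing = config$sfs$max_missing,
                       target_n = target_n)
    })
    names(sfs_by_pop) <- pops
    for (p in pops)
      write_sfs(sfs_by_pop[[p]],
                file.path(out_dir, paste0("sfs_", p, ".obs")), "obs")
    note("sfs: built folded SFS for %d population(s), max_missing=%g",
         length(pops), config$sfs$max_missing)
    results$sfs <- sfs_by_pop
  }

  if (on_stage("diversity")) {
    if (is.null(sfs_by_pop)) fail("diversity", "sfs stage was not run")
    pi_tab <- data.frame(
      pop = pops,
      pi = vapply(sfs_by_pop, pi_from_sfs, numeric(1)),
      n = vapply(sfs_by_pop, function(s) s$n, numeric(1)),
      L = vapply(sfs_by_pop, function(s) s$L, numeric(1)))
    write.table(pi_tab, file.path(out_dir, "diversity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("diversity: pi per population written (projection estimator)")
    results$diversity <- pi_tab
  }

  if (on_stage("spatial")) {
    if (length(pops) < 2) {
      note("spatial: skipped (single population)")
    } else {
      fst <- pairwise_fst(gm)
      write.table(round(fst, 6), file.path(out_dir, "fst.tsv"), sep = "\t",
                  quote = FALSE)
      results$fst <- fst
      if (!is.null(coords)) {
        ibd <- ibd_regression(fst, coords)
        scl <- scaled_population_fst(fst, coords)
        write.table(data.frame(beta = ibd$beta, alpha = ibd$alpha,
                               r2 = ibd$r2),
                    file.path(out_dir, "ibd.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(data.frame(pop = names(scl), scaled_fst = scl),
                    file.path(out_dir, "scaled_fst.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        results$ibd <- ibd
        results$scaled_fst <- scl
        note("spatial: FST, IBD (beta=%.4g) and scaled FST written", ibd$beta)
      } else {
        note("spatial: FST written; no coordinates, IBD skipped")
      }
    }
  }

  if (on_stage("demography")) {
    if (is.null(sfs_by_pop)) fail("demography", "sfs stage was not run")
    d <- config$demography
    fit_rows <- list()
    for (p in pops) {
      obs <- sfs_by_pop[[p]]
      fits <- lapply(c("SNM", "epoch2"), function(mn)
        fit_epoch_model(obs, mn, config$mu, n_starts = d$n_starts,
                        bounds = d$bounds, maxit = d$maxit,
                        seed = config$seed + match(p, pops)))
      tab <- compare_models_aic(fits)
      best <- fits[[match(tab$model[1], c("SNM", "epoch2"))]]
      fit_rows[[p]] <- data.frame(pop = p, model = tab$model[1],
                                  aic = tab$aic[1],
                                  delta_aic_next = tab$delta_aic[2],
                                  t(best$params))
      if (isTRUE(config$stages$stairway)) {
        traj <- stairway_like_fit(obs, config$mu, config$gen_time_years,
                                  n_boot = d$stairway_n_boot,
                                  seed = config$seed + 100 + match(p, pops))
        write_trajectory(traj, file.path(out_dir,
                                         paste0("trajectory_", p, ".tsv")))
        results$trajectories[[p]] <- traj
      }
    }
    fit_tab <- do.call(rbind, lapply(fit_rows, function(x) {
      miss <- setdiff(c("NCUR", "NANC", "TBOT"), names(x))
      for (m in miss) x[[m]] <- NA_real_
      x[, c("pop", "model", "aic", "delta_aic_next", "NCUR", "NANC", "TBOT")]
    }))
    write.table(fit_tab, file.path(out_dir, "epoch_fits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("demography: epoch fits written (%d starts, prior %g..%g)",
         d$n_starts, d$bounds[1], d$bounds[2])
    results$epoch_fits <- fit_tab
  }

  if (on_stage("synchrony")) {
    trajs <- results$trajectories
    if (is.null(trajs) || length(trajs) < 2)
      fail("synchrony", "needs >= 2 trajectories (enable the stairway stage)")
    aligned <- align_on_grid(lapply(trajs, trajectory_to_steps))
    sy <- config$synchrony
    res <- synchrony_randomization(aligned, w = min(sy$w,
                                                    length(aligned$grid) - 1),
                                   n_perm = sy$n_perm, level = sy$level,
                                   seed = config$seed + 999)
    write.table(data.frame(observed_max_species = res$observed_max_species,
                           observed_longest_run = res$observed_longest_run,
                           null95_max = res$null_95[["max_species"]],
                           null95_run = res$null_95[["longest_run"]],
                           p_run = res$p_run, significant = res$significant),
                file.path(out_dir, "synchrony.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("synchrony: randomization test written (%d permutations)", sy$n_perm)
    results$synchrony <- res
  }

  writeLines(log_lines, log_path)
  results$out_dir <- out_dir
  invisible(results)
}
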