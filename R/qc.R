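# Variant-, genotype- and region-level quality filters.

#' Variant-level INFO threshold filter
#'
#' Keeps a site unless any annotation violates its threshold: QD < 0.25,
#' QUAL < 20, SOR > 3.0, MQ < 30, MQRankSum < -12.5 or
#' ReadPosRankSum < -8.0 (all inequalities strict, so values exactly at a
#' threshold pass). Missing annotations pass by default, since variant
#' callers omit the rank-sum scores at sites without the required
#' genotype mix; set `missing_fails = TRUE` to invert that.
#'
#' @param info data frame of per-site annotations; recognized columns are
#'   QD, QUAL, SOR, MQ, MQRankSum, ReadPosRankSum (absent columns are
#'   simply not tested).
#' @param qd_min,qual_min,sor_max,mq_min,mqrs_min,rprs_min thresholds.
#' @param missing_fails treat `NA` annotations as failures.
#' @return Logical keep mask, one entry per site.
#' @export
site_info_filter <- function(info, qd_min = 0.25, qual_min = 20,
                             sor_max = 3.0, mq_min = 30,
                             mqrs_min = -12.5, rprs_min = -8.0,
                             missing_fails = FALSE) {
  stopifnot(is.data.frame(info))
  n <- nrow(info)
  viol <- matrix(FALSE, n, 6)
  test <- function(col, fun) {
    if (!col %in% names(info)) return(rep(FALSE, n))
    v <- fun(info[[col]])
    v[is.na(v)] <- missing_fails
    v
  }
  viol[, 1] <- test("QD", function(x) x < qd_min)
  viol[, 2] <- test("QUAL", function(x) x < qual_min)
  viol[, 3] <- test("SOR", function(x) x > sor_max)
  viol[, 4] <- test("MQ", function(x) x < mq_min)
  viol[, 5] <- test("MQRankSum", function(x) x < mqrs_min)
  viol[, 6] <- test("ReadPosRankSum", function(x) x < rprs_min)
  !apply(viol, 1, any)
}

#' Genotype-level DP/GQ masking and per-site missingness filter
#'
#' Sets genotype calls with depth below `dp_min` or genotype quality below
#' `gq_min` to missing (strict inequalities: DP = 8 and GQ = 20 are
#' retained at the defaults), then drops SNPs whose missing-call fraction
#' exceeds `site_missing_max`. The same DP/GQ rule is what available-genome
#' accounting applies to monomorphic positions.
#'
#' @param gm a [genotype_matrix].
#' @param dp_min,gq_min per-call thresholds (defaults 8 and 20).
#' @param site_missing_max maximum tolerated missing fraction per site
#'   (default 0.5; strictly greater is dropped).
#' @return A filtered [genotype_matrix]; attribute `"dropped_sites"`
#'   records the column indices removed.
#' @export
genotype_filter <- function(gm, dp_min = 8, gq_min = 20,
                            site_missing_max = 0.5) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$genotypes
  mask <- (gm$dp < dp_min) | (gm$gq < gq_min)
  g[mask] <- NA_integer_
  miss_frac <- colMeans(is.na(g))
  keep <- miss_frac <= site_missing_max
  gm$genotypes <- g
  out <- subset_gm(gm, sites = which(keep))
  attr(out, "dropped_sites") <- which(!keep)
  out
}

#' HDplot statistics for paralog detection
#'
#' For every site computes `H`, the fraction of heterozygotes among
#' non-missing calls, and `D`, the deviation of the pooled heterozygote
#' allele reads from the balanced 1:1 expectation expressed as a binomial
#' z-score: `D = (A - B) / sqrt(A + B)` with `A` and `B` the allele-1 and
#' allele-2 read totals summed over heterozygous individuals at the site.
#' Collapsed paralogs show excess heterozygosity (H) and/or skewed read
#' ratios (|D|).
#'
#' @param gm a [genotype_matrix].
#' @param reads read-count table: data frame with columns `individual`,
#'   `site`, `reads_a`, `reads_b` holding per-heterozygote allele reads.
#' @return Data frame of class `hdplot_stats` with columns `site`, `h`,
#'   `d`, `n_called`, `n_het`. Sites with no non-missing calls get `NA`
#'   for both statistics; sites with no read-covered heterozygote get
#'   `NA` for `d`.
#' @export
hdplot <- function(gm, reads) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(reads) || !nrow(reads))
    stop("read counts for heterozygous calls are required for HDplot")
  stopifnot(all(c("individual", "site", "reads_a", "reads_b") %in%
                names(reads)))
  if (any(reads$reads_a + reads$reads_b < 1))
    stop("every recorded heterozygote needs at least one read")
  g <- gm$genotypes
  S <- ncol(g)
  n_called <- colSums(!is.na(g))
  n_het <- colSums(g == 1L, na.rm = TRUE)
  h <- ifelse(n_called > 0, n_het / n_called, NA_real_)
  A <- B <- numeric(S)
  ta <- tapply(reads$reads_a, reads$site, sum)
  tb <- tapply(reads$reads_b, reads$site, sum)
  idx <- as.integer(names(ta))
  A[idx] <- ta
  B[idx] <- tb
  d <- ifelse(A + B > 0, (A - B) / sqrt(A + B), NA_real_)
  d[n_called == 0] <- NA_real_
  structure(data.frame(site = seq_len(S), h = h, d = d,
                       n_called = n_called, n_het = n_het),
            class = c("hdplot_stats", "data.frame"))
}

#' Flag putative paralog-derived SNPs from HDplot statistics
#'
#' A site is flagged when `H > h_max` or `|D| > d_abs` (strict
#' inequalities; H = 0.6 with D = 20 is not flagged at the defaults).
#' Sites with undefined statistics are never flagged.
#'
#' @param stats an `hdplot_stats` data frame from [hdplot].
#' @param h_max heterozygote-fraction threshold (default 0.6).
#' @param d_abs absolute read-ratio-deviation threshold (default 20).
#' @return Logical flag vector, one entry per site.
#' @export
flag_paralog_sites <- function(stats, h_max = 0.6, d_abs = 20) {
  stopifnot(inherits(stats, "hdplot_stats") || is.data.frame(stats))
  h_flag <- !is.na(stats$h) & stats$h > h_max
  d_flag <- !is.na(stats$d) & abs(stats$d) > d_abs
  h_flag | d_flag
}

#' Windowed paralog-region exclusion
#'
#' Delineates regions enriched in paralog-derived SNPs and excludes every
#' polymorphic position inside them. A symmetric window of `window` bp
#' centered on each flagged SNP is evaluated; when it holds at least two
#' SNPs and the flagged fraction exceeds `frac`, all SNPs inside are
#' marked. Maximal runs of marked SNPs become exclusion regions whose
#' boundaries extend to the midpoint between the outermost marked SNP and
#' the nearest clean SNP on each side (mid-distance rule; where no clean
#' neighbour exists the boundary extends `window/2` beyond the outermost
#' marked SNP). A lone flagged SNP that triggers no window is left to the
#' per-site flag filter and never expands a region.
#'
#' @param positions 1-based SNP positions, sorted increasingly per contig.
#' @param flags logical paralog flags from [flag_paralog_sites].
#' @param contig contig of each SNP (single contig assumed when omitted).
#' @param window window width in bp (default 250).
#' @param frac paralog-fraction threshold (default 0.10, strict).
#' @return List with `excluded` (indices of SNPs inside exclusion
#'   regions) and `regions` (data frame `contig`, `start`, `end` of
#'   non-overlapping half-open intervals, sorted).
#' @export
paralog_window_filter <- function(positions, flags, contig = NULL,
                                  window = 250, frac = 0.10) {
  S <- length(positions)
  stopifnot(length(flags) == S)
  if (is.null(contig)) contig <- rep("chr1", S)
  contig <- rep_len(contig, S)
  excluded <- rep(FALSE, S)
  regions <- list()

  for (ctg in unique(contig)) {
    on <- which(contig == ctg)
    pos <- positions[on]
    if (length(pos) > 1 && any(diff(pos) <= 0))
      stop("positions must be sorted increasingly within contig ", ctg)
    flg <- flags[on]
    marked <- rep(FALSE, length(on))
    for (f in which(flg)) {
      inwin <- which(pos >= pos[f] - window / 2 & pos <= pos[f] + window / 2)
      if (length(inwin) >= 2 && mean(flg[inwin]) > frac)
        marked[inwin] <- TRUE
    }
    if (!any(marked)) next
    # clean SNPs for the mid-distance rule: neither marked nor flagged
    clean <- !marked & !flg
    runs <- rle(marked)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (r in which(runs$values)) {
      i0 <- starts[r]; i1 <- ends[r]
      prev_clean <- if (any(clean[seq_len(i0 - 1)]))
        max(which(clean[seq_len(i0 - 1)])) else NA_integer_
      next_clean <- if (i1 < length(on) && any(clean[(i1 + 1):length(on)]))
        i1 + min(which(clean[(i1 + 1):length(on)])) else NA_integer_
      lo <- if (!is.na(prev_clean)) (pos[prev_clean] + pos[i0]) / 2
            else max(pos[i0] - window / 2, 0)
      hi <- if (!is.na(next_clean)) (pos[i1] + pos[next_clean]) / 2
            else pos[i1] + window / 2
      regions[[length(regions) + 1]] <-
        data.frame(contig = ctg, start = lo, end = hi)
    }
  }

  if (length(regions)) {
    reg <- do.call(rbind, regions)
    reg <- reg[order(reg$contig, reg$start), , drop = FALSE]
    # merge overlapping/adjacent regions per contig
    merged <- list()
    for (i in seq_len(nrow(reg))) {
      last <- if (length(merged)) merged[[length(merged)]] else NULL
      if (!is.null(last) && last$contig == reg$contig[i] &&
          reg$start[i] <= last$end) {
        last$end <- max(last$end, reg$end[i])
        merged[[length(merged)]] <- last
      } else merged[[length(merged) + 1]] <- reg[i, ]
    }
    reg <- do.call(rbind, merged)
    rownames(reg) <- NULL
    for (i in seq_len(nrow(reg))) {
      inside <- contig == reg$contig[i] &
        positions >= reg$start[i] & positions < reg$end[i]
      excluded <- excluded | inside
    }
  } else {
    reg <- data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0))
  }
  list(excluded = which(excluded), regions = reg)
}
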