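# Readers and writers: VCF, folded/joint SFS dialects, trajectory TSV,
# stairway-style summary files, BED, pipeline configuration.
#
# Coordinate conventions are centralized here: VCF positions are 1-based,
# BED intervals 0-based half-open; `to_bed0()` is the single conversion
# point.

# convert a 1-based half-open interval [start, end) (fractional bounds
# allowed) into 0-based half-open BED coordinates covering the same
# integer positions
to_bed0 <- function(start, end) {
  data.frame(start = ceiling(start) - 1, end = ceiling(end) - 1)
}

#' Write exclusion regions as BED
#'
#' @param regions data frame with columns `contig`, `start`, `end`
#'   (1-based half-open, as produced by [paralog_window_filter]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  b <- to_bed0(regions$start, regions$end)
  df <- data.frame(chrom = regions$contig, chromStart = b$start,
                   chromEnd = b$end)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a folded or joint SFS to disk
#'
#' Two dialects: `"obs"` is a fastsimcoal-style text block (`"1
#' observations"` header, then a count row indexed 0..n whose entry 0 is
#' the monomorphic count; joint spectra store an (n1+1) x (n2+1) labelled
#' matrix); `"tsv"` is a commented tab-separated table carrying `n` and
#' `L` in its header line.
#'
#' @param sfs a [folded_sfs] or [joint_sfs].
#' @param path output path.
#' @param dialect `"obs"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_sfs <- function(sfs, path, dialect = c("obs", "tsv")) {
  dialect <- match.arg(dialect)
  if (inherits(sfs, "folded_sfs")) {
    n <- sfs$n
    row <- c(sfs$n_mono, sfs$eta, rep(0, n - n %/% 2))
    if (dialect == "obs") {
      lines <- c("1 observations",
                 paste(paste0("d0_", 0:n), collapse = "\t"),
                 paste(format(row, scientific = FALSE, trim = TRUE),
                       collapse = "\t"))
      writeLines(lines, path)
    } else {
      lines <- c(sprintf("# folded_sfs n=%d L=%s", n,
                         format(sfs$L, scientific = FALSE)),
                 "minor_count\tcount",
                 sprintf("%d\t%s", 0:n,
                         format(row, scientific = FALSE, trim = TRUE)))
      writeLines(lines, path)
    }
  } else if (inherits(sfs, "joint_sfs")) {
    m <- sfs$counts
    if (dialect == "obs") {
      lines <- c("1 observations",
                 paste(c("", paste0("d1_", 0:sfs$n2)), collapse = "\t"))
      for (i in 0:sfs$n1)
        lines <- c(lines, paste(c(paste0("d0_", i),
                                  format(m[i + 1, ], scientific = FALSE,
                                         trim = TRUE)), collapse = "\t"))
      writeLines(lines, path)
    } else {
      lines <- c(sprintf("# joint_sfs n1=%d n2=%d L=%s", sfs$n1, sfs$n2,
                         format(sfs$L, scientific = FALSE)),
                 paste(c("", paste0("d1_", 0:sfs$n2)), collapse = "\t"))
      for (i in 0:sfs$n1)
        lines <- c(lines, paste(c(paste0("d0_", i),
                                  format(m[i + 1, ], scientific = FALSE,
                                         trim = TRUE)), collapse = "\t"))
      writeLines(lines, path)
    }
  } else stop("'sfs' must be a folded_sfs or joint_sfs")
  invisible(path)
}

#' Read a folded or joint SFS
#'
#' Auto-detects the dialect and shape written by [write_sfs]. For the
#' `obs` dialect of a single-population spectrum, `L` is recovered as the
#' sum of the count row (monomorphic cell included).
#'
#' @param path input path.
#' @return A [folded_sfs] or [joint_sfs].
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty SFS file: ", path)
  first <- lines[1]
  if (grepl("^# folded_sfs", first)) {
    n <- as.integer(sub(".*n=(\\d+).*", "\\1", first))
    L <- as.numeric(sub(".*L=([0-9.eE+-]+).*", "\\1", first))
    tab <- read.table(text = lines[-1], header = TRUE, sep = "\t")
    row <- tab$count
    if (length(row) != n + 1) stop("corrupt SFS table: expected ", n + 1,
                                   " rows, found ", length(row))
    folded_sfs(row[2:(n %/% 2 + 1)], n = n, L = L, n_mono = row[1])
  } else if (grepl("^# joint_sfs", first)) {
    n1 <- as.integer(sub(".*n1=(\\d+).*", "\\1", first))
    n2 <- as.integer(sub(".*n2=(\\d+).*", "\\1", first))
    L <- as.numeric(sub(".*L=([0-9.eE+-]+).*", "\\1", first))
    m <- as.matrix(read.table(text = lines[-(1:2)], row.names = 1,
                              sep = "\t"))
    if (!all(dim(m) == c(n1 + 1, n2 + 1)))
      stop("corrupt joint SFS: dimension mismatch")
    joint_sfs(unname(m), n1 = n1, n2 = n2, L = L)
  } else if (grepl("observations", first)) {
    body <- lines[-1]
    if (length(body) == 2 && !grepl("^d0_", body[2])) {
      vals <- as.numeric(strsplit(trimws(body[2]), "\\s+")[[1]])
      n <- length(vals) - 1
      folded_sfs(vals[2:(n %/% 2 + 1)], n = n, L = sum(vals),
                 n_mono = vals[1])
    } else {
      rows <- strsplit(trimws(body[-1]), "\\s+")
      m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
      n1 <- nrow(m) - 1
      n2 <- ncol(m) - 1
      joint_sfs(m, n1 = n1, n2 = n2, L = sum(m))
    }
  } else stop("unrecognized SFS file header: ", first)
}

#' Write an Ne trajectory as TSV
#'
#' @param traj an [ne_trajectory].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ne_trajectory"))
  hdr <- sprintf("# ne_trajectory mu=%g gen_time_years=%g time_unit=%s species=%s",
                 traj$mu, traj$gen_time_years, traj$time_unit, traj$species)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(traj$steps, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read an Ne trajectory written by [write_trajectory]
#'
#' @param path input path.
#' @return An [ne_trajectory].
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  if (!grepl("^# ne_trajectory", hdr)) stop("not a trajectory file: ", path)
  get_num <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[0-9.eE+-]+|", key, "=NA"), hdr))
    if (!length(m)) return(NA_real_)
    as.numeric(sub(paste0(key, "="), "", m))
  }
  get_chr <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=\\S+"), hdr))
    if (!length(m)) return(NA_character_)
    sub(paste0(key, "="), "", m)
  }
  steps <- read.table(text = lines[-1], header = TRUE, sep = "\t")
  ne_trajectory(steps, mu = get_num("mu"),
                gen_time_years = get_num("gen_time_years"),
                time_unit = get_chr("time_unit"),
                species = get_chr("species"))
}

#' Read a Stairway Plot 2 final-summary file
#'
#' Tolerant parser for the whitespace-delimited "final summary" output:
#' locates the `year` and `Ne_median` columns (plus `Ne_2.5%` /
#' `Ne_97.5%` bands and `mutation_per_site` when present, matching
#' case-insensitively) and converts the per-time-point rows into
#' contiguous step intervals.
#'
#' @param path input path.
#' @param species optional label.
#' @return An [ne_trajectory] with `time_unit = "years"`.
#' @export
read_stairway_summary <- function(path, species = NA_character_) {
  tab <- read.table(path, header = TRUE, check.names = FALSE,
                    comment.char = "")
  nm <- tolower(names(tab))
  pick <- function(pattern) {
    hit <- grep(pattern, nm)
    if (length(hit)) tab[[hit[1]]] else NULL
  }
  year <- pick("^year$")
  ne <- pick("^ne_median$")
  if (is.null(year) || is.null(ne))
    stop("stairway summary lacks 'year'/'Ne_median' columns: ", path)
  mu <- pick("mutation_per_site")
  lo <- pick("ne_2\\.5")
  hi <- pick("ne_97\\.5")
  o <- order(year)
  year <- year[o]; ne <- ne[o]
  keep <- !duplicated(year)
  year <- year[keep]; ne <- ne[keep]
  if (!is.null(lo)) lo <- lo[o][keep]
  if (!is.null(hi)) hi <- hi[o][keep]
  G <- length(year)
  if (G < 2) stop("stairway summary has fewer than two time points")
  steps <- data.frame(t_lo = year[-G], t_hi = year[-1], ne = ne[-G])
  if (!is.null(lo)) steps$ne_lo <- lo[-G]
  if (!is.null(hi)) steps$ne_hi <- hi[-G]
  ne_trajectory(steps, mu = if (!is.null(mu)) mu[1] else NA_real_,
                time_unit = "years", species = species)
}

#' Read a biallelic VCF into a genotype matrix
#'
#' Parses a VCF (v4.x) with vcfR, retains biallelic SNP records only
#' (multiallelic records are dropped and counted), and maps FORMAT
#' DP/GQ/AD plus the INFO scores QD, QUAL, SOR, MQ, MQRankSum and
#' ReadPosRankSum into a [genotype_matrix] and a read-count table for
#' heterozygous calls. An optional `SCLASS` INFO key carries the site
#' class.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param pop_map named character vector (individual -> population) or
#'   data frame with columns `indiv`, `pop`; `NULL` assigns everyone to
#'   `"pop1"`.
#' @param L_total total surveyed sites including monomorphic positions
#'   (defaults to the number of retained SNPs).
#' @return List with `gm` (a [genotype_matrix]), `reads` (data frame
#'   `individual`, `site`, `reads_a`, `reads_b`; zero rows when the VCF
#'   has no AD field) and `n_multiallelic_dropped`.
#' @export
read_vcf <- function(path, pop_map = NULL, L_total = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  bi <- vcfR::is.biallelic(v)
  n_dropped <- sum(!bi)
  v <- v[bi, ]
  fix <- fix[bi, , drop = FALSE]
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no genotypes")
  alleles <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/")
    vapply(a, function(p) {
      if (any(p == ".") || length(p) != 2) NA_integer_
      else sum(as.integer(p))
    }, integer(1))
  }
  g <- t(apply(gt, 1, alleles))            # sites x individuals
  g <- t(g)                                # individuals x sites
  indiv <- colnames(gt)
  rownames(g) <- indiv
  num_fmt <- function(el) {
    x <- vcfR::extract.gt(v, element = el, as.numeric = TRUE)
    if (is.null(x)) return(NULL)
    t(x)
  }
  dp <- num_fmt("DP")
  gq <- num_fmt("GQ")
  if (is.null(dp)) dp <- matrix(99L, nrow(g), ncol(g))
  if (is.null(gq)) gq <- matrix(99L, nrow(g), ncol(g))
  dp[is.na(dp)] <- 0L
  gq[is.na(gq)] <- 0L

  info_field <- function(key) {
    x <- suppressWarnings(vcfR::extract.info(v, element = key,
                                             as.numeric = TRUE))
    if (is.null(x)) rep(NA_real_, ncol(g)) else x
  }
  info <- data.frame(QD = info_field("QD"),
                     QUAL = suppressWarnings(as.numeric(fix[, "QUAL"])),
                     SOR = info_field("SOR"),
                     MQ = info_field("MQ"),
                     MQRankSum = info_field("MQRankSum"),
                     ReadPosRankSum = info_field("ReadPosRankSum"))
  sclass <- suppressWarnings(vcfR::extract.info(v, element = "SCLASS"))
  site_class <- if (is.null(sclass) || all(is.na(sclass)))
    rep("other", ncol(g)) else ifelse(is.na(sclass), "other", sclass)

  pop <- rep("pop1", nrow(g))
  if (!is.null(pop_map)) {
    if (is.data.frame(pop_map))
      pop_map <- setNames(as.character(pop_map$pop), pop_map$indiv)
    hit <- match(indiv, names(pop_map))
    if (any(is.na(hit))) stop("pop_map lacks individuals: ",
                              paste(indiv[is.na(hit)], collapse = ", "))
    pop <- unname(pop_map[hit])
  }

  ad <- vcfR::extract.gt(v, element = "AD")
  reads <- data.frame(individual = integer(0), site = integer(0),
                      reads_a = integer(0), reads_b = integer(0))
  if (!is.null(ad)) {
    het <- which(t(g) == 1L & !is.na(ad), arr.ind = TRUE)
    if (nrow(het)) {
      parts <- strsplit(ad[het], ",")
      ra <- vapply(parts, function(p) as.integer(p[1]), integer(1))
      rb <- vapply(parts, function(p) as.integer(p[2]), integer(1))
      keep <- !is.na(ra) & !is.na(rb) & (ra + rb) >= 1
      reads <- data.frame(individual = unname(het[keep, 2]),
                          site = unname(het[keep, 1]),
                          reads_a = ra[keep], reads_b = rb[keep])
    }
  }

  gm <- genotype_matrix(genotypes = g, dp = dp, gq = gq,
                        positions = as.numeric(fix[, "POS"]),
                        contig = fix[, "CHROM"], info = info,
                        site_class = site_class, pop = pop,
                        L_total = if (is.null(L_total)) ncol(g) else L_total)
  list(gm = gm, reads = reads, n_multiallelic_dropped = n_dropped)
}

#' Write a genotype matrix as a minimal biallelic VCF
#'
#' Emits a VCF v4.2 with FORMAT `GT:DP:GQ:AD` and the INFO scores carried
#' by the matrix (plus `SCLASS`); heterozygote AD values come from the
#' read-count table when supplied, homozygote AD places all reads on the
#' carried allele. Round-trips through [read_vcf].
#'
#' @param gm a [genotype_matrix].
#' @param path output path.
#' @param reads optional read-count table (columns `individual`, `site`,
#'   `reads_a`, `reads_b`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, reads = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_ind <- nrow(gm$genotypes)
  S <- ncol(gm$genotypes)
  indiv <- rownames(gm$genotypes)
  if (is.null(indiv)) indiv <- sprintf("ind%03d", seq_len(n_ind))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=glacialsfs",
           '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
           '##INFO=<ID=SOR,Number=1,Type=Float,Description="Symmetric odds ratio">',
           '##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">',
           '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="MQ rank sum">',
           '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read position rank sum">',
           '##INFO=<ID=SCLASS,Number=1,Type=String,Description="Site class">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", indiv), collapse = "\t"))
  ad_lookup <- NULL
  if (!is.null(reads) && nrow(reads))
    ad_lookup <- setNames(paste0(reads$reads_a, ",", reads$reads_b),
                          paste(reads$individual, reads$site, sep = ":"))
  info <- gm$info
  fmt_num <- function(x) ifelse(is.na(x), ".",
                                format(x, scientific = FALSE, trim = TRUE))
  body <- character(S)
  for (s in seq_len(S)) {
    info_s <- if (is.null(info)) "." else
      paste0("QD=", fmt_num(info$QD[s]), ";SOR=", fmt_num(info$SOR[s]),
             ";MQ=", fmt_num(info$MQ[s]),
             ";MQRankSum=", fmt_num(info$MQRankSum[s]),
             ";ReadPosRankSum=", fmt_num(info$ReadPosRankSum[s]),
             ";SCLASS=", gm$site_class[s])
    qual_s <- if (is.null(info) || is.null(info$QUAL)) "."
              else fmt_num(info$QUAL[s])
    cells <- character(n_ind)
    for (i in seq_len(n_ind)) {
      gval <- gm$genotypes[i, s]
      gt <- if (is.na(gval)) "./." else c("0/0", "0/1", "1/1")[gval + 1]
      dp <- gm$dp[i, s]
      ad <- if (!is.na(gval) && gval == 1L && !is.null(ad_lookup)) {
        key <- paste(i, s, sep = ":")
        if (key %in% names(ad_lookup)) ad_lookup[[key]]
        else paste0(ceiling(dp / 2), ",", floor(dp / 2))
      } else if (is.na(gval)) "."
      else if (gval == 0L) paste0(dp, ",0")
      else if (gval == 2L) paste0("0,", dp)
      else paste0(ceiling(dp / 2), ",", floor(dp / 2))
      cells[i] <- paste(gt, dp, gm$gq[i, s], ad, sep = ":")
    }
    body[s] <- paste(c(gm$contig[s], format(gm$positions[s], scientific = FALSE),
                       ".", "A", "C", qual_s, "PASS", info_s,
                       "GT:DP:GQ:AD", cells), collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Every filtering threshold defaults to its standard value (QD 0.25,
#' QUAL 20, SOR 3.0, MQ 30, MQRankSum -12.5, ReadPosRankSum -8.0; DP 8,
#' GQ 20, 50% site missingness; HDplot H 0.6 and |D| 20; 250-bp windows
#' at 10% paralog fraction; 50% SFS missing-data cut). The configuration
#' round-trips losslessly through [write_config]/[read_config].
#'
#' @param mu per-site per-generation mutation rate.
#' @param gen_time_years generation time in years.
#' @param seed integer seed for every stochastic stage.
#' @return Nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(mu = 7.77e-9, gen_time_years = 15,
                                    seed = 1L) {
  structure(list(
    version = 1L,
    seed = as.integer(seed),
    mu = mu,
    gen_time_years = gen_time_years,
    stages = list(qc = TRUE, sfs = TRUE, diversity = TRUE, spatial = TRUE,
                  demography = TRUE, stairway = FALSE, synchrony = FALSE),
    qc = list(qd_min = 0.25, qual_min = 20, sor_max = 3.0, mq_min = 30,
              mqrs_min = -12.5, rprs_min = -8.0, dp_min = 8, gq_min = 20,
              site_missing_max = 0.5, h_max = 0.6, d_abs = 20,
              window = 250, frac = 0.10),
    sfs = list(max_missing = 0.5, target_n = NA, classes = NA),
    diversity = list(n_reps = 1000),
    demography = list(n_starts = 20, bounds = c(10, 1e7), maxit = 400,
                      stairway_n_boot = 50),
    synchrony = list(w = 250, n_perm = 10000, level = 0.95)),
    class = "pipeline_config")
}

#' Write a pipeline configuration
#' @param config a `pipeline_config`.
#' @param path output path (YAML key-value text).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline configuration written by [write_config]
#' @param path input path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$version)) stop("configuration lacks a schema version")
  structure(cfg, class = "pipeline_config")
}
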