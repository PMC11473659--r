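#' Genotype matrix with per-call quality metadata
#'
#' Individuals-by-sites genotype container mirroring a filtered biallelic
#' VCF: genotype codes 0/1/2 (alternate-allele dosage) with `NA` for
#' missing, per-call depth (DP) and genotype quality (GQ), 1-based site
#' positions on a contig, per-site INFO annotations, a site-class label,
#' per-individual population assignment, and the total number of surveyed
#' sites `L_total` (monomorphic positions included) for per-site
#' diversity accounting.
#'
#' @param genotypes integer matrix (individuals x sites), values in
#'   `{0, 1, 2, NA}`.
#' @param dp,gq non-negative integer matrices matching `genotypes`;
#'   defaults mark every call as deeply covered.
#' @param positions strictly increasing 1-based positions within `contig`.
#' @param contig contig name(s), recycled to the number of sites.
#' @param info data frame of per-site INFO scores (columns among QD, QUAL,
#'   SOR, MQ, MQRankSum, ReadPosRankSum); optional.
#' @param site_class per-site label in `{"4fold", "intron", "intergenic",
#'   "0fold", "other"}`.
#' @param pop per-individual population identifier.
#' @param L_total total surveyed sites including monomorphic positions;
#'   defaults to the number of columns.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, dp = NULL, gq = NULL,
                            positions = NULL, contig = "chr1",
                            info = NULL, site_class = NULL, pop = NULL,
                            L_total = NULL) {
  genotypes <- as.matrix(genotypes)
  bad <- !is.na(genotypes) & !(genotypes %in% 0:2)
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  n_ind <- nrow(genotypes)
  n_site <- ncol(genotypes)
  if (is.null(dp)) dp <- matrix(99L, n_ind, n_site)
  if (is.null(gq)) gq <- matrix(99L, n_ind, n_site)
  if (!all(dim(dp) == dim(genotypes)) || !all(dim(gq) == dim(genotypes)))
    stop("'dp' and 'gq' must match the genotype matrix dimensions")
  if (any(dp < 0, na.rm = TRUE) || any(gq < 0, na.rm = TRUE))
    stop("'dp' and 'gq' must be non-negative")
  if (is.null(positions)) positions <- seq_len(n_site)
  contig <- rep_len(as.character(contig), n_site)
  for (ctg in unique(contig)) {
    p <- positions[contig == ctg]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("positions must be strictly increasing within contig ", ctg)
  }
  if (is.null(site_class)) site_class <- rep("other", n_site)
  site_class <- rep_len(site_class, n_site)
  if (is.null(pop)) pop <- rep("pop1", n_ind)
  pop <- rep_len(as.character(pop), n_ind)
  if (is.null(L_total)) L_total <- n_site
  if (L_total < n_site) stop("'L_total' cannot be below the number of sites")
  structure(list(genotypes = genotypes, dp = dp, gq = gq,
                 positions = as.numeric(positions), contig = contig,
                 info = info, site_class = site_class, pop = pop,
                 L_total = as.numeric(L_total)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d SNPs (L_total = %g sites)\n",
              nrow(x$genotypes), ncol(x$genotypes), x$L_total))
  cat("  populations:", paste(sprintf("%s (%d)", names(table(x$pop)),
                                      table(x$pop)), collapse = ", "), "\n")
  cat(sprintf("  missing calls: %.2f%%\n",
              100 * mean(is.na(x$genotypes))))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix].
#' @param individuals,sites index vectors (logical or integer); `NULL`
#'   keeps everything. Monomorphic accounting: `L_total` shrinks by the
#'   number of dropped SNP columns.
#' @param ... unused.
#' @return A [genotype_matrix].
#' @export
subset_gm <- function(x, individuals = NULL, sites = NULL, ...) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(individuals)) individuals <- seq_len(nrow(x$genotypes))
  if (is.null(sites)) sites <- seq_len(ncol(x$genotypes))
  if (is.logical(sites)) sites <- which(sites)
  n_dropped <- ncol(x$genotypes) - length(sites)
  genotype_matrix(
    genotypes = x$genotypes[individuals, sites, drop = FALSE],
    dp = x$dp[individuals, sites, drop = FALSE],
    gq = x$gq[individuals, sites, drop = FALSE],
    positions = x$positions[sites], contig = x$contig[sites],
    info = if (is.null(x$info)) NULL else x$info[sites, , drop = FALSE],
    site_class = x$site_class[sites], pop = x$pop[individuals],
    L_total = x$L_total - n_dropped)
}
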