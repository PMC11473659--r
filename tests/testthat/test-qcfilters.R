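test_that("INFO filter applies the printed thresholds with strict inequalities", {
  info <- data.frame(
    QD = c(0.2, 0.25, 25, 25, 25, 25, 25),
    QUAL = c(900, 20, 19, 900, 900, 900, 900),
    SOR = c(1, 3.0, 1, 3.5, 1, 1, 1),
    MQ = c(60, 30, 60, 60, 29, 60, 60),
    MQRankSum = c(0, -12.5, 0, 0, 0, -13, 0),
    ReadPosRankSum = c(0, -8.0, 0, 0, 0, 0, -8.5))
  keep <- site_info_filter(info)
  # QD = 0.2 excluded; all-at-threshold kept; QUAL 19, SOR 3.5, MQ 29,
  # MQRankSum -13, ReadPosRankSum -8.5 excluded
  expect_identical(keep, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  # missing annotations pass by default, fail when inverted
  info_na <- data.frame(QD = c(NA, 25), QUAL = 900, SOR = 1, MQ = 60,
                        MQRankSum = NA_real_, ReadPosRankSum = 0)
  expect_identical(site_info_filter(info_na), c(TRUE, TRUE))
  expect_identical(site_info_filter(info_na, missing_fails = TRUE),
                   c(FALSE, FALSE))
})

test_that("genotype filter masks DP/GQ failures and drops high-missing sites", {
  g <- matrix(1L, 10, 3)
  dp <- matrix(30L, 10, 3)
  gq <- matrix(99L, 10, 3)
  dp[1, 1] <- 7L            # DP 7 -> missing
  dp[2, 1] <- 8L            # boundary retained
  gq[3, 1] <- 19L           # GQ 19 -> missing
  gq[4, 1] <- 20L           # boundary retained
  dp[1:6, 2] <- 1L          # 6/10 calls masked -> site dropped
  gm <- toy_gm(g, dp = dp, gq = gq)
  out <- genotype_filter(gm)
  expect_identical(attr(out, "dropped_sites"), 2L)
  expect_equal(ncol(out$genotypes), 2)
  expect_true(is.na(out$genotypes[1, 1]))
  expect_false(is.na(out$genotypes[2, 1]))
  expect_true(is.na(out$genotypes[3, 1]))
  expect_false(is.na(out$genotypes[4, 1]))
  # 5/10 missing is exactly 50% and is kept
  g2 <- matrix(1L, 10, 1); dp2 <- matrix(30L, 10, 1)
  dp2[1:5, 1] <- 2L
  out2 <- genotype_filter(toy_gm(g2, dp = dp2, gq = matrix(99L, 10, 1)))
  expect_equal(ncol(out2$genotypes), 1)
})

test_that("HDplot computes H and D as binomial z-scores", {
  # 7 heterozygotes among 10 calls -> H = 0.7
  g <- matrix(c(rep(1L, 7), 0L, 2L, 0L), 10, 1)
  reads <- data.frame(individual = 1:7, site = 1,
                      reads_a = c(20, 20, 10, 10, 10, 10, 10),
                      reads_b = c(10, 10, 2, 2, 2, 2, 2))
  st <- hdplot(toy_gm(g), reads)
  expect_equal(st$h, 0.7)
  A <- 90; B <- 30
  expect_equal(st$d, (A - B) / sqrt(A + B))   # 60/sqrt(120) ~ 5.477
  # A = B -> D = 0
  st2 <- hdplot(toy_gm(matrix(1L, 4, 1)),
                data.frame(individual = 1:4, site = 1,
                           reads_a = c(5, 5, 5, 5), reads_b = c(5, 5, 5, 5)))
  expect_equal(st2$d, 0)
  # site with zero non-missing calls: stats NA, never flagged
  g3 <- matrix(NA_integer_, 4, 1)
  st3 <- hdplot(toy_gm(g3), reads)
  expect_true(is.na(st3$h[1]) && is.na(st3$d[1]))
  expect_identical(flag_paralog_sites(st3), FALSE)
})

test_that("paralog flags use strict H and |D| thresholds", {
  st <- structure(data.frame(site = 1:4,
                             h = c(0.7, 0.5, 0.6, 0.5),
                             d = c(0, 25, 20, -25)),
                  class = c("hdplot_stats", "data.frame"))
  expect_identical(flag_paralog_sites(st), c(TRUE, TRUE, FALSE, TRUE))
})

test_that("windowed paralog filter excludes enriched regions with mid-distance bounds", {
  # 10 SNPs within 250 bp, 2 flagged (20% > 10%) -> all excluded
  pos <- seq(1000, 1225, by = 25)
  flags <- rep(FALSE, 10); flags[c(3, 7)] <- TRUE
  out <- paralog_window_filter(pos, flags)
  expect_setequal(out$excluded, 1:10)
  expect_equal(nrow(out$regions), 1)
  # no flagged SNPs -> nothing
  out0 <- paralog_window_filter(pos, rep(FALSE, 10))
  expect_length(out0$excluded, 0)
  expect_equal(nrow(out0$regions), 0)
  # mid-distance rule: outermost excluded paralog at 1000, next retained
  # SNP at 1100 -> region boundary at their midpoint 1050 (window narrow
  # enough that the retained SNP stays outside every triggering window)
  pos2 <- c(950, 990, 1000, 1100)
  flags2 <- c(TRUE, TRUE, TRUE, FALSE)
  out2 <- paralog_window_filter(pos2, flags2, window = 150)
  expect_equal(out2$regions$end, 1050)
  expect_false(4 %in% out2$excluded)
  # a lone flagged SNP triggers no window and no region
  out3 <- paralog_window_filter(c(100, 5000, 10000),
                                c(FALSE, TRUE, FALSE))
  expect_length(out3$excluded, 0)
  expect_equal(nrow(out3$regions), 0)
})

test_that("exclusion regions are disjoint and contain every excluded SNP", {
  set.seed(7)
  for (rep in 1:5) {
    pos <- sort(sample.int(5000, 120))
    flags <- runif(120) < 0.15
    out <- paralog_window_filter(pos, flags)
    if (nrow(out$regions) > 1) {
      expect_true(all(out$regions$start[-1] >=
                      out$regions$end[-nrow(out$regions)]))
    }
    for (i in out$excluded) {
      inside <- any(pos[i] >= out$regions$start & pos[i] < out$regions$end)
      expect_true(inside)
    }
  }
})

test_that("filters commute with site-order permutation", {
  set.seed(11)
  g <- matrix(sample(c(0L, 1L, 2L), 50, TRUE), 5, 10)
  dp <- matrix(sample(5:40, 50, TRUE), 5, 10)
  gq <- matrix(sample(10:99, 50, TRUE), 5, 10)
  info <- data.frame(QD = runif(10, 0, 1), QUAL = runif(10, 10, 100),
                     SOR = runif(10, 0, 5), MQ = runif(10, 20, 60),
                     MQRankSum = rnorm(10), ReadPosRankSum = rnorm(10))
  keep <- site_info_filter(info)
  perm <- sample(10)
  expect_identical(site_info_filter(info[perm, ]), keep[perm])
  gm <- toy_gm(g, dp = dp, gq = gq)
  masked <- genotype_filter(gm, site_missing_max = 1)$genotypes
  gmp <- toy_gm(g[, perm], dp = dp[, perm], gq = gq[, perm])
  masked_p <- genotype_filter(gmp, site_missing_max = 1)$genotypes
  expect_identical(masked_p, masked[, perm])
})

test_that("paralog injection is recovered by HDplot at default thresholds", {
  dem <- demography(2e4, 0)
  gm <- simulate_genotype_matrix(dem, n_ind = 24, L = 5e5, mu = 1e-8,
                                 loci = 400, seed = 5)
  inj <- inject_paralogs(gm, prop = 0.06, depth = 25, seed = 6)
  st <- hdplot(inj$gm, inj$reads)
  flags <- flag_paralog_sites(st)
  truth <- seq_len(ncol(inj$gm$genotypes)) %in% inj$paralog_sites
  recall <- mean(flags[truth])
  false_rate <- mean(flags[!truth])
  expect_gte(recall, 0.95)
  expect_lte(false_rate, 0.05)
  # injected fixed-heterozygous site has H = 1 > 0.6
  expect_true(all(st$h[inj$paralog_sites] == 1))
  # prop = 0 flags (almost) nothing
  inj0 <- inject_paralogs(gm, prop = 0, depth = 25, seed = 7)
  flags0 <- flag_paralog_sites(hdplot(inj0$gm, inj0$reads))
  expect_lte(mean(flags0), 0.05)
})
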