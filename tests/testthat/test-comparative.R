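test_that("pooled SD matches hand computation and is label-symmetric", {
  lab <- class_labels(c(1, 1, 2, 2))
  m <- matrix(c(0, 2, 1, 3), 4, 1)      # group1 {0,2}, group2 {1,3}
  expect_equal(pooled_sd(m, lab), sqrt(2))

  # internally constant groups have zero pooled SD
  mc <- rbind(c(1, 5), c(1, 5), c(7, 2), c(7, 2))
  expect_equal(pooled_sd(mc, lab), c(0, 0))

  set.seed(8)
  mm <- matrix(rnorm(4 * 10), 4, 10)
  swapped <- class_labels(c(2, 2, 1, 1))
  expect_equal(pooled_sd(mm, lab), pooled_sd(mm, swapped))

  expect_error(class_labels(c(1, 2, 2)), ">= 2 samples")
})

test_that("regularization factor is the 95th percentile of pooled SD", {
  # constant-within-group profiles give f = 0
  lab <- class_labels(c(1, 1, 2, 2))
  mc <- rbind(c(1, 5), c(1, 5), c(7, 2), c(7, 2))
  expect_equal(regularization_factor(mc, lab), 0)

  # explicit vector 1..100 under type-7 interpolation
  expect_equal(unname(quantile(1:100, 0.95, type = 7)), 95.05)
  # build profiles whose pooled SD is exactly 1..100: group1 rows
  # {-a, a} have unbiased variance 2a^2, group2 rows are constant, so the
  # pooled variance is (2a^2 + 0) / 2 = a^2
  a <- 1:100
  prof <- rbind(-a, a, rep(0, 100), rep(0, 100))
  expect_equal(pooled_sd(prof, lab), as.numeric(1:100))
  expect_equal(regularization_factor(prof, lab), 95.05)

  # quantiles ignore the order of grid points
  sh <- sample(100)
  expect_equal(regularization_factor(prof[, sh], lab), 95.05)
})

test_that("SNR statistic follows its defining identity", {
  lab <- class_labels(c(1, 1, 2, 2))
  # equal group means give SNR 0
  m_eq <- rbind(c(0, 1), c(2, 3), c(0, 1), c(2, 3))
  expect_equal(snr_statistic(m_eq, lab, 0.5), c(0, 0))

  # constant 1-vs-0 groups with f = 0.5: SNR = 1 / 0.5 = 2 everywhere
  m10 <- rbind(rep(1, 5), rep(1, 5), rep(0, 5), rep(0, 5))
  expect_equal(snr_statistic(m10, lab, 0.5), rep(2, 5))

  # label swap negates the statistic exactly
  set.seed(19)
  mm <- matrix(rnorm(6 * 20), 6, 20)
  lab6 <- class_labels(c(1, 1, 1, 2, 2, 2))
  swp <- class_labels(c(2, 2, 2, 1, 1, 1))
  f <- regularization_factor(mm, lab6)
  expect_equal(snr_statistic(mm, swp, f), -snr_statistic(mm, lab6, f))

  expect_error(snr_statistic(m10, lab, 0), "zero SNR denominator")
})

test_that("SNR is invariant to common shifts and positive scalings", {
  set.seed(23)
  mm <- matrix(rnorm(8 * 30), 8, 30)
  lab <- class_labels(rep(1:2, each = 4))
  f <- regularization_factor(mm, lab)
  base <- snr_statistic(mm, lab, f)

  shifted <- mm + 3.7
  expect_equal(snr_statistic(shifted, lab,
                             regularization_factor(shifted, lab)),
               base, tolerance = 1e-12)
  scaled <- mm * 4.2
  expect_equal(snr_statistic(scaled, lab,
                             regularization_factor(scaled, lab)),
               base, tolerance = 1e-12)
})

test_that("FDR threshold is seed-stable and matches an independent oracle", {
  set.seed(71)
  prof <- matrix(rnorm(6 * 50), 6, 50)
  prof[1:3, 10:14] <- prof[1:3, 10:14] + 2      # a class-1 bump
  lab <- class_labels(rep(1:2, each = 3))
  a <- snr_fdr_threshold(prof, lab, fdr_target = 0.2, n_perms = 20,
                         seed = 77)
  b <- snr_fdr_threshold(prof, lab, fdr_target = 0.2, n_perms = 20,
                         seed = 77)
  expect_identical(a$thr, b$thr)
  expect_identical(a$snr, b$snr)

  want <- oracle_snr_threshold(prof, lab, fdr_target = 0.2, n_perms = 20,
                               seed = 77)
  expect_equal(a$thr, want, tolerance = 1e-12)

  # a target met already at the smallest |SNR| calls every point
  c_all <- snr_fdr_threshold(prof, lab, fdr_target = 0.999, n_perms = 20,
                             seed = 77)
  expect_true(all(abs(c_all$snr) >= c_all$thr))

  # degenerate (all profiles identical): no calls, no error
  flat <- matrix(1, 6, 50)
  d <- snr_fdr_threshold(flat, lab, fdr_target = 0.05, n_perms = 20,
                         seed = 1)
  expect_identical(d$thr, Inf)
})

test_that("differential region calling separates directions", {
  lay <- genome_layout("chrX", 5e5)
  grid <- build_sample_points(lay, 1e5)
  snr <- c(0, 3, 3, -3, 0)
  rs <- call_differential_regions(snr, 2, grid)
  expect_equal(nrow(rs), 2L)
  up <- rs[rs$channel == "diff_up", ]
  dn <- rs[rs$channel == "diff_down", ]
  expect_equal(up$n_points, 2L)
  expect_equal(dn$n_points, 1L)
  expect_equal(up$score, 3)
  expect_equal(dn$score, 3)

  expect_equal(nrow(call_differential_regions(snr, Inf, grid)), 0L)

  # channels can never overlap on a point
  set.seed(4)
  snr2 <- rnorm(5, sd = 3)
  rs2 <- call_differential_regions(snr2, 1, grid)
  if (nrow(rs2) > 1) {
    for (i in seq_len(length(grid$x))) {
      hits <- rs2$chrom == grid$chrom[i] & rs2$start_bp <= grid$x[i] &
        rs2$end_bp >= grid$x[i]
      expect_lte(length(unique(rs2$channel[hits])), 2L)
      expect_lte(sum(hits), 1L)
    }
  }
})

test_that("full comparative run stores a self-consistent result", {
  lay <- tiny_layout()
  sim <- generate_dataset(lay, 60, n1 = 4, n2 = 4, specs = list(
    aberration_spec("chr1", 5e5, 1e6, effect = -1, target = "class1")),
    noise_sd = 0.2, seed = 6)
  grid <- build_sample_points(lay, 1e5)
  res <- kc_compare(sim$pm, sim$labels, grid, kernel_spec(2e5),
                    fdr = 0.1, n_perms = 30, seed = 2)
  expect_equal(res$snr,
               (res$mu1 - res$mu2) / (res$pooled_sd + res$f),
               tolerance = 1e-14)
  # antisymmetry of the whole pipeline under label exchange
  swapped <- class_labels(ifelse(as.integer(sim$labels) == 1L, 2L, 1L),
                          names(sim$labels))
  res2 <- kc_compare(sim$pm, swapped, grid, kernel_spec(2e5),
                     fdr = 0.1, n_perms = 30, seed = 2)
  expect_equal(res2$snr, -res$snr, tolerance = 1e-12)
  expect_identical(res2$thr, res$thr)
  up1 <- res$regions[res$regions$channel == "diff_up", 1:3]
  dn2 <- res2$regions[res2$regions$channel == "diff_down", 1:3]
  rownames(up1) <- rownames(dn2) <- NULL
  expect_equal(up1, dn2)
})
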