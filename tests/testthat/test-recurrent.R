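make_pm <- function(seed = 1, n = 40, n_samp = 3, lay = tiny_layout()) {
  set.seed(seed)
  chrom <- c(rep("chr1", ceiling(n * 2 / 3)), rep("chr2", floor(n / 3)))
  pos <- c(sort(sample.int(2e6, ceiling(n * 2 / 3))),
           sort(sample.int(1e6, floor(n / 3))))
  probe_matrix(chrom, pos, matrix(rnorm(length(chrom) * n_samp),
                                  ncol = n_samp), lay)
}

test_that("summed profiles split the sample-summed signal by channel", {
  lay <- tiny_layout()
  grid <- build_sample_points(lay, 1e5)
  set.seed(3)
  pos <- sort(sample.int(2e6, 30))
  pm_pos <- probe_matrix(rep("chr1", 30), pos,
                         matrix(0.5, 30, 1), lay)
  res <- summed_kc(pm_pos, grid, kernel_spec(5e5))
  cov <- res$gain$weight_mass >= 1e-8
  expect_equal(res$gain$values[cov], rep(0.5, sum(cov)), tolerance = 1e-12)
  expect_true(all(res$loss$values == 0))

  # +1 and -1 samples cancel in the sum
  pm_cancel <- probe_matrix(rep("chr1", 30), pos,
                            cbind(rep(1, 30), rep(-1, 30)), lay)
  res0 <- summed_kc(pm_cancel, grid, kernel_spec(5e5))
  expect_true(all(res0$gain$values == 0) && all(res0$loss$values == 0))

  # random matrix matches the oracle on the split row-sums
  pm <- make_pm(9, n = 30, n_samp = 3)
  res3 <- suppressWarnings(summed_kc(pm, grid, kernel_spec(4e5)))
  s <- rowSums(pm$ratios)
  expect_equal(res3$gain$values,
               naive_kc(pm$chrom, pm$pos, pmax(s, 0), grid, 4e5),
               tolerance = 1e-10)
  expect_equal(res3$loss$values,
               naive_kc(pm$chrom, pm$pos, pmax(-s, 0), grid, 4e5),
               tolerance = 1e-10)
})

test_that("permutation thresholds are reproducible and match a seeded oracle", {
  pm <- make_pm(17, n = 20, n_samp = 2)
  grid <- build_sample_points(pm$layout, 2e5)
  k <- kernel_spec(4e5)
  thr <- permutation_threshold(pm, grid, k, n_perms = 10, alpha = 0.2,
                               seed = 99)
  thr2 <- permutation_threshold(pm, grid, k, n_perms = 10, alpha = 0.2,
                                seed = 99)
  expect_identical(thr$thr_gain, thr2$thr_gain)
  expect_identical(thr$null$gain$per_perm_max, thr2$null$gain$per_perm_max)

  want <- oracle_perm_threshold(pm, grid, 4e5, n_perms = 10, alpha = 0.2,
                                seed = 99)
  expect_equal(thr$thr_gain, want[["gain"]], tolerance = 1e-10)
  expect_equal(thr$thr_loss, want[["loss"]], tolerance = 1e-10)

  # all-zero data: every permutation max is 0, so the threshold is 0
  pm0 <- probe_matrix(pm$chrom, pm$pos, matrix(0, n_probes(pm), 2),
                      pm$layout)
  thr0 <- permutation_threshold(pm0, grid, k, n_perms = 5, alpha = 0.5,
                                seed = 1)
  expect_equal(thr0$thr_gain, 0)
  expect_equal(thr0$thr_loss, 0)

  expect_error(permutation_threshold(pm, grid, k, n_perms = 10,
                                     alpha = 0.05, seed = 1),
               "at least 40 permutations")
})

test_that("thresholds respond monotonically to alpha and scale with the data", {
  pm <- make_pm(31, n = 30, n_samp = 3)
  grid <- build_sample_points(pm$layout, 2e5)
  k <- kernel_spec(4e5)
  t10 <- suppressWarnings(
    permutation_threshold(pm, grid, k, n_perms = 20, alpha = 0.10,
                          seed = 5))
  t50 <- suppressWarnings(
    permutation_threshold(pm, grid, k, n_perms = 20, alpha = 0.50,
                          seed = 5))
  expect_true(t50$thr_gain <= t10$thr_gain)
  expect_true(t50$thr_loss <= t10$thr_loss)

  # doubling every ratio doubles profiles and thresholds (equivariance)
  pm2 <- probe_matrix(pm$chrom, pm$pos, 2 * pm$ratios, pm$layout)
  a <- suppressWarnings(
    kc_recurrent(pm, grid, k, n_perms = 20, alpha = 0.1, seed = 5))
  b <- suppressWarnings(
    kc_recurrent(pm2, grid, k, n_perms = 20, alpha = 0.1, seed = 5))
  expect_equal(b$gain$values, 2 * a$gain$values, tolerance = 1e-12)
  expect_equal(b$thr_gain, 2 * a$thr_gain, tolerance = 1e-12)
  expect_equal(b$thr_loss, 2 * a$thr_loss, tolerance = 1e-12)
})

test_that("region calling merges threshold exceedances run by run", {
  lay <- genome_layout("chrX", 6e5)
  grid <- build_sample_points(lay, 1e5)
  expect_equal(length(grid$x), 6L)
  prof <- list(grid = grid, values = c(0, 3, 3, 0, 4, 0), channel = "gain")

  rs <- call_regions(prof, 2)
  expect_equal(nrow(rs), 2L)
  expect_equal(rs$n_points, c(2L, 1L))
  expect_equal(rs$score, c(3, 4))
  expect_equal(rs$start_bp, c(1e5, 4e5))
  expect_equal(rs$end_bp, c(3e5, 5e5))

  expect_equal(nrow(call_regions(prof, 10)), 0L)

  # all points above threshold: one region per chromosome, clipped to it
  lay2 <- tiny_layout()
  g2 <- build_sample_points(lay2, 5e5)
  all_hi <- list(grid = g2, values = rep(9, length(g2$x)),
                 channel = "loss")
  rs2 <- call_regions(all_hi, 1)
  expect_equal(nrow(rs2), 2L)
  expect_equal(rs2$start_bp, c(1, 1))
  expect_equal(rs2$end_bp, lay2$length)

  # regions partition the exceedance set exactly
  set.seed(12)
  vals <- rnorm(length(g2$x))
  prof3 <- list(grid = g2, values = vals, channel = "gain")
  rs3 <- call_regions(prof3, 0.3)
  in_region <- rep(FALSE, length(g2$x))
  for (r in seq_len(nrow(rs3))) {
    sel <- g2$chrom == rs3$chrom[r] & g2$x >= rs3$start_bp[r] &
      g2$x <= rs3$end_bp[r]
    in_region <- in_region | sel
  }
  expect_identical(in_region, vals > 0.3)
})

test_that("scale space reduces to a standalone run and bounds its levels", {
  pm <- make_pm(41, n = 40, n_samp = 4)
  ss <- suppressWarnings(
    scale_space(pm, 2e5, c(3e5, 6e5), n_perms = 25, alpha = 0.2,
                seed = 13))
  solo <- suppressWarnings(
    kc_recurrent(pm, build_sample_points(pm$layout, 2e5),
                 kernel_spec(3e5), n_perms = 25, alpha = 0.2,
                 seed = 13))
  expect_equal(ss$results[[1]]$thr_gain, solo$thr_gain)
  expect_equal(ss$results[[1]]$gain$values, solo$gain$values)
  expect_equal(ss$results[[1]]$regions, solo$regions)

  expect_true(all(ss$sig_gain >= 0) && all(ss$sig_loss >= 0))
  expect_true(max(ss$sig_gain, ss$sig_loss) <= log10(25) + 1e-12)
  # nonzero significance only where the profile exceeds the threshold
  for (k in 1:2) {
    res <- ss$results[[k]]
    expect_identical(ss$sig_gain[k, ] > 0,
                     unname(res$gain$values > res$thr_gain))
  }
  expect_error(scale_space(pm, 2e5, c(6e5, 3e5), n_perms = 25, seed = 1),
               "strictly increasing")
})
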