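#' Summed-signal KC profiles for gains and losses
#'
#' The recurrent mode first sums the per-probe log2 ratios across all
#' samples, splits the summed signal into its gain (positive part) and
#' loss (negated negative part) channels, and smooths each channel
#' separately by kernel convolution.
#'
#' @param pm A \code{\link{probe_matrix}}.
#' @param grid A \code{sample_grid}.
#' @param kernel A \code{\link{kernel_spec}}.
#' @param wts Optional precomputed \code{\link{kc_weights}}.
#' @return List with \code{gain} and \code{loss} \code{kc_profile}s.
#' @export
summed_kc <- function(pm, grid, kernel, wts = NULL) {
  stopifnot(inherits(pm, "probe_matrix"))
  if (is.null(wts)) wts <- kc_weights(pm$chrom, pm$pos, grid, kernel)
  s <- rowSums(pm$ratios)
  gl <- split_gain_loss(s)
  list(gain = kc_convolve(pm$chrom, pm$pos, gl$gain, grid, kernel,
                          channel = "gain", wts = wts),
       loss = kc_convolve(pm$chrom, pm$pos, gl$loss, grid, kernel,
                          channel = "loss", wts = wts))
}

# deterministic per-permutation seed streams from one master seed, so runs
# are reproducible and extending n_perms keeps the first permutations fixed
perm_seeds <- function(seed, n_perms) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n_perms)
}

#' Permutation-based significance thresholds for recurrent gains and losses
#'
#' The null model destroys positional clustering while preserving the
#' marginal intensity distribution: for each permutation the per-probe
#' summed signal is shuffled across all probe positions genome-wide
#' (positions fixed, values permuted), re-split into gain/loss channels,
#' re-smoothed, and the genome-wide maximum KC score per channel recorded.
#' The gain and loss channels form one testing family: each channel's
#' threshold is the empirical (1 - alpha/2) quantile (type 7) of its own
#' null maxima, so the probability that any sample point in either channel
#' exceeds its threshold under the null is approximately alpha. The
#' half-level split keeps the thresholds channel-specific (the two null
#' maxima distributions differ when the data are asymmetric) while
#' controlling the family-wise error of the complete analysis.
#'
#' @param pm A \code{\link{probe_matrix}}.
#' @param grid A \code{sample_grid}.
#' @param kernel A \code{\link{kernel_spec}}.
#' @param n_perms Number of permutations (must be at least 2/alpha so the
#'   per-channel quantile is interpolable).
#' @param alpha Family-wise significance level (default 0.05).
#' @param seed Master RNG seed; all permutation streams derive from it.
#' @param wts Optional precomputed \code{\link{kc_weights}}.
#' @return List with \code{thr_gain}, \code{thr_loss} and \code{null}
#'   (list of two \code{perm_null} objects holding the per-permutation
#'   maxima).
#' @export
permutation_threshold <- function(pm, grid, kernel, n_perms = 1000,
                                  alpha = 0.05, seed = 1L, wts = NULL) {
  stopifnot(inherits(pm, "probe_matrix"))
  if (n_perms < 1L) stop("'n_perms' must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (alpha / 2 < 1 / n_perms)
    stop("alpha = ", alpha, " needs at least ", ceiling(2 / alpha),
         " permutations (got ", n_perms, ")")
  if (is.null(wts)) wts <- kc_weights(pm$chrom, pm$pos, grid, kernel)
  s <- rowSums(pm$ratios)
  seeds <- perm_seeds(seed, n_perms)
  max_gain <- numeric(n_perms)
  max_loss <- numeric(n_perms)
  for (p in seq_len(n_perms)) {
    set.seed(seeds[p])
    sp <- s[sample.int(length(s))]
    gl <- split_gain_loss(sp)
    max_gain[p] <- max(kc_apply(wts, gl$gain))
    max_loss[p] <- max(kc_apply(wts, gl$loss))
  }
  thr_gain <- unname(stats::quantile(max_gain, 1 - alpha / 2, type = 7))
  thr_loss <- unname(stats::quantile(max_loss, 1 - alpha / 2, type = 7))
  null <- list(
    gain = structure(list(n_perms = n_perms, seed = seed,
                          per_perm_max = max_gain), class = "perm_null"),
    loss = structure(list(n_perms = n_perms, seed = seed,
                          per_perm_max = max_loss), class = "perm_null"))
  list(thr_gain = thr_gain, thr_loss = thr_loss, null = null)
}

#' Call significant regions from a KC profile
#'
#' Maximal runs of consecutive grid points on one chromosome whose score
#' exceeds the threshold become regions. Region boundaries are the first
#' and last point of the run extended by half the grid spacing on each
#' side, clipped to the chromosome.
#'
#' @param profile A \code{kc_profile} (or any list with \code{grid} and
#'   \code{values}).
#' @param threshold Scalar threshold; points with value strictly greater
#'   are significant.
#' @param channel Channel recorded on the resulting regions; defaults to
#'   the profile's channel.
#' @return A \code{\link{region_set}} (possibly empty).
#' @export
call_regions <- function(profile, threshold, channel = NULL) {
  grid <- profile$grid
  values <- profile$values
  if (is.null(channel)) channel <- profile$channel
  if (identical(channel, "signed")) stop("call_regions needs a directional channel")
  exceed <- is.finite(threshold) & (values > threshold)
  if (!any(exceed)) return(region_set(layout = grid$layout))
  ci <- match(grid$chrom, unique(grid$chrom))
  # run starts where exceedance begins or the chromosome changes
  run_start <- exceed & (c(TRUE, !exceed[-length(exceed)]) |
                           c(TRUE, diff(ci) != 0))
  run_id <- cumsum(run_start)
  run_id[!exceed] <- 0L
  idx <- which(exceed)
  half <- grid$spacing / 2
  layout <- grid$layout
  starts <- tapply(idx, run_id[idx], min)
  ends <- tapply(idx, run_id[idx], max)
  starts <- as.integer(starts); ends <- as.integer(ends)
  chrom <- grid$chrom[starts]
  clen <- layout$length[chrom_index(chrom, layout)]
  start_bp <- pmax(grid$x[starts] - half, 1)
  end_bp <- pmin(grid$x[ends] + half, clen)
  peak <- vapply(seq_along(starts), function(k)
    max(values[starts[k]:ends[k]]), numeric(1))
  npts <- ends - starts + 1L
  region_set(chrom, start_bp, end_bp, rep(channel, length(starts)),
             peak, npts, layout = layout)
}

#' Recurrent copy-number aberration analysis
#'
#' Runs the full unsupervised pipeline at one kernel width: summed-signal
#' KC profiles per channel, permutation thresholds, and region calling.
#'
#' @inheritParams permutation_threshold
#' @return A \code{kc_recurrent} object: \code{gain} and \code{loss}
#'   profiles, \code{thr_gain} / \code{thr_loss}, \code{alpha},
#'   \code{regions} (combined \code{\link{region_set}}), and \code{null}.
#' @export
kc_recurrent <- function(pm, grid, kernel, n_perms = 1000, alpha = 0.05,
                         seed = 1L) {
  wts <- kc_weights(pm$chrom, pm$pos, grid, kernel)
  prof <- summed_kc(pm, grid, kernel, wts = wts)
  thr <- permutation_threshold(pm, grid, kernel, n_perms = n_perms,
                               alpha = alpha, seed = seed, wts = wts)
  reg_gain <- call_regions(prof$gain, thr$thr_gain)
  reg_loss <- call_regions(prof$loss, thr$thr_loss)
  regions <- rbind(reg_gain, reg_loss)
  regions <- region_set(regions$chrom, regions$start_bp, regions$end_bp,
                        regions$channel, regions$score, regions$n_points,
                        layout = grid$layout)
  structure(list(gain = prof$gain, loss = prof$loss,
                 thr_gain = thr$thr_gain, thr_loss = thr$thr_loss,
                 alpha = alpha, regions = regions, null = thr$null,
                 grid = grid, kernel = kernel),
            class = "kc_recurrent")
}

#' @export
print.kc_recurrent <- function(x, ...) {
  cat("Recurrent CNA analysis: kernel width",
      format(x$kernel$width, big.mark = ","), "bp, alpha", x$alpha, "\n")
  cat("  thresholds: gain", signif(x$thr_gain, 4), "/ loss",
      signif(x$thr_loss, 4), "\n")
  cat("  significant regions:", nrow(x$regions), "\n")
  invisible(x)
}

# -log10 empirical p of a score under the null-max distribution,
# bounded by log10(n_perms) through the max(1, .) count
sig_level <- function(score, null_max) {
  n <- length(null_max)
  p <- pmax(1, vapply(score, function(s) sum(null_max >= s), numeric(1))) / n
  -log10(p)
}

#' Multi-scale (scale-space) recurrent analysis
#'
#' Repeats the recurrent analysis over an increasing series of kernel
#' widths. Large widths reveal broad, low-amplitude (sub-chromosomal)
#' aberrations; small widths resolve focal events. For each width and
#' sample point, a significance level is recorded: -log10 of the empirical
#' p-value of the point's KC score under that width's null-max
#' distribution, for points inside significant regions, and 0 elsewhere.
#'
#' @param pm A \code{\link{probe_matrix}}.
#' @param spacing Grid spacing in bp (shared by all widths).
#' @param kernel_widths Strictly increasing vector of kernel widths (bp).
#' @param n_perms,alpha,seed As \code{\link{permutation_threshold}}; the
#'   same master seed is used at every width.
#' @return A \code{kc_scale_space} object: \code{kernel_widths},
#'   \code{grid}, per-width \code{results} (list of \code{kc_recurrent}),
#'   and \code{sig_gain} / \code{sig_loss} matrices
#'   (n_widths x n_points significance levels).
#' @export
scale_space <- function(pm, spacing, kernel_widths, n_perms = 1000,
                        alpha = 0.05, seed = 1L) {
  kernel_widths <- as.numeric(kernel_widths)
  if (length(kernel_widths) < 1L || is.unsorted(kernel_widths, strictly = TRUE))
    stop("'kernel_widths' must be strictly increasing")
  grid <- build_sample_points(pm$layout, spacing)
  results <- vector("list", length(kernel_widths))
  m <- length(kernel_widths)
  sig_gain <- matrix(0, m, length(grid$x))
  sig_loss <- matrix(0, m, length(grid$x))
  for (k in seq_len(m)) {
    res <- kc_recurrent(pm, grid, kernel_spec(kernel_widths[k]),
                        n_perms = n_perms, alpha = alpha, seed = seed)
    results[[k]] <- res
    in_gain <- res$gain$values > res$thr_gain
    in_loss <- res$loss$values > res$thr_loss
    if (any(in_gain))
      sig_gain[k, in_gain] <- sig_level(res$gain$values[in_gain],
                                        res$null$gain$per_perm_max)
    if (any(in_loss))
      sig_loss[k, in_loss] <- sig_level(res$loss$values[in_loss],
                                        res$null$loss$per_perm_max)
  }
  structure(list(kernel_widths = kernel_widths, grid = grid,
                 results = results, sig_gain = sig_gain,
                 sig_loss = sig_loss),
            class = "kc_scale_space")
}

#' @export
print.kc_scale_space <- function(x, ...) {
  cat("Scale-space analysis over", length(x$kernel_widths), "kernel widths (",
      paste(format(x$kernel_widths, big.mark = ","), collapse = ", "),
      "bp )\n")
  invisible(x)
}
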