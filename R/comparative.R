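#' Two-class sample labels
#'
#' @param labels Vector of class labels (coerced to the two values 1 and
#'   2 in order of appearance, unless already 1/2).
#' @param sample_ids Optional sample identifiers (names the labels).
#' @return A \code{class_labels} object: integer vector in \{1, 2\} with
#'   attributes \code{n1}, \code{n2}.
#' @export
class_labels <- function(labels, sample_ids = NULL) {
  u <- unique(labels)
  if (length(u) != 2L)
    stop("exactly two classes required, found ", length(u))
  lab <- if (all(sort(as.character(u)) == c("1", "2")))
    as.integer(as.character(labels)) else match(labels, u)
  n1 <- sum(lab == 1L); n2 <- sum(lab == 2L)
  if (n1 < 2L || n2 < 2L)
    stop("each class needs >= 2 samples (pooled variance requires >= 1 ",
         "degree of freedom per class); got ", n1, " and ", n2)
  if (!is.null(sample_ids)) names(lab) <- sample_ids
  structure(lab, n1 = n1, n2 = n2, class = "class_labels")
}

#' Read a two-class label file (sample_id <TAB> label)
#'
#' @param path Tab-delimited file, optional header.
#' @param sample_ids Sample ids the labels must cover (order taken from
#'   here); unmatched ids are an error.
#' @return A \code{\link{class_labels}} ordered like \code{sample_ids}.
#' @export
read_class_labels <- function(path, sample_ids) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", colClasses = "character")
  if (tolower(tab[[1]][1]) %in% c("sample", "sample_id", "id"))
    tab <- tab[-1, , drop = FALSE]
  idx <- match(sample_ids, tab[[1]])
  if (anyNA(idx))
    stop("label file is missing sample(s): ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  class_labels(tab[[2]][idx], sample_ids)
}

group_rows <- function(labels) list(g1 = which(labels == 1L),
                                    g2 = which(labels == 2L))

col_var <- function(x) {
  # unbiased per-column variance of a matrix with >= 2 rows
  n <- nrow(x)
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

#' Pooled two-group standard deviation per sample point
#'
#' At each point i:
#' sqrt(((n1 - 1) var1(i) + (n2 - 1) var2(i)) / (n1 + n2 - 2)),
#' with unbiased within-group variances.
#'
#' @param profiles n_samples x n_points matrix of per-sample KC scores
#'   (rows = samples).
#' @param labels A \code{\link{class_labels}} covering the rows.
#' @return Non-negative vector of length n_points.
#' @export
pooled_sd <- function(profiles, labels) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) != length(labels))
    stop("profiles must have one row per labelled sample")
  g <- group_rows(labels)
  n1 <- length(g$g1); n2 <- length(g$g2)
  if (n1 < 2L || n2 < 2L) stop("each class needs >= 2 samples")
  v1 <- col_var(profiles[g$g1, , drop = FALSE])
  v2 <- col_var(profiles[g$g2, , drop = FALSE])
  pv <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  sqrt(pmax(pv, 0))
}

#' Regularization factor f for the SNR statistic
#'
#' The 95th percentile (type-7 empirical quantile) of the pooled class
#' standard deviation across all sample points. Added to the SNR
#' denominator, it prevents points with very small variance from
#' dominating the statistic.
#'
#' @inheritParams pooled_sd
#' @return Scalar f >= 0.
#' @export
regularization_factor <- function(profiles, labels) {
  unname(stats::quantile(pooled_sd(profiles, labels), 0.95, type = 7))
}

#' Regularized signal-to-noise ratio per sample point
#'
#' SNR(i) = (mu1(i) - mu2(i)) / (pooled_sd(i) + f), where mu1 and mu2 are
#' the within-class means of the per-sample KC scores at point i.
#'
#' @inheritParams pooled_sd
#' @param f Non-negative regularization scalar (see
#'   \code{\link{regularization_factor}}).
#' @return Numeric vector of length n_points.
#' @export
snr_statistic <- function(profiles, labels, f) {
  profiles <- as.matrix(profiles)
  if (length(f) != 1L || !is.finite(f) || f < 0)
    stop("'f' must be a single non-negative number")
  g <- group_rows(labels)
  mu1 <- colMeans(profiles[g$g1, , drop = FALSE])
  mu2 <- colMeans(profiles[g$g2, , drop = FALSE])
  den <- pooled_sd(profiles, labels) + f
  if (any(den == 0))
    stop("zero SNR denominator at ", sum(den == 0), " point(s); ",
         "use a nonzero regularization factor f")
  (mu1 - mu2) / den
}

# count, for each threshold t in `thr` (ascending), how many values of
# `x` satisfy |x| >= t
count_ge <- function(abs_x_sorted, thr) {
  length(abs_x_sorted) - findInterval(thr, abs_x_sorted, left.open = TRUE)
}

#' Class-label permutation FDR threshold for the SNR statistic
#'
#' Estimates, for every candidate threshold t (the observed |SNR| values),
#' the false discovery rate as the mean over label permutations of the
#' number of null points with |SNR| >= t, divided by the number of
#' observed points with |SNR| >= t (clipped to [0, 1]). The reported
#' threshold is the smallest observed |SNR| whose estimated FDR is at or
#' below the target; +Inf (zero calls) if none qualifies. The
#' regularization factor f is recomputed for every permutation so the
#' permuted statistic is exchangeable with the observed one.
#'
#' @inheritParams pooled_sd
#' @param fdr_target Target false discovery rate in (0, 1).
#' @param n_perms Number of label permutations (>= 20).
#' @param seed Master RNG seed.
#' @return List: \code{thr}, \code{snr} (observed), \code{f},
#'   \code{fdr_hat} (per candidate, aligned with \code{candidates}),
#'   \code{candidates}, \code{null_exceedance} (per-permutation counts at
#'   \code{thr}), \code{n_perms}, \code{seed}.
#' @export
snr_fdr_threshold <- function(profiles, labels, fdr_target = 0.05,
                              n_perms = 500, seed = 1L) {
  profiles <- as.matrix(profiles)
  if (fdr_target <= 0 || fdr_target >= 1)
    stop("'fdr_target' must be in (0, 1)")
  if (n_perms < 20L) stop("'n_perms' must be >= 20")
  f_obs <- regularization_factor(profiles, labels)
  den <- pooled_sd(profiles, labels) + f_obs
  if (any(den == 0)) {
    # fully degenerate points (zero spread and zero f): a zero group-mean
    # difference there is an uninformative 0/0 -- report no calls rather
    # than erroring, as the permutation space carries no signal either
    g <- group_rows(labels)
    num <- colMeans(profiles[g$g1, , drop = FALSE]) -
      colMeans(profiles[g$g2, , drop = FALSE])
    if (any(num[den == 0] != 0))
      stop("zero SNR denominator with nonzero group difference; ",
           "use a nonzero regularization factor f")
    snr_obs <- ifelse(den == 0, 0, num / den)
    return(list(thr = Inf, snr = snr_obs, f = f_obs,
                fdr_hat = rep(1, length(unique(abs(snr_obs)))),
                candidates = sort(unique(abs(snr_obs))),
                null_exceedance = rep(0L, n_perms),
                n_perms = n_perms, seed = seed))
  }
  snr_obs <- snr_statistic(profiles, labels, f_obs)
  cand <- sort(unique(abs(snr_obs)))
  obs_sorted <- sort(abs(snr_obs))
  obs_count <- count_ge(obs_sorted, cand)

  lab <- as.integer(labels)
  seeds <- perm_seeds(seed, n_perms)
  null_counts <- matrix(0, n_perms, length(cand))
  for (p in seq_len(n_perms)) {
    set.seed(seeds[p])
    perm_lab <- lab[sample.int(length(lab))]
    pl <- structure(perm_lab, class = "class_labels")
    fp <- regularization_factor(profiles, pl)
    snr_p <- snr_statistic(profiles, pl, fp)
    null_counts[p, ] <- count_ge(sort(abs(snr_p)), cand)
  }
  fdr_hat <- pmin(colMeans(null_counts) / obs_count, 1)
  ok <- which(fdr_hat <= fdr_target)
  thr <- if (length(ok)) cand[min(ok)] else Inf
  null_exceedance <- if (is.finite(thr))
    null_counts[, min(ok)] else rep(0L, n_perms)
  list(thr = thr, snr = snr_obs, f = f_obs, fdr_hat = fdr_hat,
       candidates = cand, null_exceedance = null_exceedance,
       n_perms = n_perms, seed = seed)
}

#' Call differential regions from an SNR profile
#'
#' Runs of consecutive points with SNR > thr become \code{diff_up}
#' regions (class 1 above class 2); runs with SNR < -thr become
#' \code{diff_down}. Merging and boundary conventions match
#' \code{\link{call_regions}}.
#'
#' @param snr Per-point SNR vector.
#' @param thr Non-negative threshold on |SNR| (may be Inf).
#' @param grid The \code{sample_grid} the SNR was computed on.
#' @return A \code{\link{region_set}}.
#' @export
call_differential_regions <- function(snr, thr, grid) {
  up <- call_regions(list(grid = grid, values = snr, channel = "diff_up"),
                     thr)
  dn <- call_regions(list(grid = grid, values = -snr, channel = "diff_down"),
                     thr)
  both <- rbind(up, dn)
  region_set(both$chrom, both$start_bp, both$end_bp, both$channel,
             both$score, both$n_points, layout = grid$layout)
}

#' Two-class comparative copy-number analysis
#'
#' Full supervised pipeline: per-sample KC smoothing of the signed log2
#' ratios, regularized SNR statistic per sample point, class-label
#' permutation FDR threshold, and differential region calling.
#'
#' @param pm A \code{\link{probe_matrix}}.
#' @param labels A \code{\link{class_labels}} (or raw two-class vector)
#'   over the samples of \code{pm}.
#' @param grid A \code{sample_grid}.
#' @param kernel A \code{\link{kernel_spec}}.
#' @param fdr Target false discovery rate.
#' @param n_perms Number of label permutations.
#' @param seed Master RNG seed.
#' @return A \code{kc_comparative} object: \code{grid}, \code{mu1},
#'   \code{mu2}, \code{pooled_sd}, \code{f}, \code{snr}, \code{fdr},
#'   \code{thr}, \code{regions}, \code{null_exceedance}, \code{profiles}.
#' @export
kc_compare <- function(pm, labels, grid, kernel, fdr = 0.05,
                       n_perms = 500, seed = 1L) {
  stopifnot(inherits(pm, "probe_matrix"))
  if (!inherits(labels, "class_labels"))
    labels <- class_labels(labels, colnames(pm$ratios))
  if (length(labels) != n_samples(pm))
    stop("need one class label per sample")
  ps <- per_sample_kc(pm, grid, kernel)
  profiles <- ps$profiles
  g <- group_rows(labels)
  res <- snr_fdr_threshold(profiles, labels, fdr_target = fdr,
                           n_perms = n_perms, seed = seed)
  regions <- call_differential_regions(res$snr, res$thr, grid)
  structure(list(grid = grid, kernel = kernel,
                 mu1 = colMeans(profiles[g$g1, , drop = FALSE]),
                 mu2 = colMeans(profiles[g$g2, , drop = FALSE]),
                 pooled_sd = pooled_sd(profiles, labels),
                 f = res$f, snr = res$snr, fdr = fdr, thr = res$thr,
                 regions = regions, null_exceedance = res$null_exceedance,
                 profiles = profiles, labels = labels),
            class = "kc_comparative")
}

#' @export
print.kc_comparative <- function(x, ...) {
  cat("Comparative CNA analysis: kernel width",
      format(x$kernel$width, big.mark = ","), "bp, FDR", x$fdr, "\n")
  cat("  |SNR| threshold:",
      if (is.finite(x$thr)) signif(x$thr, 4) else "Inf (no calls)", "\n")
  cat("  differential regions:", nrow(x$regions), "\n")
  invisible(x)
}
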