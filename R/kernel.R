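#' Kernel specification
#'
#' The user-facing "kernel width" is the genomic scale of the aberrations
#' the analysis targets. The smoothing kernel is a Gaussian with
#' \code{sigma = width / 4}, truncated to zero beyond \code{|delta| > width},
#' so a width-w kernel spans roughly 4 sigma (~95% of its mass) over w bp.
#'
#' @param width Kernel width in bp (> 0).
#' @return A \code{kernel_spec}: list with \code{width}, \code{shape},
#'   \code{sigma}, \code{support}.
#' @examples
#' kernel_spec(2e5)
#' @export
kernel_spec <- function(width) {
  width <- as.numeric(width)
  if (length(width) != 1L || !is.finite(width) || width <= 0)
    stop("'width' must be a single positive number of bp")
  structure(list(width = width, shape = "gaussian",
                 sigma = width / 4, support = width),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("Gaussian kernel: width", format(x$width, big.mark = ","),
      "bp (sigma", format(x$sigma, big.mark = ","),
      "bp, truncated at +/-", format(x$support, big.mark = ","), "bp)\n")
  invisible(x)
}

# raw (unnormalized) kernel weight; peak value is 1 at delta = 0
kernel_weight <- function(delta, kernel) {
  w <- exp(-delta^2 / (2 * kernel$sigma^2))
  w[abs(delta) > kernel$support] <- 0
  w
}

# KC values below this fraction of peak weight mass count as "uncovered"
MASS_FLOOR <- 1e-8

#' Split a signed signal into non-negative gain and loss channels
#'
#' Gains and losses are analysed separately in the recurrent mode:
#' \code{gain = max(signal, 0)}, \code{loss = max(-signal, 0)}, so that
#' \code{gain - loss == signal} and \code{gain * loss == 0} elementwise.
#'
#' @param signal Finite numeric vector (typically per-probe summed log2
#'   ratios).
#' @return List with components \code{gain} and \code{loss}.
#' @export
split_gain_loss <- function(signal) {
  if (!is.numeric(signal) || any(!is.finite(signal)))
    stop("'signal' must be a finite numeric vector")
  list(gain = pmax(signal, 0), loss = pmax(-signal, 0))
}

#' Precompute the kernel weight structure for a probe/grid pairing
#'
#' Builds the sparse n_points x n_probes matrix W of truncated-Gaussian
#' weights, restricted per chromosome (a probe never influences points on
#' another chromosome), plus the per-point weight mass (row sums). Probe
#' positions do not change under permutation, so the analysis modes build
#' this once and reuse it for every permutation / sample.
#'
#' @param chrom,pos Per-probe chromosome and position (sorted by layout
#'   order then position).
#' @param grid A \code{sample_grid}.
#' @param kernel A \code{\link{kernel_spec}}.
#' @return A \code{kc_weights} list: \code{W} (dgCMatrix), \code{mass},
#'   \code{covered} (logical per point), \code{grid}, \code{kernel}.
#' @export
kc_weights <- function(chrom, pos, grid, kernel) {
  stopifnot(inherits(grid, "sample_grid"), inherits(kernel, "kernel_spec"))
  np <- length(pos)
  ii <- vector("list", 0L); jj <- vector("list", 0L); xx <- vector("list", 0L)
  point_offset <- 0L
  max_gap <- 0
  for (cc in unique(grid$chrom)) {
    gx <- grid$x[grid$chrom == cc]
    gpi <- which(grid$chrom == cc)
    pidx <- which(chrom == cc)
    if (length(pidx) > 0L) {
      ppos <- pos[pidx]
      if (is.unsorted(ppos))
        stop("probes must be sorted by position within each chromosome")
      if (length(ppos) > 1L)
        max_gap <- max(max_gap, max(diff(ppos)))
      lo <- findInterval(gx - kernel$support, ppos) + 1L
      hi <- findInterval(gx + kernel$support, ppos)
      cnt <- pmax(hi - lo + 1L, 0L)
      keep <- cnt > 0L
      if (any(keep)) {
        i <- rep(gpi[keep], cnt[keep])
        j <- pidx[sequence(cnt[keep]) + rep(lo[keep] - 1L, cnt[keep])]
        d <- pos[j] - grid$x[i]
        ii[[length(ii) + 1L]] <- i
        jj[[length(jj) + 1L]] <- j
        xx[[length(xx) + 1L]] <- kernel_weight(d, kernel)
      }
    }
  }
  if (max_gap > kernel$support)
    warning("kernel support (", kernel$support,
            " bp) is smaller than the largest inter-probe gap (", max_gap,
            " bp); some sample points have zero weight mass")
  W <- Matrix::sparseMatrix(i = as.integer(unlist(ii)),
                            j = as.integer(unlist(jj)),
                            x = as.numeric(unlist(xx)),
                            dims = c(length(grid$x), np))
  mass <- Matrix::rowSums(W)
  structure(list(W = W, mass = mass, covered = mass >= MASS_FLOOR,
                 grid = grid, kernel = kernel),
            class = "kc_weights")
}

# weighted-mean evaluation given a precomputed weight structure;
# uncovered points are defined as 0
kc_apply <- function(wts, signal) {
  v <- as.numeric(wts$W %*% signal)
  out <- numeric(length(v))
  out[wts$covered] <- v[wts$covered] / wts$mass[wts$covered]
  out
}

new_kc_profile <- function(grid, values, channel, kernel, weight_mass) {
  structure(list(grid = grid, values = values, channel = channel,
                 kernel = kernel, weight_mass = weight_mass),
            class = "kc_profile")
}

#' @export
print.kc_profile <- function(x, ...) {
  cat("KC profile (", x$channel, "): ", length(x$values),
      " points, kernel width ", format(x$kernel$width, big.mark = ","),
      " bp\n", sep = "")
  invisible(x)
}

#' Kernel convolution of a positional signal onto a sampling grid
#'
#' Computes, at every grid point x, the Nadaraya-Watson locally weighted
#' (local-constant) regression estimate
#' \deqn{KC(x) = \sum_i k(p_i - x) s_i / \sum_i k(p_i - x)}
#' over probes on the same chromosome within the kernel support, where k is
#' the truncated Gaussian of the kernel spec. The normalization by the
#' kernel-weighted probe mass corrects for unequally spaced probes: a
#' constant signal yields a constant KC score regardless of probe density.
#' Points whose weight mass falls below a small floor (probe deserts) get
#' KC = 0 and are flagged uncovered.
#'
#' @param chrom,pos Per-probe chromosome / 1-based bp position, sorted.
#' @param signal Per-probe numeric signal (same length as \code{pos}).
#' @param grid A \code{sample_grid}.
#' @param kernel A \code{\link{kernel_spec}}.
#' @param channel Channel label stored on the profile
#'   (\code{"signed"}, \code{"gain"} or \code{"loss"}).
#' @param wts Optional precomputed \code{\link{kc_weights}} (skips the
#'   sparse-matrix build).
#' @return A \code{kc_profile}: list with \code{grid}, \code{values},
#'   \code{channel}, \code{kernel}, \code{weight_mass}.
#' @export
kc_convolve <- function(chrom, pos, signal, grid, kernel,
                        channel = "signed", wts = NULL) {
  if (length(signal) != length(pos))
    stop("'signal' must have one value per probe")
  if (any(!is.finite(signal))) stop("'signal' must be finite")
  if (is.null(wts)) wts <- kc_weights(chrom, pos, grid, kernel)
  new_kc_profile(grid, kc_apply(wts, signal), channel, kernel, wts$mass)
}

#' Per-sample KC profiles (signed channel)
#'
#' Smooths each sample's signed log2 ratios individually onto the grid,
#' without gain/loss splitting. All samples share the same probe positions
#' and hence one weight-mass vector.
#'
#' @param pm A \code{\link{probe_matrix}}.
#' @param grid A \code{sample_grid}.
#' @param kernel A \code{\link{kernel_spec}}.
#' @param wts Optional precomputed \code{\link{kc_weights}}.
#' @return List with \code{profiles} (n_samples x n_points matrix, one row
#'   per sample), \code{weight_mass}, \code{grid}, \code{kernel}.
#' @export
per_sample_kc <- function(pm, grid, kernel, wts = NULL) {
  stopifnot(inherits(pm, "probe_matrix"))
  if (is.null(wts)) wts <- kc_weights(pm$chrom, pm$pos, grid, kernel)
  raw <- as.matrix(wts$W %*% pm$ratios)         # n_points x n_samples
  vals <- matrix(0, nrow = nrow(raw), ncol = ncol(raw))
  vals[wts$covered, ] <- raw[wts$covered, , drop = FALSE] /
    wts$mass[wts$covered]
  profiles <- t(vals)
  rownames(profiles) <- colnames(pm$ratios)
  list(profiles = profiles, weight_mass = wts$mass, grid = grid,
       kernel = kernel)
}
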