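#' Specify a spiked copy-number aberration
#'
#' Effects are log2-ratio shifts: +0.58 approximates a single-copy gain in
#' a diploid genome (log2(3/2)), -1.0 a heterozygous-to-homozygous-scale
#' loss. \code{recurrence} is the fraction of targeted samples carrying
#' the aberration; \code{target} restricts it to one class for
#' class-specific (differential) events.
#'
#' @param chrom Chromosome name.
#' @param start_bp,end_bp Interval (1-based, \code{start_bp < end_bp}).
#' @param effect Log2-ratio shift added to carrier samples' probes inside
#'   the interval.
#' @param recurrence Carrier probability among targeted samples, in (0, 1].
#' @param target \code{"all"}, \code{"class1"} or \code{"class2"}.
#' @return An \code{aberration_spec} list.
#' @export
aberration_spec <- function(chrom, start_bp, end_bp, effect,
                            recurrence = 1, target = c("all", "class1",
                                                       "class2")) {
  target <- match.arg(target)
  if (start_bp >= end_bp) stop("start_bp must be < end_bp")
  if (recurrence <= 0 || recurrence > 1)
    stop("'recurrence' must be in (0, 1]")
  if (!is.finite(effect) || effect == 0)
    stop("'effect' must be finite and nonzero")
  structure(list(chrom = as.character(chrom), start_bp = start_bp,
                 end_bp = end_bp, effect = effect,
                 recurrence = recurrence, target = target),
            class = "aberration_spec")
}

spec_channel <- function(spec) {
  if (spec$target == "all") {
    if (spec$effect > 0) "gain" else "loss"
  } else if (spec$target == "class1") {
    if (spec$effect > 0) "diff_up" else "diff_down"
  } else {
    if (spec$effect > 0) "diff_down" else "diff_up"
  }
}

draw_positions <- function(layout, n_probes_per_chrom, spacing_mode) {
  chrom <- character(0); pos <- numeric(0)
  for (k in seq_len(nrow(layout))) {
    n <- n_probes_per_chrom[k]
    len <- layout$length[k]
    p <- if (spacing_mode == "uniform") {
      round(seq(len / (2 * n), len, by = len / n))
    } else {
      # log-normal inter-probe gaps (sdlog 1), rescaled to span the
      # chromosome: exercises the probe-density correction
      gaps <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
      cum <- cumsum(gaps)
      round(cum / (cum[n] + gaps[1]) * len)
    }
    p <- pmin(pmax(p, 1), len)
    p <- sort(unique(p))
    chrom <- c(chrom, rep(layout$chrom[k], length(p)))
    pos <- c(pos, p)
  }
  list(chrom = chrom, pos = pos)
}

#' Generate a synthetic aCGH dataset with known truth regions
#'
#' Builds probe positions (uniformly spaced or with log-normal gaps),
#' assigns carrier samples per aberration spec, and produces log2 ratios
#' as the sum of spiked effects plus i.i.d. Gaussian probe noise. Samples
#' 1..n1 form class 1, samples n1+1..n1+n2 class 2.
#'
#' @param layout A \code{\link{genome_layout}}.
#' @param n_probes_per_chrom Integer (recycled across chromosomes) number
#'   of probes per chromosome; ignored if \code{probe_positions} given.
#' @param n1,n2 Class sizes (total samples = n1 + n2; use n2 = 0 for a
#'   single-class dataset).
#' @param specs List of \code{\link{aberration_spec}}s.
#' @param noise_sd Standard deviation of the Gaussian probe noise (log2
#'   units).
#' @param spacing_mode \code{"uniform"} or \code{"lognormal_gaps"}.
#' @param seed RNG seed; identical seeds give bit-identical datasets.
#' @param probe_positions Optional list(chrom, pos) overriding generated
#'   positions.
#' @return List: \code{pm} (a \code{\link{probe_matrix}}), \code{truth}
#'   (a \code{\link{region_set}} of the spiked intervals), \code{carriers}
#'   (n_specs x n_samples logical matrix), \code{labels}
#'   (\code{\link{class_labels}} when both classes are non-empty).
#' @export
generate_dataset <- function(layout, n_probes_per_chrom, n1, n2 = 0,
                             specs = list(), noise_sd = 0.3,
                             spacing_mode = c("uniform", "lognormal_gaps"),
                             seed = 1L, probe_positions = NULL) {
  spacing_mode <- match.arg(spacing_mode)
  stopifnot(inherits(layout, "genome_layout"))
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (inherits(specs, "aberration_spec")) specs <- list(specs)
  for (sp in specs) {
    ci <- chrom_index(sp$chrom, layout)
    if (sp$end_bp > layout$length[ci])
      stop("aberration on ", sp$chrom, " extends past chromosome end")
  }
  n_tot <- n1 + n2
  if (n_tot < 1L) stop("need at least one sample")
  set.seed(as.integer(seed))
  if (is.null(probe_positions)) {
    npc <- rep_len(n_probes_per_chrom, nrow(layout))
    pp <- draw_positions(layout, npc, spacing_mode)
  } else pp <- probe_positions
  np <- length(pp$pos)
  ratios <- matrix(stats::rnorm(np * n_tot, 0, noise_sd), np, n_tot)
  carriers <- matrix(FALSE, length(specs), n_tot)
  cls <- rep(c(1L, 2L), c(n1, n2))
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    targeted <- switch(sp$target, all = seq_len(n_tot),
                       class1 = which(cls == 1L),
                       class2 = which(cls == 2L))
    carry <- targeted[stats::runif(length(targeted)) < sp$recurrence]
    carriers[k, carry] <- TRUE
    in_reg <- pp$chrom == sp$chrom & pp$pos >= sp$start_bp &
      pp$pos <= sp$end_bp
    if (any(in_reg) && length(carry))
      ratios[in_reg, carry] <- ratios[in_reg, carry] + sp$effect
  }
  sample_ids <- paste0("S", seq_len(n_tot))
  pm <- probe_matrix(pp$chrom, pp$pos, ratios, layout,
                     sample_ids = sample_ids)
  truth <- if (length(specs)) {
    region_set(vapply(specs, `[[`, character(1), "chrom"),
               vapply(specs, `[[`, numeric(1), "start_bp"),
               vapply(specs, `[[`, numeric(1), "end_bp"),
               vapply(specs, spec_channel, character(1)),
               abs(vapply(specs, `[[`, numeric(1), "effect")),
               layout = layout)
  } else region_set(layout = layout)
  labels <- if (n1 >= 2 && n2 >= 2)
    class_labels(cls, sample_ids) else NULL
  list(pm = pm, truth = truth, carriers = carriers, labels = labels)
}

interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

#' Score recovery of truth regions by called regions
#'
#' Per truth region, the Jaccard index (bp overlap / bp union) against the
#' best-matching called region of the same channel. Globally, bp-level
#' sensitivity (truth bp covered by compatible calls / truth bp) and
#' specificity (non-truth bp left uncalled / non-truth bp, over the whole
#' layout).
#'
#' @param called,truth \code{\link{region_set}}s on the same layout.
#' @param layout The \code{\link{genome_layout}} (needed for specificity).
#' @return List: \code{jaccard} (per truth region), \code{sensitivity},
#'   \code{specificity}.
#' @export
score_recovery <- function(called, truth, layout) {
  nj <- nrow(truth)
  jac <- numeric(nj)
  covered_bp <- 0
  truth_bp <- 0
  for (k in seq_len(nj)) {
    tr <- truth[k, ]
    tlen <- tr$end_bp - tr$start_bp
    truth_bp <- truth_bp + tlen
    comp <- called[called$channel == tr$channel &
                     called$chrom == tr$chrom, , drop = FALSE]
    if (nrow(comp)) {
      ov <- interval_overlap(tr$start_bp, tr$end_bp,
                             comp$start_bp, comp$end_bp)
      un <- (tr$end_bp - tr$start_bp) + (comp$end_bp - comp$start_bp) - ov
      jac[k] <- max(ov / un)
      covered_bp <- covered_bp + sum(ov)
    }
  }
  genome_bp <- sum(layout$length)
  called_bp <- if (nrow(called))
    sum(called$end_bp - called$start_bp) else 0
  # false-positive bp: called bp minus overlap with same-channel truth
  fp_bp <- max(called_bp - covered_bp, 0)
  non_truth_bp <- genome_bp - truth_bp
  list(jaccard = jac,
       sensitivity = if (truth_bp > 0) covered_bp / truth_bp else NA_real_,
       specificity = if (non_truth_bp > 0)
         (non_truth_bp - fp_bp) / non_truth_bp else NA_real_)
}
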