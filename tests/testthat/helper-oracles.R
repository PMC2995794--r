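# Independent brute-force oracles and small fixture builders.

# naive double-loop Nadaraya-Watson evaluation of the KC score:
# truncated Gaussian (sigma = width/4, support = width), per chromosome
naive_kc <- function(chrom, pos, signal, grid, width) {
  sigma <- width / 4
  vapply(seq_along(grid$x), function(i) {
    cc <- grid$chrom[i]
    x <- grid$x[i]
    sel <- which(chrom == cc & abs(pos - x) <= width)
    if (!length(sel)) return(0)
    w <- exp(-(pos[sel] - x)^2 / (2 * sigma^2))
    if (sum(w) < 1e-8) return(0)
    sum(w * signal[sel]) / sum(w)
  }, numeric(1))
}

# random convolution instance on one or two chromosomes
random_kc_instance <- function(seed) {
  set.seed(seed)
  n_chrom <- sample(1:2, 1)
  lens <- sample(5:20, n_chrom) * 1e5
  lay <- genome_layout(paste0("c", seq_len(n_chrom)), lens)
  n <- sample(5:100, 1)
  chrom <- sort(sample(seq_len(n_chrom), n, replace = TRUE))
  pos <- unlist(lapply(seq_len(n_chrom), function(k) {
    m <- sum(chrom == k)
    if (m == 0) return(numeric(0))
    sort(sample.int(lens[k], m))
  }))
  chrom <- paste0("c", chrom)
  spacing <- sample(c(2e4, 5e4, 1e5), 1)
  grid <- build_sample_points(lay, spacing)
  if (length(grid$x) > 50) {
    # enlarge spacing until the instance stays small
    spacing <- max(lens) / 20
    grid <- build_sample_points(lay, spacing)
  }
  list(layout = lay, chrom = chrom, pos = pos,
       signal = rnorm(n), grid = grid,
       width = sample(c(1e5, 2e5, 5e5), 1))
}

# tiny deterministic layout/dataset used across files
tiny_layout <- function() genome_layout(c("chr1", "chr2"), c(2e6, 1e6))

tiny_probe_file <- function(path, rows) {
  writeLines(c("probe_id\tchrom\tpos\tsA\tsB", rows), path)
}

# independent seeded re-implementation of the recurrent permutation
# threshold (naive convolution, explicit shuffles)
oracle_perm_threshold <- function(pm, grid, width, n_perms, alpha, seed) {
  s <- rowSums(pm$ratios)
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, n_perms)
  mg <- numeric(n_perms)
  ml <- numeric(n_perms)
  for (p in seq_len(n_perms)) {
    set.seed(seeds[p])
    sp <- s[sample.int(length(s))]
    mg[p] <- max(naive_kc(pm$chrom, pm$pos, pmax(sp, 0), grid, width))
    ml[p] <- max(naive_kc(pm$chrom, pm$pos, pmax(-sp, 0), grid, width))
  }
  # one family across both channels: alpha is split half and half
  c(gain = unname(quantile(mg, 1 - alpha / 2, type = 7)),
    loss = unname(quantile(ml, 1 - alpha / 2, type = 7)))
}

# independent seeded re-implementation of the SNR FDR threshold
oracle_snr_threshold <- function(profiles, labels, fdr_target, n_perms,
                                 seed) {
  psd <- function(m, lab) {
    g1 <- m[lab == 1, , drop = FALSE]; g2 <- m[lab == 2, , drop = FALSE]
    v1 <- apply(g1, 2, var); v2 <- apply(g2, 2, var)
    sqrt(((nrow(g1) - 1) * v1 + (nrow(g2) - 1) * v2) /
           (nrow(g1) + nrow(g2) - 2))
  }
  snr_of <- function(m, lab) {
    s <- psd(m, lab)
    f <- unname(quantile(s, 0.95, type = 7))
    (colMeans(m[lab == 1, , drop = FALSE]) -
       colMeans(m[lab == 2, , drop = FALSE])) / (s + f)
  }
  lab <- as.integer(labels)
  obs <- abs(snr_of(profiles, lab))
  cand <- sort(unique(obs))
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, n_perms)
  nullc <- matrix(0, n_perms, length(cand))
  for (p in seq_len(n_perms)) {
    set.seed(seeds[p])
    pl <- lab[sample.int(length(lab))]
    np <- abs(snr_of(profiles, pl))
    nullc[p, ] <- vapply(cand, function(t) sum(np >= t), numeric(1))
  }
  obs_count <- vapply(cand, function(t) sum(obs >= t), numeric(1))
  fdr_hat <- pmin(colMeans(nullc) / obs_count, 1)
  ok <- which(fdr_hat <= fdr_target)
  if (length(ok)) cand[min(ok)] else Inf
}
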