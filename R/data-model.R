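#' Genome layout: ordered chromosomes and their lengths
#'
#' The layout fixes the chromosome order used for concatenated genome-wide
#' plots and for sorting probes, and owns the coordinate conventions
#' (1-based bp positions internally, 0-based half-open only on BED export).
#'
#' @param chrom Character vector of unique chromosome names, in plotting /
#'   concatenation order.
#' @param length Positive integer-ish vector of chromosome lengths in bp.
#' @return A \code{genome_layout} object (data frame with columns
#'   \code{chrom}, \code{length}).
#' @examples
#' genome_layout(c("chr1", "chr2"), c(2e6, 1e6))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (base::length(chrom) != base::length(length))
    stop("'chrom' and 'length' must have the same length")
  if (base::length(chrom) == 0L)
    stop("layout must contain at least one chromosome")
  if (anyDuplicated(chrom))
    stop("duplicate chromosome names in layout: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  if (any(!is.finite(length)) || any(length <= 0))
    stop("all chromosome lengths must be finite and > 0")
  structure(data.frame(chrom = chrom, length = length,
                       stringsAsFactors = FALSE),
            class = c("genome_layout", "data.frame"))
}

#' Read a genome layout from a two-column TSV (chrom, length)
#'
#' @param path Path to a tab-delimited file. A header line is optional and
#'   detected by a non-numeric second field.
#' @return A \code{\link{genome_layout}}.
#' @export
read_genome_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  first <- utils::read.table(path, sep = "\t", nrows = 1,
                             colClasses = "character")
  header <- is.na(suppressWarnings(as.numeric(first[[2]])))
  tab <- utils::read.table(path, sep = "\t", header = header,
                           colClasses = c("character", "numeric"))
  genome_layout(tab[[1]], tab[[2]])
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("Genome layout:", nrow(x), "chromosomes,",
      format(sum(x$length), big.mark = ","), "bp total\n")
  print.data.frame(x, ...)
  invisible(x)
}

chrom_index <- function(chrom, layout) {
  idx <- match(chrom, layout$chrom)
  if (anyNA(idx)) {
    bad <- unique(chrom[is.na(idx)])
    stop("chromosome(s) not present in layout: ",
         paste(bad, collapse = ", "))
  }
  idx
}

#' Construct a probe matrix
#'
#' Holds per-probe genomic annotation (chromosome, 1-based bp position)
#' together with an n_probes x n_samples matrix of log2 ratios. Probes are
#' stored sorted by layout chromosome order, then position. Replicate spots
#' at the same (chrom, pos) are averaged.
#'
#' @param chrom Per-probe chromosome names (must exist in \code{layout}).
#' @param pos Per-probe 1-based bp positions.
#' @param ratios Numeric matrix (or vector for a single sample) of log2
#'   ratios; one column per sample.
#' @param layout A \code{\link{genome_layout}}.
#' @param sample_ids Optional sample names; defaults to column names of
#'   \code{ratios} or S1, S2, ...
#' @param probe_id Optional per-probe identifiers.
#' @return A \code{probe_matrix} object: list with elements \code{chrom},
#'   \code{pos}, \code{probe_id}, \code{ratios}, \code{layout}.
#' @export
probe_matrix <- function(chrom, pos, ratios, layout, sample_ids = NULL,
                         probe_id = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  if (is.vector(ratios)) ratios <- matrix(ratios, ncol = 1L)
  ratios <- as.matrix(ratios)
  storage.mode(ratios) <- "double"
  n <- length(chrom)
  if (n == 0L) stop("probe matrix must contain at least one probe")
  if (length(pos) != n || nrow(ratios) != n)
    stop("chrom, pos and ratios rows must agree in length")
  if (is.null(sample_ids)) sample_ids <- colnames(ratios)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(ratios)))
  colnames(ratios) <- sample_ids
  if (is.null(probe_id)) probe_id <- paste0("p", seq_len(n))
  ci <- chrom_index(chrom, layout)
  if (any(pos < 1) || any(pos > layout$length[ci]))
    stop("probe positions must lie within [1, chromosome length]")
  if (anyNA(ratios))
    stop("probe matrix may not contain missing ratios; see load_probe_table")

  ord <- order(ci, pos)
  if (is.unsorted(ord, strictly = TRUE)) {
    warning("probes were not sorted by (chromosome, position); re-sorting")
  }
  chrom <- chrom[ord]; pos <- pos[ord]; ratios <- ratios[ord, , drop = FALSE]
  probe_id <- probe_id[ord]

  # average replicate spots at identical genomic positions
  key <- paste(chrom, pos, sep = "\r")
  if (anyDuplicated(key)) {
    message("averaging ", sum(duplicated(key)),
            " duplicate probe position(s)")
    grp <- match(key, unique(key))
    keep <- !duplicated(key)
    agg <- rowsum(ratios, grp, reorder = TRUE) /
      as.vector(table(grp))
    ratios <- agg
    colnames(ratios) <- sample_ids
    chrom <- chrom[keep]; pos <- pos[keep]; probe_id <- probe_id[keep]
  }

  structure(list(chrom = chrom, pos = pos, probe_id = probe_id,
                 ratios = ratios, layout = layout),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat("Probe matrix:", length(x$pos), "probes x", ncol(x$ratios),
      "samples on", length(unique(x$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Number of probes / samples in a probe matrix
#' @param pm A \code{probe_matrix}.
#' @return Integer count.
#' @export
n_probes <- function(pm) length(pm$pos)

#' @rdname n_probes
#' @export
n_samples <- function(pm) ncol(pm$ratios)

#' Load a tab-delimited probe table
#'
#' Expected columns: \code{probe_id}, \code{chrom}, \code{pos}, then one
#' numeric column per sample (header required). Rows are sorted by layout
#' order; rows with missing ratios are handled according to
#' \code{na_policy}; duplicate (chrom, pos) rows are averaged.
#'
#' @param path Path to the probe table.
#' @param layout A \code{\link{genome_layout}}; every chromosome in the
#'   file must appear in it.
#' @param na_policy Either \code{"drop"} (remove any probe row containing a
#'   missing ratio; default) or \code{"impute_zero"} (replace explicit NA
#'   markers by 0). Non-numeric garbage is an error under both policies.
#' @return A \code{\link{probe_matrix}}.
#' @export
load_probe_table <- function(path, layout, na_policy = c("drop", "impute_zero")) {
  na_policy <- match.arg(na_policy)
  if (!file.exists(path)) stop("probe table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "")
  if (ncol(tab) < 4L)
    stop("probe table needs columns probe_id, chrom, pos and >= 1 sample")
  pos <- suppressWarnings(as.numeric(tab[[3]]))
  if (anyNA(pos) || any(pos <= 0) || any(pos != floor(pos)))
    stop("column 3 (pos) must contain positive integers; offending row(s): ",
         paste(utils::head(which(is.na(pos) | pos <= 0), 5), collapse = ", "))
  chrom <- tab[[2]]
  unknown <- !(chrom %in% layout$chrom)
  if (any(unknown))
    stop("unknown chromosome '", chrom[which(unknown)[1]],
         "' at probe table row ", which(unknown)[1])
  samp <- as.matrix(tab[, -(1:3), drop = FALSE])
  na_mask <- samp == "NA" | samp == "" | is.na(samp)
  num <- suppressWarnings(matrix(as.numeric(samp), nrow = nrow(samp),
                                 dimnames = dimnames(samp)))
  garbage <- is.na(num) & !na_mask
  if (any(garbage))
    stop("non-numeric ratio value(s), e.g. '",
         samp[which(garbage)[1]], "' (row ",
         row(samp)[which(garbage)[1]], ")")
  if (na_policy == "drop") {
    keep <- rowSums(is.na(num)) == 0L
    if (!all(keep))
      message("dropping ", sum(!keep), " probe row(s) with missing ratios")
    num <- num[keep, , drop = FALSE]
    chrom <- chrom[keep]; pos <- pos[keep]
    ids <- tab[[1]][keep]
  } else {
    num[is.na(num)] <- 0
    ids <- tab[[1]]
  }
  if (nrow(num) == 0L) stop("no usable probes after applying na_policy")
  probe_matrix(chrom, pos, num, layout, probe_id = ids)
}

#' Write a probe matrix back to the tab-delimited probe-table dialect
#'
#' The written file round-trips through \code{\link{load_probe_table}} up to
#' the text representation's precision (ratios are written with 17
#' significant digits, which is lossless for doubles).
#'
#' @param pm A \code{\link{probe_matrix}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_probe_table <- function(pm, path) {
  tab <- data.frame(probe_id = pm$probe_id, chrom = pm$chrom,
                    pos = format(pm$pos, scientific = FALSE, trim = TRUE),
                    stringsAsFactors = FALSE)
  rat <- format(pm$ratios, digits = 17, trim = TRUE, scientific = TRUE)
  for (j in seq_len(ncol(pm$ratios)))
    tab[[colnames(pm$ratios)[j]]] <- rat[, j]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build the regular grid of sampling points
#'
#' KC scores are evaluated on a regular per-chromosome grid rather than at
#' probe positions. Within each chromosome, points lie at spacing/2,
#' 3*spacing/2, ... up to the chromosome length; the grid never spans a
#' chromosome boundary.
#'
#' @param layout A \code{\link{genome_layout}}.
#' @param spacing Distance between consecutive sampling points, in bp.
#' @return A \code{sample_grid} object: list with \code{chrom}, \code{x}
#'   (bp coordinates) and \code{spacing}.
#' @examples
#' build_sample_points(genome_layout("chr1", 1e6), 1e5)
#' @export
build_sample_points <- function(layout, spacing) {
  stopifnot(inherits(layout, "genome_layout"))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 1L || !is.finite(spacing) || spacing <= 0)
    stop("'spacing' must be a single positive number of bp")
  counts <- floor((layout$length - spacing / 2) / spacing) + 1
  empty <- layout$length < spacing / 2
  counts[empty] <- 0
  if (any(counts == 0))
    stop("spacing ", spacing, " leaves zero sample points on chromosome(s): ",
         paste(layout$chrom[counts == 0], collapse = ", "))
  chrom <- rep(layout$chrom, counts)
  x <- unlist(lapply(counts, function(k) spacing / 2 + spacing * (seq_len(k) - 1)),
              use.names = FALSE)
  structure(list(chrom = chrom, x = x, spacing = spacing, layout = layout),
            class = "sample_grid")
}

#' @export
print.sample_grid <- function(x, ...) {
  cat("Sampling grid:", length(x$x), "points, spacing",
      format(x$spacing, big.mark = ","), "bp\n")
  invisible(x)
}

#' Number of points in a sampling grid
#' @param grid A \code{sample_grid}.
#' @return Integer count.
#' @export
n_points <- function(grid) length(grid$x)

REGION_CHANNELS <- c("gain", "loss", "diff_up", "diff_down")

#' Construct a set of called (or truth) genomic regions
#'
#' @param chrom,start_bp,end_bp Region coordinates (1-based, inclusive,
#'   \code{start_bp < end_bp}).
#' @param channel One of \code{"gain"}, \code{"loss"}, \code{"diff_up"},
#'   \code{"diff_down"} per region.
#' @param score Peak statistic within the region (KC score or |SNR|).
#' @param n_points Number of grid points inside the region (NA for truth
#'   regions not derived from a grid).
#' @param layout Optional \code{\link{genome_layout}} used for sorting; if
#'   omitted, chromosomes sort alphabetically.
#' @return A \code{region_set} data frame, sorted by (chromosome, start,
#'   channel), with non-overlapping regions per (chromosome, channel).
#' @export
region_set <- function(chrom = character(), start_bp = numeric(),
                       end_bp = numeric(), channel = character(),
                       score = numeric(), n_points = integer(),
                       layout = NULL) {
  n <- length(chrom)
  if (length(score) == 0L && n > 0L) score <- rep(NA_real_, n)
  if (length(n_points) == 0L && n > 0L) n_points <- rep(NA_integer_, n)
  rs <- data.frame(chrom = as.character(chrom),
                   start_bp = as.numeric(start_bp),
                   end_bp = as.numeric(end_bp),
                   channel = as.character(channel),
                   score = as.numeric(score),
                   n_points = as.integer(n_points),
                   stringsAsFactors = FALSE)
  if (n > 0L) {
    if (any(!rs$channel %in% REGION_CHANNELS))
      stop("channel must be one of: ", paste(REGION_CHANNELS, collapse = ", "))
    if (any(rs$start_bp >= rs$end_bp))
      stop("regions must satisfy start_bp < end_bp")
    ci <- if (is.null(layout)) match(rs$chrom, sort(unique(rs$chrom)))
          else chrom_index(rs$chrom, layout)
    rs <- rs[order(ci, rs$start_bp, rs$channel), , drop = FALSE]
    rownames(rs) <- NULL
    # same-channel regions on a chromosome must not overlap
    for (ch in unique(rs$channel)) {
      sub <- rs[rs$channel == ch, , drop = FALSE]
      for (cc in unique(sub$chrom)) {
        s2 <- sub[sub$chrom == cc, , drop = FALSE]
        if (nrow(s2) > 1L &&
            any(s2$start_bp[-1] <= s2$end_bp[-nrow(s2)]))
          stop("overlapping regions on ", cc, " channel ", ch)
      }
    }
  }
  class(rs) <- c("region_set", "data.frame")
  rs
}

#' Export regions as BED
#'
#' Coordinates follow the BED convention: 0-based half-open, i.e.
#' \code{start = start_bp - 1}, \code{end = end_bp}. The name column holds
#' the channel; the score column is the peak statistic rescaled to
#' [0, 1000] by the maximum score in the file.
#'
#' @param regions A \code{\link{region_set}}.
#' @param path Output path. An empty region set yields a valid empty file.
#' @return Invisibly, \code{path}.
#' @export
write_regions_bed <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  if (nrow(regions) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  smax <- max(abs(regions$score), na.rm = TRUE)
  bedscore <- if (is.finite(smax) && smax > 0)
    round(abs(regions$score) / smax * 1000) else rep(0L, nrow(regions))
  bedscore[is.na(bedscore)] <- 0L
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start_bp - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(regions$end_bp, scientific = FALSE,
                                 trim = TRUE),
                    name = regions$channel,
                    score = bedscore,
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
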