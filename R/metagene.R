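# Anchor-centered signal matrices, difference heatmaps, k-means clustering,
# metagene averages, and simplified MNase occupancy coverage.
#
# A "signal_matrix" is anchors x bins (attributes: bin_size, flank, frame);
# a "coverage_track" is a named list of per-chromosome numeric vectors of
# per-base signal (element i = 0-based position i - 1).

new_signal_matrix <- function(values, bin_size, flank, frame) {
  nbins <- ncol(values)
  colnames(values) <- seq(-flank, flank - bin_size, by = bin_size)
  attr(values, "bin_size") <- as.integer(bin_size)
  attr(values, "flank") <- as.integer(flank)
  attr(values, "frame") <- frame
  class(values) <- c("signal_matrix", class(values))
  values
}

anchor_orientation_strand <- function(anchors, promoters) {
  m <- match(anchors$site_id, promoters$site_id)
  promoters$gene_strand[m]
}

#' Build an anchor-centered binned signal matrix
#'
#' One row per anchor, one column per bin of width `bin_size` across
#' `[-flank, flank)` relative to the anchor. Point signal (a `tss_track`)
#' is summed per bin; per-base coverage (a `coverage_track`) is averaged
#' per bin. In the `"gene"` frame the relative axis runs 5' to 3' of the
#' paired gene (bins are mirrored for `-` genes), so negative coordinates
#' are the divergent/upstream side.
#'
#' @param signal A `tss_track` data.frame or a `coverage_track` list.
#' @param anchors Anchor data.frame (site_id, chrom, pos).
#' @param flank Half-width, bp; must be divisible by `bin_size`.
#' @param bin_size Bin width, bp.
#' @param frame `"genomic"` or `"gene"` (requires `promoters`).
#' @param promoters Promoter pairing; needed for the `"gene"` frame and for
#'   `strand_sel` values `"sense"`/`"antisense"`.
#' @param strand_sel For stranded point signal: `NULL` (both strands
#'   combined), `"+"`/`"-"` (genomic strand), or `"sense"`/`"antisense"`
#'   (relative to the paired gene).
#' @param chrom_sizes Optional; anchors whose window runs off a chromosome
#'   end are dropped with a warning.
#' @return A `signal_matrix` (rows = anchor ids, columns named by the bin's
#'   5'-most relative coordinate).
#' @export
build_signal_matrix <- function(signal, anchors, flank, bin_size,
                                frame = c("genomic", "gene"),
                                promoters = NULL, strand_sel = NULL,
                                chrom_sizes = NULL) {
  frame <- match.arg(frame)
  stopifnot(flank %% bin_size == 0)
  nbins <- as.integer(2L * flank / bin_size)
  if (frame == "gene" || (!is.null(strand_sel) &&
                          strand_sel %in% c("sense", "antisense"))) {
    if (is.null(promoters)) stop("promoters required for gene-oriented output")
    gstrand <- anchor_orientation_strand(anchors, promoters)
    if (anyNA(gstrand)) stop("anchor(s) missing from promoter pairing")
  } else {
    gstrand <- rep("+", nrow(anchors))
  }
  if (!is.null(chrom_sizes)) {
    len <- chrom_sizes[anchors$chrom]
    off <- anchors$pos - flank < 0 | anchors$pos + flank > len
    if (any(off)) {
      warning(sum(off), " anchor(s) too close to a chromosome end; dropped")
      anchors <- anchors[!off, , drop = FALSE]
      gstrand <- gstrand[!off]
    }
  }
  is_point <- is.data.frame(signal)
  vals <- matrix(0, nrow = nrow(anchors), ncol = nbins,
                 dimnames = list(anchors$site_id, NULL))
  for (i in seq_len(nrow(anchors))) {
    a_chrom <- anchors$chrom[i]
    a_pos <- anchors$pos[i]
    gs <- gstrand[i]
    if (is_point) {
      sub <- signal[signal$chrom == a_chrom, , drop = FALSE]
      if (!is.null(strand_sel)) {
        want <- switch(strand_sel,
                       "+" = "+", "-" = "-",
                       sense = gs,
                       antisense = if (gs == "+") "-" else "+")
        sub <- sub[sub$strand == want, , drop = FALSE]
      }
      rel <- if (frame == "gene" && gs == "-") a_pos - sub$pos else
        sub$pos - a_pos
      keep <- rel >= -flank & rel < flank
      if (any(keep)) {
        bin <- (rel[keep] + flank) %/% bin_size + 1L
        vals[i, ] <- as.numeric(tapply_sum(sub$signal[keep], bin, nbins))
      }
    } else {
      cov <- signal[[a_chrom]]
      if (is.null(cov)) next
      rel_grid <- seq(-flank, flank - 1L)
      gpos <- if (frame == "gene" && gs == "-") a_pos - rel_grid else
        a_pos + rel_grid
      v <- rep(0, length(gpos))
      inb <- gpos >= 0 & gpos < length(cov)
      v[inb] <- cov[gpos[inb] + 1L]
      vals[i, ] <- colMeans(matrix(v, nrow = bin_size))
    }
  }
  new_signal_matrix(vals, bin_size, flank, frame)
}

tapply_sum <- function(x, bin, nbins) {
  out <- numeric(nbins)
  s <- tapply(x, bin, sum)
  out[as.integer(names(s))] <- s
  out
}

#' Element-wise difference of two signal matrices (alt - ref)
#'
#' @param alt,ref `signal_matrix` objects over identical anchors, bins and
#'   frame.
#' @return A `signal_matrix` of differences.
#' @export
difference_matrix <- function(alt, ref) {
  if (!identical(attr(alt, "frame"), attr(ref, "frame"))) {
    stop("frame mismatch between matrices")
  }
  if (!identical(dim(alt), dim(ref)) ||
      !identical(rownames(alt), rownames(ref)) ||
      !identical(attr(alt, "bin_size"), attr(ref, "bin_size"))) {
    stop("matrices must share anchors, bins and bin size")
  }
  out <- unclass(alt) - unclass(ref)
  new_signal_matrix(out, attr(alt, "bin_size"), attr(alt, "flank"),
                    attr(alt, "frame"))
}

#' k-means clustering of anchor profiles
#'
#' Lloyd-style k-means (`stats::kmeans`) with `nstart` random restarts
#' under a fixed seed, keeping the best within-cluster sum of squares.
#' Clusters are relabeled so cluster 1 has the highest mean row signal.
#'
#' @param matrix A `signal_matrix` (or plain numeric matrix).
#' @param k Number of clusters.
#' @param seed Integer seed; output is deterministic given
#'   (matrix, k, seed, nstart).
#' @param nstart Number of random restarts.
#' @param standardize Z-score rows before clustering (default off: raw
#'   change signal is clustered).
#' @return list: `assignment` (data.frame anchor_id, cluster),
#'   `ordering_stat` (per-cluster mean signal, descending), `kmeans` (the
#'   underlying fit, labels in relabeled order).
#' @export
kmeans_cluster <- function(matrix, k = 3L, seed = 1L, nstart = 10L,
                           standardize = FALSE) {
  m <- unclass(matrix)
  if (nrow(m) < k) stop("fewer rows than clusters")
  if (nrow(unique(as.data.frame(m))) < k) {
    stop("fewer than k distinct rows; cannot form ", k, " clusters")
  }
  if (standardize) {
    m <- t(scale(t(m)))
    m[is.nan(m)] <- 0
  }
  set.seed(seed)
  if (nrow(m) == k) {
    # degenerate partition: every row is its own cluster, zero inertia
    fit <- structure(list(cluster = seq_len(k), centers = m,
                          totss = sum(scale(m, scale = FALSE)^2),
                          withinss = rep(0, k), tot.withinss = 0,
                          size = rep(1L, k)),
                     class = "kmeans")
  } else {
    fit <- stats::kmeans(m, centers = k, nstart = nstart, iter.max = 100L)
  }
  stat <- tapply(rowMeans(unclass(matrix)), fit$cluster, mean)
  relabel <- rank(-stat, ties.method = "first")
  new_labels <- relabel[as.character(fit$cluster)]
  fit$cluster <- stats::setNames(as.integer(new_labels), rownames(m))
  list(assignment = data.frame(anchor_id = rownames(m),
                               cluster = as.integer(new_labels),
                               stringsAsFactors = FALSE),
       ordering_stat = sort(stats::setNames(as.numeric(stat),
                                            relabel[names(stat)]),
                            decreasing = TRUE),
       kmeans = fit)
}

#' Per-base fragment coverage track
#'
#' Counts, at every base, the fragments whose span covers it (optionally
#' restricted to one strand), scaled by `scale`.
#'
#' @param fragments Fragment data.frame (chrom, start, end, strand).
#' @param chrom_sizes Named chromosome lengths.
#' @param strand Optional strand restriction.
#' @param scale Multiplier applied to the coverage (e.g. 1/size_factor).
#' @return A `coverage_track` list.
#' @export
fragment_coverage <- function(fragments, chrom_sizes, strand = NULL,
                              scale = 1.0) {
  if (!is.null(strand)) {
    fragments <- fragments[fragments$strand == strand, , drop = FALSE]
  }
  out <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    delta <- numeric(len + 1L)
    sub <- fragments[fragments$chrom == ch, , drop = FALSE]
    if (nrow(sub)) {
      s <- pmax(sub$start, 0L) + 1L
      e <- pmin(sub$end, len) + 1L
      ok <- s <= len & e > s - 1L
      for (i in which(ok)) {
        delta[s[i]] <- delta[s[i]] + 1
        delta[e[i]] <- delta[e[i]] - 1
      }
    }
    cumsum(delta)[seq_len(len)] * scale
  })
  names(out) <- names(chrom_sizes)
  class(out) <- "coverage_track"
  out
}

#' Smoothed MNase occupancy coverage
#'
#' Each fragment contributes a fixed-width occupancy interval of `extend`
#' bp centered on its midpoint; per-base coverage is smoothed with a
#' moving average of `smooth_width` bp and scaled so the fragment total is
#' equivalent to `scale_count` fragments.
#'
#' @param fragments MNase fragment data.frame (chrom, midpoint).
#' @param chrom_sizes Named chromosome lengths.
#' @param extend Occupancy width centered on the midpoint, bp.
#' @param smooth_width Moving-average window, bp.
#' @param scale_count Fragment-count equivalent to scale to.
#' @return A `coverage_track` list.
#' @export
mnase_coverage <- function(fragments, chrom_sizes, extend = 40L,
                           smooth_width = 20L, scale_count = 1e6) {
  n_frag <- nrow(fragments)
  half <- as.integer(extend) %/% 2L
  scale <- if (n_frag > 0) scale_count / n_frag else 1.0
  out <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    delta <- numeric(len + 1L)
    mids <- fragments$midpoint[fragments$chrom == ch]
    if (length(mids)) {
      s <- pmax(mids - half, 0L) + 1L
      e <- pmin(mids - half + as.integer(extend), len) + 1L
      for (i in seq_along(mids)) {
        delta[s[i]] <- delta[s[i]] + 1
        delta[e[i]] <- delta[e[i]] - 1
      }
    }
    cov <- cumsum(delta)[seq_len(len)]
    moving_average(cov, as.integer(smooth_width)) * scale
  })
  names(out) <- names(chrom_sizes)
  class(out) <- "coverage_track"
  out
}

# Centered moving average over window w: mean of positions
# [i - floor(w/2), i + ceiling(w/2) - 1], truncated at the ends.
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - w %/% 2L, 1L)
  hi <- pmin(seq_len(n) + (w - w %/% 2L) - 1L, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Per-group mean metagene profiles
#'
#' @param matrix A `signal_matrix`.
#' @param assignment Optional cluster assignment data.frame (anchor_id,
#'   cluster); omitted means one group of all rows.
#' @return data.frame: group, rel_pos (bin 5'-most relative coordinate),
#'   value (group mean), n (group size). Empty groups are omitted with a
#'   warning.
#' @export
metagene_profile <- function(matrix, assignment = NULL) {
  m <- unclass(matrix)
  if (is.null(assignment)) {
    groups <- stats::setNames(rep("all", nrow(m)), rownames(m))
  } else {
    groups <- stats::setNames(as.character(assignment$cluster),
                              assignment$anchor_id)[rownames(m)]
    if (anyNA(groups)) {
      warning(sum(is.na(groups)), " row(s) without a group; dropped")
      m <- m[!is.na(groups), , drop = FALSE]
      groups <- groups[!is.na(groups)]
    }
  }
  rel <- as.integer(colnames(m))
  rows <- lapply(sort(unique(groups)), function(g) {
    sub <- m[groups == g, , drop = FALSE]
    data.frame(group = g, rel_pos = rel, value = colMeans(sub),
               n = nrow(sub), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
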