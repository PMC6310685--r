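# TSS-seq 5'-end tracks, windowed TSS quantification, cluster calling with
# mode peaks, and anchor-to-nearest-TSS distance statistics.
#
# A "tss_track" is a data.frame (chrom, strand, pos, signal) holding sparse
# per-base 5'-end signal in reads-per-million units, with attribute
# `mapped_total` (raw mapped-read count behind the scaling).

#' @import data.table
NULL

#' Build a per-million 5'-end track from TSS-seq reads
#'
#' `signal[chrom, strand, pos] = n_reads * 1e6 / total_mapped_reads`.
#'
#' @param reads data.frame (chrom, pos, strand) from [extract_tss_reads()].
#' @return A `tss_track` data.frame, sorted by (chrom, strand, pos).
#' @export
build_5p_tracks <- function(reads) {
  total <- nrow(reads)
  if (total == 0) stop("zero mapped reads; cannot scale to per-million")
  dt <- data.table::as.data.table(reads)
  agg <- dt[, list(n = .N), by = c("chrom", "strand", "pos")]
  agg[, "signal" := agg$n * 1e6 / total]
  data.table::setorderv(agg, c("chrom", "strand", "pos"))
  out <- as.data.frame(agg[, c("chrom", "strand", "pos", "signal")])
  attr(out, "mapped_total") <- total
  class(out) <- c("tss_track", "data.frame")
  out
}

#' Average replicate 5'-end tracks position-wise
#'
#' Positions absent from a replicate contribute 0, so the merged signal at
#' each base is the arithmetic mean of the per-million replicate signals.
#'
#' @param tracks List of `tss_track` objects.
#' @return A merged `tss_track`; `mapped_total` is the replicate sum.
#' @export
merge_replicate_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  n <- length(tracks)
  dt <- data.table::rbindlist(lapply(tracks, function(t) {
    data.table::as.data.table(t[, c("chrom", "strand", "pos", "signal")])
  }))
  agg <- dt[, list(signal = sum(signal) / n), by = c("chrom", "strand", "pos")]
  data.table::setorderv(agg, c("chrom", "strand", "pos"))
  out <- as.data.frame(agg)
  attr(out, "mapped_total") <- sum(vapply(tracks, function(t) {
    as.numeric(attr(t, "mapped_total") %||% NA_real_)
  }, numeric(1)))
  class(out) <- c("tss_track", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantify TSS-seq reads around annotated TSSs
#'
#' Counts reads whose 5' base lies within `flank` bp (inclusive) of each
#' annotated TSS on the same strand; also returns per-million values.
#'
#' @param reads data.frame (chrom, pos, strand).
#' @param annotated_tss data.frame (tss_id, chrom, pos, strand).
#' @param flank Window half-width, bp (the counting window spans
#'   `2 * flank + 1` bases).
#' @return list: `counts` (named integer), `per_million` (named numeric),
#'   `mapped_total`.
#' @export
quantify_tss_windows <- function(reads, annotated_tss, flank = 75L) {
  stopifnot(all(c("tss_id", "chrom", "pos", "strand") %in% names(annotated_tss)))
  total <- nrow(reads)
  wins <- data.frame(chrom = annotated_tss$chrom,
                     start = annotated_tss$pos - as.integer(flank),
                     end = annotated_tss$pos + as.integer(flank) + 1L,
                     strand = annotated_tss$strand)
  ov <- as_stranded_granges(wins)
  self_hits <- GenomicRanges::countOverlaps(ov, ov, ignore.strand = FALSE) > 1L
  if (any(self_hits)) {
    message(sum(self_hits), " TSS window(s) overlap another on the same ",
            "strand; shared reads are counted in each")
  }
  pts <- data.frame(chrom = reads$chrom, start = reads$pos,
                    end = reads$pos + 1L, strand = reads$strand)
  counts <- count_overlaps_stranded(pts, wins)
  names(counts) <- annotated_tss$tss_id
  list(counts = counts,
       per_million = counts * 1e6 / total,
       mapped_total = total)
}

#' Call TSS clusters and their mode peaks from a 5'-end track
#'
#' Positions with signal at least `min_signal` are grouped per chromosome
#' and strand whenever consecutive kept positions are at most `max_gap` bp
#' apart. The mode is the position of maximum signal; ties go to the
#' position closest to the cluster midpoint, then to the lowest coordinate.
#'
#' @param track A `tss_track`.
#' @param min_signal Minimum per-million signal for a position to seed or
#'   join a cluster.
#' @param max_gap Maximum distance between consecutive kept positions
#'   within one cluster, bp.
#' @return data.frame: chrom, strand, start, end (0-based half-open over
#'   kept positions), mode_pos, mode_height, total_signal, n_positions.
#' @export
call_tss_clusters <- function(track, min_signal = 1.0, max_gap = 25L) {
  stopifnot(min_signal > 0, max_gap >= 0)
  kept <- track[track$signal >= min_signal, , drop = FALSE]
  if (nrow(kept) == 0) {
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      mode_pos = integer(), mode_height = numeric(),
                      total_signal = numeric(), n_positions = integer(),
                      stringsAsFactors = FALSE))
  }
  kept <- kept[order(kept$chrom, kept$strand, kept$pos), , drop = FALSE]
  key <- paste(kept$chrom, kept$strand)
  new_grp <- c(TRUE, key[-1] != key[-length(key)] |
                 diff(kept$pos) > max_gap)
  grp <- cumsum(new_grp)
  rows <- lapply(split(seq_len(nrow(kept)), grp), function(idx) {
    sub <- kept[idx, , drop = FALSE]
    mid <- (min(sub$pos) + max(sub$pos)) / 2
    best <- which(sub$signal == max(sub$signal))
    if (length(best) > 1) {
      d <- abs(sub$pos[best] - mid)
      best <- best[d == min(d)]
      best <- best[which.min(sub$pos[best])]
    }
    data.frame(chrom = sub$chrom[1], strand = sub$strand[1],
               start = min(sub$pos), end = max(sub$pos) + 1L,
               mode_pos = sub$pos[best], mode_height = sub$signal[best],
               total_signal = sum(sub$signal), n_positions = nrow(sub),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distance from each promoter anchor to its nearest (cryptic) TSS cluster
#'
#' For each promoter anchor the nearest cluster mode on either strand is
#' found, excluding clusters whose mode falls within `mask_flank` bp of the
#' paired gene's own annotated TSS on the gene strand (the canonical coding
#' start is not a cryptic TSS). Distances are signed in gene-coding
#' orientation: positive toward the gene body, negative on the divergent
#' (upstream) side. Equidistant candidates prefer the antisense strand.
#'
#' @param clusters Cluster data.frame from [call_tss_clusters()], both
#'   strands.
#' @param promoters Promoter pairing from [pair_promoters()].
#' @param max_search Maximum |mode - anchor| considered, bp.
#' @param mask_flank Half-width of the coding-TSS exclusion zone, bp.
#' @return data.frame: site_id, gene_id, mode_pos, cluster_strand,
#'   distance, orientation; anchors with no cluster in range have NA
#'   distance and orientation `"none"`.
#' @export
nearest_tss_distance <- function(clusters, promoters, max_search = 500L,
                                 mask_flank = 75L) {
  rows <- lapply(seq_len(nrow(promoters)), function(i) {
    p <- promoters[i, ]
    cand <- clusters[clusters$chrom == p$chrom, , drop = FALSE]
    if (nrow(cand)) {
      masked <- cand$strand == p$gene_strand &
        abs(cand$mode_pos - p$gene_tss) <= mask_flank
      cand <- cand[!masked, , drop = FALSE]
    }
    if (nrow(cand)) {
      d_abs <- abs(cand$mode_pos - p$site_pos)
      cand <- cand[d_abs <= max_search, , drop = FALSE]
      d_abs <- d_abs[d_abs <= max_search]
    }
    if (!nrow(cand)) {
      return(data.frame(site_id = p$site_id, gene_id = p$gene_id,
                        mode_pos = NA_integer_, cluster_strand = NA_character_,
                        distance = NA_integer_, orientation = "none",
                        stringsAsFactors = FALSE))
    }
    anti <- cand$strand != p$gene_strand
    ord <- order(d_abs, !anti, cand$mode_pos)
    pick <- cand[ord[1], ]
    signed <- if (p$gene_strand == "+") pick$mode_pos - p$site_pos else
      p$site_pos - pick$mode_pos
    data.frame(site_id = p$site_id, gene_id = p$gene_id,
               mode_pos = pick$mode_pos, cluster_strand = pick$strand,
               distance = as.integer(signed),
               orientation = if (anti[ord[1]]) "antisense" else "sense",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Histogram of anchor-to-TSS distances in fixed-width bins
#'
#' Bins are half-open `[k*bin_width, (k+1)*bin_width)`, so a distance of
#' -1 falls in `[-bin_width, 0)` and 0 in `[0, bin_width)`.
#'
#' @param distances data.frame from [nearest_tss_distance()] or a numeric
#'   vector of distances.
#' @param bin_width Bin width, bp.
#' @return data.frame: orientation (when available), bin_start, bin_end,
#'   count. NA distances (no detected TSS) are excluded, so counts sum to
#'   the number of anchors with a detected TSS.
#' @export
histogram_distances <- function(distances, bin_width = 50L) {
  stopifnot(bin_width > 0)
  if (is.data.frame(distances)) {
    keep <- !is.na(distances$distance)
    d <- distances$distance[keep]
    ori <- distances$orientation[keep]
  } else {
    d <- distances[!is.na(distances)]
    ori <- rep("all", length(d))
  }
  if (!length(d)) {
    return(data.frame(orientation = character(), bin_start = integer(),
                      bin_end = integer(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  bin <- floor(d / bin_width) * bin_width
  tab <- as.data.frame(table(orientation = ori, bin_start = bin),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  out <- data.frame(orientation = tab$orientation,
                    bin_start = as.integer(tab$bin_start),
                    bin_end = as.integer(tab$bin_start) + as.integer(bin_width),
                    count = as.integer(tab$Freq),
                    stringsAsFactors = FALSE)
  out[order(out$orientation, out$bin_start), , drop = FALSE]
}

#' Differential TSS signal in anchor windows, depth-normalized
#'
#' TSS-window counts are normalized by sequencing depth (size factor
#' proportional to each sample's mapped-read total, centered at geometric
#' mean 1), then passed through the fold-change estimator and the
#' strict log2FC > threshold increase rule.
#'
#' @param tss_window_counts Integer matrix, windows x samples.
#' @param depths Named mapped-read totals per sample.
#' @param design Named sample -> `"ref"`/`"alt"`.
#' @param pseudocount,threshold Passed to the estimator/classifier.
#' @param windows Optional window annotation.
#' @return As [classify_increased()].
#' @export
differential_tss <- function(tss_window_counts, depths, design,
                             pseudocount = 1.0, threshold = 1.0,
                             windows = NULL) {
  samples <- colnames(tss_window_counts)
  if (!all(samples %in% names(depths))) {
    stop("depths missing sample(s): ",
         paste(setdiff(samples, names(depths)), collapse = ", "))
  }
  d <- depths[samples]
  factors <- stats::setNames(d / exp(mean(log(d))), samples)
  fc <- window_fold_changes(tss_window_counts, factors, design,
                            pseudocount = pseudocount, windows = windows)
  classify_increased(fc, threshold = threshold)
}

#' Write a 5'-end track as bedGraph (one strand)
#'
#' 4-column bedGraph, 0-based half-open, per-million signal.
#'
#' @param track A `tss_track`.
#' @param path Output path.
#' @param strand `"+"` or `"-"`.
#' @export
write_tss_bedgraph <- function(track, path, strand) {
  sub <- track[track$strand == strand, , drop = FALSE]
  df <- data.frame(sub$chrom, sub$pos, sub$pos + 1L, sub$signal)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
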