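# Shared fixtures: in-code SAM record builders, random counting instances,
# and naive oracles that the fast implementations are checked against.

CHROM_SIZES_1 <- c(chrT = 100000L)

sam_rec <- function(qname, flag, chrom, pos, mapq = 60L, cigar = "76M",
                    mrnm = "*", mpos = 0L, isize = 0L, rlen = 76L,
                    tags = "NH:i:1\tNM:i:0") {
  data.frame(qname = qname, flag = as.integer(flag), chrom = chrom,
             pos = as.integer(pos), mapq = as.integer(mapq), cigar = cigar,
             mrnm = mrnm, mpos = as.integer(mpos), isize = as.integer(isize),
             seq = strrep("N", rlen), qual = strrep("I", rlen), tags = tags,
             stringsAsFactors = FALSE)
}

# One proper read pair covering the 0-based fragment [start0, start0 + len).
# tx_strand is the transcript strand under the reverse-stranded convention
# (first-in-pair aligns opposite the transcript).
sam_pair <- function(qname, chrom, start0, len, tx_strand, rlen = 76L,
                     mapq = 60L, nh = 1L, nm = 0L, proper = TRUE,
                     cigar1 = NULL, cigar2 = NULL, extra_flag1 = 0L) {
  rlen <- min(rlen, len)
  pos_l <- start0 + 1L
  pos_r <- start0 + len - rlen + 1L
  base <- if (proper) 0x1L + 0x2L else 0x1L
  tags <- sprintf("NH:i:%d\tNM:i:%d", nh, nm)
  cg <- sprintf("%dM", rlen)
  if (tx_strand == "+") {
    f1 <- base + 0x10L + 0x40L + extra_flag1   # first mate on -, at right
    f2 <- base + 0x20L + 0x80L
    rbind(sam_rec(qname, f1, chrom, pos_r, mapq, cigar1 %||NA% cg, "=",
                  pos_l, -len, rlen, tags),
          sam_rec(qname, f2, chrom, pos_l, mapq, cigar2 %||NA% cg, "=",
                  pos_r, len, rlen, tags))
  } else {
    f1 <- base + 0x20L + 0x40L + extra_flag1   # first mate on +, at left
    f2 <- base + 0x10L + 0x80L
    rbind(sam_rec(qname, f1, chrom, pos_l, mapq, cigar1 %||NA% cg, "=",
                  pos_r, len, rlen, tags),
          sam_rec(qname, f2, chrom, pos_r, mapq, cigar2 %||NA% cg, "=",
                  pos_l, -len, rlen, tags))
    }
}

`%||NA%` <- function(a, b) if (is.null(a)) b else a

write_sam_fixture <- function(records, chrom_sizes = CHROM_SIZES_1) {
  path <- tempfile(fileext = ".sam")
  write_sam(records, chrom_sizes, path)
  path
}

# Naive O(F * W) strand-aware overlap scan: the counting contract.
bf_count_windows <- function(fragments, windows) {
  vapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    sum(fragments$chrom == w$chrom & fragments$strand == w$strand &
          fragments$start < w$end & fragments$end > w$start)
  }, numeric(1))
}

random_fragments <- function(n, chroms = c("chrA", "chrB"), len = 100000L) {
  start <- sample.int(len - 600L, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample(50:500, n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

random_windows <- function(n, chroms = c("chrA", "chrB"), len = 100000L,
                           w = 100L) {
  pos <- sample.int(len - 2L * w - 2000L, n, replace = TRUE) + 1000L
  sites <- data.frame(site_id = sprintf("s%04d", seq_len(n)),
                      chrom = sample(chroms, n, replace = TRUE),
                      pos = pos, start = pos, end = pos + 1L,
                      stringsAsFactors = FALSE)
  build_stranded_windows(sites, w)
}

# Sparse random 5'-end track for cluster-calling oracles.
random_track <- function(n_pos, len = 10000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(chrom = "chrT",
                   strand = sample(c("+", "-"), n_pos, replace = TRUE),
                   pos = sample.int(len, n_pos),
                   signal = stats::runif(n_pos, 0.1, 10))
  df <- df[!duplicated(df[, c("chrom", "strand", "pos")]), ]
  df <- df[order(df$chrom, df$strand, df$pos), ]
  rownames(df) <- NULL
  attr(df, "mapped_total") <- n_pos
  class(df) <- c("tss_track", "data.frame")
  df
}

# Naive linear-scan cluster caller used as oracle.
bf_clusters <- function(track, min_signal, max_gap) {
  kept <- track[track$signal >= min_signal, , drop = FALSE]
  out <- NULL
  for (ch in unique(kept$chrom)) for (st in c("+", "-")) {
    sub <- kept[kept$chrom == ch & kept$strand == st, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    if (!nrow(sub)) next
    cur <- sub[1, , drop = FALSE]
    flush <- function(block) {
      mx <- max(block$signal)
      cand <- block$pos[block$signal == mx]
      mid <- (min(block$pos) + max(block$pos)) / 2
      cand <- cand[abs(cand - mid) == min(abs(cand - mid))]
      data.frame(chrom = ch, strand = st, start = min(block$pos),
                 end = max(block$pos) + 1L, mode_pos = min(cand),
                 mode_height = mx, total_signal = sum(block$signal),
                 n_positions = nrow(block), stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$pos[i] - sub$pos[i - 1] <= max_gap) {
        cur <- rbind(cur, sub[i, ])
      } else {
        out <- rbind(out, flush(cur))
        cur <- sub[i, , drop = FALSE]
      }
    }
    out <- rbind(out, flush(cur))
  }
  out <- out[order(out$chrom, out$strand, out$start), ]
  rownames(out) <- NULL
  out
}
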