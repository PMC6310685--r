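test_that("5'-end tracks scale to reads per million", {
  reads <- data.frame(chrom = "chrT", pos = c(10L, 10L, 50L, 80L),
                      strand = c("+", "+", "+", "-"))
  tr <- build_5p_tracks(reads)
  expect_equal(tr$signal[tr$pos == 10L], 5e5)
  expect_equal(sum(tr$signal), 1e6)
  # per-strand totals carry the strand read share
  expect_equal(sum(tr$signal[tr$strand == "+"]), 1e6 * 3 / 4)

  uniform <- data.frame(chrom = "chrT", pos = 1:10, strand = "+")
  tu <- build_5p_tracks(uniform)
  expect_true(all(tu$signal == 1e5))
  expect_error(build_5p_tracks(uniform[0, ]), "zero mapped")
})

test_that("replicate merging is the position-wise mean with absent = 0", {
  t1 <- build_5p_tracks(data.frame(chrom = "chrT", pos = c(5L, 9L),
                                   strand = "+"))
  merged_same <- merge_replicate_tracks(list(t1, t1, t1))
  expect_equal(merged_same$signal, t1$signal)
  expect_equal(merged_same$pos, t1$pos)

  # two replicates see a position at 300 per-million, one does not
  mk <- function(sig_at_5) {
    df <- data.frame(chrom = "chrT", pos = 5L, strand = "+",
                     signal = sig_at_5)
    class(df) <- c("tss_track", "data.frame")
    attr(df, "mapped_total") <- 1L
    df
  }
  m <- merge_replicate_tracks(list(mk(300), mk(300), mk(300)[0, ]))
  expect_equal(m$signal, 200)

  set.seed(71)
  tracks <- lapply(1:3, function(i) random_track(50, seed = 70 + i))
  m3 <- merge_replicate_tracks(tracks)
  # dense-vector oracle
  key <- unique(do.call(rbind, lapply(tracks, function(t)
    t[, c("chrom", "strand", "pos")])))
  for (k in sample(nrow(key), 10)) {
    vals <- vapply(tracks, function(t) {
      hit <- t$strand == key$strand[k] & t$pos == key$pos[k]
      if (any(hit)) t$signal[hit] else 0
    }, numeric(1))
    got <- m3$signal[m3$strand == key$strand[k] & m3$pos == key$pos[k]]
    expect_equal(got, mean(vals))
  }
})

test_that("TSS windows count 5' bases within +-flank inclusive, same strand", {
  ann <- data.frame(tss_id = "t1", chrom = "chrT", pos = 1000L, strand = "+")
  reads <- data.frame(chrom = "chrT",
                      pos = c(1075L, 1076L, 925L, 924L, 1000L, 1000L),
                      strand = c("+", "+", "+", "+", "+", "-"))
  q <- quantify_tss_windows(reads, ann, flank = 75L)
  # 1075 (+75, inclusive), 925 (-75) and 1000 count; 1076/924 and the
  # opposite-strand read do not
  expect_equal(unname(q$counts), 3L)

  set.seed(72)
  ann2 <- data.frame(tss_id = sprintf("t%02d", 1:20), chrom = "chrT",
                     pos = sample(2000:90000, 20),
                     strand = sample(c("+", "-"), 20, replace = TRUE))
  reads2 <- data.frame(chrom = "chrT", pos = sample.int(95000L, 2000,
                                                        replace = TRUE),
                       strand = sample(c("+", "-"), 2000, replace = TRUE))
  q2 <- quantify_tss_windows(reads2, ann2)
  oracle <- vapply(seq_len(20), function(i) {
    sum(reads2$strand == ann2$strand[i] &
          abs(reads2$pos - ann2$pos[i]) <= 75L)
  }, numeric(1))
  expect_equal(unname(q2$counts), as.integer(oracle))
  expect_equal(q2$per_million, q2$counts * 1e6 / nrow(reads2))
})

test_that("cluster calling groups by gap and picks the documented mode", {
  tr <- data.frame(chrom = "chrT", strand = "+",
                   pos = c(100L, 101L, 130L), signal = c(5, 2, 7))
  class(tr) <- c("tss_track", "data.frame")
  cl <- call_tss_clusters(tr, min_signal = 1, max_gap = 25L)
  expect_equal(nrow(cl), 2L)  # gap 29 > 25 splits
  expect_equal(cl$mode_pos, c(100L, 130L))
  expect_equal(cl$total_signal, c(7, 7))

  single <- tr[3, , drop = FALSE]
  class(single) <- c("tss_track", "data.frame")
  c1 <- call_tss_clusters(single, 1, 25L)
  expect_equal(c1$start, 130L)
  expect_equal(c1$end, 131L)
  expect_equal(c1$mode_pos, 130L)

  # tie on height: position closest to the cluster midpoint wins
  tie <- data.frame(chrom = "chrT", strand = "+", pos = c(10L, 11L, 14L),
                    signal = c(3, 3, 3))
  class(tie) <- c("tss_track", "data.frame")
  expect_equal(call_tss_clusters(tie, 1, 5L)$mode_pos, 11L)
})

test_that("cluster calling equals the naive linear-scan reference", {
  for (s in 1:4) {
    tr <- random_track(150, len = 3000L, seed = 80 + s)
    got <- call_tss_clusters(tr, min_signal = 2, max_gap = 10L)
    want <- bf_clusters(tr, 2, 10L)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[order(got$strand, got$start), ],
                 want[order(want$strand, want$start), ],
                 ignore_attr = TRUE)
    # conservation: cluster totals sum the member signals
    expect_equal(sum(got$total_signal), sum(tr$signal[tr$signal >= 2]))
  }
})

promoter_row <- function(strand = "+", tss = 1200L, site = 1000L) {
  data.frame(gene_id = "g1", site_id = "s1", chrom = "chrT",
             gene_strand = strand, gene_tss = tss, site_pos = site,
             distance = site - tss, stringsAsFactors = FALSE)
}

test_that("nearest TSS distances are signed in gene-coding orientation", {
  cl <- data.frame(chrom = "chrT", strand = "-", start = 960L, end = 961L,
                   mode_pos = 960L, mode_height = 5, total_signal = 5,
                   n_positions = 1L)
  nd <- nearest_tss_distance(cl, promoter_row("+"))
  expect_equal(nd$distance, -40L)  # upstream of the anchor, divergent side
  expect_equal(nd$orientation, "antisense")

  # mirrored gene: same genomic offset flips sign
  cl2 <- cl; cl2$strand <- "+"; cl2$mode_pos <- 1040L
  cl2$start <- 1040L; cl2$end <- 1041L
  nd2 <- nearest_tss_distance(cl2, promoter_row("-", tss = 800L))
  expect_equal(nd2$distance, -40L)
  expect_equal(nd2$orientation, "antisense")
})

test_that("equidistant clusters prefer antisense; coding TSS is masked", {
  both <- data.frame(chrom = "chrT", strand = c("+", "-"),
                     start = c(960L, 1040L), end = c(961L, 1041L),
                     mode_pos = c(960L, 1040L), mode_height = c(5, 5),
                     total_signal = c(5, 5), n_positions = 1L)
  nd <- nearest_tss_distance(both, promoter_row("+"))
  expect_equal(nd$cluster_strand, "-")
  expect_equal(nd$orientation, "antisense")

  # a cluster at the paired gene's own coding TSS is not a cryptic TSS
  coding <- data.frame(chrom = "chrT", strand = "+", start = 1210L,
                       end = 1211L, mode_pos = 1210L, mode_height = 9,
                       total_signal = 9, n_positions = 1L)
  nd2 <- nearest_tss_distance(coding, promoter_row("+"))
  expect_equal(nd2$orientation, "none")
  expect_true(is.na(nd2$distance))

  # out of range -> none
  far <- coding; far$mode_pos <- 3000L; far$strand <- "-"
  nd3 <- nearest_tss_distance(far, promoter_row("+"), max_search = 500L)
  expect_equal(nd3$orientation, "none")
})

test_that("distance histograms use half-open 50-bp bins and conserve counts", {
  d <- data.frame(site_id = c("a", "b", "c", "d"), gene_id = "g",
                  mode_pos = 0L, cluster_strand = "-",
                  distance = c(-1L, 0L, -50L, NA),
                  orientation = c("antisense", "antisense", "sense", "none"))
  h <- histogram_distances(d, 50L)
  anti <- h[h$orientation == "antisense", ]
  expect_equal(sum(h$count), 3L)  # the NA (undetected) anchor is excluded
  expect_equal(h$bin_start[h$orientation == "sense"], -50L)
  expect_equal(anti$bin_start, c(-50L, 0L))
  expect_equal(anti$count, c(1L, 1L))
})

test_that("differential TSS normalizes by sequencing depth", {
  counts <- matrix(c(10L, 20L, 10L, 20L, 20L, 40L, 20L, 40L), nrow = 2,
                   dimnames = list(c("w1", "w2"),
                                   c("r1", "r2", "a1", "a2")))
  design <- c(r1 = "ref", r2 = "ref", a1 = "alt", a2 = "alt")
  equal_depth <- c(r1 = 1e6, r2 = 1e6, a1 = 1e6, a2 = 1e6)
  res <- classify_res <- differential_tss(counts, equal_depth, design,
                                          pseudocount = 0)
  expect_equal(res$table$log2fc, c(1, 1))
  expect_true(all(res$table$increased == FALSE))  # strict > 1

  # doubled counts at doubled depth: no real change
  dbl_depth <- c(r1 = 1e6, r2 = 1e6, a1 = 2e6, a2 = 2e6)
  res2 <- differential_tss(counts, dbl_depth, design, pseudocount = 0)
  expect_equal(res2$table$log2fc, c(0, 0), tolerance = 1e-12)

  # equal counts but doubled alt depth: apparent decrease ~ -1
  eq_counts <- matrix(rep(c(10L, 20L), 4), nrow = 2,
                      dimnames = dimnames(counts))
  res3 <- differential_tss(eq_counts, dbl_depth, design, pseudocount = 0)
  expect_equal(res3$table$log2fc, c(-1, -1), tolerance = 1e-12)
})
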