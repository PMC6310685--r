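mk_track <- function(df) {
  class(df) <- c("tss_track", "data.frame")
  df
}

test_that("signal matrices bin point signal by relative position", {
  anchors <- data.frame(site_id = "a1", chrom = "chrT", pos = 5000L)
  tr <- mk_track(data.frame(chrom = "chrT", strand = "+", pos = 5003L,
                            signal = 7))
  sm <- build_signal_matrix(tr, anchors, flank = 500L, bin_size = 5L)
  expect_equal(ncol(sm), 200L)
  expect_equal(unname(sm[1, "0"]), 7)  # bin [0, 5) holds the point at +3
  expect_equal(sum(sm), 7)

  sm10 <- build_signal_matrix(tr, anchors, flank = 500L, bin_size = 10L)
  expect_equal(ncol(sm10), 100L)
})

test_that("binning matches a naive per-bin summation and conserves signal", {
  set.seed(91)
  anchors <- data.frame(site_id = c("a1", "a2"), chrom = "chrT",
                        pos = c(3000L, 7000L))
  tr <- mk_track(data.frame(chrom = "chrT",
                            strand = sample(c("+", "-"), 300, replace = TRUE),
                            pos = sample(2000:8000, 300),
                            signal = runif(300, 0.5, 5)))
  sm <- build_signal_matrix(tr, anchors, flank = 400L, bin_size = 20L)
  for (i in 1:2) {
    rel <- tr$pos - anchors$pos[i]
    keep <- rel >= -400L & rel < 400L
    oracle <- tapply(tr$signal[keep], (rel[keep] + 400L) %/% 20L, sum)
    got <- unname(sm[i, ])
    expect_equal(got[as.integer(names(oracle)) + 1L], as.numeric(oracle))
    expect_equal(sum(got), sum(tr$signal[keep]))
  }
})

test_that("gene-oriented frames mirror bins for minus-strand genes", {
  anchors <- data.frame(site_id = c("p", "m"), chrom = "chrT",
                        pos = c(2000L, 6000L))
  prom <- data.frame(gene_id = c("gp", "gm"), site_id = c("p", "m"),
                     chrom = "chrT", gene_strand = c("+", "-"),
                     gene_tss = c(2200L, 5800L), site_pos = c(2000L, 6000L),
                     distance = 0L)
  # signal 35 bp upstream of each anchor (divergent side in both cases)
  tr <- mk_track(data.frame(chrom = "chrT", strand = c("-", "+"),
                            pos = c(1965L, 6035L), signal = c(4, 4)))
  sm <- build_signal_matrix(tr, anchors, flank = 100L, bin_size = 5L,
                            frame = "gene", promoters = prom)
  expect_equal(unname(sm["p", "-35"]), 4)
  expect_equal(unname(sm["m", "-35"]), 4)

  # antisense strand selection keeps only the divergent-strand signal
  sm_as <- build_signal_matrix(tr, anchors, flank = 100L, bin_size = 5L,
                               frame = "gene", promoters = prom,
                               strand_sel = "antisense")
  expect_equal(sum(sm_as), 8)
  sm_s <- build_signal_matrix(tr, anchors, flank = 100L, bin_size = 5L,
                              frame = "gene", promoters = prom,
                              strand_sel = "sense")
  expect_equal(sum(sm_s), 0)
})

test_that("anchors too near a chromosome end are dropped with a warning", {
  anchors <- data.frame(site_id = c("edge", "ok"), chrom = "chrT",
                        pos = c(100L, 5000L))
  tr <- mk_track(data.frame(chrom = "chrT", strand = "+", pos = 4990L,
                            signal = 1))
  expect_warning(
    sm <- build_signal_matrix(tr, anchors, flank = 500L, bin_size = 10L,
                              chrom_sizes = c(chrT = 100000L)),
    "chromosome end")
  expect_equal(rownames(sm), "ok")
})

test_that("difference matrices subtract element-wise and check frames", {
  set.seed(92)
  anchors <- data.frame(site_id = sprintf("a%d", 1:3), chrom = "chrT",
                        pos = c(2000L, 4000L, 6000L))
  mk <- function(seed) {
    set.seed(seed)
    mk_track(data.frame(chrom = "chrT", strand = "+",
                        pos = sample(1000:7000, 200),
                        signal = runif(200, 0, 3)))
  }
  alt <- build_signal_matrix(mk(1), anchors, 200L, 10L)
  ref <- build_signal_matrix(mk(2), anchors, 200L, 10L)
  d <- difference_matrix(alt, ref)
  expect_equal(unclass(d), unclass(alt) - unclass(ref), ignore_attr = TRUE)
  expect_equal(unname(unclass(difference_matrix(alt, alt))),
               matrix(0, 3, 40), ignore_attr = TRUE)
  zero <- build_signal_matrix(mk_track(mk(2)[0, ]), anchors, 200L, 10L)
  expect_equal(unclass(difference_matrix(alt, zero)), unclass(alt),
               ignore_attr = TRUE)

  attr(ref, "frame") <- "gene"
  expect_error(difference_matrix(alt, ref), "frame mismatch")
})

test_that("k-means recovers planted archetypes and is deterministic", {
  skip_if_not_installed("mclust")
  set.seed(93)
  centers <- c(10, 5, 0)
  m <- do.call(rbind, lapply(centers, function(cc) {
    matrix(cc + rnorm(30 * 20, sd = 1), nrow = 30)
  }))
  rownames(m) <- sprintf("r%03d", seq_len(nrow(m)))
  colnames(m) <- seq(-100, 90, by = 10)
  truth <- rep(1:3, each = 30)
  km <- kmeans_cluster(m, k = 3, seed = 17)
  expect_gte(mclust::adjustedRandIndex(km$assignment$cluster, truth), 0.9)
  # relabeling: cluster 1 is the strongest archetype
  expect_gt(mean(m[km$assignment$cluster == 1, ]),
            mean(m[km$assignment$cluster == 3, ]))
  km2 <- kmeans_cluster(m, k = 3, seed = 17)
  expect_identical(km$assignment, km2$assignment)

  # duplicating every row preserves the partition structure
  dup <- rbind(m, m)
  rownames(dup) <- sprintf("d%03d", seq_len(nrow(dup)))
  kmd <- kmeans_cluster(dup, k = 3, seed = 17)
  first <- kmd$assignment$cluster[1:90]
  second <- kmd$assignment$cluster[91:180]
  expect_equal(first, second)
  expect_gte(mclust::adjustedRandIndex(first, km$assignment$cluster), 0.99)
})

test_that("k == number of rows puts each row in its own cluster", {
  m <- matrix(c(0, 0, 5, 5, 9, 9), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("-10", "0")))
  km <- kmeans_cluster(m, k = 3, seed = 1)
  expect_equal(sort(km$assignment$cluster), 1:3)
  expect_equal(km$kmeans$tot.withinss, 0)
  expect_error(kmeans_cluster(m[c(1, 1, 1), ], k = 3, seed = 1), "distinct")
})

test_that("MNase coverage extends midpoints, smooths, and scales", {
  sizes <- c(chrT = 3000L)
  one <- data.frame(chrom = "chrT", start = 920L, end = 1080L,
                    midpoint = 1000L)
  cov_raw <- mnase_coverage(one, sizes, extend = 40L, smooth_width = 1L,
                            scale_count = 1)
  expect_equal(sum(cov_raw$chrT > 0), 40L)
  expect_equal(unname(cov_raw$chrT[981:1020]), rep(1, 40))  # [980, 1020)
  expect_equal(cov_raw$chrT[980], 0)
  expect_equal(cov_raw$chrT[1021], 0)

  two <- rbind(one, one)
  cov2 <- mnase_coverage(two, sizes, extend = 40L, smooth_width = 1L,
                         scale_count = 2)
  expect_equal(cov2$chrT, 2 * cov_raw$chrT)

  # smoothed + scaled track equals the naive accumulation oracle
  set.seed(94)
  frags <- data.frame(chrom = "chrT", midpoint = sample(200:2800, 150,
                                                        replace = TRUE))
  frags$start <- frags$midpoint - 80L
  frags$end <- frags$midpoint + 80L
  cov <- mnase_coverage(frags, sizes, extend = 40L, smooth_width = 20L,
                        scale_count = 1e6)
  naive <- numeric(3000)
  for (m_ in frags$midpoint) {
    idx <- (m_ - 20L):(m_ + 19L) + 1L
    naive[idx] <- naive[idx] + 1
  }
  sm <- vapply(seq_len(3000), function(i) {
    lo <- max(i - 10L, 1L); hi <- min(i + 9L, 3000L)
    mean(naive[lo:hi])
  }, numeric(1))
  expect_equal(cov$chrT, sm * 1e6 / nrow(frags))
})

test_that("metagene profiles are per-group column means", {
  m <- matrix(rep(c(1, 2, 3, 4), each = 4), nrow = 4, byrow = TRUE)
  rownames(m) <- c("a", "b", "c", "d")
  colnames(m) <- c("-20", "-10", "0", "10")
  same <- metagene_profile(m[c(1, 1), , drop = FALSE])
  expect_equal(same$value, rep(1, 4))
  asn <- data.frame(anchor_id = c("a", "b", "c", "d"),
                    cluster = c(1L, 1L, 2L, 2L))
  prof <- metagene_profile(m, asn)
  expect_equal(prof$value[prof$group == "1"], rep(1.5, 4))
  expect_equal(prof$value[prof$group == "2"], rep(3.5, 4))
  expect_equal(prof$rel_pos[prof$group == "1"], c(-20L, -10L, 0L, 10L))
})

test_that("a planted NDR produces a metagene minimum at the anchor", {
  cfg <- sim_config(seed = 9, n_genes = 16L, n_chroms = 1L,
                    chrom_length = 160000L, mnase_fragments = 40000L)
  ann <- generate_annotation(cfg)
  p <- tempfile(fileext = ".sam")
  simulate_mnase(cfg, ann, 1L, p)
  mf <- filter_mnase_fragments(p)$fragments
  cov <- mnase_coverage(mf, ann$chrom_sizes)
  sm <- build_signal_matrix(cov, ann$sites, flank = 500L, bin_size = 10L)
  prof <- metagene_profile(sm)
  min_pos <- prof$rel_pos[which.min(prof$value)]
  expect_lte(abs(min_pos - 0L), 10L)  # within one bin of the anchor
})
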