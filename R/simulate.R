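# Ground-truthed synthetic data: a toy genome of promoter units, each with
# a coding gene, a binding-site anchor upstream of its TSS, and a divergent
# noncoding transcription unit on the opposite strand upstream of the
# anchor whose initiation rate is multiplied by a planted fold change in
# the "alt" (factor-depleted) condition. Generators emit plain-text SAM
# and are pure functions of (config, condition, sample index).

#' Simulation configuration
#'
#' Rates are expected fragment (or TSS read) counts per transcription unit
#' per sample at library scale 1; per-sample library scales multiply them.
#'
#' @param seed Master integer seed; every generator derives its stream
#'   deterministically from it.
#' @param n_chroms,chrom_length Genome shape.
#' @param n_genes Total genes, tiled across chromosomes on alternating
#'   strands.
#' @param gene_length Coding-unit length, bp.
#' @param anchor_offset Anchor distance upstream of the gene TSS, bp.
#' @param divergent_tss_offset Divergent TSS distance upstream of the
#'   anchor (opposite strand), bp.
#' @param divergent_length Divergent-unit length, bp.
#' @param coding_rate Expected RNA-seq fragments per gene.
#' @param divergent_baseline Expected RNA-seq fragments per divergent unit
#'   in the reference condition.
#' @param depletion_fold Rate multiplier for affected divergent units in
#'   the alt condition.
#' @param fraction_affected Fraction of sites planted with the fold
#'   (exactly `round(fraction * n_genes)` sites, chosen from the seed).
#' @param n_replicates Replicates per condition.
#' @param library_scales Per-replicate library-size multipliers (recycled).
#' @param frag_len_mean,frag_len_sd,frag_len_range Fragment-length model
#'   (normal, truncated to the range and to the unit length).
#' @param read_length RNA-seq mate length, bp.
#' @param tss_coding_rate,tss_divergent_rate Expected TSS-seq reads per
#'   coding / divergent TSS (reference condition; same fold model).
#' @param tss_jitter_sd SD of the integer jitter around each planted TSS,
#'   bp.
#' @param tss_read_length TSS-seq read length, bp.
#' @param mnase_fragments Total MNase fragment pairs per sample.
#' @param ndr_depth,ndr_sd Depth (0..1) and width (Gaussian SD, bp) of the
#'   nucleosome-depleted dip planted at each anchor.
#' @param overdispersion Gamma-Poisson overdispersion for unit counts
#'   (0 = pure Poisson).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 200000L,
                       n_genes = 20L, gene_length = 1000L,
                       anchor_offset = 200L, divergent_tss_offset = 35L,
                       divergent_length = 300L,
                       coding_rate = 100, divergent_baseline = 50,
                       depletion_fold = 4, fraction_affected = 0.4,
                       n_replicates = 3L,
                       library_scales = c(1.0, 0.8, 1.25),
                       frag_len_mean = 250, frag_len_sd = 50,
                       frag_len_range = c(100L, 500L),
                       read_length = 76L,
                       tss_coding_rate = 100, tss_divergent_rate = 50,
                       tss_jitter_sd = 2, tss_read_length = 76L,
                       mnase_fragments = 100000L,
                       ndr_depth = 0.9, ndr_sd = 60,
                       overdispersion = 0) {
  cfg <- as.list(environment())
  stopifnot(cfg$seed == as.integer(cfg$seed),
            cfg$n_chroms >= 1, cfg$chrom_length > 0, cfg$n_genes >= 1,
            cfg$coding_rate > 0, cfg$divergent_baseline > 0,
            cfg$depletion_fold > 0,
            cfg$fraction_affected >= 0, cfg$fraction_affected <= 1,
            cfg$n_replicates >= 1, all(cfg$library_scales > 0),
            cfg$frag_len_range[1] > 0,
            cfg$frag_len_range[2] >= cfg$frag_len_range[1],
            cfg$tss_jitter_sd >= 0, cfg$ndr_depth >= 0, cfg$ndr_depth <= 1,
            cfg$overdispersion >= 0)
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic per-stream seed below 2^31.
derive_seed <- function(seed, stage, condition = "ref", sample_index = 0L) {
  stage_id <- match(stage, c("annotation", "rnaseq", "tss", "mnase"))
  cond_id <- match(condition, c("ref", "alt"))
  as.integer((as.numeric(seed) * 7919 + stage_id * 104729 +
                cond_id * 1299709 + sample_index * 15485863) %% 2147483647)
}

lib_scale_for <- function(config, sample_index) {
  sc <- config$library_scales
  sc[((sample_index - 1L) %% length(sc)) + 1L]
}

#' Generate the synthetic annotation and truth table
#'
#' Genes are tiled in non-overlapping slots (alternating strands) with the
#' anchor `anchor_offset` bp upstream of each gene TSS and the divergent
#' TSS `divergent_tss_offset` bp upstream of the anchor on the opposite
#' strand. Exactly `round(fraction_affected * n_genes)` sites carry the
#' planted fold.
#'
#' @param config A `sim_config`.
#' @return list: `chrom_sizes` (named integer), `genes`, `sites`,
#'   `divergent` (unit table), `truth` (site_id, gene_id, fold,
#'   divergent_tss, divergent_strand, coding_rate, divergent_baseline).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  margin <- 1000L
  n_per <- ceiling(config$n_genes / config$n_chroms)
  slot <- (config$chrom_length - 2L * margin) %/% n_per
  need <- config$gene_length + config$anchor_offset +
    config$divergent_tss_offset + config$divergent_length + 100L
  if (slot < need) {
    stop("infeasible tiling: need chrom_length >= ",
         2L * margin + n_per * need)
  }
  chrom_sizes <- stats::setNames(rep(as.integer(config$chrom_length),
                                     config$n_chroms),
                                 paste0("chr", seq_len(config$n_chroms)))
  idx <- seq_len(config$n_genes)
  chrom_i <- ((idx - 1L) %/% n_per) + 1L
  slot_i <- (idx - 1L) %% n_per
  base <- margin + slot_i * slot
  strand <- ifelse(idx %% 2L == 1L, "+", "-")
  up_span <- config$anchor_offset + config$divergent_tss_offset +
    config$divergent_length
  gstart <- ifelse(strand == "+", base + up_span, base)
  gend <- gstart + config$gene_length
  tss <- ifelse(strand == "+", gstart, gend - 1L)
  anchor <- ifelse(strand == "+", tss - config$anchor_offset,
                   tss + config$anchor_offset)
  dtss <- ifelse(strand == "+", anchor - config$divergent_tss_offset,
                 anchor + config$divergent_tss_offset)
  dstrand <- ifelse(strand == "+", "-", "+")
  dstart <- ifelse(dstrand == "+", dtss, dtss - config$divergent_length + 1L)
  dend <- dstart + config$divergent_length

  genes <- data.frame(gene_id = sprintf("gene%04d", idx),
                      chrom = paste0("chr", chrom_i),
                      start = as.integer(gstart), end = as.integer(gend),
                      strand = strand, tss = as.integer(tss),
                      stringsAsFactors = FALSE)
  sites <- data.frame(site_id = sprintf("site%04d", idx),
                      chrom = genes$chrom, pos = as.integer(anchor),
                      start = as.integer(anchor), end = as.integer(anchor) + 1L,
                      stringsAsFactors = FALSE)
  divergent <- data.frame(unit_id = sprintf("div%04d", idx),
                          chrom = genes$chrom,
                          start = as.integer(dstart), end = as.integer(dend),
                          strand = dstrand, tss = as.integer(dtss),
                          stringsAsFactors = FALSE)
  set.seed(derive_seed(config$seed, "annotation"))
  n_affected <- round(config$fraction_affected * config$n_genes)
  affected <- sort(sample(idx, n_affected))
  fold <- rep(1, config$n_genes)
  fold[affected] <- config$depletion_fold
  truth <- data.frame(site_id = sites$site_id, gene_id = genes$gene_id,
                      fold = fold,
                      divergent_tss = divergent$tss,
                      divergent_strand = divergent$strand,
                      coding_rate = config$coding_rate,
                      divergent_baseline = config$divergent_baseline,
                      stringsAsFactors = FALSE)
  list(chrom_sizes = chrom_sizes, genes = genes, sites = sites,
       divergent = divergent, truth = truth)
}

unit_counts <- function(rates, scale, overdispersion) {
  lambda <- rates * scale
  if (overdispersion > 0) {
    lambda <- lambda * stats::rgamma(length(lambda),
                                     shape = 1 / overdispersion,
                                     scale = overdispersion)
  }
  stats::rpois(length(lambda), lambda)
}

#' Simulate one paired-end reverse-stranded RNA-seq sample (SAM)
#'
#' Fragment counts per unit are Poisson (optionally gamma-Poisson) with
#' rate `coding_rate` for genes and `divergent_baseline * fold` (alt
#' condition, affected sites) for divergent units, times the sample's
#' library scale. Fragment starts are uniform within the unit; lengths are
#' truncated-normal. Mate flags encode a proper, reverse-stranded pair;
#' records carry MAPQ 60 and NH:i:1 so they pass the QC filters.
#'
#' @param config A `sim_config`.
#' @param annotation From [generate_annotation()].
#' @param condition `"ref"` or `"alt"`.
#' @param sample_index Replicate index (1-based).
#' @param path Output .sam path.
#' @return list: `path`, `n_fragments`, `sample_id`.
#' @export
simulate_rnaseq <- function(config, annotation, condition, sample_index,
                            path) {
  condition <- match.arg(condition, c("ref", "alt"))
  set.seed(derive_seed(config$seed, "rnaseq", condition, sample_index))
  scale <- lib_scale_for(config, sample_index)
  g <- annotation$genes
  d <- annotation$divergent
  fold <- if (condition == "alt") annotation$truth$fold else
    rep(1, nrow(annotation$truth))
  units <- data.frame(
    unit_id = c(g$gene_id, d$unit_id),
    chrom = c(g$chrom, d$chrom),
    start = c(g$start, d$start), end = c(g$end, d$end),
    strand = c(g$strand, d$strand),
    rate = c(rep(config$coding_rate, nrow(g)),
             config$divergent_baseline * fold),
    stringsAsFactors = FALSE)
  n <- unit_counts(units$rate, scale, config$overdispersion)
  u <- rep(seq_len(nrow(units)), n)
  total <- length(u)
  if (total == 0) {
    write_sam(data.frame(), annotation$chrom_sizes, path)
    return(list(path = path, n_fragments = 0L,
                sample_id = paste0("rna_", condition, sample_index)))
  }
  ulen <- units$end[u] - units$start[u]
  L <- round(stats::rnorm(total, config$frag_len_mean, config$frag_len_sd))
  L <- pmin(pmax(L, config$frag_len_range[1]), config$frag_len_range[2])
  L <- pmin(L, ulen)
  s <- units$start[u] + floor(stats::runif(total) * (ulen - L + 1))
  rlen <- pmin(config$read_length, L)
  ts <- units$strand[u]
  pos_left <- as.integer(s + 1L)              # 1-based leftmost mate
  pos_right <- as.integer(s + L - rlen + 1L)  # 1-based rightmost mate start
  cig <- sprintf("%dM", rlen)
  seqs <- strrep("N", rlen)
  qual <- strrep("I", rlen)
  qname <- sprintf("rna_%s%d_%07d", condition, sample_index, seq_len(total))
  plus_tx <- ts == "+"
  # reverse-stranded: first-in-pair aligns opposite the transcript strand
  r1 <- data.frame(qname = qname,
                   flag = ifelse(plus_tx, 83L, 99L),
                   chrom = units$chrom[u],
                   pos = ifelse(plus_tx, pos_right, pos_left),
                   mapq = 60L, cigar = cig, mrnm = "=",
                   mpos = ifelse(plus_tx, pos_left, pos_right),
                   isize = ifelse(plus_tx, -L, L),
                   seq = seqs, qual = qual, tags = "NH:i:1\tNM:i:0",
                   stringsAsFactors = FALSE)
  r2 <- data.frame(qname = qname,
                   flag = ifelse(plus_tx, 163L, 147L),
                   chrom = units$chrom[u],
                   pos = ifelse(plus_tx, pos_left, pos_right),
                   mapq = 60L, cigar = cig, mrnm = "=",
                   mpos = ifelse(plus_tx, pos_right, pos_left),
                   isize = ifelse(plus_tx, L, -L),
                   seq = seqs, qual = qual, tags = "NH:i:1\tNM:i:0",
                   stringsAsFactors = FALSE)
  write_sam(rbind(r1, r2), annotation$chrom_sizes, path)
  invisible(list(path = path, n_fragments = total,
                 sample_id = paste0("rna_", condition, sample_index)))
}

#' Simulate one single-end TSS-seq sample (SAM)
#'
#' Each read's 5' base is a planted TSS plus integer Gaussian jitter; the
#' read strand is the transcript strand. Counts follow the same rate/fold
#' model as RNA-seq with the TSS-specific rates.
#'
#' @inheritParams simulate_rnaseq
#' @return list: `path`, `n_reads`, `sample_id`.
#' @export
simulate_tss_seq <- function(config, annotation, condition, sample_index,
                             path) {
  condition <- match.arg(condition, c("ref", "alt"))
  set.seed(derive_seed(config$seed, "tss", condition, sample_index))
  scale <- lib_scale_for(config, sample_index)
  g <- annotation$genes
  d <- annotation$divergent
  fold <- if (condition == "alt") annotation$truth$fold else
    rep(1, nrow(annotation$truth))
  units <- data.frame(
    chrom = c(g$chrom, d$chrom),
    tss = c(g$tss, d$tss),
    strand = c(g$strand, d$strand),
    rate = c(rep(config$tss_coding_rate, nrow(g)),
             config$tss_divergent_rate * fold),
    stringsAsFactors = FALSE)
  n <- unit_counts(units$rate, scale, config$overdispersion)
  u <- rep(seq_len(nrow(units)), n)
  total <- length(u)
  if (total == 0) {
    write_sam(data.frame(), annotation$chrom_sizes, path)
    return(list(path = path, n_reads = 0L,
                sample_id = paste0("tss_", condition, sample_index)))
  }
  p5 <- units$tss[u] +
    as.integer(round(stats::rnorm(total, 0, config$tss_jitter_sd)))
  rlen <- config$tss_read_length
  plus <- units$strand[u] == "+"
  pos1 <- ifelse(plus, p5 + 1L, p5 - rlen + 2L)  # 1-based alignment start
  rec <- data.frame(qname = sprintf("tss_%s%d_%07d", condition, sample_index,
                                    seq_len(total)),
                    flag = ifelse(plus, 0L, 16L),
                    chrom = units$chrom[u],
                    pos = as.integer(pos1),
                    mapq = 60L, cigar = sprintf("%dM", rlen),
                    mrnm = "*", mpos = 0L, isize = 0L,
                    seq = strrep("N", rlen), qual = strrep("I", rlen),
                    tags = "NH:i:1", stringsAsFactors = FALSE)
  write_sam(rec, annotation$chrom_sizes, path)
  invisible(list(path = path, n_reads = total,
                 sample_id = paste0("tss_", condition, sample_index)))
}

#' Simulate one paired-end MNase-seq sample (SAM) with NDR dips at anchors
#'
#' Fragment midpoints follow a genome-uniform background thinned by a
#' Gaussian depletion of depth `ndr_depth` and SD `ndr_sd` centered on
#' every anchor; insert sizes are uniform on [120, 200].
#'
#' @inheritParams simulate_rnaseq
#' @return list: `path`, `n_fragments`, `sample_id`.
#' @export
simulate_mnase <- function(config, annotation, sample_index, path) {
  set.seed(derive_seed(config$seed, "mnase", "ref", sample_index))
  n_target <- config$mnase_fragments
  sizes <- annotation$chrom_sizes
  margin <- 300L
  anchors_by_chrom <- split(annotation$sites$pos, annotation$sites$chrom)
  mids <- integer(0); chroms <- character(0)
  while (length(mids) < n_target) {
    batch <- max(2L * (n_target - length(mids)), 1000L)
    ci <- sample.int(length(sizes), batch, replace = TRUE,
                     prob = as.numeric(sizes))
    m <- margin + floor(stats::runif(batch) *
                          (as.numeric(sizes[ci]) - 2 * margin))
    keep_p <- rep(1, batch)
    for (ch in names(anchors_by_chrom)) {
      sel <- names(sizes)[ci] == ch
      if (!any(sel)) next
      a <- anchors_by_chrom[[ch]]
      j <- findInterval(m[sel], a)
      d_lo <- abs(m[sel] - a[pmax(j, 1L)])
      d_hi <- abs(m[sel] - a[pmin(j + 1L, length(a))])
      dmin <- pmin(d_lo, d_hi)
      keep_p[sel] <- 1 - config$ndr_depth *
        exp(-dmin^2 / (2 * config$ndr_sd^2))
    }
    acc <- stats::runif(batch) < keep_p
    mids <- c(mids, as.integer(m[acc]))
    chroms <- c(chroms, names(sizes)[ci[acc]])
  }
  mids <- mids[seq_len(n_target)]
  chroms <- chroms[seq_len(n_target)]
  L <- as.integer(floor(stats::runif(n_target, 120, 201)))
  s <- mids - L %/% 2L
  rlen <- 50L
  pos_left <- s + 1L
  pos_right <- s + L - rlen + 1L
  qname <- sprintf("mn_%d_%07d", sample_index, seq_len(n_target))
  r1 <- data.frame(qname = qname, flag = 99L, chrom = chroms,
                   pos = pos_left, mapq = 60L,
                   cigar = sprintf("%dM", rlen), mrnm = "=",
                   mpos = pos_right, isize = L,
                   seq = strrep("N", rlen), qual = strrep("I", rlen),
                   tags = "NH:i:1\tNM:i:0", stringsAsFactors = FALSE)
  r2 <- data.frame(qname = qname, flag = 147L, chrom = chroms,
                   pos = pos_right, mapq = 60L,
                   cigar = sprintf("%dM", rlen), mrnm = "=",
                   mpos = pos_left, isize = -L,
                   seq = strrep("N", rlen), qual = strrep("I", rlen),
                   tags = "NH:i:1\tNM:i:0", stringsAsFactors = FALSE)
  write_sam(rbind(r1, r2), sizes, path)
  invisible(list(path = path, n_fragments = n_target,
                 sample_id = paste0("mnase_", sample_index)))
}

#' Export the synthetic annotation as plain-text files
#'
#' Writes chrom.sizes, anchors BED, gene table TSV, truth TSV and a config
#' echo for provenance.
#'
#' @param config A `sim_config`.
#' @param annotation From [generate_annotation()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
export_annotation <- function(config, annotation, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(chrom_sizes = file.path(dir, "chrom.sizes"),
             anchors = file.path(dir, "anchors.bed"),
             genes = file.path(dir, "genes.tsv"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.txt"))
  utils::write.table(data.frame(names(annotation$chrom_sizes),
                                as.integer(annotation$chrom_sizes)),
                     paths["chrom_sizes"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  s <- annotation$sites
  utils::write.table(data.frame(s$chrom, s$start, s$end, s$site_id),
                     paths["anchors"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  g <- annotation$genes
  utils::write.table(g[, c("gene_id", "chrom", "start", "end", "strand")],
                     paths["genes"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(annotation$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  flat <- vapply(unclass(config), function(x) paste(x, collapse = ","),
                 character(1))
  writeLines(sprintf("%s: %s", names(flat), flat), paths["config"])
  paths
}
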