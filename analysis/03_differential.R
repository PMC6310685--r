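#!/usr/bin/env Rscript
# Transcriptome-normalized fold changes per window, the >2-fold increase
# classification, fractions by window size / strand / orientation / site,
# and box-plot style distribution summaries.

source(file.path("analysis", "00_config.R"))

read_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

gene_counts <- read_counts(res_path("gene_counts.tsv"))
size_factors <- compute_size_factors(gene_counts)
write_tsv(data.frame(sample = names(size_factors),
                     size_factor = as.numeric(size_factors)),
          res_path("size_factors.tsv"),
          "median-of-ratios size factors over the gene-level counts")
message("size factors: ",
        paste(sprintf("%s=%.3f", names(size_factors), size_factors),
              collapse = ", "))

all_fracs <- NULL; all_summ <- NULL
for (w in WINDOW_SIZES) {
  wc <- read_counts(res_path(sprintf("window_counts_w%d.tsv", w)))
  win_bed <- utils::read.table(res_path(sprintf("windows_w%d.bed", w)),
                               sep = "\t")
  # recover window annotation from the BED sidecar ids (anchor:strand)
  win <- data.frame(window_id = win_bed$V4,
                    anchor = sub(":(plus|minus)$", "", win_bed$V4),
                    strand = win_bed$V6, w = w)
  truth <- utils::read.table(file.path(SIM_DIR, "truth.tsv"), header = TRUE,
                             sep = "\t")
  gene_strand <- utils::read.table(file.path(SIM_DIR, "genes.tsv"),
                                   sep = "\t")$V5
  win$orientation <- ifelse(win$strand ==
                              gene_strand[match(win$anchor, truth$site_id)],
                            "sense", "antisense")
  fc <- window_fold_changes(wc, size_factors, DESIGN, windows = win)
  cl <- classify_increased(fc, threshold = 1.0)
  write_tsv(cl$table, res_path(sprintf("fold_changes_w%d.tsv", w)),
            "log2 fold changes alt/ref, normalized means, pseudocount 1")
  fr <- cl$fractions; fr$w <- w
  all_fracs <- rbind(all_fracs, fr)
  sm <- summarize_distribution(fc$log2fc, fc$orientation); sm$w <- w
  all_summ <- rbind(all_summ, sm)
  site_fr <- fr$fraction_increased[fr$grouping == "site_level"]
  message(sprintf("w=%d: %.1f%% of sites increased >2-fold", w,
                  100 * site_fr))
}
write_tsv(all_fracs, res_path("increased_fractions.tsv"),
          "fraction of features with log2FC > 1, by grouping and window size")
write_tsv(all_summ, res_path("log2fc_distributions.tsv"),
          "box-plot summaries of log2FC by orientation and window size")
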