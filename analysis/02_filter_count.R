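#!/usr/bin/env Rscript
# QC-filter the RNA-seq alignments and count fragments in strand-separated
# windows around every anchor (w = 50/100/200/500) plus gene bodies for
# transcriptome normalization. Writes count matrices and a QC summary.

source(file.path("analysis", "00_config.R"))

sizes <- read_chrom_sizes(file.path(SIM_DIR, "chrom.sizes"))
sites <- load_binding_sites(file.path(SIM_DIR, "anchors.bed"), sizes)
genes <- read_gene_table(file.path(SIM_DIR, "genes.tsv"))
sites <- filter_chrom_end_sites(sites, sizes, margin = 500L)
prom <- pair_promoters(genes, sites)

frags <- list(); qc_rows <- NULL
for (id in SAMPLE_IDS) {
  res <- filter_rnaseq_fragments(sam_path("rna", id))
  frags[[id]] <- res$fragments
  qc_rows <- rbind(qc_rows,
                   data.frame(sample = id, rule = res$qc$rule,
                              n_failed = res$qc$n_failed,
                              n_fragments = attr(res$qc, "n_fragments")))
  message(id, ": ", nrow(res$fragments), " QC-passing fragments")
}
write_tsv(qc_rows, res_path("rnaseq_qc.tsv"),
          "per-rule rejected record counts per sample")

gene_counts <- assemble_count_matrix(
  lapply(frags, count_gene_level, genes = genes), "gene")
write_count_matrix(gene_counts, res_path("gene_counts.tsv"))

for (w in WINDOW_SIZES) {
  win <- assign_orientation(build_stranded_windows(sites, w, sizes), prom)
  wc <- assemble_count_matrix(
    lapply(frags, count_fragments_in_windows, windows = win), "window")
  write_count_matrix(wc, res_path(sprintf("window_counts_w%d.tsv", w)))
  write_windows_bed(win, res_path(sprintf("windows_w%d.bed", w)))
}
message("count matrices written under ", RES_DIR)
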