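#!/usr/bin/env Rscript
# TSS-seq: per-million 5'-end tracks, replicate-merged tracks per
# condition, TSS cluster calling, anchor-to-nearest-TSS distances with the
# 50-bp histogram, and depth-normalized differential TSS signal in +-50 bp
# anchor windows.

source(file.path("analysis", "00_config.R"))

sizes <- read_chrom_sizes(file.path(SIM_DIR, "chrom.sizes"))
sites <- load_binding_sites(file.path(SIM_DIR, "anchors.bed"), sizes)
genes <- read_gene_table(file.path(SIM_DIR, "genes.tsv"))
prom <- pair_promoters(genes, sites)

reads <- list(); depths <- c()
for (id in SAMPLE_IDS) {
  r <- extract_tss_reads(sam_path("tss", id))
  reads[[id]] <- r$reads
  depths[id] <- nrow(r$reads)
}
tracks <- lapply(reads, build_5p_tracks)
merged <- lapply(CONDITIONS, function(cond) {
  merge_replicate_tracks(tracks[DESIGN == cond])
})
names(merged) <- CONDITIONS
for (cond in CONDITIONS) for (st in c("+", "-")) {
  f <- res_path(sprintf("tss_%s_%s.bedgraph", cond,
                        if (st == "+") "plus" else "minus"))
  write_tss_bedgraph(merged[[cond]], f, st)
}

clusters <- call_tss_clusters(merged$alt, min_signal = 1, max_gap = 25L)
write_tsv(clusters, res_path("tss_clusters_alt.tsv"),
          "TSS clusters on the merged depleted-condition track")
nd <- nearest_tss_distance(clusters, prom)
write_tsv(nd, res_path("nearest_tss_distances.tsv"),
          "signed distance anchor -> nearest cryptic TSS mode, gene-coding orientation")
det <- nd[!is.na(nd$distance), ]
message(sprintf("nearest TSS detected at %d/%d anchors; %.0f%% antisense; median distance %d bp",
                nrow(det), nrow(nd),
                100 * mean(det$orientation == "antisense"),
                as.integer(stats::median(det$distance))))
write_tsv(histogram_distances(nd, 50L), res_path("tss_distance_histogram.tsv"),
          "50-bp half-open bins of anchor-to-TSS distances")

win50 <- assign_orientation(build_stranded_windows(sites, 50L, sizes), prom)
tss_counts <- assemble_count_matrix(lapply(reads, function(r) {
  pts <- data.frame(chrom = r$chrom, start = r$pos, end = r$pos + 1L,
                    strand = r$strand)
  count_fragments_in_windows(pts, win50)
}), "tss_window")
diff <- differential_tss(tss_counts, depths, DESIGN, windows = win50)
write_tsv(diff$table, res_path("tss_fold_changes_w50.tsv"),
          "depth-normalized TSS-seq log2FC in +-50 bp anchor windows")
site_fr <- diff$fractions$fraction_increased[
  diff$fractions$grouping == "site_level"]
message(sprintf("%.1f%% of promoters show >2-fold increased TSS signal within 50 bp",
                100 * site_fr))
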