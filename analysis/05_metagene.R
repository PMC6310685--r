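#!/usr/bin/env Rscript
# Anchor-centered heatmaps and metagenes: TSS-seq difference matrix
# (alt - ref, 5-bp bins, gene-oriented), k-means clustering (k = 3) of the
# antisense RNA change profiles, and the MNase-seq metagene per cluster.

source(file.path("analysis", "00_config.R"))

sizes <- read_chrom_sizes(file.path(SIM_DIR, "chrom.sizes"))
sites <- load_binding_sites(file.path(SIM_DIR, "anchors.bed"), sizes)
genes <- read_gene_table(file.path(SIM_DIR, "genes.tsv"))
prom <- pair_promoters(genes, sites)

## TSS-seq difference heatmap (5-bp bins, antisense strand, gene frame)
reads <- lapply(SAMPLE_IDS, function(id) extract_tss_reads(sam_path("tss", id))$reads)
names(reads) <- SAMPLE_IDS
tracks <- lapply(reads, build_5p_tracks)
tss_mat <- lapply(CONDITIONS, function(cond) {
  merged <- merge_replicate_tracks(tracks[DESIGN == cond])
  build_signal_matrix(merged, sites, flank = 500L, bin_size = 5L,
                      frame = "gene", promoters = prom,
                      strand_sel = "antisense", chrom_sizes = sizes)
})
names(tss_mat) <- CONDITIONS
tss_diff <- difference_matrix(tss_mat$alt, tss_mat$ref)
write_tsv(data.frame(anchor_id = rownames(tss_diff),
                     as.data.frame(unclass(tss_diff), check.names = FALSE)),
          res_path("tss_difference_heatmap_antisense.tsv"),
          "TSS-seq signal difference alt - ref, 5-bp bins, gene-oriented frame")

## RNA change profiles on the antisense strand, clustered with k-means
frags <- lapply(SAMPLE_IDS, function(id)
  filter_rnaseq_fragments(sam_path("rna", id))$fragments)
names(frags) <- SAMPLE_IDS
rna_mat <- lapply(CONDITIONS, function(cond) {
  ids <- names(DESIGN)[DESIGN == cond]
  covs <- lapply(ids, function(id) {
    lapply(c("+", "-"), function(st)
      build_signal_matrix(
        fragment_coverage(frags[[id]], sizes, strand = st),
        sites, flank = 500L, bin_size = 10L, frame = "gene",
        promoters = prom, chrom_sizes = sizes))
  })
  # antisense selection per anchor: pick the strand opposite the gene
  g_str <- prom$gene_strand[match(sites$site_id, prom$site_id)]
  per_id <- lapply(covs, function(two) {
    plus <- unclass(two[[1]]); minus <- unclass(two[[2]])
    out <- plus
    out[g_str == "+", ] <- minus[g_str == "+", ]
    out
  })
  Reduce(`+`, per_id) / length(per_id)
})
names(rna_mat) <- CONDITIONS
rna_change <- rna_mat$alt - rna_mat$ref
km <- kmeans_cluster(rna_change, k = 3L, seed = SEED)
write_tsv(km$assignment, res_path("antisense_clusters.tsv"),
          "k-means (k = 3) clusters of antisense RNA change profiles; 1 = strongest")
message("cluster sizes: ",
        paste(table(km$assignment$cluster), collapse = " / "),
        " (mean change ",
        paste(sprintf("%.2f", km$ordering_stat), collapse = " / "), ")")

## MNase metagene per cluster
mn <- filter_mnase_fragments(sam_path("mnase", "1"))$fragments
cov <- mnase_coverage(mn, sizes)
mn_mat <- build_signal_matrix(cov, sites, flank = 500L, bin_size = 10L,
                              frame = "gene", promoters = prom,
                              chrom_sizes = sizes)
prof <- metagene_profile(mn_mat, km$assignment)
write_tsv(prof, res_path("mnase_metagene_by_cluster.tsv"),
          "mean smoothed MNase occupancy per antisense cluster, gene-oriented")
overall <- metagene_profile(mn_mat)
message("NDR minimum at ", overall$rel_pos[which.min(overall$value)],
        " bp from the anchor")
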