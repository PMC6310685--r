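#!/usr/bin/env Rscript
# Generate the synthetic genome, annotation, and all sequencing samples:
# RNA-seq and TSS-seq for ref/alt x 3 replicates, plus one MNase-seq
# sample. Ground truth and annotation are exported as plain text.

source(file.path("analysis", "00_config.R"))

ann <- generate_annotation(CFG)
paths <- export_annotation(CFG, ann, SIM_DIR)
message("annotation: ", nrow(ann$genes), " genes / ", nrow(ann$sites),
        " anchors on ", length(ann$chrom_sizes), " chromosomes; ",
        sum(ann$truth$fold > 1), " sites planted at fold ",
        CFG$depletion_fold)

for (id in SAMPLE_IDS) {
  cond <- DESIGN[[id]]
  rep_i <- as.integer(sub("^(ref|alt)", "", id))
  r <- simulate_rnaseq(CFG, ann, cond, rep_i, sam_path("rna", id))
  t <- simulate_tss_seq(CFG, ann, cond, rep_i, sam_path("tss", id))
  message(sprintf("sample %s: %d RNA fragments, %d TSS reads",
                  id, r$n_fragments, t$n_reads))
}
m <- simulate_mnase(CFG, ann, 1L, sam_path("mnase", "1"))
message("MNase sample: ", m$n_fragments, " fragment pairs")
message("SAM files under ", SIM_DIR)
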