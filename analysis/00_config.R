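# Shared configuration for the analysis drivers (sourced by 01-05).
# The study design: two conditions (ref = factor present, alt = factor
# depleted) x three replicates, 200 promoter anchors, 40% of sites planted
# with a 4-fold increase in divergent initiation upon depletion.

library(divtx)

SEED <- 42L
SIM_DIR <- file.path("scratch", "analysis", "sim")
RES_DIR <- file.path("results", "analysis")
dir.create(SIM_DIR, recursive = TRUE, showWarnings = FALSE)
dir.create(RES_DIR, recursive = TRUE, showWarnings = FALSE)

CFG <- sim_config(seed = SEED, n_genes = 200L, n_chroms = 4L,
                  chrom_length = 200000L, coding_rate = 60,
                  divergent_baseline = 250, depletion_fold = 4,
                  fraction_affected = 0.4, n_replicates = 3L,
                  tss_coding_rate = 80, tss_divergent_rate = 60,
                  mnase_fragments = 60000L)

CONDITIONS <- c("ref", "alt")
SAMPLE_IDS <- as.vector(outer(CONDITIONS, seq_len(CFG$n_replicates),
                              paste0))
DESIGN <- stats::setNames(rep(CONDITIONS, CFG$n_replicates), SAMPLE_IDS)
WINDOW_SIZES <- c(50L, 100L, 200L, 500L)

sam_path <- function(assay, id) file.path(SIM_DIR, sprintf("%s_%s.sam", assay, id))
res_path <- function(name) file.path(RES_DIR, name)

write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}
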