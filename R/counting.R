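# Strand-aware overlap counting of fragments in windows and gene bodies.
# A fragment contributes 1 to every same-strand feature it overlaps by at
# least 1 bp (featureCounts -O semantics), and at most 1 per feature.

as_stranded_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
}

count_overlaps_stranded <- function(fragments, features) {
  if (nrow(fragments) == 0) return(integer(nrow(features)))
  fg <- as_stranded_granges(fragments)
  fe <- as_stranded_granges(features)
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(fe, fg, minoverlap = 1L,
                                 ignore.strand = FALSE))
  as.integer(hits)
}

#' Count fragments overlapping stranded windows (one sample)
#'
#' @param fragments Fragment data.frame (chrom, start, end, strand),
#'   already QC-filtered.
#' @param windows Window data.frame from [build_stranded_windows()].
#' @return Named integer vector, one count per window (names = window_id).
#' @export
count_fragments_in_windows <- function(fragments, windows) {
  missing_chrom <- setdiff(unique(windows$chrom), unique(fragments$chrom))
  if (length(missing_chrom) && nrow(fragments)) {
    warning("no fragments on chromosome(s): ",
            paste(missing_chrom, collapse = ", "), "; zero counts emitted")
  }
  stats::setNames(count_overlaps_stranded(fragments, windows),
                  windows$window_id)
}

#' Count fragments over gene bodies (one sample)
#'
#' Union-gene-body stranded counting used to derive transcriptome size
#' factors; a fragment overlapping several genes counts in each.
#'
#' @param fragments Fragment data.frame.
#' @param genes Gene data.frame (see [read_gene_table()]).
#' @return Named integer vector (names = gene_id).
#' @export
count_gene_level <- function(fragments, genes) {
  ov <- as_stranded_granges(genes[, c("chrom", "start", "end", "strand")])
  self_ov <- GenomicRanges::countOverlaps(ov, ov, ignore.strand = FALSE) > 1L
  if (any(self_ov)) {
    message(sum(self_ov), " gene model(s) overlap another on the same ",
            "strand; shared fragments are counted in each")
  }
  stats::setNames(count_overlaps_stranded(fragments, genes), genes$gene_id)
}

#' Assemble per-sample count columns into a matrix
#'
#' @param columns Named list of per-sample named integer vectors with
#'   identical feature names in identical order.
#' @param feature_kind One of `"window"`, `"gene"`, `"tss_window"`.
#' @return Integer matrix (features x samples) with `feature_kind`
#'   attribute; column order follows the input list.
#' @export
assemble_count_matrix <- function(columns,
                                  feature_kind = c("window", "gene", "tss_window")) {
  feature_kind <- match.arg(feature_kind)
  stopifnot(length(columns) >= 1)
  ref <- names(columns[[1]])
  if (is.null(ref) || anyDuplicated(ref)) {
    stop("count columns must carry unique feature names")
  }
  for (j in seq_along(columns)) {
    nm <- names(columns[[j]])
    if (!identical(nm, ref)) {
      div <- c(setdiff(nm, ref), setdiff(ref, nm),
               nm[which(nm != ref)[1]])
      stop("feature mismatch between samples at feature: ",
           div[!is.na(div)][1])
    }
  }
  mat <- do.call(cbind, lapply(columns, as.integer))
  rownames(mat) <- ref
  colnames(mat) <- if (!is.null(names(columns))) names(columns) else
    paste0("sample", seq_along(columns))
  attr(mat, "feature_kind") <- feature_kind
  mat
}

#' Write a count matrix as TSV
#'
#' @param mat Count matrix from [assemble_count_matrix()].
#' @param path Output path.
#' @export
write_count_matrix <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
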