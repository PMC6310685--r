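# Transcriptome normalization and a transparent fold-change estimator.
# Size factors are median-of-ratios over genes with nonzero counts in every
# sample; fold changes are log2 ratios of normalized per-condition means
# with a pseudocount, and an increase is a strict log2FC > threshold.

#' Median-of-ratios size factors from a gene-level count matrix
#'
#' For each sample j, the factor is the median over genes g (restricted to
#' genes with nonzero counts in every sample) of
#' `counts[g, j] / geometric_mean(counts[g, ])`.
#'
#' @param gene_counts Integer matrix, genes x samples (>= 2 samples).
#' @return Named positive numeric vector, one factor per sample.
#' @export
compute_size_factors <- function(gene_counts) {
  stopifnot(is.matrix(gene_counts), ncol(gene_counts) >= 2)
  keep <- rowSums(gene_counts > 0) == ncol(gene_counts)
  if (!any(keep)) {
    stop("no gene has nonzero counts in every sample; ",
         "size factors are undefined (provide more features)")
  }
  m <- gene_counts[keep, , drop = FALSE]
  geo <- exp(rowMeans(log(m)))
  # median taken on the ratio scale (not the log scale): with an even
  # number of genes the interpolated midpoint differs between the two
  factors <- apply(m, 2, function(col) stats::median(col / geo))
  stats::setNames(as.numeric(factors), colnames(gene_counts))
}

#' Per-feature log2 fold changes between two conditions
#'
#' Counts are scaled by the size factors, averaged within condition, and
#' compared as `log2((mean_alt + pseudocount) / (mean_ref + pseudocount))`.
#'
#' @param window_counts Integer matrix, features x samples.
#' @param factors Named size factors covering every sample.
#' @param design Named character vector sample -> `"ref"`/`"alt"`.
#' @param pseudocount Added to both normalized means before the ratio.
#' @param windows Optional window data.frame; when given, `anchor`,
#'   `strand`, `orientation` and `w` are carried into the result.
#' @return data.frame with `feature_id`, `mean_norm_ref`, `mean_norm_alt`,
#'   `log2fc` (plus window annotation when available).
#' @export
window_fold_changes <- function(window_counts, factors, design,
                                pseudocount = 1.0, windows = NULL) {
  samples <- colnames(window_counts)
  if (is.null(samples)) stop("count matrix must have sample names")
  if (!all(samples %in% names(design))) {
    stop("design missing sample(s): ",
         paste(setdiff(samples, names(design)), collapse = ", "))
  }
  if (!all(samples %in% names(factors))) {
    stop("size factors missing sample(s): ",
         paste(setdiff(samples, names(factors)), collapse = ", "))
  }
  cond <- design[samples]
  if (!all(cond %in% c("ref", "alt"))) stop("design values must be 'ref' or 'alt'")
  if (!any(cond == "ref") || !any(cond == "alt")) {
    stop("each condition needs at least one sample")
  }
  norm <- sweep(window_counts, 2, factors[samples], "/")
  mean_ref <- rowMeans(norm[, cond == "ref", drop = FALSE])
  mean_alt <- rowMeans(norm[, cond == "alt", drop = FALSE])
  res <- data.frame(feature_id = rownames(window_counts),
                    mean_norm_ref = mean_ref, mean_norm_alt = mean_alt,
                    log2fc = log2((mean_alt + pseudocount) /
                                  (mean_ref + pseudocount)),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(windows)) {
    m <- match(res$feature_id, windows$window_id)
    res$anchor <- windows$anchor[m]
    res$strand <- windows$strand[m]
    res$orientation <- windows$orientation[m]
    res$w <- windows$w[m]
  }
  res
}

#' Classify increased features and summarize fractions
#'
#' A feature is increased when `log2fc > threshold` (strict). A site is
#' increased when either of its strand windows is. Fractions are reported
#' per strand, per orientation, and at site level.
#'
#' @param table Fold-change data.frame from [window_fold_changes()].
#' @param threshold log2 fold-change threshold (default 1: fold change 2).
#' @return list: `table` (input plus `increased`), `site_flags`
#'   (anchor-level OR, when anchors present), `fractions` (data.frame of
#'   grouping, group, n, fraction_increased).
#' @export
classify_increased <- function(table, threshold = 1.0) {
  table$increased <- table$log2fc > threshold
  fr <- list(data.frame(grouping = "all", group = "all",
                        n = nrow(table),
                        fraction_increased = mean(table$increased),
                        stringsAsFactors = FALSE))
  add_group <- function(grouping, values) {
    spl <- split(table$increased, values)
    data.frame(grouping = grouping, group = names(spl),
               n = lengths(spl),
               fraction_increased = vapply(spl, mean, numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  if (!is.null(table$strand)) fr <- c(fr, list(add_group("strand", table$strand)))
  if (!is.null(table$orientation)) {
    fr <- c(fr, list(add_group("orientation", table$orientation)))
  }
  if (!is.null(table$w)) fr <- c(fr, list(add_group("window_size", table$w)))
  site_flags <- NULL
  if (!is.null(table$anchor)) {
    site <- tapply(table$increased, table$anchor, any)
    site_flags <- data.frame(anchor = names(site),
                             increased = as.logical(site),
                             row.names = NULL, stringsAsFactors = FALSE)
    fr <- c(fr, list(data.frame(grouping = "site_level", group = "all",
                                n = nrow(site_flags),
                                fraction_increased = mean(site_flags$increased),
                                stringsAsFactors = FALSE)))
  }
  list(table = table, site_flags = site_flags,
       fractions = do.call(rbind, fr))
}

#' Box-plot style distribution summary per group
#'
#' Quartiles use linear interpolation; whiskers extend to the most extreme
#' observations within 1.5 x IQR of the hinges.
#'
#' @param values Numeric vector (e.g. log2 fold changes).
#' @param grouping Factor/character of the same length, or NULL for one group.
#' @return data.frame with group, n, mean, median, q1, q3, whisker_lo,
#'   whisker_hi. Empty groups are omitted with a warning.
#' @export
summarize_distribution <- function(values, grouping = NULL) {
  if (is.null(grouping)) grouping <- rep("all", length(values))
  grouping <- as.character(grouping)
  if (is.factor(grouping)) grouping <- as.character(grouping)
  spl <- split(values, grouping)
  empty <- vapply(spl, function(v) length(v) == 0 || all(is.na(v)), logical(1))
  if (any(empty)) {
    warning("empty group(s) omitted: ", paste(names(spl)[empty], collapse = ", "))
    spl <- spl[!empty]
  }
  rows <- lapply(names(spl), function(g) {
    v <- spl[[g]][!is.na(spl[[g]])]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo_bound <- q[1] - 1.5 * iqr
    hi_bound <- q[3] + 1.5 * iqr
    data.frame(group = g, n = length(v), mean = mean(v), median = q[2],
               q1 = q[1], q3 = q[3],
               whisker_lo = min(v[v >= lo_bound]),
               whisker_hi = max(v[v <= hi_bound]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
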