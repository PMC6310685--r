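# All coordinates inside the package are 0-based half-open (BED convention).
# 1-based formats (SAM, GTF) are converted at the boundary.

#' Read a chromosome-sizes table
#'
#' @param path Two-column TSV: chromosome name, length in bp.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "integer"))
  if (anyDuplicated(df$chrom)) stop("duplicated chromosome in ", path)
  if (any(df$length <= 0)) stop("non-positive chromosome length in ", path)
  stats::setNames(df$length, df$chrom)
}

#' Load binding-site anchors from a BED file
#'
#' Each BED interval becomes one anchor whose coordinate is the interval
#' midpoint, `floor((start + end) / 2)`. The source interval is retained.
#'
#' @param bed_path BED3+ file of binding-site intervals.
#' @param chrom_sizes Named integer vector (see [read_chrom_sizes()]).
#' @return data.frame with columns `site_id`, `chrom`, `pos` (0-based anchor
#'   coordinate), `start`, `end` (the source interval, 0-based half-open).
#' @export
load_binding_sites <- function(bed_path, chrom_sizes) {
  lines <- readLines(bed_path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line (fewer than 3 fields) at line ",
         which(nf < 3)[1], " of ", bed_path)
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad)) stop("malformed BED coordinates at line ", bad[1], " of ", bed_path)
  name <- if (all(nf >= 4)) vapply(fields, `[[`, character(1), 4L) else
    sprintf("site%05d", seq_along(chrom))
  unknown <- setdiff(unique(chrom), names(chrom_sizes))
  if (length(unknown)) {
    stop("unknown chromosome(s) in ", bed_path, ": ",
         paste(unknown, collapse = ", "))
  }
  if (any(end > chrom_sizes[chrom])) {
    stop("BED interval beyond chromosome end at line ",
         which(end > chrom_sizes[chrom])[1], " of ", bed_path)
  }
  if (anyDuplicated(name)) name <- make.unique(name, sep = "_")
  data.frame(site_id = name, chrom = chrom,
             pos = (start + end) %/% 2L,
             start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Read a gene table (5-column TSV) or GTF/GFF annotation
#'
#' The tabular form has columns gene_id, chrom, start, end, strand with
#' 0-based half-open coordinates. GTF/GFF input (detected by extension) is
#' read with rtracklayer and converted; `gene`-type records are used.
#'
#' @param path Gene table TSV or GTF/GFF file.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   and the strand-aware 5' end `tss` (start for `+`, end - 1 for `-`).
#' @export
read_gene_table <- function(path) {
  if (grepl("\\.(gtf|gff3?|gff)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("rtracklayer is required to read GTF/GFF input")
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    ids <- if (!is.null(gr$gene_id)) gr$gene_id else as.character(seq_along(gr))
    genes <- data.frame(gene_id = as.character(ids),
                        chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr) - 1L,
                        end = GenomicRanges::end(gr),
                        strand = as.character(GenomicRanges::strand(gr)),
                        stringsAsFactors = FALSE)
  } else {
    genes <- utils::read.table(path, sep = "\t", header = FALSE,
                               col.names = c("gene_id", "chrom", "start", "end", "strand"),
                               colClasses = c("character", "character", "integer",
                                              "integer", "character"))
  }
  validate_genes(genes)
}

validate_genes <- function(genes) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  if (any(genes$start >= genes$end)) stop("gene with start >= end")
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id")
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes
}

#' Drop anchors too close to a chromosome end
#'
#' Sites are retained when `pos >= margin` and `pos < length - margin`, so
#' that symmetric windows up to half-width `margin` stay on the chromosome.
#'
#' @param sites data.frame from [load_binding_sites()].
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param margin Distance from either chromosome end, bp.
#' @return The filtered site data.frame, input order preserved.
#' @export
filter_chrom_end_sites <- function(sites, chrom_sizes, margin = 500L) {
  stopifnot(margin >= 0)
  len <- chrom_sizes[sites$chrom]
  if (anyNA(len)) stop("site on chromosome absent from chrom_sizes")
  keep <- sites$pos >= margin & sites$pos < len - margin
  sites[keep, , drop = FALSE]
}

#' Build strand-separated counting windows around anchors
#'
#' Each anchor yields two windows `[pos - w, pos + w)`, one per strand, so
#' Watson- and Crick-strand signal is counted in separate intervals.
#'
#' @param sites Anchor data.frame; every site must survive
#'   [filter_chrom_end_sites()] with `margin >= w`.
#' @param w Window half-width, bp.
#' @param chrom_sizes Optional; when given, windows running past a
#'   chromosome end raise an error telling the caller to filter first.
#' @return data.frame with `window_id`, `chrom`, `start`, `end`, `strand`,
#'   `anchor`, `w`, `orientation` (initially `"unassigned"`).
#' @export
build_stranded_windows <- function(sites, w, chrom_sizes = NULL) {
  stopifnot(w > 0)
  start <- sites$pos - as.integer(w)
  end <- sites$pos + as.integer(w)
  if (any(start < 0)) {
    stop("window extends past chromosome start; run filter_chrom_end_sites(margin >= ",
         w, ") first")
  }
  if (!is.null(chrom_sizes) && any(end > chrom_sizes[sites$chrom])) {
    stop("window extends past chromosome end; run filter_chrom_end_sites(margin >= ",
         w, ") first")
  }
  n <- nrow(sites)
  idx <- rep(seq_len(n), each = 2L)
  strand <- rep(c("+", "-"), times = n)
  data.frame(
    window_id = paste0(sites$site_id[idx], ifelse(strand == "+", ":plus", ":minus")),
    chrom = sites$chrom[idx],
    start = start[idx], end = end[idx],
    strand = strand,
    anchor = sites$site_id[idx],
    w = as.integer(w),
    orientation = "unassigned",
    stringsAsFactors = FALSE)
}

#' Pair regulated genes with their promoter anchor
#'
#' Automates the promoter-site assignment: each gene is paired with the
#' nearest anchor within `max_promoter_distance` of its TSS, preferring
#' smaller |distance| and breaking residual ties by lexicographic site_id.
#'
#' @param genes Gene data.frame (see [read_gene_table()]).
#' @param sites Anchor data.frame.
#' @param max_promoter_distance Maximum |site.pos - gene.tss|, bp.
#' @return data.frame with one row per paired gene: `gene_id`, `site_id`,
#'   `chrom`, `gene_strand`, `gene_tss`, `site_pos`, `distance`
#'   (site - TSS, signed in genomic coordinates).
#' @export
pair_promoters <- function(genes, sites, max_promoter_distance = 1000L) {
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    cand <- sites[sites$chrom == g$chrom, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    d <- abs(cand$pos - g$tss)
    cand <- cand[d <= max_promoter_distance, , drop = FALSE]
    d <- d[d <= max_promoter_distance]
    if (!nrow(cand)) return(NULL)
    ord <- order(d, cand$site_id)
    pick <- cand[ord[1], ]
    data.frame(gene_id = g$gene_id, site_id = pick$site_id, chrom = g$chrom,
               gene_strand = g$strand, gene_tss = g$tss, site_pos = pick$pos,
               distance = pick$pos - g$tss, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(), site_id = character(),
                      chrom = character(), gene_strand = character(),
                      gene_tss = integer(), site_pos = integer(),
                      distance = integer(), stringsAsFactors = FALSE)
  }
  res
}

#' Label windows as sense or antisense relative to the paired gene
#'
#' A window whose strand matches the paired gene's coding strand is
#' `sense`; the opposite strand is `antisense` (the divergent direction).
#' Anchors without a promoter pairing stay `unassigned`.
#'
#' @param windows Window data.frame from [build_stranded_windows()].
#' @param promoters Promoter pairing from [pair_promoters()].
#' @return The window data.frame with `orientation` filled in.
#' @export
assign_orientation <- function(windows, promoters) {
  if (anyDuplicated(promoters$site_id)) {
    dup <- unique(promoters$site_id[duplicated(promoters$site_id)])
    conf <- promoters[promoters$site_id %in% dup, c("site_id", "gene_id")]
    stop("anchor(s) paired to more than one gene: ",
         paste(sprintf("%s->%s", conf$site_id, conf$gene_id), collapse = ", "))
  }
  m <- match(windows$anchor, promoters$site_id)
  gene_strand <- promoters$gene_strand[m]
  windows$orientation <- ifelse(is.na(m), "unassigned",
                                ifelse(windows$strand == gene_strand,
                                       "sense", "antisense"))
  windows
}

#' Approximate binding sites at a fixed offset upstream of gene starts
#'
#' Places a surrogate anchor `offset` bp upstream of each gene's annotated
#' start (TSS - offset for `+` genes, TSS + offset for `-` genes), the
#' scheme used for factors without experimentally mapped sites.
#'
#' @param genes Gene data.frame.
#' @param offset Distance upstream of the TSS, bp.
#' @param chrom_sizes Optional named lengths; out-of-bounds sites are
#'   dropped with a warning.
#' @return Anchor data.frame as in [load_binding_sites()] (1-bp source
#'   interval at the anchor).
#' @export
approximate_control_sites <- function(genes, offset = 250L, chrom_sizes = NULL) {
  pos <- ifelse(genes$strand == "+", genes$tss - as.integer(offset),
                genes$tss + as.integer(offset))
  sites <- data.frame(site_id = paste0(genes$gene_id, ":approx"),
                      chrom = genes$chrom, pos = pos,
                      start = pos, end = pos + 1L, stringsAsFactors = FALSE)
  oob <- sites$pos < 0
  if (!is.null(chrom_sizes)) oob <- oob | sites$pos >= chrom_sizes[sites$chrom]
  if (any(oob)) {
    warning(sum(oob), " approximated site(s) out of bounds; dropped")
    sites <- sites[!oob, , drop = FALSE]
  }
  sites
}

#' Write windows as BED6
#'
#' @param windows Window data.frame.
#' @param path Output path.
#' @export
write_windows_bed <- function(windows, path) {
  df <- data.frame(windows$chrom, windows$start, windows$end,
                   windows$window_id, 0L, windows$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
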