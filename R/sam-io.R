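# SAM/BAM boundary. Reading goes through Rsamtools (SAM input is converted
# to BAM in a scratch directory first); records come back as one flat
# data.frame with 1-based positions, converted to 0-based by the callers.

#' @importFrom Rsamtools asBam scanBam ScanBamParam scanBamFlag BamFile
read_alignment_records <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, destination = dest,
                                             overwrite = TRUE,
                                             indexDestination = FALSE))
    on.exit(unlink(c(bam, paste0(bam, ".bai")), force = TRUE))
  } else {
    bam <- path
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "qwidth",
             "cigar", "mapq", "mpos", "isize"),
    tag = c("NH", "NM"))
  res <- Rsamtools::scanBam(Rsamtools::BamFile(bam, yieldSize = NA_integer_),
                            param = param)[[1]]
  df <- data.frame(qname = res$qname, flag = res$flag,
                   chrom = as.character(res$rname),
                   strand = as.character(res$strand),
                   pos = res$pos, qwidth = res$qwidth,
                   cigar = res$cigar, mapq = res$mapq,
                   mpos = res$mpos, isize = res$isize,
                   stringsAsFactors = FALSE)
  df$nh <- if (!is.null(res$tag$NH)) res$tag$NH else rep(NA_integer_, nrow(df))
  df$nm <- if (!is.null(res$tag$NM)) res$tag$NM else rep(NA_integer_, nrow(df))
  df
}

# Reference-space width of a CIGAR string (M/D/N/=/X consume reference).
cigar_ref_width <- function(cigar) {
  out <- integer(length(cigar))
  ok <- !is.na(cigar) & cigar != "*"
  if (any(ok)) {
    ops <- regmatches(cigar[ok], gregexpr("\\d+[MIDNSHP=X]", cigar[ok]))
    out[ok] <- vapply(ops, function(o) {
      op <- substring(o, nchar(o))
      len <- as.integer(substring(o, 1L, nchar(o) - 1L))
      sum(len[op %in% c("M", "D", "N", "=", "X")])
    }, integer(1))
  }
  out
}

# SAM flag bits
FLAG_PAIRED      <- 0x1L
FLAG_PROPER      <- 0x2L
FLAG_UNMAPPED    <- 0x4L
FLAG_MUNMAPPED   <- 0x8L
FLAG_REVERSE     <- 0x10L
FLAG_MREVERSE    <- 0x20L
FLAG_FIRST       <- 0x40L
FLAG_LAST        <- 0x80L
FLAG_SECONDARY   <- 0x100L
FLAG_SUPPLEMENT  <- 0x800L

has_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Write alignment records as plain-text SAM
#'
#' Used by the synthetic-data generators. `records` is a data.frame with
#' SAM's eleven mandatory fields (1-based `pos`) plus optional `tags`
#' (character, tab-joined, "" for none).
#'
#' @param records data.frame with columns qname, flag, chrom, pos, mapq,
#'   cigar, mrnm, mpos, isize, seq, qual and optionally tags.
#' @param chrom_sizes Named integer vector for the header.
#' @param path Output .sam path.
#' @param sort_coord Sort records by (chrom, pos) before writing.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, chrom_sizes, path, sort_coord = TRUE) {
  header <- c(sprintf("@HD\tVN:1.6\tSO:%s",
                      if (sort_coord) "coordinate" else "unsorted"),
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                      as.integer(chrom_sizes)))
  if (nrow(records)) {
    if (sort_coord) {
      records <- records[order(match(records$chrom, names(chrom_sizes)),
                               records$pos), , drop = FALSE]
    }
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                    records$qname, as.integer(records$flag), records$chrom,
                    as.integer(records$pos), as.integer(records$mapq),
                    records$cigar, records$mrnm, as.integer(records$mpos),
                    as.integer(records$isize), records$seq, records$qual)
    if (!is.null(records$tags)) {
      tagged <- nzchar(records$tags)
      body[tagged] <- paste(body[tagged], records$tags[tagged], sep = "\t")
    }
  } else {
    body <- character()
  }
  writeLines(c(header, body), path)
  invisible(path)
}
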