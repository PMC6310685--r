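# QC filtering of aligned reads. Three library types are handled:
# paired-end reverse-stranded RNA-seq (fragments), single-end TSS-seq
# (5' ends), paired-end MNase-seq (size-selected fragments).

qc_table <- function(rules, fails) {
  data.frame(rule = rules, n_failed = as.integer(fails),
             stringsAsFactors = FALSE)
}

# "Uniquely mapped": MAPQ >= 1 and, when a hit-count tag is present, NH == 1.
is_unique <- function(rec) {
  (!is.na(rec$mapq) & rec$mapq >= 1L) & (is.na(rec$nh) | rec$nh == 1L)
}

#' Filter paired-end stranded RNA-seq alignments into fragments
#'
#' Keeps read pairs that are unspliced (no reference skip in either CIGAR),
#' primary, uniquely mapped, properly paired, and have absolute insert size
#' at most `max_insert`. Each passing pair becomes one fragment spanning the
#' union of both mate alignments. The library is reverse-stranded (dUTP):
#' the transcript strand is the opposite of the first-in-pair mate's
#' alignment strand.
#'
#' @param path SAM or BAM file of paired-end alignments.
#' @param max_insert Maximum fragment (insert) size, bp.
#' @return list with `fragments` (data.frame: chrom, start, end — 0-based
#'   half-open, strand — transcript strand, insert_size) and `qc`
#'   (per-rule rejected record counts; attributes `n_records`,
#'   `n_passed_records`, `n_pairs_missing_mate`, `n_fragments`).
#' @export
filter_rnaseq_fragments <- function(path, max_insert = 500L) {
  rec <- read_alignment_records(path)
  if (nrow(rec) == 0) stop("no alignment records in ", path)
  if (any(!has_flag(rec$flag, FLAG_PAIRED))) {
    stop("unpaired records in a paired-end RNA-seq stream: ", path)
  }
  mapped   <- !has_flag(rec$flag, FLAG_UNMAPPED)
  primary  <- !has_flag(rec$flag, FLAG_SECONDARY) &
              !has_flag(rec$flag, FLAG_SUPPLEMENT)
  proper   <- has_flag(rec$flag, FLAG_PROPER)
  unique_m <- is_unique(rec)
  unsplice <- !is.na(rec$cigar) & !grepl("N", rec$cigar, fixed = TRUE)
  insert_ok <- !is.na(rec$isize) & abs(rec$isize) <= max_insert
  pass <- mapped & primary & proper & unique_m & unsplice & insert_ok
  qc <- qc_table(
    c("unmapped", "secondary_or_supplementary", "not_properly_paired",
      "multi_mapped", "spliced", "insert_too_large"),
    c(sum(!mapped), sum(mapped & !primary), sum(mapped & primary & !proper),
      sum(mapped & primary & proper & !unique_m),
      sum(mapped & primary & proper & unique_m & !unsplice),
      sum(mapped & primary & proper & unique_m & unsplice & !insert_ok)))

  ok <- rec[pass, , drop = FALSE]
  first <- ok[has_flag(ok$flag, FLAG_FIRST), , drop = FALSE]
  last  <- ok[has_flag(ok$flag, FLAG_LAST),  , drop = FALSE]
  m <- match(first$qname, last$qname)
  paired_first <- first[!is.na(m), , drop = FALSE]
  paired_last  <- last[m[!is.na(m)], , drop = FALSE]
  n_missing <- (nrow(first) - nrow(paired_first)) +
               (nrow(last) - nrow(paired_first))

  start0 <- pmin(paired_first$pos, paired_last$pos) - 1L
  end0 <- pmax(paired_first$pos + cigar_ref_width(paired_first$cigar),
               paired_last$pos + cigar_ref_width(paired_last$cigar)) - 1L
  frags <- data.frame(
    chrom = paired_first$chrom,
    start = start0, end = end0,
    strand = ifelse(paired_first$strand == "+", "-", "+"),
    insert_size = end0 - start0,
    stringsAsFactors = FALSE)
  attr(qc, "n_records") <- nrow(rec)
  attr(qc, "n_passed_records") <- sum(pass)
  attr(qc, "n_pairs_missing_mate") <- n_missing
  attr(qc, "n_fragments") <- nrow(frags)
  list(fragments = frags, qc = qc)
}

#' Extract strand-aware 5' ends from single-end TSS-seq alignments
#'
#' Keeps mapped, primary, uniquely mapped (MAPQ >= 1) records and emits the
#' genomic position of each read's 5'-most transcribed base: the alignment
#' start for `+` reads, the rightmost aligned base for `-` reads.
#'
#' @param path SAM or BAM file of single-end alignments.
#' @return list with `reads` (data.frame: chrom, pos — 0-based, strand) and
#'   `qc` as in [filter_rnaseq_fragments()].
#' @export
extract_tss_reads <- function(path) {
  rec <- read_alignment_records(path)
  if (nrow(rec) == 0) stop("no alignment records in ", path)
  if (any(has_flag(rec$flag, FLAG_PAIRED))) {
    stop("paired records in a single-end TSS-seq stream: ", path)
  }
  mapped  <- !has_flag(rec$flag, FLAG_UNMAPPED)
  primary <- !has_flag(rec$flag, FLAG_SECONDARY) &
             !has_flag(rec$flag, FLAG_SUPPLEMENT)
  unique_m <- is_unique(rec)
  pass <- mapped & primary & unique_m
  qc <- qc_table(
    c("unmapped", "secondary_or_supplementary", "multi_mapped"),
    c(sum(!mapped), sum(mapped & !primary),
      sum(mapped & primary & !unique_m)))
  ok <- rec[pass, , drop = FALSE]
  pos0 <- ifelse(ok$strand == "+", ok$pos - 1L,
                 ok$pos - 1L + cigar_ref_width(ok$cigar) - 1L)
  attr(qc, "n_records") <- nrow(rec)
  attr(qc, "n_passed_records") <- sum(pass)
  list(reads = data.frame(chrom = ok$chrom, pos = pos0, strand = ok$strand,
                          stringsAsFactors = FALSE),
       qc = qc)
}

#' Filter paired-end MNase-seq alignments into size-selected fragments
#'
#' Keeps pairs that are properly paired, uniquely mapped, carry at most
#' `max_mismatches` mismatches in either read (NM tag), and have an insert
#' size within `size_range` (mononucleosome selection). Emits fragment
#' spans with midpoints.
#'
#' @param path SAM or BAM file of paired-end alignments.
#' @param size_range Inclusive insert-size bounds, bp.
#' @param max_mismatches Maximum NM per read.
#' @param missing_nm What to do with records lacking an NM tag:
#'   `"reject"` (default, with a warning) or `"pass"`.
#' @return list with `fragments` (data.frame: chrom, start, end, midpoint)
#'   and `qc`.
#' @export
filter_mnase_fragments <- function(path, size_range = c(120L, 200L),
                                   max_mismatches = 2L,
                                   missing_nm = c("reject", "pass")) {
  missing_nm <- match.arg(missing_nm)
  rec <- read_alignment_records(path)
  if (nrow(rec) == 0) stop("no alignment records in ", path)
  if (any(!has_flag(rec$flag, FLAG_PAIRED))) {
    stop("unpaired records in a paired-end MNase-seq stream: ", path)
  }
  mapped   <- !has_flag(rec$flag, FLAG_UNMAPPED)
  primary  <- !has_flag(rec$flag, FLAG_SECONDARY) &
              !has_flag(rec$flag, FLAG_SUPPLEMENT)
  proper   <- has_flag(rec$flag, FLAG_PROPER)
  unique_m <- is_unique(rec)
  nm_missing <- is.na(rec$nm)
  if (any(nm_missing) && missing_nm == "reject") {
    warning(sum(nm_missing), " record(s) lack an NM tag; rejected")
  }
  nm_ok <- ifelse(nm_missing, missing_nm == "pass", rec$nm <= max_mismatches)
  size_ok <- !is.na(rec$isize) &
    abs(rec$isize) >= size_range[1] & abs(rec$isize) <= size_range[2]
  pass <- mapped & primary & proper & unique_m & nm_ok & size_ok
  qc <- qc_table(
    c("unmapped", "secondary_or_supplementary", "not_properly_paired",
      "multi_mapped", "too_many_mismatches", "insert_out_of_range"),
    c(sum(!mapped), sum(mapped & !primary), sum(mapped & primary & !proper),
      sum(mapped & primary & proper & !unique_m),
      sum(mapped & primary & proper & unique_m & !nm_ok),
      sum(mapped & primary & proper & unique_m & nm_ok & !size_ok)))

  ok <- rec[pass, , drop = FALSE]
  first <- ok[has_flag(ok$flag, FLAG_FIRST), , drop = FALSE]
  last  <- ok[has_flag(ok$flag, FLAG_LAST),  , drop = FALSE]
  m <- match(first$qname, last$qname)
  paired_first <- first[!is.na(m), , drop = FALSE]
  paired_last  <- last[m[!is.na(m)], , drop = FALSE]
  start0 <- pmin(paired_first$pos, paired_last$pos) - 1L
  end0 <- pmax(paired_first$pos + cigar_ref_width(paired_first$cigar),
               paired_last$pos + cigar_ref_width(paired_last$cigar)) - 1L
  frags <- data.frame(chrom = paired_first$chrom, start = start0, end = end0,
                      midpoint = (start0 + end0) %/% 2L,
                      stringsAsFactors = FALSE)
  attr(qc, "n_records") <- nrow(rec)
  attr(qc, "n_passed_records") <- sum(pass)
  attr(qc, "n_fragments") <- nrow(frags)
  list(fragments = frags, qc = qc)
}
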