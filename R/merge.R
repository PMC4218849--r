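# Paired-end overlap merging. Read 2 is sequenced from the reverse strand,
# so it is reverse-complemented before the 3'-overlap search; the merged
# output is on the read-1 (mRNA coding) strand.

#' Merge one read pair by quality-aware overlap consensus
#'
#' Candidate overlaps of at least `min_overlap` nucleotides are scored with
#' +1 per match and -1 per mismatch, each weighted by the mean base quality
#' of the two reads at that position; `N` never counts as a match. The
#' best-scoring overlap is selected; within it, each consensus base is the
#' base with the higher quality (ties keep the read-1 base with the maximum
#' of the two qualities; a base always beats an `N`). The pair fails when no
#' candidate overlap exists (`no_overlap`), when two candidates tie on the
#' best score (`ambiguous`; a guessed junction is never emitted), or when
#' the best overlap's mismatch fraction exceeds `max_mismatch_frac`
#' (`mismatch`).
#'
#' @param r1_seq,r1_qual read 1 sequence and Phred+33 quality.
#' @param r2_seq,r2_qual read 2 sequence and quality, as sequenced (reverse
#'   strand; reverse-complemented internally).
#' @param min_overlap minimal accepted overlap in nt (default 10).
#' @param max_mismatch_frac maximal mismatch fraction inside the overlap
#'   (default 0.1).
#' @return list with `sequence`, `quality`, `status` (`"ok"`,
#'   `"no_overlap"`, `"ambiguous"`, `"mismatch"`), `overlap_length`,
#'   `overlap_mismatches`.
#' @export
merge_pair <- function(r1_seq, r1_qual, r2_seq, r2_qual,
                       min_overlap = 10L, max_mismatch_frac = 0.1) {
  res <- merge_pairs_cpp(normalize_seq(r1_seq), r1_qual,
                         revcomp(r2_seq), reverse_chars(r2_qual),
                         as.integer(min_overlap), max_mismatch_frac)
  lapply(res, `[`, 1L)
}

reverse_chars <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Merge a batch of read pairs
#'
#' Applies [merge_pair()] to parallel vectors of records and reports the
#' merge rate. Failed pairs keep their status so they can be routed to an
#' unmerged bin.
#'
#' @param r1,r2 record lists (`id`/`seq`/`qual`, as from [read_fastq()]);
#'   ids must be synchronized.
#' @inheritParams merge_pair
#' @return object of class `merge_result`: data.frame with `id`, `sequence`,
#'   `quality`, `status`, `overlap_length`, `overlap_mismatches`, plus
#'   attributes `n_input`, `n_merged`, `merge_rate` (percent).
#' @export
merge_batch <- function(r1, r2, min_overlap = 10L, max_mismatch_frac = 0.1) {
  stopifnot(length(r1$seq) == length(r2$seq))
  n <- length(r1$seq)
  if (n == 0L) {
    out <- data.frame(id = character(0), sequence = character(0),
                      quality = character(0), status = character(0),
                      overlap_length = integer(0),
                      overlap_mismatches = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    if (!is.null(r1$id) && !is.null(r2$id) && any(r1$id != r2$id)) {
      stop("merge_batch(): read-pair ids are not synchronized")
    }
    res <- merge_pairs_cpp(normalize_seq(r1$seq), r1$qual,
                           revcomp(r2$seq), reverse_chars(r2$qual),
                           as.integer(min_overlap), max_mismatch_frac)
    out <- data.frame(id = r1$id %||% as.character(seq_len(n)),
                      res, stringsAsFactors = FALSE)
  }
  attr(out, "n_input") <- n
  attr(out, "n_merged") <- sum(out$status == "ok")
  attr(out, "merge_rate") <- if (n) 100 * sum(out$status == "ok") / n else NA_real_
  class(out) <- c("merge_result", class(out))
  out
}

#' Write merged sequences and a merge summary
#'
#' @param merged a [merge_batch()] result.
#' @param out path for the merged FASTQ (only `status == "ok"` records).
#' @param summary optional path for a one-row TSV with input/merged counts
#'   and the merge rate.
#' @return `out`, invisibly.
#' @export
write_merged <- function(merged, out, summary = NULL) {
  ok <- merged$status == "ok"
  write_fastq(list(id = merged$id[ok], seq = merged$sequence[ok],
                   qual = merged$quality[ok]), out)
  if (!is.null(summary)) {
    utils::write.table(
      data.frame(n_input = attr(merged, "n_input"),
                 n_merged = attr(merged, "n_merged"),
                 n_no_overlap = sum(merged$status == "no_overlap"),
                 n_ambiguous = sum(merged$status == "ambiguous"),
                 n_mismatch = sum(merged$status == "mismatch"),
                 merge_rate = attr(merged, "merge_rate")),
      summary, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}
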