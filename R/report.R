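# Counting and reporting: per-sample category counts, subclass frequencies
# (percentage of completely indexed, full-length variable-region
# rearrangements), replicate aggregation, run-level rates, and the
# consensus-collapse correction for identifier sequencing errors.

IGG_SUBTYPES <- c("IgG1", "IgG2", "IgG3", "IgG4")
COUNT_CATEGORIES <- c(IGG_SUBTYPES, "klMA", "undetermined")

#' Construct a counts table
#'
#' One row per (sample, category) with the three pipeline-stage counts:
#' read pairs assigned to the category, successfully merged sequences, and
#' recognized full-length variable-region rearrangements. Stage counts must
#' be non-increasing (`rearranged <= merged <= assigned_pairs`). Run-level
#' totals (total passing-filter pairs, pairs undetermined in regard of
#' sample, contaminant pairs) ride along as attributes.
#'
#' @param df data.frame with columns `sample`, `category`,
#'   `assigned_pairs`, `merged`, `rearranged` (NA allowed where a stage was
#'   not run, e.g. the undetermined category is never merged).
#' @param total_reads,sample_undetermined,contaminant run-level counts
#'   (optional, NA when unknown).
#' @return object of class `counts_table`.
#' @export
counts_table <- function(df, total_reads = NA_real_,
                         sample_undetermined = NA_real_,
                         contaminant = NA_real_) {
  need <- c("sample", "category", "assigned_pairs", "merged", "rearranged")
  stopifnot(all(need %in% names(df)))
  bad <- !df$category %in% COUNT_CATEGORIES
  if (any(bad)) {
    stop("unknown categories: ", paste(unique(df$category[bad]), collapse = ", "))
  }
  with(df, {
    chk <- function(a, b, what) {
      viol <- !is.na(a) & !is.na(b) & b > a
      if (any(viol)) stop("counts violate ", what, " for ",
                          paste(sample[viol], category[viol], collapse = ", "))
    }
    chk(assigned_pairs, merged, "merged <= assigned_pairs")
    chk(merged, rearranged, "rearranged <= merged")
  })
  structure(df[, need], class = c("counts_table", "data.frame"),
            total_reads = total_reads,
            sample_undetermined = sample_undetermined,
            contaminant = contaminant)
}

#' Read / write a counts table TSV
#'
#' Plain TSV with the five count columns; run-level totals are carried in
#' comment header lines (`# total_reads: ...`, `# sample_undetermined: ...`,
#' `# contaminant: ...`). Empty fields are NA.
#'
#' @param path file path.
#' @return `read_counts_table()` returns a [counts_table()].
#' @export
read_counts_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_num <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(m)) as.numeric(trimws(sub(".*:", "", m[1]))) else NA_real_
  }
  df <- utils::read.delim(text = lines[!grepl("^#", lines)],
                          stringsAsFactors = FALSE)
  counts_table(df,
               total_reads = get_num("total_reads"),
               sample_undetermined = get_num("sample_undetermined"),
               contaminant = get_num("contaminant"))
}

#' @rdname read_counts_table
#' @param counts a [counts_table()].
#' @export
write_counts_table <- function(counts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# total_reads: ", attr(counts, "total_reads")),
    paste0("# sample_undetermined: ", attr(counts, "sample_undetermined")),
    paste0("# contaminant: ", attr(counts, "contaminant"))
  ), con)
  utils::write.table(as.data.frame(counts), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

get_count <- function(counts, sample, category, column) {
  v <- counts[[column]][counts$sample == sample & counts$category == category]
  if (length(v) == 0L) NA_real_ else as.numeric(v[1L])
}

#' IgG subclass frequencies per sample
#'
#' Frequency of subclass c = 100 x rearranged(c) / sum over IgG1..IgG4 of
#' rearranged, i.e. the percentage of completely indexed and full-length
#' variable-region rearrangements. klMA and undetermined reads enter neither
#' numerator nor denominator. Reported half-up rounded to one decimal.
#'
#' @param counts a [counts_table()].
#' @param samples samples to report (default: all in `counts`).
#' @return data.frame with one row per sample and columns `sample`,
#'   `IgG1`..`IgG4` (percent).
#' @export
subtype_frequencies <- function(counts, samples = unique(counts$sample)) {
  rows <- lapply(samples, function(s) {
    r <- vapply(IGG_SUBTYPES, function(cc) get_count(counts, s, cc, "rearranged"),
                numeric(1))
    tot <- sum(r, na.rm = TRUE)
    if (!any(!is.na(r)) || tot == 0) {
      stop("sample ", s, ": no IgG rearranged counts; cannot compute frequencies")
    }
    r[is.na(r)] <- 0
    data.frame(sample = s, as.list(round_half_up(100 * r / tot, 1L)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate replicate preparations
#'
#' Arithmetic mean and population standard deviation (divisor n, recorded in
#' the `sd_convention` attribute) of per-subclass frequencies across
#' replicate preparations of the same sample, half-up rounded to one
#' decimal. With a single row the SD is not applicable (NA).
#'
#' @param freq a [subtype_frequencies()] table (rows = replicates).
#' @return data.frame with rows `mean` and `sd` and one column per subclass.
#' @export
aggregate_preps <- function(freq) {
  stopifnot(nrow(freq) >= 1L)
  m <- vapply(IGG_SUBTYPES, function(cc) mean(freq[[cc]]), numeric(1))
  s <- if (nrow(freq) >= 2L) {
    vapply(IGG_SUBTYPES, function(cc) {
      x <- freq[[cc]]
      sqrt(mean((x - mean(x))^2))  # population SD, ddof = 0
    }, numeric(1))
  } else {
    rep(NA_real_, length(IGG_SUBTYPES))
  }
  out <- rbind(mean = round_half_up(m, 1L), sd = round_half_up(s, 1L))
  out <- as.data.frame(out)
  attr(out, "sd_convention") <- "population (ddof 0)"
  attr(out, "n_preps") <- nrow(freq)
  out
}

#' Run-level assignment rate
#'
#' Percent of read pairs demultiplexed to a sample that were assigned to a
#' subclass or to the light-chain/other-isotype category:
#' 100 x sum(assigned pairs over all samples, categories IgG1-4 + klMA) /
#' (total reads - sample-undetermined reads).
#'
#' @param counts a [counts_table()] with run-level totals.
#' @return percent, half-up rounded to one decimal.
#' @export
run_assignment_rate <- function(counts) {
  tot <- attr(counts, "total_reads")
  und <- attr(counts, "sample_undetermined")
  if (is.na(tot) || is.na(und)) stop("run-level totals missing")
  denom <- tot - und
  if (denom <= 0) stop("zero denominator: no reads demultiplexed to a sample")
  sel <- counts$category %in% c(IGG_SUBTYPES, "klMA")
  num <- sum(counts$assigned_pairs[sel], na.rm = TRUE)
  round_half_up(100 * num / denom, 1L)
}

#' Run-level merge rate
#'
#' Percent of subclass-assigned read pairs whose mates overlapped and were
#' merged: 100 x sum(merged) / sum(assigned pairs), over categories
#' IgG1-4 + klMA.
#'
#' @inheritParams run_assignment_rate
#' @return percent, half-up rounded to one decimal.
#' @export
run_merge_rate <- function(counts) {
  sel <- counts$category %in% c(IGG_SUBTYPES, "klMA") & !is.na(counts$merged)
  denom <- sum(counts$assigned_pairs[sel], na.rm = TRUE)
  if (denom <= 0) stop("no merged categories present")
  round_half_up(100 * sum(counts$merged[sel]) / denom, 1L)
}

#' Run-level composition rates
#'
#' Percentage of all passing-filter read pairs that were undetermined in
#' regard of sample, and the share carrying the reserved contaminant index;
#' plus the grand total of rearranged variable-region sequences.
#'
#' @inheritParams run_assignment_rate
#' @return named list: `sample_undetermined_rate`, `contaminant_share`
#'   (percent, one decimal), `total_rearranged`.
#' @export
run_composition <- function(counts) {
  tot <- attr(counts, "total_reads")
  if (is.na(tot) || tot <= 0) stop("run-level totals missing")
  list(
    sample_undetermined_rate =
      round_half_up(100 * attr(counts, "sample_undetermined") / tot, 1L),
    contaminant_share =
      round_half_up(100 * attr(counts, "contaminant") / tot, 1L),
    total_rearranged = sum(counts$rearranged, na.rm = TRUE)
  )
}

#' Consensus subtype of collapsed identical variable regions
#'
#' Collapses identical (post-merge, same-orientation) variable-region
#' sequences and assigns each unique sequence the strict-majority subtype
#' among the non-undetermined calls of its members; a tie, or a group whose
#' members are all undetermined, stays undetermined. A sequencing error in
#' one member's identifier read is thereby outvoted by its identical
#' siblings.
#'
#' @param sequence character vector of merged variable-region sequences.
#' @param label parallel character vector of subclass calls.
#' @return data.frame with `sequence`, `consensus` (subclass label),
#'   `n_members`.
#' @export
consensus_collapse <- function(sequence, label) {
  stopifnot(length(sequence) == length(label))
  groups <- split(label, sequence)
  cons <- vapply(groups, function(g) {
    g <- g[g != "undetermined"]
    if (!length(g)) return("undetermined")
    t <- sort(table(g), decreasing = TRUE)
    if (length(t) > 1L && t[1L] == t[2L]) "undetermined" else names(t)[1L]
  }, character(1))
  data.frame(sequence = names(groups), consensus = unname(cons),
             n_members = unname(lengths(groups)), stringsAsFactors = FALSE)
}

#' Example run counts
#'
#' The packaged per-category counts of a published validation run: four
#' replicate IgG library preparations from one healthy donor and one sample
#' from an HIV-1-infected patient, with run-level totals. Useful for
#' exercising the reporting stage without sequence data.
#'
#' @return a [counts_table()].
#' @export
example_counts <- function() {
  read_counts_table(system.file("extdata", "example_run_counts.tsv",
                                package = "igphase", mustWork = TRUE))
}
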