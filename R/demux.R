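# Sample demultiplexing on index read 2, and the run-level router that
# splits synchronized four-read FASTQ streams into per-sample/per-category
# read-pair buckets.

#' Construct a sample sheet
#'
#' @param samples named character vector: sample name -> sample index
#'   sequence (index read 2; 8 nt under the default run design).
#' @param contaminant_index reserved index carried by spiked-in control
#'   ("PhiX-like") clusters; default `TCTTTCCC`, the index-2 region of the
#'   TruSeq Universal adaptor that unindexed control libraries present.
#' @param i2_max_mismatch mismatches tolerated when matching index 2
#'   (default 1). Sample indices must be pairwise further apart than twice
#'   this tolerance so that no read can sit in two tolerance balls.
#' @param revcomp_i2 interpret index-2 reads as reverse complements of the
#'   sheet indices (instrument-dependent dialect; default `FALSE`).
#' @return object of class `sample_sheet`.
#' @export
sample_sheet <- function(samples,
                         contaminant_index = "TCTTTCCC",
                         i2_max_mismatch = 1L,
                         revcomp_i2 = FALSE) {
  stopifnot(is.character(samples), length(samples) >= 1L)
  if (is.null(names(samples)) || any(names(samples) == "") ||
      anyDuplicated(names(samples))) {
    stop("samples must be uniquely named")
  }
  samples <- normalize_seq(samples)
  contaminant_index <- normalize_seq(contaminant_index)
  L <- unique(nchar(c(samples, contaminant_index)))
  if (length(L) != 1L) {
    stop("all sample indices (and the reserved index) must share one length")
  }
  if (anyDuplicated(samples)) stop("sample indices must be unique")
  idx <- c(samples, .contaminant = contaminant_index)
  n <- length(samples)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- hamming(samples[i], samples[j])
        if (d <= 2L * i2_max_mismatch) {
          stop(sprintf(
            "ambiguous sample sheet: indices of %s and %s are %d apart (need > %d)",
            names(samples)[i], names(samples)[j], d, 2L * i2_max_mismatch))
        }
      }
    }
  }
  structure(
    list(samples = samples, contaminant_index = contaminant_index,
         index_length = L, i2_max_mismatch = as.integer(i2_max_mismatch),
         revcomp_i2 = isTRUE(revcomp_i2)),
    class = "sample_sheet"
  )
}

#' @export
print.sample_sheet <- function(x, ...) {
  cat("Sample sheet:", length(x$samples), "samples,", x$index_length,
      "nt indices, <=", x$i2_max_mismatch, "mismatch\n")
  for (s in names(x$samples)) cat(sprintf("  %-20s %s\n", s, x$samples[s]))
  cat(sprintf("  %-20s %s\n", "(contaminant)", x$contaminant_index))
  invisible(x)
}

#' Read / write a sample sheet TSV
#'
#' The TSV has a header and columns `sample` and `index`; optional comment
#' header lines `# contaminant_index: <seq>` and `# i2_max_mismatch: <n>`
#' override the defaults.
#'
#' @param path file path.
#' @return a [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_opt <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(m)) trimws(sub(".*:", "", m[1])) else default
  }
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)],
                           stringsAsFactors = FALSE)
  if (!all(c("sample", "index") %in% names(tab))) {
    stop("sample sheet needs columns 'sample' and 'index'")
  }
  sample_sheet(
    stats::setNames(tab$index, tab$sample),
    contaminant_index = get_opt("contaminant_index", "TCTTTCCC"),
    i2_max_mismatch = as.integer(get_opt("i2_max_mismatch", "1"))
  )
}

#' @rdname read_sample_sheet
#' @param sheet a [sample_sheet()].
#' @export
write_sample_sheet <- function(sheet, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# contaminant_index: ", sheet$contaminant_index),
    paste0("# i2_max_mismatch: ", sheet$i2_max_mismatch),
    "sample\tindex",
    paste(names(sheet$samples), sheet$samples, sep = "\t")
  ), con)
  invisible(path)
}

#' The packaged default sample sheet
#'
#' Five samples on standard D501-D505 indexing primers plus the reserved
#' TruSeq-Universal contaminant index.
#'
#' @return a [sample_sheet()].
#' @export
default_sample_sheet <- function() {
  read_sample_sheet(system.file("extdata", "default_samples.tsv",
                                package = "igphase", mustWork = TRUE))
}

#' Assign clusters to samples by index read 2
#'
#' Nearest sample within `i2_max_mismatch`; the reserved contaminant index
#' participates in the same nearest-match rule. Two candidates tying at the
#' minimal distance, no candidate within tolerance, or a wrong-length index
#' all yield `undetermined`.
#'
#' @param i2 character vector of index-2 reads.
#' @param sheet a [sample_sheet()].
#' @return character vector of sample names, `"contaminant"`, or
#'   `"undetermined"`.
#' @export
assign_sample <- function(i2, sheet) {
  stopifnot(inherits(sheet, "sample_sheet"))
  i2 <- normalize_seq(i2)
  if (sheet$revcomp_i2) i2 <- revcomp(i2)
  out <- rep("undetermined", length(i2))
  ok <- nchar(i2) == sheet$index_length
  if (!any(ok)) return(out)
  targets <- c(sheet$samples, contaminant = sheet$contaminant_index)
  dmat <- vapply(targets, function(t) hamming_to(i2[ok], t),
                 numeric(sum(ok)))
  dmat <- matrix(dmat, nrow = sum(ok))
  dmin <- apply(dmat, 1L, min)
  nmin <- rowSums(dmat == dmin)
  hit <- dmin <= sheet$i2_max_mismatch & nmin == 1L
  lab <- names(targets)[apply(dmat, 1L, which.min)]
  res <- rep("undetermined", sum(ok))
  res[hit] <- lab[hit]
  out[ok] <- res
  out
}

#' Demultiplex a four-read run into per-sample, per-category buckets
#'
#' Streams the four synchronized FASTQ files, assigns every cluster to a
#' sample by index 2 and to a subclass category by index 1 / read 2, and
#' (optionally) writes per-bucket paired FASTQ files plus a tally TSV. Every
#' input cluster lands in exactly one bucket, so bucket counts always sum to
#' the input cluster count.
#'
#' @param r1,r2,i1,i2 paths to the four FASTQ files (plain or gzip).
#' @param sheet a [sample_sheet()].
#' @param scheme a [subtype_scheme()].
#' @param outdir output directory for per-bucket FASTQ files and
#'   `demux_tally.tsv`, or `NULL` to skip writing.
#' @param trim_prefix remove this many leading bases (the synthesis-phase
#'   random nucleotides) from read 1; default 0 (reads are left untrimmed).
#' @return object of class `demux_run`: list with `tally` (data.frame
#'   `sample`/`category`/`count`), `n_clusters`, `assignments`
#'   (per-cluster data.frame), and the input `records` (four read lists),
#'   for in-memory chaining into the merge stage.
#' @export
demultiplex_run <- function(r1, r2, i1, i2, sheet, scheme,
                            outdir = NULL, trim_prefix = 0L) {
  for (p in c(r1, r2, i1, i2)) {
    if (!file.exists(p)) stop("missing input stream: ", p)
  }
  rec <- list(r1 = read_fastq(r1), r2 = read_fastq(r2),
              i1 = read_fastq(i1), i2 = read_fastq(i2))
  n <- length(rec$r1$id)
  lens <- vapply(rec, function(x) length(x$id), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("desynchronized streams: record counts differ (",
         paste(names(lens), lens, sep = "=", collapse = ", "), ")")
  }
  for (nm in c("r2", "i1", "i2")) {
    bad <- rec[[nm]]$id != rec$r1$id
    if (any(bad)) {
      stop("desynchronized streams: cluster ids differ between R1 and ",
           toupper(nm), " at record(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "),
           " (", rec$r1$id[which(bad)[1L]], " vs ",
           rec[[nm]]$id[which(bad)[1L]], ")")
    }
  }
  if (trim_prefix > 0L && n > 0L) {
    rec$r1$seq <- substr(rec$r1$seq, trim_prefix + 1L, nchar(rec$r1$seq))
    rec$r1$qual <- substr(rec$r1$qual, trim_prefix + 1L, nchar(rec$r1$qual))
  }

  sample <- if (n) assign_sample(rec$i2$seq, sheet) else character(0)
  category <- rep(NA_character_, n)
  in_sample <- !sample %in% c("contaminant", "undetermined")
  if (any(in_sample)) {
    calls <- call_subtype(rec$i1$seq[in_sample], rec$r2$seq[in_sample], scheme)
    category[in_sample] <- calls$label
  }

  cats <- SUBTYPE_LEVELS
  tally <- expand.grid(sample = names(sheet$samples), category = cats,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tally$count <- mapply(function(s, cc) sum(sample == s & category == cc,
                                            na.rm = TRUE),
                        tally$sample, tally$category)
  extra <- data.frame(
    sample = c(".run", ".run"),
    category = c("contaminant", "sample_undetermined"),
    count = c(sum(sample == "contaminant"), sum(sample == "undetermined"))
  )
  tally <- rbind(tally, extra)
  stopifnot(sum(tally$count) == n)

  assignments <- data.frame(id = rec$r1$id, sample = sample,
                            category = category, stringsAsFactors = FALSE)
  out <- structure(
    list(tally = tally, n_clusters = n, assignments = assignments,
         records = rec),
    class = "demux_run"
  )
  if (!is.null(outdir)) write_demux_buckets(out, outdir)
  out
}

#' @export
print.demux_run <- function(x, ...) {
  cat("Demultiplexed run:", x$n_clusters, "clusters\n")
  t <- x$tally[x$tally$count > 0L, ]
  for (i in seq_len(nrow(t))) {
    cat(sprintf("  %-20s %-20s %d\n", t$sample[i], t$category[i], t$count[i]))
  }
  invisible(x)
}

# Write per-bucket paired FASTQ files (<sample>_<category>_R{1,2}.fastq.gz,
# plus run-level contaminant/undetermined buckets) and the tally TSV.
write_demux_buckets <- function(dx, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  a <- dx$assignments
  bucket <- ifelse(a$sample %in% c("contaminant", "undetermined"),
                   ifelse(a$sample == "contaminant",
                          "contaminant", "sample_undetermined"),
                   paste(a$sample, a$category, sep = "_"))
  for (b in unique(bucket)) {
    sel <- bucket == b
    write_fastq(fastq_subset(dx$records$r1, sel),
                file.path(outdir, paste0(b, "_R1.fastq.gz")))
    write_fastq(fastq_subset(dx$records$r2, sel),
                file.path(outdir, paste0(b, "_R2.fastq.gz")))
  }
  utils::write.table(dx$tally, file.path(outdir, "demux_tally.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
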