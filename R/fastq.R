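# FASTQ reading/writing, thin wrappers over Biostrings. Records are held as
# plain lists of character vectors (id / seq / qual), which is what the
# per-cluster decision logic and the Rcpp merge kernel consume.

#' Read a FASTQ file
#'
#' @param path FASTQ file, plain or gzip-compressed.
#' @return list with character vectors `id` (first whitespace-delimited token
#'   of the header), `seq` and `qual` (Phred+33).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) {
    stop("FASTQ file not found: ", path)
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  ids <- sub("\\s.*$", "", names(x))
  list(
    id = ids,
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities)
  )
}

#' Write a FASTQ file
#'
#' @param records list with `id`, `seq`, `qual` character vectors.
#' @param path output path; `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  stopifnot(length(records$seq) == length(records$id),
            length(records$qual) == length(records$id))
  x <- Biostrings::DNAStringSet(records$seq)
  names(x) <- records$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(records$qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

#' Subset a FASTQ record list
#'
#' @param records list with `id`, `seq`, `qual`.
#' @param i logical or integer index.
#' @return the subsetted record list.
#' @export
fastq_subset <- function(records, i) {
  list(id = records$id[i], seq = records$seq[i], qual = records$qual[i])
}
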