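# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's own code paths: plain character loops, no vectorized
# matching, so they can arbitrate the decision logic.

DEFAULT_SCHEME <- default_scheme()
DEFAULT_SHEET <- default_sample_sheet()

ID_IGG1 <- DEFAULT_SCHEME$identifiers$IgG1[1]
ID_IGG3 <- DEFAULT_SCHEME$identifiers$IgG3[1]
ID_IGG24 <- DEFAULT_SCHEME$identifiers$IgG24[1]
ID_KLMA <- DEFAULT_SCHEME$identifiers$klMA[1]

# independent reverse complement (chartr + explicit reversal)
rc_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

ham_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  sum(ca != cb)
}

# brute-force nearest-identifier subclass call under the scheme tolerances:
# scan every accepted identifier, keep those within their class tolerance,
# prefer IgG classes (exact-match tier) over klMA, resolve IgG24 by the
# discriminator base.
oracle_call <- function(i1, r2, scheme) {
  if (nchar(i1) != scheme$identifier_length) return("undetermined")
  best <- "undetermined"
  for (cls in c("IgG1", "IgG3", "IgG24")) {
    for (id in scheme$identifiers[[cls]]) {
      if (ham_oracle(i1, id) <= scheme$igg_max_mismatch && best == "undetermined") {
        best <- cls
      }
    }
  }
  if (best == "undetermined" && !is.null(scheme$identifiers$klMA)) {
    for (id in scheme$identifiers$klMA) {
      if (ham_oracle(i1, id) <= scheme$klma_max_mismatch) best <- "klMA"
    }
  }
  if (best == "IgG24") {
    d <- scheme$discriminator
    b <- substr(r2, d$position, d$position)
    best <- if (b %in% names(d$base_map)) unname(d$base_map[b]) else d$fallback
  }
  best
}

# all sequences at Hamming distance exactly 1 from s
neighbors1 <- function(s) {
  ch <- strsplit(s, "")[[1]]
  out <- character(0)
  for (i in seq_along(ch)) {
    for (b in setdiff(c("A", "C", "G", "T"), ch[i])) {
      v <- ch
      v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

# write a record list to a FASTQ under `dir` and return the path
tmp_fastq <- function(records, name = "reads.fastq",
                      dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, name)
  write_fastq(records, path)
  path
}

const_qual <- function(seqs, q = 37L) {
  strrep(rawToChar(as.raw(q + 33L)), nchar(seqs))
}

# a small three-sample simulation setup used across tests
small_sim_config <- function(n = 1000L, err = 0, contaminant = 0.05,
                             seed = 11L, ...) {
  samples <- names(DEFAULT_SHEET$samples)[1:3]
  mix <- c(IgG1 = 0.5, IgG2 = 0.3, IgG3 = 0.15, IgG4 = 0.04, klMA = 0.01)
  sim_config(
    samples = samples,
    mixtures = stats::setNames(rep(list(mix), 3), samples),
    n_clusters = n,
    error_rate_r1 = err, error_rate_r2 = err,
    error_rate_i1 = err, error_rate_i2 = err,
    contaminant_fraction = contaminant,
    seed = seed, ...
  )
}
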