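# Ground-truthed run simulator. Emulates the amplicon structure of the
# assay: read 1 starts with 4 synthesis-phase random nucleotides, a leader
# stub and the V(D)J-like core; the template ends with the first two CH1
# codons so that read 2 (reverse strand) carries the subclass discriminator
# base at position 4; index read 1 carries the subclass identifier; index
# read 2 the sample index. A configurable fraction of contaminant
# ("PhiX-like") clusters carries the reserved index.

#' Simulation configuration
#'
#' Defaults reflect the run design the pipeline targets: 2 x 250 nt
#' paired-end reads, a 12-nt identifier read and an 8-nt sample index,
#' template lengths ~ Normal(390, 15) (truncated to keep a valid overlap
#' geometry; the resulting V-region core is ~360 nt and the mate overlap
#' peaks near 110 nt), a 0.3% per-base substitution error, and a 5%
#' contaminant spike.
#'
#' @param samples character vector of sample names (must appear in the
#'   sample sheet used at generation time).
#' @param mixtures named list (one element per sample) of named numeric
#'   vectors over `IgG1`, `IgG2`, `IgG3`, `IgG4`, `klMA`; each must sum
#'   to 1.
#' @param n_clusters total clusters to emit, contaminants included.
#' @param read_len length of reads 1 and 2 (default 250).
#' @param template_len_mean,template_len_sd template length distribution
#'   (default 390 / 15); draws are clamped to
#'   `[read_len + 1, 2 * read_len - 10]` so every template is covered by
#'   both mates with an overlap of at least 10 nt.
#' @param error_rate_r1,error_rate_r2,error_rate_i1,error_rate_i2 per-base
#'   substitution error rates per read (default 0.003 each).
#' @param contaminant_fraction fraction of clusters carrying the reserved
#'   index (default 0.05).
#' @param exact_mixture allocate subtype/sample counts by largest remainder
#'   so the realized composition equals the configured one exactly
#'   (default `TRUE`); `FALSE` draws each cluster independently.
#' @param seed integer random seed; a fixed seed makes the simulated run
#'   fully reproducible.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(samples,
                       mixtures,
                       n_clusters = 10000L,
                       read_len = 250L,
                       template_len_mean = 390,
                       template_len_sd = 15,
                       error_rate_r1 = 0.003,
                       error_rate_r2 = 0.003,
                       error_rate_i1 = 0.003,
                       error_rate_i2 = 0.003,
                       contaminant_fraction = 0.05,
                       exact_mixture = TRUE,
                       seed = 1L) {
  stopifnot(length(samples) >= 1L, n_clusters >= 0L)
  if (!setequal(names(mixtures), samples)) {
    stop("mixtures must be a named list with one element per sample")
  }
  for (s in samples) {
    m <- mixtures[[s]]
    if (is.null(names(m)) || !all(names(m) %in% c(IGG_SUBTYPES, "klMA"))) {
      stop("mixture for ", s, " must be named over IgG1..IgG4, klMA")
    }
    if (abs(sum(m) - 1) > 1e-8) stop("mixture for ", s, " must sum to 1")
  }
  rates <- c(error_rate_r1, error_rate_r2, error_rate_i1, error_rate_i2)
  if (any(rates < 0 | rates >= 1)) stop("error rates must be in [0, 1)")
  if (contaminant_fraction < 0 || contaminant_fraction >= 1) {
    stop("contaminant_fraction must be in [0, 1)")
  }
  structure(
    list(samples = samples, mixtures = mixtures,
         n_clusters = as.integer(n_clusters), read_len = as.integer(read_len),
         template_len_mean = template_len_mean,
         template_len_sd = template_len_sd,
         error_rate_r1 = error_rate_r1, error_rate_r2 = error_rate_r2,
         error_rate_i1 = error_rate_i1, error_rate_i2 = error_rate_i2,
         contaminant_fraction = contaminant_fraction,
         exact_mixture = isTRUE(exact_mixture), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Substitute bases at a fixed per-base error rate
#'
#' Each base is independently replaced, with probability `rate`, by one of
#' the three other bases (uniformly). Deterministic under a fixed RNG state.
#'
#' @param seq character vector of sequences.
#' @param rate substitution probability per base, in `[0, 1)`.
#' @return character vector with substitutions applied.
#' @export
mutate_read <- function(seq, rate) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0 || !length(seq)) return(seq)
  vapply(seq, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    if (length(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1), USE.NAMES = FALSE)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Largest-remainder integer allocation of n among proportions p.
allocate_counts <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0L) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

# Leader stub used on the 5' side of every simulated template (a VH1-family
# leader primer target; the exact sequence is inert to the pipeline).
SIM_LEADER <- "ATGGACTGGACCTGGAGGAT"

# First two CH1 codons per subtype; the third base of codon 1 is the
# discriminator determinant (GCC -> read-2 'G', GCT -> read-2 'A').
SIM_CH1_STUB <- c(IgG1 = "GCCTCC", IgG2 = "GCCTCC",
                  IgG3 = "GCTTCC", IgG4 = "GCTTCC")

#' Simulate a four-read sequencing run
#'
#' Generates synchronized R1/R2/I1/I2 FASTQ files plus a ground-truth TSV
#' joinable to every FASTQ record by cluster id. Per cluster: a sample and
#' subtype are drawn from the configured composition, a template is built as
#' 4 random nt + leader stub + random V-like core + subtype CH1 stub, read 1
#' is the first `read_len` nt, read 2 the reverse complement of the last
#' `read_len` nt, index 1 the subtype's identifier (the klMA identifier for
#' klMA clusters) and index 2 the sample's index; substitution errors are
#' then injected per read at the configured rates. Contaminant clusters get
#' fully random sequence and the reserved index. Qualities are constant Q37.
#'
#' @param config a [sim_config()].
#' @param scheme a [subtype_scheme()]; identifiers must be available for
#'   every requested subtype.
#' @param sheet a [sample_sheet()] listing every configured sample.
#' @param outdir output directory (created if needed).
#' @return (invisibly) list with the four FASTQ paths, `truth` (data.frame
#'   `id`, `sample`, `subtype`, `template`, `overlap`) and `truth_path`.
#' @export
simulate_run <- function(config, scheme = default_scheme(),
                         sheet = default_sample_sheet(), outdir) {
  stopifnot(inherits(config, "sim_config"),
            inherits(scheme, "subtype_scheme"),
            inherits(sheet, "sample_sheet"))
  missing_s <- setdiff(config$samples, names(sheet$samples))
  if (length(missing_s)) {
    stop("samples absent from sheet: ", paste(missing_s, collapse = ", "))
  }
  id_of <- function(subtype) {
    cls <- switch(subtype, IgG2 = "IgG24", IgG4 = "IgG24", subtype)
    ids <- scheme$identifiers[[cls]]
    if (is.null(ids)) stop("subtype ", subtype, " absent from scheme")
    ids[1L]
  }
  used <- unique(unlist(lapply(config$mixtures, names)))
  for (st in used) id_of(st)  # fail early on missing identifiers

  set.seed(config$seed)
  n <- config$n_clusters
  n_cont <- if (config$exact_mixture) {
    as.integer(round(n * config$contaminant_fraction))
  } else {
    stats::rbinom(1L, n, config$contaminant_fraction)
  }
  n_real <- n - n_cont

  # sample, then subtype within sample
  if (config$exact_mixture) {
    per_sample <- allocate_counts(n_real, rep(1, length(config$samples)))
    sample_lab <- rep(config$samples, per_sample)
    subtype_lab <- unlist(lapply(seq_along(config$samples), function(i) {
      m <- config$mixtures[[config$samples[i]]]
      rep(names(m), allocate_counts(per_sample[i], m))
    }), use.names = FALSE)
  } else {
    sample_lab <- sample(config$samples, n_real, replace = TRUE)
    subtype_lab <- vapply(sample_lab, function(s) {
      m <- config$mixtures[[s]]
      sample(names(m), 1L, prob = m)
    }, character(1), USE.NAMES = FALSE)
  }
  lab <- data.frame(sample = c(sample_lab, rep("contaminant", n_cont)),
                    subtype = c(subtype_lab, rep("contaminant", n_cont)),
                    stringsAsFactors = FALSE)
  if (nrow(lab)) lab <- lab[sample.int(nrow(lab)), , drop = FALSE]

  L <- config$read_len
  tlen <- pmin(pmax(round(stats::rnorm(n, config$template_len_mean,
                                       config$template_len_sd)),
                    L + 1L), 2L * L - 10L)
  fixed_len <- 4L + nchar(SIM_LEADER) + 6L
  is_cont <- lab$subtype == "contaminant"
  template <- character(n)
  if (any(!is_cont)) {
    core_len <- tlen[!is_cont] - fixed_len
    stub <- ifelse(lab$subtype[!is_cont] %in% names(SIM_CH1_STUB),
                   SIM_CH1_STUB[lab$subtype[!is_cont]],
                   random_dna(rep(6L, sum(!is_cont))))
    template[!is_cont] <- paste0(random_dna(rep(4L, sum(!is_cont))),
                                 SIM_LEADER,
                                 random_dna(core_len),
                                 stub)
  }
  if (any(is_cont)) template[is_cont] <- random_dna(tlen[is_cont])

  i1 <- character(n)
  i1[!is_cont] <- vapply(lab$subtype[!is_cont], id_of, character(1),
                         USE.NAMES = FALSE)
  i1[is_cont] <- random_dna(rep(scheme$identifier_length, sum(is_cont)))
  i2 <- character(n)
  i2[!is_cont] <- unname(sheet$samples[lab$sample[!is_cont]])
  i2[is_cont] <- sheet$contaminant_index

  r1 <- substr(template, 1L, L)
  r2 <- revcomp(substr(template, tlen - L + 1L, tlen))

  r1 <- mutate_read(r1, config$error_rate_r1)
  r2 <- mutate_read(r2, config$error_rate_r2)
  i1 <- mutate_read(i1, config$error_rate_i1)
  i2 <- mutate_read(i2, config$error_rate_i2)

  ids <- sprintf("cluster%06d", seq_len(n))
  q <- function(x) strrep(rawToChar(as.raw(37L + 33L)), nchar(x))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    r1 = file.path(outdir, "sim_R1.fastq.gz"),
    r2 = file.path(outdir, "sim_R2.fastq.gz"),
    i1 = file.path(outdir, "sim_I1.fastq.gz"),
    i2 = file.path(outdir, "sim_I2.fastq.gz")
  )
  write_fastq(list(id = ids, seq = r1, qual = q(r1)), paths$r1)
  write_fastq(list(id = ids, seq = r2, qual = q(r2)), paths$r2)
  write_fastq(list(id = ids, seq = i1, qual = q(i1)), paths$i1)
  write_fastq(list(id = ids, seq = i2, qual = q(i2)), paths$i2)

  truth <- data.frame(id = ids, sample = lab$sample, subtype = lab$subtype,
                      template = template,
                      overlap = 2L * L - tlen,
                      stringsAsFactors = FALSE)
  truth_path <- file.path(outdir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, list(truth = truth, truth_path = truth_path)))
}

#' Exact probability that an identifier-read error leaves a cluster uncalled
#'
#' Closed-form binomial computation, independent of the simulator: a cluster
#' whose true class is `subtype` escapes the undetermined bin iff its
#' (error-bearing) identifier read lands inside some class's tolerance ball.
#' With per-base substitution rate `e`, the probability of reading sequence
#' `u` from source `s` is `(e/3)^d (1-e)^(L-d)` with `d = hamming(s, u)`;
#' summing over all accepted identifiers (IgG classes, exact) and the
#' radius-`klma_max_mismatch` ball around the klMA identifiers gives the
#' assignment probability. Balls are disjoint in any scheme accepted by
#' [subtype_scheme()], so the sum is exact. Read-2 errors are not modelled
#' (the discriminator base map sends unexpected bases to the fallback, so
#' set the read-2 error rate to 0 when comparing against this prediction).
#'
#' @param scheme a [subtype_scheme()].
#' @param subtype true class of the cluster (`IgG1`, `IgG2`, `IgG3`,
#'   `IgG4`, `klMA`).
#' @param error_rate per-base substitution rate on the identifier read.
#' @return probability of an undetermined call.
#' @export
predict_undetermined_fraction <- function(scheme, subtype, error_rate) {
  e <- error_rate
  L <- scheme$identifier_length
  cls <- switch(subtype, IgG2 = "IgG24", IgG4 = "IgG24", subtype)
  src <- scheme$identifiers[[cls]][1L]
  p_reach <- function(target) {
    d <- hamming(src, target)
    (e / 3)^d * (1 - e)^(L - d)
  }
  ball <- function(target, radius) {
    if (radius > 1L) stop("tolerance radius > 1 not supported in prediction")
    seqs <- target
    if (radius >= 1L) {
      ch <- strsplit(target, "", fixed = TRUE)[[1]]
      for (i in seq_len(L)) {
        for (b in setdiff(c("A", "C", "G", "T"), ch[i])) {
          v <- ch; v[i] <- b
          seqs <- c(seqs, paste(v, collapse = ""))
        }
      }
    }
    unique(seqs)
  }
  p_assigned <- 0
  for (nm in names(scheme$identifiers)) {
    tol <- if (nm == "klMA") scheme$klma_max_mismatch else scheme$igg_max_mismatch
    targets <- unique(unlist(lapply(scheme$identifiers[[nm]], ball, radius = tol)))
    p_assigned <- p_assigned + sum(vapply(targets, p_reach, numeric(1)))
  }
  1 - p_assigned
}
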