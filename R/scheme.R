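# Subclass-calling scheme: the 12-nt identifier read carried by index 1
# distinguishes IgG1, IgG3 and the pooled light-chain/other-isotype category
# (klMA); IgG2 and IgG4 share an identifier and are separated by one
# discriminator base near the start of read 2 (read 2 is the reverse strand,
# so the base is the complement of the third base of the first CH1 codon:
# GCC -> 'G' -> IgG2, GCT -> 'A' -> IgG4).

IGG_CLASSES <- c("IgG1", "IgG3", "IgG24")
SUBTYPE_LEVELS <- c("IgG1", "IgG2", "IgG3", "IgG4", "klMA", "undetermined")

#' Discriminator rule resolving a shared identifier into subclasses
#'
#' @param read which mate carries the discriminator base (1 or 2; default 2).
#' @param position 1-based offset of the base within that read (default 4).
#' @param base_map named character vector, base -> class label
#'   (default `c(G = "IgG2", A = "IgG4")`).
#' @param fallback label assigned when the observed base is not in
#'   `base_map` (default `"undetermined"`; an `N` or unexpected base never
#'   guesses a subclass).
#' @return object of class `discriminator_rule`.
#' @export
discriminator_rule <- function(read = 2L, position = 4L,
                               base_map = c(G = "IgG2", A = "IgG4"),
                               fallback = "undetermined") {
  stopifnot(position >= 1L, read %in% c(1L, 2L))
  if (!all(names(base_map) %in% c("A", "C", "G", "T"))) {
    stop("discriminator base_map keys must be single canonical bases (A/C/G/T)")
  }
  structure(
    list(read = as.integer(read), position = as.integer(position),
         base_map = base_map, fallback = fallback),
    class = "discriminator_rule"
  )
}

#' Construct a subclass-calling scheme
#'
#' A scheme maps identifier sequences (as seen on index read 1) to class
#' labels. Each class may carry several accepted identifiers (allelic
#' variants); membership is "within tolerance of any accepted sequence".
#' IgG identifiers are matched with `igg_max_mismatch` (default 0: a perfect
#' match is required), the klMA identifier with `klma_max_mismatch`
#' (default 1). Schemes whose klMA tolerance ball could swallow an IgG
#' identifier are rejected as ambiguous.
#'
#' @param identifiers named list of character vectors; names are class labels
#'   among `IgG1`, `IgG3`, `IgG24`, `klMA`.
#' @param discriminator a [discriminator_rule()] resolving `IgG24`.
#' @param identifier_length expected identifier length (default 12).
#' @param igg_max_mismatch mismatches tolerated for IgG identifiers
#'   (default 0).
#' @param klma_max_mismatch mismatches tolerated for the klMA identifier
#'   (default 1).
#' @return object of class `subtype_scheme`.
#' @export
subtype_scheme <- function(identifiers,
                           discriminator = discriminator_rule(),
                           identifier_length = 12L,
                           igg_max_mismatch = 0L,
                           klma_max_mismatch = 1L) {
  stopifnot(is.list(identifiers), length(identifiers) >= 1L)
  if (is.null(names(identifiers)) || anyDuplicated(names(identifiers))) {
    stop("identifier classes must be uniquely named")
  }
  bad <- setdiff(names(identifiers), c(IGG_CLASSES, "klMA"))
  if (length(bad)) {
    stop("unknown identifier class(es): ", paste(bad, collapse = ", "))
  }
  identifiers <- lapply(identifiers, normalize_seq)
  all_ids <- unlist(identifiers, use.names = FALSE)
  if (any(nchar(all_ids) != identifier_length)) {
    stop("all identifier sequences must have length ", identifier_length)
  }
  cls_of <- rep(names(identifiers), lengths(identifiers))
  if (anyDuplicated(all_ids)) {
    dup <- all_ids[duplicated(all_ids)]
    shared <- unique(cls_of[all_ids %in% dup])
    if (length(shared) > 1L || anyDuplicated(paste(cls_of, all_ids))) {
      stop("identifier sequence shared between classes or duplicated: ",
           paste(unique(dup), collapse = ", "))
    }
  }
  scheme <- structure(
    list(identifier_length = as.integer(identifier_length),
         identifiers = identifiers,
         igg_max_mismatch = as.integer(igg_max_mismatch),
         klma_max_mismatch = as.integer(klma_max_mismatch),
         discriminator = discriminator),
    class = "subtype_scheme"
  )
  rep_ <- validate_scheme(scheme)
  if (!rep_$safe) {
    stop("ambiguous scheme rejected: ", paste(rep_$problems, collapse = "; "))
  }
  scheme
}

#' @export
print.subtype_scheme <- function(x, ...) {
  cat("Subclass-calling scheme (identifier length ", x$identifier_length,
      " nt)\n", sep = "")
  for (cls in names(x$identifiers)) {
    tol <- if (cls == "klMA") x$klma_max_mismatch else x$igg_max_mismatch
    cat(sprintf("  %-6s <= %d mismatch: %s\n", cls, tol,
                paste(x$identifiers[[cls]], collapse = ", ")))
  }
  d <- x$discriminator
  cat(sprintf("  IgG24 resolved by read %d position %d: %s (else %s)\n",
              d$read, d$position,
              paste(names(d$base_map), d$base_map, sep = "->", collapse = ", "),
              d$fallback))
  invisible(x)
}

#' Pairwise Hamming-distance report for a scheme
#'
#' Computes the full pairwise Hamming matrix between all accepted identifier
#' sequences and judges whether the scheme is safe under its tolerances: the
#' tolerance balls of different classes must not touch, i.e. the distance
#' between identifiers of two classes must exceed the sum of their
#' tolerances.
#'
#' @param scheme a [subtype_scheme()] (or an un-validated list of the same
#'   shape).
#' @return list with `distance` (matrix, rows/cols named `class:sequence`),
#'   `min_inter_class` (matrix of minimal distances between classes),
#'   `safe` (logical) and `problems` (character vector, empty when safe).
#' @export
validate_scheme <- function(scheme) {
  ids <- scheme$identifiers
  all_ids <- unlist(ids, use.names = FALSE)
  cls <- rep(names(ids), lengths(ids))
  n <- length(all_ids)
  d <- matrix(0L, n, n,
              dimnames = list(paste(cls, all_ids, sep = ":"),
                              paste(cls, all_ids, sep = ":")))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- hamming(all_ids[i], all_ids[j])
      }
    }
  }
  tol <- ifelse(cls == "klMA", scheme$klma_max_mismatch, scheme$igg_max_mismatch)
  classes <- unique(cls)
  mic <- matrix(NA_integer_, length(classes), length(classes),
                dimnames = list(classes, classes))
  problems <- character(0)
  for (a in classes) {
    for (b in classes) {
      if (a == b) next
      sub <- d[cls == a, cls == b, drop = FALSE]
      mic[a, b] <- min(sub)
    }
  }
  if (length(classes) > 1L) {
    for (i in seq_along(classes)[-1L]) {
      for (j in seq_len(i - 1L)) {
        a <- classes[i]; b <- classes[j]
        need <- tol[cls == a][1L] + tol[cls == b][1L]
        if (mic[a, b] <= need) {
          problems <- c(problems, sprintf(
            "classes %s and %s are distance %d apart but tolerances allow %d",
            a, b, mic[a, b], need))
        }
      }
    }
  }
  list(distance = d, min_inter_class = mic,
       safe = length(problems) == 0L, problems = problems)
}

#' Call the subclass of one or many clusters
#'
#' Applies the fixed decision order: (1) membership of the identifier read
#' within `igg_max_mismatch` of an IgG1/IgG3/IgG24 identifier; (2) for IgG24,
#' the read-2 discriminator base; (3) membership within `klma_max_mismatch`
#' of a klMA identifier; (4) otherwise `undetermined`. `N` at any compared
#' position counts as a mismatch, and a discriminator base outside the base
#' map (including `N`, or a read 2 shorter than the discriminator position)
#' yields the rule's fallback label.
#'
#' @param i1 character vector of identifier reads (index read 1).
#' @param r2 character vector of read-2 sequences (only the discriminator
#'   position is inspected; may be `""`).
#' @param scheme a [subtype_scheme()].
#' @return data.frame with columns `label`, `matched_identifier`,
#'   `mismatches` (NA when undetermined) and `flag` (`""`, or
#'   `"bad_identifier_length"` for records whose identifier read has the
#'   wrong length; such records are undetermined, never an error).
#' @export
call_subtype <- function(i1, r2, scheme) {
  stopifnot(inherits(scheme, "subtype_scheme"))
  n <- length(i1)
  r2 <- rep_len(normalize_seq(r2), n)
  i1 <- normalize_seq(i1)
  label <- rep("undetermined", n)
  matched <- rep("", n)
  mism <- rep(NA_integer_, n)
  flag <- rep("", n)

  ok_len <- nchar(i1) == scheme$identifier_length
  flag[!ok_len] <- "bad_identifier_length"
  undecided <- ok_len

  assign_class <- function(classes, tol) {
    for (cls in classes) {
      if (!cls %in% names(scheme$identifiers)) next
      for (id in scheme$identifiers[[cls]]) {
        if (!any(undecided)) break
        dd <- hamming_to(i1[undecided], id)
        hit <- dd <= tol
        if (any(hit)) {
          idx <- which(undecided)[hit]
          label[idx] <<- cls
          matched[idx] <<- id
          mism[idx] <<- dd[hit]
          undecided[idx] <<- FALSE
        }
      }
    }
  }
  assign_class(IGG_CLASSES, scheme$igg_max_mismatch)
  assign_class("klMA", scheme$klma_max_mismatch)

  # resolve shared IgG2/IgG4 identifier via the discriminator base
  is24 <- label == "IgG24"
  if (any(is24)) {
    d <- scheme$discriminator
    base <- substr(r2[is24], d$position, d$position)
    res <- unname(d$base_map[base])
    res[is.na(res) | base == ""] <- d$fallback
    label[is24] <- res
    # a fallback keeps no matched identifier: no rule fired for the subclass
    fell <- is24 & label == d$fallback & d$fallback == "undetermined"
    matched[fell] <- ""
    mism[fell] <- NA_integer_
  }

  data.frame(label = label, matched_identifier = matched,
             mismatches = mism, flag = flag, stringsAsFactors = FALSE)
}

# ---- scheme derivation from CH1 references --------------------------------

#' Read CH1 constant-region references from FASTA
#'
#' Each record description must carry the subclass as `subclass=<label>`
#' (e.g. `>IGHG1-a subclass=IgG1`). Sequences must be gap-free A/C/G/T.
#'
#' @param path FASTA file.
#' @return data.frame with columns `allele`, `subclass`, `seq`
#'   (class `ch1_reference`).
#' @export
read_ch1_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  desc <- names(x)
  m <- regmatches(desc, regexpr("subclass=\\S+", desc))
  if (length(m) != length(x)) {
    stop("every CH1 FASTA record needs a 'subclass=' tag in its description")
  }
  seqs <- normalize_seq(as.character(x))
  if (any(grepl("[^ACGT]", seqs))) {
    stop("CH1 reference sequences must be gap-free A/C/G/T")
  }
  out <- data.frame(
    allele = sub("\\s.*$", "", desc),
    subclass = sub("^subclass=", "", m),
    seq = seqs,
    stringsAsFactors = FALSE
  )
  class(out) <- c("ch1_reference", class(out))
  out
}

#' Derive a subclass-calling scheme from CH1 references
#'
#' Locates the indexing-primer anchor in every allele, extracts the
#' `identifier_length`-nt window immediately 3' of the anchor, groups alleles
#' with identical windows, and emits one class per distinguishable group.
#' Groups whose window is shared by IgG2 and IgG4 become class `IgG24` and a
#' read-2 discriminator is proposed from a position on which the merged
#' subclasses still differ within the read-2 start (template positions 1-6
#' upstream of the read-2 primer site, read as the complement at read-2
#' position `7 - p`). The klMA identifier is not derivable from CH1 and is
#' supplied explicitly.
#'
#' @param ref a [read_ch1_reference()] table (or equivalent data.frame).
#' @param anchor IUPAC anchor primer marking the identifier window start
#'   (default the packaged indexing-primer sequence).
#' @param identifier_length window length in nt (default 12).
#' @param klma_identifier explicit klMA identifier sequence(s), or `NULL` to
#'   omit the class (default: packaged identifier, the position-wise
#'   complement of the IgG1 window).
#' @param anchor_max_mismatch tolerated non-degenerate mismatches when
#'   locating the anchor (default 1).
#' @param ... passed on to [subtype_scheme()] (tolerances).
#' @return a [subtype_scheme()].
#' @export
derive_scheme <- function(ref,
                          anchor = "CCATCGGTCTTCCCCCTGGCRCCCTSCTCC",
                          identifier_length = 12L,
                          klma_identifier = "TTCTCGTGGAGA",
                          anchor_max_mismatch = 1L,
                          ...) {
  stopifnot(all(c("allele", "subclass", "seq") %in% names(ref)))
  la <- nchar(anchor)
  windows <- character(nrow(ref))
  for (i in seq_len(nrow(ref))) {
    pos <- locate_anchor(anchor, ref$seq[i], anchor_max_mismatch)
    if (is.na(pos)) {
      stop("anchor primer not found in allele: ", ref$allele[i])
    }
    w_start <- pos + la
    w_end <- w_start + identifier_length - 1L
    if (w_end > nchar(ref$seq[i])) {
      stop("allele ", ref$allele[i], " too short for identifier window")
    }
    windows[i] <- substr(ref$seq[i], w_start, w_end)
  }

  groups <- split(seq_len(nrow(ref)), windows)
  identifiers <- list()
  merged_24 <- NULL
  for (w in names(groups)) {
    members <- groups[[w]]
    subclasses <- sort(unique(ref$subclass[members]))
    if (length(subclasses) == 1L) {
      cls <- subclasses
    } else if (setequal(subclasses, c("IgG2", "IgG4"))) {
      cls <- "IgG24"
      merged_24 <- members
    } else {
      stop("identifier window merges subclasses with no available ",
           "discriminator: ", paste(subclasses, collapse = "+"))
    }
    identifiers[[cls]] <- sort(unique(c(identifiers[[cls]], w)))
  }

  disc <- discriminator_rule()
  if (!is.null(merged_24)) {
    disc <- propose_discriminator(ref[merged_24, , drop = FALSE])
  }
  if (!is.null(klma_identifier)) {
    identifiers[["klMA"]] <- normalize_seq(klma_identifier)
  }
  ord <- intersect(c(IGG_CLASSES, "klMA"), names(identifiers))
  subtype_scheme(identifiers[ord], discriminator = disc,
                 identifier_length = identifier_length, ...)
}

# Find a template position p in 1..6 (the read-2 start covers the complement
# of template positions 6..1) that separates IgG2 from IgG4 alleles, and turn
# it into a read-2 discriminator rule.
propose_discriminator <- function(ref24) {
  for (p in 1:6) {
    b <- substr(ref24$seq, p, p)
    b2 <- unique(b[ref24$subclass == "IgG2"])
    b4 <- unique(b[ref24$subclass == "IgG4"])
    if (length(b2) == 1L && length(b4) == 1L && b2 != b4) {
      map <- stats::setNames(c("IgG2", "IgG4"),
                             complement_seq(c(b2, b4)))
      return(discriminator_rule(read = 2L, position = 7L - p, base_map = map))
    }
  }
  stop("IgG2 and IgG4 windows coincide and no discriminator position ",
       "separates them within the read-2 start")
}

# ---- scheme config file round trip ----------------------------------------

#' Read / write a scheme configuration file
#'
#' Schemes round-trip losslessly through a small YAML file holding the
#' identifier length, per-class identifier lists, tolerances and the
#' discriminator rule.
#'
#' @param path file path.
#' @return `read_scheme()` returns a [subtype_scheme()];
#'   `write_scheme()` returns `path` invisibly.
#' @export
read_scheme <- function(path) {
  y <- yaml::read_yaml(path)
  disc <- discriminator_rule(
    read = y$discriminator$read,
    position = y$discriminator$position,
    base_map = unlist(y$discriminator$base_map),
    fallback = y$discriminator$fallback %||% "undetermined"
  )
  subtype_scheme(
    identifiers = lapply(y$identifiers, as.character),
    discriminator = disc,
    identifier_length = y$identifier_length,
    igg_max_mismatch = y$igg_max_mismatch,
    klma_max_mismatch = y$klma_max_mismatch
  )
}

#' @rdname read_scheme
#' @param scheme a [subtype_scheme()].
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "subtype_scheme"))
  d <- scheme$discriminator
  yaml::write_yaml(list(
    identifier_length = scheme$identifier_length,
    identifiers = scheme$identifiers,
    igg_max_mismatch = scheme$igg_max_mismatch,
    klma_max_mismatch = scheme$klma_max_mismatch,
    discriminator = list(
      read = d$read, position = d$position,
      base_map = as.list(d$base_map), fallback = d$fallback
    )
  ), path)
  invisible(path)
}

#' The packaged default subclass-calling scheme
#'
#' The default scheme was derived with [derive_scheme()] from the packaged
#' CH1 reference alignment (12-nt window 3' of the indexing-primer anchor)
#' and is shipped as a versioned config file: IgG1 `AAGAGCACCTCT`, IgG3
#' `AGGAGCACCTCT`, shared IgG2/IgG4 `AGGAGCACCTCC` (resolved at read-2
#' position 4, G -> IgG2, A -> IgG4), and klMA `TTCTCGTGGAGA` (the
#' position-wise complement of the IgG1 identifier). IgG identifiers require
#' a perfect match; the klMA identifier tolerates one mismatch.
#'
#' @return a [subtype_scheme()].
#' @export
default_scheme <- function() {
  read_scheme(system.file("extdata", "default_scheme.yaml",
                          package = "igphase", mustWork = TRUE))
}
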