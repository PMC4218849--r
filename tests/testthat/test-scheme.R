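test_that("subclass calls follow the identifier and discriminator rules", {
  sch <- DEFAULT_SCHEME
  # exact identifiers, discriminator base for the shared IgG2/4 identifier
  calls <- call_subtype(
    i1 = c(ID_IGG1, ID_IGG3, ID_IGG24, ID_IGG24, ID_IGG24, ID_IGG24, ID_KLMA),
    r2 = c("GGAGGC", "GGAAGC", "GGAGGC", "GGAAGC", "GGATGC", "GGANGC", "ACGTAC"),
    scheme = sch
  )
  expect_equal(calls$label,
               c("IgG1", "IgG3", "IgG2", "IgG4",
                 "undetermined", "undetermined", "klMA"))
  expect_equal(calls$mismatches[1:4], rep(0L, 4))

  # a perfect match is required for IgG identifiers ...
  off3 <- "AGGAGCACCTAT"  # distance 1 from the IgG3 identifier, no other hit
  expect_equal(ham_oracle(off3, ID_IGG3), 1)
  expect_equal(call_subtype(off3, "GGAGGC", sch)$label, "undetermined")
  # ... but one mismatch is allowed for klMA
  off_klma <- neighbors1(ID_KLMA)[1]
  expect_equal(call_subtype(off_klma, "", sch)$label, "klMA")
  expect_equal(call_subtype(off_klma, "", sch)$mismatches, 1L)
  # distance >= 2 from everything is undetermined
  expect_equal(call_subtype("ACACACACACAC", "GGAGGC", sch)$label, "undetermined")

  # empty read 2 with the shared identifier cannot be resolved
  expect_equal(call_subtype(ID_IGG24, "", sch)$label, "undetermined")
  # N in a compared identifier position counts as a mismatch
  n_id <- sub("A", "N", ID_IGG1)
  expect_equal(call_subtype(n_id, "GGAGGC", sch)$label, "undetermined")
  # lowercase and U are normalized
  expect_equal(call_subtype(tolower(ID_IGG1), "ggaggc", sch)$label, "IgG1")
  expect_equal(call_subtype(chartr("T", "U", ID_IGG1), "GGAGGC", sch)$label,
               "IgG1")
  # wrong identifier length is flagged, not an error
  bad <- call_subtype(substr(ID_IGG1, 1, 11), "GGAGGC", sch)
  expect_equal(bad$label, "undetermined")
  expect_equal(bad$flag, "bad_identifier_length")
})

test_that("calls are deterministic and agree with the brute-force oracle at distance <= 1", {
  sch <- DEFAULT_SCHEME
  ids <- unlist(sch$identifiers, use.names = FALSE)
  probes <- unique(c(ids, unlist(lapply(ids, neighbors1))))
  r2s <- c("GGAGGC", "GGAAGC", "GGACGC")
  for (r2 in r2s) {
    got <- call_subtype(probes, r2, sch)$label
    want <- vapply(probes, oracle_call, character(1), r2 = r2, scheme = sch)
    expect_equal(got, unname(want))
    # determinism: identical inputs, identical calls
    expect_identical(got, call_subtype(probes, r2, sch)$label)
  }
})

test_that("scheme derivation from CH1 references reproduces the packaged default", {
  ref <- read_ch1_reference(system.file("extdata", "ch1_refs_synthetic.fasta",
                                        package = "igphase"))
  expect_equal(nrow(ref), 5L)
  sch <- derive_scheme(ref)
  expect_identical(sch$identifiers, DEFAULT_SCHEME$identifiers)
  expect_equal(sch$discriminator$position, 4L)
  expect_equal(sch$discriminator$base_map, c(G = "IgG2", A = "IgG4"))
  # identical windows within one subclass collapse to a single identifier
  expect_length(sch$identifiers$IgG1, 1L)
})

test_that("scheme derivation handles toy alleles, missing anchors, and unresolvable merges", {
  anchor <- "CCATCGGTCTTCCCCCTGGCRCCCTSCTCC"
  base <- function(c1, r, s, win) {
    paste0(c1, "TCCACCAAGGGCC",
           sub("R", r, sub("S", s, anchor)), win, "GGGGGCACA")
  }
  # four alleles differing only at the subtype determinants
  ref <- data.frame(
    allele = c("a1", "a2", "a3", "a4"),
    subclass = c("IgG1", "IgG2", "IgG3", "IgG4"),
    seq = c(base("GCC", "A", "C", "AAGAGCACCTCT"),
            base("GCC", "G", "G", "AGGAGCACCTCC"),
            base("GCT", "G", "G", "AGGAGCACCTCT"),
            base("GCT", "G", "G", "AGGAGCACCTCC"))
  )
  sch <- derive_scheme(ref, klma_identifier = NULL)
  expect_setequal(names(sch$identifiers), c("IgG1", "IgG3", "IgG24"))
  expect_equal(sch$discriminator$position, 4L)

  # anchor absent from one allele -> named error
  ref_bad <- ref
  ref_bad$seq[2] <- paste0(strrep("ACGT", 30))
  expect_error(derive_scheme(ref_bad, klma_identifier = NULL), "a2")

  # IgG1 and IgG3 sharing a window cannot be discriminated
  ref_merge <- ref
  ref_merge$seq[3] <- base("GCC", "A", "C", "AAGAGCACCTCT")
  expect_error(derive_scheme(ref_merge, klma_identifier = NULL),
               "no available")
})

test_that("scheme validation reports distances and tolerance safety", {
  rep_ <- validate_scheme(DEFAULT_SCHEME)
  expect_true(rep_$safe)
  igg <- c("IgG1", "IgG3", "IgG24")
  expect_equal(min(rep_$min_inter_class[igg, igg], na.rm = TRUE), 1L)
  expect_true(all(rep_$min_inter_class["klMA", igg] >= 10))

  # a klMA identifier one step from an IgG identifier is ambiguous under
  # klma_max_mismatch = 1 and must be rejected
  expect_error(
    subtype_scheme(list(IgG1 = ID_IGG1, klMA = neighbors1(ID_IGG1)[1]),
                   klma_max_mismatch = 1L),
    "ambiguous"
  )
  # single-class scheme: empty off-diagonal, safe
  solo <- subtype_scheme(list(IgG1 = ID_IGG1))
  expect_true(validate_scheme(solo)$safe)

  # malformed schemes are rejected
  expect_error(subtype_scheme(list(IgG1 = "ACGT")), "length")
  expect_error(subtype_scheme(list(IgG1 = ID_IGG1, IgG3 = ID_IGG1)), "shared")
})

test_that("scheme config files round-trip losslessly", {
  path <- file.path(withr::local_tempdir(), "scheme.yaml")
  write_scheme(DEFAULT_SCHEME, path)
  back <- read_scheme(path)
  expect_identical(back$identifiers, DEFAULT_SCHEME$identifiers)
  expect_identical(back$discriminator$base_map,
                   DEFAULT_SCHEME$discriminator$base_map)
  expect_identical(back$igg_max_mismatch, DEFAULT_SCHEME$igg_max_mismatch)
  expect_identical(back$klma_max_mismatch, DEFAULT_SCHEME$klma_max_mismatch)
  expect_identical(back$identifier_length, DEFAULT_SCHEME$identifier_length)
})
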