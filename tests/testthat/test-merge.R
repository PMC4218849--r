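test_that("constructed overlaps reconstruct the template and respect the minimum", {
  set.seed(42)
  template <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                    collapse = "")
  r1 <- substr(template, 1, 30)
  r2 <- rc_oracle(substr(template, 21, 50))  # 10 nt true overlap
  m <- merge_pair(r1, strrep("F", 30), r2, strrep("F", 30))
  expect_equal(m$status, "ok")
  expect_equal(m$sequence, template)
  expect_equal(m$overlap_length, 10L)
  expect_equal(nchar(m$sequence), 30 + 30 - m$overlap_length)

  # only 9 shared nucleotides: below the minimal overlap, must fail
  r2_short <- rc_oracle(substr(template, 22, 51 - 1))
  # mismatch tolerance 0 isolates the minimum-overlap rule from chance
  # near-matches at spurious offsets
  m9 <- merge_pair(r1, strrep("F", 30), paste0(r2_short, "A"), strrep("F", 30),
                   max_mismatch_frac = 0)
  expect_false(m9$status == "ok")

  # reconstruction property over random templates and overlaps
  for (i in 1:40) {
    tl <- sample(45:70, 1)   # true overlap 80 - tl stays >= min_overlap
    template <- paste(sample(c("A", "C", "G", "T"), tl, replace = TRUE),
                      collapse = "")
    r1 <- substr(template, 1, 40)
    r2 <- rc_oracle(substr(template, tl - 39, tl))
    ov <- 80 - tl
    m <- merge_pair(r1, strrep("F", 40), r2, strrep("F", 40))
    if (m$status == "ok") {
      expect_equal(m$sequence, template)
      expect_equal(m$overlap_length, ov)
    } else {
      # random sequence can tie a spurious junction; never a wrong merge
      expect_equal(m$status, "ambiguous")
    }
  }
})

test_that("overlap consensus takes the higher-quality base and handles N", {
  template <- "ACGGTTCAGCATTGACCGTA"               # 20 nt, aperiodic
  r1 <- substr(template, 1, 14)
  r2_true <- substr(template, 7, 20)               # 8 nt overlap at 14+14-20
  # inject a mismatch in the overlap: template pos 10 (r1 pos 10, r2rc pos 4)
  r1_mut <- r1
  substr(r1_mut, 10, 10) <- "A"                    # true base is T
  q_hi <- strrep("I", 14)                          # Q40
  q_lo <- paste0(strrep("I", 9), "#", strrep("I", 4))  # Q2 at the mutated base
  m <- merge_pair(r1_mut, q_lo, rc_oracle(r2_true), q_hi,
                  min_overlap = 8, max_mismatch_frac = 0.2)
  expect_equal(m$status, "ok")
  expect_equal(m$sequence, template)               # high-quality base wins
  expect_equal(m$overlap_mismatches, 1L)
  # reversed qualities: the mutated r1 base wins instead
  m2 <- merge_pair(r1_mut, q_hi, rc_oracle(r2_true), strrep("#", 14),
                   min_overlap = 8, max_mismatch_frac = 0.2)
  expect_equal(m2$status, "ok")
  expect_equal(substr(m2$sequence, 10, 10), "A")

  # N never counts as a match but is overridden by a real base
  r1_n <- r1
  substr(r1_n, 10, 10) <- "N"
  mn <- merge_pair(r1_n, q_hi, rc_oracle(r2_true), q_hi,
                   min_overlap = 8, max_mismatch_frac = 0.2)
  expect_equal(mn$status, "ok")
  expect_equal(mn$sequence, template)

  # consensus quality never drops below the lower input quality
  quals <- utf8ToInt(m$quality) - 33L
  expect_true(all(quals >= 2))
})

test_that("merging is strand-symmetric", {
  set.seed(7)
  for (i in 1:20) {
    tl <- sample(40:70, 1)
    template <- paste(sample(c("A", "C", "G", "T"), tl, replace = TRUE),
                      collapse = "")
    r1 <- substr(template, 1, 35)
    r2 <- rc_oracle(substr(template, tl - 34, tl))
    a <- merge_pair(r1, strrep("F", 35), r2, strrep("F", 35))
    # swap mates: read 1 becomes the reverse-strand read and vice versa
    b <- merge_pair(r2, strrep("F", 35), r1, strrep("F", 35))
    expect_equal(a$status, b$status)
    if (a$status == "ok") {
      expect_equal(b$sequence, rc_oracle(a$sequence))
      expect_equal(a$overlap_length, b$overlap_length)
    }
  }
})

test_that("ambiguous junctions fail rather than guess", {
  # two candidate overlaps with identical score: o=12 (11 match, 1 mismatch)
  # and o=10 (10 matches) both score 10 * w under constant quality
  r1 <- strrep("A", 12)
  r2rc <- paste0(strrep("A", 10), "GA")
  m <- merge_pairs_cpp(r1, strrep("F", 12), r2rc, strrep("F", 12), 10L, 0.5)
  expect_equal(m$status, "ambiguous")
  expect_equal(m$sequence, "")
})

test_that("batch merging reports rates and routes failures", {
  set.seed(3)
  n <- 50
  templates <- vapply(sample(320:380, n, replace = TRUE), function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  r1 <- list(id = sprintf("c%02d", 1:n),
             seq = substr(templates, 1, 250),
             qual = const_qual(substr(templates, 1, 250)))
  r2seq <- vapply(templates, function(t) {
    rc_oracle(substr(t, nchar(t) - 249, nchar(t)))
  }, character(1), USE.NAMES = FALSE)
  r2 <- list(id = r1$id, seq = r2seq, qual = const_qual(r2seq))
  mb <- merge_batch(r1, r2)
  expect_s3_class(mb, "merge_result")
  expect_equal(attr(mb, "n_input"), n)
  expect_equal(attr(mb, "merge_rate"), 100)        # all true overlaps >= 120
  expect_equal(nchar(mb$sequence), nchar(templates))

  # templates longer than len(r1) + len(r2) - min_overlap cannot merge
  long <- paste(sample(c("A", "C", "G", "T"), 520, replace = TRUE),
                collapse = "")
  lr1 <- list(id = "x", seq = substr(long, 1, 250),
              qual = const_qual(substr(long, 1, 250)))
  lseq <- rc_oracle(substr(long, 271, 520))
  lr2 <- list(id = "x", seq = lseq, qual = const_qual(lseq))
  mb2 <- merge_batch(lr1, lr2)
  expect_equal(attr(mb2, "merge_rate"), 0)

  # empty batch
  e <- list(id = character(0), seq = character(0), qual = character(0))
  mb3 <- merge_batch(e, e)
  expect_equal(attr(mb3, "n_input"), 0L)
})
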