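make_counts <- function(rearr, sample = "s1") {
  counts_table(data.frame(
    sample = sample,
    category = c("IgG1", "IgG2", "IgG3", "IgG4"),
    assigned_pairs = rearr + 10, merged = rearr + 5, rearranged = rearr
  ))
}

test_that("subclass frequencies are the IgG-only rearrangement percentages", {
  f <- subtype_frequencies(make_counts(c(100, 0, 0, 0)))
  expect_equal(unlist(f[, c("IgG1", "IgG2", "IgG3", "IgG4")]),
               c(IgG1 = 100.0, IgG2 = 0.0, IgG3 = 0.0, IgG4 = 0.0))

  # scale invariance: k-fold counts leave frequencies unchanged
  base <- c(505942, 354751, 34920, 3572)
  f1 <- subtype_frequencies(make_counts(base))
  f7 <- subtype_frequencies(make_counts(base * 7))
  expect_equal(f1[, -1], f7[, -1])

  # the four reported percentages sum to 100 +/- rounding
  set.seed(9)
  for (i in 1:25) {
    f <- subtype_frequencies(make_counts(sample.int(1e6, 4)))
    s <- sum(unlist(f[, -1]))
    expect_true(s >= 99.9 - 1e-9 && s <= 100.1 + 1e-9)
  }

  # klMA is excluded from numerator and denominator
  cnt <- counts_table(data.frame(
    sample = "s1",
    category = c("IgG1", "IgG2", "IgG3", "IgG4", "klMA"),
    assigned_pairs = c(60, 30, 5, 5, 900),
    merged = c(60, 30, 5, 5, 900),
    rearranged = c(60, 30, 5, 5, 900)
  ))
  expect_equal(subtype_frequencies(cnt)$IgG1, 60)

  # all-zero IgG counts: named error, no division
  expect_error(subtype_frequencies(make_counts(c(0, 0, 0, 0))), "no IgG")
})

test_that("replicate aggregation uses mean and population SD at one decimal", {
  f <- data.frame(IgG1 = c(56.3, 55.9, 55.9, 56.3),
                  IgG2 = c(1, 1, 1, 1), IgG3 = c(1, 1, 1, 1),
                  IgG4 = c(1, 1, 1, 1))
  agg <- aggregate_preps(f)
  expect_equal(agg["mean", "IgG1"], 56.1)
  expect_equal(agg["sd", "IgG1"], 0.2)
  expect_equal(agg["sd", "IgG2"], 0.0)          # identical rows -> SD 0
  expect_match(attr(agg, "sd_convention"), "population")

  two <- aggregate_preps(f[1:2, ])
  expect_equal(two["mean", "IgG1"], round((56.3 + 55.9) / 2, 1))

  one <- aggregate_preps(f[1, , drop = FALSE])  # single prep: SD n/a
  expect_true(is.na(one["sd", "IgG1"]))
  expect_equal(one["mean", "IgG1"], 56.3)
})

test_that("counts tables validate stage monotonicity and round-trip via TSV", {
  expect_error(counts_table(data.frame(
    sample = "s", category = "IgG1",
    assigned_pairs = 5, merged = 9, rearranged = 1
  )), "merged <= assigned")
  expect_error(counts_table(data.frame(
    sample = "s", category = "IgG1",
    assigned_pairs = 9, merged = 5, rearranged = 7
  )), "rearranged <= merged")
  expect_error(counts_table(data.frame(
    sample = "s", category = "IgZ9",
    assigned_pairs = 9, merged = 5, rearranged = 1
  )), "unknown categor")

  cnt <- example_counts()
  path <- file.path(withr::local_tempdir(), "counts.tsv")
  write_counts_table(cnt, path)
  back <- read_counts_table(path)
  expect_equal(as.data.frame(back), as.data.frame(cnt))
  expect_equal(attr(back, "total_reads"), attr(cnt, "total_reads"))
  expect_equal(attr(back, "sample_undetermined"),
               attr(cnt, "sample_undetermined"))
})

test_that("run-level rates have explicit degenerate-input errors", {
  cnt <- make_counts(c(10, 10, 10, 10))   # no run totals attached
  expect_error(run_assignment_rate(cnt), "totals missing")
  # all reads sample-undetermined -> zero denominator
  cnt2 <- make_counts(c(10, 10, 10, 10))
  attr(cnt2, "total_reads") <- 100
  attr(cnt2, "sample_undetermined") <- 100
  expect_error(run_assignment_rate(cnt2), "denominator")
  # everything assigned -> 100%
  cnt3 <- counts_table(data.frame(
    sample = "s1", category = c("IgG1", "IgG2", "IgG3", "IgG4"),
    assigned_pairs = c(40, 30, 20, 10), merged = c(40, 30, 20, 10),
    rearranged = c(40, 30, 20, 10)
  ), total_reads = 100, sample_undetermined = 0)
  expect_equal(run_assignment_rate(cnt3), 100)
})

test_that("consensus collapse takes the strict majority of index calls", {
  res <- consensus_collapse(
    sequence = c("SEQA", "SEQA", "SEQA", "SEQB", "SEQB", "SEQC",
                 "SEQD", "SEQD"),
    label = c("IgG1", "IgG1", "IgG3", "IgG1", "IgG3", "IgG2",
              "undetermined", "undetermined")
  )
  got <- setNames(res$consensus, res$sequence)
  expect_equal(got[["SEQA"]], "IgG1")          # majority outvotes the error
  expect_equal(got[["SEQB"]], "undetermined")  # tie
  expect_equal(got[["SEQC"]], "IgG2")          # singleton keeps its call
  expect_equal(got[["SEQD"]], "undetermined")  # all undetermined

  # undetermined members never outvote a determined minority
  res2 <- consensus_collapse(c("S", "S", "S"),
                             c("IgG4", "undetermined", "undetermined"))
  expect_equal(res2$consensus, "IgG4")

  # unanimity is never changed
  set.seed(2)
  labs <- sample(c("IgG1", "IgG2", "IgG3", "IgG4", "klMA"), 30, replace = TRUE)
  res3 <- consensus_collapse(sprintf("UNIQ%02d", 1:30), labs)
  expect_equal(setNames(res3$consensus, res3$sequence)[sprintf("UNIQ%02d", 1:30)],
               setNames(labs, sprintf("UNIQ%02d", 1:30)))
})

test_that("presentation rounding is half-up at one decimal", {
  expect_equal(round_half_up(56.25, 1), 56.3)
  expect_equal(round_half_up(56.24, 1), 56.2)
  expect_equal(round_half_up(0.05, 1), 0.1)
})
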