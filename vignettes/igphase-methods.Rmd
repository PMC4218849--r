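---
title: "Subtype-phased Ig repertoire analysis: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtype-phased Ig repertoire analysis: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igphase)
```

## The assay and its decision model

A MiSeq-style run produces four synchronized reads per cluster: paired-end
reads 1 and 2 (≤ 250 nt each) over the antibody variable region, a 12-nt
index read 1 repurposed as a *subclass identifier* over the CH1 constant
region, and an 8-nt index read 2 for sample multiplexing. `igphase`
implements the complete decision model downstream of base calling:

1. **Sample assignment** (`assign_sample`). Index 2 is matched against the
   sample sheet: the nearest index within `i2_max_mismatch` wins; a tie at
   the minimal distance, or no index within tolerance, is undetermined; a
   reserved index (default `TCTTTCCC`, the index-2 region presented by
   unindexed TruSeq-Universal/PhiX-style control libraries) routes the
   cluster to a contaminant bucket.
2. **Subclass call** (`call_subtype`). Fixed evaluation order: exact
   membership (`igg_max_mismatch = 0`) in the IgG1, IgG3 or shared
   IgG2/IgG4 identifier sets; for the shared identifier, the read-2
   discriminator base (position 4: `G` → IgG2, `A` → IgG4, anything else —
   including `N` or a truncated read — undetermined); then membership
   within `klma_max_mismatch = 1` of the klMA identifier; otherwise
   undetermined. `N` counts as a mismatch at every compared position.
   Evaluating IgG classes before klMA means the wide klMA tolerance ball
   can never shadow an exact IgG match; the constructor additionally
   rejects any scheme in which two classes' tolerance balls touch
   (distance ≤ sum of tolerances), so the order never changes a call in an
   accepted scheme.
3. **Merge** (`merge_pair`). Read 2 is reverse-complemented and the pair
   is joined at the best-scoring ungapped 3′ overlap (below).
4. **Report** (`subtype_frequencies`). Per sample,
   `f(c) = 100 · rearranged(c) / Σ rearranged(IgG1..IgG4)`; klMA and
   undetermined reads are excluded from numerator and denominator. The
   published table marks klMA frequency columns "na", which we read as
   exclusion from the IgG denominator; this is the only reading under
   which the printed percentages are reproduced, and the package adopts
   it.

## The default scheme and its derivation

Identifier sequences are never hardcoded: every operation takes a
`subtype_scheme` object, and the packaged default is a versioned YAML
config derived by `derive_scheme()` from a CH1 reference alignment. The
derivation locates the indexing-primer anchor
(`CCATCGGTCTTCCCCCTGGCRCCCTSCTCC`, IUPAC-degenerate, up to one residual
mismatch tolerated) in each allele, extracts the 12-nt window 3′ of it,
groups identical windows, and emits one class per distinguishable group.
IgG2 and IgG4 windows coincide; the deriver then searches template
positions 1–6 (covered, complemented, by the start of read 2) for a base
separating them and proposes the read-2 discriminator — position 4, from
the GCC/GCT first CH1 codon. A window shared by any other subclass pair
has no discriminator and is a hard error.

The packaged CH1 FASTA (`ch1_refs_synthetic.fasta`) is a *synthetic*
reconstruction: offline, the true database records cannot be fetched, so
the alleles were rebuilt from the assay's published primer sequences
(which pin CH1 nucleotides 7–45 and 85–106) plus the documented subclass
determinants (positions 36, 41, 46–48, 55–57, and the first codon).
Positions that do not influence any decision are shared across
subclasses. The derived identifiers are therefore exact at every position
the pipeline reads, and `derive_scheme()` on this FASTA reproduces the
shipped default scheme (tested).

Two points were genuinely open and are resolved as explicit configuration:

- **klMA identifier.** It is described only as "complementary" to the
  IgG1 identifier. Working through the klMA indexing primer shows the
  index read observes the *position-wise complement* (not the reverse
  complement): `TTCTCGTGGAGA`. It ships in the config rather than being
  derived, so alternative chemistries can override it.
- **Allele variants.** Whether within-window allelic variants were
  accepted historically is unknowable; the scheme model therefore allows
  multiple accepted identifiers per class ("within tolerance of any
  accepted sequence"), and the default carries one per class.

## Overlap merging

The published pipeline delegated merging to an external stitcher,
specifying only the 10-nt minimum overlap; the scoring objective here is
the package's own, chosen for testability. For candidate overlaps
`o ∈ [min_overlap, min(L1, L2)]` the score is `Σ ±w_i` with `+` for a
match, `−` for a mismatch, and `w_i` the mean of the two Phred qualities
at that position; `N` never counts as a match. The best-scoring overlap
wins. Tie-breaks and failure modes are explicit:

- two candidates with equal best score → `ambiguous`, the pair fails
  (a guessed junction is never emitted);
- best overlap with mismatch fraction > `max_mismatch_frac` (default
  0.1, permissive for 2 × 250 tails) → `mismatch`;
- no geometric candidate → `no_overlap`.

Within the overlap the consensus base is the higher-quality base (quality
tie → read-1 base), with quality `max(q1, q2)` on agreement and the
winner's own quality on disagreement; a real base always overrides `N`.
Consequently the consensus quality never drops below the smaller input
quality. Merging is strand-symmetric: swapping the mates yields the
reverse complement. Indel-tolerant (gapped) overlap alignment is out of
scope; the error model the assay cares about is substitution-dominated.

The per-pair search is compiled (Rcpp), as is usual for per-read inner
loops in this field's packages.

## "Rearranged variable region" stand-in

The published counts call a merged sequence "rearranged" when an external
annotation service recognizes a full-length V(D)J. The package ingests
such externally produced counts unchanged (`read_counts_table`); when
running end-to-end without an annotator it applies a clearly labelled
stand-in heuristic — merged successfully and merged length ≥
`min_vregion_len` (default 250 nt, safely below the ~360 nt median
heavy-chain V region but above primer/adapter artifacts). The manifest
records `rearranged_method = "length_heuristic"`.

## Reporting conventions

- Percentages are rounded half-up to one decimal, matching the
  presentation of the published tables (base R's `round()` is
  round-half-even and would print 56.25 as 56.2).
- Replicate aggregation reports the arithmetic mean and the *population*
  standard deviation (divisor *n*, recorded in the result's
  `sd_convention` attribute). With four replicates both SD conventions
  round to the same one-decimal values; the choice is therefore a
  convention, fixed and recorded rather than inferred.
- Run-level rates: assignment rate = assigned pairs (IgG1–4 + klMA, all
  samples) / (total reads − sample-undetermined); merge rate = merged /
  assigned over the same categories; composition rates are relative to
  total passing-filter reads.
- `consensus_collapse` groups identical merged sequences and takes the
  strict majority of their non-undetermined subclass calls (tie or
  all-undetermined → undetermined), so an identifier sequencing error in
  one member is outvoted by its identical siblings. Undetermined members
  never outvote a determined minority.

## The simulator: what it emulates and what it does not

`simulate_run()` generates the amplicon structure the pipeline keys on:
4 synthesis-phase random nucleotides + a 20-nt leader stub + a random
V-like core + the subtype's first two CH1 codons (`GCC TCC` for IgG1/2,
`GCT TCC` for IgG3/4) so the read-2 discriminator base is physically
determined by the template, not asserted; index 1 carries the class
identifier, index 2 the sample index; contaminant clusters carry random
sequence and the reserved index. Defaults are the run design the package
targets: 2 × 250 nt reads, 12/8-nt indices, template length ~
Normal(390, 15) truncated to `[251, 490]` (mate overlap ≈ 110 nt at the
peak, V-like insert ≈ 360 nt), per-base substitution rate 0.003 (typical
MiSeq), contaminant fraction 0.05 (the usual PhiX spike level), constant
Q37 qualities.

Composition is allocated by largest remainder by default
(`exact_mixture = TRUE`), so an error-free run reproduces the configured
mixture *exactly* and recovery tests have sharp expectations; multinomial
draws are available for distributional realism. All randomness flows from
one seed; a fixed seed reproduces the run record-for-record.

The simulator deliberately does **not** model: indels (the pipeline's
decision points — identifier membership, one discriminator base, ungapped
overlap — are substitution-sensitive), quality-dependent error profiles,
somatic hypermutation or clonal structure, PCR chimeras, or real V-gene
sequence (an optional FASTA of real cores can be supplied). Passing tests
therefore demonstrate the correctness of the decision logic under the
assay's geometry, not performance on biologically structured repertoires.

For identifier errors the package carries an independent closed-form
check, `predict_undetermined_fraction()`: with per-base rate *e*, the
probability of reading sequence *u* from source *s* is
`(e/3)^d (1−e)^(L−d)` with `d = hamming(s, u)`; summing over all accepted
identifiers and the radius-1 klMA ball (balls are disjoint in any accepted
scheme) gives the exact assignment probability. Simulated undetermined
fractions are compared against this prediction within 3σ binomial bounds.

## Problem sizes and numerical tolerances

The test suite and acceptance script use: desk-scale table arithmetic on
the packaged example counts (< 1 s); exhaustive distance-≤ 1 identifier
perturbations (all 36 per identifier) plus a random distance-2 sample
against a brute-force nearest-identifier oracle; simulated runs of
300–10,000 clusters with 3 samples; a 2% identifier error rate for the
binomial comparison (expected undetermined fraction ≈ 21%). These sizes
make the whole suite run in well under a minute of compute while keeping
binomial standard errors small (≈ 0.4 percentage points at n ≈ 9,400).

Degenerate inputs are defined behaviour, not crashes: wrong-length index
reads are flagged and routed to undetermined; desynchronized FASTQ
streams abort with the offending record ids; empty inputs produce empty
outputs and zero tallies; all-zero IgG counts and zero denominators raise
named errors.

## Known limitations

- Whole runs are held in memory; the design targets method development
  and validation-scale data, not full production flow cells.
- The merge objective is not a bit-exact reproduction of any external
  stitcher; published merge rates are reproduced from counts, not by
  re-merging raw reads.
- Pre-existing mutations in the constant region are indistinguishable
  from sequencing errors at the identifier and can misassign a cluster;
  the consensus-collapse correction reduces, but cannot eliminate, this.
- Full-CH1 sequencing-based calling (which would raise inter-subclass
  distances to 6–15 nt) is out of scope.
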