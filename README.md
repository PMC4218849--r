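# igphase

Subtype-phased immunoglobulin repertoire sequencing analysis in R.

## The problem

Paired-end Illumina amplicon sequencing of antibody heavy-chain variable
regions (2 × 250 nt) can reconstruct a full V(D)J rearrangement, but the
nucleotides that distinguish the four human IgG subclasses (IgG1–IgG4) sit
too far into the constant region to be reached when the HCDR3 is long. The
assay this package supports solves that by repurposing index read 1 — a
short auxiliary read normally used for sample multiplexing — as a **third
read** over the first constant-domain (CH1) region: a 12-nt *subclass
identifier*. Sample multiplexing stays on the 8-nt index read 2.

Within the 12-nt identifier window (CH1 nucleotides 46–57, immediately 3′
of the indexing-primer binding site) the subclasses read

| class | identifier | matching rule |
|---|---|---|
| IgG1 | `AAGAGCACCTCT` | perfect match |
| IgG3 | `AGGAGCACCTCT` | perfect match |
| IgG2/IgG4 (shared) | `AGGAGCACCTCC` | perfect match, then discriminator |
| klMA (light chains, IgM/IgA) | `TTCTCGTGGAGA` | ≤ 1 mismatch |

IgG2 and IgG4 are identical in the window and are separated by the third
base of the first CH1 codon (GCC vs GCT), observed as the **fourth base of
read 2** (read 2 is the reverse strand): `G` → IgG2, `A` → IgG4. Because
the minimal Hamming distance between IgG identifiers is a single
nucleotide, IgG calls require a perfect match; the klMA identifier is the
position-wise complement of the IgG1 identifier, distance ≥ 10 from every
IgG identifier, and tolerates one mismatch.

Per sample, the subclass frequency of class *c* is reported as

    f(c) = 100 · rearranged(c) / Σ_{c′ ∈ {IgG1..IgG4}} rearranged(c′)   [%]

the percentage of completely indexed, full-length variable-region
rearrangements; klMA and undetermined reads enter neither numerator nor
denominator.

The package implements the full decision pipeline — sample demultiplexing
on index 2 (nearest index within tolerance, ties undetermined, reserved
index for PhiX-like contaminant clusters), subclass calling, quality-aware
3′-overlap merging of the read pair (minimum overlap 10 nt), counting and
frequency reporting, replicate aggregation, and an optional
consensus-collapse correction that outvotes identifier sequencing errors
among identical variable regions — plus a ground-truthed run simulator and
a scheme deriver that extracts identifiers from CH1 reference alignments.

## Worked example

Reporting from a published run's printed per-category counts (packaged as
`example_counts()`):

```r
library(igphase)
cnt <- example_counts()
subtype_frequencies(cnt)
#>          sample IgG1 IgG2 IgG3 IgG4
#> 1   donor_prep1 56.3 39.5  3.9  0.4
#> 2   donor_prep2 55.9 39.6  4.0  0.5
#> 3   donor_prep3 55.9 39.7  4.0  0.5
#> 4   donor_prep4 56.3 39.0  4.2  0.6
#> 5 patient_wk213 65.8 17.9 15.8  0.4
aggregate_preps(subtype_frequencies(cnt, paste0("donor_prep", 1:4)))
#>      IgG1 IgG2 IgG3 IgG4
#> mean 56.1 39.5  4.0  0.5
#> sd    0.2  0.3  0.1  0.1
run_assignment_rate(cnt)   # % of demultiplexed pairs assigned a category
#> [1] 97.5
run_merge_rate(cnt)        # % of assigned pairs whose mates overlapped
#> [1] 96.7
```

The four healthy-donor preparations (different PCR protocols and cDNA
inputs) agree to within ±0.3 percentage points, and the patient sample
shows the elevated IgG3 fraction (15.8%) that motivates subclass-resolved
repertoire analysis.

End-to-end on simulated data:

```r
sheet <- default_sample_sheet()
scheme <- default_scheme()
cfg <- sim_config(
  samples  = names(sheet$samples)[1:2],
  mixtures = setNames(rep(list(c(IgG1 = .5, IgG2 = .3, IgG3 = .15, IgG4 = .05)), 2),
                      names(sheet$samples)[1:2]),
  n_clusters = 1000, error_rate_i1 = 0, error_rate_r1 = 0,
  error_rate_r2 = 0, error_rate_i2 = 0, seed = 61)
sim <- simulate_run(cfg, scheme, sheet, "simrun")
run <- run_igphase(sim$r1, sim$r2, sim$i1, sim$i2, sheet, scheme, outdir = "out")
run
#> igphase run: 1000 clusters; 950 demultiplexed, 50 contaminant, 0 sample-undetermined
#> merged: 950  rearranged (length heuristic): 950
#>
#> Subclass frequencies (%):
#>       sample IgG1 IgG2 IgG3 IgG4
#>  donor_prep1   50   30   15    5
#>  donor_prep2   50   30   15    5
```

With zero injected errors the realized frequencies equal the configured
mixture exactly and every read pair merges back to its template.

A thin command-line interface wraps the same functions:

```sh
exec/igphase simulate --config sim.yaml --outdir simrun
exec/igphase run --r1 ... --r2 ... --i1 ... --i2 ... --outdir out
exec/igphase report --counts out/counts.tsv --out report.tsv --aggregate donor_prep1,donor_prep2
```

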