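---
title: "Quantifying HERV family expression with hervfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying HERV family expression with hervfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hervfam)
```

## The quantification model

`hervfam` measures the expression of human endogenous retrovirus (HERV)
families — not individual loci — from RNA-seq alignments. The unit of
measurement is deliberately coarse: per-family raw read counts, turned
into within-sample ratios against housekeeping genes. This sacrifices
locus resolution but buys robustness against the main nuisance in
cross-study comparisons: samples sequenced on different platforms with
read lengths from 38 to 150 bases and very different depths.

### Counting with a read-anchored overlap requirement

A read is counted toward a family locus when at least (about) 80% of the
read overlaps it. The counter, however, expresses its minimum-overlap
requirement as a fraction `f` of the *interval*, so `f` is back-derived
per family and per sample:

$$ f = \frac{0.8\,R}{L} $$

where $R$ is the sample's nominal read length and $L$ an assumed
full-length element size for the family. The defaults are 9,000 bp for
HML-3, HML-5 and HML-6, 10,000 bp for HML-1, HML-2, HML-4, HERV-W, ERV-L,
HERV-E, HERV-I and HERV-FRD, 12,000 bp for HERV-9 and 17,000 bp for
HERV-H — values near the *longest* elements of each family, so that reads
falling inside long proviruses are not lost. The consequence, accepted by
design, is that the requirement at a locus of length $\ell$ is
$0.8 R \cdot \ell / L \le 0.8R$: shorter loci require proportionally less
overlap, never more.

Numerical choices in the counter:

* the comparison is **inclusive** (`overlap >= f * length`) on the exact
  floating-point product, with no integer rounding, so a read whose
  overlap equals the requirement counts;
* overlaps are computed on 0-based half-open spans everywhere; SAM's
  1-based coordinates are converted once at ingestion, and the aligned
  span uses reference-consuming CIGAR operations only (soft clips extend
  the read length, not the span);
* a read may count for several intervals, and each mate of a pair counts
  independently (the behaviour of standard multi-interval coverage
  counters); duplicate-marked reads are kept;
* strand is ignored;
* intervals are used verbatim — overlapping loci within a family are not
  merged, since the upstream coordinate sets are curated per element and
  merging would silently change the denominator of the `f` rule;
* setting `f` to the smallest positive double reproduces plain
  ≥ 1 bp overlap counting, which the tests exploit as a degenerate case.

Housekeeping genes (SDHA, HPRT1, RBX1, RRAGA) are counted with the same
rule, using each gene's own annotated length as $L$, which makes the
required overlap exactly $0.8R$ regardless of the gene's size. The genes'
role is purely that of a within-sample depth denominator.

Mapping-quality filtering keeps records with MAPQ ≥ 20. The description
"quality over 20" and `samtools -q 20` (which keeps ≥ 20) conflict by one
point; we default to the `-q` semantics (`strict_mapq = FALSE`) and expose
the strict variant as a switch. Secondary and supplementary alignments are
dropped by default to avoid double counting; `include_secondary = TRUE`
restores them for tools that pre-filtered differently.

### Normalization

The order of operations is fixed and recorded in the run manifest,
because two of the steps do not commute:

1. **Pooling.** CD3+/CD3− fraction files of one patient are summed at the
   *raw count* level (families and housekeeping genes alike), before any
   ratio is formed. Summing counts is exactly equivalent to counting the
   concatenated alignment files, which the tests verify.
2. **Ratios.** Each family count is divided by each housekeeping gene
   count, giving four per-gene ratios per family and dataset. A
   housekeeping count of zero is a hard error: the ratios and the
   downstream `ln` transform cannot absorb it, and silently adding a
   pseudocount would change every number. A pseudocount mode exists but
   must be enabled explicitly.
3. **Duplicate averaging.** The per-gene ratios of a patient's biological
   duplicates are averaged arithmetically.
4. **Median combination.** The normalized expression value (NEV) is the
   median of the four per-gene ratios — with four genes, the mean of the
   two middle values.

Averaging before the median (rather than after) follows the narrative
order of the procedure this package operationalizes; the two orders give
different numbers when a patient's duplicates disagree about which genes
are extreme, so the choice is recorded in the manifest. The NEV is
invariant to multiplying all of a sample's counts by a constant — the
property that makes samples of different depths comparable.

### Group statistics

Per family, the package reports

* **fold change** — mean case NEV / mean control NEV, on the natural
  scale;
* **heterogeneity ratios** — each case unit's NEV over the control mean;
  their average equals the fold change exactly, so they decompose it;
* **p-value** — two-sided independent-samples t-test on `ln(NEV)`.
  Student's pooled-variance test is the default (`df = n1 + n2 − 2`);
  which variance treatment the original SPSS analyses reported is not
  recoverable, so Welch's test is available by flag. NEV = 0 aborts
  before the log rather than being patched.

No multiple-testing correction gates the results — thirteen families are
tested marginally — but a Benjamini–Hochberg column is emitted alongside
as supplementary output.

The **sensitivity grid** re-runs the comparison in six modes: the main
analysis (median combiner, per patient), four single-gene analyses (per
patient), and a per-dataset analysis (median combiner, duplicates kept
separate). Whether the per-dataset mode should use the median combiner is
not externally specified; we use the median for symmetry with the main
analysis. When every gene has identical counts the six rows coincide, and
without duplicates per-patient equals per-dataset — both degeneracies are
asserted in the tests.

## The simulator

`simulation_config()` defines a seeded toy study; `make_study_fixture()`
materializes it as BED + SAM + sample sheet + truth ledger. Three design
profiles mirror the study layouts the pipeline targets:

* **BALF** — 7 case patients vs 3 controls; three cases have biological
  duplicates (one pair mixing 76 bp and 100 bp reads), three are
  CD3+/CD3− fraction pairs at 150 bp; controls are 50 bp.
* **PBMC** — 3 vs 3 bulk samples at 100/150 bp.
* **HBEC** — 12 senescence-induced vs 12 noninduced samples at 38 bp.

The noise model: reads per locus are Poisson with mean `base ×
locus weight × depth factor × fold change` (fold change applied to case
samples only); read starts are uniform within the locus; a configured
fraction of reads straddles a locus boundary with a uniform 1..R−1 bp
overlap (exercising the overlap rule); a configured fraction carries
sub-threshold MAPQ; background reads fall uniformly in intergenic gaps
and never touch a feature. Per-sample depth factors are log-normal
(sdlog 0.2), emulating unequal sequencing depths. Defaults: 200 expected
reads per family per unit-depth control dataset (three loci at 50/70/90%
of the assumed length with weights 0.5/0.3/0.2), housekeeping depths
1,000–1,800, 10% low-MAPQ reads, 2% boundary reads, 2% background — sizes
chosen so a full study simulates and counts in tens of seconds while
keeping per-family Poisson noise a few percent. The default planted fold
changes per profile are the corresponding published main-analysis
estimates, so the generator's defaults reproduce the study conditions it
emulates.

The **truth ledger** records, per feature, the reads emitted and the
reads that both pass MAPQ and meet the overlap rule; because features are
separated by 1 kb gaps and reads are ≤ 150 bp, a read can touch at most
one feature and the ledger is exact even with all noise sources enabled.
The tests require the pipeline's count table to equal the ledger
cell-for-cell.

Because the MAPQ filter and the overlap rule thin each locus's Poisson
reads independently, the post-filter counts are again Poisson with the
analytically known mean (`expected_counts()`). `simulate_count_table()`
draws from that distribution directly — distributionally identical to
counting a simulated read file — and is what the replicated calibration
studies use (500 null replicates for the type-I error of the t-test;
100 seeds for the sign-recovery of planted fold changes, where the sign
criterion is applied to families whose planted fold change differs
from 1, since `ln 1 = 0` has no sign). Single fixed-seed checks of
parameter recovery, ledger fidelity and determinism run the full
SAM-on-disk path.

What the simulator does **not** emulate: sequence content and sequencing
error (reads carry `*` SEQ/QUAL; read length comes from the CIGAR),
multi-mapping ambiguity (every simulated read has one alignment; real
HERV reads are frequently multi-mapped, which the MAPQ filter handles
only bluntly), splicing, fragment-length structure (reads are emitted
single-end, since the counting model treats mates independently; the
SAM reader and writer do handle mate flags), barcodes/UMIs, and any
biological covariance between families. Passing tests therefore
demonstrate the correctness of the counting, normalization and testing
machinery under the stated noise model — not that the 80%-overlap +
MAPQ-20 scheme resolves family attribution on real repetitive genomes.

## Limitations

* Family attribution is entirely inherited from the input coordinate set
  and the MAPQ filter; there is no probabilistic reassignment of
  multi-mapping reads.
* Ratio normalization assumes the housekeeping panel is stable across
  groups; a condition that dysregulates SDHA, HPRT1, RBX1 or RRAGA
  biases every fold change, which is exactly why the per-gene
  sensitivity analyses are first-class outputs.
* With three controls, the t-test on `ln(NEV)` leans on approximate
  normality of log-ratios; the null calibration in the tests supports
  the operating range of the simulator, not arbitrary designs.
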