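# hervfam

Family-level quantification of human endogenous retrovirus (HERV)
expression from aligned RNA-seq reads, with housekeeping-gene ratio
normalization and group-comparison statistics.

## The problem

HERVs are remnants of ancient retroviral infections that occupy roughly 8%
of the human genome, grouped into families (HML-1 through HML-6, HERV-H,
HERV-W, HERV-9, ERV-L, HERV-I, HERV-FRD, HERV-E). Their transcription is
normally silenced but rises in inflammation, cancer and cellular
senescence, which makes family-level expression differences between
patient and control transcriptomes biologically interesting. Comparing
such datasets is awkward: the samples of interest typically come from
different sequencing platforms with read lengths anywhere between 38 and
150 bases and very different depths, some patients have biological
duplicates, and some single-cell runs arrive as separate CD3+/CD3− cell
fraction files. `hervfam` implements a counting-and-ratio scheme designed
to be robust to exactly that heterogeneity.

## The method

For a sample with read length *R* and a HERV family with assumed
full-length element size *L* (9–17 kb depending on the family), reads with
mapping quality ≥ 20 are counted toward a family locus when their overlap
with it is at least

```
f × locus_length,   f = 0.8 R / L
```

i.e. approximately 80% of the read must overlap the element. Per-family
raw counts are the sum over that family's loci. Four housekeeping genes
(SDHA, HPRT1, RBX1, RRAGA) are counted the same way, with each gene's own
annotated length as *L*, so their required overlap is exactly `0.8 R`.

Normalization then proceeds in a fixed order:

1. **pool** CD3+/CD3− fraction files of one sample by summing raw counts;
2. **ratio** — each family count divided by each housekeeping gene count
   ("HERV reads per housekeeping gene reads");
3. **average** the per-gene ratios across a patient's biological
   duplicates;
4. **median** across the four per-gene ratios → the normalized expression
   value (NEV).

Group comparisons report, per family: the fold change (mean case NEV /
mean control NEV), per-unit heterogeneity ratios (each case NEV over the
control mean), and a two-sided independent-samples t-test on `ln(NEV)`
(pooled variance by default, Welch optional). A sensitivity grid re-runs
the comparison per single housekeeping gene and per dataset (duplicates
not averaged), six analysis modes in all.

A seeded simulator (`simulation_config()`, `make_study_fixture()`)
generates toy references, annotations and SAM files with planted
per-family fold changes and a truth ledger, so the full pipeline runs and
is testable without any external download.

## Worked example

Simulate a BALF-like study (7 case patients — three with biological
duplicates, three sequenced as CD3+/CD3− pairs — versus 3 controls, read
lengths 50–150 bp) and run the pipeline:

```r
library(hervfam)
fx  <- make_study_fixture("BALF", dir = file.path(tempdir(), "ex"), seed = 1)
res <- run_pipeline(fx$sheet_path, fx$bed_path, file.path(tempdir(), "ex_out"))
main <- subset(res$grid, analysis == "Main analysis",
               select = c(family, fold_change, p))
head(main[order(-main$fold_change), ], 5)
```

```
   family fold_change       p
 HERV-FRD       47.74 6.7e-16
   HERV-H       19.55 9.0e-15
   HERV-9       11.46 4.5e-11
   HERV-W        9.11 1.7e-14
    ERV-L        7.31 1.3e-11
```

The generator's default planted fold changes for this profile are 43.44
(HERV-FRD), 18.46 (HERV-H), 11.18 (HERV-9), 8.69 (HERV-W) and 7.37
(ERV-L), so the pipeline recovers the planted effects to within sampling
noise; `res$heterogeneity` holds the per-patient ratios to the control
mean, and `ex_out/differential.tsv` holds all six sensitivity rows per
family.

A thin command-line wrapper with subcommands `simulate | count |
normalize | diff | all` is installed at
`system.file("cli", "hervfam.R", package = "hervfam")`.

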