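---
title: "Complex structural variant classification and TAD-expression analysis with svtopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complex structural variant classification and TAD-expression analysis with svtopo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svtopo)
library(data.table)
```

# The problem

Multiple myeloma genomes carry a median of a few dozen structural variants
(SVs) per tumour, ranging from isolated deletions to chained rearrangements
that restructure several chromosomes at once. Three classes of complex
rearrangement recur: **chromothripsis** (localized clusters of breakpoints
with copy number oscillating between two states and loss of heterozygosity),
**chromoplexy** (chains whose bridge segments — the intervals between chained
breakends on one chromosome — are deleted) and **templated insertion** (chains
whose bridges are gained). Because SVs act largely through non-coding space,
their transcriptional consequences are best read through chromatin topology:
a rearrangement that fuses two topologically associated domains (TADs) can
place a super-enhancer next to a new target gene (a neo-TAD) and upregulate
it.

svtopo implements this analysis as a testable pipeline: junction ingestion
(BEDPE / Manta-dialect VCF), per-sample burden summaries and elbow
stratification, translocation hotspot binning, junction-graph construction and
complex-event classification, TAD assignment and the filtered ANOVA +
Benjamini–Hochberg (BH) gene scan, and paired-timepoint event comparison. A
seeded synthetic cohort generator stands in for controlled-access patient
data, so every stage ships with a recovery test against planted truth.

# Junction model and coordinate conventions

A junction is a pair of oriented breakends. Internally all coordinates are
**0-based, half-open**; conversions from 1-based formats (VCF POS/END) happen
in the readers and nowhere else. Orientation is `head` when the junction
retains the sequence to the *left* of the position in the derivative
chromosome and `tail` when it retains the right; BEDPE strand `+` maps to
`head`, `-` to `tail`, and the four VCF 4.2 bracket forms map as

| ALT form | local | mate |
|----------|-------|------|
| `t[p[`   | head  | tail |
| `t]p]`   | head  | head |
| `]p]t`   | tail  | head |
| `[p[t`   | tail  | tail |

Within a junction, breakends are stored in (chromosome, position) order, which
makes the VCF and BEDPE encodings of one junction identical after reading —
a property the tests assert on all four bracket forms. Unpaired breakend
records are dropped with a warning rather than an error because real caller
output contains them. Chromosome names are taken verbatim; mixed-reference
inputs are meant to fail loudly.

# Complex event calling

**Graph.** Junctions of one sample are nodes; an edge joins two junctions with
breakends on the same chromosome within `w_chain` (default 1 Mb). Connected
components with at least `min_junctions` (default 3) members are candidate
events. The defaults make desk-scale recovery unambiguous and are exposed in
`complex_params()`.

**Bridges.** Adjacent breakends of a candidate on one chromosome, belonging to
different junctions and within `w_chain`, bound a bridge. Its copy-number
delta is the overlap-weighted modal total copy number inside the bridge minus
the modal copy number of the two 1 Mb flanks (modes are robust to focal noise;
ties break toward the smaller copy number for determinism). Sign gives the
bridge kind: `del`, `gain` or `neutral`.

**Chromothripsis gate.** Breakends on a chromosome are clustered with a
maximal-gap rule (`window`, default 50 Mb). A cluster is chromothripsis when
it has ≥ `min_breakends` (default 10) breakends, the CN segments across its
span make ≥ `min_oscillations` (default 7) transitions between the two most
frequent CN states (a transition through any other state breaks the run), and
the span contains LOH (`minor_cn = 0` with at least one copy retained). The
thresholds follow the consensus-criteria style used in the field, since the
source definition is qualitative; `require_loh` is a flag because genuinely
tetraploid genomes can oscillate without LOH.

**Classification precedence.** An event whose junctions are at least half
inside called chromothripsis regions is labelled `chromothripsis`. Otherwise
deletion bridges in the majority (and ≥ 2) give `chromoplexy`; gain bridges in
the majority (and ≥ 2) give `templated_insertion` (flagged `simple_chain` when
only two chromosomes are involved, since the "complex" flavour requires more
than two); anything else is `unclassified_complex`. Two details matter in
practice. First, bridges that overlap a called chromothripsis region are
excluded from the del/gain tally: oscillating regions generate incidental
deletion bridges, and in high-burden genomes a chromothriptic cluster is often
absorbed into a larger chained component that would otherwise be mislabelled
chromoplexy. Second, the per-sample `has_chromothripsis` flag is true whenever
a region call passes the gate — chromothripsis is defined as a localized
region property, not a property of the (possibly much larger) chained
component around it.

`unclassified_complex` is an explicit "cannot classify" bucket: chains of
incidentally co-located simple SVs have copy-neutral bridges and land there.
The false-positive rate we quote for clean samples counts only the three named
labels.

# Burden, hotspots, elbow, timepoints

**Burden.** Per-sample totals split into intra- and interchromosomal
junctions; group comparisons use the Kruskal–Wallis rank test.

**Hotspots.** Both breakends of every translocation are binned (default 1 Mb,
matching locus-level resolution; the bin size is configurable because the
source analysis reports hotspots descriptively). Each bin counts *distinct*
samples; raw breakend incidences are reported alongside, since either
convention is defensible. The null is a uniform genome-wide rate; each bin
gets a one-sided binomial tail p-value for excess over expectation — bins at
or below expectation get p = 1, which makes the degenerate cases (all bins
equal; a single-bin genome) behave sensibly — followed by BH across bins.

**Elbow split.** Counts are sorted descending and the elbow is the point of
maximal perpendicular distance to the chord joining the first and last points:
deterministic, order-invariant and scale-free. Samples strictly above the
elbow count are high-burden; ties go low, and a constant vector yields an
empty high set. On a seeded 90/10 negative-binomial mixture (means 30/120,
n = 500) the split recovers the planted fraction within a few points, with
group medians near 100 versus 30 — qualitatively the split reported for real
cohorts.

**Timepoints.** Two events match when at least half of the *smaller* event's
junctions have a counterpart (both breakends within 1 kb by default) in the
other. The predicate is symmetric, so `gained(t1, t2)` equals `lost(t2, t1)`
exactly, and an event that acquires an extra junction at relapse — a
t(8;11) growing into a t(6;8;11) — is reported stable, not gained.

# TAD-expression analysis

Breakends are assigned to TADs by binary search under half-open containment;
positions in inter-TAD gaps get a `boundary` sentinel and TAD-less
chromosomes a `no_tad` sentinel. A TAD–TAD rearrangement joins two different
real TADs (sentinel-touching junctions are kept but flagged and excluded).
Neo-TADs retain `[tad.start, pos)` for a `head` breakend and `[pos, tad.end)`
for a `tail` breakend, and collect the genes overlapping either retained
interval.

For every TAD, carriers are samples with at least one TAD–TAD junction
touching it and controls are everyone else — carriers versus *all*
non-carriers, the simpler of the two readings of the source design. Grouping
is per single TAD rather than per TAD pair: pair-level resolution is
underpowered once a ≥ 5-case filter applies. Each gene in the TAD is tested
with a two-group one-way ANOVA on log2 expression (identical to the pooled
t-test in the two-group design; degenerate inputs are defined explicitly —
identical constant groups give p = 1). BH runs across **all** (TAD, gene)
tests in the run, the widest and most conservative family. A result passes
when the TAD has ≥ `min_cases` carriers (default 5), median expression
exceeds `min_median` (default 2, interpreted on the same normalized log2
scale as the input matrix — the unit is configurable because it is not pinned
down by the source) in at least one group, and q < `alpha` (default 0.05).

The boundary contrast for a single gene splits samples into *inside* (a
breakend inside the gene's TAD), *outside* (a breakend within 2 Mb of the TAD
but none inside; inside takes precedence for mixed samples) and *none*, and
compares expression across the groups with a Kruskal–Wallis test.

# The synthetic cohort generator

`simulate_cohort()` is first-class, tested code, not a fixture. Given a seed
it deterministically emits a toy genome (default 5 chromosomes of 50 Mb, 1 Mb
TADs with 50 kb boundary gaps, 3 genes per TAD), per-sample junctions, CN
segments that tile every chromosome, an expression matrix and a ground-truth
record. Its defaults are the study conditions:

* simple SV counts are negative binomial with mean 31 (size 10, so the median
  sits at ~30) and a 10% high-burden subpopulation at mean 120 (size 8) —
  reproducing a low group spanning roughly 5–80 events and a high group
  roughly 50–250;
* complex events are planted in 23% / 10% / 37% of samples (chromothripsis /
  chromoplexy / templated insertion), at most one class per sample so label
  recovery is unambiguous (real genomes mix them; that is a deliberate
  simplification);
* chromothripsis plants 16 breakends with 50–900 kb gaps and alternating
  2/1 CN with LOH, guaranteeing ≥ 7 oscillations; chains visit 3 chromosomes
  with 100–800 kb bridges at CN 1 (del) or CN 3 (gain);
* enhancer-hijack translocations from a fixed donor locus into selected
  target TADs add `effect_log2fc` (default +2) to the target TAD's genes in
  carrier samples, on a Normal(5, 1) log2 baseline.

For the TAD-expression recovery and null-calibration runs the generator is
used at 10 chromosomes × 50 Mb, 1 Mb TADs with one gene each (500 genes),
mean 6 simple SVs per sample and 25 hijack TADs with 8–14 carriers. This is a
calibration of breakend density per TAD, fixed at design time: the default
toy genome is ~12× denser per TAD than a real whole-genome cohort (a few
dozen SVs over ~3000 TADs), and at that density random background carriers
dilute any planted carrier group beyond what the real analysis experiences.
The problem sizes throughout (200-sample cohorts, 500 samples for the elbow
mixture, 50 gate trials, 500 genes) were chosen once as desk-scale versions of
the real cohort.

What the generator does **not** emulate — and what passing recovery tests
therefore do not show about real data: subclonality and tumour purity
(breakpoints and CN are clonal and exact), breakpoint-calling jitter and
false-positive junctions, copy-number effects of *simple* DELs/DUPs (simple
SVs are copy-neutral junctions here, so bridge logic is exercised only by
planted events), co-occurring complex events in one sample, replication
timing and chromatin covariates of real hotspots, and count-level expression
noise (expression is simulated directly on the log2 scale, since the pipeline
consumes a normalized matrix).

# Numerical and degenerate-input choices

* Modal copy number is overlap-length-weighted; ties break toward the smaller
  copy number. The two dominant oscillation states are chosen by segment
  count, ties again toward the smaller value.
* A breakend not covered by any CN segment is a hard error naming the
  position; flanks clipped at chromosome start use whatever coverage exists.
* Binomial hotspot p-values are defined as 1 when a bin is at or below its
  expectation (the test is one-sided for excess).
* `elbow_split` needs ≥ 3 samples; all-equal counts give an empty high set.
* Empty junction sets, empty event lists and SNV-only VCFs are all legal
  inputs that produce empty, typed outputs.

# Known limitations

Chromothripsis thresholds are consensus-style defaults, not a re-derivation
of any published caller; prevalences on real cohorts will depend on them.
The hotspot null ignores genome covariates, so real-data hotspot lists should
be read as descriptive. The pipeline assumes all inputs share one assembly
and does not lift over. Expression units for the median filter follow the
input matrix and must be set knowingly. The paired-timepoint matcher is
intentionally permissive (50% of the smaller event) and will merge events
that share half their junctions.

# A worked run

```{r example, eval = FALSE}
sim <- simulate_cohort(sim_params(seed = 7, n_samples = 200))
cx <- call_complex_events_cohort(sim$junctions, sim$cn,
                                 sample_ids = sim$truth$samples$sample_id)
table(cx$events$label)
scan <- tad_gene_scan(sim$junctions, sim$tads, sim$genes, sim$expression)
head(scan$results[scan$results$passes_filters, ])
```

The same quantities, recomputed end to end, are what
`scripts/acceptance.R --seed <int> --out <path>` writes as JSON.
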