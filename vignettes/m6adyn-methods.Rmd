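---
title: "Quantifying m6A dynamics across cardiomyocyte differentiation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying m6A dynamics across cardiomyocyte differentiation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6adyn)
```

# The measurement model

MeRIP-seq quantifies N6-methyladenosine by sequencing two libraries per
sample: an immunoprecipitated (IP) fraction enriched for methylated
fragments, and an input fraction measuring plain abundance. Within a
called peak, the ratio of depth-normalized IP coverage to depth-normalized
input coverage estimates the **m6A level** of that peak. `m6adyn` takes
peak-by-stage count matrices for both libraries across four
differentiation stages — hESC (D0), mesoderm (D2), cardiac progenitor
(D5), cardiomyocyte (D15) — and computes:

* **peak level**: `IP_cpm / input_cpm` per peak and stage;
* **gene level**: the pooled ratio `sum(IP_cpm) / sum(input_cpm)` over the
  gene's peaks. The pooled ratio (rather than a mean of ratios) weights
  peaks by their coverage and reduces exactly to the peak level for
  single-peak genes;
* **sample level**: the same pooled ratio over all retained peaks;
* **region level**: pooled ratios per transcript region (5'UTR, CDS,
  3'UTR, stop-proximal).

Peaks with an input count below 5 in **any** stage are removed before any
ratio is formed; this both mirrors standard MeRIP practice and guarantees
finite ratios without a pseudocount (a pseudocount would bias low-coverage
ratios toward 1, so we deliberately avoid one).

Normalization is counts-per-million against the whole-library read total.
Only the ratio of the two normalizations matters downstream: rescaling
every library by a common factor changes nothing, and rescaling the IP
libraries alone rescales all levels by the inverse factor (a property the
test suite asserts).

# Classifying dynamics

A stage transition (D0→D2, D2→D5, D5→D15) of a peak is **differential**
when two conditions hold jointly:

1. the symmetric fold change of the normalized level,
   `max(r2/r1, r1/r2)`, strictly exceeds 1.2;
2. a Pearson chi-square test (no continuity correction) on the 2×2
   coverage table `[[IP1, input1], [IP2, input2]]` gives `p < 0.05`.

The chi-square is computed on **depth-normalized** counts: each of the
four cells is scaled to the smallest of the four library sizes involved.
On raw counts the IP:input odds are confounded by the stage-specific
ratio of IP to input sequencing depth — a library-size imbalance can
manufacture or cancel an apparent change in methylation. Scaling to the
*smallest* library only ever shrinks the counts, so the test becomes
conservative, never anticalibrated. Tables with a minimum expected cell
below 1 are flagged and handed to Fisher's exact test instead. Raw
per-transition p-values drive the calls (no multiplicity correction is
applied to the classification; a Benjamini–Hochberg column is emitted for
reference).

From the three transition calls each peak gets a **change count** (0–3).
Per stage, a peak or gene is **modified** when its level strictly exceeds
1.5; the **origin** of a peak is the earliest modified stage (or
`never`). A **dynamic gene** shows fold change above 1.2 in at least one
transition of its pooled level. Trajectories are clustered with k-means
(k = 8 by default, k-means++ initialization, 10 restarts, fixed seed) on
row-z-scored levels; zero-variance rows cannot be z-scored and are
assigned to the nearest unscaled centroid, flagged. The boundary
comparisons at 1.2 and 1.5 are strict everywhere.

# Writer/eraser target discovery

Regulator expression is correlated with every gene's m6A level and with
every gene's expression across the four stage points (Pearson r over
n = 4). Per signal, genes are ranked and the top and bottom
`floor(0.05 n)` become the positively / negatively correlated classes
(ties broken lexicographically by gene id so runs are reproducible);
among the remainder, genes with `|r| < 0.1` are "not correlated", the
rest stay unclassified, as do genes with zero variance. Candidate
**writer targets** (METTL14, RBM15) are the intersection of the
m6A-positive and expression-negative extremes — methylation written onto
a transcript tracks writer abundance while, m6A being destabilizing, the
transcript itself anticorrelates. **Eraser targets** (ALKBH5) reverse
both signs. Intersection significance is a one-tailed hypergeometric test
over the genes with defined correlations for both signals (the package's
universe choice; the analysis is insensitive to reasonable alternatives,
but the choice is fixed for determinism).

With only four stage points a per-gene correlation p-value would be
meaningless; the package reports r and rank only, and never a per-gene
significance.

# Chromatin integration

Gene-level ATAC accessibility enters pre-aggregated (one value per gene
and stage). The module provides rank-sum comparisons of accessibility
between modified and unmodified genes, between target genes and
all/random genes (size-matched control drawn without replacement under a
fixed seed), m6A distributions across a 10%/80%/10% accessibility split
(floor-sized extremes, deterministic ties), m6A groups at thresholds
1.5/4 (low < 1.5 < medium < 4 < high) for TF-binding comparisons, and two
joint-dynamics views:

* the **five co-dynamics categories**: (1) neither m6A nor accessibility
  changes (fold-change rule at 1.2, reused for accessibility since no
  separate criterion is established for it); (2) accessibility only; (3)
  m6A only; both change with (4) opposite or (5) concordant trends. For
  the whole trajectory, trend agreement is the sign of the Pearson
  correlation between the two 3-length change-ratio vectors; zero or
  undefined correlations fall into (4) with a flag so the map stays a
  partition. Because it is unstated whether such labels are per window or
  per whole trajectory, the package computes both: per-transition labels
  use the direction signs of the single transition.
* **PCC bins**: genes ranked by the correlation of their m6A level with
  their accessibility, top and bottom 5% dropped, the remainder split
  into 18 contiguous 5% bins (sizes differ by at most one), with the mean
  absolute m6A fold change reported per bin and transition.

Wilcoxon rank-sum tests are exact when the smaller group has ≤ 20
observations and the data are tie-free, and use the tie-corrected normal
approximation otherwise.

# The synthetic study generator

No public sequencing data is bundled; instead `simulate_study()` builds a
complete four-stage study whose ground truth is known, so every module is
testable end to end. What it emulates, and how:

**Trajectories.** Each gene receives a true m6A trajectory over the four
stages. Before its origin stage a trajectory stays in a low band
(0.6–1.3), from the origin onward in a high band (1.7–6): the safety
margins around the 1.5 threshold ensure that realistic counting noise
does not flip modified calls, i.e. the planted labels are *identifiable*.
Change classes are planted by multiplying with factors of at least 1.38
(changing transitions) or at most 1.08 (static transitions) — again with
margin on both sides of the 1.2 rule. A peak whose origin is D2/D5/D15
necessarily changes on the transition entering its origin, so its change
pattern is forced to include it; an unchanged peak with a late origin is
infeasible and is reassigned origin D0. Defaults plant 14% unchanged
peaks, 47%/30%/9% changing once/twice/thrice, 90% of peaks modified at
D0, and 5% never modified. Peaks of one gene share the gene's trajectory,
so pooled gene levels equal the planted values exactly.

**Counts.** IP counts are negative-binomial with mean
`depth_mean × weight × mu × sizefactor`, input counts the same without
`mu`; the abundance weight is proportional to the gene's expression and
per-stage sizefactors are drawn log-uniform from [0.5, 2] to exercise
normalization. Library sizes are proportional to the sizefactors, so CPM
ratios recover `mu` in expectation. The negative-binomial size is
`dispersion × mean` (default dispersion 10, i.e. variance
`mean × 1.1`): a mild constant overdispersion *factor*, chosen so that —
as for real sequencing — deeper libraries give proportionally tighter
level estimates. A size held fixed while the mean grows would instead put
a floor on the coefficient of variation and no depth could ever estimate
levels accurately, contradicting the precision the multiplexed
single-antibody protocol achieves. At the default depth of 10^4 reads
per peak, level estimates carry ≈ 2–3% noise.

**Regulator coupling.** Eleven regulators (3 writers, 2 erasers, 6
readers) carry fixed smooth expression templates; METTL14, RBM15 and
ALKBH5 get the high-dispersion curves. For each of those three, 60 target
genes (default) are planted with trajectories constructed as
`r·z + sqrt(1-r²)·e`, where `z` is the standardized regulator curve and
`e` standardized noise orthogonalized against `z` — the sample Pearson
correlation is then *exactly* `±r_plant` (sign by role). The noise
component is additionally resampled until the planted direction
correlates at most 0.8 with the other targeted regulators, so one
regulator's targets cannot leak into another's extremes. With four
points, the null distribution of a Pearson correlation against an
arbitrary trajectory is uniform on [−1, 1]: an unconstrained background
would place 5% of genes above any planted r < 1 and no method could
separate targets from chance. Identifiable truth therefore requires
shaping the background too: non-target trajectories (m6A and expression)
are rejection-sampled until they correlate at most 0.8 with every
targeted regulator. This is the strongest idealization in the generator:
real transcriptomes contain genes accidentally correlated with any
4-point curve, and real target discovery at n = 4 inherits that false
positive floor. Passing recovery tests show the pipeline's logic is
correct, not that four time points suffice in real data.

**Accessibility.** Each gene is assigned a co-dynamics category
compatible with whether its m6A actually changes (the two
m6A-static categories together must equal the unchanged fraction —
validated at configuration time). Category-4 genes get accessibility
change ratios reciprocal to their m6A ratios, category-5 genes equal
ratios, categories 1/3 stay within 6% jitter, category 2 changes by
1.35–1.7× on random transitions. Mild log-normal noise (2%) is added.
TF-binding scores are log-normal, with POU5F1 (D0) and GATA4 (D15)
coupled to the m6A level and NANOG uncoupled.

**Genome.** A toy genome (one chromosome per 50 genes, non-overlapping
genes, 10%/60%/30% UTR/CDS/UTR splits, peaks biased toward stop codons)
exercises the BED/GTF round trip and the metagene machinery; peak
sequences carry a planted DRACH in 85% of peaks. None of this pretends to
mimic real genome architecture.

Everything is drawn under a single seed; identical configurations yield
byte-identical studies, and the whole demo pipeline is byte-deterministic.

# Numerical and design choices

* Coordinates are 0-based half-open (BED convention); GTF is converted on
  read and write.
* Peak-to-gene assignment is by midpoint containment in the transcript
  interval, ties resolved by longest overlap then lexicographic gene id.
  The stop-proximal label applies within ±50 nt of the stop codon
  (strand aware) — a common metagene convention, configurable.
* The metagene histogram uses 90 bins (30 per segment) over the
  normalized coordinate [0, 3), area-normalized; genes lacking a UTR
  contribute to the CDS segment only.
* `classify_correlations` requires ≥ 40 genes with defined correlations
  so the 5% extremes are non-degenerate.
* Degenerate inputs are handled explicitly rather than silently: all-equal
  correlations fall back to tie-break ordering with a message,
  zero-variance cluster rows are flagged, empty m6A groups skip their
  rank-sum pair with a warning, and an all-modified gene set is an error
  for the modified-vs-unmodified comparison.

Default problem sizes — 2000 genes, 3000 peaks, depth 10^4, and for the
heavier recovery checks 20 seeds at 500 genes — were chosen so the full
suite and the acceptance script complete comfortably on a laptop-class
single core while keeping multinomial 3σ intervals tight enough to be
informative.

# Limitations

* Four stage points make every correlation-based quantity coarse; the
  package deliberately reports no per-gene correlation significance.
* The generator's background-decorrelation (above) removes the chance
  correlation floor that real data has.
* The simulator draws one library per stage (as in the pooled-barcode
  design); biological replicates and replicate-aware differential
  testing are out of scope.
* Reads, alignment, peak calling, motif *enrichment* and GO analysis are
  upstream/downstream of this package and are not modelled: counts on a
  fixed peak catalog are the interface.

# A worked run

```{r demo, eval = FALSE}
library(m6adyn)
demo <- demo_m6a(seed = 42, out_dir = "m6adyn_demo")
glance(demo$result$profile)
glance(demo$result$dynamics)
glance(demo$result$chromatin$co_dynamics)
autoplot(demo$result$profile)
```

The README walks through the same run with its printed output.
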