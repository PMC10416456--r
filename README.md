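# m6adyn

Quantitative analysis of N6-methyladenosine (m6A) dynamics across a
four-stage cardiomyocyte differentiation time course (hESC D0 → mesoderm
D2 → cardiac progenitor D5 → cardiomyocyte D15), starting from
peak-level MeRIP-seq count matrices.

m6A is the most prevalent internal mRNA modification; it is written by a
METTL3/METTL14/RBM15 methyltransferase complex, erased by FTO/ALKBH5,
and read by YTHDF/YTHDC/IGF2BP proteins. During differentiation the
overall m6A level stays roughly constant while individual genes gain and
lose methylation, and those gene-level dynamics interact with chromatin
accessibility. `m6adyn` implements that analysis for anyone with paired
IP/input counts on a fixed peak catalog (plus gene-level expression and,
optionally, ATAC accessibility and TF-binding tables) — and ships a
fully-specified synthetic study generator so the entire pipeline runs,
and is tested, without any sequencing data.

## The quantities it computes

With CPM-normalized coverage, the **m6A level** of a peak at stage *s* is

```
level(p, s) = IP_cpm(p, s) / input_cpm(p, s)
```

and the level of a gene (or region, or whole sample) is the pooled ratio
`Σ IP_cpm / Σ input_cpm` over its peaks. On top of these levels:

* **differential transitions** — symmetric fold change > 1.2 *and*
  chi-square p < 0.05 on the depth-normalized 2×2 IP/input table;
  per-peak **change counts** (0–3 of the three consecutive transitions);
* **modified calls** (level > 1.5) and per-peak **origin stage** (the
  earliest modified stage);
* k-means **trajectory clusters**, metagene density, DRACH scanning,
  expression **dispersion scores** (SD of log2 expression over stages);
* **writer/eraser target genes** — genes in the top 5% of correlation
  with a regulator's expression on one signal and the bottom 5% on the
  other (m6A positive + expression negative for writers; reversed for
  erasers), with a one-tailed hypergeometric test of the intersection;
* **chromatin integration** — accessibility of modified vs unmodified
  genes, 10/80/10 accessibility groups, the five m6A × accessibility
  **co-dynamics categories** (no change / accessibility only / m6A only /
  discordant / concordant), PCC-ranked bins, and stage-window overlaps.

## A worked example

The demo simulates a default-scale study (2000 genes, 3000 peaks, depth
10⁴, planted truth) and runs the full analysis:

```r
library(m6adyn)
demo <- demo_m6a(seed = 42, out_dir = "m6adyn_demo")

demo$result$profile
#> <m6a_profile> 3000 peaks / 2000 genes (0 peaks removed by input filter)
#> sample m6A levels: D0=2.501, D2=2.74, D5=2.744, D15=3.285

demo$result$dynamics
#> <peak_dynamics> 3000 peaks
#> change classes: 0x=13.3%, 1x=45.1%, 2x=32.8%, 3x=8.9%

glance(demo$result$dynamics)
#> # A tibble: 1 × 6
#>   n_peaks frac_unchanged frac_change_1 frac_change_2 frac_change_3 frac_origin_D0
#> 1    3000          0.133         0.451         0.328        0.0887          0.910
```

Reading: sample-wide methylation is fairly stable across stages
(2.50–3.28) while only 13% of individual peaks keep a constant level —
the generator plants 14% — and 91% of peaks are already modified at the
stem-cell stage. Target discovery and the chromatin categories:

```r
glance(demo$result$targets$METTL14)
#> # A tibble: 1 × 5
#>   role   n_targets overlap n_universe        p
#> 1 writer        61      61       1999 3.35e-63

demo$result$chromatin$co_dynamics
#> <m6a_codynamics> 2000 genes
#>   category     n fraction
#> 1        1   143   0.0715
#> 2        2   122   0.061
#> 3        3   607   0.304
#> 4        4   575   0.288
#> 5        5   553   0.276
```

61 candidate METTL14 targets are found (60 were planted) with a vanishing
hypergeometric p, and every gene lands in exactly one co-dynamics
category. `autoplot()` works on profiles, dynamics and co-dynamics
objects; `tidy()`/`glance()` return tibbles throughout. All result tables
are also written as TSV (plus a JSON manifest) into `out_dir`, and
identical seeds give byte-identical outputs.

Real data enters through `read_peak_bed()`, `read_gene_annotation()` /
`read_annotation_table()`, `read_stage_matrix()` and `stage_counts()`,
then the same functions apply; `run_m6a_pipeline(run_config(...))`
orchestrates the whole run from file paths or in-memory objects, and
`validate_config()` reads thresholds from YAML.

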