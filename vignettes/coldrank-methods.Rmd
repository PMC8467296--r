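---
title: "Methods: ranking DNA variants for cold-stress temperature maintenance"
author: "coldrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ranking DNA variants for cold-stress temperature maintenance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`coldrank` prioritises DNA variants associated with body-temperature
maintenance under acute cold stress, for the study design where a herd
carries in-ear temperature sensors through a winter campaign and the animals
with the most extreme phenotypes are whole-genome resequenced in two small
contrast groups. This vignette documents the model and every tunable or
numerical convention; the README shows the surface workflow.

## The phenotype: AUC over the coldest days

An animal's capacity to maintain body temperature is summarised as the area
under its in-ear temperature curve over the coldest contiguous five days of
the campaign, in °C·hours. Choices:

* **"Coldest five days"** is the contiguous five-day window (candidate
  starts: the first observation plus whole-day offsets) minimising the mean
  ambient temperature of the observations it contains; ties go to the
  earliest start. Contiguity is implied by treating the phenotype as a
  response to one sustained spell rather than to scattered cold days.
* **Quadrature** is the trapezoid rule on the piecewise-linear interpolant,
  with linear interpolation at the interval boundaries when samples straddle
  them. For sensor data at regular intervals this is exact up to sensor
  noise; `temp_auc()` needs at least two observations inside the interval.
* Higher AUC = better maintenance = the *tolerant* group; lower AUC =
  *sensitive*. No sensor QC or gap-filling is applied.

### Breed-balanced extreme groups

`select_extreme_groups()` picks `per_group` (default 6) animals per extreme
subject to the balance constraint that each breed's count differs by at most
one between groups. Rather than repairing the naive top/bottom split by
heuristic swaps, the implementation enumerates all feasible per-breed
compositions of the two groups, fills each composition with that breed's
top-AUC (tolerant) and bottom-AUC (sensitive) animals, and keeps the
composition maximising the separation of AUC sums. An exchange argument
shows every optimal balanced pair has this top/bottom-fill form, so the
search is exactly the brute-force optimum over all balanced group pairs
while staying deterministic (AUC ties broken by animal id, objective ties by
enumeration order) and cheap — at most a few hundred compositions for two
breeds and groups of six. The test suite checks it against explicit
enumeration of all disjoint balanced six-subsets.

## Variant quality control

Hard filtering uses the standard caller-annotation thresholds: a record
fails when QD < 2, MQ < 40, FS > 60, MQRankSum < −12.5 or
ReadPosRankSum < −8. Conventions:

* Inequalities are strict: a value exactly at a threshold passes.
* A missing annotation never fails its rule — rank-sum annotations are
  undefined at sites without both allele classes, and treating absence as
  failure would silently discard well-behaved homozygous sites.
* Removal counts attribute each removed record to *every* rule it violates,
  so per-rule counts can exceed the removed total. Filtering is idempotent
  and order-independent, and commutes with biallelic-SNP selection.
* `keep_biallelic_snps()` retains single-base REF/ALT with exactly one
  alternate allele; `ts_tv_ratio()` reports transitions (A↔G, C↔T) over
  transversions as a quality heuristic (≈ 2 for mammalian whole-genome
  sets).
* The autosome restriction is applied in the ranking universe, not here, so
  the filter stays general.

## Weir–Cockerham F_ST

For two populations (`r = 2`; more are rejected rather than silently
generalised) with per-group called sample sizes $n_i$, reference-allele
frequencies $p_i$ and observed heterozygote proportions $h_i$:

$$\bar n = \tfrac{1}{r}\sum n_i,\quad
  n_c = \frac{r\bar n - \sum n_i^2/(r\bar n)}{r-1},\quad
  \bar p = \frac{\sum n_i p_i}{r\bar n},\quad
  s^2 = \frac{\sum n_i (p_i-\bar p)^2}{(r-1)\bar n},\quad
  \bar h = \frac{\sum n_i h_i}{r\bar n}$$

$$a = \frac{\bar n}{n_c}\Big[s^2 - \frac{1}{\bar n - 1}\big(\bar p(1-\bar p)
      - \tfrac{r-1}{r}s^2 - \tfrac{\bar h}{4}\big)\Big],\qquad
  b = \frac{\bar n}{\bar n - 1}\Big[\bar p(1-\bar p) - \tfrac{r-1}{r}s^2
      - \tfrac{2\bar n - 1}{4\bar n}\bar h\Big],\qquad
  c = \frac{\bar h}{2}$$

and $\theta = a/(a+b+c)$. Conventions:

* Counts use non-missing genotypes only; sites where a group has no called
  genotype are skipped with a warning; $\bar n \le 1$ is an error.
* $\theta$ is undefined (flagged `NA`) when $a+b+c = 0$, i.e. the pooled
  sample is monomorphic; such sites are excluded from per-site output and
  from window sums.
* Negative components and negative $\theta$ are *retained*: the moment
  estimator's small negative excursions around zero are part of its
  sampling behaviour, and clamping would bias window sums.
* A 6v6 fixed difference gives $\theta = 1$ exactly; the suite cross-checks
  1,000 random fixtures against an independently transcribed evaluation at
  1e−12.

**Windows.** Each chromosome is tiled from position 1 with 50 kb windows
stepped by 25 kb (1-based inclusive; half-open arithmetic internally), so
every position beyond the first step lies in exactly two overlapping
windows. A window's estimate is the weighted ratio of sums
$\sum a / \sum(a+b+c)$ over its sites (the plain mean of per-site $\theta$
is reported alongside); windows with no sites are omitted, and no minimum
site count is imposed. A SNP's window value is the maximum weighted
$\theta$ among its covering windows.

## Rank aggregation

Each SNP is annotated with three fractional ranks in $[0,1]$, computed by
descending sort with rank $(\text{mean ordinal position among ties} - 1)/(N-1)$:
the highest value maps to 0 exactly and the lowest to 1 exactly (a single
value maps to 0). Tie averaging and this normalisation are the package's
choice of the many "fractional rank" conventions; it was picked because the
endpoints are attained exactly and ties are order-independent.

The universes follow a universe-per-rank convention:

* **AFD/F_ST universe**: autosomal biallelic SNPs with ≥ 3 called genotypes
  in each group (`min_called`) and at least one covering non-empty window.
* **Scored universe**: the subset with a functional-score annotation. SNPs
  without a score are dropped from the final table but still shape the AFD
  and F_ST rank denominators, mirroring how an annotation-limited score
  table restricts the rankable set without changing the genome-wide ranks.

The F_ST rank is computed per SNP from its better-window value. Whether the
rank denominator should be the SNP universe or the window list is genuinely
ambiguous; both give the same ordering, so the implementation defaults to
the SNP-universe normalisation and exposes
`fst_rank_basis = "windows"` for the window-rank reading (under which SNPs
sharing a window share a rank value). The allele-frequency difference is the
absolute difference of reference-allele frequencies — candidates deviate in
both directions, so sign carries no ranking information.

Ranks are summed and SNPs sorted ascending; **candidates** are SNPs with
rank sum strictly below the threshold (default 0.1). Strict inequality is
the conservative reading of "< 0.1"; selection counts are non-decreasing in
the threshold, and raising any SNP's functional score can only lower (never
raise) its rank sum.

## Consequence annotation

`classify_variants()` is a deliberately small re-implementation of the
consequence classes an Ensembl-era annotator reports, from one GTF and one
FASTA:

* Coding positions: the affected codon is extracted strand- and frame-aware
  from the spliced CDS; the reference codon must match the FASTA (a
  mismatch is a consistency error naming the transcript); reference and
  alternate codons are translated to give synonymous / missense /
  stop_gained / stop_lost.
* Splice region: 1–3 exonic or 1–8 intronic bases from an internal splice
  junction, with the 1–2 bp donor/acceptor collapsed into `splice_region`
  (the Ensembl convention, since no finer definition is needed here).
* UTRs are exonic non-CDS positions, sided by strand relative to the CDS
  span; other in-gene positions are intronic; positions within 5 kb
  (Ensembl's default flank) are upstream/downstream, strand-aware;
  everything else is intergenic.
* One most-severe class per SNP–transcript pair and per SNP, with severity
  stop_gained > stop_lost > missense > splice_region > synonymous > UTR >
  intron > up/downstream > intergenic.
* The synthetic GTF (and hence the classifier's expectation for it) includes
  the terminal stop codon inside the CDS, one self-consistent dialect for
  generator and classifier; external GTFs that exclude the stop codon are
  classified identically everywhere except inside that final codon.
* A single GTF is consumed; transcripts without CDS and positions on
  sequences absent from the annotation yield `NA` classes rather than
  errors.

## The synthetic study generator

`simulate_study()` emulates the full design with known ground truth. What it
reproduces, and the defaults (all overridable in `sim_config()`):

* **Campaign**: 200 animals, two breeds (Hereford 0.58 / Kazakh Whiteheaded
  0.42), 14 days at 60-minute sampling. Ambient temperature is a −12 °C
  mean plus a 4 °C diurnal cycle (coldest pre-dawn) and AR(1)-smoothed
  noise, with a five-day spell whose minimum is scaled to hit −32 °C
  exactly. In-ear temperature is a 38.5 °C baseline minus the animal's
  cold-sensitivity coefficient times the ambient deficit below −15 °C, plus
  0.15 °C sensor noise. Sensitivity is linear in the animal's planted-locus
  dosages (equal per-locus effects summing to 0.012 °C/°C at full dosage,
  plus a 0.010 baseline and half-normal polygenic term), which makes the
  genotype–phenotype link recoverable in sign by construction.
* **Genome**: 10,000 background + 20 planted biallelic SNPs on 5 autosomes
  of 50 Mb. The genome size is chosen so a 50 kb window holds ~1–2 SNPs at
  this density: window estimates then carry the planted per-site signal
  rather than averaging it away over dozens of null sites, matching the
  sparse-signal regime the windowed scan targets. Background SNPs share one
  alternate-allele frequency `p ~ U(0.05, 0.95)` across groups; planted
  SNPs draw per-group frequencies at least 0.8 apart (random side), and
  genotypes are binomial within group (Hardy–Weinberg) — the simplest null
  consistent with per-group frequencies, with no linkage disequilibrium
  between sites. Alternate alleles are transitions with probability 2/3
  (expected Ts/Tv = 2, the typical mammalian value). Genotypes are missing
  at 3%.
* **INFO fields** are drawn from passing distributions clipped clear of the
  thresholds, and 5% of *background* records receive one filter-violating
  value (2% are INDELs). Planted records always pass and are never INDELs:
  the failure machinery exists to exercise the filter, and discovered
  candidates are by definition records that survived QC — destroying
  planted truth with QC failures would conflate two unrelated properties.
* **Functional scores**: background `Beta(1.2, 6)`; planted SNPs receive,
  with probability 0.9, a score drawn uniformly above the 99th percentile
  of the background scores (otherwise a background draw), and are always
  present in the table, while 10% of background SNPs are absent. Drawing
  enriched scores from the extreme upper tail reflects that causal
  functional variants sit at the very top of a functional-score
  distribution rather than uniformly inside its top decile.
* **Toy annotated genome**: two multi-exon protein-coding genes (one per
  strand) with ATG…stop CDS, GT..AG introns and UTR ends on a separate
  30 kb contig ("25"). The annotation contig is deliberately small and
  separate from the 50 Mb SNP chromosomes — consequence classification is
  validated position-by-position on the toy contig, and candidates on
  unannotated sequences simply return `NA`.
* **Determinism**: every output is a pure function of `(config, seed)`;
  `simulate_study()` derives its stage seeds by fixed offsets from the base
  seed (+1 genotypes, +2 scores, +3 gene models), and writers emit
  byte-identical files on identical inputs.

What it does **not** emulate: linkage disequilibrium, read-level artefacts
(the pipeline starts at the VCF), population structure beyond the two-group
contrast, real FAETH score construction, and sensor dropout. Passing tests
therefore demonstrate correctness of the estimators and the selection
machinery under an idealised sparse-signal genome, not robustness to LD
leakage or structured confounding in real data.

## Problem sizes and test design

The suite validates each stage against an independent oracle: a naively
transcribed estimator evaluation (1,000 random fixtures, 1e−12), exhaustive
window scans, brute-force enumeration of balanced group pairs (n = 12–13),
hand-enumerated filter fixtures, and a position-by-position truth map of a
26 kb toy genome built by independent code. The planted-locus recovery
check runs ten cohorts of 10,020 SNPs (seeds 1–10 through the study's
canonical seed offsets) and asks for ≥ 90% of planted loci selected at
threshold 0.1 on average; these sizes keep the full suite under half a
minute while leaving the per-window SNP density and group sizes at the
study's values.

## Known limitations

* `r = 2` populations only; no Hudson/Nei estimators, no per-site p-values,
  no multiple-testing control (the rank sum is a prioritisation score, not
  a test).
* Window anchoring at position 1 is a convention; tools that anchor
  elsewhere will report shifted windows with the same content.
* The annotation module classifies against a single transcript set and
  reports no protein-level features or regulatory classes.
* With heavy ties (e.g. allele-frequency differences over 12 diploids) the
  tie-averaged fractional ranks do not attain the endpoints exactly; with
  continuous inputs they do.
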