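# coldrank

Candidate-locus discovery for **body-temperature maintenance under acute cold
stress** from whole-genome resequencing of phenotypic extremes.

Breeding cold-resilient cattle needs causal variants, but cold tolerance is
rarely under direct selection and mapping cohorts are small. One practical
design records in-ear temperature (RFID-tag sensors) across a herd through a
winter cold spell, resequences the animals with the most extreme
temperature-maintenance phenotypes, and asks which variants separate the
cold-*tolerant* from the cold-*sensitive* group. `coldrank` implements that
analysis end to end for R users:

* **Phenotype** — the area under an animal's in-ear temperature curve (AUC,
  °C·h) over the coldest contiguous five days of the campaign, a proxy for
  body-temperature maintenance; breed-balanced extreme groups (six animals
  per group) chosen by an exact search over per-breed compositions.
* **Variant QC** — GATK-style hard filtering (fail when QD < 2, MQ < 40,
  FS > 60, MQRankSum < −12.5 or ReadPosRankSum < −8; a missing annotation
  never fails its rule), INDEL/multiallelic removal, Ts/Tv summary.
* **Differentiation** — the Weir–Cockerham (1984) two-population moment
  estimator. Per site, from per-group sample sizes *n*ᵢ, reference-allele
  frequencies *p*ᵢ and heterozygosities *h*ᵢ it returns the variance
  components *a* (between populations), *b* (between individuals within
  populations), *c* (within individuals) and θ = *a*/(*a*+*b*+*c*).
  Windows of 50 kb stepped by 25 kb aggregate sites with the weighted
  ratio-of-sums form Σ*a* / Σ(*a*+*b*+*c*).
* **Rank aggregation** — each SNP gets three fractional ranks in [0, 1]
  (highest value ↦ 0): the weighted F_ST of its better overlapping window,
  its absolute group allele-frequency difference, and a per-SNP functional
  score (FAETH-style, consumed as an input table). Candidates are SNPs with
  rank sum < 0.1.
* **Annotation** — gene-context and coding-consequence classes (missense,
  synonymous, stop gain/loss, splice region, UTRs, intron,
  upstream/downstream within 5 kb, intergenic) from a GTF gene model and
  genome FASTA.
* **Synthetic study generator** — a fully deterministic simulator of the
  whole design (sensor campaign with a −32 °C spell, two breeds, planted
  divergent loci with enriched functional scores, INFO fields straddling the
  filter thresholds, toy annotated genome) with a ground-truth table, so the
  pipeline can be validated end to end without any external data.

## Worked example

Generate a small synthetic study, filter the variants and run the scan:

```r
library(coldrank)

cfg <- sim_config(n_animals = 24, n_background_snps = 2000,
                  n_planted_snps = 10, n_chromosomes = 2,
                  chrom_length = 2e7)
study <- simulate_study(cfg, "study", seed = 42)

vs  <- read_vcf(study$paths[["variants.vcf"]])
flt <- apply_hard_filters(vs)
flt$removed_by_rule
#>             qd             mq             fs      mqranksum readposranksum
#>             17             12             21             31             16

snps <- keep_biallelic_snps(flt$variants)
round(ts_tv_ratio(snps), 2)
#> [1] 1.96

scan <- cold_rank(snps, study$groups, study$faeth)
scan
#> Rank-aggregation scan for cold-adaptation candidate SNPs
#>   input SNPs: 1874; AFD/F_ST universe: 1872; scored universe: 1692
#>   windows: 1424; F_ST rank basis: snps
#>   selected: 12 SNPs with rank sum < 0.1
#>
#> Top SNPs:
#>   chrom      pos ref alt window_fst    afd  faeth    r_fst     r_afd  r_faeth
#> 1     1 17041671   T   G     0.6752 0.9167 0.8436 0.001069 0.0018707 0.001774
#> 2     1  4617951   A   C     0.9091 0.9167 0.7944 0.000000 0.0018707 0.002957
#> 3     2  7573179   C   G     0.6715 1.0000 0.6776 0.002672 0.0005345 0.005322
#> ...
```

The three rank columns are each SNP's fractional position within its own
universe (window F_ST, allele-frequency difference, functional score); their
sum orders the genome, and `candidates(scan)` returns the SNPs below the 0.1
threshold. In this run 9 of the 10 planted truth loci are recovered
(`study$truth` lists them). `plot(scan)` draws the window-F_ST landscape with
candidates highlighted, and

```r
idx <- read_gene_models(study$paths[["genes.gtf"]])
annotate_candidates(scan, idx, study$paths[["genome.fa"]])
```

adds gene names and consequence classes for SNPs on annotated sequences.

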