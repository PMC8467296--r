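small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_animals = 30, n_background_snps = 1500, n_planted_snps = 10,
         n_chromosomes = 2, chrom_length = 2e7),
    list(...))
  do.call(sim_config, args)
}

test_that("all generator outputs are pure functions of (config, seed)", {
  cfg <- small_cfg()
  groups <- two_groups(6)
  t1 <- simulate_temperatures(cfg, seed = 3)
  t2 <- simulate_temperatures(cfg, seed = 3)
  expect_identical(t1, t2)
  g1 <- simulate_genotypes(cfg, groups, seed = 3)
  g2 <- simulate_genotypes(cfg, groups, seed = 3)
  expect_identical(g1, g2)
  f1 <- simulate_faeth(g1$variants, g1$truth, cfg, seed = 3)
  expect_identical(f1, simulate_faeth(g2$variants, g2$truth, cfg, seed = 3))
  m1 <- simulate_gene_models(cfg, seed = 3)
  m2 <- simulate_gene_models(cfg, seed = 3)
  expect_identical(m1$gtf, m2$gtf)
  expect_identical(as.character(m1$genome), as.character(m2$genome))
})

test_that("re-written artefacts are byte-identical under the same seed", {
  cfg <- small_cfg()
  groups <- two_groups(6)
  gen <- simulate_genotypes(cfg, groups, seed = 9)
  f1 <- tempfile(fileext = ".vcf")
  f2 <- tempfile(fileext = ".vcf")
  write_vcf(gen$variants, f1)
  write_vcf(simulate_genotypes(cfg, groups, seed = 9)$variants, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  tm <- simulate_temperatures(small_cfg(n_animals = 12), seed = 9)
  c1 <- tempfile(fileext = ".csv")
  c2 <- tempfile(fileext = ".csv")
  write_temperatures(tm$readings, c1)
  write_temperatures(simulate_temperatures(small_cfg(n_animals = 12),
                                           seed = 9)$readings, c2)
  expect_identical(readLines(c1), readLines(c2))
  unlink(c(f1, f2, c1, c2))
})

test_that("series shape follows the campaign configuration", {
  tm <- simulate_temperatures(small_cfg(n_animals = 12, n_days = 14,
                                        sampling_interval = 60), seed = 1)
  expect_equal(nrow(tm$ambient), 14 * 24)
  expect_equal(sum(tm$readings$animal_id == tm$animals$animal_id[1]),
               14 * 24)
  expect_equal(nrow(tm$animals), 12)
})

test_that("the cold spell reaches the configured extreme exactly", {
  for (s in 1:3) {
    tm <- simulate_temperatures(small_cfg(n_animals = 12), seed = s)
    expect_equal(min(tm$ambient$temp_c), -32)
  }
})

test_that("zero noise and zero sensitivity give a flat baseline series", {
  cfg <- small_cfg(n_animals = 12, noise_sd = 0, sens_base = 0,
                   sens_effect = 0, sens_sd = 0)
  tm <- simulate_temperatures(cfg, seed = 2)
  expect_true(all(tm$readings$temp_c == cfg$baseline_temp))
})

test_that("a campaign too short for the cold spell is rejected", {
  expect_error(simulate_temperatures(small_cfg(n_days = 5), seed = 1),
               "n_days")
})

test_that("planted dosage raises cold sensitivity (parameter recovery)", {
  cfg <- small_cfg(n_animals = 120, noise_sd = 0.05, sens_sd = 0.001)
  tm <- simulate_temperatures(cfg, seed = 4)
  iv <- coldest_interval(tm$ambient, cfg$cold_spell_days)
  phen <- compute_phenotypes(tm$readings, iv)
  score <- tm$animals$genetic_score[match(phen$animal_id,
                                          tm$animals$animal_id)]
  # higher planted-allele dosage -> more heat lost -> lower AUC
  expect_lt(stats::cor(score, phen$auc), 0)
})

test_that("planted_afd = 1 yields fixed opposite genotypes", {
  cfg <- small_cfg(planted_afd = 1, missing_genotype_rate = 0)
  groups <- two_groups(6)
  gen <- simulate_genotypes(cfg, groups, seed = 5)
  gs <- split(groups$sample_id, groups$group)
  key <- paste(gen$variants$variants$chrom, gen$variants$variants$pos)
  for (i in seq_len(nrow(gen$truth))) {
    row <- which(key == paste(gen$truth$chrom[i], gen$truth$pos[i]))
    d1 <- gen$variants$geno[row, gs[[1]]]
    d2 <- gen$variants$geno[row, gs[[2]]]
    expect_true((all(d1 == 0) && all(d2 == 2)) ||
                  (all(d1 == 2) && all(d2 == 0)))
  }
})

test_that("zero missingness emits no missing genotypes", {
  cfg <- small_cfg(missing_genotype_rate = 0)
  gen <- simulate_genotypes(cfg, two_groups(6), seed = 6)
  expect_false(anyNA(gen$variants$geno))
})

test_that("the hard-filter failing fraction is honoured (binomial error)", {
  cfg <- sim_config(fraction_failing_filters = 0.05, indel_fraction = 0)
  gen <- simulate_genotypes(cfg, two_groups(6), seed = 7)
  res <- apply_hard_filters(gen$variants)
  n_bg <- cfg$n_background_snps
  bounds <- qbinom(c(0.0005, 0.9995), n_bg, 0.05)
  expect_gte(res$n_removed, bounds[1])
  expect_lte(res$n_removed, bounds[2])
  # planted records always survive filtering
  kept <- paste(res$variants$variants$chrom, res$variants$variants$pos)
  expect_true(all(paste(gen$truth$chrom, gen$truth$pos) %in% kept))
})

test_that("planted divergence separates planted from background |dp|", {
  cfg <- small_cfg(planted_afd = 0.8)
  groups <- two_groups(6)
  gen <- simulate_genotypes(cfg, groups, seed = 8)
  afd <- allele_freq_diff(keep_biallelic_snps(gen$variants), groups,
                          min_called = 1)
  planted <- paste(afd$chrom, afd$pos) %in%
    paste(gen$truth$chrom, gen$truth$pos)
  expect_gte(mean(afd$afd[planted]) - mean(afd$afd[!planted]), 0.5)
})

test_that("groups must define two labels of the configured size", {
  cfg <- small_cfg()
  bad <- data.frame(sample_id = sprintf("S%02d", 1:12),
                    group = c(rep("a", 4), rep("b", 4), rep("c", 4)))
  expect_error(simulate_genotypes(cfg, bad, seed = 1), "two group labels")
  wrong_size <- data.frame(sample_id = sprintf("S%02d", 1:10),
                           group = rep(c("a", "b"), each = 5))
  expect_error(simulate_genotypes(cfg, wrong_size, seed = 1), "exactly 6")
})

test_that("functional-score enrichment and coverage behave as configured", {
  cfg <- small_cfg(faeth_enrichment = 1, faeth_missing_rate = 0)
  groups <- two_groups(6)
  gen <- simulate_genotypes(cfg, groups, seed = 10)
  fa <- simulate_faeth(gen$variants, gen$truth, cfg, seed = 10)
  expect_equal(nrow(fa), n_variants(gen$variants))  # full coverage
  planted <- paste(fa$chrom, fa$pos) %in% paste(gen$truth$chrom,
                                                gen$truth$pos)
  q90 <- stats::quantile(fa$score[!planted], 0.9, names = FALSE)
  expect_true(all(fa$score[planted] >= q90))
  # half-missing coverage within binomial error
  cfg2 <- sim_config(faeth_missing_rate = 0.5, n_planted_snps = 20)
  gen2 <- simulate_genotypes(cfg2, groups, seed = 11)
  fa2 <- simulate_faeth(gen2$variants, gen2$truth, cfg2, seed = 11)
  n_bg <- cfg2$n_background_snps
  bounds <- qbinom(c(0.0005, 0.9995), n_bg, 0.5)
  n_bg_kept <- nrow(fa2) - cfg2$n_planted_snps
  expect_gte(n_bg_kept, n_bg - bounds[2])
  expect_lte(n_bg_kept, n_bg - bounds[1])
})

test_that("invalid configurations are rejected up front", {
  expect_error(sim_config(planted_afd = 1.2), "proportions")
  expect_error(sim_config(breeds = c(a = 0.5, b = 0.3)), "sum to 1")
  expect_error(sim_config(n_background_snps = 0), "positive")
})

test_that("emitted VCF round-trips through a standard reader", {
  cfg <- small_cfg(n_background_snps = 300, n_planted_snps = 5)
  gen <- simulate_genotypes(cfg, two_groups(6), seed = 12)
  path <- tempfile(fileext = ".vcf")
  write_vcf(gen$variants, path)
  back <- read_vcf(path)
  expect_equal(back$variants$chrom, gen$variants$variants$chrom)
  expect_equal(back$variants$pos, gen$variants$variants$pos)
  expect_equal(back$variants$ref, gen$variants$variants$ref)
  expect_equal(back$variants$alt, gen$variants$variants$alt)
  expect_identical(back$geno, gen$variants$geno)
  expect_equal(back$variants$qd, gen$variants$variants$qd,
               tolerance = 1e-5)
  unlink(path)
})

test_that("synthetic gene models are internally consistent", {
  cfg <- small_cfg()
  gm <- simulate_gene_models(cfg, seed = 13)
  contig <- gm$genome[[cfg$gene_contig]]
  for (g in gm$genes) {
    spliced <- paste(vapply(seq_len(nrow(g$cds)), function(k) {
      as.character(Biostrings::subseq(contig, g$cds[k, 1], g$cds[k, 2]))
    }, character(1)), collapse = "")
    if (g$strand == "-") {
      spliced <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(spliced)))
    }
    expect_equal(nchar(spliced) %% 3, 0)
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(spliced)))
    expect_equal(substr(prot, 1, 1), "M")
    # exactly one stop, at the end
    expect_equal(nchar(prot), g$protein_len + 1)
    expect_equal(substr(prot, nchar(prot), nchar(prot)), "*")
    expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)))
  }
  expect_setequal(vapply(gm$genes, `[[`, character(1), "strand"),
                  c("+", "-"))
})

test_that("GTF and FASTA round-trip through standard readers", {
  cfg <- small_cfg()
  gm <- simulate_gene_models(cfg, seed = 14)
  gtf_path <- tempfile(fileext = ".gtf")
  fa_path <- tempfile(fileext = ".fa")
  write_gtf(gm$gtf, gtf_path)
  Biostrings::writeXStringSet(gm$genome, fa_path)
  idx <- read_gene_models(gtf_path)
  expect_equal(nrow(idx$genes), cfg$n_genes)
  for (g in gm$genes) {
    tx <- idx$transcripts[[g$transcript_id]]
    expect_equal(unname(tx$exons), unname(g$exons))
    expect_equal(unname(tx$cds), unname(g$cds))
    expect_equal(tx$strand, g$strand)
  }
  fa <- Biostrings::readDNAStringSet(fa_path)
  expect_equal(as.character(fa[[1]]), as.character(gm$genome[[1]]))
  unlink(c(gtf_path, fa_path))
})

test_that("simulate_study writes a complete, consistent artefact set", {
  cfg <- small_cfg(n_animals = 24, n_background_snps = 400,
                   n_planted_snps = 5)
  outdir <- tempfile("study")
  res <- simulate_study(cfg, outdir, seed = 15)
  expect_true(all(file.exists(res$paths)))
  groups <- read_groups(file.path(outdir, "groups.csv"))
  expect_equal(sort(unique(groups$group)), c("sensitive", "tolerant"))
  expect_equal(nrow(groups), 12)
  tab <- table(groups$breed, groups$group)
  expect_true(all(abs(tab[, 1] - tab[, 2]) <= 1))
  vs <- read_vcf(file.path(outdir, "variants.vcf"))
  expect_equal(n_variants(vs), 405)
  expect_setequal(vcf_samples(vs), groups$sample_id)
  truth <- utils::read.csv(file.path(outdir, "truth.csv"))
  expect_equal(nrow(truth), 5)
  expect_true(all(paste(truth$chrom, truth$pos) %in%
                    paste(vs$variants$chrom, vs$variants$pos)))
  amb <- read_temperatures(file.path(outdir, "ambient.csv"))
  expect_equal(min(amb$temp_c), -32, tolerance = 1e-4)
  unlink(outdir, recursive = TRUE)
})
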