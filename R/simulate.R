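#' Configuration for the synthetic cold-stress study
#'
#' Bundles every tunable of the synthetic-data generator: herd size and the
#' two-breed composition, the winter sensor campaign (days, sampling
#' interval, ambient model with a five-day extreme-cold spell), the
#' sequenced contrast-group size, the genome (chromosome count/length,
#' background and planted SNP counts, target allele-frequency divergence at
#' planted loci), the functional-score table (enrichment of planted loci,
#' fraction of unannotated SNPs), caller INFO-field distributions with a
#' controllable hard-filter-failing fraction, and the toy gene-model contig.
#'
#' Defaults emulate the study conditions the pipeline targets: ~200 animals
#' monitored for two winter weeks including a five-day spell reaching
#' -32 degrees C, two contrast groups of six resequenced animals drawn from
#' two breeds, and a genome of mostly shared-frequency biallelic SNPs plus
#' strongly divergent planted loci.
#'
#' @param n_animals herd size carrying temperature sensors.
#' @param n_sequenced_per_group resequenced animals per contrast group.
#' @param breeds named numeric vector of breed proportions (must sum to 1).
#' @param n_days length of the sensor campaign in days.
#' @param sampling_interval minutes between sensor readings.
#' @param start_time first reading timestamp (`POSIXct`, UTC).
#' @param baseline_temp baseline in-ear temperature, degrees C.
#' @param noise_sd sensor noise standard deviation, degrees C.
#' @param ambient_mean,ambient_diurnal_amp,ambient_noise_sd ambient
#'   temperature model: mean level, diurnal amplitude and AR(1)-smoothed
#'   noise SD, degrees C.
#' @param cold_spell_days length of the contiguous extreme-cold spell.
#' @param cold_spell_min minimum ambient temperature reached in the spell.
#' @param stress_threshold ambient temperature below which in-ear
#'   temperature is depressed, degrees C.
#' @param sens_base,sens_effect,sens_sd cold-sensitivity coefficient model:
#'   baseline, per-unit-genetic-score effect and polygenic/noise SD, in
#'   degrees C lost per degree of ambient deficit.
#' @param n_chromosomes,chrom_length autosome count and length (bp).
#' @param n_background_snps,n_planted_snps SNP counts.
#' @param planted_afd minimum absolute allele-frequency difference between
#'   groups at planted loci, in `[0, 1]`.
#' @param faeth_enrichment probability a planted SNP receives an extreme
#'   top-tail functional score.
#' @param faeth_missing_rate fraction of background SNPs absent from the
#'   functional-score table.
#' @param faeth_planted_quantile background-score quantile above which
#'   enriched planted scores are drawn.
#' @param info_field_distributions list with elements `qd = c(mean, sd)`,
#'   `mq = c(mean, sd)`, `fs` (exponential mean) and `ranksum = c(mean, sd)`
#'   for passing INFO values.
#' @param fraction_failing_filters fraction of background records given at
#'   least one hard-filter-failing INFO value.
#' @param indel_fraction fraction of background records emitted as INDELs.
#' @param missing_genotype_rate per-genotype missingness probability.
#' @param gene_contig,gene_contig_length,n_genes toy annotation contig:
#'   name, length (bp) and number of protein-coding genes (alternating
#'   strand).
#' @param seed default RNG seed for the generator functions.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_animals = 200,
                       n_sequenced_per_group = 6,
                       breeds = c(Hereford = 0.58, KazakhWhiteheaded = 0.42),
                       n_days = 14,
                       sampling_interval = 60,
                       start_time = as.POSIXct("2021-01-11 00:00:00",
                                               tz = "UTC"),
                       baseline_temp = 38.5,
                       noise_sd = 0.15,
                       ambient_mean = -12,
                       ambient_diurnal_amp = 4,
                       ambient_noise_sd = 1.5,
                       cold_spell_days = 5,
                       cold_spell_min = -32,
                       stress_threshold = -15,
                       sens_base = 0.010,
                       sens_effect = 0.012,
                       sens_sd = 0.004,
                       n_chromosomes = 5,
                       chrom_length = 5e7,
                       n_background_snps = 10000,
                       n_planted_snps = 20,
                       planted_afd = 0.8,
                       faeth_enrichment = 0.9,
                       faeth_missing_rate = 0.1,
                       faeth_planted_quantile = 0.99,
                       info_field_distributions = list(
                         qd = c(25, 6), mq = c(59, 3), fs = 5,
                         ranksum = c(0, 1.5)),
                       fraction_failing_filters = 0.05,
                       indel_fraction = 0.02,
                       missing_genotype_rate = 0.03,
                       gene_contig = "25",
                       gene_contig_length = 30000,
                       n_genes = 2,
                       seed = 1) {
  cfg <- as.list(environment())
  props <- c(cfg$planted_afd, cfg$faeth_enrichment, cfg$faeth_missing_rate,
             cfg$faeth_planted_quantile, cfg$fraction_failing_filters,
             cfg$indel_fraction, cfg$missing_genotype_rate, cfg$breeds)
  if (any(props < 0 | props > 1)) {
    stop("all proportions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$breeds) - 1) > 1e-8) {
    stop("breed proportions must sum to 1", call. = FALSE)
  }
  counts <- c(cfg$n_animals, cfg$n_sequenced_per_group, cfg$n_days,
              cfg$sampling_interval, cfg$n_chromosomes, cfg$chrom_length,
              cfg$n_background_snps, cfg$n_planted_snps, cfg$n_genes)
  if (any(counts <= 0)) stop("counts must be positive", call. = FALSE)
  if (cfg$n_animals < 2 * cfg$n_sequenced_per_group) {
    stop("n_animals must cover both sequenced groups", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_animals, "animals /", x$n_days, "days;",
      x$n_background_snps, "background +", x$n_planted_snps,
      "planted SNPs on", x$n_chromosomes, "chromosomes\n")
  invisible(x)
}

#' Simulate the winter temperature-sensor campaign
#'
#' Generates one ambient series and one in-ear series per animal. The
#' ambient model is a mean level plus a diurnal cycle (coldest pre-dawn) and
#' AR(1)-smoothed noise, with a contiguous cold spell whose minimum reaches
#' exactly `cold_spell_min`. Each animal's in-ear temperature is its
#' baseline body temperature minus its cold-sensitivity coefficient times
#' the ambient deficit below `stress_threshold`, plus Gaussian sensor
#' noise. The sensitivity coefficient is a linear function of the animal's
#' planted-locus genotype dosages (equal per-locus effects) plus a
#' half-normal polygenic/noise term.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list with elements `ambient` (data frame `timestamp`, `temp_c`),
#'   `readings` (long data frame `animal_id`, `timestamp`, `temp_c`),
#'   `animals` (data frame `animal_id`, `breed`, `genetic_score`,
#'   `sensitivity`), `dosages` (animals x planted-loci dosage matrix) and
#'   `effect_size` (per-locus sensitivity effect).
#' @export
simulate_temperatures <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_days < 6) {
    stop("invalid config: n_days must be at least 6 to contain a ",
         "five-day cold spell", call. = FALSE)
  }
  if (config$cold_spell_days > config$n_days) {
    stop("invalid config: cold spell longer than the campaign", call. = FALSE)
  }
  with_seed(seed, {
    dt <- config$sampling_interval * 60
    n_pts <- (config$n_days * 24 * 60) %/% config$sampling_interval
    tsec <- as.numeric(config$start_time) + (seq_len(n_pts) - 1) * dt
    hour <- (tsec %% 86400) / 3600
    diurnal <- -config$ambient_diurnal_amp * cospi((hour - 4) / 12)
    e <- stats::rnorm(n_pts, 0, config$ambient_noise_sd * sqrt(1 - 0.9^2))
    ar <- as.numeric(stats::filter(e, 0.9, method = "recursive"))
    ambient <- config$ambient_mean + diurnal + ar
    # carve the cold spell so its minimum hits cold_spell_min exactly
    spell_start <- sample.int(config$n_days - config$cold_spell_days + 1, 1)
    day_idx <- floor((tsec - tsec[1]) / 86400) + 1
    in_spell <- day_idx >= spell_start &
      day_idx < spell_start + config$cold_spell_days
    frac <- (tsec[in_spell] - min(tsec[in_spell])) /
      (max(tsec[in_spell]) - min(tsec[in_spell]))
    w <- sinpi(frac)
    pos <- w > 1e-8
    depth <- min((ambient[in_spell][pos] - config$cold_spell_min) / w[pos])
    depth <- max(depth, 0)
    ambient[in_spell] <- ambient[in_spell] - depth * w

    ids <- sprintf("A%03d", seq_len(config$n_animals))
    breed <- sample(names(config$breeds), config$n_animals, replace = TRUE,
                    prob = config$breeds)
    dos <- matrix(stats::rbinom(config$n_animals * config$n_planted_snps,
                                2, 0.5),
                  nrow = config$n_animals)
    effect <- config$sens_effect / (2 * config$n_planted_snps)
    genetic <- as.numeric(dos %*% rep(effect, ncol(dos)))
    sens <- pmax(0, config$sens_base + genetic +
                   abs(stats::rnorm(config$n_animals, 0, config$sens_sd)))
    deficit <- pmax(0, config$stress_threshold - ambient)
    temps <- config$baseline_temp - outer(sens, deficit) +
      matrix(stats::rnorm(config$n_animals * n_pts, 0, config$noise_sd),
             nrow = config$n_animals)
    stamps <- as.POSIXct(tsec, origin = "1970-01-01", tz = "UTC")
    list(
      ambient = data.frame(timestamp = stamps, temp_c = ambient),
      readings = data.frame(
        animal_id = rep(ids, each = n_pts),
        timestamp = rep(stamps, config$n_animals),
        temp_c = as.vector(t(temps)),
        stringsAsFactors = FALSE
      ),
      animals = data.frame(animal_id = ids, breed = breed,
                           genetic_score = genetic, sensitivity = sens,
                           stringsAsFactors = FALSE),
      dosages = dos,
      effect_size = effect
    )
  })
}

# transition partner of each base
.transition <- c(A = "G", G = "A", C = "T", T = "C")

#' Simulate genotypes for the two sequenced contrast groups
#'
#' Emits a biallelic-SNP genome with mostly shared allele frequencies plus
#' planted strongly divergent loci, and a truth table of the planted loci.
#' Background SNPs draw one alternate-allele frequency `p ~ U(0.05, 0.95)`
#' shared by both groups; planted SNPs draw per-group frequencies with
#' `|p1 - p2| >= planted_afd` (which side is high is random). Genotypes are
#' binomial (Hardy-Weinberg within group) and missing at
#' `missing_genotype_rate`. INFO fields are drawn from passing
#' distributions; a `fraction_failing_filters` of background records gets
#' one filter-violating value, and an `indel_fraction` of background records
#' is emitted as INDELs. Planted records always pass filters and are never
#' INDELs, so the planted truth stays discoverable downstream.
#'
#' @param config a [sim_config()].
#' @param groups data frame (`sample_id`, `group`) with exactly two labels
#'   and `n_sequenced_per_group` samples each.
#' @param seed RNG seed.
#' @return list with elements `variants` (a [variant_set()]) and `truth`
#'   (data frame `chrom`, `pos`, `ref`, `alt`, `af_alt_group1`,
#'   `af_alt_group2`, with attribute `group_labels`).
#' @export
simulate_genotypes <- function(config, groups, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  gs <- group_samples(groups)
  sizes <- lengths(gs)
  if (any(sizes != config$n_sequenced_per_group)) {
    stop("invalid config: each group must have exactly ",
         config$n_sequenced_per_group, " samples", call. = FALSE)
  }
  with_seed(seed, {
    n_snps <- config$n_background_snps + config$n_planted_snps
    chroms <- as.character(seq_len(config$n_chromosomes))
    chrom <- sort(sample(chroms, n_snps, replace = TRUE))
    pos <- unlist(lapply(split(seq_along(chrom), chrom), function(i) {
      sort(sample.int(config$chrom_length, length(i)))
    }), use.names = FALSE)
    ord <- order(as.integer(chrom), pos)
    chrom <- chrom[ord]
    pos <- pos[ord]
    planted <- rep(FALSE, n_snps)
    planted[sample.int(n_snps, config$n_planted_snps)] <- TRUE

    ref <- sample(c("A", "C", "G", "T"), n_snps, replace = TRUE)
    is_ts <- stats::runif(n_snps) < 2 / 3
    tv_pool <- list(A = c("C", "T"), C = c("A", "G"),
                    G = c("C", "T"), T = c("A", "G"))
    alt <- ifelse(is_ts, .transition[ref],
                  vapply(ref, function(b) sample(tv_pool[[b]], 1),
                         character(1)))
    names(alt) <- NULL

    # alternate-allele frequencies per group
    p1 <- p2 <- stats::runif(n_snps, 0.05, 0.95)
    np <- sum(planted)
    d <- stats::runif(np, config$planted_afd, 1)
    lo <- stats::runif(np, 0, 1 - d)
    hi_first <- stats::runif(np) < 0.5
    p1[planted] <- ifelse(hi_first, lo + d, lo)
    p2[planted] <- ifelse(hi_first, lo, lo + d)

    k <- config$n_sequenced_per_group
    g1 <- matrix(stats::rbinom(n_snps * k, 2, rep(p1, k)), nrow = n_snps)
    g2 <- matrix(stats::rbinom(n_snps * k, 2, rep(p2, k)), nrow = n_snps)
    geno <- cbind(g1, g2)
    colnames(geno) <- c(gs[[1]], gs[[2]])
    if (config$missing_genotype_rate > 0) {
      miss <- matrix(stats::runif(length(geno)) <
                       config$missing_genotype_rate, nrow = n_snps)
      geno[miss] <- NA_integer_
    }

    # INDELs among background records only
    bg <- which(!planted)
    n_indel <- round(config$indel_fraction * length(bg))
    if (n_indel > 0) {
      idx <- sample(bg, n_indel)
      ins <- stats::runif(n_indel) < 0.5
      extra <- vapply(seq_len(n_indel), function(i) {
        paste(sample(c("A", "C", "G", "T"),
                     sample(1:3, 1), replace = TRUE), collapse = "")
      }, character(1))
      ref[idx] <- ifelse(ins, ref[idx], paste0(ref[idx], extra))
      alt[idx] <- ifelse(ins, paste0(alt[idx], extra), alt[idx])
    }

    # INFO fields: passing draws, clipped clear of the thresholds
    info <- config$info_field_distributions
    qd <- pmax(2.5, stats::rnorm(n_snps, info$qd[1], info$qd[2]))
    mq <- pmax(41, pmin(60, stats::rnorm(n_snps, info$mq[1], info$mq[2])))
    fs <- pmin(55, stats::rexp(n_snps, 1 / info$fs))
    mqrs <- pmax(-11, stats::rnorm(n_snps, info$ranksum[1], info$ranksum[2]))
    rprs <- pmax(-7, stats::rnorm(n_snps, info$ranksum[1], info$ranksum[2]))
    fail <- !planted & stats::runif(n_snps) < config$fraction_failing_filters
    which_rule <- sample(5, n_snps, replace = TRUE)
    set_fail <- function(vals, rule, draw) {
      sel <- fail & which_rule == rule
      vals[sel] <- draw(sum(sel))
      vals
    }
    qd <- set_fail(qd, 1, function(n) stats::runif(n, 0, 2))
    mq <- set_fail(mq, 2, function(n) stats::runif(n, 20, 40))
    fs <- set_fail(fs, 3, function(n) stats::runif(n, 60.001, 250))
    mqrs <- set_fail(mqrs, 4, function(n) stats::runif(n, -30, -12.5))
    rprs <- set_fail(rprs, 5, function(n) stats::runif(n, -20, -8.001))

    variants <- data.frame(
      chrom = chrom, pos = pos, id = ".", ref = ref, alt = alt,
      qd = qd, mq = mq, fs = fs, mqranksum = mqrs, readposranksum = rprs,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      chrom = chrom[planted], pos = pos[planted],
      ref = ref[planted], alt = alt[planted],
      af_alt_group1 = p1[planted], af_alt_group2 = p2[planted],
      stringsAsFactors = FALSE
    )
    attr(truth, "group_labels") <- names(gs)
    list(variants = variant_set(variants, geno), truth = truth)
  })
}

#' Simulate the per-SNP functional-score table
#'
#' Background SNPs draw scores from a right-skewed continuous distribution;
#' planted SNPs receive, with probability `faeth_enrichment`, a score from
#' the extreme upper tail (uniform above the `faeth_planted_quantile`
#' background quantile) and otherwise a background-distribution score.
#' A `faeth_missing_rate` fraction of background SNPs is absent from the
#' table, emulating that only annotated SNPs are rankable; planted SNPs are
#' always present.
#'
#' @param x a [variant_set()] (typically from [simulate_genotypes()]).
#' @param truth truth table from [simulate_genotypes()].
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return data frame with columns `chrom`, `pos`, `ref`, `alt`, `score`.
#' @export
simulate_faeth <- function(x, truth, config, seed = config$seed) {
  stopifnot(inherits(x, "variant_set"))
  if (!n_variants(x)) stop("empty variant set", call. = FALSE)
  with_seed(seed, {
    v <- x$variants
    key <- paste(v$chrom, v$pos)
    planted <- key %in% paste(truth$chrom, truth$pos)
    n <- nrow(v)
    score <- stats::rbeta(n, 1.2, 6)
    np <- sum(planted)
    if (np > 0) {
      q_hi <- stats::quantile(score[!planted], config$faeth_planted_quantile,
                              names = FALSE)
      enriched <- stats::runif(np) < config$faeth_enrichment
      top <- stats::runif(np, q_hi, 1)
      score[planted] <- ifelse(enriched, top, score[planted])
    }
    drop <- !planted & stats::runif(n) < config$faeth_missing_rate
    out <- data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                      score = score, stringsAsFactors = FALSE)[!drop, ]
    rownames(out) <- NULL
    out
  })
}
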