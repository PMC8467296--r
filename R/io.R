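# CSV interchange: ISO-8601 timestamps in UTC, plain unquoted fields

.fmt_time <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

.parse_time <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%SZ",
                                      tz = "UTC")

.write_plain_csv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Write / read temperature series CSV
#'
#' Long format with columns `animal_id` (or `"ambient"`), `timestamp`
#' (ISO-8601, UTC) and `temp_c`. Output is byte-deterministic.
#'
#' @param readings data frame with columns `animal_id`, `timestamp`,
#'   `temp_c` (for the ambient series, use `animal_id = "ambient"` or omit
#'   the column).
#' @param path file path.
#' @return `path` invisibly (writer); the parsed data frame (reader).
#' @export
write_temperatures <- function(readings, path) {
  df <- readings
  df$timestamp <- .fmt_time(df$timestamp)
  df$temp_c <- sprintf("%.4f", df$temp_c)
  .write_plain_csv(df, path)
}

#' @rdname write_temperatures
#' @export
read_temperatures <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- .parse_time(df$timestamp)
  df
}

#' Write / read the sample-to-group assignment CSV
#'
#' Columns `sample_id`, `group`, `breed`.
#'
#' @param groups data frame (`sample_id`, `group`, `breed`).
#' @param path file path.
#' @return `path` invisibly (writer); the parsed data frame (reader).
#' @export
write_groups <- function(groups, path) .write_plain_csv(groups, path)

#' @rdname write_groups
#' @export
read_groups <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Generate and write a complete synthetic study
#'
#' Runs the full generator: temperature campaign, AUC phenotypes over the
#' coldest spell, breed-balanced extreme groups, genotypes with planted
#' divergent loci, functional-score table and toy annotated genome — all
#' derived deterministically from `(config, seed)` — and writes every
#' artefact to `outdir` as plain-text files (CSV, VCF, GTF, FASTA).
#'
#' Files written: `ambient.csv`, `temperatures.csv`, `phenotypes.csv`,
#' `groups.csv`, `variants.vcf`, `faeth.csv`, `genes.gtf`, `genome.fa`,
#' `truth.csv` (planted loci with their simulated group allele frequencies,
#' assigned functional score and per-locus phenotype effect).
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @param seed RNG seed; sub-generators use fixed offsets from it.
#' @return invisibly, a list with the written `paths` and the in-memory
#'   objects (`temps`, `interval`, `phenotypes`, `groups`, `variants`,
#'   `truth`, `faeth`, `gene_models`).
#' @export
simulate_study <- function(config = sim_config(), outdir, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  p <- function(f) file.path(outdir, f)

  temps <- simulate_temperatures(config, seed = seed)
  interval <- coldest_interval(temps$ambient, config$cold_spell_days)
  phen <- compute_phenotypes(temps$readings, interval)
  phen$breed <- temps$animals$breed[match(phen$animal_id,
                                          temps$animals$animal_id)]
  groups <- select_extreme_groups(phen, config$n_sequenced_per_group)

  gen <- simulate_genotypes(config, groups, seed = seed + 1L)
  faeth <- simulate_faeth(gen$variants, gen$truth, config, seed = seed + 2L)
  gm <- simulate_gene_models(config, seed = seed + 3L)

  truth <- gen$truth
  fkey <- paste(faeth$chrom, faeth$pos)
  truth$faeth_score <- faeth$score[match(paste(truth$chrom, truth$pos), fkey)]
  truth$effect_size <- temps$effect_size
  labs <- attr(gen$truth, "group_labels")
  names(truth)[names(truth) == "af_alt_group1"] <- paste0("af_alt_", labs[1])
  names(truth)[names(truth) == "af_alt_group2"] <- paste0("af_alt_", labs[2])

  write_temperatures(cbind(animal_id = "ambient", temps$ambient),
                     p("ambient.csv"))
  write_temperatures(temps$readings, p("temperatures.csv"))
  phen_out <- phen
  phen_out$auc <- sprintf("%.4f", phen_out$auc)
  .write_plain_csv(phen_out, p("phenotypes.csv"))
  write_groups(groups, p("groups.csv"))
  write_vcf(gen$variants, p("variants.vcf"),
            contig_lengths = stats::setNames(
              rep(config$chrom_length, config$n_chromosomes),
              as.character(seq_len(config$n_chromosomes))))
  faeth_out <- faeth
  faeth_out$score <- sprintf("%.6f", faeth_out$score)
  .write_plain_csv(faeth_out, p("faeth.csv"))
  write_gtf(gm$gtf, p("genes.gtf"))
  Biostrings::writeXStringSet(gm$genome, p("genome.fa"))
  truth_out <- truth
  num <- vapply(truth_out, is.numeric, logical(1)) &
    !(names(truth_out) %in% c("pos"))
  truth_out[num] <- lapply(truth_out[num], function(z) sprintf("%.6f", z))
  .write_plain_csv(truth_out, p("truth.csv"))

  invisible(list(
    paths = vapply(c("ambient.csv", "temperatures.csv", "phenotypes.csv",
                     "groups.csv", "variants.vcf", "faeth.csv", "genes.gtf",
                     "genome.fa", "truth.csv"), p, character(1)),
    temps = temps, interval = interval, phenotypes = phen, groups = groups,
    variants = gen$variants, truth = truth, faeth = faeth, gene_models = gm
  ))
}
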