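# Independent oracles, written as naive transcriptions / brute-force
# enumerations. They deliberately share no code with the package internals.

# Weir & Cockerham (1984) two-population estimator, scalar, with explicit
# sums over populations exactly as the component formulas are written.
wc84_naive <- function(n, p, h) {
  r <- length(n)
  n_bar <- sum(n) / r
  n_c <- (r * n_bar - sum(n^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n * p) / (r * n_bar)
  s2 <- sum(n * (p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n * h) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# random group-count fixtures realisable as genotype data
random_counts <- function(n_sites, seed) {
  set.seed(seed)
  draw_group <- function() {
    n <- sample(2:8, n_sites, replace = TRUE)
    n_alt <- rbinom(n_sites, 2 * n, runif(n_sites, 0.02, 0.98))
    # heterozygote count consistent with the allele count (same parity,
    # non-negative homozygote counts)
    max_het <- pmin(n_alt, 2 * n - n_alt)
    het <- vapply(max_het, function(m) {
      ok <- seq(m %% 2, m, by = 2)
      ok[sample.int(length(ok), 1)]
    }, numeric(1))
    list(n = n, p = 1 - n_alt / (2 * n), h = het / n)
  }
  g1 <- draw_group()
  g2 <- draw_group()
  data.frame(n1 = g1$n, p1 = g1$p, h1 = g1$h,
             n2 = g2$n, p2 = g2$p, h2 = g2$h)
}

# brute-force balanced extreme-group search: enumerate all disjoint pairs of
# per_group-subsets, keep breed-balanced ones, maximise AUC-sum separation
brute_force_groups <- function(phen, per_group = 6) {
  n <- nrow(phen)
  idx_t <- utils::combn(n, per_group)
  best <- NULL
  best_obj <- -Inf
  for (i in seq_len(ncol(idx_t))) {
    tol <- idx_t[, i]
    rest <- setdiff(seq_len(n), tol)
    idx_s <- utils::combn(rest, per_group)
    for (j in seq_len(ncol(idx_s))) {
      sen <- idx_s[, j]
      tab_t <- table(factor(phen$breed[tol], levels = unique(phen$breed)))
      tab_s <- table(factor(phen$breed[sen], levels = unique(phen$breed)))
      if (any(abs(tab_t - tab_s) > 1)) next
      obj <- sum(phen$auc[tol]) - sum(phen$auc[sen])
      if (obj > best_obj) {
        best_obj <- obj
        best <- list(tolerant = sort(phen$animal_id[tol]),
                     sensitive = sort(phen$animal_id[sen]))
      }
    }
  }
  best
}

# small variant-set builder: geno is a sites x samples matrix of dosages
make_vset <- function(chrom, pos, ref, alt, geno,
                      qd = NA, mq = NA, fs = NA, mqrs = NA, rprs = NA) {
  n <- length(pos)
  variant_set(
    data.frame(chrom = chrom, pos = pos, id = ".", ref = ref, alt = alt,
               qd = rep_len(qd, n), mq = rep_len(mq, n), fs = rep_len(fs, n),
               mqranksum = rep_len(mqrs, n),
               readposranksum = rep_len(rprs, n),
               stringsAsFactors = FALSE),
    geno)
}

two_groups <- function(n_per = 6, labels = c("sensitive", "tolerant")) {
  data.frame(sample_id = sprintf("S%02d", seq_len(2 * n_per)),
             group = rep(labels, each = n_per),
             stringsAsFactors = FALSE)
}
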