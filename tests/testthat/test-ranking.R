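test_that("fractional ranks rescale descending order to [0, 1]", {
  expect_equal(fractional_ranks(c(5, 3, 1)), c(0, 0.5, 1))
  expect_equal(fractional_ranks(c(7, 7)), c(0.5, 0.5))
  expect_equal(fractional_ranks(3.14), 0)
  set.seed(11)
  x <- sample(rnorm(1001))
  r <- fractional_ranks(x)
  expect_equal(sort(r), seq(0, 1, by = 0.001))           # a permutation
  expect_equal(r[which.max(x)], 0)
  expect_equal(r[which.min(x)], 1)
  expect_error(fractional_ranks(numeric(0)), "non-empty")
  expect_error(fractional_ranks(c(1, NA)), "finite")
})

test_that("allele-frequency differences reproduce reported group contrasts", {
  groups <- two_groups(6)
  # ~0.08 vs 0.80 reference-allele frequencies
  ddx_like <- c(2L, 2L, 2L, 2L, 2L, 1L, 1L, 1L, 0L, 0L, 0L, NA)
  # 1.00 vs 0.125 (prints as 0.13) with two missing in group 2
  maats_like <- c(0L, 0L, 0L, 0L, 0L, 0L, 2L, 2L, 2L, 1L, NA, NA)
  geno <- rbind(ddx_like, maats_like)
  colnames(geno) <- groups$sample_id
  vs <- make_vset("5", c(31112894L, 65062344L), c("C", "T"), c("T", "C"),
                  geno)
  res <- allele_freq_diff(vs, groups)
  expect_equal(res$afd[1], abs(1 / 12 - 0.8), tolerance = 1e-12)
  expect_equal(round(res$afd[1], 2), 0.72)
  expect_equal(res$afd[2], 1 - 1 / 8, tolerance = 1e-12)
  # agrees with the printed contrast 1.00 - 0.13 = 0.87 to within half a
  # unit in the last printed digit of the group frequencies
  expect_lte(abs(res$afd[2] - 0.87), 0.005 + 1e-12)
  expect_false(any(res$excluded))
})

test_that("too few called genotypes or a sex chromosome excludes a SNP", {
  groups <- two_groups(6)
  two_called <- c(1L, 1L, rep(NA_integer_, 4), rep(0L, 6))
  full <- rep(c(0L, 2L), each = 6)
  geno <- rbind(two_called, full, full)
  colnames(geno) <- groups$sample_id
  vs <- make_vset(c("1", "1", "X"), c(10L, 20L, 30L), "A", "G", geno)
  res <- allele_freq_diff(vs, groups, min_called = 3)
  expect_equal(res$excluded, c(TRUE, FALSE, TRUE))
})

test_that("a 3-SNP toy universe matches hand-computed rank sums", {
  groups <- two_groups(6)
  g1 <- function(x) c(x, rep(0L, 6))
  geno <- rbind(c(rep(2L, 6), rep(0L, 6)),
                c(2L, 2L, 1L, 1L, 0L, 0L, rep(0L, 6)),
                c(1L, rep(0L, 5), rep(0L, 6)))
  colnames(geno) <- groups$sample_id
  vs <- make_vset("1", c(1000L, 2000L, 3000L), c("A", "C", "G"),
                  c("G", "T", "A"), geno)
  faeth <- data.frame(chrom = "1", pos = c(1000L, 2000L, 3000L),
                      score = c(0.9, 0.5, 0.1))
  cr <- cold_rank(vs, groups, faeth, threshold = 0.6)
  # all three SNPs share the single window, so r_fst ties at 0.5;
  # AFD = 1, 0.5, 1/12 and scores 0.9, 0.5, 0.1 rank as 0, 0.5, 1
  expect_equal(cr$snps$pos, c(1000L, 2000L, 3000L))
  expect_equal(cr$snps$r_fst, c(0.5, 0.5, 0.5))
  expect_equal(cr$snps$r_afd, c(0, 0.5, 1))
  expect_equal(cr$snps$r_faeth, c(0, 0.5, 1))
  expect_equal(cr$snps$rank_sum, c(0.5, 1.5, 2.5))
  expect_equal(cr$snps$selected, c(TRUE, FALSE, FALSE))
  expect_equal(cr$n$windows, 1L)
})

test_that("SNPs without functional annotation are dropped from the output
           but keep shaping the AFD rank denominator", {
  groups <- two_groups(6)
  afds <- list(c(rep(2L, 6), rep(0L, 6)),          # afd 1.00
               c(rep(2L, 5), 1L, rep(0L, 6)),      # afd 11/12
               c(rep(2L, 4), 1L, 1L, rep(0L, 6)),  # afd 10/12
               c(rep(2L, 3), 1L, 1L, 1L, rep(0L, 6)))  # afd 9/12
  geno <- do.call(rbind, afds)
  colnames(geno) <- groups$sample_id
  vs <- make_vset("1", c(100L, 200L, 300L, 400L), "A", "G", geno)
  faeth <- data.frame(chrom = "1", pos = c(100L, 300L, 400L),
                      score = c(0.3, 0.2, 0.1))
  cr <- cold_rank(vs, groups, faeth)
  expect_equal(cr$snps$pos, c(100L, 300L, 400L))  # pos 200 dropped
  # AFD ranks are fractional over the 4-SNP universe, not over the 3 kept
  expect_equal(sort(cr$snps$r_afd), c(0, 2 / 3, 1))
  expect_equal(cr$n$afd_universe, 4L)
  expect_equal(cr$n$faeth_universe, 3L)
})

test_that("raising a SNP's functional score never increases its rank sum", {
  set.seed(21)
  groups <- two_groups(6)
  n <- 50
  geno <- matrix(rbinom(n * 12, 2, runif(n, 0.1, 0.9)), nrow = n)
  colnames(geno) <- groups$sample_id
  geno[1, ] <- c(rep(2L, 6), rep(0L, 6))  # keep at least one divergent SNP
  vs <- make_vset("1", seq_len(n) * 1000L, "A", "G", geno)
  faeth <- data.frame(chrom = "1", pos = seq_len(n) * 1000L,
                      score = runif(n))
  base <- cold_rank(vs, groups, faeth)
  target <- base$snps$pos[25]
  for (bump in c(0.05, 0.2, 1)) {
    f2 <- faeth
    f2$score[f2$pos == target] <- f2$score[f2$pos == target] + bump
    bumped <- cold_rank(vs, groups, f2)
    expect_lte(bumped$snps$rank_sum[bumped$snps$pos == target],
               base$snps$rank_sum[base$snps$pos == target])
  }
})

test_that("any strictly increasing score transform leaves ranks unchanged", {
  set.seed(22)
  groups <- two_groups(6)
  n <- 40
  geno <- matrix(rbinom(n * 12, 2, runif(n, 0.1, 0.9)), nrow = n)
  colnames(geno) <- groups$sample_id
  vs <- make_vset("1", seq_len(n) * 1000L, "A", "G", geno)
  faeth <- data.frame(chrom = "1", pos = seq_len(n) * 1000L,
                      score = runif(n))
  base <- cold_rank(vs, groups, faeth)
  f2 <- faeth
  f2$score <- exp(3 * f2$score) - 0.5
  trans <- cold_rank(vs, groups, f2)
  expect_equal(trans$snps$r_faeth, base$snps$r_faeth)
  expect_equal(trans$snps$rank_sum, base$snps$rank_sum)
})

test_that("the selection count is non-decreasing in the threshold", {
  set.seed(23)
  groups <- two_groups(6)
  n <- 60
  geno <- matrix(rbinom(n * 12, 2, runif(n, 0.1, 0.9)), nrow = n)
  colnames(geno) <- groups$sample_id
  vs <- make_vset("1", seq_len(n) * 1000L, "A", "G", geno)
  faeth <- data.frame(chrom = "1", pos = seq_len(n) * 1000L,
                      score = runif(n))
  counts <- vapply(c(0.05, 0.1, 0.5, 1, 3), function(th) {
    sum(candidates(cold_rank(vs, groups, faeth, threshold = th))$selected)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[5], nrow(cold_rank(vs, groups, faeth)$snps))
})

test_that("both F_ST rank bases agree on the candidate ordering", {
  set.seed(24)
  groups <- two_groups(6)
  n <- 80
  geno <- matrix(rbinom(n * 12, 2, runif(n, 0.1, 0.9)), nrow = n)
  colnames(geno) <- groups$sample_id
  pos <- sort(sample(1:3e6, n))
  vs <- make_vset("1", pos, "A", "G", geno)
  faeth <- data.frame(chrom = "1", pos = pos, score = runif(n))
  by_snp <- cold_rank(vs, groups, faeth, fst_rank_basis = "snps")
  by_win <- cold_rank(vs, groups, faeth, fst_rank_basis = "windows")
  # same SNPs, and the F_ST rank orderings agree (including tie groups)
  key <- function(cr) paste(cr$snps$chrom, cr$snps$pos)
  m <- match(key(by_snp), key(by_win))
  expect_false(anyNA(m))
  expect_equal(rank(by_snp$snps$window_fst), rank(by_win$snps$window_fst[m]))
  expect_equal(stats::cor(by_snp$snps$r_fst, by_win$snps$r_fst[m],
                          method = "spearman"), 1)
})
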