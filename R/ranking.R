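#' Fractional ranks on [0, 1], highest value first
#'
#' Ranks values in descending order and rescales ordinal positions to the
#' unit interval: the highest value gets rank 0, the lowest rank 1, and ties
#' share the average of their ordinal positions. With a single value the
#' rank is 0.
#'
#' @param values numeric vector (finite, non-empty).
#' @return numeric vector of ranks in `[0, 1]`.
#' @examples
#' fractional_ranks(c(5, 3, 1))  # 0, 0.5, 1
#' @export
fractional_ranks <- function(values) {
  if (!length(values)) stop("`values` must be non-empty", call. = FALSE)
  if (!all(is.finite(values))) {
    stop("`values` must be finite", call. = FALSE)
  }
  n <- length(values)
  if (n == 1L) return(0)
  (rank(-values, ties.method = "average") - 1) / (n - 1)
}

#' Group allele-frequency difference per SNP
#'
#' Absolute difference between the two groups' reference-allele frequencies
#' over called alleles. A SNP is flagged `excluded` (rather than erroring)
#' when either group has fewer than `min_called` called genotypes or the
#' chromosome is non-autosomal; excluded SNPs do not enter the ranking
#' universe.
#'
#' @inheritParams min_called_mask
#' @return data frame with columns `chrom`, `pos`, `n1`, `n2`, `afd`,
#'   `excluded` (one row per site of `x`, in input order).
#' @export
allele_freq_diff <- function(x, groups, min_called = 3) {
  stopifnot(inherits(x, "variant_set"))
  gs <- group_samples(groups)
  freq <- function(samps) {
    g <- x$geno[, samps, drop = FALSE]
    n <- rowSums(!is.na(g))
    alt <- rowSums(g, na.rm = TRUE)
    list(n = n, p = ifelse(n > 0, 1 - alt / (2 * n), NA_real_))
  }
  g1 <- freq(gs[[1]])
  g2 <- freq(gs[[2]])
  afd <- abs(g1$p - g2$p)
  excluded <- !is_autosome(x$variants$chrom) |
    g1$n < min_called | g2$n < min_called
  data.frame(chrom = x$variants$chrom, pos = x$variants$pos,
             n1 = g1$n, n2 = g2$n, afd = afd, excluded = excluded,
             stringsAsFactors = FALSE)
}

#' Rank-aggregation scan for candidate cold-adaptation SNPs
#'
#' The package's core estimator. Combines three lines of evidence per SNP —
#' the weighted F_ST of its best overlapping window, the absolute group
#' allele-frequency difference (AFD), and a per-SNP functional score — into
#' fractional ranks whose sum orders SNPs; candidates are those with
#' `rank_sum < threshold`.
#'
#' The ranking follows a universe-per-rank convention: the AFD and window-F_ST
#' ranks are fractional within the universe of autosomal biallelic SNPs with
#' at least `min_called` called genotypes per group (and a covering F_ST
#' window); the functional-score rank is fractional within the subset of that
#' universe that has a functional annotation. SNPs without a functional
#' annotation are dropped from the final table but still shape the AFD and
#' F_ST rank denominators.
#'
#' @param x a [variant_set()] (hard filtering should already have been
#'   applied; non-biallelic records are dropped internally).
#' @param groups data frame with columns `sample_id` and `group` (two
#'   labels).
#' @param faeth data frame of per-SNP functional scores with columns
#'   `chrom`, `pos`, `score` (extra columns ignored).
#' @param window_size,step sliding-window tiling for the F_ST scan, in bp.
#' @param threshold rank-sum cutoff below which a SNP is selected.
#' @param min_called minimum called genotypes per group.
#' @param fst_rank_basis `"snps"` (default) ranks SNPs directly by their best
#'   window value; `"windows"` ranks the windows themselves and gives each
#'   SNP the fractional rank of its best window, so SNPs sharing a window
#'   share a rank value. Both orderings agree.
#' @return an object of class `cold_rank`: a list with elements `snps` (the
#'   ranked candidate table, ascending `rank_sum`), `windows` (the window
#'   F_ST table), `sites` (per-site F_ST components), `threshold`,
#'   `min_called`, `fst_rank_basis` and `n` (universe sizes).
#' @seealso [fractional_ranks()], [windowed_fst()], [annotate_candidates()]
#' @export
cold_rank <- function(x, groups, faeth,
                      window_size = 50000, step = 25000,
                      threshold = 0.1, min_called = 3,
                      fst_rank_basis = c("snps", "windows")) {
  fst_rank_basis <- match.arg(fst_rank_basis)
  stopifnot(inherits(x, "variant_set"))
  if (!all(c("chrom", "pos", "score") %in% names(faeth))) {
    stop("`faeth` must have columns chrom, pos, score", call. = FALSE)
  }
  x <- keep_biallelic_snps(x)
  if (!n_variants(x)) stop("no biallelic SNPs in input", call. = FALSE)

  afd_tab <- allele_freq_diff(x, groups, min_called = min_called)
  sites <- fst_scan(x, groups)
  windows <- windowed_fst(sites, window_size = window_size, step = step)
  wval <- snp_window_value(afd_tab[c("chrom", "pos")], windows,
                           window_size = window_size, step = step,
                           strict = FALSE)

  # AFD/F_ST universe: autosomal, min-called, covered by a non-empty window
  universe <- !afd_tab$excluded & !is.na(wval)
  if (!any(universe)) stop("ranking universe is empty", call. = FALSE)

  r_afd <- rep(NA_real_, nrow(afd_tab))
  r_afd[universe] <- fractional_ranks(afd_tab$afd[universe])

  r_fst <- rep(NA_real_, nrow(afd_tab))
  if (fst_rank_basis == "snps") {
    r_fst[universe] <- fractional_ranks(wval[universe])
  } else {
    wr <- fractional_ranks(windows$weighted_theta)
    wkey <- paste(windows$chrom, windows$start)
    best <- function(i) {
      kw <- .covering_windows(afd_tab$pos[i], window_size, step)
      ks <- seq(kw$lo, kw$hi)
      m <- match(paste(afd_tab$chrom[i], ks * step + 1), wkey)
      m <- m[!is.na(m)]
      m[which.max(windows$weighted_theta[m])]
    }
    idx <- vapply(which(universe), best, integer(1))
    r_fst[universe] <- wr[idx]
  }

  key <- paste(afd_tab$chrom, afd_tab$pos)
  fkey <- paste(faeth$chrom, faeth$pos)
  fmatch <- match(key, fkey)
  score <- faeth$score[fmatch]
  final <- universe & !is.na(score)
  if (!any(final)) {
    stop("no SNPs with functional annotation in the ranking universe",
         call. = FALSE)
  }
  r_faeth <- rep(NA_real_, nrow(afd_tab))
  r_faeth[final] <- fractional_ranks(score[final])

  snps <- data.frame(
    chrom = x$variants$chrom[final],
    pos = x$variants$pos[final],
    ref = x$variants$ref[final],
    alt = x$variants$alt[final],
    window_fst = wval[final],
    afd = afd_tab$afd[final],
    faeth = score[final],
    r_fst = r_fst[final],
    r_afd = r_afd[final],
    r_faeth = r_faeth[final],
    stringsAsFactors = FALSE
  )
  snps$rank_sum <- snps$r_fst + snps$r_afd + snps$r_faeth
  snps$selected <- snps$rank_sum < threshold
  snps <- snps[order(snps$rank_sum, snps$chrom, snps$pos), , drop = FALSE]
  rownames(snps) <- NULL

  structure(list(
    snps = snps,
    windows = windows,
    sites = sites,
    threshold = threshold,
    min_called = min_called,
    fst_rank_basis = fst_rank_basis,
    n = list(sites_input = n_variants(x),
             afd_universe = sum(universe),
             faeth_universe = sum(final),
             windows = nrow(windows))
  ), class = "cold_rank")
}

#' Extract the selected candidate SNPs
#' @param object a [cold_rank()] object.
#' @return data frame of SNPs with `rank_sum < threshold`.
#' @export
candidates <- function(object) {
  stopifnot(inherits(object, "cold_rank"))
  object$snps[object$snps$selected, , drop = FALSE]
}

#' @export
print.cold_rank <- function(x, ...) {
  cat("Rank-aggregation scan for cold-adaptation candidate SNPs\n")
  cat(sprintf("  input SNPs: %d; AFD/F_ST universe: %d; scored universe: %d\n",
              x$n$sites_input, x$n$afd_universe, x$n$faeth_universe))
  cat(sprintf("  windows: %d; F_ST rank basis: %s\n",
              x$n$windows, x$fst_rank_basis))
  cat(sprintf("  selected: %d SNPs with rank sum < %g\n",
              sum(x$snps$selected), x$threshold))
  cat("\nTop SNPs:\n")
  print(utils::head(x$snps, 5), digits = 4)
  invisible(x)
}

#' @export
summary.cold_rank <- function(object, ...) {
  s <- list(
    n = object$n,
    threshold = object$threshold,
    n_selected = sum(object$snps$selected),
    rank_sum_quantiles = stats::quantile(object$snps$rank_sum,
                                         c(0, .01, .1, .5, 1)),
    max_window_fst = max(object$windows$weighted_theta, na.rm = TRUE),
    top = utils::head(object$snps, 10)
  )
  class(s) <- "summary.cold_rank"
  s
}

#' @export
print.summary.cold_rank <- function(x, ...) {
  cat("Candidate SNP scan summary\n")
  cat(sprintf("  universes: %d AFD / %d scored; %d windows\n",
              x$n$afd_universe, x$n$faeth_universe, x$n$windows))
  cat(sprintf("  max window weighted F_ST: %.4f\n", x$max_window_fst))
  cat(sprintf("  %d candidates at rank sum < %g\n", x$n_selected, x$threshold))
  cat("  rank-sum quantiles:\n")
  print(x$rank_sum_quantiles, digits = 3)
  cat("\nTop SNPs:\n")
  print(x$top, digits = 4)
  invisible(x)
}

#' Plot a candidate scan
#'
#' Window weighted F_ST along a concatenated genome coordinate, with
#' candidate SNPs (rank sum below the threshold) overplotted.
#'
#' @param x a [cold_rank()] object.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cold_rank <- function(x, ...) {
  w <- x$windows
  chroms <- unique(w$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch) {
    max(w$end[w$chrom == ch])
  }, numeric(1))))
  names(offs) <- c(chroms, "_end")
  wx <- (w$start + w$end) / 2 + offs[w$chrom]
  graphics::plot(wx, w$weighted_theta, pch = 16, cex = 0.4, col = "grey40",
                 xlab = "genome position (concatenated)",
                 ylab = expression("window weighted" ~ F[ST]), ...)
  sel <- candidates(x)
  if (nrow(sel)) {
    graphics::points(sel$pos + offs[sel$chrom], sel$window_fst,
                     pch = 21, bg = "firebrick", cex = 0.9)
  }
  graphics::abline(v = offs[seq_along(chroms)], col = "grey80", lty = 3)
  invisible(x)
}
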