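#' Weir-Cockerham variance components for two populations
#'
#' Moment estimator of the fixation index for a biallelic site observed in
#' two populations, from per-group sample sizes, reference-allele
#' frequencies and observed heterozygote proportions. Returns the
#' between-population (`a`), between-individual-within-population (`b`) and
#' within-individual (`c`) components together with
#' `theta = a / (a + b + c)`. `theta` is `NA` (undefined) when
#' `a + b + c == 0`, i.e. the pooled sample is monomorphic. Negative
#' components and negative `theta` are retained, as the estimator's small
#' negative excursions around zero are part of its sampling behaviour.
#'
#' All arguments are vectorised over sites.
#'
#' @param n1,n2 number of individuals with called genotypes per group.
#' @param p1,p2 reference-allele frequency among called alleles per group.
#' @param h1,h2 observed heterozygote proportion among called individuals.
#' @return data frame with columns `n_bar`, `n_c`, `p_bar`, `s2`, `h_bar`,
#'   `a`, `b`, `c`, `theta`.
#' @references Weir, B.S. and Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @examples
#' wc_fst(6, 1, 0, 6, 0, 0)$theta  # fixed difference -> 1
#' @export
wc_fst <- function(n1, p1, h1, n2, p2, h2) {
  stopifnot(length(p1) == length(n1), length(h1) == length(n1),
            length(n2) == length(n1), length(p2) == length(n1),
            length(h2) == length(n1))
  r <- 2
  n_bar <- (n1 + n2) / r
  if (any(n_bar <= 1)) {
    stop("degenerate sample: mean sample size must exceed 1", call. = FALSE)
  }
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  denom <- a + b + cc
  theta <- ifelse(denom == 0, NA_real_, a / denom)
  data.frame(n_bar = n_bar, n_c = n_c, p_bar = p_bar, s2 = s2, h_bar = h_bar,
             a = a, b = b, c = cc, theta = theta)
}

#' Per-site group counts from genotypes
#'
#' Computes, over non-missing genotypes only, each group's called sample
#' size, reference-allele frequency and observed heterozygote proportion.
#' Sites where either group has no called genotype are dropped with a
#' warning (their frequencies are undefined). Group 1 is the
#' alphabetically first group label.
#'
#' @inheritParams min_called_mask
#' @return data frame with columns `chrom`, `pos`, `n1`, `p1`, `h1`, `n2`,
#'   `p2`, `h2`.
#' @export
site_group_counts <- function(x, groups) {
  stopifnot(inherits(x, "variant_set"))
  gs <- group_samples(groups)
  one <- function(samps) {
    g <- x$geno[, samps, drop = FALSE]
    called <- !is.na(g)
    n <- rowSums(called)
    alt <- rowSums(g, na.rm = TRUE)
    het <- rowSums(g == 1L, na.rm = TRUE)
    list(n = n, p = ifelse(n > 0, 1 - alt / (2 * n), NA_real_),
         h = ifelse(n > 0, het / n, NA_real_))
  }
  g1 <- one(gs[[1]])
  g2 <- one(gs[[2]])
  out <- data.frame(chrom = x$variants$chrom, pos = x$variants$pos,
                    n1 = g1$n, p1 = g1$p, h1 = g1$h,
                    n2 = g2$n, p2 = g2$p, h2 = g2$h,
                    stringsAsFactors = FALSE)
  empty <- out$n1 == 0 | out$n2 == 0
  if (any(empty)) {
    warning(sum(empty), " site(s) skipped: a group has no called genotypes",
            call. = FALSE)
    out <- out[!empty, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Per-site F_ST scan between two groups
#'
#' Applies [wc_fst()] to every biallelic site of a variant set. Sites where
#' theta is undefined (pooled sample monomorphic) are excluded from the
#' output, and therefore also from window sums downstream.
#'
#' @inheritParams min_called_mask
#' @return data frame with columns `chrom`, `pos`, `a`, `b`, `c`, `theta`,
#'   sorted by (`chrom`, `pos`).
#' @export
fst_scan <- function(x, groups) {
  counts <- site_group_counts(keep_biallelic_snps(x), groups)
  comp <- wc_fst(counts$n1, counts$p1, counts$h1,
                 counts$n2, counts$p2, counts$h2)
  out <- data.frame(chrom = counts$chrom, pos = counts$pos,
                    a = comp$a, b = comp$b, c = comp$c, theta = comp$theta,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$theta), , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# window indices (0-based) covering a position, for windows anchored at 1
.covering_windows <- function(pos, window_size, step) {
  k_hi <- (pos - 1) %/% step
  k_lo <- pmax(0, ceiling((pos - window_size) / step))
  list(lo = k_lo, hi = k_hi)
}

#' Sliding-window weighted F_ST
#'
#' Tiles each chromosome with windows of `window_size` bp anchored at
#' position 1 and stepped by `step` bp (1-based inclusive intervals). Every
#' site contributes its `(a, a+b+c)` components to every window containing
#' its position; the window estimate is the ratio of sums
#' `weighted_theta = sum(a) / sum(a+b+c)`, reported alongside the plain mean
#' of per-site theta. Windows containing no sites are omitted.
#'
#' @param sites per-site component table from [fst_scan()] (columns `chrom`,
#'   `pos`, `a`, `b`, `c`, `theta`).
#' @param window_size window width in bp.
#' @param step distance between successive window starts in bp.
#' @return data frame with columns `chrom`, `start`, `end`, `n_sites`,
#'   `weighted_theta`, `mean_theta`.
#' @export
windowed_fst <- function(sites, window_size = 50000, step = 25000) {
  if (step > window_size) {
    stop("`step` must not exceed `window_size`", call. = FALSE)
  }
  stopifnot(all(c("chrom", "pos", "a", "theta") %in% names(sites)))
  d <- sites$a + sites$b + sites$c
  kw <- .covering_windows(sites$pos, window_size, step)
  n_win <- kw$hi - kw$lo + 1
  idx <- rep(seq_len(nrow(sites)), n_win)
  k <- unlist(mapply(seq, kw$lo, kw$hi, SIMPLIFY = FALSE))
  key <- paste(sites$chrom[idx], k, sep = "\r")
  sum_a <- tapply(sites$a[idx], key, sum)
  sum_d <- tapply(d[idx], key, sum)
  mean_t <- tapply(sites$theta[idx], key, mean)
  n_sites <- tapply(idx, key, length)
  parts <- strsplit(names(sum_a), "\r", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1)
  kk <- as.integer(vapply(parts, `[`, character(1), 2))
  out <- data.frame(
    chrom = chrom,
    start = kk * step + 1,
    end = kk * step + window_size,
    n_sites = as.integer(n_sites),
    weighted_theta = ifelse(sum_d == 0, NA_real_, sum_a / sum_d),
    mean_theta = as.numeric(mean_t),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best overlapping-window F_ST value per SNP
#'
#' Under 50 kb / 25 kb tiling nearly every SNP falls in two overlapping
#' windows; each SNP is assigned the maximum `weighted_theta` among the
#' windows containing its position.
#'
#' @param snps data frame with columns `chrom` and `pos`.
#' @param windows window table from [windowed_fst()].
#' @param window_size,step the tiling used to build `windows`.
#' @param strict if `TRUE` (default), a SNP covered by no non-empty window is
#'   an error; if `FALSE` such SNPs get `NA`.
#' @return numeric vector of per-SNP window values.
#' @export
snp_window_value <- function(snps, windows, window_size = 50000, step = 25000,
                             strict = TRUE) {
  if (!nrow(windows)) stop("empty window table", call. = FALSE)
  wkey <- paste(windows$chrom, (windows$start - 1) %/% step, sep = "\r")
  val <- windows$weighted_theta
  kw <- .covering_windows(snps$pos, window_size, step)
  out <- rep(NA_real_, nrow(snps))
  for (off in 0:max(kw$hi - kw$lo)) {
    k <- kw$lo + off
    ok <- k <= kw$hi
    m <- match(paste(snps$chrom, k, sep = "\r"), wkey)
    cand <- ifelse(ok, val[m], NA_real_)
    out <- pmax(out, cand, na.rm = TRUE)
  }
  if (strict && anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop(sprintf("SNP %s:%d is covered by no window in the window table",
                 snps$chrom[bad], snps$pos[bad]), call. = FALSE)
  }
  out
}
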