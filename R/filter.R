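#' Hard-filter thresholds
#'
#' The standard GATK-style site thresholds: a record fails when
#' `QD < qd_min`, `MQ < mq_min`, `FS > fs_max`, `MQRankSum < mqranksum_min`
#' or `ReadPosRankSum < readposranksum_min`. Inequalities are strict, so a
#' value exactly at a threshold passes.
#'
#' @param qd_min minimum variant confidence / quality by depth.
#' @param mq_min minimum RMS mapping quality.
#' @param fs_max maximum Phred-scaled strand-bias (Fisher) score.
#' @param mqranksum_min minimum mapping-quality rank-sum Z-score.
#' @param readposranksum_min minimum read-position rank-sum Z-score.
#' @return an object of class `filter_thresholds`.
#' @export
hard_filter_thresholds <- function(qd_min = 2.0, mq_min = 40.0, fs_max = 60.0,
                                   mqranksum_min = -12.5,
                                   readposranksum_min = -8.0) {
  th <- list(qd_min = qd_min, mq_min = mq_min, fs_max = fs_max,
             mqranksum_min = mqranksum_min,
             readposranksum_min = readposranksum_min)
  if (!all(vapply(th, function(x) is.numeric(x) && is.finite(x), logical(1)))) {
    stop("all thresholds must be finite numbers", call. = FALSE)
  }
  structure(th, class = "filter_thresholds")
}

#' Apply hard filters to a variant set
#'
#' Removes records violating any of the five threshold rules. A missing
#' (absent) annotation never fails its rule — the convention for rank-sum
#' annotations, which are undefined at sites without both allele classes.
#' Each removed record is attributed to every rule it violates, so per-rule
#' counts can sum to more than the number of removed records.
#'
#' @param x a [variant_set()].
#' @param thresholds a [hard_filter_thresholds()] object.
#' @return a list with elements `variants` (the passing [variant_set()]),
#'   `removed_by_rule` (named integer vector: `qd`, `mq`, `fs`, `mqranksum`,
#'   `readposranksum`), `n_input` and `n_removed`.
#' @export
apply_hard_filters <- function(x, thresholds = hard_filter_thresholds()) {
  stopifnot(inherits(x, "variant_set"))
  if (!inherits(thresholds, "filter_thresholds")) {
    stop("`thresholds` must come from hard_filter_thresholds()", call. = FALSE)
  }
  v <- x$variants
  lt <- function(val, th) !is.na(val) & val < th
  gt <- function(val, th) !is.na(val) & val > th
  fails <- cbind(
    qd = lt(v$qd, thresholds$qd_min),
    mq = lt(v$mq, thresholds$mq_min),
    fs = gt(v$fs, thresholds$fs_max),
    mqranksum = lt(v$mqranksum, thresholds$mqranksum_min),
    readposranksum = lt(v$readposranksum, thresholds$readposranksum_min)
  )
  bad <- rowSums(fails) > 0
  list(
    variants = x[!bad],
    removed_by_rule = colSums(fails),
    n_input = nrow(v),
    n_removed = sum(bad)
  )
}

#' Keep biallelic SNP records
#'
#' Retains records whose REF and ALT are both single bases (A/C/G/T) with
#' exactly one alternate allele; INDELs and multiallelic sites are dropped.
#'
#' @param x a [variant_set()].
#' @return the filtered [variant_set()].
#' @export
keep_biallelic_snps <- function(x) {
  stopifnot(inherits(x, "variant_set"))
  bases <- c("A", "C", "G", "T")
  keep <- x$variants$ref %in% bases & x$variants$alt %in% bases
  x[keep]
}

#' Transition/transversion ratio
#'
#' Transitions are the purine-purine (A<->G) and pyrimidine-pyrimidine
#' (C<->T) substitutions; everything else among single-base substitutions is
#' a transversion. Non-SNP records are ignored.
#'
#' @param x a [variant_set()].
#' @return the Ts/Tv ratio (numeric scalar).
#' @export
ts_tv_ratio <- function(x) {
  stopifnot(inherits(x, "variant_set"))
  v <- keep_biallelic_snps(x)$variants
  pair <- paste0(pmin(v$ref, v$alt), pmax(v$ref, v$alt))
  ts <- sum(pair %in% c("AG", "CT"))
  tv <- nrow(v) - ts
  if (tv == 0L) {
    stop("Ts/Tv undefined: no transversions among ", nrow(v), " SNPs",
         call. = FALSE)
  }
  ts / tv
}

#' Minimum-called-genotypes mask
#'
#' `TRUE` where each of the two contrast groups has at least `min_called`
#' successfully called (non-missing) diploid genotypes at the site.
#'
#' @param x a [variant_set()].
#' @param groups data frame with columns `sample_id` and `group` (exactly two
#'   group labels) covering samples of `x`.
#' @param min_called minimum called genotypes required per group.
#' @return logical vector, one element per site.
#' @export
min_called_mask <- function(x, groups, min_called = 3) {
  stopifnot(inherits(x, "variant_set"))
  gs <- group_samples(groups)
  missing_samp <- setdiff(unlist(gs), vcf_samples(x))
  if (length(missing_samp)) {
    stop("samples in `groups` absent from the variant set: ",
         paste(missing_samp, collapse = ", "), call. = FALSE)
  }
  called <- !is.na(x$geno)
  n1 <- rowSums(called[, gs[[1]], drop = FALSE])
  n2 <- rowSums(called[, gs[[2]], drop = FALSE])
  n1 >= min_called & n2 >= min_called
}
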