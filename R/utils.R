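# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code with a temporary RNG state; restores the caller's .Random.seed
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Is a chromosome label autosomal?
#'
#' Sex chromosomes, mitochondrial and similar non-autosomal labels are
#' excluded from the allele-frequency-difference and ranking universes.
#'
#' @param chrom character vector of chromosome labels (with or without a
#'   `"chr"` prefix).
#' @return logical vector.
#' @examples
#' is_autosome(c("1", "chr12", "X", "MT"))
#' @export
is_autosome <- function(chrom) {
  core <- toupper(sub("^chr", "", as.character(chrom), ignore.case = TRUE))
  !(core %in% c("X", "Y", "MT", "M", "W", "Z"))
}

# validate a sample -> group assignment and return list(label -> sample ids),
# labels sorted so downstream "group 1"/"group 2" order is deterministic
group_samples <- function(groups) {
  if (!is.data.frame(groups) || !all(c("sample_id", "group") %in% names(groups))) {
    stop("`groups` must be a data frame with columns sample_id and group",
         call. = FALSE)
  }
  labs <- sort(unique(as.character(groups$group)))
  if (length(labs) != 2L) {
    stop("`groups` must define exactly two group labels, got: ",
         paste(labs, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(groups$sample_id)) {
    stop("duplicated sample_id in `groups`", call. = FALSE)
  }
  out <- lapply(labs, function(l) as.character(groups$sample_id[groups$group == l]))
  names(out) <- labs
  out
}

# format numbers for text output (VCF INFO, GTF) without scientific notation
fmt_num <- function(x, digits = 6) {
  vapply(x, function(xi) {
    if (is.na(xi)) return(".")
    format(signif(xi, digits), trim = TRUE, scientific = FALSE)
  }, character(1))
}
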