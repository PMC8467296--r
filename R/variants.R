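#' Variant set container
#'
#' A light in-memory representation of a multi-sample VCF: a site table with
#' the INFO annotations used by hard filtering (QD, MQ, FS, MQRankSum,
#' ReadPosRankSum) and an integer matrix of per-sample alternate-allele
#' dosages (0, 1, 2; `NA` = missing or not representable as a biallelic
#' diploid call).
#'
#' @param variants data frame with columns `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `qd`, `mq`, `fs`, `mqranksum`, `readposranksum`.
#' @param geno integer matrix, one row per variant, one column per sample
#'   (column names are sample ids).
#' @return an object of class `variant_set`.
#' @seealso [read_vcf()], [write_vcf()]
#' @export
variant_set <- function(variants, geno) {
  req <- c("chrom", "pos", "id", "ref", "alt",
           "qd", "mq", "fs", "mqranksum", "readposranksum")
  miss <- setdiff(req, names(variants))
  if (length(miss)) {
    stop("`variants` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.matrix(geno) || nrow(geno) != nrow(variants)) {
    stop("`geno` must be a matrix with one row per variant", call. = FALSE)
  }
  if (any(variants$pos < 1L, na.rm = TRUE)) {
    stop("positions must be >= 1", call. = FALSE)
  }
  rownames(variants) <- NULL
  rownames(geno) <- NULL
  structure(list(variants = variants, geno = geno), class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$variants), "sites x", ncol(x$geno), "samples\n")
  cat("chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.variant_set` <- function(x, i, ...) {
  variant_set(x$variants[i, , drop = FALSE], x$geno[i, , drop = FALSE])
}

#' Number of variant records
#' @param x a [variant_set()].
#' @return integer count of sites.
#' @export
n_variants <- function(x) nrow(x$variants)

#' Sample identifiers of a variant set
#' @param x a [variant_set()].
#' @return character vector of sample ids.
#' @export
vcf_samples <- function(x) colnames(x$geno)

# dosage coding of diploid GT strings; anything not biallelic-diploid -> NA
.gt_dosage_map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)

#' Read a VCF into a variant set
#'
#' Parses a VCF v4.2 file (plain or bgzip) with `vcfR` and extracts the
#' numeric INFO annotations used by [apply_hard_filters()] together with
#' GT-based alternate-allele dosages. A present but non-numeric value in one
#' of those INFO keys is an error naming the offending record; an absent
#' annotation becomes `NA` (and never fails a filter rule).
#'
#' @param path path to a `.vcf` or `.vcf.gz` file.
#' @return a [variant_set()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  info_num <- function(key) {
    raw <- vcfR::extract.info(v, element = key)
    if (is.null(raw)) return(rep(NA_real_, length(chrom)))
    raw[raw %in% c("", ".")] <- NA
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad)) {
      stop(sprintf("malformed numeric INFO value %s='%s' at %s:%d",
                   key, raw[bad[1]], chrom[bad[1]], pos[bad[1]]),
           call. = FALSE)
    }
    num
  }
  if (!is.null(v@gt) && ncol(v@gt) >= 2L) {
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gsub("|", "/", gt, fixed = TRUE)
    geno <- .gt_dosage_map[gt]
    dim(geno) <- dim(gt)
    colnames(geno) <- colnames(gt)
  } else {
    geno <- matrix(integer(0), nrow = length(chrom), ncol = 0)
  }
  variants <- data.frame(
    chrom = chrom,
    pos = pos,
    id = as.character(fix[, "ID"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    qd = info_num("QD"),
    mq = info_num("MQ"),
    fs = info_num("FS"),
    mqranksum = info_num("MQRankSum"),
    readposranksum = info_num("ReadPosRankSum"),
    stringsAsFactors = FALSE
  )
  variant_set(variants, geno)
}

#' Write a variant set as plain-text VCF v4.2
#'
#' Emits a minimal VCF with the hard-filter INFO keys and GT genotypes;
#' missing calls are written as `"./."`. Output is deterministic for a given
#' variant set, so identical simulations produce byte-identical files.
#'
#' @param x a [variant_set()].
#' @param path output file path (plain text).
#' @param contig_lengths optional named integer vector of contig lengths for
#'   the header; defaults to the maximum observed position per chromosome.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, contig_lengths = NULL) {
  v <- x$variants
  if (is.null(contig_lengths)) {
    contig_lengths <- vapply(split(v$pos, v$chrom), max, numeric(1))
    contig_lengths <- contig_lengths[unique(v$chrom)]  # keep input order
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=coldrank",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            as.integer(contig_lengths)),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Variant Confidence/Quality by Depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS Mapping Quality\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled p-value using Fisher's exact test to detect strand bias\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Z-score From Wilcoxon rank sum test of Alt vs. Ref read mapping qualities\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Z-score from Wilcoxon rank sum test of Alt vs. Ref read position bias\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(x$geno)), collapse = "\t")
  )
  info_part <- function(key, val) {
    ifelse(is.na(val), NA_character_, paste0(key, "=", fmt_num(val)))
  }
  parts <- cbind(info_part("QD", v$qd), info_part("MQ", v$mq),
                 info_part("FS", v$fs), info_part("MQRankSum", v$mqranksum),
                 info_part("ReadPosRankSum", v$readposranksum))
  info <- apply(parts, 1, function(p) {
    p <- p[!is.na(p)]
    if (!length(p)) "." else paste(p, collapse = ";")
  })
  gt_str <- matrix(c("0/0", "0/1", "1/1")[x$geno + 1L], nrow = nrow(x$geno))
  gt_str[is.na(gt_str)] <- "./."
  body <- paste(v$chrom, v$pos, ifelse(is.na(v$id) | v$id == "", ".", v$id),
                v$ref, v$alt, ".", ".", info, "GT",
                sep = "\t")
  if (ncol(gt_str) > 0) {
    body <- paste(body, apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  }
  con <- file(path, open = "wb")  # binary: fixed "\n" line endings everywhere
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}
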