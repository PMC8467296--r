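# consequence classes in decreasing severity; summary calls use this order
.severity <- c("stop_gained", "stop_lost", "missense", "splice_region",
               "synonymous", "5_prime_UTR", "3_prime_UTR", "intron",
               "upstream", "downstream", "intergenic")

.most_severe <- function(classes) {
  classes <- classes[!is.na(classes)]
  if (!length(classes)) return(NA_character_)
  .severity[min(match(classes, .severity))]
}

#' Build a queryable gene index from a GTF file
#'
#' Parses an Ensembl-dialect GTF (1-based inclusive) with `rtracklayer` and
#' organises exon and CDS intervals per transcript for point queries.
#'
#' @param gtf path to a GTF file, or a feature data frame as produced by
#'   [simulate_gene_models()].
#' @return an object of class `gene_index`.
#' @export
read_gene_models <- function(gtf) {
  if (is.character(gtf)) {
    df <- tryCatch(as.data.frame(rtracklayer::import(gtf, format = "gtf")),
                   error = function(e) {
                     stop("failed to parse GTF '", gtf, "': ",
                          conditionMessage(e), call. = FALSE)
                   })
    df$chrom <- as.character(df$seqnames)
    df$feature <- as.character(df$type)
    df$strand <- as.character(df$strand)
  } else {
    df <- gtf
  }
  need <- c("chrom", "feature", "start", "end", "strand", "gene_id",
            "transcript_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("GTF is missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!("gene_name" %in% names(df))) df$gene_name <- df$gene_id
  feat <- df[df$feature %in% c("exon", "CDS"), , drop = FALSE]
  tx_ids <- unique(feat$transcript_id[!is.na(feat$transcript_id)])
  transcripts <- lapply(tx_ids, function(tid) {
    sub <- feat[feat$transcript_id %in% tid, , drop = FALSE]
    ex <- sub[sub$feature == "exon", c("start", "end"), drop = FALSE]
    ex <- as.matrix(ex[order(ex$start), , drop = FALSE])
    cd <- sub[sub$feature == "CDS", c("start", "end"), drop = FALSE]
    cd <- as.matrix(cd[order(cd$start), , drop = FALSE])
    if (!nrow(ex) && nrow(cd)) ex <- cd
    gname <- sub$gene_name[1]
    n_ex <- nrow(ex)
    list(transcript_id = tid, gene_id = sub$gene_id[1],
         gene_name = if (is.na(gname)) sub$gene_id[1] else gname,
         chrom = sub$chrom[1], strand = sub$strand[1],
         exons = ex, cds = cd,
         # exon edges that adjoin introns (internal splice junctions)
         left_edges = if (n_ex > 1) ex[-1, 1] else numeric(0),
         right_edges = if (n_ex > 1) ex[-n_ex, 2] else numeric(0),
         cds_lens = if (nrow(cd)) cd[, 2] - cd[, 1] + 1 else numeric(0),
         start = min(ex[, 1]), end = max(ex[, 2]))
  })
  names(transcripts) <- tx_ids
  genes <- data.frame(
    transcript_id = tx_ids,
    gene_id = vapply(transcripts, `[[`, character(1), "gene_id"),
    gene_name = vapply(transcripts, `[[`, character(1), "gene_name"),
    chrom = vapply(transcripts, `[[`, character(1), "chrom"),
    start = vapply(transcripts, `[[`, numeric(1), "start"),
    end = vapply(transcripts, `[[`, numeric(1), "end"),
    strand = vapply(transcripts, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(transcripts = transcripts, genes = genes),
            class = "gene_index")
}

#' @export
print.gene_index <- function(x, ...) {
  cat("gene_index:", nrow(x$genes), "transcript(s) on",
      length(unique(x$genes$chrom)), "sequence(s)\n")
  invisible(x)
}

#' Query transcripts at a genomic point
#'
#' @param index a [read_gene_models()] index.
#' @param chrom,pos query position (1-based).
#' @param flank flanking distance (bp) within which a gene is reported as an
#'   upstream/downstream neighbour.
#' @return data frame of matching transcripts with a `where` column
#'   (`"body"`, `"upstream"` or `"downstream"`, strand-aware).
#' @export
query_gene_index <- function(index, chrom, pos, flank = 5000) {
  g <- index$genes
  sel <- g$chrom == chrom & pos >= g$start - flank & pos <= g$end + flank
  hits <- g[sel, , drop = FALSE]
  if (!nrow(hits)) return(cbind(hits, where = character(0)))
  before <- pos < hits$start
  after <- pos > hits$end
  hits$where <- ifelse(!before & !after, "body",
                       ifelse(xor(before, hits$strand == "-"),
                              "upstream", "downstream"))
  rownames(hits) <- NULL
  hits
}

# spliced CDS (5'->3') of a transcript from the genome, cached per call set
.spliced_cds <- function(tx, genome) {
  seqs <- vapply(seq_len(nrow(tx$cds)), function(k) {
    as.character(Biostrings::subseq(genome[[tx$chrom]],
                                    tx$cds[k, 1], tx$cds[k, 2]))
  }, character(1))
  s <- paste(seqs, collapse = "")
  if (tx$strand == "-") s <- .revcomp(s)
  s
}

.comp_base <- function(b) chartr("ACGT", "TGCA", b)

# classify one SNP against one transcript; returns list(class, aa_change)
.classify_tx <- function(tx, pos, ref, alt, genome, flank, cds_cache) {
  if (pos < tx$start - flank || pos > tx$end + flank) return(NULL)
  if (pos < tx$start || pos > tx$end) {
    before <- pos < tx$start
    cls <- if (xor(before, tx$strand == "-")) "upstream" else "downstream"
    return(list(class = cls, aa_change = NA_character_))
  }
  ex <- tx$exons
  hit <- which(pos >= ex[, 1] & pos <= ex[, 2])
  left_edges <- tx$left_edges
  right_edges <- tx$right_edges
  splice <- FALSE
  if (length(hit)) {
    e <- ex[hit[1], ]
    if ((e[1] %in% left_edges && pos - e[1] <= 2) ||
        (e[2] %in% right_edges && e[2] - pos <= 2)) {
      splice <- TRUE  # 1-3 exonic bases from a splice site
    }
    cd <- tx$cds
    in_cds <- nrow(cd) > 0 && any(pos >= cd[, 1] & pos <= cd[, 2])
    if (in_cds) {
      res <- .classify_coding(tx, pos, ref, alt, genome, cds_cache)
      cls <- if (splice && .severity_lt(res$class, "splice_region"))
        "splice_region" else res$class
      return(list(class = cls, aa_change = res$aa_change))
    }
    if (!nrow(cd)) return(list(class = NA_character_,
                               aa_change = NA_character_))
    # untranslated exon sequence: side relative to the CDS span
    five <- if (tx$strand == "+") pos < min(cd[, 1]) else pos > max(cd[, 2])
    cls <- if (splice) "splice_region"
      else if (five) "5_prime_UTR" else "3_prime_UTR"
    return(list(class = cls, aa_change = NA_character_))
  }
  # intronic: distance into the intron from the nearest splice site
  d_left <- pos - right_edges   # bases past an exon end (>=1 in intron)
  d_right <- left_edges - pos   # bases before an exon start
  d <- min(c(d_left[d_left > 0], d_right[d_right > 0]))
  cls <- if (d <= 8) "splice_region" else "intron"
  list(class = cls, aa_change = NA_character_)
}

.severity_lt <- function(a, b) match(a, .severity) > match(b, .severity)

.classify_coding <- function(tx, pos, ref, alt, genome, cds_cache) {
  cd <- tx$cds
  lens <- tx$cds_lens
  hit <- which(pos >= cd[, 1] & pos <= cd[, 2])[1]
  if (tx$strand == "+") {
    cds_pos <- sum(lens[seq_len(hit - 1)]) + (pos - cd[hit, 1] + 1)
  } else {
    cds_pos <- sum(lens[-seq_len(hit)]) + (cd[hit, 2] - pos + 1)
  }
  spliced <- cds_cache(tx)
  codon_i <- (cds_pos - 1) %/% 3 + 1
  off <- (cds_pos - 1) %% 3 + 1
  codon <- substr(spliced, 3 * (codon_i - 1) + 1, 3 * codon_i)
  ref_sense <- if (tx$strand == "+") ref else .comp_base(ref)
  alt_sense <- if (tx$strand == "+") alt else .comp_base(alt)
  if (substr(codon, off, off) != ref_sense) {
    stop(sprintf(
      "reference/annotation inconsistency at %s:%d in transcript %s: VCF ref '%s' vs genome '%s'",
      tx$chrom, pos, tx$transcript_id, ref,
      if (tx$strand == "+") substr(codon, off, off)
      else .comp_base(substr(codon, off, off))), call. = FALSE)
  }
  alt_codon <- codon
  substr(alt_codon, off, off) <- alt_sense
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[codon])
  alt_aa <- unname(code[alt_codon])
  cls <- if (ref_aa == alt_aa) "synonymous"
    else if (alt_aa == "*") "stop_gained"
    else if (ref_aa == "*") "stop_lost"
    else "missense"
  list(class = cls, aa_change = paste0(ref_aa, codon_i, alt_aa))
}

#' Classify SNPs by gene context and coding consequence
#'
#' Assigns each SNP one consequence class per overlapping transcript and a
#' most-severe summary class. Coding positions are classified by extracting
#' the affected codon (strand- and frame-aware) and translating reference
#' and alternate codons; the reference codon must match the genome FASTA,
#' otherwise a consistency error names the transcript. Splice regions follow
#' the Ensembl convention (1-3 exonic or 1-8 intronic bases from an internal
#' splice site, donor/acceptor collapsed into `splice_region`). Positions in
#' untranslated exon sequence are 5'/3' UTR; other in-gene positions are
#' intronic; positions within `flank` bp of a gene are upstream/downstream
#' (strand-aware); everything else is intergenic. SNPs on sequences absent
#' from the index get an `NA` class.
#'
#' @param snps data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param index a [read_gene_models()] gene index.
#' @param genome a [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param flank upstream/downstream flanking distance in bp.
#' @param detail if `TRUE`, also return the per-transcript calls.
#' @return data frame `chrom`, `pos`, `ref`, `alt`, `gene_name`, `class`,
#'   `aa_change`; with `detail = TRUE` a list with elements `summary` and
#'   `transcripts`.
#' @export
classify_variants <- function(snps, index, genome, flank = 5000,
                              detail = FALSE) {
  stopifnot(inherits(index, "gene_index"))
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  cache <- new.env(parent = emptyenv())
  cds_cache <- function(tx) {
    key <- tx$transcript_id
    if (is.null(cache[[key]])) cache[[key]] <- .spliced_cds(tx, genome)
    cache[[key]]
  }
  g <- index$genes
  n <- nrow(snps)
  out_class <- rep(NA_character_, n)
  out_gene <- rep(NA_character_, n)
  out_aa <- rep(NA_character_, n)
  details <- if (detail) vector("list", n) else NULL
  for (i in seq_len(n)) {
    chrom <- snps$chrom[i]
    pos <- snps$pos[i]
    if (!(chrom %in% g$chrom)) next
    sel <- which(g$chrom == chrom & pos >= g$start - flank &
                   pos <= g$end + flank)
    if (!length(sel)) {
      if (chrom %in% names(genome)) out_class[i] <- "intergenic"
      next
    }
    cls <- gene <- aa <- tid <- character(0)
    for (k in sel) {
      tx <- index$transcripts[[g$transcript_id[k]]]
      res <- .classify_tx(tx, pos, snps$ref[i], snps$alt[i], genome, flank,
                          cds_cache)
      if (is.null(res)) next
      cls <- c(cls, res$class)
      gene <- c(gene, tx$gene_name)
      aa <- c(aa, res$aa_change)
      tid <- c(tid, tx$transcript_id)
    }
    if (!length(cls)) {
      out_class[i] <- "intergenic"
      next
    }
    best <- which.min(match(cls, .severity))
    if (!length(best)) {
      out_class[i] <- NA_character_
      next
    }
    out_class[i] <- cls[best]
    out_gene[i] <- gene[best]
    out_aa[i] <- aa[best]
    if (detail) {
      details[[i]] <- data.frame(transcript_id = tid, gene_name = gene,
                                 class = cls, aa_change = aa,
                                 stringsAsFactors = FALSE)
    }
  }
  summary_df <- data.frame(chrom = snps$chrom, pos = snps$pos,
                           ref = snps$ref, alt = snps$alt,
                           gene_name = out_gene, class = out_class,
                           aa_change = out_aa, stringsAsFactors = FALSE)
  if (detail) list(summary = summary_df, transcripts = details)
  else summary_df
}

#' Annotate the candidates of a ranking scan
#'
#' Convenience wrapper: classifies the selected SNPs of a [cold_rank()]
#' object (or all its SNPs) and merges gene name, consequence class and
#' amino-acid change into the ranked table.
#'
#' @param ranking a [cold_rank()] object.
#' @param index a [read_gene_models()] gene index.
#' @param genome a [Biostrings::DNAStringSet] or FASTA path.
#' @param flank flanking distance in bp.
#' @param only_selected annotate only SNPs below the rank-sum threshold.
#' @return the ranked SNP data frame with annotation columns appended.
#' @export
annotate_candidates <- function(ranking, index, genome, flank = 5000,
                                only_selected = TRUE) {
  stopifnot(inherits(ranking, "cold_rank"))
  snps <- if (only_selected) candidates(ranking) else ranking$snps
  ann <- classify_variants(snps[c("chrom", "pos", "ref", "alt")],
                           index, genome, flank = flank)
  cbind(snps, ann[c("gene_name", "class", "aa_change")])
}
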