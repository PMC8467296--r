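# Independent per-position consequence oracle for the toy annotated genome.
# Shares the package's conventions (documented splice-region definition,
# severity order) but none of its code: it paints classes from the generated
# gene structures using translation-order position vectors.

.oracle_severity <- c("stop_gained", "stop_lost", "missense", "splice_region",
                      "synonymous", "5_prime_UTR", "3_prime_UTR", "intron",
                      "upstream", "downstream", "intergenic")

.oracle_pick <- function(classes) {
  classes <- classes[!is.na(classes)]
  if (!length(classes)) return(NA_character_)
  .oracle_severity[min(match(classes, .oracle_severity))]
}

.comp <- c(A = "T", C = "G", G = "C", T = "A")

# next base in a fixed cycle; used as the deterministic alt allele
cyclic_alt <- function(ref) {
  c(A = "C", C = "G", G = "T", T = "A")[ref]
}

# genomic CDS positions of a transcript in translation (5'->3') order
translation_order <- function(gene) {
  pos <- unlist(lapply(seq_len(nrow(gene$cds)),
                       function(k) seq(gene$cds[k, 1], gene$cds[k, 2])))
  if (gene$strand == "-") rev(pos) else pos
}

# precompute the static per-gene structures the oracle needs
oracle_prep <- function(gene) {
  ex <- gene$exons
  n_ex <- nrow(ex)
  exonic_splice <- intronic_splice <- integer(0)
  for (k in seq_len(n_ex)) {
    if (k < n_ex) {  # junction at the right end of exon k
      exonic_splice <- c(exonic_splice, (ex[k, 2] - 2):ex[k, 2])
      intronic_splice <- c(intronic_splice, (ex[k, 2] + 1):(ex[k, 2] + 8))
    }
    if (k > 1) {     # junction at the left end of exon k
      exonic_splice <- c(exonic_splice, ex[k, 1]:(ex[k, 1] + 2))
      intronic_splice <- c(intronic_splice, (ex[k, 1] - 8):(ex[k, 1] - 1))
    }
  }
  gene$exonic_splice <- exonic_splice
  gene$intronic_splice <- intronic_splice
  gene$tord <- translation_order(gene)
  gene
}

oracle_gene_class <- function(gene, pos, genome_chars, flank = 5000) {
  if (pos < gene$start - flank || pos > gene$end + flank) return(NA_character_)
  if (pos < gene$start || pos > gene$end) {
    before <- pos < gene$start
    if (gene$strand == "+") return(if (before) "upstream" else "downstream")
    return(if (before) "downstream" else "upstream")
  }
  ex <- gene$exons
  exonic_splice <- gene$exonic_splice
  intronic_splice <- gene$intronic_splice
  in_exon <- any(pos >= ex[, 1] & pos <= ex[, 2])
  if (!in_exon) {
    return(if (pos %in% intronic_splice) "splice_region" else "intron")
  }
  tord <- gene$tord
  idx <- match(pos, tord)
  if (!is.na(idx)) {  # coding
    ci <- (idx - 1) %/% 3 + 1
    codon_pos <- tord[(3 * (ci - 1) + 1):(3 * ci)]
    bases <- genome_chars[codon_pos]
    if (gene$strand == "-") bases <- .comp[bases]
    codon <- paste(bases, collapse = "")
    ref <- genome_chars[pos]
    alt <- cyclic_alt(ref)
    sense_alt <- if (gene$strand == "-") .comp[alt] else alt
    off <- match(pos, codon_pos)
    alt_bases <- bases
    alt_bases[off] <- sense_alt
    code <- Biostrings::GENETIC_CODE
    aa_ref <- unname(code[codon])
    aa_alt <- unname(code[paste(alt_bases, collapse = "")])
    coding_cls <- if (aa_ref == aa_alt) "synonymous"
      else if (aa_alt == "*") "stop_gained"
      else if (aa_ref == "*") "stop_lost"
      else "missense"
    if (pos %in% exonic_splice) {
      return(.oracle_pick(c(coding_cls, "splice_region")))
    }
    return(coding_cls)
  }
  # untranslated exonic sequence
  if (pos %in% exonic_splice) return("splice_region")
  cd <- gene$cds
  five <- if (gene$strand == "+") pos < min(cd[, 1]) else pos > max(cd[, 2])
  if (five) "5_prime_UTR" else "3_prime_UTR"
}

oracle_truth_map <- function(genes, genome_chars, flank = 5000) {
  prepped <- lapply(genes, oracle_prep)
  vapply(seq_along(genome_chars), function(pos) {
    calls <- vapply(prepped, oracle_gene_class, character(1),
                    pos = pos, genome_chars = genome_chars, flank = flank)
    cls <- .oracle_pick(calls)
    if (is.na(cls)) "intergenic" else cls
  }, character(1))
}
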