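.bases <- c("A", "C", "G", "T")

.sense_codons <- function() {
  all64 <- as.vector(outer(outer(.bases, .bases, paste0), .bases, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

.rand_seq <- function(n) paste(sample(.bases, n, replace = TRUE),
                               collapse = "")

# one gene in sense (5'->3') coordinates: exon/CDS intervals + sequence
.build_sense_gene <- function(aa_len, n_exons, utr5, utr3, intron_lens) {
  cds_len <- 3 * (aa_len + 1)  # incl. terminal stop codon
  chunk <- rep(cds_len %/% n_exons, n_exons)
  chunk[n_exons] <- chunk[n_exons] + cds_len %% n_exons
  codons <- c("ATG", sample(.sense_codons(), aa_len - 1, replace = TRUE),
              sample(c("TAA", "TAG", "TGA"), 1))
  cds_seq <- paste(codons, collapse = "")
  introns <- vapply(intron_lens, function(l) {
    s <- .rand_seq(l)
    paste0("GT", substr(s, 3, l - 2), "AG")
  }, character(1))
  pieces <- character(0)
  exons <- matrix(0L, nrow = n_exons, ncol = 2)
  cds <- matrix(0L, nrow = n_exons, ncol = 2)
  cur <- 0L
  off <- 0L  # consumed cds
  for (k in seq_len(n_exons)) {
    ex_start <- cur + 1L
    if (k == 1L) {
      pieces <- c(pieces, .rand_seq(utr5))
      cur <- cur + utr5
    }
    cds[k, ] <- c(cur + 1L, cur + chunk[k])
    pieces <- c(pieces, substr(cds_seq, off + 1L, off + chunk[k]))
    cur <- cur + chunk[k]
    off <- off + chunk[k]
    if (k == n_exons) {
      pieces <- c(pieces, .rand_seq(utr3))
      cur <- cur + utr3
    }
    exons[k, ] <- c(ex_start, cur)
    if (k < n_exons) {
      pieces <- c(pieces, introns[k])
      cur <- cur + intron_lens[k]
    }
  }
  list(length = cur, seq = paste(pieces, collapse = ""),
       exons = exons, cds = cds, chunk = chunk, protein_len = aa_len)
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate a toy annotated genome (GTF + FASTA)
#'
#' Places `n_genes` multi-exon protein-coding genes (alternating strand) on
#' one contig, with valid CDS (ATG start, in-frame sense codons, terminal
#' stop), untranslated exon ends, GT..AG introns and intergenic gaps. The
#' FASTA sequence is consistent with the CDS annotations by construction:
#' translating a gene's spliced CDS yields a protein with no internal stop.
#' CDS features include the terminal stop codon.
#'
#' @param config a [sim_config()] (fields `gene_contig`,
#'   `gene_contig_length`, `n_genes`).
#' @param seed RNG seed.
#' @return list with elements `gtf` (feature data frame), `genome`
#'   (a [Biostrings::DNAStringSet]) and `genes` (per-gene structures in
#'   genome coordinates, used by tests).
#' @export
simulate_gene_models <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    n <- config$n_genes
    built <- lapply(seq_len(n), function(i) {
      n_exons <- sample(3:4, 1)
      .build_sense_gene(
        aa_len = sample(120:200, 1),
        n_exons = n_exons,
        utr5 = sample(80:150, 1),
        utr3 = sample(120:250, 1),
        intron_lens = sample(150:400, n_exons - 1, replace = TRUE)
      )
    })
    lens <- vapply(built, `[[`, numeric(1), "length")
    margin <- (config$gene_contig_length - sum(lens)) / (n + 1)
    if (margin < 1) {
      stop("invalid config: gene_contig_length too small to place ",
           n, " genes", call. = FALSE)
    }
    starts <- round(cumsum(rep(margin, n)) + cumsum(c(0, lens[-n])))
    genome_chars <- sample(.bases, config$gene_contig_length, replace = TRUE)
    gtf <- list()
    genes <- list()
    for (i in seq_len(n)) {
      g <- built[[i]]
      strand <- if (i %% 2 == 1) "+" else "-"
      s <- starts[i]
      seq_fwd <- if (strand == "+") g$seq else .revcomp(g$seq)
      genome_chars[s:(s + g$length - 1)] <- strsplit(seq_fwd, "")[[1]]
      map <- function(iv) {  # sense interval -> genome interval
        if (strand == "+") cbind(s + iv[, 1] - 1L, s + iv[, 2] - 1L)
        else cbind(s + g$length - iv[, 2], s + g$length - iv[, 1])
      }
      ex <- map(g$exons)
      cd <- map(g$cds)
      o <- order(ex[, 1])
      ex <- ex[o, , drop = FALSE]
      cd_o <- cd[order(cd[, 1]), , drop = FALSE]
      cum <- cumsum(c(0, g$chunk))
      frame <- (3 - cum[-length(cum)] %% 3) %% 3  # translation order
      frame_genomic <- if (strand == "+") frame else rev(frame)
      gid <- sprintf("SYNG%04d", i)
      tid <- sprintf("SYNT%04d", i)
      gname <- sprintf("TG%d", i)
      row <- function(feature, st, en, fr) {
        data.frame(chrom = config$gene_contig, source = "coldrank_sim",
                   feature = feature, start = st, end = en, score = ".",
                   strand = strand, frame = fr, gene_id = gid,
                   transcript_id = tid, gene_name = gname,
                   stringsAsFactors = FALSE)
      }
      gtf[[length(gtf) + 1L]] <- rbind(
        row("gene", s, s + g$length - 1L, "."),
        row("transcript", s, s + g$length - 1L, "."),
        row("exon", ex[, 1], ex[, 2], "."),
        row("CDS", cd_o[, 1], cd_o[, 2], as.character(frame_genomic))
      )
      genes[[gname]] <- list(gene_id = gid, transcript_id = tid,
                             gene_name = gname, strand = strand,
                             start = s, end = s + g$length - 1L,
                             exons = ex, cds = cd_o,
                             protein_len = g$protein_len)
    }
    genome <- Biostrings::DNAStringSet(
      structure(paste(genome_chars, collapse = ""),
                names = config$gene_contig))
    list(gtf = do.call(rbind, gtf), genome = genome, genes = genes)
  })
}

#' Write a GTF feature table (Ensembl attribute dialect)
#'
#' @param gtf feature data frame from [simulate_gene_models()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(gtf, path) {
  attrs <- sprintf(
    'gene_id "%s"; transcript_id "%s"; gene_name "%s"; gene_biotype "protein_coding";',
    gtf$gene_id, gtf$transcript_id, gtf$gene_name)
  attrs[gtf$feature == "gene"] <- sprintf(
    'gene_id "%s"; gene_name "%s"; gene_biotype "protein_coding";',
    gtf$gene_id[gtf$feature == "gene"], gtf$gene_name[gtf$feature == "gene"])
  lines <- paste(gtf$chrom, gtf$source, gtf$feature, gtf$start, gtf$end,
                 gtf$score, gtf$strand, gtf$frame, attrs, sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
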