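SENSE_CODONS <- setdiff(
  apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                    c("T", "C", "A", "G")), 1, paste0, collapse = ""),
  c("TAA", "TAG", "TGA"))
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Construct a transcript model
#'
#' Coordinates are 0-based half-open on the forward genome strand; exon and
#' CDS intervals are sorted and non-overlapping. A CDS whose total length is
#' not divisible by 3 is flagged incomplete and only receives non-coding
#' consequence calls.
#'
#' @param transcript_id,gene_id identifiers
#' @param chrom chromosome name
#' @param strand "+" or "-"
#' @param exons,cds two-column integer matrices (start0, end0)
#' @return object of class `transcript_model`
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons, cds) {
  stopifnot(strand %in% c("+", "-"), is.matrix(exons))
  dimnames(exons) <- NULL
  dimnames(cds) <- NULL
  storage.mode(exons) <- "integer"
  if (length(cds)) storage.mode(cds) <- "integer"
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(cds)) cds <- cds[order(cds[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1])) stop_fmt("empty exon in %s", transcript_id)
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop_fmt("overlapping exons in %s", transcript_id)
  cds_len <- if (nrow(cds)) sum(cds[, 2] - cds[, 1]) else 0L
  structure(list(
    transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
    strand = strand, exons = exons, cds = cds,
    incomplete = nrow(cds) > 0 && cds_len %% 3L != 0L
  ), class = "transcript_model")
}

tx_span <- function(t) c(min(t$exons[, 1]), max(t$exons[, 2]))

# introns (0-based half-open), in forward-genome order
tx_introns <- function(t) {
  e <- t$exons
  if (nrow(e) < 2) return(matrix(integer(0), 0, 2))
  cbind(e[-nrow(e), 2], e[-1, 1])
}

#' Simulate a genome with consistent multi-exon gene models
#'
#' Emits random-sequence chromosomes carrying non-overlapping protein-coding
#' genes on both strands. Every CDS starts ATG, ends at a stop codon, has
#' length divisible by 3 and no internal stop; every intron begins GT and
#' ends AG on the coding strand; transcripts carry 5' and 3' UTRs.
#'
#' @param n_genes number of genes
#' @param seed integer seed
#' @param n_chrom chromosomes to spread genes over
#' @return list with `genome` (a [Biostrings::DNAStringSet]) and `models`
#'   (list of [transcript_model()])
#' @export
simulate_gene_models <- function(n_genes = 10, seed = 1, n_chrom = 1) {
  set.seed(seed)
  chroms <- paste0("chr", seq_len(n_chrom))
  chrom_seq <- setNames(rep("", n_chrom), chroms)
  models <- vector("list", n_genes)
  gene_chrom <- sort(rep_len(chroms, n_genes))
  for (i in seq_len(n_genes)) {
    L <- sample(50:150, 1)                      # protein length (aa)
    codons <- c("ATG", sample(SENSE_CODONS, L - 1, replace = TRUE),
                sample(STOP_CODONS, 1))
    cds_seq <- paste(codons, collapse = "")
    utr5 <- random_dna(sample(30:120, 1))
    utr3 <- random_dna(sample(50:200, 1))
    tx_seq <- paste0(utr5, cds_seq, utr3)
    tx_len <- nchar(tx_seq)
    n_ex <- sample(2:4, 1)
    # exon lengths >= 25 bp, random composition of the transcript
    repeat {
      cuts <- sort(sample(seq(25, tx_len - 25), n_ex - 1))
      lens <- diff(c(0, cuts, tx_len))
      if (all(lens >= 25)) break
    }
    ex_tx_start <- cumsum(c(0, lens[-n_ex]))    # transcript coords
    intron_seqs <- vapply(seq_len(n_ex - 1), function(k) {
      paste0("GT", random_dna(sample(76:296, 1)), "AG")
    }, character(1))
    # gene-local genomic coords on the coding strand
    gstart <- integer(n_ex); off <- 0L
    pieces <- character(0)
    for (k in seq_len(n_ex)) {
      gstart[k] <- off
      pieces <- c(pieces, substr(tx_seq, ex_tx_start[k] + 1,
                                 ex_tx_start[k] + lens[k]))
      off <- off + lens[k]
      if (k < n_ex) {
        pieces <- c(pieces, intron_seqs[k])
        off <- off + nchar(intron_seqs[k])
      }
    }
    gene_seq <- paste(pieces, collapse = "")
    glen <- nchar(gene_seq)
    strand <- sample(c("+", "-"), 1)
    # map transcript interval [a, b) -> gene-local coding-strand intervals
    map_iv <- function(a, b) {
      out <- NULL
      for (k in seq_len(n_ex)) {
        s <- max(a, ex_tx_start[k]); e <- min(b, ex_tx_start[k] + lens[k])
        if (s < e) out <- rbind(out, gstart[k] + c(s, e) - ex_tx_start[k])
      }
      out
    }
    exons_g <- cbind(gstart, gstart + lens)
    cds_g <- map_iv(nchar(utr5), nchar(utr5) + nchar(cds_seq))
    ch <- gene_chrom[i]
    placed_seq <- if (strand == "+") gene_seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(gene_seq)))
    offset <- nchar(chrom_seq[ch]) + sample(300:800, 1)
    chrom_seq[ch] <- paste0(chrom_seq[ch],
                            random_dna(offset - nchar(chrom_seq[ch])), placed_seq)
    flip <- function(iv) {
      out <- cbind(glen - iv[, 2], glen - iv[, 1])
      out[order(out[, 1]), , drop = FALSE]
    }
    if (strand == "-") { exons_g <- flip(exons_g); cds_g <- flip(cds_g) }
    models[[i]] <- transcript_model(
      transcript_id = sprintf("tx%03d", i), gene_id = sprintf("gene%03d", i),
      chrom = ch, strand = strand,
      exons = exons_g + offset, cds = cds_g + offset)
  }
  # trailing intergenic tail so planted intergenic variants have room
  for (ch in chroms) chrom_seq[ch] <- paste0(chrom_seq[ch], random_dna(500))
  genome <- Biostrings::DNAStringSet(chrom_seq)
  names(genome) <- chroms
  list(genome = genome, models = models)
}

# extract spliced CDS on the coding strand
cds_sequence <- function(t, genome) {
  parts <- vapply(seq_len(nrow(t$cds)), function(k) {
    as.character(Biostrings::subseq(genome[[t$chrom]],
                                    t$cds[k, 1] + 1L, t$cds[k, 2]))
  }, character(1))
  s <- paste(parts, collapse = "")
  if (t$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}
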