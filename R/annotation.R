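#' Consequence classes and their severity ranks
#'
#' Severity resolves multi-transcript calls: a variant hitting several
#' transcripts is reported with its most severe consequence. Splice donor
#' and acceptor share a rank; both outrank plain intronic.
#'
#' @return named integer vector, higher = more severe
#' @export
consequence_severity <- function() {
  c(stop_gain = 120L, stop_loss = 110L, frameshift = 100L,
    splice_donor = 90L, splice_acceptor = 90L, missense = 80L,
    inframe_indel = 70L, synonymous = 60L, noncoding_transcript = 45L,
    utr5 = 40L, utr3 = 40L, intronic = 30L, intergenic = 20L)
}

check_ref <- function(chrom, pos, ref, genome) {
  obs <- as.character(Biostrings::subseq(genome[[chrom]], pos, pos + nchar(ref) - 1L))
  if (!identical(obs, ref))
    stop_fmt("REF mismatch at %s:%d: VCF says %s, genome has %s",
             chrom, pos, ref, obs)
}

splice_windows <- function(t) {
  iv <- tx_introns(t)
  if (!nrow(iv)) return(NULL)
  if (t$strand == "+") {
    list(donor = cbind(iv[, 1], iv[, 1] + 2L),
         acceptor = cbind(iv[, 2] - 2L, iv[, 2]))
  } else {
    list(donor = cbind(iv[, 2] - 2L, iv[, 2]),
         acceptor = cbind(iv[, 1], iv[, 1] + 2L))
  }
}

in_any <- function(pos0, iv) {
  !is.null(iv) && nrow(iv) > 0 && any(pos0 >= iv[, 1] & pos0 < iv[, 2])
}

overlaps_any <- function(a, b, iv) {
  !is.null(iv) && nrow(iv) > 0 && any(pmax(a, iv[, 1]) < pmin(b, iv[, 2]))
}

utr_side <- function(pos0, t) {
  if (!nrow(t$cds)) return("noncoding_transcript")
  cds_lo <- min(t$cds[, 1]); cds_hi <- max(t$cds[, 2])
  if (pos0 < cds_lo) { if (t$strand == "+") "utr5" else "utr3" }
  else if (pos0 >= cds_hi) { if (t$strand == "+") "utr3" else "utr5" }
  else "noncoding_transcript"   # inside an incomplete CDS span
}

complement_base <- function(b)
  c(A = "T", C = "G", G = "C", T = "A")[[b]]

#' Classify a single-nucleotide variant against one transcript
#'
#' Codon-level consequences are computed on the coding strand (the CDS is
#' reverse-complemented for minus-strand transcripts). A SNV at either of
#' the two intronic bases adjacent to an exon boundary is a splice call
#' (donor at the intron's 5' end, acceptor at its 3' end, in coding-strand
#' orientation); splice outranks intronic. Transcripts whose CDS length is
#' not a multiple of 3 only receive non-coding classes.
#'
#' @param v list/row with `chrom`, `pos` (1-based), `ref`, `alt` (single bases)
#' @param t a [transcript_model()]
#' @param genome a [Biostrings::DNAStringSet]
#' @return consequence class (character scalar)
#' @export
classify_snv <- function(v, t, genome) {
  stopifnot(nchar(v$ref) == 1L, nchar(v$alt) == 1L)
  check_ref(v$chrom, v$pos, v$ref, genome)
  if (!identical(v$chrom, t$chrom)) return("intergenic")
  pos0 <- from_vcf_pos(v$pos)
  span <- tx_span(t)
  if (pos0 < span[1] || pos0 >= span[2]) return("intergenic")
  if (!in_any(pos0, t$exons)) {
    sw <- splice_windows(t)
    if (in_any(pos0, sw$donor)) return("splice_donor")
    if (in_any(pos0, sw$acceptor)) return("splice_acceptor")
    return("intronic")
  }
  in_cds <- in_any(pos0, t$cds)
  if (!in_cds || t$incomplete || !nrow(t$cds)) {
    if (in_cds) return("noncoding_transcript")
    return(utr_side(pos0, t))
  }
  # coding offset on the coding strand
  starts <- t$cds[, 1]; ends <- t$cds[, 2]
  fwd_off <- 0L
  for (k in seq_along(starts)) {
    if (pos0 >= starts[k] && pos0 < ends[k]) {
      fwd_off <- fwd_off + (pos0 - starts[k]); break
    }
    fwd_off <- fwd_off + (ends[k] - starts[k])
  }
  cds_len <- sum(ends - starts)
  coff <- if (t$strand == "+") fwd_off else cds_len - 1L - fwd_off
  cds_seq <- cds_sequence(t, genome)
  codon_i <- coff %/% 3L
  within <- coff %% 3L
  ref_codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  alt_coding <- if (t$strand == "+") v$alt else complement_base(v$alt)
  alt_codon <- ref_codon
  substr(alt_codon, within + 1L, within + 1L) <- alt_coding
  ref_aa <- Biostrings::GENETIC_CODE[[ref_codon]]
  alt_aa <- Biostrings::GENETIC_CODE[[alt_codon]]
  if (ref_aa != "*" && alt_aa == "*") return("stop_gain")
  if (ref_aa == "*" && alt_aa != "*") return("stop_loss")
  if (ref_aa == alt_aa) return("synonymous")
  "missense"
}

#' Left-normalize an anchored indel against the genome
#'
#' Applies the usual VCF parsimony rules: shared suffix bases are trimmed
#' (shifting the window left through repeat context), then shared prefix
#' bases beyond the single anchor base are dropped.
#'
#' @inheritParams classify_snv
#' @return the variant with possibly updated `pos`, `ref`, `alt`
#' @export
normalize_variant <- function(v, genome) {
  ref <- v$ref; alt <- v$alt; pos <- v$pos
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    if (lr > 0 && la > 0 &&
        substr(ref, lr, lr) == substr(alt, la, la)) {
      if (lr == 1L || la == 1L) {
        if (pos == 1L) break
        b <- as.character(Biostrings::subseq(genome[[v$chrom]], pos - 1L, pos - 1L))
        ref <- paste0(b, substr(ref, 1L, lr - 1L))
        alt <- paste0(b, substr(alt, 1L, la - 1L))
        pos <- pos - 1L
      } else {
        ref <- substr(ref, 1L, lr - 1L)
        alt <- substr(alt, 1L, la - 1L)
      }
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  v$ref <- ref; v$alt <- alt; v$pos <- pos
  v
}

#' Classify an insertion or deletion against one transcript
#'
#' The indel is left-normalized, then every transcript feature it touches is
#' given a candidate class (CDS overlap yields frameshift when the length
#' change is not a multiple of 3, in-frame otherwise) and the most severe
#' candidate is returned.
#'
#' @inheritParams classify_snv
#' @return consequence class (character scalar)
#' @export
classify_indel <- function(v, t, genome) {
  check_ref(v$chrom, v$pos, v$ref, genome)
  v <- normalize_variant(v, genome)
  if (!identical(v$chrom, t$chrom)) return("intergenic")
  lr <- nchar(v$ref); la <- nchar(v$alt)
  pos0 <- from_vcf_pos(v$pos)
  if (lr > la) { a <- pos0 + la; b <- pos0 + lr }           # deleted bases
  else { a <- pos0 + lr; b <- a }                           # insertion point
  span <- tx_span(t)
  if ((b > a && (b <= span[1] || a >= span[2])) ||
      (b == a && (a <= span[1] || a >= span[2]))) return("intergenic")
  sev <- consequence_severity()
  cand <- character(0)
  hit <- function(iv) if (b > a) overlaps_any(a, b, iv) else
    (!is.null(iv) && nrow(iv) > 0 && any(a > iv[, 1] & a < iv[, 2]))
  if (hit(t$cds)) {
    cand <- c(cand, if (t$incomplete) "noncoding_transcript"
              else if (abs(lr - la) %% 3L != 0L) "frameshift" else "inframe_indel")
  }
  sw <- splice_windows(t)
  if (hit(sw$donor)) cand <- c(cand, "splice_donor")
  if (hit(sw$acceptor)) cand <- c(cand, "splice_acceptor")
  introns <- tx_introns(t)
  if (hit(introns)) cand <- c(cand, "intronic")
  if (hit(t$exons)) {
    probe <- if (b > a) a else a - 1L
    if (!in_any(probe, t$cds) || !nrow(t$cds))
      cand <- c(cand, utr_side(probe, t))
  }
  if (!length(cand)) return("intronic")
  cand[which.max(sev[cand])]
}

classify_variant <- function(v, t, genome) {
  if (nchar(v$ref) == 1L && nchar(v$alt) == 1L) classify_snv(v, t, genome)
  else classify_indel(v, t, genome)
}

#' Annotate a variant table against a set of transcript models
#'
#' Each variant is classified against every transcript whose span it
#' overlaps and reported once with the most severe consequence; variants
#' overlapping no transcript are intergenic. Output order is deterministic
#' (chromosome, position, ref, alt).
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` and
#'   optionally `variant_id`
#' @param models list of [transcript_model()]
#' @param genome a [Biostrings::DNAStringSet]
#' @return list with `table` (one row per variant: ids, coordinates, class,
#'   gene and transcript of the most severe call) and `counts` (named vector
#'   over all consequence classes)
#' @export
annotate_vcf <- function(variants, models, genome) {
  sev <- consequence_severity()
  classes <- names(sev)
  if (is.null(variants$variant_id))
    variants$variant_id <- sprintf("var%05d", seq_len(nrow(variants)))
  if (nrow(variants) == 0) {
    tab <- data.frame(variant_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      class = character(0), gene_id = character(0),
                      transcript_id = character(0), stringsAsFactors = FALSE)
    return(list(table = tab, counts = setNames(integer(length(classes)), classes)))
  }
  spans <- data.frame(
    chrom = vapply(models, `[[`, "", "chrom"),
    start = vapply(models, function(t) tx_span(t)[1], 0),
    end = vapply(models, function(t) tx_span(t)[2], 0))
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- as.list(variants[i, , drop = FALSE])
    pos0 <- from_vcf_pos(v$pos)
    cand <- which(spans$chrom == v$chrom & spans$start <= pos0 + nchar(v$ref) &
                    spans$end > pos0)
    cls <- "intergenic"; gene <- NA_character_; tx <- NA_character_
    for (j in cand) {
      cj <- classify_variant(v, models[[j]], genome)
      if (sev[[cj]] > sev[[cls]]) {
        cls <- cj; gene <- models[[j]]$gene_id; tx <- models[[j]]$transcript_id
      }
    }
    data.frame(variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
               ref = v$ref, alt = v$alt, class = cls, gene_id = gene,
               transcript_id = tx, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$chrom, tab$pos, tab$ref, tab$alt), , drop = FALSE]
  rownames(tab) <- NULL
  counts <- setNames(integer(length(classes)), classes)
  tt <- table(tab$class)
  counts[names(tt)] <- as.integer(tt)
  list(table = tab, counts = counts)
}

#' Platform-specific overall false-positive rate
#'
#' Given the total calls of one platform, the calls shared with a second
#' platform (assumed valid), and the false-positive rate measured on
#' resequenced platform-specific calls, returns the platform-wide rate:
#' `(total - shared) * specific_fpr / total`.
#'
#' @param total_calls total variant calls on the platform
#' @param shared_calls calls also detected by the other platform
#' @param specific_fpr false-positive proportion among platform-specific calls
#' @return overall false-positive proportion
#' @export
platform_fpr <- function(total_calls, shared_calls, specific_fpr) {
  if (total_calls == 0) stop_fmt("total_calls must be positive")
  if (shared_calls > total_calls) stop_fmt("shared_calls exceeds total_calls")
  if (specific_fpr < 0 || specific_fpr > 1) stop_fmt("specific_fpr outside [0, 1]")
  (total_calls - shared_calls) * specific_fpr / total_calls
}
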