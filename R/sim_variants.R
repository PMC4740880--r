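# genomic 0-based positions of the CDS, in coding-strand order
cds_positions <- function(t) {
  p <- unlist(lapply(seq_len(nrow(t$cds)),
                     function(k) seq.int(t$cds[k, 1], t$cds[k, 2] - 1L)))
  if (t$strand == "-") rev(p) else p
}

genome_base <- function(genome, chrom, pos0)
  as.character(Biostrings::subseq(genome[[chrom]], pos0 + 1L, pos0 + 1L))

#' Plant a catalog of variants with known consequence labels
#'
#' Constructs variants of each requested consequence class directly from the
#' gene models (the truth labels come from the construction, never from the
#' classifier, so they can serve as an annotation oracle). Indels are built
#' so that left-normalization is a no-op, keeping the planted coordinates
#' authoritative. SNVs and indels never collide within 5 bp of each other.
#'
#' @param models list of [transcript_model()]
#' @param genome a [Biostrings::DNAStringSet]
#' @param n_per_class named integer vector over classes among synonymous,
#'   missense, stop_gain, stop_loss, splice_donor, splice_acceptor,
#'   frameshift, inframe_indel, intronic, intergenic, utr5, utr3
#' @param seed integer seed
#' @return list with `variants` (chrom, pos, ref, alt, variant_id) and
#'   `truth` (variant_id, class, transcript_id)
#' @export
simulate_variant_catalog <- function(models, genome, n_per_class, seed = 1) {
  set.seed(seed)
  used <- list()  # per-chrom occupied positions (1 bp padding)
  occupied <- function(chrom, a, b) {
    u <- used[[chrom]]
    !is.null(u) && any(u >= a - 1L & u <= b + 1L)
  }
  occupy <- function(chrom, a, b) used[[chrom]] <<- c(used[[chrom]], a:b)

  out <- list()
  add <- function(chrom, pos0, ref, alt, class, tx) {
    out[[length(out) + 1L]] <<- data.frame(
      chrom = chrom, pos = to_vcf_pos(pos0), ref = ref, alt = alt,
      class = class, transcript_id = tx, stringsAsFactors = FALSE)
    occupy(chrom, pos0, pos0 + nchar(ref) - 1L)
  }

  plant_codon_snv <- function(target, n) {
    made <- 0L; tries <- 0L
    while (made < n && tries < n * 500L) {
      tries <- tries + 1L
      t <- models[[sample.int(length(models), 1)]]
      if (t$incomplete || !nrow(t$cds)) next
      cds_seq <- cds_sequence(t, genome)
      n_codon <- nchar(cds_seq) %/% 3L
      ci <- if (target == "stop_loss") n_codon - 1L
            else sample(seq.int(1L, n_codon - 2L), 1)   # skip start & stop
      ref_codon <- substr(cds_seq, ci * 3L + 1L, ci * 3L + 3L)
      hits <- NULL
      for (w in 0:2) for (b in c("A", "C", "G", "T")) {
        if (b == substr(ref_codon, w + 1L, w + 1L)) next
        alt_codon <- ref_codon
        substr(alt_codon, w + 1L, w + 1L) <- b
        ra <- Biostrings::GENETIC_CODE[[ref_codon]]
        aa <- Biostrings::GENETIC_CODE[[alt_codon]]
        cls <- if (ra != "*" && aa == "*") "stop_gain"
               else if (ra == "*" && aa != "*") "stop_loss"
               else if (ra == aa) "synonymous" else "missense"
        if (cls == target) hits <- rbind(hits, c(w, b))
      }
      if (is.null(hits)) next
      pick <- hits[sample.int(nrow(hits), 1), ]
      coff <- ci * 3L + as.integer(pick[1])
      pos0 <- cds_positions(t)[coff + 1L]
      if (occupied(t$chrom, pos0, pos0)) next
      ref <- genome_base(genome, t$chrom, pos0)
      alt <- if (t$strand == "+") pick[2] else complement_base(pick[2])
      add(t$chrom, pos0, ref, alt, target, t$transcript_id)
      made <- made + 1L
    }
    if (made < n) stop_fmt("could not plant %d %s variants", n, target)
  }

  plant_splice <- function(target, n) {
    made <- 0L; tries <- 0L
    while (made < n && tries < n * 500L) {
      tries <- tries + 1L
      t <- models[[sample.int(length(models), 1)]]
      iv <- tx_introns(t)
      if (!nrow(iv)) next
      k <- sample.int(nrow(iv), 1)
      donor_end <- t$strand == "+"
      at_start <- (target == "splice_donor") == donor_end
      pos0 <- if (at_start) iv[k, 1] + sample(0:1, 1) else iv[k, 2] - 1L - sample(0:1, 1)
      if (occupied(t$chrom, pos0, pos0)) next
      ref <- genome_base(genome, t$chrom, pos0)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      add(t$chrom, pos0, ref, alt, target, t$transcript_id)
      made <- made + 1L
    }
    if (made < n) stop_fmt("could not plant %d %s variants", n, target)
  }

  plant_cds_indel <- function(target, n) {
    lens <- if (target == "frameshift") c(1L, 2L, 4L) else 3L
    made <- 0L; tries <- 0L
    while (made < n && tries < n * 500L) {
      tries <- tries + 1L
      t <- models[[sample.int(length(models), 1)]]
      if (t$incomplete || !nrow(t$cds)) next
      len <- if (length(lens) > 1) sample(lens, 1) else lens
      insertion <- runif(1) < 0.5
      widths <- t$cds[, 2] - t$cds[, 1]
      ok <- which(widths >= len + 10L)
      if (!length(ok)) next
      k <- if (length(ok) > 1) sample(ok, 1) else ok
      lo <- t$cds[k, 1] + 3L
      hi <- t$cds[k, 2] - len - 4L
      if (hi < lo) next
      pos0 <- sample(seq.int(lo, hi), 1)
      anchor <- genome_base(genome, t$chrom, pos0)
      if (insertion) {
        seg <- c(sample(c("A", "C", "G", "T"), len, replace = TRUE))
        seg[len] <- sample(setdiff(c("A", "C", "G", "T"), anchor), 1)
        ref <- anchor; alt <- paste0(anchor, paste(seg, collapse = ""))
        span_hi <- pos0
      } else {
        seg <- as.character(Biostrings::subseq(genome[[t$chrom]],
                                               pos0 + 2L, pos0 + 1L + len))
        if (substr(seg, len, len) == anchor) next  # keep left-normal form
        ref <- paste0(anchor, seg); alt <- anchor
        span_hi <- pos0 + len
      }
      if (occupied(t$chrom, pos0, span_hi)) next
      add(t$chrom, pos0, ref, alt, target, t$transcript_id)
      made <- made + 1L
    }
    if (made < n) stop_fmt("could not plant %d %s variants", n, target)
  }

  plant_positional_snv <- function(target, n) {
    made <- 0L; tries <- 0L
    while (made < n && tries < n * 500L) {
      tries <- tries + 1L
      if (target == "intergenic") {
        chrom <- sample(names(genome), 1)
        spans <- do.call(rbind, lapply(models, function(t)
          if (t$chrom == chrom) tx_span(t)))
        pos0 <- sample.int(length(genome[[chrom]]), 1) - 1L
        if (!is.null(spans) &&
            any(pos0 >= spans[, 1] - 20L & pos0 < spans[, 2] + 20L)) next
        tx <- NA_character_; chrom_ok <- chrom
      } else {
        t <- models[[sample.int(length(models), 1)]]
        if (target == "intronic") {
          iv <- tx_introns(t)
          iv <- iv[iv[, 2] - iv[, 1] >= 12L, , drop = FALSE]
          if (!nrow(iv)) next
          k <- sample.int(nrow(iv), 1)
          pos0 <- sample(seq.int(iv[k, 1] + 4L, iv[k, 2] - 5L), 1)
        } else {  # utr5 / utr3
          if (!nrow(t$cds)) next
          cds_lo <- min(t$cds[, 1]); cds_hi <- max(t$cds[, 2])
          want_low <- (target == "utr5") == (t$strand == "+")
          ex <- t$exons
          pool <- integer(0)
          for (k in seq_len(nrow(ex))) {
            lo <- ex[k, 1]; hi <- ex[k, 2]
            rng <- if (want_low) seq.int(lo, min(hi, cds_lo) - 1L)
                   else seq.int(max(lo, cds_hi), hi - 1L)
            if (length(rng) > 0 && rng[1] <= rng[length(rng)])
              pool <- c(pool, rng)
          }
          pool <- pool[pool >= 0]
          if (!length(pool)) next
          pos0 <- if (length(pool) > 1) sample(pool, 1) else pool
        }
        tx <- t$transcript_id; chrom_ok <- t$chrom
      }
      if (occupied(chrom_ok, pos0, pos0)) next
      ref <- genome_base(genome, chrom_ok, pos0)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      add(chrom_ok, pos0, ref, alt, target, tx)
      made <- made + 1L
    }
    if (made < n) stop_fmt("could not plant %d %s variants", n, target)
  }

  for (cls in names(n_per_class)) {
    n <- n_per_class[[cls]]
    if (n == 0) next
    switch(cls,
      synonymous = , missense = , stop_gain = , stop_loss =
        plant_codon_snv(cls, n),
      splice_donor = , splice_acceptor = plant_splice(cls, n),
      frameshift = , inframe_indel = plant_cds_indel(cls, n),
      intronic = , intergenic = , utr5 = , utr3 =
        plant_positional_snv(cls, n),
      stop_fmt("unknown variant class: %s", cls))
  }
  all <- do.call(rbind, out)
  all$variant_id <- sprintf("pv%05d", seq_len(nrow(all)))
  list(
    variants = all[, c("variant_id", "chrom", "pos", "ref", "alt")],
    truth = all[, c("variant_id", "class", "transcript_id")]
  )
}
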