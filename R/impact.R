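#' Bundle functional annotation tracks
#'
#' @param regulatory data.frame `chrom,start,end` (0-based half-open)
#'   regulatory elements (promoters, TF binding sites, ...)
#' @param conserved data.frame `chrom,start,end,score` conserved elements
#'   with per-element scores in `[0, 1]`
#' @param track data.frame `chrom,pos,score` per-base conservation values
#'   (0-based positions; the track may have gaps)
#' @return object of class `functional_annotations`
#' @export
functional_annotations <- function(regulatory, conserved, track) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regulatory)),
            all(c("chrom", "start", "end", "score") %in% names(conserved)),
            all(c("chrom", "pos", "score") %in% names(track)))
  if (nrow(conserved) && any(conserved$score < 0 | conserved$score > 1))
    stop_fmt("conserved-element scores must lie in [0, 1]")
  if (any(regulatory$end <= regulatory$start) ||
      (nrow(conserved) && any(conserved$end <= conserved$start)))
    stop_fmt("empty or inverted intervals in annotation")
  structure(list(regulatory = regulatory, conserved = conserved,
                 track = track, track_ecdf = stats::ecdf(track$score)),
            class = "functional_annotations")
}

#' Functional-element score of a position
#'
#' A position inside a known regulatory element scores 1; otherwise, inside
#' a conserved element, the element's own score; otherwise missing. When a
#' position lies in both, the regulatory element wins.
#'
#' @param chrom,pos0 chromosome and 0-based position
#' @param ann a [functional_annotations()]
#' @return score in `[0, 1]`, or `NA` when no element overlaps
#' @export
functional_element_score <- function(chrom, pos0, ann) {
  r <- ann$regulatory
  if (any(r$chrom == chrom & r$start <= pos0 & pos0 < r$end)) return(1)
  cv <- ann$conserved
  hit <- cv$chrom == chrom & cv$start <= pos0 & pos0 < cv$end
  if (any(hit)) return(max(cv$score[hit]))
  NA_real_
}

#' Mutation-effect score of a position
#'
#' The raw per-base conservation value is mapped to `[0, 1]` through the
#' empirical CDF of all values present in the track, so the most conserved
#' position scores 1 regardless of the track's native scale. Positions with
#' no track data are missing.
#'
#' @inheritParams functional_element_score
#' @return score in `(0, 1]`, or `NA` when the track has a gap here
#' @export
mutation_effect_score <- function(chrom, pos0, ann) {
  i <- which(ann$track$chrom == chrom & ann$track$pos == pos0)
  if (!length(i)) return(NA_real_)
  ann$track_ecdf(ann$track$score[i[1]])
}

#' Composite impact score of a noncoding SNP
#'
#' The impact score is the product of the functional-element score `F` and
#' the mutation-effect score `M`. If exactly one component is missing it is
#' replaced by a non-zero stand-in smaller than every observed value of that
#' component (half the observed positive minimum), so single-source evidence
#' is never discarded; if both are missing the score is 0.
#'
#' @param F,M component scores (may be `NA`)
#' @param observed_minima named list/vector with `F` and `M`: the minimum
#'   positive value of each component observed across the full scoring pass;
#'   required whenever a component is missing
#' @return impact score in `[0, 1]`
#' @export
impact_score <- function(F, M, observed_minima = NULL) {
  if (is.na(F) && is.na(M)) return(0)
  fill <- function(x, comp) {
    if (!is.na(x)) return(x)
    m <- observed_minima[[comp]]
    if (is.null(m) || is.na(m))
      stop_fmt("missing %s requires the observed positive minimum: score in two passes", comp)
    m / 2
  }
  fill(F, "F") * fill(M, "M")
}

#' Score a table of noncoding SNP positions (two-pass)
#'
#' First pass computes per-position `F` and `M`; the second pass fills
#' missing components with half the observed positive minimum and takes the
#' product.
#'
#' @param positions data.frame with `chrom` and `pos` (0-based)
#' @param ann a [functional_annotations()]
#' @return the input with columns `F`, `M`, `S` appended
#' @export
score_snps <- function(positions, ann) {
  Fv <- mapply(functional_element_score, positions$chrom, positions$pos,
               MoreArgs = list(ann = ann))
  Mv <- mapply(mutation_effect_score, positions$chrom, positions$pos,
               MoreArgs = list(ann = ann))
  mins <- list(
    F = if (any(!is.na(Fv) & Fv > 0)) min(Fv[!is.na(Fv) & Fv > 0]) else NA_real_,
    M = if (any(!is.na(Mv) & Mv > 0)) min(Mv[!is.na(Mv) & Mv > 0]) else NA_real_)
  S <- vapply(seq_along(Fv), function(i) impact_score(Fv[i], Mv[i], mins),
              numeric(1))
  positions$F <- Fv; positions$M <- Mv; positions$S <- S
  positions
}

#' Comparative-genomics deleteriousness call for one alignment column
#'
#' A substitution at a position invariant across mammals is likely
#' deleterious; if the position is additionally invariant across
#' non-mammalian taxa the call is strengthened. Positions variable among
#' mammals — in particular within rodents or primates — are unlikely to be
#' deleterious. Fewer than two mammalian taxa yields no call.
#'
#' @param residues character vector, one aligned residue per taxon
#' @param groups taxon group per residue: one of `rodent`, `primate`,
#'   `other_mammal`, `non_mammal`
#' @param variant_residue the residue introduced by the variant
#' @return one of `likely_deleterious`, `likely_deleterious_enhanced`,
#'   `unlikely_deleterious`, `no_call`
#' @export
comparative_call <- function(residues, groups, variant_residue) {
  stopifnot(length(residues) == length(groups))
  ok <- c("rodent", "primate", "other_mammal", "non_mammal")
  if (!all(groups %in% ok)) stop_fmt("unknown taxon group")
  mam <- residues[groups != "non_mammal"]
  if (length(mam) < 2) return("no_call")
  rp <- residues[groups %in% c("rodent", "primate")]
  if (length(unique(mam)) > 1 || length(unique(rp)) > 1)
    return("unlikely_deleterious")
  if (mam[1] == variant_residue) return("unlikely_deleterious")
  nonm <- residues[groups == "non_mammal"]
  if (length(nonm) > 0 && all(nonm == mam[1]))
    return("likely_deleterious_enhanced")
  "likely_deleterious"
}

#' Simulate regulatory, conserved-element and per-base conservation tracks
#'
#' Regulatory and conserved elements are placed uniformly with the requested
#' genome-wide density; the per-base conservation track carries a value at
#' each non-gap position (gaps exercise the missing-data rule of the impact
#' score).
#'
#' @param genome_length chromosome length in bp (single chromosome `chr1`)
#' @param element_density expected elements per kb (each element 50-300 bp)
#' @param gap_fraction fraction of positions absent from the per-base track
#' @param seed integer seed
#' @return a [functional_annotations()]
#' @export
simulate_conservation_tracks <- function(genome_length, element_density = 0.5,
                                         gap_fraction = 0.3, seed = 1) {
  set.seed(seed)
  n_el <- rpois(2, element_density * genome_length / 1000)
  mk <- function(n, score = FALSE) {
    if (n == 0) {
      d <- data.frame(chrom = character(0), start = integer(0), end = integer(0))
      if (score) d$score <- numeric(0)
      return(d)
    }
    start <- sort(sample.int(genome_length - 300L, n))
    len <- sample(50:300, n, replace = TRUE)
    d <- data.frame(chrom = "chr1", start = start,
                    end = pmin(start + len, genome_length))
    if (score) d$score <- round(runif(n), 3)
    d
  }
  keep <- runif(genome_length) >= gap_fraction
  track <- data.frame(chrom = "chr1", pos = which(keep) - 1L,
                      score = round(rnorm(sum(keep)), 4))
  functional_annotations(mk(n_el[1]), mk(n_el[2], score = TRUE), track)
}
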