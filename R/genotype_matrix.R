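#' Construct a strain-by-marker genotype matrix
#'
#' Genotypes of a fully inbred two-parent panel are coded 0 (one parental
#' allele) and 2 (the other); there are no heterozygous calls. Missing
#' genotypes are `NA`.
#'
#' @param codes numeric matrix, strains in rows, markers in columns; values
#'   in \{0, 2, NA\}
#' @param map a [marker_map()] whose marker ids match `colnames(codes)`
#' @return an object of class `genotype_matrix` (list with `codes`, `map`)
#' @export
genotype_matrix <- function(codes, map) {
  stopifnot(is.matrix(codes), inherits(map, "marker_map"))
  if (is.null(rownames(codes)) || is.null(colnames(codes)))
    stop_fmt("genotype matrix needs strain rownames and marker colnames")
  if (!identical(colnames(codes), map$marker_id))
    stop_fmt("marker columns must match the map order")
  bad <- !(codes %in% c(0, 2) | is.na(codes))
  if (any(bad)) stop_fmt("genotype codes must be 0, 2 or NA")
  structure(list(codes = codes, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d strains x %d markers on %d chromosome(s)\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$map$chrom))))
  invisible(x)
}

#' Simulate genotypes for a recombinant-inbred panel
#'
#' Each strain is generated as a fixed homozygous mosaic of the two parental
#' genomes. The first marker of each chromosome draws a parental allele with
#' probability 1/2; between adjacent markers the allele switches with
#' probability `R = 4r / (1 + 6r)`, the map expansion of a recombinant-inbred
#' line fixed by repeated sib-mating, where `r` is the one-meiosis Haldane
#' recombination fraction implied by the cM gap.
#'
#' @param map a [marker_map()]
#' @param n_strains number of strains (>= 2)
#' @param seed integer seed
#' @return a [genotype_matrix()] with codes in \{0, 2\}
#' @export
simulate_ri_genotypes <- function(map, n_strains, seed = 1) {
  stopifnot(inherits(map, "marker_map"))
  if (n_strains < 2) stop_fmt("n_strains must be >= 2")
  set.seed(seed)
  m <- nrow(map)
  codes <- matrix(NA_real_, n_strains, m,
                  dimnames = list(sprintf("RI%03d", seq_len(n_strains)),
                                  map$marker_id))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    k <- length(idx)
    switch_p <- if (k > 1) ri_expansion(haldane_r(diff(map$pos_cM[idx]))) else numeric(0)
    first <- sample(c(0, 2), n_strains, replace = TRUE)
    chrom_codes <- matrix(0, n_strains, k)
    chrom_codes[, 1] <- first
    if (k > 1) {
      # cumulative XOR of switch indicators gives the mosaic directly
      switches <- matrix(rbinom(n_strains * (k - 1), 1,
                                rep(switch_p, each = n_strains)),
                         n_strains, k - 1)
      parity <- t(apply(switches, 1, cumsum)) %% 2
      chrom_codes[, -1] <- ifelse(parity == 1, 2 - first, first)
    }
    codes[, idx] <- chrom_codes
  }
  genotype_matrix(codes, map)
}
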