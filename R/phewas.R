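#' Collapse markers into unique haplotype-block representatives
#'
#' Consecutive markers on a chromosome whose strain-genotype vectors are
#' identical (including the missingness pattern) belong to one haplotype
#' block and are collapsed to the leftmost marker. Monomorphic markers are
#' dropped with a warning before collapsing.
#'
#' @param geno a [genotype_matrix()]
#' @return a reduced [genotype_matrix()]; the block extent of each
#'   representative is attached as attribute `blocks` (data.frame
#'   `marker_id, chrom, start_bp, end_bp, n_members`)
#' @export
select_block_markers <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  codes <- geno$codes; map <- geno$map
  mono <- vapply(seq_len(ncol(codes)), function(j) {
    v <- codes[, j]
    length(unique(v[!is.na(v)])) < 2
  }, logical(1))
  if (any(mono)) {
    warning(sprintf("dropping %d monomorphic marker(s)", sum(mono)))
    codes <- codes[, !mono, drop = FALSE]
    map <- map[!mono, , drop = FALSE]
  }
  keep <- logical(nrow(map))
  blocks <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    sig <- vapply(idx, function(j) paste(codes[, j], collapse = ","), "")
    new_block <- c(TRUE, sig[-1] != sig[-length(sig)])
    block_id <- cumsum(new_block)
    for (b in unique(block_id)) {
      members <- idx[block_id == b]
      keep[members[1]] <- TRUE
      blocks[[length(blocks) + 1L]] <- data.frame(
        marker_id = map$marker_id[members[1]], chrom = ch,
        start_bp = map$pos_bp[members[1]],
        end_bp = map$pos_bp[members[length(members)]],
        n_members = length(members), stringsAsFactors = FALSE)
    }
  }
  red <- genotype_matrix(codes[, keep, drop = FALSE],
                         marker_map(map$marker_id[keep], map$chrom[keep],
                                    map$pos_bp[keep], map$pos_cM[keep]))
  attr(red, "blocks") <- do.call(rbind, blocks)
  red
}

#' Map a variant to its nearest genotyped marker
#'
#' @param chrom,pos_bp variant coordinates (1-based bp)
#' @param map a [marker_map()]
#' @param window maximum distance in bp (default 1 Mb); more distant
#'   variants map to nothing
#' @return marker id, or `NA` if no marker lies within the window; ties are
#'   broken toward the lower-coordinate marker
#' @export
map_variant_to_marker <- function(chrom, pos_bp, map, window = 1e6) {
  cand <- map[map$chrom == chrom, , drop = FALSE]
  if (!nrow(cand)) return(NA_character_)
  d <- abs(cand$pos_bp - pos_bp)
  if (min(d) > window) return(NA_character_)
  hit <- which(d == min(d))
  cand$marker_id[hit[which.min(cand$pos_bp[hit])]]
}

#' Correlation scan of one marker against a phenome
#'
#' Pearson correlation on pairwise-complete strains; the two-tailed p-value
#' comes from `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of
#' freedom (`|r| = 1` maps to `p = 0` by convention). Traits with fewer than
#' `min_n` complete pairs, or zero variance over the complete pairs, are
#' skipped with an explicit status.
#'
#' @param g genotype vector over strains (codes 0/2, NA allowed)
#' @param phenome a [phenome_table()] whose strains match `g`'s names
#' @param min_n minimum pairwise-complete sample size (default 6)
#' @return data.frame `trait_id, r, n, p, status` (status `ok`,
#'   `insufficient_n` or `zero_variance`)
#' @export
correlation_scan <- function(g, phenome, min_n = 6L) {
  stopifnot(inherits(phenome, "phenome_table"))
  vals <- phenome$values
  if (!is.null(names(g))) {
    stopifnot(all(rownames(vals) %in% names(g)))
    g <- g[rownames(vals)]
  }
  stopifnot(length(g) == nrow(vals))
  res <- lapply(seq_len(ncol(vals)), function(j) {
    y <- vals[, j]
    use <- !is.na(g) & !is.na(y)
    n <- sum(use)
    if (n < min_n)
      return(data.frame(trait_id = colnames(vals)[j], r = NA_real_, n = n,
                        p = NA_real_, status = "insufficient_n"))
    gx <- g[use]; yx <- y[use]
    if (var(gx) == 0 || var(yx) == 0)
      return(data.frame(trait_id = colnames(vals)[j], r = NA_real_, n = n,
                        p = NA_real_, status = "zero_variance"))
    r <- cor(gx, yx)
    p <- if (abs(r) >= 1) 0 else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    }
    data.frame(trait_id = colnames(vals)[j], r = r, n = n, p = p,
               status = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Storey q-values with smoothed pi0 estimation
#'
#' Estimates the null proportion `pi0` from `pi0(lambda) =
#' #\{p > lambda\} / (m (1 - lambda))` over a lambda grid, smoothed with a
#' cubic polynomial and evaluated at the largest lambda, clamped to (0, 1].
#' Then `q_i = min over p_j >= p_i of pi0 * m * p_j / rank(p_j)`, capped at
#' 1. With fewer than 20 p-values `pi0` falls back to 1, which makes the
#' procedure exactly Benjamini-Hochberg.
#'
#' @param p vector of p-values (NA allowed; propagated)
#' @param lambda_grid grid for pi0 estimation
#' @param pi0 optionally force the null proportion (e.g. 1 for BH)
#' @return vector of q-values aligned with `p`; estimated `pi0` is attached
#'   as an attribute
#' @export
storey_qvalues <- function(p, lambda_grid = seq(0.05, 0.95, by = 0.05),
                           pi0 = NULL) {
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(p)
  if (any(pv < 0 | pv > 1)) stop_fmt("p-values outside [0, 1]")
  if (is.null(pi0)) {
    if (m < 20) {
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda_grid, function(l) sum(pv > l) / (m * (1 - l)),
                      numeric(1))
      fit <- lm(pi0_l ~ poly(lambda_grid, 3))
      pi0 <- predict(fit, newdata = data.frame(lambda_grid = max(lambda_grid)))
      pi0 <- min(max(pi0, .Machine$double.eps), 1)
    }
  }
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  qv <- pmin(1, cummin(pi0 * m * pv[o] / rank(pv, ties.method = "max")[o]))[ro]
  out <- rep(NA_real_, length(p))
  out[ok] <- qv
  attr(out, "pi0") <- pi0
  out
}

#' Phenome-wide association scan for a set of variants
#'
#' Each variant is mapped to its nearest haplotype-block marker (within the
#' mapping window); every distinct mapped marker is scanned against the full
#' phenome, q-values are computed per scan family (one marker against all
#' traits of the phenome), and rows below the q threshold are flagged.
#'
#' @param variants data.frame with `variant_id`, `chrom`, `pos`
#' @param geno a [genotype_matrix()] (block representatives)
#' @param phenome a [phenome_table()]
#' @param q_threshold FDR flagging threshold (default 0.01)
#' @param map_window variant-to-marker window in bp (default 1 Mb)
#' @return list with `table` (variant, marker, trait, category, r, n, p, q,
#'   flagged, plus `neg_log10_q` for Manhattan plots) and `summary`
#' @export
phewas <- function(variants, geno, phenome, q_threshold = 0.01,
                   map_window = 1e6) {
  if (nrow(variants) == 0) {
    tab <- data.frame(variant_id = character(0), marker_id = character(0),
                      trait_id = character(0), category = character(0),
                      r = numeric(0), n = integer(0), p = numeric(0),
                      q = numeric(0), flagged = logical(0),
                      neg_log10_q = numeric(0))
    return(list(table = tab,
                summary = list(n_variants = 0L, n_mapped = 0L, n_flagged = 0L)))
  }
  variants$marker_id <- vapply(seq_len(nrow(variants)), function(i)
    map_variant_to_marker(variants$chrom[i], variants$pos[i], geno$map,
                          window = map_window), "")
  mapped <- variants[!is.na(variants$marker_id), , drop = FALSE]
  scans <- list()
  for (mk in unique(mapped$marker_id)) {
    sc <- correlation_scan(geno$codes[, mk], phenome)
    sc$q <- storey_qvalues(sc$p)
    sc$marker_id <- mk
    scans[[mk]] <- sc
  }
  rows <- lapply(seq_len(nrow(mapped)), function(i) {
    sc <- scans[[mapped$marker_id[i]]]
    data.frame(variant_id = mapped$variant_id[i],
               marker_id = sc$marker_id, trait_id = sc$trait_id,
               category = phenome$meta$category[match(sc$trait_id,
                                                      phenome$meta$trait_id)],
               r = sc$r, n = sc$n, p = sc$p, q = sc$q,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$flagged <- !is.na(tab$q) & tab$q < q_threshold
  tab$neg_log10_q <- -log10(pmax(tab$q, .Machine$double.xmin))
  list(table = tab,
       summary = list(n_variants = nrow(variants), n_mapped = nrow(mapped),
                      n_markers = length(scans), n_flagged = sum(tab$flagged),
                      q_threshold = q_threshold))
}

#' Scan the first principal component of a trait group
#'
#' Traits are centered and scaled, missing values are mean-imputed, and PC
#' scores are taken from the singular-value decomposition. The PC1 strain
#' scores are then scanned against every marker with [correlation_scan()].
#'
#' @param phenome a [phenome_table()] restricted to the trait group
#' @param geno a [genotype_matrix()]
#' @return data.frame `marker_id, r, n, p`; the explained-variance fractions
#'   of all components are attached as attribute `explained`
#' @export
group_pc_scan <- function(phenome, geno) {
  X <- phenome$values
  X <- scale(X)
  X[is.na(X)] <- 0   # mean imputation after scaling
  sv <- svd(X)
  explained <- sv$d^2 / sum(sv$d^2)
  pc1 <- sv$u[, 1] * sv$d[1]
  names(pc1) <- rownames(phenome$values)
  pc_tab <- phenome_table(matrix(pc1, ncol = 1,
                                 dimnames = list(names(pc1), "PC1")),
                          data.frame(trait_id = "PC1", category = "composite",
                                     stringsAsFactors = FALSE))
  res <- lapply(geno$map$marker_id, function(mk) {
    sc <- correlation_scan(geno$codes[, mk], pc_tab)
    data.frame(marker_id = mk, r = sc$r, n = sc$n, p = sc$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "explained") <- explained
  out
}
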