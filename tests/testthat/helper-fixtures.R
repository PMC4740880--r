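# shared fixtures, built in code and cached for the session
.fx <- new.env(parent = emptyenv())

fx_gene_models <- function() {
  if (is.null(.fx$gm)) .fx$gm <- simulate_gene_models(10, seed = 7)
  .fx$gm
}

fx_catalog <- function() {
  if (is.null(.fx$cat)) {
    gm <- fx_gene_models()
    n <- c(synonymous = 20, missense = 20, stop_gain = 10, stop_loss = 5,
           splice_donor = 10, splice_acceptor = 10, frameshift = 10,
           inframe_indel = 10, intronic = 20, intergenic = 10,
           utr5 = 5, utr3 = 5)
    .fx$cat <- simulate_variant_catalog(gm$models, gm$genome, n, seed = 8)
  }
  .fx$cat
}

fx_map <- function() {
  if (is.null(.fx$map)) .fx$map <- simulate_marker_map(60, n_chrom = 2, seed = 3)
  .fx$map
}

fx_geno <- function() {
  if (is.null(.fx$geno))
    .fx$geno <- simulate_ri_genotypes(fx_map(), 80, seed = 4)
  .fx$geno
}

# reverse-complement a genome + models + SNV set (strand-symmetry probe)
fx_revcomp_world <- function(genome, models, variants) {
  lens <- setNames(Biostrings::width(genome), names(genome))
  genome2 <- Biostrings::reverseComplement(genome)
  names(genome2) <- names(genome)
  flip_iv <- function(iv, L) {
    out <- cbind(L - iv[, 2], L - iv[, 1])
    out[order(out[, 1]), , drop = FALSE]
  }
  models2 <- lapply(models, function(t) {
    L <- lens[[t$chrom]]
    transcript_model(t$transcript_id, t$gene_id, t$chrom,
                     if (t$strand == "+") "-" else "+",
                     flip_iv(t$exons, L), flip_iv(t$cds, L))
  })
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  v2 <- variants
  v2$pos <- lens[v2$chrom] - (v2$pos - 1L)
  v2$ref <- unname(comp[v2$ref])
  v2$alt <- unname(comp[v2$alt])
  list(genome = genome2, models = models2, variants = v2)
}

# vectorized permutation p-value for a Pearson correlation (two-tailed)
perm_cor_pvalue <- function(g, y, B) {
  n <- length(g)
  gs <- (g - mean(g)) / sd(g)
  ys <- (y - mean(y)) / sd(y)
  r_obs <- sum(gs * ys) / (n - 1)
  idx <- vapply(seq_len(B), function(i) sample.int(n), integer(n))
  perm <- colSums(gs * matrix(ys[idx], n, B)) / (n - 1)
  p <- mean(abs(perm) >= abs(r_obs) - 1e-12)
  list(r = r_obs, p = p)
}

# vectorized null correlation scan: r and two-tailed t-based p for every
# (marker, trait) pair; matches correlation_scan on complete data
fast_cor_scan <- function(G, Y) {
  n <- nrow(G)
  r <- suppressWarnings(cor(G, Y))
  t_ <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(abs(t_), df = n - 2, lower.tail = FALSE)
  list(r = r, p = p)
}
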