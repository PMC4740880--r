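test_that("haplotype-block collapsing matches a brute-force run count", {
  geno <- fx_geno()
  red <- select_block_markers(geno)
  # brute force: count runs of distinct consecutive strain vectors per chrom
  brute <- 0L
  for (ch in unique(geno$map$chrom)) {
    idx <- which(geno$map$chrom == ch)
    sig <- apply(geno$codes[, idx, drop = FALSE], 2, paste, collapse = ",")
    brute <- brute + sum(c(TRUE, sig[-1] != sig[-length(sig)]))
  }
  expect_equal(ncol(red$codes), brute)
  # representative is the leftmost member and block extents are recorded
  blocks <- attr(red, "blocks")
  expect_true(all(blocks$start_bp <= blocks$end_bp))
  expect_identical(blocks$marker_id, red$map$marker_id)

  # 10 identical consecutive markers collapse to one; alternating do not
  codes <- cbind(matrix(rep(c(0, 2, 0, 2), 10), 4, 10),
                 matrix(c(0, 0, 2, 2, 2, 2, 0, 0), 4, 2))
  rownames(codes) <- paste0("s", 1:4)
  colnames(codes) <- sprintf("m%02d", 1:12)
  mm <- marker_map(colnames(codes), "chr1", seq(1e5, 12e5, by = 1e5),
                   seq(0, 11))
  red2 <- select_block_markers(genotype_matrix(codes, mm))
  expect_equal(ncol(red2$codes), 3)  # one 10-block + two singleton blocks
})

test_that("variant-to-marker mapping honors the 1 Mb window and tie rule", {
  mm <- marker_map(c("m1", "m2"), "chr1", c(1e6, 3e6), c(0, 2))
  expect_equal(map_variant_to_marker("chr1", 1.5e6, mm), "m1")
  expect_equal(map_variant_to_marker("chr1", 4.2e6, mm), NA_character_)
  expect_equal(map_variant_to_marker("chr1", 2e6, mm), "m1")  # equidistant
  expect_equal(map_variant_to_marker("chr2", 1e6, mm), NA_character_)
})

test_that("correlation scan p-values behave and skip degenerate traits", {
  geno <- fx_geno()
  mk <- geno$map$marker_id[5]
  g <- geno$codes[, mk]
  # exact trait: r = 1, p = 0
  vals <- cbind(exact = g, flat = rep(1, length(g)))
  rownames(vals) <- rownames(geno$codes)
  ph <- suppressWarnings(phenome_table(vals,
    data.frame(trait_id = c("exact", "flat"), category = "behavior")))
  sc <- correlation_scan(g, ph)
  expect_equal(sc$r[1], 1)
  expect_equal(sc$p[1], 0)
  expect_equal(sc$status[2], "zero_variance")
  # tiny n is skipped
  small <- phenome_table(matrix(rnorm(8), 4,
                                dimnames = list(rownames(vals)[1:4],
                                                c("a", "b"))),
                         data.frame(trait_id = c("a", "b"),
                                    category = "behavior"))
  sc2 <- correlation_scan(g[1:4], small)
  expect_true(all(sc2$status == "insufficient_n"))
})

test_that("t-based p-values agree with a permutation oracle (spot check)", {
  set.seed(77)
  B <- 2e4
  for (case in 1:5) {
    n <- sample(20:40, 1)
    g <- sample(c(0, 2), n, replace = TRUE)
    if (length(unique(g)) < 2) g[1:2] <- c(0, 2)
    y <- 0.3 * g + rnorm(n)
    pp <- perm_cor_pvalue(g, y, B)
    t_ <- pp$r * sqrt((n - 2) / (1 - pp$r^2))
    p_t <- 2 * pt(abs(t_), df = n - 2, lower.tail = FALSE)
    se <- sqrt(max(pp$p * (1 - pp$p), 1 / B) / B)
    expect_lt(abs(p_t - pp$p), 4 * se + 2e-3)
  }
})

test_that("Storey q-values reduce to BH at pi0 = 1 and estimate pi0 near 1 under the null", {
  set.seed(11)
  p <- runif(500)
  q <- storey_qvalues(p, pi0 = 1)
  expect_equal(as.numeric(q), p.adjust(p, "BH"))
  # all p = 1 -> all q = 1
  expect_true(all(storey_qvalues(rep(1, 50)) == 1))
  # uniform null, m = 1e4: pi0 in [0.9, 1]
  for (s in 1:5) {
    set.seed(100 + s)
    qn <- storey_qvalues(runif(1e4))
    expect_gte(attr(qn, "pi0"), 0.9)
    expect_lte(attr(qn, "pi0"), 1)
  }
  # q monotone non-decreasing in p
  o <- order(p)
  expect_true(all(diff(storey_qvalues(p)[o]) >= -1e-12))
  # small m falls back to pi0 = 1
  expect_equal(attr(storey_qvalues(runif(10)), "pi0"), 1)
})

test_that("phewas flags the planted association and handles empty input", {
  geno <- fx_geno()
  red <- select_block_markers(geno)
  mk <- red$map$marker_id[8]
  spec <- data.frame(
    trait_id = sprintf("t%03d", 1:120),
    marker_id = c(mk, rep(NA, 119)),
    effect_fraction = c(0.5, rep(0, 119)))
  ph <- simulate_phenome(geno, spec, seed = 31)
  vdf <- data.frame(variant_id = "v1", chrom = red$map$chrom[8],
                    pos = red$map$pos_bp[8] + 1000)
  res <- phewas(vdf, red, ph)
  hit <- res$table[res$table$trait_id == "t001", ]
  expect_equal(hit$marker_id, mk)
  expect_true(hit$flagged)
  expect_equal(res$summary$n_mapped, 1)
  empty <- phewas(data.frame(variant_id = character(0), chrom = character(0),
                             pos = integer(0)), red, ph)
  expect_equal(nrow(empty$table), 0)
})

test_that("scan output is invariant to strain and trait ordering", {
  geno <- fx_geno()
  mk <- geno$map$marker_id[3]
  spec <- data.frame(trait_id = sprintf("t%02d", 1:20),
                     marker_id = c(mk, rep(NA, 19)),
                     effect_fraction = c(0.6, rep(0, 19)))
  ph <- simulate_phenome(geno, spec, seed = 41)
  sc <- correlation_scan(geno$codes[, mk], ph)
  # permute strains and traits
  so <- sample(nrow(ph$values)); to <- sample(ncol(ph$values))
  ph2 <- phenome_table(ph$values[so, to], ph$meta[to, ])
  g2 <- geno$codes[so, mk]
  sc2 <- correlation_scan(g2, ph2)
  m <- match(sc$trait_id, sc2$trait_id)
  expect_equal(sc$r, sc2$r[m])
  expect_equal(sc$p, sc2$p[m])
})

test_that("PC1 group scan recovers co-regulated traits' driver", {
  geno <- fx_geno()
  mk <- geno$map$marker_id[12]
  spec <- data.frame(trait_id = sprintf("co%d", 1:6), marker_id = mk,
                     effect_fraction = 0.6)
  ph <- simulate_phenome(geno, spec, seed = 51)
  res <- group_pc_scan(ph, geno)
  best <- res$marker_id[which.min(res$p)]
  # the peak marker is the driver (or a block-mate with identical genotypes)
  expect_equal(cor(geno$codes[, best], geno$codes[, mk])^2, 1)
  expl <- attr(res, "explained")
  expect_gt(expl[1], 0.5)
  # single trait: PC1 is that trait up to sign
  ph1 <- phenome_table(ph$values[, 1, drop = FALSE], ph$meta[1, ])
  res1 <- group_pc_scan(ph1, geno)
  sc1 <- correlation_scan(geno$codes[, mk], ph1)
  expect_equal(abs(res1$r[res1$marker_id == mk]), abs(sc1$r), tolerance = 1e-8)
  # duplicating the trait set leaves PC1 structure intact
  dup_vals <- cbind(ph$values, ph$values)
  colnames(dup_vals) <- c(ph$meta$trait_id, paste0(ph$meta$trait_id, "_b"))
  dup <- phenome_table(dup_vals,
                       data.frame(trait_id = colnames(dup_vals),
                                  category = "behavior"))
  resd <- group_pc_scan(dup, geno)
  expect_equal(attr(resd, "explained")[1], expl[1], tolerance = 1e-8)
})
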