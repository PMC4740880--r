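test_that("RI genotype mosaics follow the sib-mating map expansion", {
  # two markers at identical cM: no recombination at all
  map0 <- marker_map(c("a", "b"), "chr1", c(100, 200), c(5, 5))
  g0 <- simulate_ri_genotypes(map0, 50, seed = 1)
  expect_true(all(g0$codes[, 1] == g0$codes[, 2]))

  # unlinked markers: R = 4*0.5/(1+6*0.5) = 0.5
  map1 <- marker_map(c("a", "b"), "chr1", c(100, 2e6), c(0, 1e4))
  g1 <- simulate_ri_genotypes(map1, 2000, seed = 2)
  disc <- mean(g1$codes[, 1] != g1$codes[, 2])
  expect_lt(abs(disc - 0.5), 3 * sqrt(0.25 / 2000))

  # r = 0.1 (Haldane d such that r=0.1): R = 0.4/1.6 = 0.25
  d <- -50 * log(1 - 2 * 0.1)
  map2 <- marker_map(c("a", "b"), "chr1", c(100, 200000), c(0, d))
  g2 <- simulate_ri_genotypes(map2, 200, seed = 3)
  disc2 <- mean(g2$codes[, 1] != g2$codes[, 2])
  expect_lt(abs(disc2 - 0.25), 3 * sqrt(0.25 * 0.75 / 200))

  # fully inbred: only parental codes
  expect_true(all(g2$codes %in% c(0, 2)))
  expect_error(simulate_ri_genotypes(map2, 1), "n_strains")
})

test_that("genotype simulation is bit-reproducible and map is validated", {
  a <- simulate_ri_genotypes(fx_map(), 30, seed = 9)
  b <- simulate_ri_genotypes(fx_map(), 30, seed = 9)
  expect_identical(a, b)
  expect_error(marker_map(c("a", "b"), "chr1", c(100, 100), c(0, 1)),
               "strictly increasing")
  expect_error(marker_map(c("a", "b"), "chr1", c(100, 200), c(2, 1)),
               "monotone")
})

test_that("planted phenome effects explain the requested variance", {
  geno <- fx_geno()
  mk <- geno$map$marker_id[10]

  # effect_fraction 1: trait is an affine function of the genotype
  spec1 <- data.frame(trait_id = "t", marker_id = mk, effect_fraction = 1)
  ph1 <- simulate_phenome(geno, spec1, seed = 1)
  expect_equal(abs(cor(ph1$values[, 1], geno$codes[, mk])), 1)

  # effect_fraction 0: independent of every marker
  spec0 <- data.frame(trait_id = "t", marker_id = NA, effect_fraction = 0)
  ph0 <- simulate_phenome(geno, spec0, seed = 2)
  r0 <- abs(cor(geno$codes, ph0$values[, 1]))
  expect_lt(max(r0), 0.5)

  # effect_fraction 0.5 recovered across replicates (Monte-Carlo oracle)
  spec <- data.frame(trait_id = "t", marker_id = mk, effect_fraction = 0.5)
  r2 <- vapply(1:200, function(s) {
    ph <- simulate_phenome(geno, spec, seed = 1000 + s)
    cor(ph$values[, 1], geno$codes[, mk])^2
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.5), 3 * sd(r2) / sqrt(200))

  expect_error(simulate_phenome(geno, data.frame(trait_id = "t",
    marker_id = mk, effect_fraction = 1.2)), "effect_fraction")
  expect_error(simulate_phenome(geno, spec, missing_rate = 1), "missing_rate")
})

test_that("missingness is inserted at the configured MCAR rate", {
  geno <- fx_geno()
  spec <- data.frame(trait_id = sprintf("t%d", 1:50), marker_id = NA,
                     effect_fraction = 0)
  ph <- simulate_phenome(geno, spec, missing_rate = 0.2, seed = 5)
  frac <- mean(is.na(ph$values))
  n <- length(ph$values)
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("emitted gene models are internally consistent", {
  gm <- fx_gene_models()
  for (t in gm$models) {
    cds <- cds_sequence(t, gm$genome)
    expect_equal(nchar(cds) %% 3, 0)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
    iv <- riphewas:::tx_introns(t)
    for (k in seq_len(nrow(iv))) {
      intron <- as.character(Biostrings::subseq(gm$genome[[t$chrom]],
                                                iv[k, 1] + 1, iv[k, 2]))
      if (t$strand == "-")
        intron <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(intron)))
      expect_equal(substr(intron, 1, 2), "GT")
      expect_equal(substr(intron, nchar(intron) - 1, nchar(intron)), "AG")
    }
  }
})

test_that("planted variant catalog honors requested classes and counts", {
  gm <- fx_gene_models()
  cat_ <- fx_catalog()
  counts <- table(cat_$truth$class)
  expect_equal(unname(counts[["stop_gain"]]), 10)
  expect_equal(unname(counts[["frameshift"]]), 10)
  expect_equal(unname(counts[["synonymous"]]), 20)
  # stop gains really create stop codons, checked on the coding strand
  sg <- merge(cat_$variants, cat_$truth)
  sg <- sg[sg$class == "stop_gain", ]
  for (i in seq_len(nrow(sg))) {
    t <- Filter(function(m) m$transcript_id == sg$transcript_id[i],
                gm$models)[[1]]
    alt_c <- if (t$strand == "+") sg$alt[i] else
      riphewas:::complement_base(sg$alt[i])
    expect_true(alt_c %in% c("T", "A", "G"))  # stop codons carry no C
  }
  # in-frame truth labels are mod-3 arithmetic
  ifr <- merge(cat_$variants, cat_$truth)
  ifr <- ifr[ifr$class == "inframe_indel", ]
  expect_true(all(abs(nchar(ifr$ref) - nchar(ifr$alt)) %% 3 == 0))
})

test_that("depth track simulation matches its Poisson model", {
  # no CNV: exchangeable Poisson(depth_mean)
  tr0 <- simulate_depth_track(5e4, depth_mean = 30, seed = 1)
  expect_lt(abs(mean(tr0$counts) - 30), 3 * sqrt(30 / length(tr0$counts)))
  # copy ratio 8 over 30 kb: mean depth ~4x flanks
  spec <- data.frame(start = 10000, end = 40000, copy_ratio = 8)
  tr <- simulate_depth_track(1e5, depth_mean = 30, cnv_spec = spec, seed = 2)
  inside <- tr$counts[101:400]
  outside <- tr$counts[-(101:400)]
  expect_lt(abs(mean(inside) / mean(outside) - 4), 0.2)
  # copy ratio 0: hard zero
  spec0 <- data.frame(start = 10000, end = 40000, copy_ratio = 0)
  trz <- simulate_depth_track(1e5, depth_mean = 30, cnv_spec = spec0, seed = 3)
  expect_true(all(trz$counts[101:400] == 0))
})

test_that("ICD cohort exercises the two-code rule and exclusions", {
  coh <- simulate_icd_cohort(1500, seed = 6, two_code_fraction = 0.75)
  st <- assign_case_control(coh$records, synthetic_phecode_map(),
                            persons = coh$persons)
  stat <- st[, coh$truth$phecode]
  n_case <- sum(stat == "case")
  n_one <- sum(stat == "excluded")
  # among planted-affected people, the case fraction tracks the configured
  # multiplicity (exclusions also arise from the exclusion-range codes)
  frac <- n_case / coh$truth$n_affected
  expect_lt(abs(frac - 0.75),
            3 * sqrt(0.75 * 0.25 / coh$truth$n_affected))
  expect_gt(n_one, 0)

  # monomorphic genotype: scan skips with explicit status
  coh0 <- simulate_icd_cohort(300, maf = 0, seed = 7)
  st0 <- assign_case_control(coh0$records, synthetic_phecode_map(),
                             persons = coh0$persons)
  res0 <- logistic_scan(coh0$genotype, st0, coh0$covariates)
  expect_true(all(res0$status == "monomorphic"))
})

test_that("conservation tracks honor the gap fraction and round-trip", {
  ann <- simulate_conservation_tracks(20000, gap_fraction = 0.4, seed = 4)
  gap <- 1 - nrow(ann$track) / 20000
  expect_lt(abs(gap - 0.4), 3 * sqrt(0.4 * 0.6 / 20000))
  expect_true(all(ann$conserved$score >= 0 & ann$conserved$score <= 1))
  f <- tempfile(fileext = ".bedgraph")
  riphewas:::write_conservation_track(ann$track, f)
  back <- riphewas:::read_conservation_track(f)
  expect_equal(back$pos, ann$track$pos)
  expect_equal(back$score, ann$track$score)
})
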