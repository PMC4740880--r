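test_that("codon-level SNV calls follow the genetic code", {
  # hand-built plus-strand gene: 5'UTR(6) + ATG AAA TAT CAT TGA + 3'UTR(6)
  seq <- paste0("GGGGGG", "ATGAAATATCATTGA", "CCCCCC")
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  t <- transcript_model("t1", "g1", "chr1", "+",
                        exons = cbind(0L, nchar(seq)),
                        cds = cbind(6L, 21L))
  v <- function(pos, ref, alt) list(chrom = "chr1", pos = pos, ref = ref,
                                    alt = alt)
  # AAA -> AAG: Lys -> Lys
  expect_equal(classify_snv(v(12, "A", "G"), t, genome), "synonymous")
  # TAT -> TAA: Tyr -> stop
  expect_equal(classify_snv(v(15, "T", "A"), t, genome), "stop_gain")
  # TAT -> CAT: Tyr -> His
  expect_equal(classify_snv(v(13, "T", "C"), t, genome), "missense")
  # TGA -> TGG: stop read-through
  expect_equal(classify_snv(v(21, "A", "G"), t, genome), "stop_loss")
  # UTRs and intergenic flanks
  expect_equal(classify_snv(v(3, "G", "A"), t, genome), "utr5")
  expect_equal(classify_snv(v(25, "C", "A"), t, genome), "utr3")
  # ref mismatch errors with the position
  expect_error(classify_snv(v(12, "C", "G"), t, genome), "chr1:12")
})

test_that("splice dinucleotide positions outrank intronic", {
  # exon1(9) GT..intron(10)..AG exon2(9); CDS spans both exons
  seq <- paste0("ATGAAACCC", "GTGGGGGGAG", "TTTAAATGA")
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  t <- transcript_model("t1", "g1", "chr1", "+",
                        exons = rbind(c(0L, 9L), c(19L, 28L)),
                        cds = rbind(c(0L, 9L), c(19L, 28L)))
  v <- function(pos, ref, alt) list(chrom = "chr1", pos = pos, ref = ref,
                                    alt = alt)
  expect_equal(classify_snv(v(10, "G", "A"), t, genome), "splice_donor")
  expect_equal(classify_snv(v(11, "T", "A"), t, genome), "splice_donor")
  expect_equal(classify_snv(v(18, "A", "C"), t, genome), "splice_acceptor")
  expect_equal(classify_snv(v(19, "G", "C"), t, genome), "splice_acceptor")
  expect_equal(classify_snv(v(14, "G", "C"), t, genome), "intronic")
})

test_that("indel classification uses mod-3 arithmetic and severity", {
  seq <- paste0("ATGAAACCC", "GTGGGGGGAG", "TTTAAATGA")
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  t <- transcript_model("t1", "g1", "chr1", "+",
                        exons = rbind(c(0L, 9L), c(19L, 28L)),
                        cds = rbind(c(0L, 9L), c(19L, 28L)))
  # 3-bp deletion wholly in CDS -> in-frame
  v3 <- list(chrom = "chr1", pos = 3, ref = "GAAA", alt = "G")
  expect_equal(classify_indel(v3, t, genome), "inframe_indel")
  # 4-bp insertion in CDS -> frameshift
  v4 <- list(chrom = "chr1", pos = 21, ref = "T", alt = "TACGT")
  expect_equal(classify_indel(v4, t, genome), "frameshift")
  # intron-only deletion away from splice dinucleotides -> intronic
  vi <- list(chrom = "chr1", pos = 13, ref = "GGGG", alt = "G")
  expect_equal(classify_indel(vi, t, genome), "intronic")
  # deletion spanning CDS and donor takes the most severe overlapped class
  vs <- list(chrom = "chr1", pos = 8, ref = "CCGT", alt = "C")
  expect_equal(classify_indel(vs, t, genome), "splice_donor")
})

test_that("indels are left-normalized before classification", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AATTTTGCAA"))
  # deleting one T of the TTTT run, written right-aligned
  v <- list(chrom = "chr1", pos = 5, ref = "TT", alt = "T")
  nv <- normalize_variant(v, genome)
  expect_equal(nv$pos, 2)
  expect_equal(nv$ref, "AT")
  expect_equal(nv$alt, "A")
})

test_that("annotation agrees with generator truth on >= 1000 planted variants", {
  gm <- simulate_gene_models(40, seed = 21, n_chrom = 2)
  n <- c(synonymous = 250, missense = 250, stop_gain = 100, stop_loss = 30,
         splice_donor = 60, splice_acceptor = 60, frameshift = 100,
         inframe_indel = 90, intronic = 100, intergenic = 60)
  cat_ <- simulate_variant_catalog(gm$models, gm$genome, n, seed = 22)
  expect_gte(nrow(cat_$variants), 1000)
  strands <- vapply(gm$models, `[[`, "", "strand")
  expect_setequal(unique(strands), c("+", "-"))
  ann <- annotate_vcf(cat_$variants, gm$models, gm$genome)
  m <- merge(ann$table, cat_$truth, by = "variant_id")
  expect_equal(nrow(m), nrow(cat_$variants))
  expect_identical(m$class.x, m$class.y)
})

test_that("SNV consequences are invariant to reverse-complementing the world", {
  gm <- fx_gene_models()
  cat_ <- fx_catalog()
  snv <- cat_$variants[nchar(cat_$variants$ref) == 1 &
                         nchar(cat_$variants$alt) == 1, ]
  orig <- annotate_vcf(snv, gm$models, gm$genome)$table
  rc <- fx_revcomp_world(gm$genome, gm$models, snv)
  flipped <- annotate_vcf(rc$variants, rc$models, rc$genome)$table
  key <- match(orig$variant_id, flipped$variant_id)
  expect_identical(orig$class, flipped$class[key])
})

test_that("multi-transcript aggregation picks the most severe class", {
  seq <- paste0("GGGGGG", "ATGAAATATCATTGA", "CCCCCC")
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  coding <- transcript_model("t1", "g1", "chr1", "+",
                             exons = cbind(0L, nchar(seq)),
                             cds = cbind(6L, 21L))
  # second transcript where the same position is intronic
  noncod <- transcript_model("t2", "g2", "chr1", "+",
                             exons = rbind(c(0L, 3L), c(24L, 27L)),
                             cds = matrix(integer(0), 0, 2))
  vdf <- data.frame(chrom = "chr1", pos = 13, ref = "T", alt = "C")
  ann <- annotate_vcf(vdf, list(coding, noncod), genome)
  expect_equal(ann$table$class, "missense")
  expect_equal(ann$table$transcript_id, "t1")

  empty <- annotate_vcf(vdf[0, ], list(coding), genome)
  expect_equal(nrow(empty$table), 0)
  expect_true(all(empty$counts == 0))
})

test_that("incomplete CDS models only get non-coding classes", {
  seq <- paste0("GGGGGG", "ATGAAATATCATTG", "CCCCCC")  # CDS length 14
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  t <- transcript_model("t1", "g1", "chr1", "+",
                        exons = cbind(0L, nchar(seq)), cds = cbind(6L, 20L))
  expect_true(t$incomplete)
  cls <- classify_snv(list(chrom = "chr1", pos = 12, ref = "A", alt = "G"),
                      t, genome)
  expect_false(cls %in% c("synonymous", "missense", "stop_gain", "stop_loss"))
})

test_that("platform-wide FPR arithmetic matches the printed worked numbers", {
  expect_equal(platform_fpr(4160570, 3375198, 0.0234), 0.0044, tolerance = 0.01)
  expect_equal(platform_fpr(4090000, 3375198, 0.0373), 0.0065, tolerance = 0.01)
  expect_equal(platform_fpr(100, 100, 0.5), 0)
  expect_error(platform_fpr(0, 0, 0.1), "positive")
  expect_error(platform_fpr(10, 20, 0.1), "exceeds")
})
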