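#' Default pipeline configuration
#'
#' All thresholds default to the values the analysis is defined with: FDR
#' q < 0.01, CNV event alpha 1e-6 with >= 10 windows of 100 bp and >= 1 kb,
#' variant-to-marker window 1 Mb, two-code case rule, >= 20 cases per
#' phecode, MAF > 1%.
#'
#' @param seed master seed; every stage derives its own substream
#' @param out output directory
#' @param ... overrides for any config entry
#' @return a named list of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1, out = tempfile("riphewas_run"), ...) {
  cfg <- list(
    seed = seed, out = out,
    stages = c("simulate", "annotate", "score", "cnv", "scan", "human"),
    # simulation scale
    n_strains = 80, n_markers = 120, n_traits = 200, n_genes = 12,
    missing_rate = 0.02, depth_mean = 30, depth_genome_length = 3e5,
    cnv_spec = data.frame(start = 150000, end = 180000, copy_ratio = 8),
    n_individuals = 2000, planted_or = 2, planted_maf = 0.3,
    # analysis thresholds (method defaults)
    q_threshold = 0.01, cnv_alpha = 1e-6, min_consec = 10L, min_bp = 1000L,
    window = 100L, map_window = 1e6, min_code_count = 2L,
    min_individuals = 20L, maf = 0.01)
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline
#'
#' Executes simulate -> annotate -> score -> cnv -> scan -> human-phewas,
#' writing plain-text intermediates to the output directory. Every stage
#' seeds its randomness from a substream of the master seed, so a fixed
#' seed yields bit-identical outputs. A provenance block (config, seed,
#' package and R versions) is written alongside the results.
#'
#' @param config a [pipeline_config()]
#' @return the output directory, invisibly
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(cfg$out, ...)
  has <- function(s) s %in% cfg$stages

  # fail early on missing inputs before any compute; an input is available
  # if cached on disk or produced by an earlier stage of this same run
  needs <- list(annotate = "sim/genome.fa", score = "annotation.tsv",
                cnv = "sim/depth.tsv", scan = "annotation.tsv",
                human = "sim/icd_records.csv")
  produced_by <- c(`sim/genome.fa` = "simulate", `sim/depth.tsv` = "simulate",
                   `sim/icd_records.csv` = "simulate",
                   annotation.tsv = "annotate")
  for (s in intersect(names(needs), cfg$stages)) {
    f <- needs[[s]]
    if (!file.exists(pth(f)) && !(produced_by[[f]] %in% cfg$stages))
      stop_fmt("stage '%s' needs missing input %s", s, pth(f))
  }

  if (has("simulate")) {
    map <- simulate_marker_map(cfg$n_markers, n_chrom = 2,
                               seed = derive_seed(cfg$seed, "map"))
    geno <- simulate_ri_genotypes(map, cfg$n_strains,
                                  seed = derive_seed(cfg$seed, "geno"))
    planted <- map$marker_id[c(10, 40)]
    spec <- data.frame(
      trait_id = sprintf("trait%04d", seq_len(cfg$n_traits)),
      marker_id = c(planted, rep(NA, cfg$n_traits - 2)),
      effect_fraction = c(0.5, 0.5, rep(0, cfg$n_traits - 2)))
    phen <- simulate_phenome(geno, spec, missing_rate = cfg$missing_rate,
                             seed = derive_seed(cfg$seed, "phenome"))
    gm <- simulate_gene_models(cfg$n_genes,
                               seed = derive_seed(cfg$seed, "genes"))
    cat_n <- c(synonymous = 8, missense = 8, stop_gain = 4, stop_loss = 2,
               splice_donor = 4, splice_acceptor = 4, frameshift = 4,
               inframe_indel = 4, intronic = 8, intergenic = 8)
    cat <- simulate_variant_catalog(gm$models, gm$genome, cat_n,
                                    seed = derive_seed(cfg$seed, "variants"))
    depth <- simulate_depth_track(cfg$depth_genome_length, cfg$depth_mean,
                                  cfg$cnv_spec, window_size = cfg$window,
                                  seed = derive_seed(cfg$seed, "depth"))
    cons <- simulate_conservation_tracks(
      sum(Biostrings::width(gm$genome)),
      seed = derive_seed(cfg$seed, "conservation"))
    icd <- simulate_icd_cohort(cfg$n_individuals, maf = cfg$planted_maf,
                               odds_ratio = cfg$planted_or,
                               seed = derive_seed(cfg$seed, "icd"))
    dir.create(pth("sim"), showWarnings = FALSE)
    write_genotypes(geno, pth("sim", "genotypes.tsv"), pth("sim", "map.tsv"))
    write_phenome(phen, pth("sim", "phenome.tsv"), pth("sim", "traits.tsv"))
    write_fasta(gm$genome, pth("sim", "genome.fa"))
    write_gff3(gm$models, pth("sim", "models.gff3"))
    write_vcf(cat$variants, pth("sim", "variants.vcf"),
              contigs = setNames(Biostrings::width(gm$genome),
                                 names(gm$genome)))
    write_tsv(cat$truth, pth("sim", "variant_truth.tsv"))
    write_depth_track(depth, pth("sim", "depth.tsv"))
    write_bed(cons$regulatory, pth("sim", "regulatory.bed"))
    write_bedgraph(cons$conserved, pth("sim", "conserved.bedgraph"))
    write_conservation_track(cons$track, pth("sim", "conservation.bedgraph"))
    write_icd_records(icd$records, pth("sim", "icd_records.csv"))
    write_phecode_map(synthetic_phecode_map(), pth("sim", "icd_map.csv"),
                      pth("sim", "phecodes.csv"))
    gcov <- data.frame(person_id = icd$persons, genotype = icd$genotype,
                       icd$covariates)
    write_tsv(gcov, pth("sim", "cohort_genotypes.tsv"))
  }

  if (has("annotate")) {
    genome <- read_fasta(pth("sim", "genome.fa"))
    models <- read_gff3(pth("sim", "models.gff3"))
    variants <- read_vcf(pth("sim", "variants.vcf"), genome = genome)
    ann <- annotate_vcf(variants, models, genome)
    write_tsv(ann$table, pth("annotation.tsv"))
    write_tsv(data.frame(class = names(ann$counts),
                         count = as.integer(ann$counts)),
              pth("annotation_counts.tsv"))
  }

  if (has("score")) {
    ann_tab <- read_tsv(pth("annotation.tsv"))
    nc <- ann_tab[ann_tab$class %in% c("intronic", "intergenic", "utr5",
                                       "utr3"), , drop = FALSE]
    cons <- functional_annotations(
      read_bed(pth("sim", "regulatory.bed")),
      read_bedgraph(pth("sim", "conserved.bedgraph")),
      read_conservation_track(pth("sim", "conservation.bedgraph")))
    pos <- data.frame(chrom = nc$chrom, pos = nc$pos - 1L,
                      variant_id = nc$variant_id)
    write_tsv(score_snps(pos, cons), pth("impact_scores.tsv"))
  }

  if (has("cnv")) {
    depth <- read_depth_track(pth("sim", "depth.tsv"))
    calls <- ewt_scan(depth, alpha = cfg$cnv_alpha,
                      min_consec = cfg$min_consec, min_bp = cfg$min_bp)
    write_tsv(calls, pth("cnv_calls.tsv"))
  }

  if (has("scan")) {
    geno <- read_genotypes(pth("sim", "genotypes.tsv"), pth("sim", "map.tsv"))
    phen <- read_phenome(pth("sim", "phenome.tsv"), pth("sim", "traits.tsv"))
    blocks <- select_block_markers(geno)
    ann_tab <- read_tsv(pth("annotation.tsv"))
    dmg <- ann_tab[ann_tab$class %in% c("stop_gain", "stop_loss", "missense",
                                        "splice_donor", "splice_acceptor",
                                        "frameshift"), , drop = FALSE]
    # variant coordinates live on the synthetic gene genome; place them onto
    # the marker map's coordinate system so nearest-marker mapping applies
    set.seed(derive_seed(cfg$seed, "placement"))
    idx <- sample.int(nrow(blocks$map), nrow(dmg), replace = TRUE)
    vdf <- data.frame(
      variant_id = dmg$variant_id,
      chrom = blocks$map$chrom[idx],
      pos = pmax(1, blocks$map$pos_bp[idx] +
                   sample(-5e5:5e5, nrow(dmg), replace = TRUE)))
    res <- phewas(vdf, blocks, phen, q_threshold = cfg$q_threshold,
                  map_window = cfg$map_window)
    write_tsv(res$table, pth("associations.tsv"))
    jsonlite::write_json(res$summary, pth("scan_summary.json"),
                         auto_unbox = TRUE)
  }

  if (has("human")) {
    recs <- read_icd_records(pth("sim", "icd_records.csv"))
    pmap <- read_phecode_map(pth("sim", "icd_map.csv"),
                             pth("sim", "phecodes.csv"))
    gcov <- read_tsv(pth("sim", "cohort_genotypes.tsv"))
    g <- setNames(gcov$genotype, gcov$person_id)
    covars <- gcov[, c("age", "sex", "PC1", "PC2", "PC3")]
    rownames(covars) <- gcov$person_id
    status <- assign_case_control(recs, pmap,
                                  min_code_count = cfg$min_code_count,
                                  persons = gcov$person_id)
    keep <- filter_phenotypes(status, cfg$min_individuals)
    res <- logistic_scan(g, status, covars, phecodes = keep)
    res$pass_bonferroni <- !is.na(res$p) &
      res$p < bonferroni_threshold(0.05, length(keep))
    write_tsv(res, pth("human_phewas.tsv"))
  }

  prov <- list(config = cfg[setdiff(names(cfg), c("cnv_spec", "out"))],
               cnv_spec = as.list(cfg$cnv_spec),
               package_version = as.character(utils::packageVersion("riphewas")),
               r_version = R.version.string)
  jsonlite::write_json(prov, pth("provenance.json"), auto_unbox = TRUE,
                       force = TRUE)
  invisible(cfg$out)
}
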