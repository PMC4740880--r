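# ---- TSV / CSV helpers -----------------------------------------------------

write_tsv <- function(x, file) data.table::fwrite(x, file, sep = "\t")
read_tsv <- function(file) as.data.frame(data.table::fread(file, sep = "\t"))

#' @rdname io_genotypes
#' @export
write_genotypes <- function(geno, geno_file, map_file) {
  df <- data.frame(strain_id = rownames(geno$codes), geno$codes,
                   check.names = FALSE)
  write_tsv(df, geno_file)
  write_tsv(as.data.frame(geno$map), map_file)
}

#' Read and write genotype matrices as TSV
#'
#' Genotypes are strains x markers with a leading `strain_id` column; the
#' marker map is a separate TSV (`marker_id, chrom, pos_bp, pos_cM`).
#'
#' @param geno a [genotype_matrix()]
#' @param geno_file,map_file file paths
#' @return `read_genotypes` returns a [genotype_matrix()]
#' @name io_genotypes
#' @export
read_genotypes <- function(geno_file, map_file) {
  df <- read_tsv(geno_file)
  m <- read_tsv(map_file)
  codes <- as.matrix(df[, -1, drop = FALSE])
  rownames(codes) <- df$strain_id
  genotype_matrix(codes, marker_map(m$marker_id, m$chrom, m$pos_bp, m$pos_cM))
}

#' @rdname io_phenome
#' @export
write_phenome <- function(phenome, values_file, meta_file) {
  df <- data.frame(strain_id = rownames(phenome$values), phenome$values,
                   check.names = FALSE)
  write_tsv(df, values_file)
  write_tsv(phenome$meta, meta_file)
}

#' Read and write phenome tables as TSV
#'
#' @param phenome a [phenome_table()]
#' @param values_file,meta_file file paths
#' @return `read_phenome` returns a [phenome_table()]
#' @name io_phenome
#' @export
read_phenome <- function(values_file, meta_file) {
  df <- read_tsv(values_file)
  meta <- read_tsv(meta_file)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$strain_id
  phenome_table(vals, meta)
}

#' @rdname io_depth
#' @export
write_depth_track <- function(track, file) {
  n <- length(track$counts)
  write_tsv(data.frame(chrom = track$chrom,
                       window_start = (seq_len(n) - 1L) * track$window_size,
                       count = track$counts,
                       mask = as.integer(track$mask)), file)
}

#' Read and write windowed depth tracks as TSV
#'
#' Columns: `chrom, window_start, count, mask` (0-based window starts).
#'
#' @param track a [depth_track()]
#' @param file file path
#' @return `read_depth_track` returns a [depth_track()]
#' @name io_depth
#' @export
read_depth_track <- function(file) {
  df <- read_tsv(file)
  ws <- if (nrow(df) > 1) df$window_start[2] - df$window_start[1] else 100L
  depth_track(df$count, chrom = df$chrom[1], window_size = ws,
              mask = as.logical(df$mask))
}

# ---- FASTA -----------------------------------------------------------------

#' @rdname io_fasta
#' @export
write_fasta <- function(genome, file) {
  Biostrings::writeXStringSet(genome, file)
}

#' Read and write genome FASTA
#'
#' @param genome a [Biostrings::DNAStringSet]
#' @param file file path
#' @return `read_fasta` returns a [Biostrings::DNAStringSet]
#' @name io_fasta
#' @export
read_fasta <- function(file) {
  Biostrings::readDNAStringSet(file)
}

# ---- GFF3 ------------------------------------------------------------------

#' @rdname io_gff3
#' @export
write_gff3 <- function(models, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (t in models) {
    span <- tx_span(t)
    gff <- function(type, s0, e0, id, parent = NULL) {
      attrs <- paste0("ID=", id)
      if (!is.null(parent)) attrs <- paste0(attrs, ";Parent=", parent)
      sprintf("%s\triphewas\t%s\t%d\t%d\t.\t%s\t.\t%s",
              t$chrom, type, s0 + 1L, e0, t$strand, attrs)
    }
    lines <- c(gff("gene", span[1], span[2], t$gene_id),
               gff("mRNA", span[1], span[2], t$transcript_id, t$gene_id))
    for (k in seq_len(nrow(t$exons)))
      lines <- c(lines, gff("exon", t$exons[k, 1], t$exons[k, 2],
                            sprintf("%s.exon%d", t$transcript_id, k),
                            t$transcript_id))
    for (k in seq_len(nrow(t$cds)))
      lines <- c(lines, gff("CDS", t$cds[k, 1], t$cds[k, 2],
                            sprintf("%s.cds", t$transcript_id),
                            t$transcript_id))
    writeLines(lines, con)
  }
}

#' Read and write transcript models as GFF3
#'
#' The writer emits gene/mRNA/exon/CDS features with 1-based inclusive
#' coordinates; the reader (built on [rtracklayer::import()]) reconstructs
#' [transcript_model()] objects, converting back to the internal 0-based
#' half-open convention.
#'
#' @param models list of [transcript_model()]
#' @param file file path
#' @return `read_gff3` returns a list of [transcript_model()]
#' @name io_gff3
#' @export
read_gff3 <- function(file) {
  gr <- rtracklayer::import(file, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, "")
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  lapply(seq_len(nrow(mrna)), function(i) {
    tid <- mrna$ID[i]
    ex <- df[df$type == "exon" & df$Parent == tid, , drop = FALSE]
    cd <- df[df$type == "CDS" & df$Parent == tid, , drop = FALSE]
    iv <- function(d) {
      if (!nrow(d)) return(matrix(integer(0), 0, 2))
      unname(cbind(d$start - 1L, d$end))
    }
    transcript_model(tid, mrna$Parent[i], as.character(mrna$seqnames[i]),
                     as.character(mrna$strand[i]), iv(ex), iv(cd))
  })
}

# ---- VCF -------------------------------------------------------------------

#' @rdname io_vcf
#' @export
write_vcf <- function(variants, file, contigs = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               if (!is.null(contigs))
                 sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                         unname(contigs)),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants)) {
    ids <- variants$variant_id %||% rep(".", nrow(variants))
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.",
                       variants$chrom, variants$pos, ids, variants$ref,
                       variants$alt), con)
  }
}

#' Read and write variant tables as VCF 4.2
#'
#' The writer emits one line per biallelic variant; the reader is built on
#' [VariantAnnotation::readVcf()] and returns the first ALT allele of each
#' record. When a genome is supplied, REF alleles are checked against it and
#' a mismatch is an error naming the offending position.
#'
#' @param variants data.frame `chrom, pos, ref, alt` (+ optional `variant_id`)
#' @param file file path
#' @param contigs optional named integer vector of contig lengths for the
#'   VCF header
#' @param genome optional [Biostrings::DNAStringSet] for REF checking
#' @return `read_vcf` returns a data.frame `variant_id, chrom, pos, ref, alt`
#' @name io_vcf
#' @export
read_vcf <- function(file, genome = NULL) {
  vcf <- VariantAnnotation::readVcf(file)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- vapply(VariantAnnotation::alt(vcf),
                function(a) as.character(a)[1], "")
  out <- data.frame(
    variant_id = names(rr) %||% rep(".", length(rr)),
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(genome))
    for (i in seq_len(nrow(out)))
      check_ref(out$chrom[i], out$pos[i], out$ref[i], genome)
  out
}

# ---- BED / bedGraph --------------------------------------------------------

#' @rdname io_bed
#' @export
write_bed <- function(intervals, file) {
  df <- data.frame(chrom = intervals$chrom, start = intervals$start,
                   end = intervals$end)
  data.table::fwrite(df, file, sep = "\t", col.names = FALSE)
}

#' Read and write interval files (BED, 0-based half-open)
#'
#' Readers are built on [rtracklayer::import()]; coordinates are converted
#' between BED's 0-based half-open convention and the identical internal
#' one (so the reader subtracts 1 from the 1-based `GRanges` starts).
#'
#' @param intervals data.frame `chrom, start, end` (+ `score` for bedGraph)
#' @param file file path
#' @return readers return data.frames in the internal convention
#' @name io_bed
#' @export
read_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "bed")
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr), stringsAsFactors = FALSE)
}

#' @rdname io_bed
#' @export
write_bedgraph <- function(intervals, file) {
  df <- data.frame(chrom = intervals$chrom, start = intervals$start,
                   end = intervals$end, score = intervals$score)
  data.table::fwrite(df, file, sep = "\t", col.names = FALSE)
}

#' @rdname io_bed
#' @export
read_bedgraph <- function(file) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr), score = gr$score,
             stringsAsFactors = FALSE)
}

# per-base conservation track <-> bedGraph (one row per base)
write_conservation_track <- function(track, file) {
  write_bedgraph(data.frame(chrom = track$chrom, start = track$pos,
                            end = track$pos + 1L, score = track$score), file)
}

read_conservation_track <- function(file) {
  bg <- read_bedgraph(file)
  # expand multi-base rows back to per-base values
  n <- bg$end - bg$start
  data.frame(chrom = rep(bg$chrom, n),
             pos = unlist(Map(function(s, e) seq.int(s, e - 1L),
                              bg$start, bg$end)),
             score = rep(bg$score, n), stringsAsFactors = FALSE)
}

# ---- clinical records ------------------------------------------------------

#' @rdname io_icd
#' @export
write_icd_records <- function(records, file) {
  data.table::fwrite(records, file)
}

#' Read and write ICD records and phecode maps as CSV
#'
#' @param records data.frame `person_id, icd9, date`
#' @param map a [phecode_map()]
#' @param file,icd_file,phecode_file file paths
#' @return readers return the corresponding objects
#' @name io_icd
#' @export
read_icd_records <- function(file) {
  df <- as.data.frame(data.table::fread(file,
                                        colClasses = list(character = 1:3)))
  df
}

#' @rdname io_icd
#' @export
write_phecode_map <- function(map, icd_file, phecode_file) {
  data.table::fwrite(map$icd_map, icd_file)
  data.table::fwrite(map$phecodes, phecode_file)
}

#' @rdname io_icd
#' @export
read_phecode_map <- function(icd_file, phecode_file) {
  icd <- as.data.frame(data.table::fread(icd_file, colClasses = "character"))
  ph <- as.data.frame(data.table::fread(phecode_file, colClasses = "character",
                                        na.strings = ""))
  ph$exclusion[is.na(ph$exclusion)] <- ""
  phecode_map(icd, ph)
}
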