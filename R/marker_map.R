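#' Construct and validate a marker map
#'
#' A marker map lists genotyping markers with genetic (cM) and physical (bp)
#' coordinates. Within a chromosome, physical positions must be strictly
#' increasing and genetic positions monotone non-decreasing with them.
#'
#' @param marker_id character vector of unique marker names
#' @param chrom chromosome label per marker
#' @param pos_bp 1-based physical position (integer, >= 1)
#' @param pos_cM genetic position in centimorgans (>= 0)
#' @return a `data.frame` of class `marker_map`, ordered by (chrom, pos_bp)
#' @export
marker_map <- function(marker_id, chrom, pos_bp, pos_cM) {
  map <- data.frame(
    marker_id = as.character(marker_id),
    chrom = as.character(chrom),
    pos_bp = as.integer(pos_bp),
    pos_cM = as.numeric(pos_cM),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(map$marker_id))
    stop_fmt("duplicate marker ids: %s",
             paste(unique(map$marker_id[duplicated(map$marker_id)]), collapse = ", "))
  if (any(map$pos_bp < 1L)) stop_fmt("physical positions must be >= 1")
  if (any(map$pos_cM < 0)) stop_fmt("genetic positions must be >= 0")
  map <- map[order(map$chrom, map$pos_bp), , drop = FALSE]
  rownames(map) <- NULL
  for (ch in unique(map$chrom)) {
    sub <- map[map$chrom == ch, ]
    if (any(diff(sub$pos_bp) <= 0))
      stop_fmt("positions not strictly increasing on chromosome %s", ch)
    if (any(diff(sub$pos_cM) < 0))
      stop_fmt("cM positions not monotone with bp on chromosome %s", ch)
  }
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Generate an evenly spaced synthetic marker map
#'
#' @param n_markers total markers
#' @param n_chrom chromosomes to spread them over
#' @param chrom_length_bp physical length of each chromosome
#' @param chrom_length_cM genetic length of each chromosome
#' @param seed integer seed (marker spacing is jittered)
#' @return a [marker_map()]
#' @export
simulate_marker_map <- function(n_markers = 100, n_chrom = 2,
                                chrom_length_bp = 100e6,
                                chrom_length_cM = 80, seed = 1) {
  set.seed(seed)
  per <- diff(round(seq(0, n_markers, length.out = n_chrom + 1)))
  out <- list()
  for (i in seq_len(n_chrom)) {
    m <- per[i]
    if (m == 0) next
    bp <- sort(sample.int(chrom_length_bp - 1L, m)) + 1L
    cM <- (bp - 1) / chrom_length_bp * chrom_length_cM
    out[[i]] <- data.frame(
      marker_id = sprintf("chr%d_mk%03d", i, seq_len(m)),
      chrom = paste0("chr", i), pos_bp = bp, pos_cM = cM,
      stringsAsFactors = FALSE
    )
  }
  all <- do.call(rbind, out)
  marker_map(all$marker_id, all$chrom, all$pos_bp, all$pos_cM)
}
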