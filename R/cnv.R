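#' Construct a windowed read-depth track
#'
#' @param counts non-negative integer read counts per consecutive window
#' @param chrom chromosome label
#' @param window_size window width in bp (default 100)
#' @param mask logical per window; `TRUE` marks excluded windows (assembly
#'   gaps) that never receive a test
#' @return object of class `depth_track`
#' @export
depth_track <- function(counts, chrom = "chr1", window_size = 100L,
                        mask = NULL) {
  if (any(counts < 0, na.rm = TRUE)) stop_fmt("negative window counts")
  mask <- mask %||% rep(FALSE, length(counts))
  stopifnot(length(mask) == length(counts))
  structure(list(chrom = chrom, window_size = as.integer(window_size),
                 counts = as.numeric(counts), mask = mask),
            class = "depth_track")
}

#' Simulate a windowed depth track with planted copy-number events
#'
#' Window counts are Poisson with mean `depth_mean * copy_ratio / 2`
#' (copy ratio 2 is the diploid baseline), so a copy ratio of 8 yields a
#' four-fold coverage gain over flanking sequence and copy ratio 0 a
#' homozygous loss.
#'
#' @param genome_length track length in bp
#' @param depth_mean expected count per window at the diploid baseline
#' @param cnv_spec data.frame `start,end,copy_ratio` (bp coordinates,
#'   half-open; ratios > 0, or 0 for a full deletion); may be empty
#' @param window_size window width in bp
#' @param seed integer seed
#' @return a [depth_track()]
#' @export
simulate_depth_track <- function(genome_length, depth_mean = 30,
                                 cnv_spec = NULL, window_size = 100L,
                                 seed = 1) {
  set.seed(seed)
  n <- genome_length %/% window_size
  ratio <- rep(2, n)
  if (!is.null(cnv_spec) && nrow(cnv_spec)) {
    if (any(cnv_spec$copy_ratio < 0)) stop_fmt("copy_ratio must be >= 0")
    for (i in seq_len(nrow(cnv_spec))) {
      w0 <- cnv_spec$start[i] %/% window_size + 1L
      w1 <- max(w0, cnv_spec$end[i] %/% window_size)
      if (w0 > n) next
      ratio[w0:min(w1, n)] <- cnv_spec$copy_ratio[i]
    }
  }
  depth_track(rpois(n, depth_mean * ratio / 2), window_size = window_size)
}

#' Normalize window depths and compute per-window tail probabilities
#'
#' The baseline is the median of unmasked window counts and the dispersion a
#' MAD-derived standard deviation, both robust to contamination by the CNVs
#' being sought. Each unmasked window gets a Gaussian upper-tail p (gain
#' evidence) and lower-tail p (loss evidence); log-scale values are kept for
#' downstream combination.
#'
#' @param track a [depth_track()]
#' @return list with `baseline`, `sigma`, `z`, `log_p_upper`, `log_p_lower`
#'   (masked windows are `NA`)
#' @export
normalize_windows <- function(track) {
  stopifnot(inherits(track, "depth_track"))
  use <- !track$mask
  if (sum(use) < 100)
    stop_fmt("need >= 100 unmasked windows for a reliable baseline (have %d)",
             sum(use))
  baseline <- median(track$counts[use])
  sigma <- mad(track$counts[use])
  if (sigma == 0) sigma <- sqrt(max(baseline, 1))  # Poisson fallback
  z <- (track$counts - baseline) / sigma
  z[!use] <- NA_real_
  list(baseline = baseline, sigma = sigma, z = z,
       log_p_upper = pnorm(z, lower.tail = FALSE, log.p = TRUE),
       log_p_lower = pnorm(z, log.p = TRUE))
}

# maximal runs of TRUE in a logical vector (NA breaks runs)
runs_of <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# boundary refinement: drop edge windows whose count sits closer to the
# baseline than to the event mean, so runs formed at the permissive
# per-window threshold do not drag flanking noise into the call
trim_run <- function(counts, i0, i1, baseline) {
  repeat {
    if (i0 > i1) break
    m <- mean(counts[i0:i1])
    changed <- FALSE
    if (i0 <= i1 &&
        abs(counts[i0] - baseline) < abs(counts[i0] - m)) {
      i0 <- i0 + 1L; changed <- TRUE
    }
    if (i0 <= i1 &&
        abs(counts[i1] - baseline) < abs(counts[i1] - m)) {
      i1 <- i1 - 1L; changed <- TRUE
    }
    if (!changed) break
  }
  c(i0, i1)
}

#' Event-wise scan for copy-number gains and losses
#'
#' Windows individually significant at `alpha^(1/min_consec)` per tail form
#' maximal same-direction runs; run edges are then refined by trimming
#' windows whose depth sits closer to the baseline than to the event mean.
#' The event significance is Fisher's combination of the member windows'
#' tail probabilities, and events failing the minimum run length, minimum
#' size or the event-level significance are discarded. The per-window
#' threshold is chosen so that a minimal qualifying run meets the
#' event-level `alpha`.
#'
#' @param track a [depth_track()]
#' @param alpha event-level significance (default 1e-6)
#' @param min_consec minimum consecutive windows per event (default 10)
#' @param min_bp minimum event size in bp (default 1000)
#' @return data.frame of calls: `chrom,start,end,type,n_windows,mean_ratio,
#'   event_p` (coordinates 0-based half-open in bp)
#' @export
ewt_scan <- function(track, alpha = 1e-6, min_consec = 10L, min_bp = 1000L) {
  nz <- normalize_windows(track)
  log_thresh <- log(alpha) / min_consec
  ws <- track$window_size
  calls <- list()
  for (type in c("gain", "loss")) {
    lp <- if (type == "gain") nz$log_p_upper else nz$log_p_lower
    rr <- runs_of(lp < log_thresh)
    for (k in seq_len(nrow(rr))) {
      tt <- trim_run(track$counts, rr[k, 1], rr[k, 2], nz$baseline)
      i0 <- tt[1]; i1 <- tt[2]
      if (i0 > i1) next
      nw <- i1 - i0 + 1L
      bp <- nw * ws
      if (nw < min_consec || bp < min_bp) next
      # Fisher's method on member-window tail probabilities
      stat <- -2 * sum(lp[i0:i1])
      event_p <- pchisq(stat, df = 2 * nw, lower.tail = FALSE)
      event_p <- max(event_p, .Machine$double.xmin)
      if (event_p > alpha) next
      mean_ratio <- mean(track$counts[i0:i1]) / nz$baseline
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = track$chrom, start = (i0 - 1L) * ws, end = i1 * ws,
        type = type, n_windows = nw, mean_ratio = mean_ratio,
        event_p = event_p, stringsAsFactors = FALSE)
    }
  }
  if (!length(calls))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), type = character(0),
                      n_windows = integer(0), mean_ratio = numeric(0),
                      event_p = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify an event as gain or loss from its depth ratio
#'
#' @param mean_ratio observed/baseline depth ratio of the merged event
#' @return `"gain"` if the ratio exceeds 1, `"loss"` below 1
#' @export
classify_gain_loss <- function(mean_ratio) {
  if (mean_ratio == 1)
    stop_fmt("ratio exactly 1 cannot survive the significance filter")
  if (mean_ratio > 1) "gain" else "loss"
}
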