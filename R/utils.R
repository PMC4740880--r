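#' Derive a reproducible sub-seed from a master seed
#'
#' Stage-level randomness is driven by sub-seeds derived deterministically
#' from one master seed, so stages can be re-run in isolation without
#' replaying the whole stream.
#'
#' @param seed master integer seed
#' @param k stream index (1-based) or a character stream label
#' @return an integer seed in `[0, 2^31 - 1)`
#' @export
derive_seed <- function(seed, k) {
  if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  # multiplicative hash mod a prime below 2^31; keeps results in int range
  p <- 2147483629
  as.integer((abs(seed) %% p * 48271 + k * 69621) %% p)
}

# Haldane map function: cM distance -> recombination fraction
haldane_r <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

# RI-by-sib-mating map expansion: one-meiosis r -> fixed-strain discordance
ri_expansion <- function(r) 4 * r / (1 + 6 * r)

# coordinate conversions; internal convention is 0-based half-open
to_vcf_pos <- function(start0) start0 + 1L
from_vcf_pos <- function(pos1) pos1 - 1L
to_gff_interval <- function(start0, end0) c(start0 + 1L, end0)
from_gff_interval <- function(start1, end1) c(start1 - 1L, end1)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
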