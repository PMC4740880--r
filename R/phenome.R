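#' The controlled vocabulary of broad phenotype categories
#'
#' Fifteen broad phenotypic categories used to organize a mouse phenome
#' (for example central nervous system, immune system, metabolism).
#'
#' @return character vector of length 15
#' @export
phenome_categories <- function() {
  c("behavior", "blood chemistry", "cancer biology",
    "cardiovascular system", "central nervous system", "development",
    "endocrine system", "immune system", "metabolism",
    "morphology", "musculoskeletal system", "nervous system pharmacology",
    "reproductive system", "respiratory system", "toxicology")
}

#' Construct a strain-by-trait phenome table
#'
#' @param values numeric matrix, strains in rows, traits in columns; missing
#'   values are `NA`
#' @param meta data.frame with columns `trait_id`, `category` and optionally
#'   `tissue` (for molecular endophenotypes); row per trait, matching columns
#'   of `values`
#' @return an object of class `phenome_table`
#' @export
phenome_table <- function(values, meta) {
  stopifnot(is.matrix(values), is.data.frame(meta))
  if (!identical(colnames(values), meta$trait_id))
    stop_fmt("trait columns must match metadata order")
  if (is.null(rownames(values)))
    stop_fmt("phenome needs strain rownames")
  all_na <- colSums(!is.na(values)) == 0
  if (any(all_na)) {
    warning(sprintf("dropping %d trait(s) with no data", sum(all_na)))
    values <- values[, !all_na, drop = FALSE]
    meta <- meta[!all_na, , drop = FALSE]
  }
  structure(list(values = values, meta = meta), class = "phenome_table")
}

#' @export
print.phenome_table <- function(x, ...) {
  cat(sprintf("phenome_table: %d strains x %d traits (%d categories)\n",
              nrow(x$values), ncol(x$values), length(unique(x$meta$category))))
  invisible(x)
}

#' Simulate a phenome with planted marker effects
#'
#' Each trait is `b * genotype + e`, with `b` and the Gaussian noise variance
#' scaled so that the planted marker explains `effect_fraction` of the trait
#' variance in expectation (computed against the realized genotype variance
#' in the panel). Traits without a planted marker are pure noise. Missing
#' values are inserted completely at random.
#'
#' @param geno a [genotype_matrix()]
#' @param trait_spec data.frame with columns `trait_id`, `marker_id`
#'   (NA for null traits), `effect_fraction` in `[0, 1]`
#' @param missing_rate probability in `[0, 1)` that a cell is set missing
#' @param seed integer seed
#' @return a [phenome_table()]; trait categories are drawn from
#'   [phenome_categories()]
#' @export
simulate_phenome <- function(geno, trait_spec, missing_rate = 0, seed = 1) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (missing_rate < 0 || missing_rate >= 1)
    stop_fmt("missing_rate must be in [0, 1)")
  if (any(trait_spec$effect_fraction < 0 | trait_spec$effect_fraction > 1))
    stop_fmt("effect_fraction must lie in [0, 1]")
  planted <- trait_spec$marker_id[!is.na(trait_spec$marker_id)]
  unknown <- setdiff(planted, geno$map$marker_id)
  if (length(unknown))
    stop_fmt("planted markers not in map: %s", paste(unknown, collapse = ", "))
  set.seed(seed)
  n <- nrow(geno$codes)
  k <- nrow(trait_spec)
  vals <- matrix(NA_real_, n, k,
                 dimnames = list(rownames(geno$codes), trait_spec$trait_id))
  for (j in seq_len(k)) {
    f <- trait_spec$effect_fraction[j]
    mk <- trait_spec$marker_id[j]
    if (is.na(mk) || f == 0) {
      vals[, j] <- rnorm(n)
    } else {
      g <- geno$codes[, mk]
      vg <- var(g, na.rm = TRUE)
      if (!is.finite(vg) || vg == 0)
        stop_fmt("planted marker %s is monomorphic in this panel", mk)
      noise_sd <- if (f >= 1) 0 else sqrt(vg * (1 - f) / f)
      vals[, j] <- g + rnorm(n, sd = noise_sd)
    }
  }
  if (missing_rate > 0) {
    drop <- matrix(runif(n * k) < missing_rate, n, k)
    vals[drop] <- NA_real_
  }
  meta <- data.frame(
    trait_id = trait_spec$trait_id,
    category = sample(phenome_categories(), k, replace = TRUE),
    stringsAsFactors = FALSE
  )
  phenome_table(vals, meta)
}
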