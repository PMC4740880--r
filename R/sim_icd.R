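#' A small synthetic phecode map
#'
#' A hand-built stand-in for a clinical phecode table: a handful of
#' hierarchical phecodes, two ICD9 codes each, and a reciprocal
#' control-exclusion pair to exercise the exclusion logic. Entirely
#' synthetic; no real phecode table is bundled.
#'
#' @return a [phecode_map()]
#' @export
synthetic_phecode_map <- function() {
  phecodes <- data.frame(
    phecode = c("008", "249", "250", "250.1", "250.2", "401", "555",
                "555.1", "555.2"),
    parent = c(NA, NA, NA, "250", "250", NA, NA, "555", "555"),
    exclusion = c("", "250", "249", "249", "249", "", "", "", ""),
    stringsAsFactors = FALSE)
  icd <- do.call(rbind, lapply(phecodes$phecode, function(ph)
    data.frame(icd9 = paste0("ICD", ph, c("a", "b")), phecode = ph,
               stringsAsFactors = FALSE)))
  phecode_map(icd, phecodes)
}

#' Simulate an ICD-coded cohort with one planted genotype effect
#'
#' Generates an additive genotype at the stated minor allele frequency,
#' age/sex/three principal-component covariates, and per-person ICD code
#' lists. Disease liability for the planted phecode follows a logistic
#' model with the stated odds ratio per allele (plus small age and sex
#' effects); other leaf phecodes occur as genotype-independent background.
#' Affected individuals receive codes on at least two distinct dates with
#' probability `two_code_fraction` and exactly one otherwise, so the
#' two-code case rule is exercised.
#'
#' @param n_individuals cohort size
#' @param map a [phecode_map()] (default [synthetic_phecode_map()])
#' @param maf planted SNP minor allele frequency
#' @param odds_ratio per-allele odds ratio on the planted phecode
#' @param phecode the planted phecode (must map from some ICD code)
#' @param baseline_prev baseline prevalence of the planted phecode
#' @param background_prev per-phecode prevalence of background diagnoses
#' @param two_code_fraction probability an affected person gets >= 2
#'   distinct-date codes
#' @param seed integer seed
#' @return list with `records` (person_id, icd9, date), `genotype` (named
#'   0/1/2 vector), `covariates` (age, sex, PC1-PC3), `persons`, `truth`
#' @export
simulate_icd_cohort <- function(n_individuals, map = synthetic_phecode_map(),
                                maf = 0.3, odds_ratio = 2,
                                phecode = "250.1", baseline_prev = 0.10,
                                background_prev = 0.05,
                                two_code_fraction = 0.9, seed = 1) {
  stopifnot(phecode %in% map$phecodes$phecode)
  set.seed(seed)
  persons <- sprintf("P%05d", seq_len(n_individuals))
  g <- rbinom(n_individuals, 2, maf)
  names(g) <- persons
  covars <- data.frame(
    age = round(rnorm(n_individuals, 55, 10), 1),
    sex = rbinom(n_individuals, 1, 0.5),
    PC1 = rnorm(n_individuals), PC2 = rnorm(n_individuals),
    PC3 = rnorm(n_individuals))
  rownames(covars) <- persons
  eta <- qlogis(baseline_prev) + log(odds_ratio) * g +
    0.01 * (covars$age - 55) + 0.2 * covars$sex
  affected <- runif(n_individuals) < plogis(eta)
  icd_for <- function(ph) map$icd_map$icd9[map$icd_map$phecode == ph]
  dates <- format(as.Date("2000-01-01") + 0:3652)
  recs <- list()
  emit <- function(pid, ph) {
    k <- if (runif(1) < two_code_fraction) 2L + rpois(1, 0.7) else 1L
    d <- sample(dates, k)
    recs[[length(recs) + 1L]] <<- data.frame(
      person_id = pid, icd9 = sample(icd_for(ph), k, replace = TRUE),
      date = d, stringsAsFactors = FALSE)
  }
  for (i in which(affected)) emit(persons[i], phecode)
  leaves <- setdiff(map$phecodes$phecode,
                    c(na.omit(map$phecodes$parent), phecode))
  for (ph in leaves) {
    hit <- which(runif(n_individuals) < background_prev)
    for (i in hit) emit(persons[i], ph)
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(person_id = character(0), icd9 = character(0),
               date = character(0))
  list(records = records, genotype = g, covariates = covars,
       persons = persons,
       truth = list(phecode = phecode, maf = maf, odds_ratio = odds_ratio,
                    two_code_fraction = two_code_fraction,
                    n_affected = sum(affected)))
}
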