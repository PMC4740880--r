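#' Construct a phecode map
#'
#' Maps ICD9 billing codes to hierarchical phecodes. Child-phecode cases
#' count toward their parents. Each phecode may carry a control-exclusion
#' set: people with any code in that set are not eligible controls.
#'
#' @param icd_map data.frame `icd9, phecode`
#' @param phecodes data.frame `phecode, parent, exclusion`; `parent` is `NA`
#'   for roots, `exclusion` a comma-separated list of phecodes (may be "")
#' @return object of class `phecode_map`
#' @export
phecode_map <- function(icd_map, phecodes) {
  stopifnot(all(c("icd9", "phecode") %in% names(icd_map)),
            all(c("phecode", "parent", "exclusion") %in% names(phecodes)))
  if (anyDuplicated(phecodes$phecode)) stop_fmt("duplicate phecodes")
  unknown <- setdiff(icd_map$phecode, phecodes$phecode)
  if (length(unknown))
    stop_fmt("icd map references unknown phecodes: %s",
             paste(unknown, collapse = ", "))
  # cycle check by repeated parent-following
  for (ph in phecodes$phecode) {
    seen <- character(0); cur <- ph
    while (!is.na(cur)) {
      if (cur %in% seen) stop_fmt("phecode hierarchy contains a cycle at %s", ph)
      seen <- c(seen, cur)
      cur <- phecodes$parent[match(cur, phecodes$phecode)]
    }
  }
  structure(list(icd_map = icd_map, phecodes = phecodes),
            class = "phecode_map")
}

# phecode -> itself plus all transitive children
phecode_descendants <- function(map) {
  ph <- map$phecodes
  desc <- setNames(as.list(ph$phecode), ph$phecode)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(ph))) {
      par <- ph$parent[i]
      if (is.na(par)) next
      add <- setdiff(desc[[ph$phecode[i]]], desc[[par]])
      if (length(add)) { desc[[par]] <- c(desc[[par]], add); changed <- TRUE }
    }
    if (!changed) break
  }
  desc
}

#' Assign case/control/excluded status per person and phecode
#'
#' A person is a case for a phecode with at least `min_code_count` mapped
#' code instances on distinct dates (instances of descendant phecodes count
#' toward the parent), excluded with exactly one, and a control with none --
#' unless they carry any code in the phecode's control-exclusion set, which
#' also excludes them. Unmapped ICD codes are ignored and counted.
#'
#' @param records data.frame `person_id, icd9, date`
#' @param map a [phecode_map()]
#' @param min_code_count distinct-date instances required for a case
#' @param persons optional person universe (ids without any record are
#'   controls everywhere)
#' @return character matrix persons x phecodes with values `case`,
#'   `control`, `excluded`; the number of unmapped records is attached as
#'   attribute `n_unmapped`
#' @export
assign_case_control <- function(records, map, min_code_count = 2L,
                                persons = NULL) {
  stopifnot(inherits(map, "phecode_map"))
  persons <- persons %||% sort(unique(records$person_id))
  records$phecode <- map$icd_map$phecode[match(records$icd9, map$icd_map$icd9)]
  n_unmapped <- sum(is.na(records$phecode))
  rec <- records[!is.na(records$phecode), , drop = FALSE]
  desc <- phecode_descendants(map)
  phs <- map$phecodes$phecode
  status <- matrix("control", length(persons), length(phs),
                   dimnames = list(persons, phs))
  # distinct (person, phecode, date) instances
  inst <- unique(rec[, c("person_id", "phecode", "date")])
  for (ph in phs) {
    sub <- inst[inst$phecode %in% desc[[ph]], , drop = FALSE]
    cnt <- table(unique(sub[, c("person_id", "date")])$person_id)
    cases <- names(cnt)[cnt >= min_code_count]
    ones <- names(cnt)[cnt > 0 & cnt < min_code_count]
    status[intersect(cases, persons), ph] <- "case"
    status[intersect(ones, persons), ph] <- "excluded"
    excl <- map$phecodes$exclusion[match(ph, map$phecodes$phecode)]
    if (!is.na(excl) && nzchar(excl)) {
      excl_ph <- unlist(lapply(strsplit(excl, ",")[[1]], function(e)
        desc[[trimws(e)]] %||% trimws(e)))
      carriers <- unique(inst$person_id[inst$phecode %in% excl_ph])
      hit <- intersect(carriers, persons)
      hit <- hit[status[hit, ph] == "control"]
      status[hit, ph] <- "excluded"
    }
  }
  attr(status, "n_unmapped") <- n_unmapped
  status
}

#' Retain phecodes with enough cases for analysis
#'
#' @param status matrix from [assign_case_control()]
#' @param min_individuals minimum case count (default 20)
#' @return character vector of retained phecodes
#' @export
filter_phenotypes <- function(status, min_individuals = 20L) {
  n_case <- colSums(status == "case")
  colnames(status)[n_case >= min_individuals]
}

#' SNP and sample quality control
#'
#' Samples with call rate at or below `sample_cr` are removed first; SNP
#' call rate and minor allele frequency are then computed on the retained
#' samples. All comparisons are strict.
#'
#' @param genotypes numeric matrix persons x SNPs with additive codes
#'   0/1/2 and `NA` for missing calls
#' @param maf_min strict lower MAF bound (default 0.01)
#' @param snp_cr strict lower SNP call-rate bound (default 0.95)
#' @param sample_cr strict lower sample call-rate bound (default 0.99)
#' @return list with `samples` (retained ids) and `snps` (data.frame
#'   `snp, call_rate, maf, pass`)
#' @export
snp_qc <- function(genotypes, maf_min = 0.01, snp_cr = 0.95,
                   sample_cr = 0.99) {
  stopifnot(is.matrix(genotypes))
  s_rate <- rowMeans(!is.na(genotypes))
  samples <- rownames(genotypes)[s_rate > sample_cr]
  gm <- genotypes[samples, , drop = FALSE]
  call_rate <- colMeans(!is.na(gm))
  af <- colMeans(gm, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  snps <- data.frame(snp = colnames(gm), call_rate = call_rate, maf = maf,
                     pass = call_rate > snp_cr & maf > maf_min,
                     stringsAsFactors = FALSE)
  rownames(snps) <- NULL
  list(samples = samples, snps = snps)
}

# IRLS for logistic regression; returns coefficients, s.e., diagnostics
fit_logistic_irls <- function(X, y, tol = 1e-8, max_iter = 25L) {
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    new_beta <- tryCatch(solve(XtW %*% X, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(new_beta)) break
    new_beta <- drop(new_beta)
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta; converged <- TRUE; break
    }
    beta <- new_beta
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  cov_beta <- tryCatch(solve(t(X * w) %*% X), error = function(e) NULL)
  se <- if (is.null(cov_beta)) rep(NA_real_, length(beta)) else
    sqrt(diag(cov_beta))
  separated <- any(abs(beta) > 20) ||
    (all(mu[y == 1] > 0.9999) && all(mu[y == 0] < 1e-4))
  list(beta = beta, se = se, converged = converged, separated = separated)
}

#' Additive logistic PheWAS scan of one SNP
#'
#' Fits, per phecode, a logistic regression of case status on the additive
#' genotype plus covariates by iteratively reweighted least squares
#' (tolerance 1e-8, at most 25 iterations) and reports the two-tailed Wald
#' p-value of the genotype term. Non-convergence or separation is flagged
#' with no p-value; phecodes whose genotype is monomorphic among the
#' analyzed individuals are skipped.
#'
#' @param g named additive genotype vector (0/1/2)
#' @param status matrix from [assign_case_control()] (excluded people are
#'   dropped per phecode)
#' @param covariates data.frame with rownames matching persons (e.g. age,
#'   sex, PC1-PC3); may be `NULL`
#' @param phecodes phecodes to scan (default: all columns of `status`)
#' @return data.frame `phecode, n_case, n_control, beta, or, se, p, status`
#' @export
logistic_scan <- function(g, status, covariates = NULL, phecodes = NULL) {
  phecodes <- phecodes %||% colnames(status)
  persons <- rownames(status)
  stopifnot(!is.null(names(g)), all(persons %in% names(g)))
  res <- lapply(phecodes, function(ph) {
    st <- status[, ph]
    use <- persons[st != "excluded" & !is.na(g[persons])]
    y <- as.integer(status[use, ph] == "case")
    gg <- g[use]
    row <- data.frame(phecode = ph, n_case = sum(y), n_control = sum(1 - y),
                      beta = NA_real_, or = NA_real_, se = NA_real_,
                      p = NA_real_, status = "ok", stringsAsFactors = FALSE)
    if (length(unique(gg)) < 2) { row$status <- "monomorphic"; return(row) }
    if (sum(y) == 0 || sum(y) == length(y)) {
      row$status <- "no_cases_or_controls"; return(row)
    }
    X <- cbind(intercept = 1, genotype = gg)
    if (!is.null(covariates))
      X <- cbind(X, as.matrix(covariates[use, , drop = FALSE]))
    fit <- fit_logistic_irls(X, y)
    if (!fit$converged || fit$separated) {
      row$status <- "no_convergence_or_separation"; return(row)
    }
    b <- fit$beta[2]; se <- fit$se[2]
    row$beta <- b; row$or <- exp(b); row$se <- se
    row$p <- 2 * pnorm(abs(b / se), lower.tail = FALSE)
    row
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate (default 0.05)
#' @param m number of phenotypes tested
#' @return per-test threshold `alpha / m`
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop_fmt("m must be >= 1")
  alpha / m
}
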