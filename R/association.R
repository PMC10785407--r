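#' Per-SNP genotype call rate
#'
#' @param cohort a [SnpCohort-class].
#' @param snp_id one or more SNP ids in the panel.
#' @return Named numeric vector of call rates in `[0, 1]`.
#' @export
callRate <- function(cohort, snp_id = NULL) {
  g <- genotypes(cohort)
  if (is.null(snp_id)) snp_id <- rownames(g)
  unknown <- setdiff(snp_id, rownames(g))
  if (length(unknown))
    stop("unknown SNP(s): ", paste(unknown, collapse = ", "))
  rowMeans(!is.na(g[snp_id, , drop = FALSE]))
}

#' Pearson chi-square test of Hardy-Weinberg equilibrium
#'
#' Compares observed genotype counts with the expectations `p^2`, `2pq`,
#' `q^2` computed from the estimated allele frequency (1 df).  A
#' monomorphic SNP (allele frequency 0 or 1) is returned as `chi2 = 0`,
#' `p = 1` with `monomorphic = TRUE`.
#'
#' @param n_AA,n_AB,n_BB genotype counts.
#' @return List with `chi2`, `p`, `monomorphic`.
#' @examples
#' hweTest(25, 50, 25)  # chi2 0, p 1
#' hweTest(30, 40, 30)  # chi2 4, p ~0.0455
#' @export
hweTest <- function(n_AA, n_AB, n_BB) {
  counts <- c(n_AA, n_AB, n_BB)
  if (any(counts < 0) || sum(counts) == 0)
    stop("genotype counts must be non-negative with positive total")
  n <- sum(counts)
  p <- (2 * n_AA + n_AB) / (2 * n)  # wild-allele frequency
  if (p == 0 || p == 1)
    return(list(chi2 = 0, p = 1, monomorphic = TRUE))
  expect <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((counts - expect)^2 / expect)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       monomorphic = FALSE)
}

genotypeCounts <- function(calls) {
  c(n_AA = sum(calls == "AA", na.rm = TRUE),
    n_AB = sum(calls == "AB", na.rm = TRUE),
    n_BB = sum(calls == "BB", na.rm = TRUE))
}

#' SNP quality-control filter
#'
#' Excludes SNPs whose call rate falls below `call_rate_min` or whose
#' control-group genotypes deviate from Hardy-Weinberg equilibrium at
#' `hwe_alpha` (HWE is tested in controls only).  The default combines the
#' two criteria with OR (failing either excludes the SNP); `combine =
#' "and"` requires both to fail.
#'
#' @param cohort a [SnpCohort-class] with at least one control.
#' @param call_rate_min minimum call rate (default 0.90).
#' @param hwe_alpha HWE significance cutoff in controls (default 0.01).
#' @param combine `"or"` (default) or `"and"`.
#' @return List with `kept` (character vector of SNP ids) and `log`
#'   (`data.frame` of per-SNP call rate, control-HWE p, flags and reason).
#' @export
qcFilter <- function(cohort, call_rate_min = 0.90, hwe_alpha = 0.01,
                     combine = c("or", "and")) {
  combine <- match.arg(combine)
  if (nControls(cohort) == 0)
    stop("cohort has no controls; HWE cannot be tested")
  cr <- callRate(cohort)
  ctrl <- genotypes(cohort)[, caseStatus(cohort) == "control", drop = FALSE]
  hwe <- apply(ctrl, 1L, function(calls) {
    cc <- genotypeCounts(calls)
    if (sum(cc) == 0) return(NA_real_)
    hweTest(cc[1], cc[2], cc[3])$p
  })
  fail_cr <- cr < call_rate_min
  fail_hwe <- !is.na(hwe) & hwe < hwe_alpha
  excluded <- if (combine == "or") fail_cr | fail_hwe else fail_cr & fail_hwe
  reason <- rep("", length(cr))
  reason[excluded] <- vapply(which(excluded), function(i)
    paste(c("call_rate"[fail_cr[i]], "hwe"[fail_hwe[i]]), collapse = "+"),
    character(1))
  log <- data.frame(snp_id = names(cr), call_rate = unname(cr),
                    hwe_p_controls = unname(hwe),
                    fail_call_rate = unname(fail_cr),
                    fail_hwe = unname(fail_hwe),
                    excluded = unname(excluded), reason = reason,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(kept = names(cr)[!excluded], log = log)
}

#' Encode genotype calls under a genetic model
#'
#' Dichotomizes the three genotypes per model: `recessive` exposes `BB`;
#' `dominant` exposes variant carriers (`AB`/`BB`); `super_dominant`
#' (overdominant) exposes `AB`; `homozygote` exposes `BB`, takes `AA` as
#' unexposed and excludes `AB`.  The `additive` and `allele` models return
#' the variant-allele count 0/1/2 instead of a binary state (`additive` as
#' a regression dosage, `allele` consumed as per-subject allele
#' contributions by [contingency2x2()]).
#'
#' @param calls character vector of calls `AA`/`AB`/`BB` (no missing).
#' @param model one of `"recessive"`, `"dominant"`, `"super_dominant"`,
#'   `"homozygote"`, `"additive"`, `"allele"`.
#' @return Factor with levels `unexposed`, `exposed`, `excluded` for the
#'   binary models; integer 0/1/2 for `additive`/`allele`.
#' @export
encodeGeneticModel <- function(calls, model) {
  model <- matchModel(model)
  if (anyNA(calls))
    stop("missing genotype calls must be filtered before encoding")
  if (!all(calls %in% GENOTYPE_LEVELS))
    stop("invalid genotype calls")
  if (model %in% c("additive", "allele"))
    return(c(AA = 0L, AB = 1L, BB = 2L)[calls])
  enc <- switch(model,
    recessive      = ifelse(calls == "BB", "exposed", "unexposed"),
    dominant       = ifelse(calls == "AA", "unexposed", "exposed"),
    super_dominant = ifelse(calls == "AB", "exposed", "unexposed"),
    homozygote     = ifelse(calls == "BB", "exposed",
                            ifelse(calls == "AA", "unexposed", "excluded")))
  factor(enc, levels = c("unexposed", "exposed", "excluded"))
}

#' Case-control 2x2 contingency table for a SNP under a genetic model
#'
#' Counts cases/controls by exposure after dropping missing calls and
#' model-excluded subjects.  The `allele` model counts alleles (each
#' subject contributes two) with the variant allele as exposure; the
#' `additive` model has no 2x2 reduction and is rejected here.
#'
#' @param cohort a [SnpCohort-class].
#' @param snp_id SNP id.
#' @param model genetic model name (not `"additive"`).
#' @return A list of class `ContingencyTable2x2` with counts `a` (cases
#'   exposed), `b` (controls exposed), `c` (cases unexposed), `d`
#'   (controls unexposed), plus `level` (`"person"`/`"allele"`) and
#'   `n_used` (subjects contributing).
#' @export
contingency2x2 <- function(cohort, snp_id, model) {
  model <- matchModel(model)
  if (model == "additive")
    stop("the additive model is a dosage, not a 2x2 table; use snpAssociation")
  status <- caseStatus(cohort)
  keep <- status %in% c("case", "control")
  calls <- genotypes(cohort)[snp_id, keep]
  status <- status[keep]
  ok <- !is.na(calls)
  calls <- calls[ok]; status <- status[ok]
  if (model == "allele") {
    dose <- encodeGeneticModel(calls, "allele")
    a <- sum(dose[status == "case"])
    b <- sum(dose[status == "control"])
    cc <- 2 * sum(status == "case") - a
    d <- 2 * sum(status == "control") - b
    n_used <- length(calls)
    level <- "allele"
  } else {
    enc <- encodeGeneticModel(calls, model)
    use <- enc != "excluded"
    enc <- enc[use]; st <- status[use]
    a <- sum(st == "case" & enc == "exposed")
    b <- sum(st == "control" & enc == "exposed")
    cc <- sum(st == "case" & enc == "unexposed")
    d <- sum(st == "control" & enc == "unexposed")
    n_used <- sum(use)
    level <- "person"
  }
  contingencyTable2x2(a, b, cc, d, level = level, n_used = n_used)
}

#' Build a 2x2 case-control table from counts
#'
#' @param a,b,c,d cases exposed, controls exposed, cases unexposed and
#'   controls unexposed.
#' @param level `"person"` or `"allele"` counting.
#' @param n_used subjects contributing (defaults to the table total).
#' @return A `ContingencyTable2x2` list.
#' @export
contingencyTable2x2 <- function(a, b, c, d, level = "person", n_used = NULL) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("2x2 counts must be non-negative integers")
  structure(list(a = a, b = b, c = c, d = d, level = level,
                 n_used = if (is.null(n_used)) a + b + c + d else n_used),
            class = "ContingencyTable2x2")
}

#' @export
print.ContingencyTable2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("exposed", "unexposed"),
                              c("case", "control")))
  cat(sprintf("2x2 table (%s level, n_used = %d)\n", x$level, x$n_used))
  print(m)
  invisible(x)
}

#' Crude odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio `OR = a*d / (b*c)` with the Woolf (log-scale
#' Wald) 95% interval `exp(log OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`
#' and a Wald p-value.  When any cell is zero, the Haldane-Anscombe
#' continuity correction adds `cc` to all four cells and the result is
#' flagged `corrected`.
#'
#' @param table a `ContingencyTable2x2`, or the count `a` with `b`, `c`,
#'   `d` supplied.
#' @param b,c,d counts when `table` is given as a scalar `a`.
#' @param cc continuity correction added to every cell when a cell is 0.
#' @param conf confidence level (default 0.95).
#' @return List with `or`, `ci_low`, `ci_high`, `p`, `log_or`, `se`,
#'   `corrected`.
#' @examples
#' oddsRatioWoolf(105, 112, 48, 140)$or  # 2.734
#' @export
oddsRatioWoolf <- function(table, b = NULL, c = NULL, d = NULL, cc = 0.5,
                           conf = 0.95) {
  if (inherits(table, "ContingencyTable2x2")) {
    a <- table$a; b <- table$b; c <- table$c; d <- table$d
  } else {
    a <- table
  }
  if (a + c == 0) stop("no cases in the table")
  if (b + d == 0) stop("no controls in the table")
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    a <- a + cc; b <- b + cc; c <- c + cc; d <- d + cc
  }
  log_or <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - conf) / 2)
  list(or = exp(log_or),
       ci_low = exp(log_or - z * se),
       ci_high = exp(log_or + z * se),
       p = 2 * pnorm(-abs(log_or / se)),
       log_or = log_or, se = se, corrected = corrected)
}

#' Pearson chi-square test for a 2x2 table
#'
#' @param table a `ContingencyTable2x2` (or scalar `a` with `b`, `c`, `d`).
#' @param b,c,d counts when `table` is a scalar.
#' @param correct apply the Yates continuity correction (default `FALSE`).
#' @return List with `chi2`, `p` and `small_expected` (any expected cell
#'   below 1).
#' @export
chiSquare2x2 <- function(table, b = NULL, c = NULL, d = NULL,
                         correct = FALSE) {
  if (inherits(table, "ContingencyTable2x2")) {
    a <- table$a; b <- table$b; c <- table$c; d <- table$d
  } else {
    a <- table
  }
  n <- a + b + c + d
  e <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  small <- any(e < 1)
  if (small)
    warning("expected cell count below 1; chi-square approximation unreliable")
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - n / 2)
  chi2 <- n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  if (!is.finite(chi2)) chi2 <- 0
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE),
       small_expected = small)
}

#' Maximum-likelihood logistic regression
#'
#' Fits a binomial GLM (logit link) by iteratively reweighted least
#' squares and reports per-term odds ratios with Wald confidence
#' intervals.  Perfect separation is detected heuristically (a diverging
#' coefficient or IRLS non-convergence) and flagged rather than raised.
#'
#' @param outcome binary vector (0/1 or logical).
#' @param design numeric matrix of predictors with named columns (no
#'   intercept column; one is added).
#' @param conf confidence level for the Wald intervals.
#' @return List with `coef`, `se`, `p` (Wald), `or`, `ci_low`, `ci_high`
#'   (all named, excluding the intercept unless requested via
#'   `$coef_full`), and `converged`.
#' @export
fitLogistic <- function(outcome, design, conf = 0.95) {
  y <- as.numeric(outcome)
  X <- as.matrix(design)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(y) <= ncol(X) + 1)
    stop("more parameters than observations")
  Xi <- cbind(`(Intercept)` = 1, X)
  if (qr(Xi)$rank < ncol(Xi))
    stop("design matrix is rank deficient")
  fit <- suppressWarnings(
    glm.fit(Xi, y, family = binomial(), control = list(epsilon = 1e-8,
                                                       maxit = 100)))
  cf <- fit$coefficients
  # Wald covariance from the weighted cross-product at convergence
  w <- fit$weights
  XtWX <- crossprod(Xi * sqrt(w))
  vc <- tryCatch(chol2inv(chol(XtWX)), error = function(e)
    matrix(NA_real_, ncol(Xi), ncol(Xi)))
  se <- sqrt(diag(vc))
  names(se) <- names(cf)
  separated <- any(abs(cf) > 15)
  converged <- isTRUE(fit$converged) && !separated
  z <- qnorm(1 - (1 - conf) / 2)
  keep <- setdiff(names(cf), "(Intercept)")
  list(coef = cf[keep], se = se[keep],
       p = 2 * pnorm(-abs(cf[keep] / se[keep])),
       or = exp(cf[keep]),
       ci_low = exp(cf[keep] - z * se[keep]),
       ci_high = exp(cf[keep] + z * se[keep]),
       coef_full = cf, se_full = se,
       converged = converged, separated = separated)
}

# numeric covariate matrix (possibly zero-column) aligned with a data.frame
.covMatrix <- function(cd, adjust_for) {
  if (is.null(adjust_for) || !length(adjust_for))
    return(matrix(numeric(0), nrow = nrow(cd), ncol = 0))
  as.matrix(data.frame(lapply(cd[adjust_for], as.numeric)))
}

.covComplete <- function(covmat) {
  if (ncol(covmat) == 0) rep(TRUE, nrow(covmat)) else complete.cases(covmat)
}

# fast adjusted Wald p for one exposure column given a fixed covariate
# matrix; returns c(log_or, se, p) or NAs when the fit degenerates
.fastAdjusted <- function(y, exposure, covmat) {
  Xi <- cbind(1, exposure, covmat)
  fit <- tryCatch(suppressWarnings(
    glm.fit(Xi, y, family = binomial(),
            control = list(epsilon = 1e-8, maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit)) return(c(NA_real_, NA_real_, NA_real_))
  vc <- tryCatch(chol2inv(chol(crossprod(Xi * sqrt(fit$weights)))),
                 error = function(e) NULL)
  if (is.null(vc)) return(c(NA_real_, NA_real_, NA_real_))
  b <- fit$coefficients[2]
  s <- sqrt(vc[2, 2])
  if (!is.finite(b) || abs(b) > 15)
    return(c(b, s, NA_real_))
  c(b, s, 2 * pnorm(-abs(b / s)))
}

#' Single-SNP association under one genetic model
#'
#' Crude estimates come from the 2x2 cross-product ([oddsRatioWoolf()];
#' for the `additive` model, from an unadjusted dosage logistic fit) and
#' adjusted estimates from multivariable logistic regression on the model
#' exposure plus covariates.  The `allele` model is adjusted at the
#' subject level using the additive dosage (covariate adjustment of an
#' allele-level table is ill-defined), flagged in the result.  The
#' significance tier uses the crude p-value by default: `significant`
#' (p < 0.05), `marginal` (0.05 <= p < 0.10), else `null`.
#'
#' @param cohort a [SnpCohort-class].
#' @param snp_id SNP id.
#' @param model genetic model name.
#' @param adjust_for character vector of covariate column names in
#'   `colData`; `character(0)` gives an exposure-only logistic fit
#'   (equal to the crude OR), `NULL` (default) skips the adjusted
#'   analysis.
#' @param tier_on `"crude"` (default) or `"adjusted"`.
#' @param alpha,alpha_marginal tier thresholds.
#' @return A list of class `AssociationResult`; see fields in the details.
#' @export
snpAssociation <- function(cohort, snp_id, model,
                           adjust_for = NULL,
                           tier_on = c("crude", "adjusted"),
                           alpha = 0.05, alpha_marginal = 0.10) {
  model <- matchModel(model)
  tier_on <- match.arg(tier_on)
  status <- caseStatus(cohort)
  keep <- status %in% c("case", "control")
  calls <- genotypes(cohort)[snp_id, keep]
  y_all <- as.numeric(status[keep] == "case")
  ok <- !is.na(calls)

  crude <- list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p = NA_real_)
  tab <- NULL
  if (model == "additive") {
    dose <- encodeGeneticModel(calls[ok], "additive")
    f <- fitLogistic(y_all[ok], cbind(dose = dose))
    crude <- list(or = unname(f$or["dose"]), ci_low = unname(f$ci_low["dose"]),
                  ci_high = unname(f$ci_high["dose"]), p = unname(f$p["dose"]))
    n_used <- sum(ok)
  } else {
    tab <- contingency2x2(cohort, snp_id, model)
    w <- oddsRatioWoolf(tab)
    crude <- list(or = w$or, ci_low = w$ci_low, ci_high = w$ci_high, p = w$p)
    n_used <- tab$n_used
  }

  adjusted <- NULL
  allele_as_dosage <- FALSE
  if (!is.null(adjust_for)) {
    cd <- covariates(cohort)[keep, , drop = FALSE]
    missing_cov <- setdiff(adjust_for, colnames(cd))
    if (length(missing_cov))
      stop("unknown covariate(s): ", paste(missing_cov, collapse = ", "))
    covmat <- .covMatrix(cd, adjust_for)
    if (model %in% c("additive", "allele")) {
      expo <- rep(NA_real_, length(calls))
      expo[ok] <- encodeGeneticModel(calls[ok], "additive")
      allele_as_dosage <- model == "allele"
    } else {
      enc <- rep(NA_real_, length(calls))
      e <- encodeGeneticModel(calls[ok], model)
      enc[ok] <- ifelse(e == "exposed", 1,
                        ifelse(e == "unexposed", 0, NA))
      expo <- enc
    }
    use <- !is.na(expo) & .covComplete(covmat)
    f <- fitLogistic(y_all[use],
                     cbind(exposure = expo[use], covmat[use, , drop = FALSE]))
    adjusted <- list(or = unname(f$or["exposure"]),
                     ci_low = unname(f$ci_low["exposure"]),
                     ci_high = unname(f$ci_high["exposure"]),
                     p = unname(f$p["exposure"]),
                     converged = f$converged, n_used = sum(use))
  }

  p_tier <- if (tier_on == "adjusted" && !is.null(adjusted))
    adjusted$p else crude$p
  tier <- if (is.na(p_tier)) NA_character_
          else if (p_tier < alpha) "significant"
          else if (p_tier < alpha_marginal) "marginal"
          else "null"

  structure(list(snp_id = snp_id, model = model, table = tab,
                 or_crude = crude$or, ci_crude = c(crude$ci_low, crude$ci_high),
                 p_crude = crude$p, adjusted = adjusted,
                 or_adjusted = if (is.null(adjusted)) NA_real_ else adjusted$or,
                 p_adjusted = if (is.null(adjusted)) NA_real_ else adjusted$p,
                 n_used = n_used, tier = tier,
                 allele_adjusted_as_dosage = allele_as_dosage),
            class = "AssociationResult")
}

#' @export
print.AssociationResult <- function(x, ...) {
  cat(sprintf("%s [%s]: crude OR %.3f (%.3f, %.3f), p = %.3g; n = %d; tier %s\n",
              x$snp_id, x$model, x$or_crude, x$ci_crude[1], x$ci_crude[2],
              x$p_crude, x$n_used, x$tier))
  if (!is.null(x$adjusted))
    cat(sprintf("  adjusted OR %.3f (%.3f, %.3f), p = %.3g\n",
                x$adjusted$or, x$adjusted$ci_low, x$adjusted$ci_high,
                x$adjusted$p))
  invisible(x)
}

#' Association table across SNPs and genetic models
#'
#' Runs [snpAssociation()] over a SNP-by-model grid and stacks the
#' results into one data frame shaped like the usual per-SNP association
#' report (one row per SNP x model, crude and adjusted columns).
#'
#' @inheritParams snpAssociation
#' @param snp_ids SNPs to test (default: the whole panel).
#' @param models genetic models (default: all but `additive`).
#' @return `data.frame`.
#' @export
associationTable <- function(cohort, snp_ids = NULL,
                             models = setdiff(GENETIC_MODELS, "additive"),
                             adjust_for = NULL, ...) {
  if (is.null(snp_ids)) snp_ids <- snpPanel(cohort)$snp_id
  rows <- list()
  for (s in snp_ids) for (m in models) {
    r <- snpAssociation(cohort, s, m, adjust_for = adjust_for, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = s, model = m,
      a = if (is.null(r$table)) NA else r$table$a,
      b = if (is.null(r$table)) NA else r$table$b,
      c = if (is.null(r$table)) NA else r$table$c,
      d = if (is.null(r$table)) NA else r$table$d,
      or_crude = r$or_crude, ci_crude_low = r$ci_crude[1],
      ci_crude_high = r$ci_crude[2], p_crude = r$p_crude,
      or_adjusted = r$or_adjusted, p_adjusted = r$p_adjusted,
      n_used = r$n_used, tier = r$tier, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Two-stage screen-and-replicate SNP selection
#'
#' Stage 1 (screening cohort) keeps SNPs significant (adjusted p < `alpha`)
#' or marginal (`alpha` <= p < `alpha_marginal`) under at least one genetic
#' model; stage 2 (replication cohort) keeps, from those, SNPs with
#' adjusted p < `alpha` under at least one model.  QC
#' ([qcFilter()]) is applied per stage; a SNP must pass in the stage where
#' it is tested.  Adjusted p-values come from subject-level logistic
#' regression on the model exposure plus `adjust_for` covariates (the
#' allele model via additive dosage).
#'
#' @param screening,replication [SnpCohort-class] objects sharing a panel.
#' @param models genetic models screened.
#' @param alpha,alpha_marginal significance and marginal thresholds.
#' @param adjust_for covariate columns for the adjusted fits.
#' @param qc apply [qcFilter()] per stage (default `TRUE`).
#' @param ... passed to [qcFilter()].
#' @return List with `validated` (`data.frame`: snp_id and the models
#'   driving stage-2 selection), `stage1`, `stage2` (per-SNP x model
#'   adjusted summaries), and `qc` logs.
#' @export
twoStageScreen <- function(screening, replication,
                           models = setdiff(GENETIC_MODELS, "additive"),
                           alpha = 0.05, alpha_marginal = 0.10,
                           adjust_for = c("age", "years_exposure",
                                          "smoking", "drinking"),
                           qc = TRUE, ...) {
  if (!identical(snpPanel(screening)$snp_id, snpPanel(replication)$snp_id))
    stop("screening and replication cohorts must share the same SNP panel")
  qc1 <- if (qc) qcFilter(screening, ...) else
    list(kept = snpPanel(screening)$snp_id, log = NULL)
  s1 <- .stageAdjustedP(screening, qc1$kept, models, adjust_for)
  keep1 <- unique(s1$snp_id[!is.na(s1$p_adjusted) &
                              s1$p_adjusted < alpha_marginal])
  if (!length(keep1)) {
    warning("no SNPs passed the stage-1 screen")
    return(list(validated = data.frame(snp_id = character(),
                                       models = character()),
                stage1 = s1, stage2 = NULL,
                qc = list(screening = qc1$log, replication = NULL)))
  }
  qc2 <- if (qc) qcFilter(replication, ...) else
    list(kept = snpPanel(replication)$snp_id, log = NULL)
  test2 <- intersect(keep1, qc2$kept)
  s2 <- .stageAdjustedP(replication, test2, models, adjust_for)
  hit <- !is.na(s2$p_adjusted) & s2$p_adjusted < alpha
  validated <- if (any(hit)) {
    agg <- split(s2$model[hit], s2$snp_id[hit])
    data.frame(snp_id = names(agg),
               models = vapply(agg, paste, character(1), collapse = ","),
               stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(snp_id = character(), models = character())
  # keep panel order
  validated <- validated[order(match(validated$snp_id,
                                     snpPanel(replication)$snp_id)), ,
                         drop = FALSE]
  rownames(validated) <- NULL
  list(validated = validated, stage1 = s1, stage2 = s2,
       qc = list(screening = qc1$log, replication = qc2$log))
}

# adjusted log-OR/p for each kept SNP x model in one cohort (fast path)
.stageAdjustedP <- function(cohort, snp_ids, models, adjust_for) {
  status <- caseStatus(cohort)
  keep <- status %in% c("case", "control")
  y <- as.numeric(status[keep] == "case")
  cd <- covariates(cohort)[keep, , drop = FALSE]
  covmat <- .covMatrix(cd, adjust_for)
  cov_ok <- .covComplete(covmat)
  g <- genotypes(cohort)[, keep, drop = FALSE]
  rows <- list()
  for (s in snp_ids) {
    calls <- g[s, ]
    ok0 <- !is.na(calls) & cov_ok
    for (m in models) {
      if (m %in% c("additive", "allele")) {
        expo <- encodeGeneticModel(calls[ok0], "additive")
        ok <- ok0
      } else {
        e <- encodeGeneticModel(calls[ok0], m)
        expo <- ifelse(e == "exposed", 1, ifelse(e == "unexposed", 0, NA))
        ok <- ok0
        ok[ok0] <- !is.na(expo)
        expo <- expo[!is.na(expo)]
      }
      if (length(unique(expo)) < 2 || sum(ok) < ncol(covmat) + 3) {
        est <- c(NA_real_, NA_real_, NA_real_)
      } else {
        est <- .fastAdjusted(y[ok], expo, covmat[ok, , drop = FALSE])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = s, model = m, log_or_adjusted = est[1], se = est[2],
        or_adjusted = exp(est[1]), p_adjusted = est[3], n_used = sum(ok),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
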