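#' Assign per-SNP risk alleles from the replication-stage allele model
#'
#' The risk allele of a SNP is the allele whose allele-model (per-allele)
#' crude odds ratio exceeds 1 in the supplied cohort — by design the
#' replication cohort, the study's final word on each SNP.  A tie
#' (OR exactly 1) is broken toward the variant allele with a warning.
#'
#' @param cohort a [SnpCohort-class] (normally the replication stage).
#' @param snp_ids SNPs to orient (default: whole panel).
#' @return Named character vector with values `"wild"`/`"variant"`.
#' @export
assignRiskAlleles <- function(cohort, snp_ids = NULL) {
  if (is.null(snp_ids)) snp_ids <- snpPanel(cohort)$snp_id
  vapply(snp_ids, function(s) {
    or <- oddsRatioWoolf(contingency2x2(cohort, s, "allele"))$or
    assignRiskAllele(or, s)
  }, character(1))
}

#' @rdname assignRiskAlleles
#' @param allele_or allele-model odds ratio of the variant allele.
#' @param snp_id SNP id, for the tie warning.
#' @export
assignRiskAllele <- function(allele_or, snp_id = "SNP") {
  if (is.na(allele_or)) stop("allele-model odds ratio unavailable")
  if (allele_or == 1) {
    warning("allele OR exactly 1 for ", snp_id,
            "; risk allele set to the variant allele by convention")
    return("variant")
  }
  if (allele_or > 1) "variant" else "wild"
}

#' Risk-allele genotype code (0/1/2)
#'
#' Counts copies of the risk allele in each genotype: homozygous non-risk
#' genotypes score 0, heterozygotes 1, homozygous risk genotypes 2.
#'
#' @param calls character vector of calls `AA`/`AB`/`BB` (no missing).
#' @param risk_allele `"wild"` or `"variant"`.
#' @return Integer vector in `{0, 1, 2}`.
#' @export
genotypeRiskCode <- function(calls, risk_allele) {
  risk_allele <- match.arg(risk_allele, c("wild", "variant"))
  if (anyNA(calls)) stop("missing calls must be handled before scoring")
  if (!all(calls %in% GENOTYPE_LEVELS)) stop("invalid genotype calls")
  code <- c(AA = 0L, AB = 1L, BB = 2L)[calls]
  if (risk_allele == "wild") code <- 2L - code
  unname(code)
}

#' Unweighted genetic risk score
#'
#' GRS is the sum over the scored SNPs of the per-subject risk-allele
#' genotype codes ([genotypeRiskCode()]).  Subjects missing any scored
#' genotype get `NA` under the default complete-score policy; the
#' `"prorate"` policy rescales the observed sum to the full SNP count
#' (flagged via `n_missing_snps > 0`).
#'
#' @param cohort a [SnpCohort-class].
#' @param scored_snps character vector of SNP ids to score.
#' @param risk_alleles named `"wild"`/`"variant"` vector as returned by
#'   [assignRiskAlleles()]; assigned from `cohort` itself when omitted.
#' @param policy `"complete"` (default) or `"prorate"`.
#' @return `data.frame` with `subject_id`, `grs`, `n_missing_snps`.
#' @export
computeGRS <- function(cohort, scored_snps, risk_alleles = NULL,
                       policy = c("complete", "prorate")) {
  policy <- match.arg(policy)
  if (!length(scored_snps)) stop("'scored_snps' must not be empty")
  if (is.null(risk_alleles))
    risk_alleles <- assignRiskAlleles(cohort, scored_snps)
  if (!all(scored_snps %in% names(risk_alleles)))
    stop("risk alleles missing for: ",
         paste(setdiff(scored_snps, names(risk_alleles)), collapse = ", "))
  g <- genotypes(cohort)[scored_snps, , drop = FALSE]
  codes <- matrix(NA_integer_, nrow(g), ncol(g), dimnames = dimnames(g))
  for (s in scored_snps) {
    ok <- !is.na(g[s, ])
    codes[s, ok] <- genotypeRiskCode(g[s, ok], risk_alleles[[s]])
  }
  n_missing <- colSums(is.na(codes))
  grs <- if (policy == "complete") {
    out <- colSums(codes)
    out  # NA when any scored SNP missing
  } else {
    obs <- colSums(codes, na.rm = TRUE)
    k <- length(scored_snps) - n_missing
    ifelse(k == 0, NA_real_, obs * length(scored_snps) / k)
  }
  data.frame(subject_id = colnames(g), grs = unname(grs),
             n_missing_snps = unname(n_missing),
             stringsAsFactors = FALSE)
}

# bin GRS values: intervals (..., upper1], (upper1, upper2], ..., (last, Inf)
.grsBins <- function(grs, breaks) {
  breaks <- sort(unique(breaks))
  labels <- c(paste0("<=", breaks[1]),
              if (length(breaks) > 1)
                vapply(seq_along(breaks)[-1], function(i) {
                  lo <- breaks[i - 1] + 1; hi <- breaks[i]
                  if (lo == hi) as.character(hi) else paste0(lo, "-", hi)
                }, character(1)),
              paste0(">=", breaks[length(breaks)] + 1))
  idx <- findInterval(grs, c(breaks + 0.5)) + 1L
  factor(labels[idx], levels = labels)
}

#' Binned GRS risk table with per-bin odds ratios and trend test
#'
#' Bins the GRS (default bins `<=5, 6, 7, 8, 9, >=10`), takes the lowest
#' bin as the reference, and computes each bin's crude odds ratio against
#' the reference via [oddsRatioWoolf()]; the reference row is printed
#' with OR 1.  A Cochran-Armitage trend test over the ordered bins
#' ([grsTrendTest()]) quantifies the dose-response relationship.
#'
#' @param grs numeric GRS vector (NAs dropped).
#' @param status case/control vector aligned with `grs`.
#' @param breaks upper bin bounds; `c(5, 6, 7, 8, 9)` gives the default
#'   six bins.
#' @return `data.frame` of class `GrsRiskTable` (one row per bin:
#'   label, counts, OR, CI, p) with attributes `trend_chi2`, `trend_p`,
#'   `reference`.
#' @export
grsRiskTable <- function(grs, status, breaks = c(5, 6, 7, 8, 9)) {
  status <- normalizeStatus(status)
  keep <- !is.na(grs) & status %in% c("case", "control")
  grs <- grs[keep]; status <- status[keep]
  bins <- .grsBins(grs, breaks)
  n_case <- tapply(status == "case", bins, sum, default = 0L)
  n_ctrl <- tapply(status == "control", bins, sum, default = 0L)
  if (n_case[1] + n_ctrl[1] == 0)
    stop("reference GRS bin is empty")
  ors <- lapply(seq_along(levels(bins)), function(i) {
    if (i == 1)
      return(list(or = 1, ci_low = NA_real_, ci_high = NA_real_,
                  p = NA_real_))
    oddsRatioWoolf(n_case[i], n_ctrl[i], n_case[1], n_ctrl[1])
  })
  out <- data.frame(
    bin = levels(bins),
    n_case = as.integer(n_case), n_control = as.integer(n_ctrl),
    or = vapply(ors, `[[`, numeric(1), "or"),
    ci_low = vapply(ors, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(ors, `[[`, numeric(1), "ci_high"),
    p = vapply(ors, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE)
  trend <- grsTrendTest(out$n_case, out$n_case + out$n_control)
  attr(out, "trend_chi2") <- trend$chi2
  attr(out, "trend_p") <- trend$p
  attr(out, "reference") <- levels(bins)[1]
  class(out) <- c("GrsRiskTable", "data.frame")
  out
}

#' Dichotomized GRS odds ratio
#'
#' Odds ratio for high (`GRS >= cutoff`) versus low GRS.
#'
#' @param grs numeric GRS vector (NAs dropped).
#' @param status case/control vector aligned with `grs`.
#' @param cutoff high-GRS threshold (default 6).
#' @return [oddsRatioWoolf()] result plus the 2x2 counts.
#' @export
grsDichotomy <- function(grs, status, cutoff = 6) {
  status <- normalizeStatus(status)
  keep <- !is.na(grs) & status %in% c("case", "control")
  grs <- grs[keep]; status <- status[keep]
  hi <- grs >= cutoff
  if (!any(hi) || all(hi))
    stop("GRS cutoff ", cutoff, " leaves an empty group")
  a <- sum(hi & status == "case"); b <- sum(hi & status == "control")
  cc <- sum(!hi & status == "case"); d <- sum(!hi & status == "control")
  res <- oddsRatioWoolf(a, b, cc, d)
  res$table <- contingencyTable2x2(a, b, cc, d)
  res
}

#' Cochran-Armitage trend test over ordered bins
#'
#' Tests for a linear trend in the case proportion across ordered GRS
#' bins using integer scores (0, 1, ..., k-1 by default); one-df
#' chi-square.  Implemented via [stats::prop.trend.test()].
#'
#' @param cases per-bin case counts (>= 3 bins).
#' @param totals per-bin totals (cases + controls).
#' @param scores bin scores (default ordinal).
#' @return List with `chi2` and `p`.
#' @export
grsTrendTest <- function(cases, totals, scores = seq_along(cases) - 1) {
  if (length(cases) < 3)
    stop("trend test needs at least 3 ordered bins")
  if (length(totals) != length(cases) || any(totals < cases))
    stop("'totals' must match 'cases' and be at least as large")
  tt <- suppressWarnings(prop.trend.test(cases, totals, score = scores))
  list(chi2 = unname(tt$statistic), p = tt$p.value)
}
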