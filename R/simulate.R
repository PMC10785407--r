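#' Default SNP panel for simulated cohorts
#'
#' Builds a panel of `n_snps` biallelic SNPs with generic rs-style ids and
#' alternating allele pairs; used by the simulator when no panel is given.
#'
#' @param n_snps number of SNPs.
#' @param maf per-SNP minor (variant) allele frequency, recycled.
#' @return `data.frame` with `snp_id`, `gene`, `wild_allele`,
#'   `variant_allele`, `maf`.
#' @export
defaultPanel <- function(n_snps = 6, maf = 0.3) {
  bases <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"), ncol = 2,
                  byrow = TRUE)
  i <- (seq_len(n_snps) - 1) %% 4 + 1
  data.frame(snp_id = sprintf("rs%06d", seq_len(n_snps)),
             gene = sprintf("GENE%d", (seq_len(n_snps) - 1) %/% 2 + 1),
             wild_allele = bases[i, 1], variant_allele = bases[i, 2],
             maf = rep_len(maf, n_snps), stringsAsFactors = FALSE)
}

#' Specification of one simulated SNP effect
#'
#' @param snp_id SNP id in the panel.
#' @param model genetic model whose coding multiplies `ln_or` in the
#'   disease logit.
#' @param ln_or log odds ratio of the exposed coding.
#' @return A list of class `EffectSpec`.
#' @export
effectSpec <- function(snp_id, model, ln_or) {
  structure(list(snp_id = snp_id, model = matchModel(model),
                 ln_or = ln_or), class = "EffectSpec")
}

#' Simulation configuration for a synthetic case-control cohort
#'
#' Describes one cohort of the two-stage design: sample sizes, the SNP
#' panel with per-SNP minor allele frequencies and Hardy-Weinberg
#' inbreeding coefficients, covariate distributions, and the logistic
#' disease model (intercept, per-SNP effects, optional interaction and
#' covariate terms).  The covariate defaults emulate an occupational
#' noise-exposed workforce: age ~ N(48.32, 5.69) years, years of noise
#' exposure ~ N(12.24, 5.75) truncated above 3 years, SPL ~ N(85.79,
#' 5.13) dB(A) (so that CNE averages ~96.5 dB(A)-years), and Bernoulli
#' PPE use, smoking and drinking.
#'
#' @param n_cases,n_controls target case and control counts.
#' @param panel SNP panel (see [defaultPanel()]); a `maf` column supplies
#'   per-SNP variant allele frequencies.
#' @param maf fallback MAF when the panel has no `maf` column.
#' @param hwe_f per-SNP inbreeding coefficient (0 = HWE), recycled.
#' @param call_rate per-SNP genotype call rate in (0, 1], recycled.
#' @param covariates named list overriding the covariate distribution
#'   parameters (`age_mean`, `age_sd`, `years_mean`, `years_sd`,
#'   `years_min`, `spl_mean`, `spl_sd`, `ppe_p`, `smoking_p`,
#'   `drinking_p`, `male_p`, `han_p`).
#' @param intercept logistic intercept (baseline log-odds of disease).
#' @param effects list of [effectSpec()] main effects.
#' @param covariate_effects named numeric vector of per-unit log odds
#'   ratios for covariates (booleans coded 0/1).
#' @param interactions list of interaction terms; each term is
#'   `list(terms = list(...), ln_or = )` where every element of `terms`
#'   is either `list(snp = , model = )` or `list(covariate = , threshold = )`
#'   (with a threshold the covariate enters as the indicator `x >=
#'   threshold`, without one as its raw value).  The term's coding is the
#'   product over its elements.
#' @param audiometry also simulate status-conditional audiograms
#'   (synthetic thresholds consistent with the BHFTA/MTWV case
#'   definition; no age-dependence is modelled).
#' @param seed integer seed; every draw of the cohort is a deterministic
#'   function of it.
#' @param draw_budget maximum subject draws before accrual aborts
#'   (default `500 * (n_cases + n_controls)`).
#' @return A list of class `SimulationConfig`.
#' @export
simulationConfig <- function(n_cases, n_controls, panel = defaultPanel(),
                             maf = 0.3, hwe_f = 0, call_rate = 1,
                             covariates = list(), intercept = -1,
                             effects = list(),
                             covariate_effects = numeric(),
                             interactions = list(),
                             audiometry = FALSE, seed = 1,
                             draw_budget = NULL) {
  stopifnot(n_cases > 0, n_controls > 0)
  if (!"maf" %in% colnames(panel)) panel$maf <- rep_len(maf, nrow(panel))
  cov_def <- list(age_mean = 48.32, age_sd = 5.69,
                  years_mean = 12.24, years_sd = 5.75, years_min = 3,
                  spl_mean = 85.79, spl_sd = 5.13,
                  ppe_p = 0.70, smoking_p = 0.40, drinking_p = 0.30,
                  male_p = 0.85, han_p = 0.95)
  unknown <- setdiff(names(covariates), names(cov_def))
  if (length(unknown))
    stop("unknown covariate parameter(s): ", paste(unknown, collapse = ", "))
  cov_def[names(covariates)] <- covariates
  for (e in effects)
    if (!e$snp_id %in% panel$snp_id)
      stop("effect references unknown SNP: ", e$snp_id)
  cfg <- list(n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              panel = panel,
              hwe_f = rep_len(hwe_f, nrow(panel)),
              call_rate = rep_len(call_rate, nrow(panel)),
              covariates = cov_def, intercept = intercept,
              effects = effects, covariate_effects = covariate_effects,
              interactions = interactions, audiometry = audiometry,
              seed = as.integer(seed),
              draw_budget = if (is.null(draw_budget))
                500L * (as.integer(n_cases) + as.integer(n_controls))
              else as.integer(draw_budget))
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate genotype calls under (possible deviation from) HWE
#'
#' Draws `n` genotypes with variant-allele frequency `maf` and inbreeding
#' coefficient `f`:
#' `P(BB) = q^2 + f q (1-q)`, `P(AB) = 2 q (1-q) (1-f)`,
#' `P(AA) = p^2 + f p (1-p)` with `q = maf`, `p = 1 - maf`.  `f = 0` is
#' exact HWE; `f = 1` removes all heterozygotes.  Uses the current RNG
#' stream (seed at the caller).
#'
#' @param maf variant allele frequency in (0, 1).
#' @param f inbreeding coefficient; must keep all three probabilities
#'   non-negative.
#' @param n number of calls.
#' @return Character vector of `"AA"`/`"AB"`/`"BB"`.
#' @export
simulateGenotypes <- function(maf, f = 0, n) {
  assertScalarNumber(maf, "maf")
  if (maf <= 0 || maf >= 1) stop("'maf' must be in (0, 1)")
  q <- maf; p <- 1 - maf
  probs <- c(AA = p^2 + f * p * q, AB = 2 * p * q * (1 - f),
             BB = q^2 + f * p * q)
  if (any(probs < -1e-12) || abs(sum(probs) - 1) > 1e-9)
    stop("invalid genotype probabilities for maf = ", maf, ", f = ", f)
  probs <- pmax(probs, 0)
  sample(GENOTYPE_LEVELS, n, replace = TRUE, prob = probs)
}

# truncated-normal draw by resampling below the bound
rtruncnorm <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

#' Simulate the environmental covariate table
#'
#' Draws `n` subjects' age, years of noise exposure (truncated above
#' `years_min`), SPL, derived CNE ([computeCNE()]), PPE use, smoking,
#' drinking, sex and ethnicity from the distributions in the
#' configuration.  Uses the current RNG stream.
#'
#' @param config a [simulationConfig()].
#' @param n number of subjects.
#' @return `data.frame` of covariates.
#' @export
simulateCovariates <- function(config, n) {
  cv <- config$covariates
  age <- rnorm(n, cv$age_mean, cv$age_sd)
  years <- rtruncnorm(n, cv$years_mean, cv$years_sd, cv$years_min)
  spl <- rnorm(n, cv$spl_mean, cv$spl_sd)
  data.frame(age = age, years_exposure = years, spl = spl,
             cne = computeCNE(spl, years),
             ppe = runif(n) < cv$ppe_p,
             smoking = runif(n) < cv$smoking_p,
             drinking = runif(n) < cv$drinking_p,
             sex = ifelse(runif(n) < cv$male_p, "male", "female"),
             ethnicity = ifelse(runif(n) < cv$han_p, "Han", "other"),
             stringsAsFactors = FALSE)
}

# coding of one interaction/effect term for a pool of subjects
.termCoding <- function(term, geno, covs) {
  if (!is.null(term$snp)) {
    as.numeric(encodeBinaryCoding(geno[term$snp, ], term$model))
  } else if (!is.null(term$covariate)) {
    x <- covs[[term$covariate]]
    if (!is.null(term$threshold)) as.numeric(x >= term$threshold)
    else as.numeric(x)
  } else stop("interaction term needs 'snp' or 'covariate'")
}

# numeric disease-model coding of genotypes under a genetic model
# (homozygote: AB carries 0 -- no subject can be 'excluded' from risk)
encodeBinaryCoding <- function(calls, model) {
  model <- matchModel(model)
  if (model %in% c("additive", "allele"))
    return(c(AA = 0, AB = 1, BB = 2)[calls])
  switch(model,
    recessive      = as.numeric(calls == "BB"),
    dominant       = as.numeric(calls != "AA"),
    super_dominant = as.numeric(calls == "AB"),
    homozygote     = as.numeric(calls == "BB"))
}

# linear predictor of the disease model for a pool
.diseaseLogit <- function(config, geno, covs) {
  eta <- rep(config$intercept, ncol(geno))
  for (e in config$effects)
    eta <- eta + e$ln_or * encodeBinaryCoding(geno[e$snp_id, ], e$model)
  if (length(config$covariate_effects)) {
    for (nm in names(config$covariate_effects))
      eta <- eta + config$covariate_effects[[nm]] * as.numeric(covs[[nm]])
  }
  for (ia in config$interactions) {
    coding <- rep(1, ncol(geno))
    for (term in ia$terms) coding <- coding * .termCoding(term, geno, covs)
    eta <- eta + ia$ln_or * coding
  }
  eta
}

#' Simulate one case-control cohort
#'
#' Generates a subject pool (genotypes in HWE at the panel MAFs,
#' covariates from [simulateCovariates()]), assigns disease by the
#' logistic model `logit P(case) = intercept + sum(effects) +
#' sum(interactions) + sum(covariate effects)`, and accrues subjects by
#' rejection sampling until exactly `n_cases` cases and `n_controls`
#' controls are collected (crude odds ratios are invariant under this
#' outcome-dependent sampling, so the specified ORs remain the estimand).
#' Genotype calls are then masked to missing at rate `1 - call_rate`.
#' Fully deterministic given `config$seed`.
#'
#' @param config a [simulationConfig()].
#' @param stageLabel stage label for the cohort.
#' @return A [SnpCohort-class].
#' @export
simulateCaseControl <- function(config, stageLabel = "simulated") {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(config$seed, .simulateCaseControlImpl(config, stageLabel))
}

.simulateCaseControlImpl <- function(config, stageLabel) {
  panel <- config$panel
  n_target <- c(case = config$n_cases, control = config$n_controls)
  chunk <- max(1000L, 4L * sum(n_target))
  got_g <- NULL; got_cov <- NULL; got_status <- character()
  drawn <- 0L
  while (any(c(sum(got_status == "case"),
               sum(got_status == "control")) < n_target)) {
    if (drawn >= config$draw_budget)
      stop("case-control accrual exceeded the draw budget (",
           config$draw_budget, " draws); adjust the intercept toward ",
           "a less extreme disease prevalence")
    m <- min(chunk, config$draw_budget - drawn)
    drawn <- drawn + m
    geno <- matrix(NA_character_, nrow(panel), m,
                   dimnames = list(panel$snp_id, NULL))
    for (i in seq_len(nrow(panel)))
      geno[i, ] <- simulateGenotypes(panel$maf[i], config$hwe_f[i], m)
    covs <- simulateCovariates(config, m)
    pr <- plogis(.diseaseLogit(config, geno, covs))
    y <- ifelse(runif(m) < pr, "case", "control")
    need_case <- n_target["case"] - sum(got_status == "case")
    need_ctrl <- n_target["control"] - sum(got_status == "control")
    take <- c(which(y == "case")[seq_len(min(need_case, sum(y == "case")))],
              which(y == "control")[seq_len(min(need_ctrl,
                                                sum(y == "control")))])
    take <- sort(take)
    got_g <- cbind(got_g, geno[, take, drop = FALSE])
    got_cov <- rbind(got_cov, covs[take, , drop = FALSE])
    got_status <- c(got_status, y[take])
  }
  n <- length(got_status)
  ids <- sprintf("S%05d", seq_len(n))
  colnames(got_g) <- ids
  rownames(got_cov) <- ids
  got_cov$status <- got_status
  # mask calls to missing per SNP
  for (i in seq_len(nrow(panel))) {
    if (config$call_rate[i] < 1) {
      miss <- runif(n) > config$call_rate[i]
      got_g[i, miss] <- NA_character_
    }
  }
  if (config$audiometry)
    got_cov <- cbind(got_cov, .simulateAudiograms(got_status))
  SnpCohort(t(got_g), panel, got_cov, stageLabel = stageLabel)
}

# status-conditional synthetic audiograms: thresholds are constructed so
# the derived BHFTA/MTWV land on the correct side of the case definition
.simulateAudiograms <- function(status) {
  n <- length(status)
  is_case <- status == "case"
  bhfta <- ifelse(is_case, rtruncnorm(n, 55.23, 10.38, 40),
                  pmin(rtruncnorm(n, 28.02, 7.49, -9), 39.5))
  mtwv <- ifelse(is_case, rtruncnorm(n, 35, 6, 26),
                 pmin(rtruncnorm(n, 15, 5, -5), 25.5))
  hi <- pmin(pmax(bhfta, -10), 120)          # 3000/4000/6000 Hz both ears
  lo <- (mtwv - 0.1 * hi) / 0.9              # 500/1000/2000 Hz both ears
  lo <- pmin(pmax(lo, -10), 120)
  out <- data.frame(row.names = seq_len(n))
  for (f in c("500", "1000", "2000")) {
    out[[paste0("thr_left_", f)]] <- lo
    out[[paste0("thr_right_", f)]] <- lo
  }
  for (f in c("3000", "4000", "6000")) {
    out[[paste0("thr_left_", f)]] <- hi
    out[[paste0("thr_right_", f)]] <- hi
  }
  out
}

#' Simulate a full two-stage study
#'
#' Generates the screening and replication cohorts from one effect
#' specification with independent, label-derived sub-seeds of a single
#' master seed, so the whole study reproduces from one integer.
#'
#' @param config_screen,config_replicate [simulationConfig()] objects
#'   sharing a panel (their `seed` fields are overridden).
#' @param seed master seed.
#' @return List with elements `screening` and `replication`
#'   ([SnpCohort-class] objects).
#' @export
generateTwoStageStudy <- function(config_screen, config_replicate,
                                  seed = 1) {
  if (!identical(config_screen$panel$snp_id,
                 config_replicate$panel$snp_id))
    stop("the two stages must share the same SNP panel")
  config_screen$seed <- subSeed(seed, "screening")
  config_replicate$seed <- subSeed(seed, "replication")
  list(screening = simulateCaseControl(config_screen, "screening"),
       replication = simulateCaseControl(config_replicate, "replication"))
}
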