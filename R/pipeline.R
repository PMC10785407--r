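#' Baseline descriptive comparison of cases and controls
#'
#' For each covariate, summarizes cases and controls and tests the
#' group difference: continuous variables get a Student t-test and are
#' displayed as mean +/- SD when Shapiro-Wilk finds no departure from
#' normality in either group (at `shapiro_alpha`), otherwise as
#' median (P25, P75); categorical variables get an uncorrected Pearson
#' chi-square test.  Zero-variance variables are reported with the test
#' skipped and a note.
#'
#' @param cohort a [SnpCohort-class] with cases and controls.
#' @param variables covariate columns to compare (default: the standard
#'   demographic/exposure set present in the cohort).
#' @param shapiro_alpha normality cutoff for the display rule.
#' @return `data.frame`: variable, per-group summary, test, p, note.
#' @export
baselineTable <- function(cohort,
                          variables = NULL, shapiro_alpha = 0.05) {
  cd <- covariates(cohort)
  status <- caseStatus(cohort)
  if (!any(status == "case") || !any(status == "control"))
    stop("baseline table needs both cases and controls")
  if (is.null(variables))
    variables <- intersect(c("age", "sex", "ethnicity", "years_exposure",
                             "cne", "ppe", "smoking", "drinking", "bhfta"),
                           colnames(cd))
  rows <- lapply(variables, function(v) {
    x <- cd[[v]]
    grp <- status
    keep <- grp %in% c("case", "control") & !is.na(x)
    x <- x[keep]; grp <- grp[keep]
    if (is.numeric(x)) {
      if (sd(x) == 0)
        return(data.frame(variable = v, case = .msd(x[grp == "case"]),
                          control = .msd(x[grp == "control"]),
                          test = "t", p = NA_real_,
                          note = "zero variance; test skipped"))
      sh <- vapply(c("case", "control"), function(g) {
        xs <- x[grp == g]
        if (length(xs) < 3 || length(xs) > 5000 || sd(xs) == 0) return(1)
        shapiro.test(xs)$p.value
      }, numeric(1))
      normal <- all(sh >= shapiro_alpha)
      summ <- if (normal) .msd else .mq
      p <- t.test(x[grp == "case"], x[grp == "control"],
                  var.equal = TRUE)$p.value
      data.frame(variable = v, case = summ(x[grp == "case"]),
                 control = summ(x[grp == "control"]), test = "t", p = p,
                 note = if (normal) "" else "skewed; median (P25, P75)")
    } else {
      x <- as.character(x)
      if (length(unique(x)) < 2)
        return(data.frame(variable = v, case = .pct(x[grp == "case"]),
                          control = .pct(x[grp == "control"]),
                          test = "chisq", p = NA_real_,
                          note = "zero variance; test skipped"))
      tab <- table(grp, x)
      p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
      data.frame(variable = v, case = .pct(x[grp == "case"]),
                 control = .pct(x[grp == "control"]), test = "chisq",
                 p = p, note = "")
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.msd <- function(x) sprintf("%.2f ± %.2f", mean(x), sd(x))
.mq <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  sprintf("%.1f (%.1f, %.1f)", q[2], q[1], q[3])
}
.pct <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  paste(sprintf("%s: %d (%.1f%%)", names(tab), tab, 100 * tab / length(x)),
        collapse = "; ")
}

#' Run the full two-stage pipeline
#'
#' Orchestrates the whole analysis: simulate (or read) the two cohorts,
#' QC, two-stage association screen, GRS dose-response on the replication
#' cohort over the validated SNPs, CART interaction analysis, and report
#' rendering.  Every output is written to `out_dir` as TSV plus a JSON
#' manifest recording the configuration hash and master seed, so a rerun
#' with the same configuration is byte-identical.
#'
#' @param config either a list or a path to a YAML file.  Recognized
#'   fields: `seed`; `simulate` (list with `n_snps`, `maf`,
#'   `screening`/`replication` sample sizes, `effects` as a list of
#'   `snp_id`/`model`/`ln_or`); or `paths` (per-stage genotype,
#'   phenotype, panel file paths); `qc` (`call_rate_min`, `hwe_alpha`);
#'   `models`; `adjust_for`; `grs` (`breaks`, `cutoff`); `cart`
#'   (forwarded to [cartConfig()]).
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list with the cohorts, screen result, GRS table
#'   and CART outputs, plus the manifest.
#' @export
runPipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  cohorts <- stage("ingest", {
    if (!is.null(config$simulate)) {
      sc <- config$simulate
      panel <- defaultPanel(if (is.null(sc$n_snps)) 6 else sc$n_snps,
                            if (is.null(sc$maf)) 0.3 else sc$maf)
      effects <- lapply(sc$effects, function(e)
        effectSpec(e$snp_id, e$model, e$ln_or))
      mk <- function(sz) simulationConfig(
        n_cases = sz[1], n_controls = sz[2], panel = panel,
        intercept = if (is.null(sc$intercept)) -1 else sc$intercept,
        effects = effects)
      generateTwoStageStudy(
        mk(if (is.null(sc$screening)) c(83, 83) else unlist(sc$screening)),
        mk(if (is.null(sc$replication)) c(153, 252)
           else unlist(sc$replication)),
        seed = seed)
    } else if (!is.null(config$paths)) {
      p <- config$paths
      list(screening = readCohort(p$screening$genotypes,
                                  p$screening$phenotypes, p$screening$panel,
                                  stageLabel = "screening"),
           replication = readCohort(p$replication$genotypes,
                                    p$replication$phenotypes,
                                    p$replication$panel,
                                    stageLabel = "replication"))
    } else stop("config needs either 'simulate' or 'paths'")
  })

  wtsv <- function(x, name) {
    write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
  }

  stage("baseline", {
    wtsv(baselineTable(cohorts$screening), "baseline_screening.tsv")
    wtsv(baselineTable(cohorts$replication), "baseline_replication.tsv")
  })

  qc_cfg <- config$qc
  models <- if (is.null(config$models))
    setdiff(GENETIC_MODELS, "additive") else config$models
  adjust_for <- if (is.null(config$adjust_for))
    c("age", "years_exposure", "smoking", "drinking") else config$adjust_for

  screen <- stage("association", {
    twoStageScreen(cohorts$screening, cohorts$replication,
                   models = models, adjust_for = adjust_for,
                   call_rate_min = if (is.null(qc_cfg$call_rate_min)) 0.90
                                   else qc_cfg$call_rate_min,
                   hwe_alpha = if (is.null(qc_cfg$hwe_alpha)) 0.01
                               else qc_cfg$hwe_alpha)
  })
  wtsv(screen$stage1, "association_stage1.tsv")
  if (!is.null(screen$stage2)) wtsv(screen$stage2, "association_stage2.tsv")
  wtsv(screen$validated, "validated_snps.tsv")

  grs_out <- cart_out <- NULL
  snps <- screen$validated$snp_id
  if (length(snps) >= 1) {
    grs_out <- stage("grs", {
      risk <- assignRiskAlleles(cohorts$replication, snps)
      profiles <- computeGRS(cohorts$replication, snps, risk)
      status <- caseStatus(cohorts$replication)
      breaks <- if (is.null(config$grs$breaks)) c(5, 6, 7, 8, 9)
                else config$grs$breaks
      # fall back to quantile-ish breaks when the default bins are empty
      tbl <- tryCatch(grsRiskTable(profiles$grs, status, breaks),
                      error = function(e) NULL)
      dich <- tryCatch(
        grsDichotomy(profiles$grs, status,
                     if (is.null(config$grs$cutoff)) 6
                     else config$grs$cutoff),
        error = function(e) NULL)
      list(risk_alleles = risk, profiles = profiles, table = tbl,
           dichotomy = dich)
    })
    if (!is.null(grs_out$table)) {
      tb <- grs_out$table
      tb$trend_chi2 <- c(attr(tb, "trend_chi2"), rep(NA, nrow(tb) - 1))
      tb$trend_p <- c(attr(tb, "trend_p"), rep(NA, nrow(tb) - 1))
      wtsv(tb, "grs_risk_table.tsv")
    }
    cart_out <- stage("cart", {
      cc <- do.call(cartConfig, c(config$cart,
                                  list(seed = subSeed(seed, "cart"))))
      cd <- cartData(cohorts$replication, snps)
      part <- partitionLearningTesting(cd$y, cc$learning_fraction,
                                       seed = subSeed(seed, "cart-split"))
      tree <- growTree(cd$data[part$learning, , drop = FALSE],
                       cd$y[part$learning], cc)
      pr <- cvPrune(tree, cd$data[part$learning, , drop = FALSE],
                    cd$y[part$learning], cc)
      risk <- if (nTerminalNodes(pr$tree) >= 2)
        nodeRiskTable(pr$tree, cd$data, cd$y) else NULL
      test_err <- .misclassification(pr$tree,
                                     cd$data[part$testing, , drop = FALSE],
                                     cd$y[part$testing])
      list(tree = pr$tree, cv = pr$cv, risk = risk,
           testing_error = test_err,
           testing_n = length(part$testing))
    })
    if (!is.null(cart_out$risk)) wtsv(cart_out$risk, "cart_node_risk.tsv")
  }

  manifest <- list(
    package = "grscart",
    version = as.character(utils::packageVersion("grscart")),
    seed = seed,
    config_hash = configHash(config),
    n_screening = ncol(cohorts$screening),
    n_replication = ncol(cohorts$replication),
    n_validated_snps = length(snps),
    outputs = list.files(out_dir, pattern = "\\.tsv$"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohorts = cohorts, screen = screen, grs = grs_out,
                 cart = cart_out, manifest = manifest))
}

# stable md5 of the canonicalized configuration
configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
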