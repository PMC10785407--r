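# shared fixture builders (everything generated in code; no binary data)

toyPanel <- function(n = 2) defaultPanel(n)

# minimal cohort from an explicit subjects x SNPs call matrix
cohortFromCalls <- function(calls, status, panel = NULL, covs = NULL) {
  if (is.null(panel)) panel <- defaultPanel(ncol(calls))
  colnames(calls) <- panel$snp_id
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("s%03d", seq_len(nrow(calls)))
  phen <- data.frame(status = status, row.names = rownames(calls),
                     stringsAsFactors = FALSE)
  if (!is.null(covs)) phen <- cbind(phen, covs)
  SnpCohort(calls, panel, phen, stageLabel = "fixture")
}

# cohort whose subjects carry prescribed GRS values over 6 SNPs
# (risk allele = variant everywhere); grs in 0..12
grsCohort <- function(grs_values, status) {
  stopifnot(all(grs_values >= 0 & grs_values <= 12))
  calls <- t(vapply(grs_values, function(g) {
    codes <- integer(6)
    full <- g %/% 2
    if (full > 0) codes[seq_len(full)] <- 2L
    if (g %% 2 == 1) codes[full + 1] <- 1L
    c("AA", "AB", "BB")[codes + 1]
  }, character(6)))
  cohortFromCalls(calls, status, panel = defaultPanel(6))
}

# published replication-arm summary counts shipped as plain-text extdata
publishedGrsCounts <- function() {
  read.delim(system.file("extdata", "nihl_grs_bins.tsv",
                         package = "grscart"))
}

publishedCartCounts <- function() {
  read.delim(system.file("extdata", "nihl_cart_nodes.tsv",
                         package = "grscart"))
}

# write a 3-subject toy cohort to TSV files, return the paths
writeToyCohortFiles <- function(dir, missing_cell = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gpath <- file.path(dir, "geno.tsv")
  ppath <- file.path(dir, "phen.tsv")
  papath <- file.path(dir, "panel.tsv")
  panel <- defaultPanel(2)
  gt <- data.frame(subject_id = c("s1", "s2", "s3"),
                   a = c("AA", "AB", "BB"),
                   b = c("AB", if (missing_cell) "./." else "AA", "BB"),
                   stringsAsFactors = FALSE)
  colnames(gt)[2:3] <- panel$snp_id
  ph <- data.frame(subject_id = c("s1", "s2", "s3"),
                   status = c("case", "control", "case"),
                   age = c(50, 45, 52), years_exposure = c(10, 12, 15),
                   spl = c(88, 85, 90), smoking = c(TRUE, FALSE, TRUE),
                   drinking = c(FALSE, FALSE, TRUE),
                   stringsAsFactors = FALSE)
  write.table(gt, gpath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ph, ppath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(panel, papath, sep = "\t", quote = FALSE, row.names = FALSE)
  list(genotypes = gpath, phenotypes = ppath, panel = papath)
}

# small deterministic CART fixture: predictors + outcome with a planted
# genotype effect, sized for brute-force oracle comparison
cartFixture <- function(n = 50, seed = 1, n_vars = 4, effect = TRUE) {
  withr::with_seed(seed, {
    d <- data.frame(row.names = seq_len(n))
    d$g1 <- factor(sample(c("AA", "AB", "BB"), n, TRUE, c(.4, .4, .2)),
                   levels = c("AA", "AB", "BB"))
    if (n_vars >= 2)
      d$g2 <- factor(sample(c("AA", "AB", "BB"), n, TRUE, c(.5, .4, .1)),
                     levels = c("AA", "AB", "BB"))
    if (n_vars >= 3) d$age <- round(rnorm(n, 48, 6), 1)
    if (n_vars >= 4) d$smoking <- runif(n) < 0.4
    if (n_vars >= 5) d$cne <- round(rnorm(n, 96, 5), 1)
    if (n_vars >= 6) d$ppe <- runif(n) < 0.6
    eta <- -0.3 + if (effect) 1.5 * (d$g1 == "BB") else 0
    y <- runif(n) < plogis(eta)
    list(data = d, y = y)
  })
}

# brute-force best split: enumerate every variable x candidate partition
bruteForceBestSplit <- function(data, y, config) {
  impf <- if (config$impurity == "gini") grscart:::nodeGini else nodeEntropy
  n <- length(y); n_case <- sum(y)
  parent <- impf(n_case, n - n_case)
  best <- NULL
  for (v in colnames(data)) {
    for (split in candidateSplits(data[[v]], config$cutpoints[[v]])) {
      left <- if (split$type == "cat")
        as.character(data[[v]]) %in% split$left
      else data[[v]] < split$threshold
      nl <- sum(left); nr <- n - nl
      if (nl < config$min_node_size || nr < config$min_node_size) next
      cl <- sum(y[left]); cr <- n_case - cl
      gain <- parent - (nl * impf(cl, nl - cl) + nr * impf(cr, nr - cr)) / n
      if (is.null(best) || gain > best$gain + 1e-12)
        best <- list(variable = v, split = split, gain = gain)
    }
  }
  best
}
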