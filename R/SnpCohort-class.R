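#' SnpCohort: a case-control SNP cohort
#'
#' An S4 container for one arm of a case-control candidate-SNP study,
#' extending
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class].
#' The single assay `"geno"` is a character matrix of genotype calls with
#' SNPs as rows and subjects as columns; values are `"AA"` (homozygous
#' wild), `"AB"` (heterozygous), `"BB"` (homozygous variant) or `NA`
#' (missing call).  `rowData` holds the SNP panel (`snp_id`, `gene`,
#' `wild_allele`, `variant_allele`, optionally `risk_allele`); `colData`
#' holds the phenotype and covariates, at minimum a `status` column with
#' values `"case"`, `"control"` or `"indeterminate"`.
#'
#' @slot .. no additional slots; see the constructor [SnpCohort()].
#' @seealso [SnpCohort()], [readCohort()], [simulateCaseControl()]
#' @name SnpCohort-class
#' @aliases SnpCohort-class
#' @exportClass SnpCohort
setClass("SnpCohort", contains = "SummarizedExperiment")

STATUS_LEVELS <- c("case", "control", "indeterminate")

setValidity("SnpCohort", function(object) {
  msg <- character()
  if (!"geno" %in% assayNames(object))
    return("assay 'geno' is required")
  g <- assay(object, "geno")
  if (!is.character(g))
    msg <- c(msg, "genotype assay must be a character matrix")
  bad <- !(g %in% GENOTYPE_LEVELS | is.na(g))
  if (any(bad))
    msg <- c(msg, sprintf("invalid genotype calls: %s",
                          paste(unique(g[bad]), collapse = ", ")))
  rd <- rowData(object)
  need <- c("snp_id", "gene", "wild_allele", "variant_allele")
  if (!all(need %in% colnames(rd))) {
    msg <- c(msg, sprintf("rowData must contain columns: %s",
                          paste(need, collapse = ", ")))
  } else {
    if (anyDuplicated(rd$snp_id))
      msg <- c(msg, "duplicate snp_id in panel")
    same <- !is.na(rd$wild_allele) & !is.na(rd$variant_allele) &
      rd$wild_allele == rd$variant_allele
    if (any(same))
      msg <- c(msg, sprintf("wild and variant allele identical for %s",
                            paste(rd$snp_id[same], collapse = ", ")))
  }
  cd <- colData(object)
  if (!"status" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'status' column")
  } else if (!all(cd$status %in% STATUS_LEVELS)) {
    msg <- c(msg, "status values must be 'case', 'control' or 'indeterminate'")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate subject ids")
  # CNE must be the equal-energy combination of SPL and years of exposure
  if (all(c("cne", "spl", "years_exposure") %in% colnames(cd))) {
    ok <- is.na(cd$cne) | is.na(cd$spl) | is.na(cd$years_exposure)
    expect <- suppressWarnings(computeCNE(cd$spl[!ok], cd$years_exposure[!ok]))
    if (length(expect) && any(abs(expect - cd$cne[!ok]) > 0.05))
      msg <- c(msg, "cne inconsistent with spl and years_exposure")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SnpCohort
#'
#' @param genotypes character matrix of calls in `{"AA","AB","BB",NA}`,
#'   either subjects x SNPs (default orientation of the flat-file inputs)
#'   or SNPs x subjects; orientation is resolved against `panel$snp_id`.
#' @param panel `data.frame` with columns `snp_id`, `gene`, `wild_allele`,
#'   `variant_allele` and optionally `risk_allele`.
#' @param phenotype `data.frame` with one row per subject, rownames (or a
#'   `subject_id` column) giving subject ids, and at least a `status`
#'   column (`"case"`/`"control"`/`"indeterminate"`, or 1/0).
#' @param stageLabel free-text label for the study stage
#'   (e.g. `"screening"`, `"replication"`).
#' @return A validated [SnpCohort-class] object.
#' @examples
#' panel <- data.frame(snp_id = "rs1", gene = "GJB2",
#'                     wild_allele = "A", variant_allele = "B")
#' geno <- matrix(c("AA", "AB", "BB"), nrow = 3,
#'                dimnames = list(c("s1", "s2", "s3"), "rs1"))
#' phen <- data.frame(status = c("case", "control", "case"),
#'                    row.names = c("s1", "s2", "s3"))
#' SnpCohort(geno, panel, phen, stageLabel = "demo")
#' @export
SnpCohort <- function(genotypes, panel, phenotype, stageLabel = "cohort") {
  panel <- as.data.frame(panel, stringsAsFactors = FALSE)
  if (!"risk_allele" %in% colnames(panel))
    panel$risk_allele <- NA_character_
  genotypes <- as.matrix(genotypes)
  if (!is.null(colnames(genotypes)) &&
      all(panel$snp_id %in% colnames(genotypes)) &&
      !all(panel$snp_id %in% rownames(genotypes))) {
    genotypes <- t(genotypes)  # subjects x SNPs -> SNPs x subjects
  }
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- panel$snp_id
  phenotype <- as.data.frame(phenotype, stringsAsFactors = FALSE)
  if ("subject_id" %in% colnames(phenotype)) {
    if (anyDuplicated(phenotype$subject_id))
      stop("duplicate subject ids: ",
           paste(unique(phenotype$subject_id[duplicated(phenotype$subject_id)]),
                 collapse = ", "))
    rownames(phenotype) <- phenotype$subject_id
    phenotype$subject_id <- NULL
  }
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- rownames(phenotype)
  orphans_g <- setdiff(colnames(genotypes), rownames(phenotype))
  orphans_p <- setdiff(rownames(phenotype), colnames(genotypes))
  if (length(orphans_g) || length(orphans_p))
    stop("phenotype/genotype subject id mismatch; orphans: ",
         paste(c(orphans_g, orphans_p), collapse = ", "))
  genotypes <- genotypes[panel$snp_id, rownames(phenotype), drop = FALSE]
  phenotype$status <- normalizeStatus(phenotype$status)
  if (all(c("spl", "years_exposure") %in% colnames(phenotype)) &&
      !"cne" %in% colnames(phenotype)) {
    phenotype$cne <- computeCNE(phenotype$spl, phenotype$years_exposure)
  }
  se <- SummarizedExperiment(
    assays = list(geno = genotypes),
    rowData = DataFrame(panel, row.names = panel$snp_id),
    colData = DataFrame(phenotype))
  metadata(se)$stage_label <- stageLabel
  new("SnpCohort", se)
}

normalizeStatus <- function(status) {
  if (is.numeric(status) || is.logical(status))
    return(ifelse(is.na(status), "indeterminate",
                  ifelse(as.numeric(status) == 1, "case", "control")))
  s <- tolower(as.character(status))
  s[is.na(s)] <- "indeterminate"
  s
}

#' @rdname SnpCohort
#' @param object,x a `SnpCohort`.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname SnpCohort
#' @export
setMethod("genotypes", "SnpCohort", function(x) assay(x, "geno"))

#' @rdname SnpCohort
#' @export
setGeneric("snpPanel", function(x) standardGeneric("snpPanel"))

#' @rdname SnpCohort
#' @export
setMethod("snpPanel", "SnpCohort",
          function(x) as.data.frame(rowData(x)))

#' @rdname SnpCohort
#' @export
setGeneric("caseStatus", function(x) standardGeneric("caseStatus"))

#' @rdname SnpCohort
#' @export
setMethod("caseStatus", "SnpCohort", function(x) {
  setNames(colData(x)$status, colnames(x))
})

#' @rdname SnpCohort
#' @export
setGeneric("stageLabel", function(x) standardGeneric("stageLabel"))

#' @rdname SnpCohort
#' @export
setMethod("stageLabel", "SnpCohort", function(x) metadata(x)$stage_label)

#' @rdname SnpCohort
#' @export
setGeneric("nCases", function(x) standardGeneric("nCases"))

#' @rdname SnpCohort
#' @export
setMethod("nCases", "SnpCohort",
          function(x) sum(colData(x)$status == "case"))

#' @rdname SnpCohort
#' @export
setGeneric("nControls", function(x) standardGeneric("nControls"))

#' @rdname SnpCohort
#' @export
setMethod("nControls", "SnpCohort",
          function(x) sum(colData(x)$status == "control"))

setMethod("show", "SnpCohort", function(object) {
  cat(sprintf("SnpCohort '%s': %d SNPs x %d subjects (%d cases, %d controls)\n",
              stageLabel(object), nrow(object), ncol(object),
              nCases(object), nControls(object)))
  covs <- setdiff(colnames(colData(object)), "status")
  if (length(covs))
    cat("covariates:", paste(covs, collapse = ", "), "\n")
  invisible(NULL)
})

#' Subject-level covariate table of a cohort
#'
#' @param x a [SnpCohort-class].
#' @return `data.frame` of colData with subject ids as rownames.
#' @export
covariates <- function(x) {
  stopifnot(is(x, "SnpCohort"))
  as.data.frame(colData(x))
}
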