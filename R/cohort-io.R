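#' Read a cohort from genotype, phenotype and panel tables
#'
#' The genotype table has one row per subject (first column `subject_id`)
#' and one column per SNP, with calls written as `AA`/`AB`/`BB` or in
#' VCF-style `0/0`, `0/1`, `1/1`, `./.` notation.  The phenotype table has
#' one row per subject with a `status` column plus covariates; the panel
#' table describes the SNPs (`snp_id`, `gene`, `wild_allele`,
#' `variant_allele`).  Unparseable genotype strings become missing calls
#' with a single summary warning.
#'
#' @param genotype_path,phenotype_path,panel_path paths to delimited text
#'   files.
#' @param sep field delimiter (default tab; use `","` for CSV).
#' @param missing token denoting a missing value (default `"NA"`).
#' @param stageLabel stage label stored in the cohort metadata.
#' @return A [SnpCohort-class].
#' @seealso [writeCohort()], [importVCF()]
#' @export
readCohort <- function(genotype_path, phenotype_path, panel_path,
                       sep = "\t", missing = "NA", stageLabel = "cohort") {
  for (p in c(genotype_path, phenotype_path, panel_path))
    if (!file.exists(p)) stop("file not found: ", p)
  rd <- function(p) read.table(p, header = TRUE, sep = sep,
                               na.strings = missing, check.names = FALSE,
                               stringsAsFactors = FALSE, quote = "\"")
  gt <- rd(genotype_path)
  ph <- rd(phenotype_path)
  panel <- rd(panel_path)
  if (!"subject_id" %in% colnames(gt))
    stop("genotype table must have a 'subject_id' column")
  if (anyDuplicated(gt$subject_id))
    stop("duplicate subject ids in genotype table: ",
         paste(unique(gt$subject_id[duplicated(gt$subject_id)]), collapse = ", "))
  ids <- gt$subject_id
  g <- as.matrix(gt[, setdiff(colnames(gt), "subject_id"), drop = FALSE])
  rownames(g) <- ids
  parsed <- parseCalls(g)
  if (parsed$n_bad > 0)
    warning(sprintf("%d unparseable genotype call(s) set to missing",
                    parsed$n_bad))
  SnpCohort(parsed$calls, panel, ph, stageLabel = stageLabel)
}

# normalize genotype strings to AA/AB/BB/NA; counts unparseable cells
parseCalls <- function(g) {
  out <- matrix(NA_character_, nrow(g), ncol(g), dimnames = dimnames(g))
  v <- gsub("\\s", "", as.character(g))
  v[v %in% c("", ".", "./.", ".|.")] <- NA
  map <- c("AA" = "AA", "AB" = "AB", "BA" = "AB", "BB" = "BB",
           "0/0" = "AA", "0|0" = "AA", "0/1" = "AB", "1/0" = "AB",
           "0|1" = "AB", "1|0" = "AB", "1/1" = "BB", "1|1" = "BB")
  ok <- v %in% names(map) | is.na(v)
  out[] <- unname(map[v])
  list(calls = out, n_bad = sum(!ok))
}

#' Write a cohort back to its three flat tables
#'
#' Inverse of [readCohort()]: writes the genotype matrix (subjects x SNPs),
#' the phenotype table and the SNP panel as delimited text.  Round-trips
#' genotype calls and covariates exactly.
#'
#' @param cohort a [SnpCohort-class].
#' @param genotype_path,phenotype_path,panel_path output paths.
#' @param sep field delimiter.
#' @param missing token written for missing values.
#' @return Invisibly, the three paths.
#' @export
writeCohort <- function(cohort, genotype_path, phenotype_path, panel_path,
                        sep = "\t", missing = "NA") {
  g <- t(genotypes(cohort))
  gt <- data.frame(subject_id = rownames(g), g, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ph <- covariates(cohort)
  ph <- data.frame(subject_id = rownames(ph), ph, check.names = FALSE,
                   stringsAsFactors = FALSE)
  wr <- function(x, p) write.table(x, p, sep = sep, quote = FALSE,
                                   row.names = FALSE, na = missing)
  wr(gt, genotype_path)
  wr(ph, phenotype_path)
  wr(snpPanel(cohort), panel_path)
  invisible(c(genotype_path, phenotype_path, panel_path))
}

#' Import genotype calls from a VCF
#'
#' Reads diploid `GT` fields and converts them to panel-oriented calls:
#' `0/0 -> AA`, `0/1` or `1/0 -> AB`, `1/1 -> BB`, anything else missing.
#' Calls are stored relative to the panel's declared wild allele, never to
#' the VCF REF: when the panel says the variant allele is the reference
#' base, homozygote calls are flipped.  Requires the VariantAnnotation
#' package.
#'
#' @param vcf_path path to a VCF 4.x file (plain or bgzipped).
#' @param panel SNP panel `data.frame` (`snp_id`, `wild_allele`,
#'   `variant_allele`); sites are matched by VCF ID.
#' @return Character matrix of calls, subjects x SNPs (panel order).
#' @export
importVCF <- function(vcf_path, panel) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("importVCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "unknown")
  ids <- rownames(vcf)
  hit <- match(panel$snp_id, ids)
  if (anyNA(hit))
    stop("panel SNPs absent from VCF: ",
         paste(panel$snp_id[is.na(hit)], collapse = ", "))
  alt <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(alt)[hit]
  if (any(nalt > 1))
    stop("multi-allelic site(s) matching panel SNPs: ",
         paste(ids[hit][nalt > 1], collapse = ", "))
  gtm <- VariantAnnotation::geno(vcf)$GT[hit, , drop = FALSE]
  parsed <- parseCalls(gtm)
  calls <- parsed$calls
  ref <- as.character(VariantAnnotation::ref(vcf))[hit]
  altc <- vapply(alt[hit], function(a)
    if (length(a)) as.character(a)[1] else NA_character_, character(1))
  flip <- !is.na(ref) & ref == panel$variant_allele &
    !is.na(altc) & altc == panel$wild_allele
  if (any(flip)) {
    sub <- calls[flip, , drop = FALSE]
    sub[sub == "AA"] <- "xx"
    sub[sub == "BB"] <- "AA"
    sub[sub == "xx"] <- "BB"
    calls[flip, ] <- sub
  }
  rownames(calls) <- panel$snp_id
  t(calls)
}
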