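#' Read panel genotypes from a VCF file
#'
#' Extracts hard-call genotypes (GT) for the loci of a risk-allele map from
#' a VCF and returns a dosage matrix counting the risk allele: the ALT
#' allele count is taken per sample and flipped (`2 - d`) at sites where the
#' REF allele is the risk allele. Requires the `vcfR` package.
#'
#' @param path Path to a VCF file (sites must carry the map's SNP ids in
#'   the ID column).
#' @param map Risk-allele map, default [risk_allele_map()].
#' @return Dosage matrix (samples x loci, `NA` for missing calls) with a
#'   `counted_allele` attribute; already risk-aligned.
#' @export
read_genotypes_vcf <- function(path, map = risk_allele_map()) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  keep <- ids %in% map$snp
  if (!any(keep)) stop("no panel SNPs found in VCF", call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  alt_count <- function(s) {
    if (is.na(s)) return(NA_integer_)
    alleles <- strsplit(sub(":.*", "", s), "[/|]")[[1L]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles != "0")
  }
  dos <- t(apply(gt, 1L, function(r) vapply(r, alt_count, integer(1))))
  rownames(dos) <- fix[, "ID"]
  dos <- t(dos)  # samples x loci
  m <- match(colnames(dos), map$snp)
  risk <- map$risk_allele[m]
  bad <- risk != fix[, "REF"] & risk != fix[, "ALT"]
  if (any(bad)) {
    stop(sprintf("risk allele matches neither REF nor ALT at: %s",
                 paste(colnames(dos)[bad], collapse = ", ")), call. = FALSE)
  }
  counted <- ifelse(risk == fix[, "ALT"], fix[, "ALT"], fix[, "REF"])
  flip <- counted == fix[, "REF"]
  dos[, flip] <- 2L - dos[, flip, drop = FALSE]
  attr(dos, "counted_allele") <- stats::setNames(map$risk_allele[m],
                                                 colnames(dos))
  storage.mode(dos) <- "integer"
  dos
}

#' Write a simulated cohort to TSV
#'
#' Plain-text tab-separated export of a cohort table (see
#' [simulate_cohort()]) for use outside R.
#'
#' @param cohort Cohort `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from TSV
#'
#' @param path Path to a tab-separated cohort table with a header.
#' @return A `data.frame`.
#' @export
read_cohort_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
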