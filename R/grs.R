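#' The 12-locus obesity susceptibility panel
#'
#' Default risk-allele map for the unweighted GRS: one row per locus with the
#' SNP id, nearest gene, the BMI-raising (risk) allele reported by the
#' discovery meta-analyses, and the other allele. Dosages are counted on the
#' risk allele, so a GRS ranges over 0-24 alleles.
#'
#' @return A `data.frame` with columns `snp`, `gene`, `risk_allele`,
#'   `other_allele` (12 rows, panel order FTO, SH2B1, SEC16B, MTCH2, MC4R,
#'   NEGR1, TMEM18, GNPDA2, BDNF, KCTD15, ETV5, FAIM2).
#' @export
risk_allele_map <- function() {
  data.frame(
    snp = c("rs1121980", "rs7498665", "rs10913469", "rs10838738",
            "rs17782313", "rs3101336", "rs6548238", "rs10938397",
            "rs925946", "rs368794", "rs7647305", "rs7132908"),
    gene = c("FTO", "SH2B1", "SEC16B", "MTCH2", "MC4R", "NEGR1", "TMEM18",
             "GNPDA2", "BDNF", "KCTD15", "ETV5", "FAIM2"),
    risk_allele = c("T", "G", "C", "G", "C", "C", "C", "G", "T", "T",
                    "C", "A"),
    other_allele = c("C", "A", "T", "A", "T", "T", "T", "A", "G", "C",
                     "T", "G"),
    stringsAsFactors = FALSE)
}

ambiguous_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Orient genotype dosages onto the risk allele
#'
#' Ensures every column of a dosage matrix counts the BMI-raising allele.
#' Columns whose counted allele is the map's other allele are flipped
#' (`d -> 2 - d`); columns already counting the risk allele pass unchanged.
#' A counted allele matching neither allele of the locus is an error.
#' Strand-ambiguous loci (A/T or C/G pairs) cannot be checked against an
#' opposite-strand report; by convention they are assumed to be reported on
#' the map's strand, with a warning.
#'
#' @param geno Dosage matrix (participants x loci) with column names
#'   matching `map$snp` or `map$gene`, and a `counted_allele` attribute (or
#'   the `counted` argument) naming the allele each column counts.
#' @param map Risk-allele map, default [risk_allele_map()].
#' @param counted Optional character vector of counted alleles per column;
#'   overrides the attribute.
#' @return The matrix with all columns risk-aligned; attribute `flipped`
#'   records which loci were complemented.
#' @export
align_risk_alleles <- function(geno, map = risk_allele_map(),
                               counted = attr(geno, "counted_allele")) {
  loci <- colnames(geno)
  if (is.null(loci)) stop("`geno` must have column names", call. = FALSE)
  idx <- match(loci, map$snp)
  idx[is.na(idx)] <- match(loci[is.na(idx)], map$gene)
  if (anyNA(idx)) {
    stop(sprintf("locus absent from the risk-allele map: %s",
                 paste(loci[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  if (is.null(counted)) {
    stop("counted alleles unknown: supply `counted` or a `counted_allele` attribute",
         call. = FALSE)
  }
  risk <- map$risk_allele[idx]
  other <- map$other_allele[idx]
  amb <- ambiguous_pair(risk, other)
  if (any(amb)) {
    warning(sprintf(
      "strand-ambiguous loci assumed reported on the map strand: %s",
      paste(loci[amb], collapse = ", ")), call. = FALSE)
  }
  flip <- counted == other
  bad <- !flip & counted != risk
  if (any(bad)) {
    stop(sprintf("counted allele matches neither allele at: %s",
                 paste(loci[bad], collapse = ", ")), call. = FALSE)
  }
  out <- geno
  if (any(flip)) out[, flip] <- 2 - out[, flip, drop = FALSE]
  attr(out, "counted_allele") <- stats::setNames(risk, loci)
  attr(out, "flipped") <- loci[flip]
  out
}

#' Per-locus genotype quality control
#'
#' Computes, for each locus, the call rate, counted-allele frequency,
#' genotype counts, and a 1-df chi-square Hardy-Weinberg equilibrium test
#' (no continuity correction) on the called genotypes. Loci failing either
#' threshold are flagged, not dropped: in a small fixed panel a failing
#' variant is a sensitivity-analysis question, not an automatic exclusion.
#'
#' @param geno Dosage matrix with entries 0/1/2 or `NA`.
#' @param min_call_rate Minimum acceptable call rate (default 0.95).
#' @param hwe_alpha HWE rejection level (default 0.001).
#' @return A `data.frame` (class `grs_qc`) with one row per locus: `locus`,
#'   `n_called`, `call_rate`, `freq`, `n0`, `n1`, `n2`, `hwe_chisq`,
#'   `hwe_p`, `pass_call_rate`, `pass_hwe`, `note`.
#' @export
qc_variants <- function(geno, min_call_rate = 0.95, hwe_alpha = 0.001) {
  stop_if_not_scalar_prob(min_call_rate, "min_call_rate", open = FALSE)
  stop_if_not_scalar_prob(hwe_alpha, "hwe_alpha")
  loci <- colnames(geno)
  if (is.null(loci)) loci <- paste0("locus", seq_len(ncol(geno)))
  rows <- lapply(seq_len(ncol(geno)), function(j) {
    d <- geno[, j]
    called <- d[!is.na(d)]
    n0 <- sum(called == 0); n1 <- sum(called == 1); n2 <- sum(called == 2)
    nc <- length(called)
    freq <- if (nc > 0) (n1 + 2 * n2) / (2 * nc) else NA_real_
    h <- hwe_chisq_test(n0, n1, n2)
    data.frame(locus = loci[j], n_called = nc,
               call_rate = nc / nrow(geno), freq = freq,
               n0 = n0, n1 = n1, n2 = n2,
               hwe_chisq = h$chisq, hwe_p = h$p,
               pass_call_rate = nc / nrow(geno) >= min_call_rate,
               pass_hwe = h$p > hwe_alpha,
               note = h$note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("grs_qc", "data.frame")
  out
}

# 1-df chi-square HWE test on genotype counts (hom-ref, het, hom-alt).
hwe_chisq_test <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0) return(list(chisq = NA_real_, p = NA_real_, note = "no calls"))
  p <- (n1 + 2 * n2) / (2 * n)
  if (p == 0 || p == 1) {
    return(list(chisq = 0, p = 1, note = "monomorphic"))
  }
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chisq <- sum((c(n0, n1, n2) - expected)^2 / expected)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       note = "")
}

#' Compute the unweighted genetic risk score
#'
#' Sums risk-allele dosages over the panel. Participants missing at most
#' `max_missing` genotypes have each missing dosage replaced by its expected
#' value, twice the risk-allele frequency among participants called at that
#' locus; participants missing more are excluded (GRS `NA`, `excluded` set).
#'
#' @param geno Risk-aligned dosage matrix (0/1/2/`NA`).
#' @param max_missing Maximum missing loci tolerated per participant
#'   (default 4).
#' @return A `data.frame` (class `grs_result`) with columns `grs`,
#'   `n_missing_loci`, `excluded`; attribute `n_imputed` counts imputed
#'   entries and `imputed_dosage` gives the per-locus expected dosage used.
#' @export
compute_grs <- function(geno, max_missing = 4) {
  stopifnot(max_missing >= 0)
  freqs <- vapply(seq_len(ncol(geno)), function(j) {
    d <- geno[, j]
    d <- d[!is.na(d)]
    if (length(d) == 0L) {
      nm <- colnames(geno)[j]
      stop(sprintf("locus %s has no called genotypes; cannot impute",
                   if (is.null(nm)) j else nm), call. = FALSE)
    }
    mean(d) / 2
  }, numeric(1))
  expected <- 2 * freqs
  n_missing <- rowSums(is.na(geno))
  excluded <- n_missing > max_missing
  filled <- geno
  miss <- is.na(filled)
  filled[miss] <- expected[col(filled)[miss]]
  grs <- rowSums(filled)
  grs[excluded] <- NA_real_
  out <- data.frame(grs = grs, n_missing_loci = n_missing,
                    excluded = excluded)
  attr(out, "n_imputed") <- sum(miss & !excluded)
  attr(out, "imputed_dosage") <- stats::setNames(expected, colnames(geno))
  class(out) <- c("grs_result", "data.frame")
  out
}

#' Dichotomize a genetic risk score
#'
#' Splits the score at a cut point: 1 for `grs > cut`, 0 otherwise. The data
#' analyses split at 11 alleles; the power framework splits at the GRS mean,
#' where the indicator variance attains its maximum 0.25.
#'
#' @param grs Numeric GRS vector.
#' @param cut Threshold in alleles (default 11).
#' @return Integer 0/1 vector (`NA` preserved).
#' @export
#' @examples
#' dichotomize_grs(c(10, 11, 11.01, 14))
dichotomize_grs <- function(grs, cut = 11) {
  stopifnot(is.numeric(grs), is.finite(cut))
  as.integer(grs > cut)
}
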