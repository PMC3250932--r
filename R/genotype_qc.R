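#' Read an allele-dosage matrix
#'
#' Reads a PLINK-RAW-style rectangular table: identifier column(s) followed
#' by one column per locus holding B-allele dosages 0/1/2 (`NA` = missing).
#' An `IID` column (or the first column, if no `FID`/`IID` header is
#' present) provides animal ids. Any entry outside \{0, 1, 2, NA\} is a
#' fatal error reported with its coordinates.
#'
#' @param path Path to a whitespace- or tab-delimited file with header.
#' @return A `kinfold_markers` object: list with `geno` (animals x loci
#'   numeric matrix, dimnames set) and `qc` (per-locus call rate, MAF and
#'   Hardy-Weinberg chi-square, see [locus_qc()]).
#' @export
read_dosages <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  id_cols <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                       names(tab))
  ids <- if ("IID" %in% names(tab)) as.character(tab$IID) else
    as.character(tab[[1]])
  if (!length(id_cols)) id_cols <- names(tab)[1]
  locus_cols <- setdiff(names(tab), id_cols)
  if (!length(locus_cols)) stop("no dosage columns found")
  geno <- as.matrix(tab[, locus_cols, drop = FALSE])
  if (!is.numeric(geno)) {
    suppressWarnings(storage.mode(geno) <- "double")
  }
  bad <- which(!(is.na(geno) | geno %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid dosage at animal '%s', locus '%s'",
                 ids[bad[1, 1]], locus_cols[bad[1, 2]]))
  }
  dimnames(geno) <- list(ids, locus_cols)
  as_markers(geno)
}

#' Build a marker matrix object
#'
#' @param geno Animals x loci numeric matrix of B-allele dosages with
#'   dimnames; `NA` = missing.
#' @return A `kinfold_markers` with freshly computed per-locus QC.
#' @export
as_markers <- function(geno) {
  stopifnot(is.matrix(geno), !is.null(rownames(geno)), !is.null(colnames(geno)))
  out <- list(geno = geno, qc = locus_qc(geno))
  class(out) <- "kinfold_markers"
  out
}

#' Per-locus quality-control statistics
#'
#' Call rate, B-allele frequency, minor allele frequency, and the Pearson
#' Hardy-Weinberg chi-square on the three genotype classes with expected
#' counts \eqn{n(1-p)^2, 2np(1-p), np^2} from the sample allele frequency
#' (1 degree of freedom). Monomorphic loci have chi-square 0; loci with no
#' observed calls have `NA` frequency statistics.
#'
#' @param geno Animals x loci dosage matrix.
#' @return Data frame: `locus`, `n_obs`, `cr`, `p_b`, `maf`, `hwe_chi2`.
#' @export
locus_qc <- function(geno) {
  n <- nrow(geno)
  n0 <- colSums(geno == 0, na.rm = TRUE)
  n1 <- colSums(geno == 1, na.rm = TRUE)
  n2 <- colSums(geno == 2, na.rm = TRUE)
  n_obs <- n0 + n1 + n2
  p <- ifelse(n_obs > 0, (n1 + 2 * n2) / (2 * n_obs), NA_real_)
  maf <- pmin(p, 1 - p)
  chi2 <- hwe_chisq(n0, n1, n2)
  data.frame(locus = colnames(geno), n_obs = n_obs, cr = n_obs / n,
             p_b = p, maf = maf, hwe_chi2 = chi2,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Pearson 1-df HWE chi-square from genotype class counts (vectorised).
hwe_chisq <- function(n0, n1, n2) {
  n_obs <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * n_obs)
  e0 <- n_obs * (1 - p)^2
  e1 <- n_obs * 2 * p * (1 - p)
  e2 <- n_obs * p^2
  term <- function(o, e) ifelse(e > 0, (o - e)^2 / e, 0)
  chi2 <- term(n0, e0) + term(n1, e1) + term(n2, e2)
  chi2[n_obs == 0] <- NA_real_
  chi2
}

#' Remove animals with low genotype call rate
#'
#' @param M A `kinfold_markers`.
#' @param min_call Minimum per-animal call rate; animals below it are
#'   removed (default 0.95).
#' @return Filtered `kinfold_markers`; removed ids in attribute
#'   `removed_animals`.
#' @export
filter_animals <- function(M, min_call = 0.95) {
  stopifnot(inherits(M, "kinfold_markers"))
  cr <- rowMeans(!is.na(M$geno))
  drop <- cr < min_call
  if (all(drop)) stop("all animals removed by the call-rate filter")
  out <- as_markers(M$geno[!drop, , drop = FALSE])
  attr(out, "removed_animals") <- rownames(M$geno)[drop]
  out
}

#' Remove loci failing quality control
#'
#' A locus is removed if it fails any of: call rate below `min_cr`
#' (default 0.90), minor allele frequency below `min_maf` (default 0.01,
#' which also removes monomorphic loci), or Hardy-Weinberg chi-square above
#' `max_hwe_chi2` (default 300). The criteria overlap, so per-criterion
#' counts (attribute `filter_counts`) can sum to more than the number of
#' loci removed.
#'
#' @param M A `kinfold_markers`.
#' @param min_cr,min_maf,max_hwe_chi2 Thresholds.
#' @return Filtered `kinfold_markers` with attributes `filter_counts` and
#'   `removed_loci`.
#' @export
filter_loci <- function(M, min_cr = 0.90, min_maf = 0.01,
                        max_hwe_chi2 = 300) {
  stopifnot(inherits(M, "kinfold_markers"))
  qc <- M$qc
  fail_cr <- qc$cr < min_cr
  fail_maf <- is.na(qc$maf) | qc$maf < min_maf
  fail_hwe <- !is.na(qc$hwe_chi2) & qc$hwe_chi2 > max_hwe_chi2
  drop <- fail_cr | fail_maf | fail_hwe
  if (all(drop)) stop("all loci removed by quality-control filters")
  out <- as_markers(M$geno[, !drop, drop = FALSE])
  attr(out, "filter_counts") <- c(call_rate = sum(fail_cr),
                                  maf = sum(fail_maf),
                                  hwe = sum(fail_hwe),
                                  removed = sum(drop))
  attr(out, "removed_loci") <- qc$locus[drop]
  out
}

#' Impute missing dosages with the locus mean
#'
#' Deterministically replaces each missing dosage with the mean observed
#' dosage at that locus (real-valued dosages are accepted downstream).
#'
#' @param M A `kinfold_markers`.
#' @return A `kinfold_markers` with no missing entries.
#' @export
impute_missing <- function(M) {
  stopifnot(inherits(M, "kinfold_markers"))
  geno <- M$geno
  means <- colMeans(geno, na.rm = TRUE)
  if (any(!is.finite(means))) {
    stop("locus with zero observed calls: ",
         paste(colnames(geno)[!is.finite(means)][1:1], collapse = ", "))
  }
  nas <- which(is.na(geno), arr.ind = TRUE)
  if (nrow(nas)) geno[nas] <- means[nas[, 2]]
  as_markers(geno)
}

#' @export
print.kinfold_markers <- function(x, ...) {
  cat("Marker matrix:", nrow(x$geno), "animals x", ncol(x$geno), "loci;",
      format(100 * mean(is.na(x$geno)), digits = 3), "% missing\n")
  invisible(x)
}
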