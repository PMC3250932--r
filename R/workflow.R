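#' Run the full genomic-prediction analysis
#'
#' Orchestrates the pipeline for one trait: genotype quality control and
#' imputation, deregression of EBVs, pedigree relationship and
#' dissimilarity matrices, fold construction (relationship-aware K-means,
#' random, or birth-year split), a preliminary full-data BayesC run for
#' variance priors, per-fold training and prediction so every animal's
#' DGV excludes its own record, and validation statistics (per-group and
#' pooled accuracy, bias slope, parent-average blending). Optionally fits
#' the bivariate animal model for the genetic correlation between the
#' trait and its DGV. All randomness derives from `seed`, so a
#' configuration fully determines the report.
#'
#' @param ped Pedigree: a `kinfold_pedigree` or a file path for
#'   [read_pedigree()].
#' @param markers Genotypes: a `kinfold_markers`, a dosage matrix, or a
#'   file path for [read_dosages()].
#' @param records Trait-record table (see [deregress_table()]); may
#'   include a `birth_year` column, otherwise years come from the
#'   pedigree.
#' @param h2 Trait heritability.
#' @param scheme Fold construction: `"kmeans"`, `"random"` or `"age"`.
#' @param K Number of folds (kmeans/random).
#' @param n_start K-means restarts.
#' @param valid_fraction Validation share for the age split.
#' @param replicate Replicate index for random folds.
#' @param c Deregression marker-variance fraction parameter.
#' @param bayesc A [bayesc_config()]; its seed is re-derived from `seed`.
#' @param min_animal_call,min_locus_cr,min_maf,max_hwe_chi2 QC thresholds.
#' @param bivar If `TRUE`, also fit [fit_bivariate()].
#' @param outdir Optional directory for TSV artifacts.
#' @param seed Master seed.
#' @return A `kinfold_report`: per-animal table (`animals`), `accuracy`
#'   (pooled), `group_accuracy`, `slope`, blending results, variance
#'   components, the partition, diagnostics, and optionally `bivar_fit`.
#' @export
run_pipeline <- function(ped, markers, records, h2,
                         scheme = c("kmeans", "random", "age"),
                         K = 5, n_start = 25, valid_fraction = 0.20,
                         replicate = 1, c = 0.5,
                         bayesc = bayesc_config(),
                         min_animal_call = 0.95, min_locus_cr = 0.90,
                         min_maf = 0.01, max_hwe_chi2 = 300,
                         bivar = FALSE, outdir = NULL, seed = 1) {
  scheme <- match.arg(scheme)
  if (is.character(ped)) ped <- read_pedigree(ped)
  if (is.character(markers)) markers <- read_dosages(markers)
  if (is.matrix(markers)) markers <- as_markers(markers)

  # --- QC and imputation
  markers <- filter_animals(markers, min_animal_call)
  markers <- filter_loci(markers, min_locus_cr, min_maf, max_hwe_chi2)
  markers <- impute_missing(markers)

  # --- deregression
  dereg <- deregress_table(records, h2 = h2, c = c)
  usable <- dereg$flag %in% c("ok", "founder")
  ids <- intersect(dereg$animal[usable], rownames(markers$geno))
  if (length(ids) < 2 * K) stop("too few usable genotyped records")
  dtab <- dereg[match(ids, dereg$animal), ]
  geno <- markers$geno[ids, , drop = FALSE]

  yr_lookup <- stats::setNames(ped$birth_year, ped$animal)
  birth_years <- if ("birth_year" %in% names(records)) {
    stats::setNames(records$birth_year, records$animal)[ids]
  } else yr_lookup[ids]
  if (anyNA(birth_years)) stop("birth years required for validation")

  # --- relationship machinery
  relmat <- build_A(prune_founders(ped, keep = ids), subset = ids)
  parts <- switch(scheme,
    kmeans = kmeans_folds(dissimilarity(relmat), K = K, n_start = n_start,
                          seed = seed),
    random = random_folds(ids, K = K, replicate = replicate, seed = seed),
    age = age_split(ids, birth_years, valid_fraction = valid_fraction))
  diagnostics <- amax_diagnostics(relmat, parts, birth_years = birth_years)

  # --- preliminary variances (full data)
  prelim_cfg <- bayesc
  prelim_cfg$seed <- seed + 1000L
  prelim <- preliminary_variances(geno, dtab$debv, dtab$w, h2 = h2,
                                  config = prelim_cfg)
  var_g <- genetic_variance(h2, prelim$var_p)

  # --- per-fold training and prediction
  folds <- cv_plan(parts)
  dgv <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    cfg_f <- bayesc
    cfg_f$seed <- seed + 2000L + f
    tr <- match(fold$train, ids)
    fit <- bayesc_train(geno[tr, , drop = FALSE], dtab$debv[tr], dtab$w[tr],
                        config = cfg_f, var_g = prelim$var_g,
                        var_e = prelim$var_e)
    dgv[fold$validate] <- predict_dgv(geno[fold$validate, , drop = FALSE],
                                      fit)
  }
  predicted <- !is.na(dgv)
  assignment <- partition_assignments(parts)[ids]

  # --- validation statistics
  pool_ids <- ids[predicted]
  accuracy <- pooled_accuracy(dtab$debv[match(pool_ids, ids)],
                              dgv[pool_ids], birth_years[pool_ids], var_g)
  slope <- bias_slope(dtab$debv[match(pool_ids, ids)], dgv[pool_ids])
  grps <- sort(unique(assignment[pool_ids]))
  group_accuracy <- vapply(grps, function(g) {
    gi <- pool_ids[assignment[pool_ids] == g]
    tryCatch(pooled_accuracy(dtab$debv[match(gi, ids)], dgv[gi],
                             birth_years[gi], var_g),
             error = function(e) NA_real_)
  }, 0)
  names(group_accuracy) <- grps

  blending <- NULL
  has_pa <- predicted & !is.na(dtab$pa_adj[match(ids, ids)])
  if (sum(has_pa) > 3 * K) {
    bi <- ids[has_pa]
    blending <- tryCatch({
      bl <- blend_gebv(dtab$debv[match(bi, ids)], dtab$pa_adj[match(bi, ids)],
                       dgv[bi], assignment[bi], birth_years[bi])
      list(
        b1 = bl$b1, b2 = bl$b2,
        cor_pa_dgv = stats::cor(dtab$pa_adj[match(bi, ids)], dgv[bi]),
        accuracy_pa = pooled_accuracy(dtab$debv[match(bi, ids)],
                                      dtab$pa_adj[match(bi, ids)],
                                      birth_years[bi], var_g),
        accuracy_gebv = pooled_accuracy(dtab$debv[match(bi, ids)], bl$gebv,
                                        birth_years[bi], var_g))
    }, error = function(e) NULL)
  }

  bivar_fit <- NULL
  if (bivar) {
    bivar_fit <- fit_bivariate(dtab$debv[match(pool_ids, ids)], dgv[pool_ids],
                               dtab$w[match(pool_ids, ids)],
                               relmat$A[pool_ids, pool_ids],
                               assignment[pool_ids])
  }

  animals <- data.frame(animal = ids, group = assignment,
                        birth_year = birth_years,
                        debv = dtab$debv, weight = dtab$w,
                        pa_adj = dtab$pa_adj, dgv = dgv[ids],
                        stringsAsFactors = FALSE, row.names = NULL)
  report <- list(scheme = scheme, seed = seed, n = length(ids),
                 animals = animals, accuracy = accuracy,
                 group_accuracy = group_accuracy, slope = slope,
                 blending = blending, var_g = var_g,
                 var_p = prelim$var_p, var_e = prelim$var_e, h2 = h2,
                 partition = parts, diagnostics = diagnostics,
                 bivar_fit = bivar_fit)
  class(report) <- "kinfold_report"

  if (!is.null(outdir)) write_report(report, outdir)
  report
}

# TSV artifacts with a provenance header line
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# kinfold scheme=%s seed=%d n=%d", report$scheme,
                 report$seed, report$n)
  wr <- function(df, file) {
    path <- file.path(outdir, file)
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(df, path, sep = "\t",
                                        row.names = FALSE, quote = FALSE,
                                        append = TRUE))
    path
  }
  wr(report$animals, "animals.tsv")
  wr(data.frame(group = names(report$group_accuracy),
                accuracy = report$group_accuracy,
                stringsAsFactors = FALSE), "group_accuracy.tsv")
  wr(report$diagnostics$summary, "group_diagnostics.tsv")
  summary_df <- data.frame(
    accuracy = report$accuracy, slope = report$slope,
    var_p = report$var_p, var_g = report$var_g, h2 = report$h2,
    b1 = if (is.null(report$blending)) NA else report$blending$b1,
    b2 = if (is.null(report$blending)) NA else report$blending$b2)
  wr(summary_df, "summary.tsv")
  invisible(outdir)
}

#' @export
print.kinfold_report <- function(x, ...) {
  cat("kinfold report (", x$scheme, " folds, n = ", x$n, ")\n", sep = "")
  cat("  pooled accuracy:", format(x$accuracy, digits = 3),
      " bias slope:", format(x$slope, digits = 3), "\n")
  cat("  per-group accuracy:",
      paste(format(x$group_accuracy, digits = 2), collapse = " "), "\n")
  invisible(x)
}
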