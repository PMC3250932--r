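#' Additive genetic variance from heritability
#'
#' \eqn{\sigma_g^2 = h^2 \sigma_p^2}, with the phenotypic variance taken
#' from the full-data analysis (sum of estimated genetic and residual
#' variances).
#'
#' @param h2 Heritability in (0, 1].
#' @param var_p Phenotypic variance (trait units squared).
#' @return Additive genetic variance.
#' @export
genetic_variance <- function(h2, var_p) {
  stopifnot(h2 > 0, h2 <= 1, var_p > 0)
  h2 * var_p
}

# 5-year contemporary-group bins anchored at the minimum birth year of the
# analysed animals.
birth_year_bins <- function(birth_years, width = 5) {
  anchor <- min(birth_years)
  floor((birth_years - anchor) / width)
}

#' Pooled accuracy of genomic predictions
#'
#' Estimates the correlation between true genetic values and DGV as
#' \eqn{\hat\rho = \hat\sigma_{DEBV,DGV} / \sqrt{\sigma_g^2
#' \hat\sigma_{DGV}^2}}, using the DEBV in place of the unobservable
#' genetic values (their covariance with DGV has the same expectation).
#' Contemporary groups (5-year birth intervals anchored at the minimum
#' birth year) are removed by centring within groups; cross-products and
#' degrees of freedom are pooled across groups, which absorbs genetic
#' trend that would otherwise inflate the correlation. Groups with fewer
#' than two animals contribute no degrees of freedom and are dropped.
#'
#' @param debv,dgv Aligned vectors of deregressed EBVs and direct genomic
#'   values.
#' @param birth_years Birth years aligned with the records.
#' @param var_g Additive genetic variance used for standardisation.
#' @return The pooled accuracy estimate (scalar).
#' @export
pooled_accuracy <- function(debv, dgv, birth_years, var_g) {
  stopifnot(length(debv) == length(dgv), length(dgv) == length(birth_years),
            var_g > 0)
  bins <- birth_year_bins(birth_years)
  s_xy <- 0; s_yy <- 0; df <- 0
  for (b in unique(bins)) {
    i <- bins == b
    n_g <- sum(i)
    if (n_g < 2) next
    x <- debv[i] - mean(debv[i])
    y <- dgv[i] - mean(dgv[i])
    s_xy <- s_xy + sum(x * y)
    s_yy <- s_yy + sum(y * y)
    df <- df + (n_g - 1)
  }
  if (df == 0) stop("no contemporary group with two or more animals")
  var_dgv <- s_yy / df
  if (var_dgv == 0) stop("DGV variance is zero within contemporary groups")
  (s_xy / df) / sqrt(var_g * var_dgv)
}

#' Bias of genomic predictions
#'
#' Ordinary least-squares slope of DEBV on DGV (intercept included, no
#' contemporary groups). An unbiased prediction has expected slope 1;
#' values below 1 indicate inflated DGV spread.
#'
#' @param debv,dgv Aligned record vectors.
#' @return The regression slope.
#' @export
bias_slope <- function(debv, dgv) {
  if (stats::var(dgv) == 0) stop("DGV variance is zero")
  unname(stats::coef(stats::lm(debv ~ dgv))[2])
}

#' Blend adjusted parent averages with genomic predictions
#'
#' Fits \eqn{DEBV = fixed + b_1 PA_{adj} + b_2 DGV} by least squares, with
#' contemporary-group fixed effects formed as partition-group x 5-year
#' birth-interval classes, and returns the blending coefficients and the
#' genomic-enhanced breeding values \eqn{GEBV = b_1 PA_{adj} + b_2 DGV}.
#'
#' @param debv,pa_adj,dgv Aligned record vectors.
#' @param groups Partition group of each record.
#' @param birth_years Birth years of the records.
#' @return List with `b1`, `b2`, `gebv`, and the fitted `model`.
#' @export
blend_gebv <- function(debv, pa_adj, dgv, groups, birth_years) {
  stopifnot(length(debv) == length(pa_adj), length(debv) == length(dgv),
            length(debv) == length(groups),
            length(debv) == length(birth_years))
  if (abs(stats::cor(pa_adj, dgv)) > 0.9999) {
    stop("PA_adj and DGV are collinear; blending coefficients undefined")
  }
  cg <- interaction(groups, birth_year_bins(birth_years), drop = TRUE)
  fit <- stats::lm(debv ~ cg + pa_adj + dgv)
  b1 <- unname(stats::coef(fit)["pa_adj"])
  b2 <- unname(stats::coef(fit)["dgv"])
  list(b1 = b1, b2 = b2, gebv = b1 * pa_adj + b2 * dgv, model = fit)
}

#' Summarise a validation report across traits
#'
#' Arithmetic means over traits of the per-trait accuracy, bias slope and
#' PA/DGV correlation columns, the cross-trait aggregates used to headline
#' a multi-trait validation.
#'
#' @param report Data frame with one row per trait; recognised columns:
#'   `accuracy`, `slope`, `cor_pa_dgv` (missing columns are skipped).
#' @param digits Rounding for the summary (default 3).
#' @return Named numeric vector of means.
#' @export
summarize_validation <- function(report, digits = 3) {
  cols <- intersect(c("accuracy", "slope", "cor_pa_dgv"), names(report))
  out <- vapply(cols, function(cl) mean(report[[cl]], na.rm = TRUE), 0)
  round(out, digits)
}
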