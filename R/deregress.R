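#' EBV and reliability from EPD and BIF accuracy
#'
#' Expected progeny differences are half breeding values, so EBV = 2 * EPD;
#' the Beef Improvement Federation accuracy maps to reliability as
#' \eqn{r^2 = 1 - (1 - BIF)^2}.
#'
#' @param epd Expected progeny difference (trait units). Vectorised.
#' @param bif BIF accuracy in \[0, 1\].
#' @return Data frame with columns `ebv` and `r2`.
#' @export
ebv_from_epd <- function(epd, bif) {
  if (any(!is.na(bif) & (bif < 0 | bif > 1))) {
    stop("BIF accuracy must lie in [0, 1]")
  }
  data.frame(ebv = 2 * epd, r2 = 1 - (1 - bif)^2)
}

# Effective information contents (Z'Z_PA, Z'Z_i) of the two-variable
# parent-average / individual mixed-model system
#   C = diag(Z'Z_PA, Z'Z_i) + lambda * [[4, -2], [-2, 2]],
# solved so the model-implied reliabilities match the inputs:
#   lambda * (C^-1)_11 = 0.5 - r2_pa   (PA as predictor of the individual,
#                                       capped at 0.5 by Mendelian sampling)
#   lambda * (C^-1)_22 = 1 - r2_i.
# The closed forms (alpha = 1/(0.5 - r2_pa), delta = (0.5-r2_pa)/(1-r2_i))
# solve this system exactly; a Newton polish enforces the reliability
# residuals below `tol` and guards against degradation near the r2_i ->
# r2_pa boundary. Z'Z_PA may legitimately be negative when the parents'
# published reliability is low relative to the individual's own (their
# apparent information is dominated by the individual's contribution).
garrick_information <- function(r2_pa, r2_i, lambda, tol = 1e-10) {
  stopifnot(r2_pa >= 0, r2_pa < 0.5, r2_i > 0, r2_i < 1)
  alpha <- 1 / (0.5 - r2_pa)
  delta <- (0.5 - r2_pa) / (1 - r2_i)
  ztz_pa <- lambda * (0.5 * alpha - 4) +
    0.5 * lambda * sqrt(alpha^2 + 16 / delta)
  ztz_i <- delta * ztz_pa + 2 * lambda * (2 * delta - 1)

  resid <- function(th) {
    C <- matrix(c(th[1] + 4 * lambda, -2 * lambda,
                  -2 * lambda, th[2] + 2 * lambda), 2, 2)
    Ci <- solve(C)
    c(lambda * Ci[1, 1] - (0.5 - r2_pa), lambda * Ci[2, 2] - (1 - r2_i))
  }
  th <- c(ztz_pa, ztz_i)
  for (it in 1:20) {
    r <- resid(th)
    if (max(abs(r)) < tol) break
    eps <- 1e-6 * (abs(th) + 1)
    J <- cbind((resid(th + c(eps[1], 0)) - r) / eps[1],
               (resid(th + c(0, eps[2])) - r) / eps[2])
    th <- th - solve(J, r)
  }
  r <- resid(th)
  if (max(abs(r)) > 1e-8) {
    stop("deregression information solve did not converge (residual ",
         format(max(abs(r))), ")")
  }
  list(ztz_pa = th[1], ztz_i = th[2], lambda = lambda,
       alpha = alpha, delta = delta, resid = max(abs(r)))
}

# Parent-average inputs under the package conventions: both parents unknown
# -> no PA (founder); one parent known -> r2_pa = r2_known/4, g_pa =
# ebv_known/2; both known -> r2_pa = (r2_s + r2_d)/4, g_pa = (ebv_s+ebv_d)/2.
parent_average_inputs <- function(ebv_s, r2_s, ebv_d, r2_d) {
  s_known <- !is.na(r2_s) && r2_s > 0
  d_known <- !is.na(r2_d) && r2_d > 0
  if (!s_known && !d_known) {
    return(list(g_pa = NA_real_, r2_pa = 0, n_known = 0L))
  }
  if (s_known && d_known) {
    list(g_pa = (ebv_s + ebv_d) / 2, r2_pa = (r2_s + r2_d) / 4, n_known = 2L)
  } else if (s_known) {
    list(g_pa = ebv_s / 2, r2_pa = r2_s / 4, n_known = 1L)
  } else {
    list(g_pa = ebv_d / 2, r2_pa = r2_d / 4, n_known = 1L)
  }
}

#' Deregress one animal's EBV
#'
#' Removes the parent-average contribution from an EBV and undoes the BLUP
#' shrinkage, producing a pseudo-phenotype (DEBV) with its reliability and
#' the analysis weight used for heterogeneous residual variance. The
#' two-variable parent-average/individual mixed-model system is solved for
#' the effective information contents matching the input reliabilities;
#' the right-hand sides are reconstructed as \eqn{(y_{PA}, y_i)' = C (g_{PA},
#' EBV_i)'} and the DEBV is the individual's data average \eqn{y_i / Z'Z_i}.
#'
#' Weight: \eqn{w = (1-h^2) / ((c + (1-r^{*2})/r^{*2}) h^2)}, where `c` is
#' the fraction of genetic variance not captured by markers.
#'
#' @param ebv_i,r2_i Individual EBV and reliability.
#' @param ebv_s,r2_s,ebv_d,r2_d Sire and dam EBV/reliability (`NA` =
#'   unknown parent).
#' @param h2 Trait heritability in (0, 1).
#' @param c Fraction of genetic variance not explained by markers,
#'   in \[0, 1) (default 0.5).
#' @return List with `debv`, `r2_star`, `w`, `flag` (`"ok"`, `"founder"`,
#'   or `"insufficient_own_info"`), and the solved system components
#'   (`g_pa`, `r2_pa`, `ztz_pa`, `ztz_i`, `y_pa`, `y_i`, `lambda`).
#' @export
deregress_animal <- function(ebv_i, r2_i, ebv_s = NA, r2_s = NA,
                             ebv_d = NA, r2_d = NA, h2, c = 0.5) {
  stopifnot(h2 > 0, h2 < 1, c >= 0, c < 1)
  lambda <- (1 - h2) / h2
  weight <- function(r2star) (1 - h2) / ((c + (1 - r2star) / r2star) * h2)
  base <- list(debv = NA_real_, r2_star = NA_real_, w = NA_real_,
               g_pa = NA_real_, r2_pa = NA_real_, ztz_pa = NA_real_,
               ztz_i = NA_real_, y_pa = NA_real_, y_i = NA_real_,
               lambda = lambda)
  if (is.na(r2_i) || r2_i <= 0 || r2_i >= 1) {
    base$flag <- "insufficient_own_info"
    return(base)
  }
  pa <- parent_average_inputs(ebv_s, r2_s, ebv_d, r2_d)
  if (pa$n_known == 0L) {
    # founder: no parent average to remove
    base$debv <- ebv_i
    base$r2_star <- r2_i
    base$w <- weight(r2_i)
    base$r2_pa <- 0
    base$flag <- "founder"
    return(base)
  }
  if (r2_i <= pa$r2_pa) {
    base$g_pa <- pa$g_pa
    base$r2_pa <- pa$r2_pa
    base$flag <- "insufficient_own_info"
    return(base)
  }
  sys <- garrick_information(pa$r2_pa, r2_i, lambda)
  C <- matrix(c(sys$ztz_pa + 4 * lambda, -2 * lambda,
                -2 * lambda, sys$ztz_i + 2 * lambda), 2, 2)
  y <- as.vector(C %*% c(pa$g_pa, ebv_i))
  r2_star <- sys$ztz_i / (sys$ztz_i + lambda)
  list(debv = y[2] / sys$ztz_i, r2_star = r2_star, w = weight(r2_star),
       g_pa = pa$g_pa, r2_pa = pa$r2_pa, ztz_pa = sys$ztz_pa,
       ztz_i = sys$ztz_i, y_pa = y[1], y_i = y[2], lambda = lambda,
       flag = "ok")
}

#' Deregress a table of trait records
#'
#' Applies [deregress_animal()] to each record of a per-trait table of EPD
#' and BIF accuracies for genotyped animals and their parents. Records
#' whose own reliability does not exceed their parent-average reliability
#' carry no usable own information and are excluded (flagged).
#'
#' @param records Data frame with columns `animal`, `epd`, `bif`,
#'   `sire_epd`, `sire_bif`, `dam_epd`, `dam_bif` (parent columns `NA` when
#'   unknown).
#' @param h2 Trait heritability.
#' @param c Marker-variance fraction parameter passed to
#'   [deregress_animal()].
#' @param min_r2_star Minimum DEBV reliability retained (default 0.10).
#'   Deregression divides by the record's effective own information, so a
#'   record whose reliability barely exceeds its parent average yields an
#'   explosive pseudo-phenotype with near-zero weight; such records are
#'   excluded (`"low_reliability"`), extending the zero-information rule.
#' @return Data frame with per-animal `ebv`, `r2`, `debv`, `r2_star`, `w`,
#'   `pa_adj`, `r2_pa_adj`, `flag`; excluded records have `NA` outputs.
#'   Attribute `n_retained` counts usable records.
#' @export
deregress_table <- function(records, h2, c = 0.5, min_r2_star = 0.10) {
  need <- c("animal", "epd", "bif")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "))
  }
  for (col in c("sire_epd", "sire_bif", "dam_epd", "dam_bif")) {
    if (!col %in% names(records)) records[[col]] <- NA_real_
  }
  own <- ebv_from_epd(records$epd, records$bif)
  sire <- ebv_from_epd(records$sire_epd, records$sire_bif)
  dam <- ebv_from_epd(records$dam_epd, records$dam_bif)
  n <- nrow(records)
  out <- data.frame(animal = as.character(records$animal),
                    ebv = own$ebv, r2 = own$r2,
                    debv = NA_real_, r2_star = NA_real_, w = NA_real_,
                    pa_adj = NA_real_, r2_pa_adj = NA_real_,
                    flag = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    d <- deregress_animal(own$ebv[i], own$r2[i], sire$ebv[i], sire$r2[i],
                          dam$ebv[i], dam$r2[i], h2 = h2, c = c)
    out$debv[i] <- d$debv
    out$r2_star[i] <- d$r2_star
    out$w[i] <- d$w
    out$flag[i] <- d$flag
    if (d$flag %in% c("ok", "founder") && !is.na(d$r2_star) &&
        d$r2_star < min_r2_star) {
      out$flag[i] <- "low_reliability"
      out$debv[i] <- NA_real_
      out$r2_star[i] <- NA_real_
      out$w[i] <- NA_real_
      next
    }
    if (identical(d$flag, "ok")) {
      pa <- pa_adjust_from_system(d)
      out$pa_adj[i] <- pa$pa_adj
      out$r2_pa_adj[i] <- pa$r2_pa_adj
    }
  }
  attr(out, "n_retained") <- sum(out$flag %in% c("ok", "founder"))
  attr(out, "excluded") <- out$animal[!out$flag %in% c("ok", "founder")]
  out
}

# PA_adj from a solved deregression system: BLUP of the parent-average
# variable from the parent-side information alone. The PA variable has
# variance 0.5 * sigma_g2, hence prior precision 2 * lambda, so
#   PA_adj = y_PA / (Z'Z_PA + 2 * lambda).
# Its reliability as a predictor of the individual's genetic value is half
# the PA variable's own reliability:
#   r2_PAadj = 0.5 * Z'Z_PA / (Z'Z_PA + 2 * lambda)  (< 0.5 always).
pa_adjust_from_system <- function(d) {
  if (!is.finite(d$ztz_pa) || d$ztz_pa <= 0) {
    return(list(pa_adj = NA_real_, r2_pa_adj = NA_real_,
                flag = "uninformative_parents"))
  }
  list(pa_adj = d$y_pa / (d$ztz_pa + 2 * d$lambda),
       r2_pa_adj = 0.5 * d$ztz_pa / (d$ztz_pa + 2 * d$lambda),
       flag = "ok")
}

#' Adjusted parent average
#'
#' Parent-average prediction with the genotyped individual's own
#' contribution to its parents' apparent information removed: the
#' individual/parent-average system of [deregress_animal()] is solved, and
#' the parent-side right-hand side is re-shrunken using only the
#' parent-side effective information. Flagged undefined when the parents
#' carry no net information of their own.
#'
#' @inheritParams deregress_animal
#' @return List with `pa_adj`, `r2_pa_adj` and `flag`.
#' @export
adjusted_parent_average <- function(ebv_i, r2_i, ebv_s = NA, r2_s = NA,
                                    ebv_d = NA, r2_d = NA, h2) {
  d <- deregress_animal(ebv_i, r2_i, ebv_s, r2_s, ebv_d, r2_d, h2 = h2)
  if (!identical(d$flag, "ok")) {
    return(list(pa_adj = NA_real_, r2_pa_adj = NA_real_, flag = d$flag))
  }
  pa_adjust_from_system(d)
}
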