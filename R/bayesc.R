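#' BayesC sampler configuration
#'
#' Defaults follow routine genomic-evaluation practice for 50K panels:
#' prior fraction of null markers `pi = 0.995`, a 41 000-iteration chain
#' with the first 1 000 samples discarded as burn-in, and mildly
#' informative scaled inverse chi-square priors on the marker-effect and
#' residual variances (df 4 and 10). Prior scales are derived at run time
#' from variance estimates (see [preliminary_variances()]) so that the
#' prior means equal \eqn{\hat\sigma_g^2 / ((1-\pi) \sum_j var(z_j))} and
#' \eqn{\hat\sigma_e^2}.
#'
#' @param pi Prior probability that a marker has zero effect.
#' @param chain_length,burn_in MCMC length and burn-in (samples).
#' @param nu_u,nu_e Prior degrees of freedom for the marker-effect and
#'   residual variances.
#' @param seed Integer seed for the chain.
#' @return A `kinfold_bayesc_config` list.
#' @export
bayesc_config <- function(pi = 0.995, chain_length = 41000, burn_in = 1000,
                          nu_u = 4, nu_e = 10, seed = 1) {
  stopifnot(pi >= 0, pi <= 1, burn_in < chain_length)
  out <- list(pi = pi, chain_length = as.integer(chain_length),
              burn_in = as.integer(burn_in), nu_u = nu_u, nu_e = nu_e,
              seed = as.integer(seed))
  class(out) <- "kinfold_bayesc_config"
  out
}

# Prior scale S2 of a scaled inverse chi-square with df nu whose prior
# mean equals `target` (requires nu > 2).
inv_chisq_scale <- function(target, nu) target * (nu - 2) / nu

#' Train the weighted BayesC model
#'
#' Runs the single-site Gibbs sampler on training records: deregressed
#' EBVs as response, per-record weights scaling the residual variance,
#' B-allele dosages as covariates, and a point-mass/normal mixture prior
#' on marker effects with common variance. Marker update order is the map
#' order, fixed across iterations, so a seed fully determines the chain.
#'
#' @param geno Training animals x loci dosage matrix (imputed; real-valued
#'   dosages allowed), or a `kinfold_markers`.
#' @param debv Response vector aligned with the rows of `geno`.
#' @param weights Positive per-record weights.
#' @param config A [bayesc_config()].
#' @param var_g,var_e Variance estimates used to set the prior scales
#'   (e.g. from [preliminary_variances()]).
#' @param fix_variances If `TRUE` the variances are held at `var_u_init` /
#'   `var_e` rather than sampled (used for method checks against ridge
#'   regression).
#' @param var_u_init Optional starting/fixed marker-effect variance;
#'   defaults to the prior mean.
#' @param batch_size Optional batch length for Monte-Carlo standard errors
#'   of the posterior-mean effects (0 = off).
#' @return A `kinfold_posterior`: per-marker posterior mean effects
#'   (`u_hat`), inclusion frequencies, posterior means of `mu`, variances
#'   and genetic variance, and the post-burn-in chains.
#' @export
bayesc_train <- function(geno, debv, weights, config = bayesc_config(),
                         var_g, var_e, fix_variances = FALSE,
                         var_u_init = NULL, batch_size = 0) {
  if (inherits(geno, "kinfold_markers")) geno <- geno$geno
  stopifnot(is.matrix(geno), nrow(geno) == length(debv),
            length(weights) == length(debv))
  if (anyNA(geno)) stop("genotypes must be imputed before training")
  if (any(weights <= 0)) stop("weights must be positive")
  sum_var_z <- sum(apply(geno, 2, stats::var))
  pi0 <- config$pi
  prior_mean_u <- if (pi0 < 1 && sum_var_z > 0) {
    var_g / ((1 - pi0) * sum_var_z)
  } else {
    var_g / max(sum_var_z, 1)
  }
  if (is.null(var_u_init)) var_u_init <- prior_mean_u
  s2_u <- inv_chisq_scale(prior_mean_u, config$nu_u)
  s2_e <- inv_chisq_scale(var_e, config$nu_e)

  fit <- withr_seed(config$seed, {
    .bayesc_gibbs(geno, as.numeric(debv), as.numeric(weights),
                  pi0, config$chain_length, config$burn_in,
                  config$nu_u, s2_u, config$nu_e, s2_e,
                  var_u_init, var_e,
                  !fix_variances, !fix_variances, as.integer(batch_size))
  })
  out <- list(
    loci = colnames(geno),
    u_hat = stats::setNames(fit$u_hat, colnames(geno)),
    incl_freq = stats::setNames(fit$incl_freq, colnames(geno)),
    mu = mean(fit$chain_mu),
    var_u = mean(fit$chain_var_u),
    var_e = mean(fit$chain_var_e),
    var_g = mean(fit$chain_var_g),
    mean_m_incl = mean(fit$chain_m_incl),
    chains = fit[c("chain_mu", "chain_var_u", "chain_var_e",
                   "chain_m_incl", "chain_var_g")],
    batch_u = fit$batch_u,
    config = config
  )
  class(out) <- "kinfold_posterior"
  out
}

#' Preliminary variance components from a full-data chain
#'
#' Runs the BayesC chain on all genotyped animals with records to estimate
#' the genetic variance (posterior mean of the across-animal variance of
#' the model genetic values \eqn{\sum_j z_{ij} u_j}), the residual
#' variance, and their sum, the phenotypic variance of the response. These
#' seed the prior scales of the per-fold training runs and provide the
#' \eqn{\sigma_p^2} used in accuracy computations.
#'
#' @inheritParams bayesc_train
#' @param h2 Heritability used to split the weighted response variance
#'   into starting genetic/residual values for the preliminary chain.
#' @return List with `var_g`, `var_e`, `var_p` (= var_g + var_e) and the
#'   full `fit`.
#' @export
preliminary_variances <- function(geno, debv, weights, h2,
                                  config = bayesc_config()) {
  vy <- stats::var(debv)
  if (vy == 0) {
    return(list(var_g = 0, var_e = 0, var_p = 0, fit = NULL))
  }
  fit <- bayesc_train(geno, debv, weights, config = config,
                      var_g = h2 * vy, var_e = (1 - h2) * vy)
  list(var_g = fit$var_g, var_e = fit$var_e,
       var_p = fit$var_g + fit$var_e, fit = fit)
}

#' Direct genomic values from posterior-mean marker effects
#'
#' \eqn{DGV_i = \sum_j z_{ij} \hat u_j}: the linear score of an animal's
#' dosages on the posterior-mean effects. Loci must match the training
#' loci exactly (same ids, same order).
#'
#' @param geno Validation animals x loci dosage matrix (or
#'   `kinfold_markers`).
#' @param posterior A `kinfold_posterior` from [bayesc_train()].
#' @return Named numeric vector of DGV.
#' @export
predict_dgv <- function(geno, posterior) {
  if (inherits(geno, "kinfold_markers")) geno <- geno$geno
  stopifnot(inherits(posterior, "kinfold_posterior"))
  if (!identical(colnames(geno), posterior$loci)) {
    stop("validation loci do not match training loci (ids/order)")
  }
  drop(geno %*% posterior$u_hat)
}

#' @export
print.kinfold_posterior <- function(x, ...) {
  cat("BayesC posterior:", length(x$u_hat), "loci; mean included/iter:",
      format(x$mean_m_incl, digits = 4),
      "; var_g:", format(x$var_g, digits = 4),
      "; var_e:", format(x$var_e, digits = 4), "\n")
  invisible(x)
}
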