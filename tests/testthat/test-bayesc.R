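# small simulated training sets for sampler checks
sim_train <- function(n, m, n_qtl = 5, h2 = 0.5, seed = 1) {
  set.seed(seed)
  Z <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.9)[rep(1:m, each = n)]),
              n, m, dimnames = list(sprintf("a%03d", 1:n),
                                    sprintf("L%03d", 1:m)))
  qtl <- sample(m, n_qtl)
  u <- rnorm(n_qtl)
  g <- drop(Z[, qtl, drop = FALSE] %*% u)
  g <- (g - mean(g)) / sd(g)
  y <- g + rnorm(n, 0, sqrt((1 - h2) / h2))
  list(Z = Z, y = y, g = g, w = runif(n, 0.5, 2))
}

test_that("pi = 1 forces the null model and mu matches the weighted mean", {
  d <- sim_train(40, 15, seed = 2)
  fit <- bayesc_train(d$Z, d$y, d$w,
                      config = bayesc_config(pi = 1, chain_length = 3000,
                                             burn_in = 500, seed = 1),
                      var_g = 1, var_e = 1)
  expect_true(all(fit$u_hat == 0))
  expect_true(all(fit$incl_freq == 0))
  expect_equal(fit$mu, weighted.mean(d$y, d$w), tolerance = 0.05)
})

test_that("pi = 0 with fixed variances reproduces the ridge solution", {
  d <- sim_train(40, 20, seed = 3)
  var_u <- 0.02; var_e <- 1
  fit <- bayesc_train(d$Z, d$y, d$w,
                      config = bayesc_config(pi = 0, chain_length = 12000,
                                             burn_in = 2000, seed = 4),
                      var_g = 1, var_e = var_e, fix_variances = TRUE,
                      var_u_init = var_u, batch_size = 100)
  ora <- oracle_ridge(d$Z, d$y, d$w, var_u, var_e)
  bm <- fit$batch_u
  mcse <- apply(bm, 1, sd) / sqrt(ncol(bm))
  excess <- abs(fit$u_hat - ora$u) / pmax(3 * mcse, 1e-8)
  expect_lt(mean(excess > 1), 0.1)
  expect_equal(unname(fit$u_hat), unname(ora$u), tolerance = 0.02)
})

test_that("single-marker inclusion probability matches 1-D quadrature", {
  set.seed(5)
  n <- 20
  z <- rbinom(n, 2, 0.4)
  w <- runif(n, 0.5, 2)
  u_true <- 0.8
  y <- 1 + z * u_true + rnorm(n, 0, 1 / sqrt(w))
  var_u <- 0.5; var_e <- 1; pi0 <- 0.9

  # marginal likelihood of y given u, with the mean profiled out under a
  # flat prior: integrate the weighted Gaussian likelihood over mu
  log_lik_given_u <- function(u) {
    r <- y - z * u
    sw <- sum(w)
    mu_hat <- sum(w * r) / sw
    ss <- sum(w * (r - mu_hat)^2)
    0.5 * sum(log(w)) - 0.5 * (n - 1) * log(2 * pi * var_e) -
      0.5 * log(sw) - ss / (2 * var_e)
  }
  scale <- log_lik_given_u(u_true)
  L1 <- integrate(Vectorize(function(u) {
    exp(log_lik_given_u(u) - scale) * dnorm(u, 0, sqrt(var_u))
  }), -10, 10, rel.tol = 1e-10)$value
  L0 <- exp(log_lik_given_u(0) - scale)
  p_incl_oracle <- (1 - pi0) * L1 / ((1 - pi0) * L1 + pi0 * L0)

  fit <- bayesc_train(matrix(z, ncol = 1, dimnames = list(NULL, "L1")),
                      y, w,
                      config = bayesc_config(pi = pi0, chain_length = 60000,
                                             burn_in = 5000, seed = 6),
                      var_g = 1, var_e = var_e, fix_variances = TRUE,
                      var_u_init = var_u)
  se <- sqrt(p_incl_oracle * (1 - p_incl_oracle) / 55000) * 5  # autocorrelation slack
  expect_equal(unname(fit$incl_freq), p_incl_oracle,
               tolerance = max(0.03, 3 * se / p_incl_oracle))
})

test_that("chains are bitwise reproducible from the seed", {
  d <- sim_train(30, 10, seed = 7)
  cfg <- bayesc_config(chain_length = 500, burn_in = 100, seed = 11)
  f1 <- bayesc_train(d$Z, d$y, d$w, config = cfg, var_g = 0.5, var_e = 0.5)
  f2 <- bayesc_train(d$Z, d$y, d$w, config = cfg, var_g = 0.5, var_e = 0.5)
  expect_identical(f1$u_hat, f2$u_hat)
  expect_identical(f1$chains, f2$chains)
  cfg$seed <- 12
  f3 <- bayesc_train(d$Z, d$y, d$w, config = cfg, var_g = 0.5, var_e = 0.5)
  expect_false(identical(f1$u_hat, f3$u_hat))
})

test_that("inclusion count under a pure-noise response follows the prior", {
  set.seed(8)
  n <- 60; m <- 100
  Z <- matrix(rbinom(n * m, 2, 0.5), n, m,
              dimnames = list(NULL, sprintf("L%03d", 1:m)))
  y <- rnorm(n)
  pi0 <- 0.95
  fit <- bayesc_train(Z, y, rep(1, n),
                      config = bayesc_config(pi = pi0, chain_length = 4000,
                                             burn_in = 500, seed = 9),
                      var_g = 0.05, var_e = 1, fix_variances = TRUE,
                      var_u_init = 0.05 / (0.05 * sum(apply(Z, 2, var))))
  # mean inclusions per iteration ~ (1 - pi) * m up to binomial noise and
  # the data's mild likelihood contribution
  expect_gt(fit$mean_m_incl, 0.2 * (1 - pi0) * m)
  expect_lt(fit$mean_m_incl, 4 * (1 - pi0) * m)
})

test_that("DGV prediction is a linear score over matching loci", {
  d <- sim_train(25, 12, seed = 10)
  fit <- bayesc_train(d$Z, d$y, d$w,
                      config = bayesc_config(chain_length = 800,
                                             burn_in = 100, seed = 2),
                      var_g = 0.5, var_e = 0.5)
  Zv <- d$Z[1:6, , drop = FALSE]
  dgv <- predict_dgv(Zv, fit)
  expect_equal(unname(dgv), unname(drop(Zv %*% fit$u_hat)))
  # duplicate animals get identical scores; linearity holds exactly
  expect_equal(unname(dgv[1]), unname(predict_dgv(Zv[c(1, 1), ], fit)[2]))
  half <- 0.5 * Zv[1, ] + 0.5 * Zv[2, ]
  combo <- matrix(half, 1, dimnames = list("c", colnames(Zv)))
  expect_equal(unname(predict_dgv(combo, fit)),
               unname(0.5 * dgv[1] + 0.5 * dgv[2]))
  # zero effects -> zero scores
  fit0 <- fit; fit0$u_hat[] <- 0
  expect_true(all(predict_dgv(Zv, fit0) == 0))
  # locus mismatch is fatal
  bad <- Zv; colnames(bad)[1] <- "other"
  expect_error(predict_dgv(bad, fit), "loci")
})

test_that("preliminary variances recover the simulated heritability split", {
  ratios <- c()
  for (s in 1:3) {
    set.seed(20 + s)
    n <- 500; m <- 1000
    Z <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.8)[rep(1:m, each = n)]),
                n, m, dimnames = list(sprintf("p%03d", 1:n),
                                      sprintf("L%04d", 1:m)))
    g <- drop(Z[, sample(m, 20)] %*% rnorm(20))
    g <- (g - mean(g)) / sd(g)
    y <- g + rnorm(n)                     # h2 = 0.5
    pv <- preliminary_variances(Z, y, rep(1, n), h2 = 0.5,
                                config = bayesc_config(pi = 0.98,
                                                       chain_length = 1500,
                                                       burn_in = 300,
                                                       seed = s))
    expect_equal(pv$var_p, pv$var_g + pv$var_e)
    ratios <- c(ratios, pv$var_g / pv$var_p)
  }
  expect_gt(mean(ratios), 0.35)
  expect_lt(mean(ratios), 0.65)

  # zero-variance response degenerates to zero genetic variance
  pop <- simulate_population(sim_config(n_chr = 1, markers_per_chr = 50,
                                        n_qtl = 5, qtl_pool = 10), seed = 1)
  pv0 <- preliminary_variances(pop$geno, rep(1, nrow(pop$geno)),
                               rep(1, nrow(pop$geno)), h2 = 0.5)
  expect_equal(pv0$var_g, 0)
})

test_that("held-out prediction accuracy is well calibrated on simulated data", {
  hits <- 0
  for (s in 1:10) {
    set.seed(40 + s)
    n <- 500; m <- 1000; n_qtl <- 20
    Z <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.8)[rep(1:m, each = n)]),
                n, m, dimnames = list(sprintf("i%03d", 1:n),
                                      sprintf("L%03d", 1:m)))
    qtl <- sample(m, n_qtl)
    g <- drop(Z[, qtl, drop = FALSE] %*% rnorm(n_qtl))
    g <- (g - mean(g)) / sd(g)
    rel <- 0.8
    y <- rel * g + sqrt(rel * (1 - rel)) * rnorm(n)
    tr <- 1:400; va <- 401:500
    fit <- bayesc_train(Z[tr, ], y[tr], rep(1, 400),
                        config = bayesc_config(pi = 0.98,
                                               chain_length = 1500,
                                               burn_in = 300, seed = s),
                        var_g = rel^2, var_e = rel * (1 - rel))
    r <- cor(predict_dgv(Z[va, ], fit), g[va])
    if (r > 0.35) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
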