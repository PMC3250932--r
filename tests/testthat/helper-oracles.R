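# Independent oracles and small generators used across the suite.

# Monte-Carlo gene-dropping estimate of the additive relationship matrix:
# founders get unique alleles, alleles drop through the pedigree, and
# a_ij is estimated as twice the coancestry (probability that random
# alleles drawn from i and j are identical by descent). Returns the
# estimate and its per-pair Monte-Carlo standard error.
gene_drop_relmat <- function(ped, n_rep = 1e5, seed = 42) {
  set.seed(seed)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  al1 <- matrix(0L, n_rep, n)
  al2 <- matrix(0L, n_rep, n)
  next_allele <- 0L
  for (i in seq_len(n)) {
    if (si[i] == 0L) {
      al1[, i] <- next_allele + 1L
      next_allele <- next_allele + 1L
    } else {
      pick <- runif(n_rep) < 0.5
      al1[, i] <- ifelse(pick, al1[, si[i]], al2[, si[i]])
    }
    if (di[i] == 0L) {
      al2[, i] <- next_allele + 1L
      next_allele <- next_allele + 1L
    } else {
      pick <- runif(n_rep) < 0.5
      al2[, i] <- ifelse(pick, al1[, di[i]], al2[, di[i]])
    }
  }
  A_hat <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  SE <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        k <- 0.5 * (1 + (al1[, i] == al2[, i]))
      } else {
        k <- 0.25 * ((al1[, i] == al1[, j]) + (al1[, i] == al2[, j]) +
                     (al2[, i] == al1[, j]) + (al2[, i] == al2[, j]))
      }
      a <- 2 * k
      A_hat[i, j] <- A_hat[j, i] <- mean(a)
      SE[i, j] <- SE[j, i] <- sd(a) / sqrt(n_rep)
    }
  }
  list(A = A_hat, SE = SE)
}

# Random multi-generation pedigree for property tests: founders plus
# `n_gen` generations of random matings among earlier animals.
random_pedigree <- function(n_founder = 10, n_gen = 3, per_gen = 10,
                            seed = 1) {
  set.seed(seed)
  animal <- sprintf("F%02d", seq_len(n_founder))
  sire <- rep(NA_character_, n_founder)
  dam <- rep(NA_character_, n_founder)
  year <- rep(0L, n_founder)
  sex <- rep(c("M", "F"), length.out = n_founder)
  for (g in seq_len(n_gen)) {
    males <- animal[sex == "M"]
    females <- animal[sex == "F"]
    for (k in seq_len(per_gen)) {
      id <- sprintf("G%d_%02d", g, k)
      animal <- c(animal, id)
      sire <- c(sire, sample(males, 1))
      dam <- c(dam, sample(females, 1))
      year <- c(year, g)
      sex <- c(sex, sample(c("M", "F"), 1))
    }
  }
  as_pedigree(data.frame(animal = animal, sire = sire, dam = dam,
                         birth_year = year, stringsAsFactors = FALSE))
}

# Independent solver for the deregression information contents: direct
# minimisation of the squared reliability residuals over (Z'Z_PA, Z'Z_i),
# no closed forms involved.
oracle_garrick <- function(r2_pa, r2_i, lambda) {
  obj <- function(th) {
    C <- matrix(c(th[1] + 4 * lambda, -2 * lambda,
                  -2 * lambda, th[2] + 2 * lambda), 2, 2)
    Ci <- tryCatch(solve(C), error = function(e) return(NULL))
    if (is.null(Ci)) return(1e10)
    (lambda * Ci[1, 1] - (0.5 - r2_pa))^2 +
      (lambda * Ci[2, 2] - (1 - r2_i))^2
  }
  best <- NULL
  for (start in list(c(1, 1), c(5, 5), c(0.1, 2), c(-1, 1))) {
    fit <- optim(start * lambda, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  for (round in 1:5) {
    best <- optim(best$par, obj, method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-15))
  }
  stopifnot(best$value < 1e-16)
  list(ztz_pa = best$par[1], ztz_i = best$par[2])
}

# Weighted ridge-regression oracle: joint normal equations for (mu, u)
# with flat prior on mu and ridge sigma_e^2/sigma_u^2 on u.
oracle_ridge <- function(Z, y, w, var_u, var_e) {
  lambda <- var_e / var_u
  X <- cbind(1, Z)
  W <- diag(w)
  pen <- diag(c(0, rep(lambda, ncol(Z))))
  sol <- solve(crossprod(X, W %*% X) + pen, crossprod(X, W %*% y))
  list(mu = sol[1], u = sol[-1])
}

# Simulate from the bivariate animal model: alpha ~ N(0, G0 (x) A),
# y1 = mu1 + alpha1 + e1 (Var e1_i = ve1/w_i),
# y2 = group effect + alpha2 + e2 (Var = ve2).
sim_bivar <- function(A, G0, ve1, ve2, w, groups, seed = 1) {
  set.seed(seed)
  n <- nrow(A)
  LA <- t(chol(A + diag(1e-10, n)))
  LG <- t(chol(G0))
  alpha <- LA %*% matrix(rnorm(2 * n), n, 2) %*% t(LG)
  ge <- rnorm(length(unique(groups)), 0, 1)
  names(ge) <- as.character(unique(groups))
  y1 <- 2 + alpha[, 1] + rnorm(n, 0, sqrt(ve1 / w))
  y2 <- ge[as.character(groups)] + alpha[, 2] + rnorm(n, 0, sqrt(ve2))
  list(y1 = y1, y2 = as.numeric(y2), alpha = alpha)
}

# Pedigree + relationship matrix for REML simulations: founders and two
# descendant generations, all animals phenotyped.
reml_testbed <- function(n_founder = 60, n_gen = 2, per_gen = 120,
                         seed = 1) {
  ped <- random_pedigree(n_founder, n_gen, per_gen, seed = seed)
  A <- build_A(ped)$A
  list(ped = ped, A = A, ids = ped$animal)
}
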