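# Multi-trait fold-scheme comparison on one simulated population: builds
# the relationship machinery once, then for each simulated trait runs the
# deregression -> preliminary variances -> per-fold BayesC -> pooled
# validation chain under both K-means and random folds. Group accuracies
# are averaged over traits (the way a multi-trait study reports per-group
# accuracy), which tames the sampling noise of single-trait group
# estimates.
.pattern_cache <- new.env(parent = emptyenv())

pattern_experiment <- function(seed, n_traits = 3,
                               chain = bayesc_config(pi = 0.97,
                                                     chain_length = 1000,
                                                     burn_in = 100)) {
  key <- paste0("s", seed, "_t", n_traits)
  if (!is.null(.pattern_cache[[key]])) return(.pattern_cache[[key]])
  cfg <- sim_config()
  pop <- simulate_population(cfg, seed = seed)
  geno <- pop$geno
  gids <- rownames(geno)
  relmat <- build_A(prune_founders(pop$ped, keep = gids), subset = gids)
  yr <- stats::setNames(pop$ped$birth_year, pop$ped$animal)[gids]
  parts <- list(
    kmeans = kmeans_folds(dissimilarity(relmat), K = 5, n_start = 10,
                          seed = seed),
    random = random_folds(gids, K = 5, replicate = 1, seed = seed),
    age = age_split(gids, yr, valid_fraction = 0.20))
  summ <- amax_diagnostics(relmat, parts$kmeans)$summary
  inbred_group <- as.character(summ$group[which.max(summ$mean_F)])

  acc <- c(kmeans = 0, random = 0, age = 0)
  ga_mean <- NULL
  for (tr in seq_len(n_traits)) {
    truth <- if (tr == 1) pop$truth else {
      simulate_trait(pop, cfg, seed = 1000L * seed + tr)
    }
    rec <- simulate_trait_records(pop, cfg, seed = 100L * seed + tr,
                                  truth = truth)
    dtab <- deregress_table(rec$records, h2 = cfg$h2)
    ok <- dtab$flag %in% c("ok", "founder")
    ids <- dtab$animal[ok]
    dt <- dtab[ok, ]
    Zt <- geno[ids, , drop = FALSE]
    cfg_prelim <- chain; cfg_prelim$seed <- seed + 17L * tr
    prelim <- preliminary_variances(Zt, dt$debv, dt$w, h2 = cfg$h2,
                                    config = cfg_prelim)
    var_g <- genetic_variance(cfg$h2, prelim$var_p)
    for (scheme in names(parts)) {
      assign_ids <- parts[[scheme]]$assignment[ids]
      val_groups <- if (scheme == "age") 2L else sort(unique(assign_ids))
      dgv <- stats::setNames(rep(NA_real_, length(ids)), ids)
      for (g in val_groups) {
        va <- ids[assign_ids == g]
        trn <- setdiff(ids, va)
        cfg_f <- chain; cfg_f$seed <- seed + 31L * tr + 7L * g
        fit <- bayesc_train(Zt[trn, , drop = FALSE],
                            dt$debv[match(trn, ids)],
                            dt$w[match(trn, ids)], config = cfg_f,
                            var_g = prelim$var_g, var_e = prelim$var_e)
        dgv[va] <- predict_dgv(Zt[va, , drop = FALSE], fit)
      }
      pred <- ids[!is.na(dgv[ids])]
      acc[scheme] <- acc[scheme] +
        pooled_accuracy(dt$debv[match(pred, ids)], dgv[pred], yr[pred],
                        var_g) / n_traits
      if (scheme == "kmeans") {
        ga <- vapply(sort(unique(assign_ids)), function(g) {
          gi <- ids[assign_ids == g]
          tryCatch(pooled_accuracy(dt$debv[match(gi, ids)], dgv[gi],
                                   yr[gi], var_g),
                   error = function(e) NA_real_)
        }, 0)
        names(ga) <- sort(unique(assign_ids))
        ga_mean <- if (is.null(ga_mean)) ga / n_traits else
          ga_mean + ga / n_traits
      }
    }
  }
  out <- list(acc = acc, group_acc = ga_mean, inbred_group = inbred_group)
  .pattern_cache[[key]] <- out
  out
}
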