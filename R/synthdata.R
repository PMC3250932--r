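#' Simulation configuration
#'
#' Defaults describe a small beef-cattle-like population with the
#' structural features the analysis machinery assumes: several open herds
#' with patrilineal half-sib sire families, family sizes growing over
#' generations (so birth years skew recent), occasional dam migration
#' between herds plus rare use of closed-line sires in the open herds, and
#' one small line closed for many generations whose inbreeding
#' accumulates to roughly 0.1. Genotypes descend from a small ancestral
#' haplotype pool via mosaic founders and Poisson-crossover meiosis
#' (Haldane mapping, 1 Morgan per chromosome), which induces linkage
#' disequilibrium decaying with map distance.
#'
#' @param n_chr,markers_per_chr Genome layout (default 5 x 200).
#' @param pool_size Number of ancestral haplotypes per chromosome.
#' @param switch_rate Pool switches per Morgan in founder mosaics;
#'   smaller values mean longer shared segments and stronger LD.
#' @param n_qtl Number of QTL per trait, drawn from the off-panel pool.
#' @param qtl_pool Number of loci reserved as potential QTL. These loci
#'   are simulated on the same haplotypes but excluded from the returned
#'   marker panel, so predictions must work through marker-QTL linkage
#'   disequilibrium, as with a genotyping array; the panel is identical
#'   for every trait simulated on the population.
#' @param var_g Target additive genetic variance of the trait.
#' @param n_herds,founder_males,founder_females Open-population structure.
#' @param sires_per_herd Sires selected per herd and generation.
#' @param fam_size Offspring per sire in each open generation (its length
#'   sets the number of open generations).
#' @param migration_rate Probability a dam is sampled from another herd.
#' @param closed_size,closed_generations,closed_sires,closed_founders
#'   Closed-line structure: animals per generation, generations closed,
#'   sires used per generation, founder count.
#' @param link_rate Probability an open mating in the last two
#'   generations uses a closed-line sire.
#' @param closed_pool_mix Fraction of closed-line founder haplotypes drawn
#'   from a line-specific ancestral pool (default 1: the closed herd is of
#'   fully distinct origin, so its marker-QTL linkage phase is not shared
#'   with the open herds and cross-prediction into it is hard).
#' @param year0,gen_interval Birth-year schedule: founders at `year0`,
#'   each generation `gen_interval` years later.
#' @param genotyped_generations Number of most recent generations (per
#'   stratum) whose males form the genotyped set.
#' @param rel_mean,rel_sd Target EBV reliability distribution of the
#'   genotyped candidates.
#' @param rel_sire_mean,rel_sire_sd,rel_dam_mean,rel_dam_sd Reliability
#'   distributions of animals used as sires (progeny-tested, high) and
#'   dams (moderate), keeping parent and offspring reliabilities coherent
#'   the way a joint national evaluation would.
#' @param h2 Trait heritability used when records are simulated.
#' @return A `kinfold_sim_config` list.
#' @export
sim_config <- function(n_chr = 5, markers_per_chr = 200, pool_size = 10,
                       switch_rate = 1.5, n_qtl = 30, qtl_pool = 100,
                       var_g = 1,
                       n_herds = 4, founder_males = 8, founder_females = 24,
                       sires_per_herd = 5, fam_size = c(8, 10, 12, 14),
                       migration_rate = 0.10,
                       closed_size = 36, closed_generations = 9,
                       closed_sires = 8, closed_founders = 20,
                       link_rate = 0, closed_pool_mix = 1,
                       year0 = 1950, gen_interval = 5,
                       genotyped_generations = 2,
                       rel_mean = 0.6, rel_sd = 0.15,
                       rel_sire_mean = 0.85, rel_sire_sd = 0.05,
                       rel_dam_mean = 0.5, rel_dam_sd = 0.1, h2 = 0.4) {
  stopifnot(n_qtl <= qtl_pool, qtl_pool < n_chr * markers_per_chr,
            closed_founders >= 4, closed_sires < closed_size)
  cfg <- as.list(environment())
  class(cfg) <- "kinfold_sim_config"
  cfg
}

# One meiosis: recombine a parent's two haplotypes with Poisson crossovers
# (Haldane; chromosome length in Morgans), independently per chromosome.
# hap1/hap2 are full-genome vectors; chr_index/pos give each marker's
# chromosome and map position.
meiose <- function(hap1, hap2, chr_index, pos, chr_len = 1) {
  out <- numeric(length(hap1))
  for (ch in unique(chr_index)) {
    i <- which(chr_index == ch)
    k <- stats::rpois(1, chr_len)
    start <- stats::rbinom(1, 1, 0.5)
    phase <- if (k > 0) {
      (start + findInterval(pos[i], sort(stats::runif(k, 0, chr_len)))) %% 2
    } else rep(start, length(i))
    out[i] <- ifelse(phase == 0, hap1[i], hap2[i])
  }
  out
}

# Founder haplotype as a mosaic of ancestral pool haplotypes: segment
# boundaries Poisson(switch_rate per Morgan), each segment copied from a
# random pool member. Nearby markers share a source, producing LD.
founder_haplotype <- function(pool, chr_index, pos, switch_rate, chr_len = 1) {
  out <- numeric(length(chr_index))
  for (ch in unique(chr_index)) {
    i <- which(chr_index == ch)
    k <- stats::rpois(1, switch_rate * chr_len)
    bounds <- sort(stats::runif(k, 0, chr_len))
    src <- sample(nrow(pool[[ch]]), k + 1, replace = TRUE)
    seg <- findInterval(pos[i], bounds) + 1
    out[i] <- pool[[ch]][cbind(src[seg], seq_along(i))]
  }
  out
}

#' Simulate a structured population with genotypes and breeding values
#'
#' Builds the pedigree, drops haplotypes through it, and computes true
#' breeding values from randomly placed QTL, rescaled so the genetic
#' variance among the genotyped animals equals `cfg$var_g`. The genotyped
#' set comprises the males of the most recent generations (open herds and
#' closed line), mimicking a sire-genotyping design.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return List: `ped` (a `kinfold_pedigree`), `geno` (genotyped animals x
#'   markers dosage matrix), `truth` (per-animal `tbv`, per-locus QTL
#'   table, `var_g`), `genotyped` ids, `herd` assignment, `map` (marker
#'   chromosome/position).
#' @export
simulate_population <- function(cfg = sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "kinfold_sim_config"))
  withr_seed(seed, simulate_population_impl(cfg))
}

simulate_population_impl <- function(cfg) {
  m <- cfg$n_chr * cfg$markers_per_chr
  chr_index <- rep(seq_len(cfg$n_chr), each = cfg$markers_per_chr)
  pos <- rep((seq_len(cfg$markers_per_chr) - 0.5) / cfg$markers_per_chr,
             cfg$n_chr)
  make_pool <- function() lapply(seq_len(cfg$n_chr), function(ch) {
    p <- stats::runif(cfg$markers_per_chr, 0.1, 0.9)
    matrix(stats::rbinom(cfg$pool_size * cfg$markers_per_chr, 1,
                         rep(p, each = cfg$pool_size)),
           nrow = cfg$pool_size)
  })
  pool <- make_pool()
  # separate ancestral pool for the closed line's distinct origin
  pool_closed <- make_pool()

  ids <- character(0); sires <- character(0); dams <- character(0)
  years <- integer(0); sexes <- character(0); herds <- integer(0)
  gens <- integer(0)
  H1 <- list(); H2 <- list()
  counter <- 0L
  add_animal <- function(sire, dam, year, sex, herd, gen, h1, h2) {
    counter <<- counter + 1L
    id <- sprintf("A%05d", counter)
    ids <<- c(ids, id); sires <<- c(sires, sire); dams <<- c(dams, dam)
    years <<- c(years, year); sexes <<- c(sexes, sex)
    herds <<- c(herds, herd); gens <<- c(gens, gen)
    H1[[id]] <<- h1; H2[[id]] <<- h2
    id
  }
  new_founder <- function(year, sex, herd) {
    draw <- function() {
      src_pool <- if (herd == 0L && stats::runif(1) < cfg$closed_pool_mix) {
        pool_closed
      } else pool
      founder_haplotype(src_pool, chr_index, pos, cfg$switch_rate)
    }
    add_animal(NA_character_, NA_character_, year, sex, herd, 0L,
               draw(), draw())
  }
  offspring <- function(sire, dam, year, herd, gen) {
    add_animal(sire, dam, year, sample(c("M", "F"), 1), herd, gen,
               meiose(H1[[sire]], H2[[sire]], chr_index, pos),
               meiose(H1[[dam]], H2[[dam]], chr_index, pos))
  }

  # open-herd founders
  for (h in seq_len(cfg$n_herds)) {
    for (i in seq_len(cfg$founder_males)) new_founder(cfg$year0, "M", h)
    for (i in seq_len(cfg$founder_females)) new_founder(cfg$year0, "F", h)
  }
  # closed-line founders (herd 0)
  n_cm <- ceiling(cfg$closed_founders / 2)
  for (i in seq_len(n_cm)) new_founder(cfg$year0, "M", 0L)
  for (i in seq_len(cfg$closed_founders - n_cm)) new_founder(cfg$year0, "F", 0L)

  n_open_gen <- length(cfg$fam_size)
  n_gen <- max(n_open_gen, cfg$closed_generations)
  closed_sire_pool <- character(0)
  for (g in seq_len(n_gen)) {
    year <- cfg$year0 + g * cfg$gen_interval
    # snapshot of the previous generation before this one grows the vectors
    prev_ids <- ids[gens == g - 1L]
    prev_sex <- sexes[gens == g - 1L]
    prev_herd <- herds[gens == g - 1L]
    # closed line: balanced parental contributions slow inbreeding to the
    # few-percent-per-generation pace of a managed closed herd
    if (g <= cfg$closed_generations) {
      cm <- prev_ids[prev_herd == 0L & prev_sex == "M"]
      cf <- prev_ids[prev_herd == 0L & prev_sex == "F"]
      line_sires <- sample(cm, min(cfg$closed_sires, length(cm)))
      sire_cycle <- rep(sample(line_sires), length.out = cfg$closed_size)
      dam_cycle <- rep(sample(cf), length.out = cfg$closed_size)
      for (i in seq_len(cfg$closed_size)) {
        offspring(sire_cycle[i], dam_cycle[i], year, 0L, g)
      }
      if (g >= n_open_gen - 1L) {
        closed_sire_pool <- c(closed_sire_pool, line_sires)
      }
    }
    # open herds
    if (g <= n_open_gen) {
      for (h in seq_len(cfg$n_herds)) {
        hm <- prev_ids[prev_herd == h & prev_sex == "M"]
        hf_all <- lapply(seq_len(cfg$n_herds),
                         function(k) prev_ids[prev_herd == k & prev_sex == "F"])
        herd_sires <- sample(hm, min(cfg$sires_per_herd, length(hm)))
        for (s in herd_sires) {
          sire_used <- s
          if (g >= n_open_gen - 1L && length(closed_sire_pool) &&
              stats::runif(1) < cfg$link_rate) {
            sire_used <- sample(closed_sire_pool, 1)
          }
          nf <- cfg$fam_size[g]
          migrate <- stats::runif(nf) < cfg$migration_rate
          home <- hf_all[[h]]
          dam_pick <- character(nf)
          dam_pick[!migrate] <- sample(home, sum(!migrate),
                                       replace = sum(!migrate) > length(home))
          for (o in which(migrate)) {
            dam_pick[o] <- sample(hf_all[[sample(setdiff(seq_len(cfg$n_herds),
                                                         h), 1)]], 1)
          }
          for (o in seq_len(nf)) {
            offspring(sire_used, dam_pick[o], year, h, g)
          }
        }
      }
    }
  }

  ped <- as_pedigree(data.frame(animal = ids, sire = sires, dam = dams,
                                birth_year = years,
                                stringsAsFactors = FALSE))
  # genotyped set: males of the most recent generations of each stratum
  gg <- cfg$genotyped_generations
  open_recent <- gens > n_open_gen - gg & herds > 0L
  closed_recent <- gens > cfg$closed_generations - gg & herds == 0L
  genotyped <- ids[sexes == "M" & (open_recent | closed_recent)]

  geno <- t(vapply(ids, function(id) H1[[id]] + H2[[id]], numeric(m)))
  colnames(geno) <- sprintf("M%04d", seq_len(m))

  pool_idx <- sort(sample(m, cfg$qtl_pool))
  pool_geno <- geno[, pool_idx, drop = FALSE]
  panel <- setdiff(colnames(geno), colnames(pool_geno))
  genotyped_mask <- ids %in% genotyped
  truth <- draw_trait_truth(pool_geno, genotyped_mask, cfg)

  info <- data.frame(animal = ids, sex = sexes, herd = herds,
                     generation = gens, birth_year = years,
                     stringsAsFactors = FALSE)
  list(ped = ped,
       geno = geno[genotyped, panel, drop = FALSE],
       truth = truth,
       qtl_pool_geno = pool_geno,
       genotyped = genotyped,
       herd = stats::setNames(herds, ids),
       info = info,
       map = data.frame(locus = colnames(geno), chr = chr_index, pos = pos,
                        on_panel = !colnames(geno) %in% colnames(pool_geno)))

}

# sample a trait architecture from the reserved QTL pool and rescale so
# the genetic variance among genotyped animals equals cfg$var_g
draw_trait_truth <- function(pool_geno, genotyped_mask, cfg) {
  sel <- sort(sample(ncol(pool_geno), cfg$n_qtl))
  eff <- stats::rnorm(cfg$n_qtl)
  tbv_raw <- drop(pool_geno[, sel, drop = FALSE] %*% eff)
  v_raw <- stats::var(tbv_raw[genotyped_mask])
  scale <- if (v_raw > 0) sqrt(cfg$var_g / v_raw) else 1
  tbv <- tbv_raw * scale
  names(tbv) <- rownames(pool_geno)
  list(tbv = tbv,
       qtl = data.frame(locus = colnames(pool_geno)[sel],
                        effect = eff * scale),
       var_g = cfg$var_g)
}

#' Simulate EBV records at target reliabilities
#'
#' Generates EBVs with the BLUP shrinkage property: for target reliability
#' \eqn{r^2}, \eqn{EBV = r^2 TBV + \sqrt{r^2 (1 - r^2)}\, \sigma_g \zeta}
#' with \eqn{\zeta \sim N(0,1)}, so that \eqn{cor(EBV, TBV) = r} and
#' \eqn{Var(EBV) = r^2 \sigma_g^2}. EPD = EBV / 2 and the BIF accuracy is
#' recovered as \eqn{1 - \sqrt{1 - r^2}}.
#'
#' @param tbv Named vector of true breeding values.
#' @param r2 Target reliabilities, recycled to `length(tbv)`; values must
#'   lie in (0, 1).
#' @param var_g Genetic variance of the trait.
#' @param seed Integer seed.
#' @return Data frame: `animal`, `tbv`, `r2`, `ebv`, `epd`, `bif`.
#' @export
simulate_ebv <- function(tbv, r2, var_g, seed = 1) {
  n <- length(tbv)
  r2 <- rep_len(r2, n)
  if (any(r2 <= 0 | r2 >= 1)) stop("reliabilities must lie in (0, 1)")
  ebv <- withr_seed(seed, {
    r2 * tbv + sqrt(r2 * (1 - r2)) * sqrt(var_g) * stats::rnorm(n)
  })
  data.frame(animal = names(tbv), tbv = as.numeric(tbv), r2 = r2,
             ebv = ebv, epd = ebv / 2, bif = 1 - sqrt(1 - r2),
             stringsAsFactors = FALSE, row.names = NULL)
}

# reliability draws: normal clipped into (0.05, 0.95)
draw_reliabilities <- function(n, mean, sd) {
  pmin(pmax(stats::rnorm(n, mean, sd), 0.05), 0.95)
}

#' Assemble the trait-record table for a simulated population
#'
#' Builds EBV records for every animal in the pedigree so that the
#' deregression machinery is exercised with a correct measurement model:
#' non-genotyped animals (parents) get BLUP-calibrated EBVs
#' (\eqn{E[g | EBV] = EBV}); each genotyped animal gets an EBV constructed
#' as the model-implied blend of an unbiased own-data average
#' (\eqn{DEBV = g + \epsilon}, \eqn{Var(\epsilon) = \sigma_g^2 (1 -
#' r^{*2})/r^{*2}}) with its parent average, using the same two-variable
#' mixed-model system that deregression solves. Deregressing these
#' records therefore returns exactly the unbiased pseudo-phenotypes the
#' validation statistics assume.
#'
#' @param pop Result of [simulate_population()].
#' @param cfg The [sim_config()] used (supplies reliability targets,
#'   heritability and `var_g`).
#' @param seed Integer seed.
#' @param truth Trait truth to use (default the population's first trait;
#'   see [simulate_trait()] for additional traits).
#' @return List: `records` (deregression input for genotyped animals,
#'   with birth years), `ebv_table` (all animals; `debv_true` holds the
#'   embedded own-data average where one was constructed),
#'   `truth_tbv` (genotyped animals).
#' @export
simulate_trait_records <- function(pop, cfg, seed = 1, truth = pop$truth) {
  withr_seed(seed, simulate_trait_records_impl(pop, cfg, truth))
}

simulate_trait_records_impl <- function(pop, cfg, truth = pop$truth) {
  ped <- pop$ped
  all_ids <- ped$animal
  n <- length(all_ids)
  role <- rep("candidate", n)
  role[all_ids %in% ped$sire] <- "sire"
  role[all_ids %in% ped$dam] <- "dam"
  r2 <- draw_reliabilities(n, cfg$rel_mean, cfg$rel_sd)
  r2[role == "sire"] <- draw_reliabilities(sum(role == "sire"),
                                           cfg$rel_sire_mean,
                                           cfg$rel_sire_sd)
  r2[role == "dam"] <- draw_reliabilities(sum(role == "dam"),
                                          cfg$rel_dam_mean, cfg$rel_dam_sd)
  names(r2) <- all_ids

  h2 <- cfg$h2
  lambda <- (1 - h2) / h2
  var_g <- cfg$var_g
  sg <- sqrt(var_g)
  tbv <- truth$tbv[all_ids]
  is_geno <- all_ids %in% pop$genotyped

  ebv <- stats::setNames(rep(NA_real_, n), all_ids)
  debv_true <- stats::setNames(rep(NA_real_, n), all_ids)
  shrunken <- function(i) {
    r2[i] * tbv[i] + sqrt(r2[i] * (1 - r2[i])) * sg * stats::rnorm(1)
  }
  for (i in seq_len(n)) {        # pedigree order: parents come first
    if (!is_geno[i]) {
      ebv[i] <- shrunken(i)
      next
    }
    sire <- ped$sire[i]; dam <- ped$dam[i]
    pa <- parent_average_inputs(
      if (is.na(sire)) NA else ebv[sire],
      if (is.na(sire)) NA else r2[sire],
      if (is.na(dam)) NA else ebv[dam],
      if (is.na(dam)) NA else r2[dam])
    if (pa$n_known == 0L) {
      # unbiased founder record: the record IS the own-data average
      debv_true[i] <- tbv[i] + sqrt(var_g * (1 - r2[i]) / r2[i]) *
        stats::rnorm(1)
      ebv[i] <- debv_true[i]
      next
    }
    if (r2[i] <= pa$r2_pa + 1e-6) {
      # no usable own information: conventional shrunken EBV (the
      # analysis will exclude this record)
      ebv[i] <- shrunken(i)
      next
    }
    sys <- garrick_information(pa$r2_pa, r2[i], lambda)
    r2star <- sys$ztz_i / (sys$ztz_i + lambda)
    debv_true[i] <- tbv[i] + sqrt(var_g * (1 - r2star) / r2star) *
      stats::rnorm(1)
    ebv[i] <- (sys$ztz_i * debv_true[i] + 2 * lambda * pa$g_pa) /
      (sys$ztz_i + 2 * lambda)
  }

  ebv_tab <- data.frame(animal = all_ids, tbv = as.numeric(tbv), r2 = r2,
                        ebv = as.numeric(ebv), epd = as.numeric(ebv) / 2,
                        bif = 1 - sqrt(1 - r2),
                        debv_true = as.numeric(debv_true),
                        stringsAsFactors = FALSE, row.names = all_ids)
  g <- pop$genotyped
  rownames(ped) <- ped$animal
  look <- function(ids, col) {
    out <- rep(NA_real_, length(ids))
    known <- !is.na(ids)
    out[known] <- ebv_tab[ids[known], col]
    out
  }
  records <- data.frame(
    animal = g,
    epd = ebv_tab[g, "epd"],
    bif = ebv_tab[g, "bif"],
    sire_epd = look(ped[g, "sire"], "epd"),
    sire_bif = look(ped[g, "sire"], "bif"),
    dam_epd = look(ped[g, "dam"], "epd"),
    dam_bif = look(ped[g, "dam"], "bif"),
    birth_year = ped[g, "birth_year"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(records = records, ebv_table = ebv_tab,
       truth_tbv = truth$tbv[g])
}

#' Simulate an additional trait on an existing population
#'
#' Draws a fresh QTL architecture from the population's reserved off-panel
#' pool (new loci and effects), giving an independent trait on the same
#' genotypes and pedigree. Feed the result to [simulate_trait_records()]
#' via its `truth` argument.
#'
#' @param pop Result of [simulate_population()].
#' @param cfg The [sim_config()] used.
#' @param seed Integer seed.
#' @return Truth list (`tbv`, `qtl`, `var_g`) like `pop$truth`.
#' @export
simulate_trait <- function(pop, cfg, seed = 1) {
  withr_seed(seed, draw_trait_truth(pop$qtl_pool_geno,
                                    rownames(pop$qtl_pool_geno) %in%
                                      pop$genotyped, cfg))
}

#' Write a self-contained fixture dataset
#'
#' Generates a population and trait records and writes the plain-text
#' files every reader in the package consumes: `pedigree.csv`,
#' `genotypes.raw` (PLINK-RAW-style dosage table), `trait.tsv`
#' (deregression input) and `truth.tsv` (true breeding values, for test
#' oracles only). The `tiny` scale (about 300 genotyped animals x 1000
#' markers) is sized for routine testing; `paper_like` mirrors the shape
#' of a national sire-genotyping study (about 3500 genotyped bulls,
#' 45 000 markers, five latent subpopulations) and is correspondingly
#' expensive.
#'
#' @param scale `"tiny"` or `"paper_like"`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return List with file `paths`, the population `pop`, `cfg` and the
#'   record bundle `trait`.
#' @export
make_fixture <- function(scale = c("tiny", "paper_like"), dir = tempfile(),
                         seed = 1) {
  scale <- match.arg(scale)
  cfg <- switch(scale,
    tiny = sim_config(),
    paper_like = sim_config(n_chr = 29, markers_per_chr = 1552,
                            pool_size = 30, n_qtl = 300,
                            n_herds = 4, founder_males = 15,
                            founder_females = 60, sires_per_herd = 12,
                            fam_size = c(18, 24, 30, 38, 48),
                            closed_size = 60, closed_generations = 9,
                            closed_sires = 10, closed_founders = 24,
                            year0 = 1955, gen_interval = 5))
  pop <- simulate_population(cfg, seed = seed)
  trait <- simulate_trait_records(pop, cfg, seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    pedigree = file.path(dir, "pedigree.csv"),
    genotypes = file.path(dir, "genotypes.raw"),
    trait = file.path(dir, "trait.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  ped_out <- pop$ped
  ped_out$sire[is.na(ped_out$sire)] <- "0"
  ped_out$dam[is.na(ped_out$dam)] <- "0"
  utils::write.csv(as.data.frame(ped_out), paths$pedigree, row.names = FALSE,
                   quote = FALSE)
  geno_out <- data.frame(FID = "SIM", IID = rownames(pop$geno),
                         pop$geno, check.names = FALSE,
                         stringsAsFactors = FALSE)
  utils::write.table(geno_out, paths$genotypes, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(trait$records, paths$trait, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(animal = names(trait$truth_tbv), tbv = trait$truth_tbv),
    paths$truth, sep = "\t", row.names = FALSE, quote = FALSE)
  list(paths = paths, pop = pop, cfg = cfg, trait = trait)
}
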