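#' Read a pedigree file
#'
#' Reads a pedigree table with columns `animal`, `sire`, `dam`, `birth_year`
#' (extra columns are ignored). Unknown parents are coded `0`, `NA` or an
#' empty string. Parents that are named but have no record of their own get
#' an implicit founder record (unknown parents, unknown birth year). The
#' result is topologically sorted so that parents always precede offspring.
#'
#' @param path Path to a CSV file (or anything `read.csv` accepts).
#' @return A `kinfold_pedigree` object: a `data.frame` with character columns
#'   `animal`, `sire`, `dam` (`NA` = unknown) and integer `birth_year`.
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(raw))) {
    stop("pedigree file must have columns 'animal', 'sire', 'dam'")
  }
  if (!"birth_year" %in% names(raw)) raw$birth_year <- NA_integer_
  as_pedigree(raw[, c("animal", "sire", "dam", "birth_year")])
}

#' Build a pedigree object from a data frame
#'
#' @param df Data frame with columns `animal`, `sire`, `dam` and optionally
#'   `birth_year`. Unknown parents: `0`, `""` or `NA`.
#' @return A topologically sorted `kinfold_pedigree`.
#' @export
as_pedigree <- function(df) {
  if (inherits(df, "kinfold_pedigree")) return(df)
  clean_id <- function(x) {
    x <- trimws(as.character(x))
    x[x == "0" | x == "" | is.na(x)] <- NA_character_
    x
  }
  animal <- trimws(as.character(df$animal))
  if (anyDuplicated(animal)) {
    stop("duplicate animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  }
  sire <- clean_id(df$sire)
  dam <- clean_id(df$dam)
  year <- if ("birth_year" %in% names(df)) {
    suppressWarnings(as.integer(df$birth_year))
  } else rep(NA_integer_, length(animal))

  # implicit founder records for named parents without a row of their own
  missing_parents <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(missing_parents)) {
    animal <- c(animal, missing_parents)
    sire <- c(sire, rep(NA_character_, length(missing_parents)))
    dam <- c(dam, rep(NA_character_, length(missing_parents)))
    year <- c(year, rep(NA_integer_, length(missing_parents)))
  }

  ord <- ped_toposort(animal, sire, dam)
  ped <- data.frame(animal = animal[ord], sire = sire[ord], dam = dam[ord],
                    birth_year = year[ord], stringsAsFactors = FALSE)
  rownames(ped) <- NULL
  class(ped) <- c("kinfold_pedigree", "data.frame")
  ped
}

# Kahn topological sort over the parent -> offspring DAG; reports a cycle
# chain on failure.
ped_toposort <- function(animal, sire, dam) {
  n <- length(animal)
  idx <- seq_len(n)
  names(idx) <- animal
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam), 0L, idx[dam])
  indeg <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (p > 0L) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[[1]]
    queue <- queue[-1]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    stuck <- setdiff(seq_len(n), ord)
    # walk parent links among the stuck set to exhibit one cycle
    chain <- stuck[[1]]
    repeat {
      nxt <- c(si[chain[length(chain)]], di[chain[length(chain)]])
      nxt <- nxt[nxt %in% stuck][1]
      if (nxt %in% chain) {
        chain <- c(chain[which(chain == nxt):length(chain)], nxt)
        break
      }
      chain <- c(chain, nxt)
    }
    stop("pedigree cycle detected: ",
         paste(animal[chain], collapse = " -> "))
  }
  ord
}

#' Prune single-use founders from a pedigree
#'
#' Removes parentless animals that appear exactly once as a parent and are
#' not in `keep`; such founders link no two retained animals, so additive
#' relationships among the kept animals are unchanged. The rule is applied
#' repeatedly until a fixed point is reached, because removing a founder can
#' turn its mate or other animals into prunable founders.
#'
#' @param ped A `kinfold_pedigree`.
#' @param keep Character vector of ids that must be retained.
#' @return The pruned `kinfold_pedigree`.
#' @export
prune_founders <- function(ped, keep = character(0)) {
  stopifnot(inherits(ped, "kinfold_pedigree"))
  keep <- as.character(keep)
  if (length(setdiff(keep, ped$animal))) {
    stop("keep contains ids not in the pedigree")
  }
  repeat {
    parent_counts <- table(c(ped$sire, ped$dam))
    parentless <- is.na(ped$sire) & is.na(ped$dam)
    n_as_parent <- as.integer(parent_counts[ped$animal])
    n_as_parent[is.na(n_as_parent)] <- 0L
    drop <- parentless & n_as_parent == 1L & !(ped$animal %in% keep)
    if (!any(drop)) break
    dropped <- ped$animal[drop]
    ped <- ped[!drop, , drop = FALSE]
    ped$sire[ped$sire %in% dropped] <- NA_character_
    ped$dam[ped$dam %in% dropped] <- NA_character_
  }
  rownames(ped) <- NULL
  class(ped) <- c("kinfold_pedigree", "data.frame")
  ped
}

#' Pedigree numerator relationship matrix
#'
#' Computes additive genetic relationships by the tabular method over the
#' full pedigree: \eqn{a_{ii} = 1 + 0.5 a_{sd}} and
#' \eqn{a_{ij} = 0.5 (a_{js} + a_{jd})} for \eqn{j < i} in topological
#' order, with unknown parents treated as unrelated non-inbred founders.
#' The matrix is then restricted to `subset`, so relationships through
#' non-subset ancestors are fully accounted for.
#'
#' @param ped A `kinfold_pedigree`.
#' @param subset Ids to retain in the returned matrix (default: all).
#' @return A `kinfold_relmat` object: list with `ids`, the symmetric
#'   relationship matrix `A` and inbreeding coefficients `F` (= diag(A) - 1).
#' @export
build_A <- function(ped, subset = NULL) {
  stopifnot(inherits(ped, "kinfold_pedigree"))
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- if (s > 0L && d > 0L) 1 + 0.5 * A[s, d] else 1
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (s > 0L) A[j, s] else 0
      ad_ <- if (d > 0L) A[j, d] else 0
      v <- 0.5 * (as_ + ad_)
      A[j, i] <- v
      A[i, j] <- v
    }
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  if (!is.null(subset)) {
    subset <- as.character(subset)
    if (length(setdiff(subset, ped$animal))) {
      stop("subset contains ids not in the pedigree")
    }
    A <- A[subset, subset, drop = FALSE]
  }
  out <- list(ids = rownames(A), A = A, F = diag(A) - 1)
  class(out) <- "kinfold_relmat"
  out
}

#' Pedigree dissimilarity matrix
#'
#' Transforms a relationship matrix into the pedigree distance
#' \eqn{d_{ij} = 1 - a_{ij} / \sqrt{a_{ii} a_{jj}}}. Normalising by the
#' diagonal removes the effect of inbreeding, so the diagonal of D is zero
#' and entries lie in \[0, 1\] for pedigree relationships.
#'
#' @param relmat A `kinfold_relmat` from [build_A()].
#' @return A `kinfold_dissim` object: list with `ids` and matrix `D`.
#' @export
dissimilarity <- function(relmat) {
  stopifnot(inherits(relmat, "kinfold_relmat"))
  dd <- diag(relmat$A)
  D <- 1 - relmat$A / sqrt(outer(dd, dd))
  D[D < 0] <- 0
  D[D > 1] <- 1
  diag(D) <- 0
  out <- list(ids = relmat$ids, D = D)
  class(out) <- "kinfold_dissim"
  out
}

#' Maximum-relationship diagnostics for a grouping
#'
#' For every animal, computes its maximum additive relationship
#' (\eqn{a_{max}}) with the members of each group (itself excluded), the
#' diagnostic used to judge how well a fold assignment separates related
#' animals. Also returns per-group summaries: size, mean birth year, mean
#' inbreeding, mean pairwise relationship within the group, and mean/sd of
#' within- and between-group \eqn{a_{max}}.
#'
#' @param relmat A `kinfold_relmat` covering all grouped animals.
#' @param parts A `kinfold_partition` (or a named group vector) assigning
#'   each animal to exactly one group.
#' @param birth_years Optional named vector of birth years for the summary.
#' @return List with `amax` (animals x groups matrix), `own_group`, and
#'   `summary` (one row per group).
#' @export
amax_diagnostics <- function(relmat, parts, birth_years = NULL) {
  stopifnot(inherits(relmat, "kinfold_relmat"))
  assign <- partition_assignments(parts)
  ids <- relmat$ids
  if (length(setdiff(ids, names(assign)))) {
    stop("every animal in the relationship matrix must be assigned to a group")
  }
  grp <- assign[ids]
  groups <- sort(unique(grp))
  A <- relmat$A
  n <- length(ids)
  amax <- matrix(NA_real_, n, length(groups), dimnames = list(ids, groups))
  for (gi in seq_along(groups)) {
    members <- which(grp == groups[gi])
    for (i in seq_len(n)) {
      others <- setdiff(members, i)
      if (length(others)) amax[i, gi] <- max(A[i, others])
    }
  }
  within <- amax[cbind(seq_len(n), match(grp, groups))]
  between <- amax
  between[cbind(seq_len(n), match(grp, groups))] <- NA_real_

  summ <- do.call(rbind, lapply(groups, function(g) {
    members <- which(grp == g)
    Ag <- A[members, members, drop = FALSE]
    off <- Ag[upper.tri(Ag)]
    bet <- between[members, , drop = FALSE]
    data.frame(
      group = g,
      n = length(members),
      mean_birth_year = if (is.null(birth_years)) NA_real_ else
        mean(birth_years[ids[members]], na.rm = TRUE),
      sd_birth_year = if (is.null(birth_years)) NA_real_ else
        stats::sd(birth_years[ids[members]], na.rm = TRUE),
      mean_F = mean(relmat$F[members]),
      sd_F = stats::sd(relmat$F[members]),
      mean_a_within = if (length(off)) mean(off) else NA_real_,
      sd_a_within = if (length(off)) stats::sd(off) else NA_real_,
      mean_amax_within = mean(within[members], na.rm = TRUE),
      sd_amax_within = stats::sd(within[members], na.rm = TRUE),
      mean_amax_between = mean(bet, na.rm = TRUE),
      sd_amax_between = stats::sd(bet, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  rownames(summ) <- NULL
  list(amax = amax, own_group = grp, summary = summ)
}

#' Mean generation interval
#'
#' Mean age of parents at the birth of their progeny, over all
#' parent-progeny pairs in which the parent's birth year falls inside
#' `year_window` and both birth years are known.
#'
#' @param ped A `kinfold_pedigree`.
#' @param year_window Length-2 integer vector, inclusive parent birth-year
#'   window.
#' @return Mean parent age (years) at progeny birth.
#' @export
generation_interval <- function(ped, year_window = c(-Inf, Inf)) {
  stopifnot(inherits(ped, "kinfold_pedigree"))
  yr <- ped$birth_year
  names(yr) <- ped$animal
  ages <- c()
  for (col in c("sire", "dam")) {
    p <- ped[[col]]
    ok <- !is.na(p) & !is.na(yr) & !is.na(yr[p]) &
      yr[p] >= year_window[1] & yr[p] <= year_window[2]
    ages <- c(ages, yr[ok] - yr[p[ok]])
  }
  if (!length(ages)) {
    stop("no parent-progeny pairs with known birth years in the window")
  }
  mean(ages)
}

#' @export
print.kinfold_pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "animals,",
      sum(is.na(x$sire) & is.na(x$dam)), "founders\n")
  invisible(x)
}

#' @export
print.kinfold_relmat <- function(x, ...) {
  cat("Relationship matrix:", length(x$ids), "animals, mean F =",
      format(mean(x$F), digits = 4), "\n")
  invisible(x)
}
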