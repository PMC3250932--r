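#' K-means folds from a pedigree dissimilarity matrix
#'
#' Clusters animals into K groups by Hartigan-Wong K-means applied to the
#' rows of the dissimilarity matrix (each animal's vector of pedigree
#' distances to all animals is its feature vector). This concentrates
#' related animals in the same group, so cross-validation folds built from
#' the groups minimise training-validation relatedness.
#'
#' @param dissim A `kinfold_dissim` from [dissimilarity()].
#' @param K Number of groups (default 5).
#' @param n_start Random restarts; the best objective is kept (default 25).
#' @param seed Integer seed.
#' @return A `kinfold_partition`: list with `method`, `K`, `assignment`
#'   (named integer vector), `objective` (total within-cluster sum of
#'   squares) and `seed`.
#' @export
kmeans_folds <- function(dissim, K = 5, n_start = 25, seed = 1) {
  stopifnot(inherits(dissim, "kinfold_dissim"), K >= 2)
  X <- dissim$D
  if (K == nrow(X)) {
    # degenerate: one animal per cluster, zero within-cluster scatter
    assignment <- seq_len(K)
    names(assignment) <- dissim$ids
    return(new_partition("kmeans", K, assignment, seed = seed,
                         objective = 0))
  }
  if (K > nrow(X)) stop("more clusters than animals")
  fit <- NULL
  for (attempt in 0:4) {
    fit <- withr_seed(seed + attempt, {
      tryCatch(stats::kmeans(X, centers = K, nstart = n_start,
                             iter.max = 100, algorithm = "Hartigan-Wong"),
               error = function(e) e)
    })
    if (!inherits(fit, "error")) break
    message("kmeans restart (", conditionMessage(fit), "), seed bumped")
  }
  if (inherits(fit, "error")) stop("kmeans failed: ", conditionMessage(fit))
  assignment <- fit$cluster
  names(assignment) <- dissim$ids
  new_partition("kmeans", K, assignment, seed = seed,
                objective = fit$tot.withinss)
}

#' Random folds
#'
#' Splits animals uniformly at random into K groups whose sizes differ by
#' at most one, as a baseline against relationship-aware folds.
#'
#' @param ids Animal ids.
#' @param K Number of groups.
#' @param replicate Replicate index (alters the stream so replicates of the
#'   same seed differ reproducibly).
#' @param seed Integer seed.
#' @return A `kinfold_partition`.
#' @export
random_folds <- function(ids, K = 5, replicate = 1, seed = 1) {
  stopifnot(K >= 2, length(ids) >= K)
  ids <- as.character(ids)
  perm <- withr_seed(seed + 7919L * (replicate - 1L), sample(length(ids)))
  assignment <- rep(seq_len(K), length.out = length(ids))[order(perm)]
  names(assignment) <- ids
  new_partition("random", K, assignment, seed = seed, replicate = replicate)
}

#' Birth-year split for validation on young animals
#'
#' Chooses the largest threshold year such that animals born after it make
#' up at least `valid_fraction` of the records; those animals form the
#' validation set and the older animals the training set. Ties at the
#' threshold year go to training.
#'
#' @param ids Animal ids.
#' @param birth_years Birth years aligned with `ids`.
#' @param valid_fraction Target validation share (default 0.20).
#' @return A `kinfold_partition` with two groups: 1 = training (old),
#'   2 = validation (young), and the chosen `threshold_year`.
#' @export
age_split <- function(ids, birth_years, valid_fraction = 0.20) {
  stopifnot(length(ids) == length(birth_years))
  ids <- as.character(ids)
  yrs <- sort(unique(birth_years))
  if (length(yrs) < 2) stop("all animals share one birth year; cannot split")
  share <- vapply(yrs, function(t) mean(birth_years > t), 0)
  ok <- which(share >= valid_fraction)
  if (!length(ok)) stop("no threshold achieves the requested validation share")
  threshold <- yrs[max(ok)]
  assignment <- ifelse(birth_years > threshold, 2L, 1L)
  names(assignment) <- ids
  if (!any(assignment == 1L)) stop("training set empty at chosen threshold")
  p <- new_partition("age", 2L, assignment, seed = NA_integer_)
  p$threshold_year <- threshold
  p$valid_fraction <- mean(assignment == 2L)
  p
}

#' Cross-validation plan from a partition
#'
#' One fold per group: the group is the validation set and all other
#' animals form the training set, so every animal's prediction is obtained
#' without its own record. For an age split only the young group is a
#' validation fold.
#'
#' @param parts A `kinfold_partition`.
#' @return List of folds, each `list(group, train, validate)`.
#' @export
cv_plan <- function(parts) {
  assignment <- partition_assignments(parts)
  ids <- names(assignment)
  groups <- if (identical(parts$method, "age")) 2L else sort(unique(assignment))
  folds <- lapply(groups, function(g) {
    validate <- ids[assignment == g]
    train <- ids[assignment != g]
    if (length(intersect(train, validate))) {
      stop("animal present in both training and validation sets")
    }
    list(group = g, train = train, validate = validate)
  })
  folds
}

new_partition <- function(method, K, assignment, seed,
                          replicate = NA_integer_, objective = NA_real_) {
  out <- list(method = method, K = as.integer(K), assignment = assignment,
              replicate = replicate, seed = seed, objective = objective)
  class(out) <- "kinfold_partition"
  out
}

partition_assignments <- function(parts) {
  if (inherits(parts, "kinfold_partition")) return(parts$assignment)
  if (is.null(names(parts))) stop("group vector must be named by animal id")
  parts
}

#' @export
print.kinfold_partition <- function(x, ...) {
  cat("Partition (", x$method, "): ", length(x$assignment), " animals in ",
      length(unique(x$assignment)), " groups\n", sep = "")
  print(table(x$assignment))
  invisible(x)
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
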