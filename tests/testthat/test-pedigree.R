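test_that("pedigree reading forces topological order and implicit founders", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,sire,dam,birth_year",
               "X,S,D,2004",
               "S,0,,1999",
               "D,0,0,2000"), f)
  ped <- read_pedigree(f)
  expect_s3_class(ped, "kinfold_pedigree")
  expect_equal(nrow(ped), 3)
  expect_equal(ped$animal[3], "X")
  expect_true(all(is.na(ped[ped$animal %in% c("S", "D"), c("sire", "dam")])))

  # offspring listed before its sire: same pedigree after sorting
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,sire,dam,birth_year",
               "X,S,D,2004",
               "D,0,0,2000",
               "S,0,0,1999"), f2)
  ped2 <- read_pedigree(f2)
  expect_equal(ped2[order(ped2$animal), ], ped[order(ped$animal), ],
               ignore_attr = TRUE)

  # parent not listed as a record gets an implicit founder row
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,sire,dam,birth_year", "X,S,D,2004"), f3)
  expect_equal(nrow(read_pedigree(f3)), 3)
})

test_that("pedigree cycles and duplicate ids are fatal", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,sire,dam,birth_year",
               "A,B,0,2000", "B,A,0,2001"), f)
  expect_error(read_pedigree(f), "cycle")
  expect_error(as_pedigree(data.frame(animal = c("A", "A"),
                                      sire = c(NA, NA), dam = c(NA, NA))),
               "duplicate")
})

test_that("founder pruning removes single-use founders only, preserving A", {
  ped <- as_pedigree(data.frame(
    animal = c("F1", "F2", "F3", "X", "Y"),
    sire = c(NA, NA, NA, "F1", "F2"),
    dam = c(NA, NA, NA, "F2", "F3"),
    birth_year = c(0, 0, 0, 1, 1)))
  pruned <- prune_founders(ped, keep = c("X", "Y"))
  # F1 and F3 each appear once as a parent; F2 links X and Y
  expect_setequal(pruned$animal, c("F2", "X", "Y"))
  A_full <- build_A(ped, subset = c("X", "Y"))$A
  A_pruned <- build_A(pruned, subset = c("X", "Y"))$A
  expect_equal(A_pruned, A_full, tolerance = 1e-12)

  # pruning iterates to a fixed point on random pedigrees without
  # changing relationships among the kept set
  for (s in 1:3) {
    rped <- random_pedigree(12, 3, 8, seed = s)
    keep <- tail(rped$animal, 10)
    pr <- prune_founders(rped, keep = keep)
    expect_equal(build_A(pr, subset = keep)$A,
                 build_A(rped, subset = keep)$A, tolerance = 1e-12)
    # fixed point: pruning again changes nothing
    expect_equal(nrow(prune_founders(pr, keep = keep)), nrow(pr))
  }
})

test_that("tabular relationships reproduce textbook values", {
  founders <- as_pedigree(data.frame(animal = c("A", "B", "C"),
                                     sire = NA, dam = NA))
  expect_equal(build_A(founders)$A, diag(3), ignore_attr = TRUE)

  ped <- as_pedigree(data.frame(
    animal = c("S", "D", "X", "Y", "Z"),
    sire = c(NA, NA, "S", "S", "X"),
    dam = c(NA, NA, "D", "D", "Y")))
  A <- build_A(ped)
  expect_equal(A$A["S", "X"], 0.5)      # parent-offspring
  expect_equal(A$A["X", "Y"], 0.5)      # full sibs
  expect_equal(A$A["Z", "Z"], 1.25)     # offspring of full-sib mating
  expect_equal(unname(A$F["Z"]), 0.25)
  # subsetting after computing over the full pedigree keeps ancestral paths
  expect_equal(build_A(ped, subset = c("X", "Z"))$A["X", "Z"], 0.75)
})

test_that("tabular relationships match the gene-dropping oracle", {
  ped <- random_pedigree(8, 3, 7, seed = 7)  # ~29 animals
  A <- build_A(ped)$A
  gd <- gene_drop_relmat(ped, n_rep = 3e4, seed = 11)
  err <- abs(A - gd$A)
  tol <- 3 * gd$SE + 1e-12
  expect_lt(mean(err > tol), 0.01)
  expect_lt(max(err), 6 * max(gd$SE))
})

test_that("relationship matrices are PSD and self-consistent", {
  for (s in 1:4) {
    ped <- random_pedigree(12, 4, 25, seed = s)
    A <- build_A(ped)
    expect_gt(min(eigen(A$A, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
    # a_ii - 1 = 0.5 * a_sd for every non-founder
    for (i in which(!is.na(ped$sire) & !is.na(ped$dam))) {
      expect_equal(A$A[ped$animal[i], ped$animal[i]] - 1,
                   0.5 * A$A[ped$sire[i], ped$dam[i]], tolerance = 1e-12)
    }
    D <- dissimilarity(A)$D
    expect_true(all(D >= 0 & D <= 1))
    expect_true(all(diag(D) == 0))
  }
})

test_that("dissimilarity removes inbreeding and maps kinship to distance", {
  ped <- as_pedigree(data.frame(
    animal = c("S", "D", "U", "X"),
    sire = c(NA, NA, NA, "S"),
    dam = c(NA, NA, NA, "D")))
  D <- dissimilarity(build_A(ped))$D
  expect_equal(D["S", "U"], 1)    # unrelated, non-inbred
  expect_equal(D["S", "X"], 0.5)  # non-inbred parent-offspring
  expect_equal(dissimilarity(build_A(as_pedigree(
    data.frame(animal = c("A", "B"), sire = NA, dam = NA))))$D,
    1 - diag(2), ignore_attr = TRUE)
})

test_that("a_max diagnostics match exhaustive maxima and handle edge groups", {
  # two disjoint families -> between-group a_max identically zero
  ped <- as_pedigree(data.frame(
    animal = c("S1", "D1", "X1", "Y1", "S2", "D2", "X2", "Y2"),
    sire = c(NA, NA, "S1", "S1", NA, NA, "S2", "S2"),
    dam = c(NA, NA, "D1", "D1", NA, NA, "D2", "D2")))
  A <- build_A(ped)
  fam <- setNames(rep(c(1L, 2L), each = 4),
                  c("S1", "D1", "X1", "Y1", "S2", "D2", "X2", "Y2"))
  diag1 <- amax_diagnostics(A, fam)
  between <- diag1$amax
  between[cbind(seq_along(A$ids), match(fam[A$ids], colnames(between)))] <- NA
  expect_true(all(between == 0, na.rm = TRUE))

  # one group covering everything: within a_max is each animal's global max
  all_one <- setNames(rep(1L, length(A$ids)), A$ids)
  d2 <- amax_diagnostics(A, all_one)
  Amat <- A$A; diag(Amat) <- -Inf
  expect_equal(unname(d2$amax[, 1]), unname(apply(Amat, 1, max)))

  # exhaustive-max oracle on a random pedigree with arbitrary groups
  rped <- random_pedigree(10, 3, 10, seed = 3)
  rA <- build_A(rped)
  grp <- setNames(rep(1:3, length.out = length(rA$ids)), rA$ids)
  dg <- amax_diagnostics(rA, grp)
  for (g in 1:3) {
    members <- names(grp)[grp == g]
    for (id in rA$ids) {
      others <- setdiff(members, id)
      expect_equal(dg$amax[id, as.character(g)], max(rA$A[id, others]))
    }
  }

  # singleton group: within-group a_max undefined for its only member
  solo <- grp
  solo[1] <- 9L
  ds <- amax_diagnostics(rA, solo)
  expect_true(is.na(ds$amax[1, "9"]))
})

test_that("generation interval averages parent ages inside the window", {
  ped <- as_pedigree(data.frame(
    animal = c("P", "Q", "C1", "C2"),
    sire = c(NA, NA, "P", "P"),
    dam = c(NA, NA, "Q", "Q"),
    birth_year = c(0, 2, 5, 9)))
  expect_equal(generation_interval(ped, c(0, 0)), mean(c(5, 9)))
  expect_equal(generation_interval(ped), mean(c(5, 9, 3, 7)))
  expect_error(generation_interval(ped, c(100, 200)), "no parent-progeny")

  # fixed 4-year mating age by construction
  ped4 <- as_pedigree(data.frame(
    animal = c("A", "B", "C"), sire = c(NA, "A", "B"),
    dam = NA, birth_year = c(2000, 2004, 2008)))
  expect_equal(generation_interval(ped4), 4)
})
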