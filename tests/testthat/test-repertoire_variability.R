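toy_fold_setup <- function() {
  groups <- c(c1 = "cytoplasmome", c2 = "cytoplasmome", c3 = "cytoplasmome",
              c4 = "cytoplasmome", c5 = "cytoplasmome",
              s1 = "secretome", s2 = "secretome", s3 = "secretome")
  ft <- data.frame(
    accession = c("c1", "c2", "c3", "c4", "c5",   # fold X: 5 cytoplasmic
                  "c1", "c2", "s1",               # fold Y: 2 cyto + 1 secr
                  "s1", "s2", "s3", "c3"),        # fold Z: shared, frequent
    fold_id = c(rep("X", 5), rep("Y", 3), rep("Z", 4)),
    scop_class = c(rep("c", 5), rep("a", 3), rep("b", 4)),
    start = 1L, end = 50L)
  list(ft = ft, groups = groups)
}

test_that("fold census applies the rare/frequent and unique/shared rules", {
  s <- toy_fold_setup()
  cen <- fold_census(s$ft, s$groups)
  f <- cen$folds
  x <- f[f$fold_id == "X", ]
  expect_equal(x$status, "unique")
  expect_equal(x$rarity, "frequent")   # 5 >= 4
  y <- f[f$fold_id == "Y", ]
  expect_equal(y$status, "shared")
  expect_equal(y$rarity, "rare")       # 3 <= 3
  z <- f[f$fold_id == "Z", ]
  expect_equal(z$rarity, "frequent")   # exactly 4: the >= 4 boundary
  ## partition invariants
  expect_equal(f$total, f$cytoplasmome + f$secretome)
  expect_setequal(unique(f$status), c("unique", "shared"))
  expect_setequal(unique(f$rarity), c("rare", "frequent"))
})

test_that("class composition counts each distinct fold once per group", {
  s <- toy_fold_setup()
  cen <- fold_census(s$ft, s$groups)
  ## cytoplasmome sees folds X(c), Y(a), Z(b): 1/3 each of a, b, c
  expect_equal(unname(cen$class_composition["cytoplasmome", c("a", "b", "c")]),
               rep(1 / 3, 3))
  ## secretome sees Y(a), Z(b)
  expect_equal(unname(cen$class_composition["secretome", "a"]), 0.5)
  expect_equal(unname(cen$class_composition["secretome", "b"]), 0.5)
})

test_that("a fold at exactly 3% of a group's instances is popular", {
  groups <- setNames(rep("cytoplasmome", 100), sprintf("p%03d", 1:100))
  ## 100 instances: fold "rare3" has exactly 3 -> 3%
  ft <- data.frame(
    accession = sprintf("p%03d", 1:100),
    fold_id = c(rep("big", 97), rep("rare3", 3)),
    scop_class = "a", start = 1L, end = 50L)
  cen <- fold_census(ft, groups)
  expect_true("rare3" %in% cen$popular$cytoplasmome)
  ## at 2.9% it is not
  ft2 <- data.frame(
    accession = sprintf("q%03d", 1:104),
    fold_id = c(rep("big", 101), rep("rare3", 3)),
    scop_class = "a", start = 1L, end = 50L)
  groups2 <- setNames(rep("cytoplasmome", 104), sprintf("q%03d", 1:104))
  cen2 <- fold_census(ft2, groups2)
  expect_false("rare3" %in% cen2$popular$cytoplasmome)
})

test_that("soluble-only filtering removes class f and unassigned rows warn", {
  s <- toy_fold_setup()
  ft <- rbind(s$ft, data.frame(accession = "c1", fold_id = "M", scop_class = "f",
                               start = 1L, end = 50L))
  cen <- fold_census(ft, s$groups, soluble_only = TRUE)
  expect_false("M" %in% cen$folds$fold_id)

  ft2 <- rbind(s$ft, data.frame(accession = "nogroup", fold_id = "W",
                                scop_class = "a", start = 1L, end = 50L))
  expect_warning(fold_census(ft2, s$groups), "without a group")
})

test_that("folds per protein counts duplicate domain rows as real domains", {
  groups <- c(a = "cytoplasmome", b = "cytoplasmome", c = "cytoplasmome")
  ft <- data.frame(accession = c("a", "b", "b", "c", "c", "c"),
                   fold_id = c("f1", "f1", "f2", "f1", "f1", "f3"),
                   scop_class = "a", start = 1L, end = 50L)
  fp <- folds_per_protein(ft, groups)
  expect_equal(fp$nfold_fraction, 2 / 3)
  expect_equal(fp$mean_folds, 2.0)
  expect_equal(fp$mean_folds_nfold, 2.5)

  single <- data.frame(accession = c("a", "b"), fold_id = "f1",
                       scop_class = "a", start = 1L, end = 50L)
  fp2 <- folds_per_protein(single, groups)
  expect_equal(fp2$nfold_fraction, 0)
})

test_that("variability score is zero for constant rows and scale-free", {
  m <- matrix(5, 3, 13, dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(unname(variability_score(m)), rep(0, 3))

  set.seed(41)
  m <- matrix(2^rnorm(4 * 13, 8), 4, 13,
              dimnames = list(letters[1:4], NULL))
  expect_equal(variability_score(m * 7), variability_score(m))
  expect_equal(variability_score(2 * m), variability_score(m))

  r1 <- matrix(c(rep(1, 12), 8), 1, 13, dimnames = list("r1", NULL))
  r2 <- matrix(c(rep(1, 12), 2), 1, 13, dimnames = list("r2", NULL))
  expect_gt(variability_score(r1), variability_score(r2))
  ## frozen against direct computation: sd of log2 row
  expect_equal(unname(variability_score(r1)), sd(log2(r1[1, ])))

  expect_error(variability_score(matrix(c(1, -1), 1, 2)), "positive")
  expect_error(variability_score(matrix(1, 2, 1)), "2 conditions")
})

test_that("variability binning respects quartiles, cutoffs and tie rules", {
  set.seed(42)
  v <- runif(100)
  cls <- bin_variability(v)
  expect_equal(as.vector(table(cls)), c(25L, 25L, 25L, 25L))
  expect_equal(levels(cls), c("very_low", "low", "moderate", "high"))

  cls2 <- bin_variability(c(0.05, 0.2, 0.5, 0.9), mode = "explicit",
                          cutoffs = c(0.1, 0.3, 0.6))
  expect_equal(as.character(cls2), c("very_low", "low", "moderate", "high"))
  ## boundary ties go to the lower class
  cls3 <- bin_variability(c(0.1, 0.3, 0.6), mode = "explicit",
                          cutoffs = c(0.1, 0.3, 0.6))
  expect_equal(as.character(cls3), c("very_low", "low", "moderate"))

  expect_equal(as.character(bin_variability(rep(0.2, 8))),
               rep("very_low", 8))
  expect_error(bin_variability(1:10, mode = "explicit", cutoffs = c(3, 2, 1)),
               "ascending")
  expect_error(bin_variability(1:3), ">= 4")
})
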