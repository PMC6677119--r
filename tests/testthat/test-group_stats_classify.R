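test_that("group comparisons route to the right test with the star scheme", {
  set.seed(51)
  x <- rnorm(200)
  g <- rep(c("A", "B"), each = 100)
  null_res <- compare_groups(x, g, "noise")
  expect_equal(null_res$test, "kruskal_wallis")
  expect_gt(null_res$p, 0.05)
  expect_equal(null_res$stars, "#")

  ## a 2-pooled-SD shift at n = 100/group is overwhelming
  x2 <- c(rnorm(100), rnorm(100, mean = 2))
  shift_res <- compare_groups(x2, g, "shift")
  expect_lt(shift_res$p, 0.001)
  expect_equal(shift_res$stars, "***")
  expect_equal(shift_res$direction, "B")

  b <- c(rep(TRUE, 60), rep(FALSE, 40), rep(TRUE, 30), rep(FALSE, 70))
  fish <- compare_groups(b, g, "flag")
  expect_equal(fish$test, "fisher_exact")
  expect_equal(fish$direction, "A")

  expect_error(compare_groups(1:5, c("A", "A", "A", "A", "B")),
               "< 2 observations")
})

test_that("Fisher test matches the hypergeometric enumeration oracle", {
  ## the balanced toy table [[20,10],[10,20]]: the sample odds ratio is
  ## (20*20)/(10*10) = 4 exactly; the p-value must match exact enumeration
  tab <- matrix(c(20, 10, 10, 20), 2, byrow = TRUE)
  ht <- fisher.test(tab)
  expect_equal(unname((tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])), 4.0)
  expect_equal(ht$p.value, oracle_fisher_p(20, 10, 10, 20), tolerance = 1e-9)

  set.seed(52)
  for (i in 1:50) {
    cells <- sample(0:12, 4, replace = TRUE)
    if (sum(cells) == 0) next
    ht <- fisher.test(matrix(cells, 2))
    expect_equal(ht$p.value,
                 oracle_fisher_p(cells[1], cells[3], cells[2], cells[4]),
                 tolerance = 1e-9)
  }
})

test_that("feature tables assemble with masking and collision detection", {
  b1 <- data.frame(accession = c("p1", "p2", "p3"), f1 = 1:3, f2 = c(TRUE, FALSE, TRUE))
  b2 <- data.frame(accession = c("p1", "p3"), rco = c(0.1, 0.2))
  ft <- assemble_feature_table(list(seqs = b1, struct = b2),
                               groups = c(p1 = "A", p2 = "B", p3 = "A"))
  expect_equal(nrow(ft), 3)
  expect_true(is.na(ft$rco[ft$accession == "p2"]))   # masked, row kept
  expect_equal(sum(is.na(ft$f1)), 0)
  man <- attr(ft, "manifest")
  expect_equal(man$type[man$feature == "f2"], "boolean")

  dup <- data.frame(accession = c("p1", "p1"), f9 = 1:2)
  expect_error(assemble_feature_table(list(a = dup), c(p1 = "A")), "duplicate")
  clash <- data.frame(accession = "p1", f1 = 9)
  expect_error(assemble_feature_table(list(a = b1, b = clash), c(p1 = "A")),
               "collision")
})

test_that("positional profiles average per position with length dropout", {
  tracks <- list(a1 = rep(0.8, 50), a2 = rep(0.8, 90),
                 b1 = rep(0.2, 90), b2 = rep(0.2, 90))
  mem <- c(a1 = "interactor", a2 = "interactor",
           b1 = "non_interactor", b2 = "non_interactor")
  pp <- positional_profile(tracks, mem, n_positions = 90)
  expect_equal(nrow(pp), 90)
  expect_equal(unique(pp$difference), 0.6)
  ## the length-50 protein drops out after position 50
  expect_equal(pp$n_interactor[50], 2)
  expect_equal(pp$n_interactor[51], 1)

  flat <- list(a1 = rep(0.5, 90), a2 = rep(0.5, 90),
               b1 = rep(0.5, 90), b2 = rep(0.5, 90))
  pf <- positional_profile(flat, mem, n_positions = 10)
  expect_equal(unique(pf$mean_interactor), 0.5)
  expect_equal(unique(pf$difference), 0)

  expect_error(positional_profile(tracks, c(a1 = "x", a2 = "x", b1 = "x",
                                            b2 = "x")), "2 groups")
})

make_toy_table <- function(n = 120, p_noise = 6, seed = 1,
                           separation = 6) {
  set.seed(seed)
  g <- rep(c("cytoplasmome", "secretome"), each = n / 2)
  blocks <- data.frame(accession = sprintf("t%03d", 1:n))
  blocks$signal <- rnorm(n) + ifelse(g == "secretome", separation, 0)
  blocks$disorder_mean <- rnorm(n) + ifelse(g == "secretome", separation / 2, 0)
  for (k in seq_len(p_noise)) blocks[[paste0("noise", k)]] <- rnorm(n)
  ft <- assemble_feature_table(
    list(main = blocks),
    groups = setNames(g, blocks$accession),
    disorder_features = "disorder_mean")
  ft
}

test_that("a widely separated feature yields AUC 1 and nulls stay at chance", {
  ft <- make_toy_table()
  rep_sep <- train_evaluate_classifier(ft, n_folds = 5, n_repeats = 2, seed = 9)
  expect_equal(rep_sep$metrics$estimate[rep_sep$metrics$metric == "auc"], 1.0)
  expect_true("signal" %in% rep_sep$selected$feature)

  ## permuted labels: AUC near 0.5
  set.seed(10)
  perm <- sample(ft$group)
  rep_null <- train_evaluate_classifier(ft, labels = perm, n_folds = 5,
                                        n_repeats = 4, seed = 9)
  auc_null <- rep_null$metrics$estimate[rep_null$metrics$metric == "auc"]
  expect_gt(auc_null, 0.4)
  expect_lt(auc_null, 0.6)

  ## pure-noise table: accuracy near the majority-class fraction
  ftn <- make_toy_table(separation = 0)
  ftn$signal <- NULL; ftn$disorder_mean <- NULL
  attr(ftn, "manifest") <- data.frame(
    feature = paste0("noise", 1:6), type = "numeric", disorder = FALSE,
    block = "main")
  rep_noise <- train_evaluate_classifier(ftn, n_folds = 5, n_repeats = 2,
                                         seed = 9)
  acc <- rep_noise$metrics$estimate[rep_noise$metrics$metric == "accuracy"]
  expect_gt(acc, 0.30)
  expect_lt(acc, 0.70)

  expect_error(train_evaluate_classifier(ft, labels = rep("A", nrow(ft))),
               "2 classes")
})

test_that("classifier reports are bit-identical under a fixed seed", {
  ft <- make_toy_table()
  r1 <- train_evaluate_classifier(ft, n_folds = 5, n_repeats = 2, seed = 33)
  r2 <- train_evaluate_classifier(ft, n_folds = 5, n_repeats = 2, seed = 33)
  expect_identical(r1, r2)
  ## a different seed draws different cross-validation splits
  expect_false(identical(make_cv_splits(ft$group, 5, 2, seed = 33),
                         make_cv_splits(ft$group, 5, 2, seed = 34)))
})

test_that("fold-internal imputation and selection do not leak labels", {
  ## canary: a feature equal to the label itself, but labels permuted --
  ## a leaking pipeline would still reach AUC 1 via the canary computed on
  ## the full data; a clean one stays at chance because the permuted labels
  ## carry no signal
  ft <- make_toy_table(separation = 0)
  set.seed(60)
  perm <- sample(ft$group)
  ft$canary <- as.numeric(factor(ft$group))   # original labels as feature
  man <- attr(ft, "manifest")
  attr(ft, "manifest") <- rbind(man, data.frame(
    feature = "canary", type = "numeric", disorder = FALSE, block = "main"))
  rep_canary <- train_evaluate_classifier(ft, labels = perm, n_folds = 5,
                                          n_repeats = 4, seed = 61)
  auc <- rep_canary$metrics$estimate[rep_canary$metrics$metric == "auc"]
  expect_gt(auc, 0.4)
  expect_lt(auc, 0.6)
})

test_that("the ablation suite pairs splits across three labeled runs", {
  ft <- make_toy_table()
  suite <- ablation_suite(ft, n_folds = 5, n_repeats = 2, seed = 77)
  expect_named(suite, c("all_features", "non_disorder", "disorder_only"))
  auc_of <- function(r) r$metrics$estimate[r$metrics$metric == "auc"]
  expect_gte(auc_of(suite$all_features), auc_of(suite$disorder_only))
  ## identical CV design across runs: per-fold AUC vectors are comparable
  expect_equal(length(suite$all_features$fold_auc),
               length(suite$disorder_only$fold_auc))

  no_dis <- ft
  man <- attr(ft, "manifest"); man$disorder <- FALSE
  attr(no_dis, "manifest") <- man
  expect_error(ablation_suite(no_dis, seed = 1), "disorder")
})
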