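## Cytoplasmome-vs-secretome classification with repeated stratified
## cross-validation, fold-internal median imputation and embedded feature
## selection (L1-penalized logistic regression), plus the three-way
## feature-family ablation design (all features / non-disorder / disorder
## only) evaluated on identical CV splits for paired comparison.

#' Build repeated stratified cross-validation splits
#'
#' @param labels Factor or character vector of binary class labels.
#' @param n_folds Folds per repeat (default 10).
#' @param n_repeats Repeats (default 10).
#' @param seed Integer seed; splits are deterministic given the seed.
#' @return List of length `n_folds * n_repeats`; each element an integer
#'   vector of test-set row indices.
#' @export
make_cv_splits <- function(labels, n_folds = 10L, n_repeats = 10L, seed = 1L) {
  y <- as.factor(labels)
  if (nlevels(y) != 2L) stop("make_cv_splits: need binary labels")
  if (any(table(y) < n_folds)) {
    stop("make_cv_splits: a class has fewer members than folds")
  }
  rng <- local_rng(seed)
  on.exit(rng())
  splits <- list()
  for (r in seq_len(n_repeats)) {
    fold_of <- integer(length(y))
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      fold_of[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    for (f in seq_len(n_folds)) {
      splits[[length(splits) + 1L]] <- which(fold_of == f)
    }
  }
  splits
}

## Save/restore the global RNG so seeded helpers do not disturb callers.
local_rng <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  }
}

feature_matrix <- function(ft, features) {
  x <- vapply(features, function(f) as.numeric(ft[[f]]), numeric(nrow(ft)))
  matrix(x, nrow = nrow(ft), dimnames = list(NULL, features))
}

percentile_ci <- function(values, n_boot = 1000L) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) return(c(NA_real_, NA_real_))
  boots <- vapply(seq_len(n_boot), function(b) {
    mean(sample(values, replace = TRUE))
  }, numeric(1))
  unname(quantile(boots, c(0.025, 0.975)))
}

#' Train and evaluate the topology-group classifier
#'
#' Repeated stratified cross-validation of an L1-penalized logistic
#' regression (the embedded feature selection).  Inside each training fold
#' only: masked cells are imputed with the per-feature training median,
#' zero-variance features are dropped, and the penalty is tuned by an inner
#' cross-validation with deterministic fold assignment.  Metrics (AUC,
#' accuracy, per-class precision) are averaged over fold results with
#' percentile-bootstrap 95% confidence intervals; the selected-feature
#' report aggregates nonzero coefficients over folds.  Deterministic given
#' the seed.
#'
#' @param ft Feature table from [assemble_feature_table()] /
#'   [compute_feature_table()].
#' @param features Character vector of feature columns to use; default all
#'   manifest features.
#' @param labels Binary labels; default `ft$group`.
#' @param positive Positive class; default the second factor level.
#' @param n_folds,n_repeats CV design (default 10 x 10).
#' @param seed Integer seed.
#' @param splits Precomputed splits from [make_cv_splits()] (used by the
#'   ablation suite to pair runs); overrides `n_folds`/`n_repeats`.
#' @param label Free-text ablation label carried into the report.
#' @return Object of class `classifier_report`: list with `metrics`
#'   (data.frame of point estimates and CI bounds), `selected` (data.frame
#'   `feature`, `weight`, `frequency`), `fold_auc`, `label`, `positive`,
#'   `n_folds`, `n_repeats`, `seed`.
#' @export
train_evaluate_classifier <- function(ft, features = NULL, labels = ft$group,
                                      positive = NULL,
                                      n_folds = 10L, n_repeats = 10L,
                                      seed = 1L, splits = NULL,
                                      label = "all_features") {
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("train_evaluate_classifier: need 2 classes")
  if (is.null(positive)) positive <- levels(y)[2]
  negative <- setdiff(levels(y), positive)
  if (is.null(features)) {
    manifest <- attr(ft, "manifest")
    features <- if (!is.null(manifest)) manifest$feature
                else setdiff(names(ft), c("accession", "group"))
  }
  x <- feature_matrix(ft, features)
  if (is.null(splits)) {
    splits <- make_cv_splits(y, n_folds, n_repeats, seed)
  } else {
    n_folds <- NA_integer_; n_repeats <- NA_integer_
  }
  rng <- local_rng(seed + 1L)
  on.exit(rng())

  fold_metrics <- vector("list", length(splits))
  coef_sum <- setNames(numeric(length(features)), features)
  coef_hits <- setNames(integer(length(features)), features)
  for (k in seq_along(splits)) {
    test <- splits[[k]]
    train <- setdiff(seq_len(nrow(x)), test)
    xtr <- x[train, , drop = FALSE]; xte <- x[test, , drop = FALSE]
    med <- apply(xtr, 2, median, na.rm = TRUE)
    med[is.na(med)] <- 0
    for (jc in seq_len(ncol(xtr))) {
      xtr[is.na(xtr[, jc]), jc] <- med[jc]
      xte[is.na(xte[, jc]), jc] <- med[jc]
    }
    keep <- apply(xtr, 2, function(v) length(unique(v)) > 1L)
    xtr <- xtr[, keep, drop = FALSE]; xte <- xte[, keep, drop = FALSE]
    ytr <- y[train]; yte <- y[test]
    foldid <- rep_len(1:5, length(train))[order(order(as.integer(ytr)))]
    prob <- if (ncol(xtr) >= 2L) {
      fit <- suppressWarnings(
        glmnet::cv.glmnet(xtr, ytr, family = "binomial", alpha = 1,
                          foldid = foldid, nlambda = 50))
      cf <- as.matrix(stats::coef(fit, s = "lambda.min"))[-1, 1]
      nz <- names(cf)[cf != 0]
      coef_sum[nz] <- coef_sum[nz] + cf[nz]
      coef_hits[nz] <- coef_hits[nz] + 1L
      as.numeric(predict(fit, xte, s = "lambda.min", type = "response"))
    } else {
      fit <- suppressWarnings(
        stats::glm(yv ~ ., family = stats::binomial(),
                   data = data.frame(yv = ytr, xtr)))
      nm <- colnames(xtr)
      coef_sum[nm] <- coef_sum[nm] + stats::coef(fit)[-1]
      coef_hits[nm] <- coef_hits[nm] + 1L
      as.numeric(predict(fit, data.frame(xte), type = "response"))
    }
    ## glmnet models P(second level); flip if positive is the first level
    p_pos <- if (positive == levels(y)[2]) prob else 1 - prob
    auc <- as.numeric(pROC::auc(pROC::roc(
      response = yte, predictor = p_pos, levels = c(negative, positive),
      direction = "<", quiet = TRUE)))
    pred <- factor(ifelse(p_pos >= 0.5, positive, negative), levels = levels(y))
    acc <- mean(pred == yte)
    prec <- vapply(levels(y), function(lv) {
      np <- sum(pred == lv)
      if (np == 0L) NA_real_ else sum(pred == lv & yte == lv) / np
    }, numeric(1))
    fold_metrics[[k]] <- c(auc = auc, accuracy = acc,
                           setNames(prec, paste0("precision_", levels(y))))
  }
  fm <- do.call(rbind, fold_metrics)
  metrics <- do.call(rbind, lapply(colnames(fm), function(m) {
    ci <- percentile_ci(fm[, m])
    data.frame(metric = m, estimate = mean(fm[, m], na.rm = TRUE),
               ci_lower = ci[1], ci_upper = ci[2])
  }))
  selected <- data.frame(feature = features,
                         weight = ifelse(coef_hits > 0, coef_sum /
                                           pmax(coef_hits, 1L), 0),
                         frequency = coef_hits / length(splits))
  selected <- selected[selected$frequency > 0, , drop = FALSE]
  selected <- selected[order(-abs(selected$weight) * selected$frequency), ,
                       drop = FALSE]
  rownames(selected) <- NULL
  structure(list(metrics = metrics, selected = selected,
                 fold_auc = unname(fm[, "auc"]), label = label,
                 positive = positive, n_folds = n_folds,
                 n_repeats = n_repeats, seed = seed),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report '%s'>\n", x$label))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-24s %.3f (%.3f, %.3f)\n", m$metric[i], m$estimate[i],
                m$ci_lower[i], m$ci_upper[i]))
  }
  cat(sprintf("  selected features: %d\n", nrow(x$selected)))
  invisible(x)
}

#' Feature-family ablation suite
#'
#' Three classifier runs on identical CV splits: all features, non-disorder
#' features only, and disorder features only, so that AUC differences are
#' paired.  The disorder family is the manifest's disorder-tagged columns.
#'
#' @inheritParams train_evaluate_classifier
#' @return Named list of three `classifier_report`s: `all_features`,
#'   `non_disorder`, `disorder_only`.
#' @export
ablation_suite <- function(ft, labels = ft$group, n_folds = 10L,
                           n_repeats = 10L, seed = 1L) {
  manifest <- attr(ft, "manifest")
  if (is.null(manifest)) stop("ablation_suite: feature table lacks a manifest")
  dis <- manifest$feature[manifest$disorder]
  non <- manifest$feature[!manifest$disorder]
  if (!length(dis)) stop("ablation_suite: no disorder-tagged features")
  splits <- make_cv_splits(labels, n_folds, n_repeats, seed)
  list(
    all_features = train_evaluate_classifier(
      ft, features = manifest$feature, labels = labels, seed = seed,
      splits = splits, label = "all_features"),
    non_disorder = train_evaluate_classifier(
      ft, features = non, labels = labels, seed = seed,
      splits = splits, label = "non_disorder"),
    disorder_only = train_evaluate_classifier(
      ft, features = dis, labels = labels, seed = seed,
      splits = splits, label = "disorder_only"))
}
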