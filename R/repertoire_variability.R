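## Fold-repertoire census across topology groups and protein abundance
## variability scoring.

#' Fold census across topology groups
#'
#' For each fold: total proteome occurrence count, per-group counts,
#' unique/shared status (unique when all occurrences fall in one group) and
#' rarity (rare: 1-3 occurrences in the whole proteome; frequent: >= 4).
#' For each group: fold-class composition over SCOP classes a, b, c, d
#' (each distinct fold counted once per group), the popular-fold list
#' (folds representing >= `popular_frac` of the group's fold instances) and
#' one-fold / n-fold protein counts.
#'
#' @param fold_table data.frame from [read_fold_table()].
#' @param groups Named character vector accession -> group.
#' @param soluble_only Drop class f (membrane) folds before the census.
#' @param popular_frac Popularity threshold on the fraction of a group's
#'   fold instances (default 0.03).
#' @return List: `folds` (per-fold data.frame with `fold_id`, `scop_class`,
#'   `total`, one count column per group, `status`, `rarity`),
#'   `class_composition` (group x class fraction matrix over a-d),
#'   `popular` (named list of fold_id vectors), `per_group` (data.frame of
#'   one-fold/n-fold counts and mean folds per protein).
#' @export
fold_census <- function(fold_table, groups, soluble_only = FALSE,
                        popular_frac = 0.03) {
  ft <- fold_table
  if (soluble_only) ft <- ft[ft$scop_class != "f", , drop = FALSE]
  grp <- unname(groups[ft$accession])
  if (any(is.na(grp))) {
    drop_acc <- unique(ft$accession[is.na(grp)])
    warning("fold_census: ", length(drop_acc),
            " accession(s) without a group assignment excluded")
    ft <- ft[!is.na(grp), , drop = FALSE]
    grp <- unname(groups[ft$accession])
  }
  if (nrow(ft) == 0L) stop("fold_census: no group-assigned fold rows")
  group_names <- sort(unique(grp))
  fold_ids <- unique(ft$fold_id)
  cls <- vapply(fold_ids, function(f) ft$scop_class[ft$fold_id == f][1], "")
  counts <- vapply(group_names, function(g) {
    vapply(fold_ids, function(f) sum(ft$fold_id == f & grp == g), integer(1))
  }, integer(length(fold_ids)))
  counts <- matrix(counts, nrow = length(fold_ids),
                   dimnames = list(fold_ids, group_names))
  total <- rowSums(counts)
  status <- ifelse(rowSums(counts > 0L) == 1L, "unique", "shared")
  rarity <- ifelse(total <= 3L, "rare", "frequent")
  folds <- data.frame(fold_id = fold_ids, scop_class = unname(cls),
                      total = as.integer(total),
                      counts, status = status, rarity = rarity,
                      check.names = FALSE, row.names = NULL)

  soluble_classes <- c("a", "b", "c", "d")
  class_composition <- t(vapply(group_names, function(g) {
    present <- folds$scop_class[counts[, g] > 0L]
    present <- present[present %in% soluble_classes]
    if (!length(present)) return(setNames(rep(NA_real_, 4), soluble_classes))
    tab <- table(factor(present, levels = soluble_classes))
    as.numeric(tab) / length(present)
  }, numeric(4)))
  colnames(class_composition) <- soluble_classes

  popular <- lapply(group_names, function(g) {
    inst <- counts[, g]
    tot <- sum(inst)
    if (tot == 0L) return(character(0))
    fold_ids[inst / tot >= popular_frac & inst > 0L]
  })
  names(popular) <- group_names

  per_group <- folds_per_protein(ft, groups)

  list(folds = folds, class_composition = class_composition,
       popular = popular, per_group = per_group)
}

#' Domains per protein within topology groups
#'
#' A protein is "n-fold" when it carries two or more domain records
#' (repeated identical domains count individually).  Reports, per group,
#' the one-fold/n-fold split, the mean number of folds over all proteins
#' and over n-fold proteins only.
#'
#' @param fold_table data.frame of domain assignments.
#' @param groups Named character vector accession -> group.
#' @return data.frame with one row per group.
#' @export
folds_per_protein <- function(fold_table, groups) {
  if (nrow(fold_table) == 0L) stop("folds_per_protein: empty fold table")
  grp <- unname(groups[fold_table$accession])
  ft <- fold_table[!is.na(grp), , drop = FALSE]
  grp <- grp[!is.na(grp)]
  group_names <- sort(unique(grp))
  rows <- lapply(group_names, function(g) {
    acc <- ft$accession[grp == g]
    if (!length(acc)) stop("folds_per_protein: empty group '", g, "'")
    n_domains <- table(acc)
    nfold <- sum(n_domains >= 2L)
    data.frame(group = g,
               n_proteins = length(n_domains),
               onefold = sum(n_domains == 1L),
               nfold = nfold,
               nfold_fraction = nfold / length(n_domains),
               mean_folds = mean(n_domains),
               mean_folds_nfold = if (nfold) mean(n_domains[n_domains >= 2L])
                                  else NA_real_)
  })
  do.call(rbind, rows)
}

#' Abundance variability score
#'
#' Per-protein dispersion of abundance across growth conditions.  The
#' default score is the standard deviation of log2 abundance across
#' conditions: scale-free under multiplicative noise, zero for constant
#' rows, and invariant under global rescaling of the matrix.  A
#' coefficient-of-variation mode (`sd/mean` on the linear scale) is
#' provided as an alternative.
#'
#' @param abundance Matrix of positive abundances, proteins x conditions
#'   (>= 2 conditions).
#' @param method `"log_sd"` (default) or `"cv"`.
#' @return Named numeric vector of variability scores (>= 0).
#' @export
variability_score <- function(abundance, method = c("log_sd", "cv")) {
  method <- match.arg(method)
  if (!is.matrix(abundance) || ncol(abundance) < 2L) {
    stop("variability_score: need a matrix with >= 2 conditions")
  }
  if (any(!is.finite(abundance)) || any(abundance <= 0)) {
    stop("variability_score: abundances must be finite and positive")
  }
  vs <- switch(method,
    log_sd = apply(log2(abundance), 1, sd),
    cv = apply(abundance, 1, function(x) sd(x) / mean(x)))
  setNames(vs, rownames(abundance))
}

#' Bin variability scores into abundance-change classes
#'
#' Four classes -- very_low, low, moderate, high -- assigned either by
#' ascending quartiles of the observed scores or by explicit cutoffs.  Ties
#' at a boundary go to the lower class, so a degenerate all-equal input
#' lands entirely in very_low.
#'
#' @param vs Numeric variability scores.
#' @param mode `"quartiles"` (default) or `"explicit"`.
#' @param cutoffs Ascending numeric vector of 3 class boundaries (explicit
#'   mode).
#' @return Factor with levels very_low, low, moderate, high.
#' @export
bin_variability <- function(vs, mode = c("quartiles", "explicit"),
                            cutoffs = NULL) {
  mode <- match.arg(mode)
  if (mode == "quartiles") {
    if (length(vs) < 4L) stop("bin_variability: need >= 4 values for quartiles")
    cutoffs <- unname(quantile(vs, c(0.25, 0.5, 0.75)))
  } else {
    if (is.null(cutoffs) || length(cutoffs) != 3L) {
      stop("bin_variability: explicit mode needs 3 cutoffs")
    }
    if (is.unsorted(cutoffs, strictly = FALSE)) {
      stop("bin_variability: cutoffs must be ascending")
    }
  }
  lv <- c("very_low", "low", "moderate", "high")
  cls <- ifelse(vs <= cutoffs[1], lv[1],
         ifelse(vs <= cutoffs[2], lv[2],
         ifelse(vs <= cutoffs[3], lv[3], lv[4])))
  factor(cls, levels = lv)
}
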