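## Group-comparison statistics: Kruskal-Wallis for numeric features,
## Fisher's exact test for boolean features, with the star scheme
## *** p < 0.001, ** p < 0.01, * p < 0.05, # p >= 0.05 on raw p-values
## (no multiplicity correction by default, with an opt-in flag).

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "#")))
}

#' Compare one feature between topology groups
#'
#' Numeric features are tested with the Kruskal-Wallis rank-sum test
#' (midranks with tie correction); boolean features with Fisher's exact
#' test on the 2 x k contingency table.  Direction is the group with the
#' higher median (numeric) or higher proportion (boolean).
#'
#' @param x Feature values (numeric or logical).
#' @param groups Group label per value (>= 2 groups, >= 2 observations
#'   each).
#' @param feature Feature name carried into the result.
#' @return One-row data.frame: `feature`, `test`, `statistic`, `p`,
#'   `stars`, `direction` (group name), `higher_value` (median or
#'   proportion in that group).
#' @export
compare_groups <- function(x, groups, feature = deparse(substitute(x))) {
  keep <- !is.na(x) & !is.na(groups)
  x <- x[keep]; groups <- as.character(groups[keep])
  tab_n <- table(groups)
  if (length(tab_n) < 2L) stop("compare_groups: need >= 2 groups")
  if (any(tab_n < 2L)) {
    stop("compare_groups: group(s) with < 2 observations: ",
         paste(names(tab_n)[tab_n < 2L], collapse = ","))
  }
  if (is.logical(x)) {
    tab <- table(groups, x)
    ht <- fisher.test(tab)
    props <- tapply(x, groups, mean)
    dir <- names(which.max(props))
    data.frame(feature = feature, test = "fisher_exact",
               statistic = if (!is.null(ht$estimate)) unname(ht$estimate)
                           else NA_real_,
               p = ht$p.value, stars = p_stars(ht$p.value),
               direction = dir, higher_value = unname(props[dir]))
  } else {
    ht <- kruskal.test(x, factor(groups))
    med <- tapply(x, groups, median)
    dir <- names(which.max(med))
    data.frame(feature = feature, test = "kruskal_wallis",
               statistic = unname(ht$statistic),
               p = ht$p.value, stars = p_stars(ht$p.value),
               direction = dir, higher_value = unname(med[dir]))
  }
}

#' Compare every feature of a feature table between two or more groups
#'
#' @param ft Feature table from [assemble_feature_table()].
#' @param groups Which group labels to compare (default: all present).
#' @param adjust Optional p-adjustment method (see [stats::p.adjust()]);
#'   default `"none"`, matching the raw-p star scheme.
#' @return data.frame with one row per testable feature.
#' @export
compare_feature_table <- function(ft, groups = NULL, adjust = "none") {
  lab <- ft$group
  if (is.null(groups)) groups <- unique(na.omit(lab))
  keep <- lab %in% groups
  manifest <- attr(ft, "manifest")
  feats <- setdiff(names(ft), c("accession", "group"))
  rows <- lapply(feats, function(f) {
    x <- ft[[f]][keep]
    g <- lab[keep]
    ok <- !is.na(x)
    if (length(unique(g[ok])) < 2L || any(table(g[ok]) < 2L)) return(NULL)
    if (is.numeric(x) && length(unique(x[ok])) < 2L) return(NULL)
    compare_groups(x, g, feature = f)
  })
  out <- do.call(rbind, rows)
  if (adjust != "none") {
    out$p_adjusted <- stats::p.adjust(out$p, method = adjust)
  }
  if (!is.null(manifest)) {
    out$disorder_family <- out$feature %in% manifest$feature[manifest$disorder]
  }
  rownames(out) <- NULL
  out
}

#' Positional N-terminal profile of a score track
#'
#' For each of the first `n_positions` mature-sequence positions, the mean
#' track score over proteins of each membership group; proteins shorter
#' than a position simply drop out at that position.  Positions start at
#' mature residue 1 (signal peptides already removed), covering the
#' ribosome-exposed N-terminal region.
#'
#' @param tracks Named list of numeric tracks (or [score_track()]s) keyed
#'   by accession.
#' @param membership Named character vector accession -> group (two
#'   groups, e.g. interactor / non-interactor).
#' @param n_positions Number of N-terminal positions (default 90).
#' @return data.frame: `position`, one mean column per group, `difference`
#'   (first group minus second), `n_<group>` counts, `p` (Kruskal-Wallis
#'   per position), `stars`.
#' @export
positional_profile <- function(tracks, membership, n_positions = 90L) {
  vals <- lapply(tracks, function(t) if (inherits(t, "score_track")) t$values else t)
  acc <- names(vals)
  grp <- unname(membership[acc])
  if (any(is.na(grp))) stop("positional_profile: track without membership")
  gl <- unique(grp)
  if (length(gl) != 2L) stop("positional_profile: need exactly 2 groups")
  if (!any(grp == gl[1]) || !any(grp == gl[2])) {
    stop("positional_profile: empty group")
  }
  rows <- lapply(seq_len(n_positions), function(p) {
    have <- vapply(vals, function(v) length(v) >= p, logical(1))
    x <- vapply(vals[have], function(v) v[p], numeric(1))
    g <- grp[have]
    m1 <- mean(x[g == gl[1]]); m2 <- mean(x[g == gl[2]])
    pval <- if (length(unique(g)) == 2L && all(table(g) >= 2L) &&
                length(unique(x)) > 1L) {
      kruskal.test(x, factor(g))$p.value
    } else NA_real_
    out <- data.frame(position = p, m1 = m1, m2 = m2,
                      difference = m1 - m2,
                      n1 = sum(g == gl[1]), n2 = sum(g == gl[2]),
                      p = pval)
    names(out)[2:3] <- paste0("mean_", gl)
    names(out)[5:6] <- paste0("n_", gl)
    out
  })
  out <- do.call(rbind, rows)
  out$stars <- ifelse(is.na(out$p), NA_character_, p_stars(out$p))
  out
}
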