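## Assembly of the per-protein feature table that feeds the group statistics
## and the classifier.

## Feature columns tagged as the "disorder family" for the ablation design.
DISORDER_FEATURES <- c("idrs_per_100", "idr_coverage", "is_idp",
                       "disorder_mean", "n_short_idr", "n_long_idr",
                       "longest_idr", "idr_N", "idr_M", "idr_C")

#' Assemble a per-protein feature table from module outputs
#'
#' Joins named feature blocks (data.frames keyed by `accession`) into one
#' row per protein.  Proteins missing from a block get masked (NA) cells in
#' that block's columns but keep their row.  Duplicate accessions within a
#' block and feature-name collisions across blocks are errors.
#'
#' @param blocks Named list of data.frames, each with an `accession` column
#'   and feature columns.
#' @param groups Named character vector accession -> group label.
#' @param disorder_features Feature names tagged as the disorder family in
#'   the manifest (used by [ablation_suite()]).
#' @return data.frame with `accession`, `group` and feature columns;
#'   attribute `manifest` is a data.frame (`feature`, `type`, `disorder`,
#'   `block`).
#' @export
assemble_feature_table <- function(blocks, groups,
                                   disorder_features = DISORDER_FEATURES) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  all_acc <- unique(unlist(lapply(blocks, function(b) b$accession)))
  out <- data.frame(accession = all_acc, stringsAsFactors = FALSE)
  manifest <- list()
  for (bn in names(blocks)) {
    b <- blocks[[bn]]
    if (!"accession" %in% names(b)) {
      stop("assemble_feature_table: block '", bn, "' lacks an accession column")
    }
    if (anyDuplicated(b$accession)) {
      stop("assemble_feature_table: duplicate accession in block '", bn, "'")
    }
    feats <- setdiff(names(b), "accession")
    clash <- intersect(feats, setdiff(names(out), "accession"))
    if (length(clash)) {
      stop("assemble_feature_table: feature name collision: ",
           paste(clash, collapse = ","))
    }
    idx <- match(out$accession, b$accession)
    for (f in feats) {
      out[[f]] <- b[[f]][idx]
      manifest[[f]] <- data.frame(
        feature = f,
        type = if (is.logical(b[[f]])) "boolean" else "numeric",
        disorder = f %in% disorder_features,
        block = bn)
    }
  }
  out$group <- unname(groups[out$accession])
  out <- out[c("accession", "group", setdiff(names(out), c("accession", "group")))]
  attr(out, "manifest") <- do.call(rbind, c(manifest, list(make.row.names = FALSE)))
  out
}

#' Per-protein features from a study bundle
#'
#' Runs the sequence, track-segmentation, structure and
#' repertoire/variability modules over a bundle (records plus per-kind
#' track lists, structures, fold table, abundance matrix and optional
#' scalar columns) and assembles the joined feature table.  Missing inputs
#' (no structure, no abundance row) yield masked cells.
#'
#' @param bundle List with elements `records` (list of
#'   [protein_record()]s), `tracks` (named list by kind of named track
#'   lists by accession), and optionally `structures` (named list of
#'   [structure_model()]s), `fold_table`, `abundance`, `scalars`
#'   (data.frame keyed by accession).
#' @param groups Named character vector accession -> group.
#' @param config Named list of thresholds overriding the defaults of the
#'   underlying calls: `disorder_threshold`, `idp_threshold`,
#'   `early_folding_threshold`, `aggregation_threshold`, `min_len`,
#'   `contact_cutoff`, `min_sep`, `ca_only`, `vs_method`.
#' @return Feature table (see [assemble_feature_table()]).
#' @export
compute_feature_table <- function(bundle, groups, config = list()) {
  cfg <- utils::modifyList(list(
    disorder_threshold = 0.5, idp_threshold = 0.30,
    early_folding_threshold = 0.163, aggregation_threshold = 5.0,
    min_len = 5L, contact_cutoff = 6.0, min_sep = 1L, ca_only = FALSE,
    vs_method = "log_sd"), config)
  records <- bundle$records
  acc <- vapply(records, `[[`, "", "accession")
  mature <- vapply(records, mature_sequence, "")

  seq_block <- do.call(rbind, lapply(seq_along(records), function(i) {
    s <- mature[i]
    comp <- composition_profile(s)
    hp <- hydrophobic_patches(s, min_len = cfg$min_len)
    data.frame(accession = acc[i],
               as.list(comp[setdiff(names(comp), "length")]),
               length = unname(comp[["length"]]),
               gravy = gravy(s),
               pI = isoelectric_point(s),
               cost = biosynthetic_cost(s),
               patches_per_100 = hp$per_100,
               patch_mean_length = hp$mean_length,
               patch_mean_score = hp$mean_score)
  }))

  track_block <- NULL
  tr <- bundle$tracks
  if (!is.null(tr)) {
    rows <- lapply(seq_along(records), function(i) {
      a <- acc[i]
      out <- data.frame(accession = a)
      if (!is.null(tr$disorder[[a]])) {
        idr <- idr_summary(tr$disorder[[a]],
                           threshold = cfg$disorder_threshold,
                           min_len = cfg$min_len,
                           idp_threshold = cfg$idp_threshold)
        pos <- idr$segments$position_class
        out <- cbind(out, data.frame(
          idrs_per_100 = idr$idrs_per_100, idr_coverage = idr$coverage,
          is_idp = idr$is_idp, disorder_mean = idr$mean_score,
          n_short_idr = idr$n_short, n_long_idr = idr$n_long,
          longest_idr = idr$longest,
          idr_N = "N" %in% pos, idr_M = "M" %in% pos, idr_C = "C" %in% pos))
      }
      if (!is.null(tr$early_folding[[a]])) {
        fo <- foldon_summary(tr$early_folding[[a]],
                             threshold = cfg$early_folding_threshold,
                             min_len = cfg$min_len)
        ef <- tr$early_folding[[a]]
        if (inherits(ef, "score_track")) ef <- ef$values
        out <- cbind(out, data.frame(
          foldons_per_100 = fo$foldons_per_100,
          foldon_mean_length = fo$mean_length,
          foldon_mean_score = fo$mean_score,
          early_folding_mean = mean(ef)))
      }
      if (!is.null(tr$aggregation[[a]])) {
        ap <- apr_gatekeepers(tr$aggregation[[a]], mature[i],
                              threshold = cfg$aggregation_threshold,
                              min_len = cfg$min_len)
        agg <- tr$aggregation[[a]]
        if (inherits(agg, "score_track")) agg <- agg$values
        out <- cbind(out, data.frame(
          aprs_per_100 = ap$aprs_per_100,
          aggregation_mean = mean(agg)))
      }
      if (!is.null(tr$backbone_dynamics[[a]])) {
        bd <- tr$backbone_dynamics[[a]]
        if (inherits(bd, "score_track")) bd <- bd$values
        out <- cbind(out, data.frame(backbone_dynamics_mean = mean(bd)))
      }
      out
    })
    nm <- unique(unlist(lapply(rows, names)))
    rows <- lapply(rows, function(r) {
      for (f in setdiff(nm, names(r))) r[[f]] <- NA
      r[nm]
    })
    track_block <- do.call(rbind, rows)
  }

  struct_block <- NULL
  if (!is.null(bundle$structures) && length(bundle$structures)) {
    rows <- lapply(names(bundle$structures), function(a) {
      m <- bundle$structures[[a]]
      rc <- tryCatch(relative_contact_order(m, cutoff = cfg$contact_cutoff,
                                            min_sep = cfg$min_sep,
                                            ca_only = cfg$ca_only),
                     error = function(e) NULL)
      td <- tryCatch(termini_distance(m), error = function(e) NA_real_)
      data.frame(accession = a,
                 rco = if (is.null(rc)) NA_real_ else rc$rco,
                 co_abs = if (is.null(rc)) NA_real_ else rc$co_abs,
                 n_contacts = if (is.null(rc)) NA_real_ else rc$n_contacts,
                 termini_dist = td)
    })
    struct_block <- do.call(rbind, rows)
  }

  fold_block <- NULL
  if (!is.null(bundle$fold_table) && nrow(bundle$fold_table)) {
    ftab <- bundle$fold_table
    rows <- lapply(unique(ftab$accession), function(a) {
      d <- ftab[ftab$accession == a, , drop = FALSE]
      data.frame(accession = a,
                 n_folds = nrow(d),
                 has_a_fold = "a" %in% d$scop_class,
                 has_b_fold = "b" %in% d$scop_class,
                 has_c_fold = "c" %in% d$scop_class,
                 has_d_fold = "d" %in% d$scop_class)
    })
    fold_block <- do.call(rbind, rows)
  }

  abund_block <- NULL
  if (!is.null(bundle$abundance)) {
    vs <- variability_score(bundle$abundance, method = cfg$vs_method)
    abund_block <- data.frame(accession = rownames(bundle$abundance),
                              abundance_mean = rowMeans(log2(bundle$abundance)),
                              variability = unname(vs))
  }

  blocks <- list(sequence = seq_block)
  if (!is.null(track_block)) blocks$tracks <- track_block
  if (!is.null(struct_block)) blocks$structure <- struct_block
  if (!is.null(fold_block)) blocks$folds <- fold_block
  if (!is.null(abund_block)) blocks$abundance <- abund_block
  if (!is.null(bundle$scalars)) blocks$scalars <- bundle$scalars

  ft <- assemble_feature_table(blocks, groups)
  manifest <- attr(ft, "manifest")
  ft <- ft[match(acc, ft$accession), , drop = FALSE]
  rownames(ft) <- NULL
  attr(ft, "manifest") <- manifest
  ft
}
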