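## Synthetic proteome generator.  Produces two-group proteomes (cytoplasmome
## vs secretome) whose statistical structure embodies the qualitative
## direction ledger of the real-proteome analysis -- composition shifts,
## disorder/early-folding/aggregation segment rates, backbone-dynamics
## baseline shifts, fold-pool sharing structure, contact-order contrasts and
## abundance variability classes -- with every planted effect recorded as
## ground truth for recovery testing.  All generators are deterministic
## under a seed.

#' Default per-group residue composition targets
#'
#' Twenty-residue frequency vectors for the two groups, built from an
#' E. coli-like background tilted in opposite directions: the secretome
#' toward polar/small residues (N, Q, S, T, G, D, A up; aliphatic,
#' aromatic, E/K/R down), the cytoplasmome the other way.  The tilts
#' realize the qualitative direction ledger (polar, small and
#' disorder-promoting fractions higher in the secretome; hydrophobic,
#' charged, aromatic and aliphatic fractions, GRAVY and biosynthetic cost
#' higher in the cytoplasmome).
#'
#' @return Named list with `cytoplasmome` and `secretome` frequency
#'   vectors, each summing to 1.
#' @export
default_composition_targets <- function() {
  base <- c(A = 0.089, R = 0.055, N = 0.040, D = 0.054, C = 0.012,
            Q = 0.044, E = 0.058, G = 0.074, H = 0.022, I = 0.060,
            L = 0.106, K = 0.044, M = 0.028, F = 0.039, P = 0.044,
            S = 0.058, T = 0.054, W = 0.015, Y = 0.029, V = 0.071)
  up_secr <- c(N = 1.40, Q = 1.30, S = 1.40, T = 1.30, G = 1.35,
               D = 1.15, A = 1.10)
  dn_secr <- c(L = 0.72, I = 0.72, V = 0.78, F = 0.72, M = 0.70,
               W = 0.78, Y = 0.82, E = 0.85, K = 0.78, R = 0.78,
               H = 0.90, C = 0.90)
  secr <- base
  secr[names(up_secr)] <- secr[names(up_secr)] * up_secr
  secr[names(dn_secr)] <- secr[names(dn_secr)] * dn_secr
  cyto <- base
  cyto[names(up_secr)] <- cyto[names(up_secr)] / sqrt(up_secr)
  cyto[names(dn_secr)] <- cyto[names(dn_secr)] / sqrt(dn_secr)
  list(cytoplasmome = cyto / sum(cyto), secretome = secr / sum(secr))
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a two-group synthetic proteome
#'
#' Per-protein residue frequencies are drawn from a Dirichlet centred on
#' the group composition target; lengths are log-normal; secretome records
#' carry a signal peptide (hydrophobicity-biased composition) whose length
#' is annotated, cytoplasmic records carry none.  At 500+ proteins per
#' group the realized group-mean set fractions sit within about 0.01 of
#' the targets.
#'
#' @param n_per_group Named counts for `cytoplasmome` and `secretome`.
#' @param composition Per-group frequency targets
#'   ([default_composition_targets()]); each vector must sum to 1.
#' @param length_meanlog,length_sdlog Log-normal mature-length parameters
#'   per group (cytoplasmic proteins longer by default, as observed for
#'   soluble secreted proteins).
#' @param min_length Minimum mature length.
#' @param concentration Dirichlet concentration around the target
#'   (larger = tighter per-protein composition).
#' @param sp_length_range Signal-peptide lengths sampled for secretome
#'   records.
#' @param essential_prob Per-group probability of the essential flag.
#' @param seed Integer seed.
#' @return List: `records` (list of [protein_record()]s) and `truth`
#'   (group labels, composition targets, per-record signal-peptide
#'   lengths).
#' @export
generate_proteome <- function(n_per_group = c(cytoplasmome = 400L,
                                              secretome = 400L),
                              composition = default_composition_targets(),
                              length_meanlog = c(cytoplasmome = log(330),
                                                 secretome = log(270)),
                              length_sdlog = 0.35,
                              min_length = 80L,
                              concentration = 300,
                              sp_length_range = 15:25,
                              essential_prob = c(cytoplasmome = 0.106,
                                                 secretome = 0.022),
                              seed = 1L) {
  for (g in names(composition)) {
    if (abs(sum(composition[[g]]) - 1) > 1e-6) {
      stop("generate_proteome: composition for '", g, "' does not sum to 1")
    }
    if (!setequal(names(composition[[g]]), AMINO_ACIDS)) {
      stop("generate_proteome: composition for '", g,
           "' must cover the 20 canonical residues")
    }
  }
  rng <- local_rng(seed)
  on.exit(rng())
  sp_freq <- c(A = 0.17, L = 0.25, V = 0.10, I = 0.06, F = 0.07, M = 0.06,
               S = 0.08, T = 0.06, G = 0.05, W = 0.02, C = 0.02, K = 0.03,
               R = 0.02, Q = 0.02, P = 0.02, H = 0.01, N = 0.01, E = 0.01,
               D = 0.01, Y = 0.03)
  sp_freq <- sp_freq / sum(sp_freq)
  records <- list()
  group <- character(0)
  prefix <- c(cytoplasmome = "CYT", secretome = "SEC")
  classes <- list(cytoplasmome = c("A", "N", "F1", "r"),
                  secretome = c("G", "H", "I", "X"))
  class_prob <- list(cytoplasmome = c(0.70, 0.12, 0.10, 0.08),
                     secretome = c(0.45, 0.25, 0.20, 0.10))
  for (g in names(n_per_group)) {
    n <- n_per_group[[g]]
    tgt <- composition[[g]][AMINO_ACIDS]
    for (i in seq_len(n)) {
      L <- max(min_length,
               round(stats::rlnorm(1, length_meanlog[[g]], length_sdlog)))
      p <- rdirichlet1(concentration * tgt)
      mat <- paste(sample(AMINO_ACIDS, L, replace = TRUE, prob = p),
                   collapse = "")
      sp_len <- 0L
      seq_full <- mat
      if (g == "secretome") {
        sp_len <- sample(sp_length_range, 1L)
        sp <- paste(sample(names(sp_freq), sp_len, replace = TRUE,
                           prob = sp_freq), collapse = "")
        seq_full <- paste0(sp, mat)
      }
      acc <- sprintf("%s%04d", prefix[[g]], i)
      records[[length(records) + 1L]] <- protein_record(
        acc, seq_full, sp_length = sp_len,
        topology_class = sample(classes[[g]], 1L, prob = class_prob[[g]]),
        essential = stats::runif(1) < essential_prob[[g]])
      group <- c(group, g)
    }
  }
  names(records) <- vapply(records, `[[`, "", "accession")
  truth <- list(group = setNames(group, names(records)),
                composition_targets = composition,
                sp_length = setNames(vapply(records, `[[`, 0L, "sp_length"),
                                     names(records)))
  list(records = records, truth = truth)
}

## Place n non-overlapping segments (gap >= 2 so calls stay separate) of
## lengths drawn from len_range on a chain of length L.
plant_positions <- function(L, n, len_range) {
  seg <- data.frame(start = integer(), end = integer())
  tries <- 0L
  while (nrow(seg) < n && tries < 200L) {
    tries <- tries + 1L
    len <- sample(len_range, 1L)
    if (len + 2L > L) next
    st <- sample.int(L - len + 1L, 1L)
    en <- st + len - 1L
    if (nrow(seg) == 0L ||
        all(st > seg$end + 2L | en < seg$start - 2L)) {
      seg <- rbind(seg, data.frame(start = st, end = en))
    }
  }
  seg[order(seg$start), , drop = FALSE]
}

#' Generate a score track with planted segments
#'
#' Autocorrelated Gaussian noise (moving-average smoothing, default window
#' 5, mimicking the residue-to-residue correlation of per-residue predictor
#' outputs) around a baseline, with plateaus at the planted coordinates
#' raised `snr` noise standard deviations above the calling threshold.
#'
#' @param L Track length (mature-sequence residues).
#' @param baseline Baseline score (must sit below `threshold`).
#' @param noise_sd Noise standard deviation after smoothing.
#' @param threshold Calling threshold the plateaus must clear.
#' @param planted data.frame with `start`, `end` (non-overlapping).
#' @param snr Signal-to-noise ratio of plateau elevation (default 3).
#' @param smooth_window Moving-average window (default 5).
#' @param seed Optional integer seed.
#' @return Numeric track of length `L`.
#' @export
generate_track_with_segments <- function(L, baseline, noise_sd, threshold,
                                         planted = NULL, snr = 3,
                                         smooth_window = 5L, seed = NULL) {
  if (baseline >= threshold) {
    stop("generate_track_with_segments: baseline must be below threshold")
  }
  if (!is.null(seed)) {
    rng <- local_rng(seed)
    on.exit(rng())
  }
  if (!is.null(planted) && nrow(planted) > 1L) {
    s <- planted[order(planted$start), ]
    if (any(s$start[-1] <= s$end[-nrow(s)])) {
      stop("generate_track_with_segments: overlapping planted segments")
    }
  }
  w <- smooth_window
  raw <- stats::rnorm(L + w - 1L, sd = noise_sd * sqrt(w))
  noise <- as.numeric(stats::filter(raw, rep(1 / w, w), sides = 2))
  noise <- noise[!is.na(noise)][seq_len(L)]
  values <- baseline + noise
  if (!is.null(planted)) {
    for (i in seq_len(nrow(planted))) {
      idx <- planted$start[i]:planted$end[i]
      values[idx] <- threshold + snr * noise_sd + noise[idx]
    }
  }
  values
}

#' Generate an ideal-geometry toy structure
#'
#' CA-trace models exercising the contact-order machinery: `helix` (rise
#' 1.5 A, 100 degrees per residue, radius 2.3 A; contacts dominated by
#' small sequence separations, low rCO), `extended` (3.8 A spacing, only
#' adjacent contacts), `hairpin` (two extended strands 5 A apart, giving
#' long-range cross-strand contacts and high rCO).
#'
#' @param kind One of "helix", "extended", "hairpin".
#' @param length Number of residues (>= 3).
#' @param accession Identifier.
#' @return A [structure_model()] with CA atoms only.
#' @export
generate_toy_structure <- function(kind = c("helix", "extended", "hairpin"),
                                   length, accession = paste0("toy_", kind[1])) {
  kind <- match.arg(kind)
  if (length < 3L) stop("generate_toy_structure: length must be >= 3")
  i <- seq_len(length)
  xyz <- switch(kind,
    helix = {
      t <- (i - 1) * 100 * pi / 180
      cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * (i - 1))
    },
    extended = cbind(3.8 * (i - 1), 0, 0),
    hairpin = {
      k <- ceiling(length / 2)
      x <- ifelse(i <= k, 3.8 * (i - 1), 3.8 * (k - 1) - 3.8 * (i - k - 1))
      y <- ifelse(i <= k, 0, 5)
      cbind(x, y, 0)
    })
  structure_model(accession,
                  data.frame(resno = i, elety = "CA", element = "C",
                             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

#' Default planted fold-pool design
#'
#' A pool of shared folds (mixed classes, occurring in both groups), a
#' larger set of folds unique to the cytoplasmome (alpha- and
#' alpha/beta-heavy, many rare) and a small set of folds unique to the
#' secretome (beta-dominated), mirroring the qualitative repertoire
#' structure of the real proteome.
#'
#' @return data.frame with `fold_id`, `scop_class`, `n_cytoplasmome`,
#'   `n_secretome`.
#' @export
default_fold_design <- function() {
  shared <- data.frame(
    fold_id = sprintf("sh%02d", 1:12),
    scop_class = rep(c("a", "b", "c", "d"), 3),
    n_cytoplasmome = c(6L, 4L, 8L, 5L, 3L, 2L, 7L, 4L, 2L, 3L, 5L, 2L),
    n_secretome = c(3L, 5L, 2L, 3L, 2L, 4L, 2L, 2L, 1L, 3L, 1L, 2L))
  uniq_cyto <- data.frame(
    fold_id = sprintf("uc%02d", 1:15),
    scop_class = c("a", "a", "a", "a", "c", "c", "c", "c", "c", "d", "d",
                   "d", "a", "c", "b"),
    n_cytoplasmome = c(5L, 2L, 1L, 3L, 6L, 2L, 1L, 4L, 2L, 3L, 1L, 2L,
                       2L, 3L, 1L),
    n_secretome = 0L)
  uniq_secr <- data.frame(
    fold_id = sprintf("us%02d", 1:5),
    scop_class = c("b", "b", "b", "b", "d"),
    n_cytoplasmome = 0L,
    n_secretome = c(4L, 2L, 1L, 3L, 2L))
  rbind(shared, uniq_cyto, uniq_secr)
}

#' Generate a fold assignment table from a planted design
#'
#' Assigns each fold's per-group occurrence counts to distinct proteins
#' sampled from the group's accession pool, so a census of the generated
#' table recovers the design exactly.
#'
#' @param design data.frame with `fold_id`, `scop_class` and one
#'   `n_<group>` count column per group.
#' @param accessions Named list of accession pools per group.
#' @param seed Integer seed.
#' @return Fold table data.frame (`accession`, `fold_id`, `scop_class`,
#'   `start`, `end`).
#' @export
generate_fold_table <- function(design, accessions, seed = 1L) {
  count_cols <- grep("^n_", names(design), value = TRUE)
  groups <- sub("^n_", "", count_cols)
  if (!all(groups %in% names(accessions))) {
    stop("generate_fold_table: accession pool missing for some group(s)")
  }
  if (any(rowSums(design[count_cols]) == 0L)) {
    stop("generate_fold_table: fold assigned to zero proteins")
  }
  rng <- local_rng(seed)
  on.exit(rng())
  rows <- list()
  for (r in seq_len(nrow(design))) {
    for (gi in seq_along(groups)) {
      n <- design[[count_cols[gi]]][r]
      if (n == 0L) next
      pool <- accessions[[groups[gi]]]
      if (n > length(pool)) {
        stop("generate_fold_table: pool for '", groups[gi], "' too small")
      }
      acc <- sample(pool, n)
      rows[[length(rows) + 1L]] <- data.frame(
        accession = acc, fold_id = design$fold_id[r],
        scop_class = design$scop_class[r], start = 1L, end = 50L)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate an abundance matrix with planted variability classes
#'
#' Per-protein log2 abundance is a protein-level mean plus condition noise
#' whose standard deviation is set by the planted variability class
#' (very_low defaults to exactly zero, i.e. constant rows).
#'
#' @param accessions Protein accessions (rows).
#' @param n_conditions Number of growth conditions (default 13).
#' @param class_mix Named class proportions (very_low/low/moderate/high).
#' @param log_sd Named per-class log2 noise standard deviations.
#' @param mean_log2 Per-protein mean log2 abundance (recycled).
#' @param seed Integer seed.
#' @return List: `abundance` (positive matrix), `classes` (named factor of
#'   planted classes).
#' @export
generate_abundance <- function(accessions, n_conditions = 13L,
                               class_mix = c(very_low = 0.104, low = 0.41,
                                             moderate = 0.40, high = 0.086),
                               log_sd = c(very_low = 0, low = 0.2,
                                          moderate = 0.6, high = 1.5),
                               mean_log2 = 9, seed = 1L) {
  rng <- local_rng(seed)
  on.exit(rng())
  n <- length(accessions)
  lv <- names(class_mix)
  classes <- sample(lv, n, replace = TRUE, prob = class_mix)
  mu <- rep_len(mean_log2, n)
  m <- t(vapply(seq_len(n), function(i) {
    mu[i] + stats::rnorm(n_conditions, sd = log_sd[[classes[i]]])
  }, numeric(n_conditions)))
  dimnames(m) <- list(accessions, sprintf("cond%02d", seq_len(n_conditions)))
  list(abundance = 2^m,
       classes = setNames(factor(classes, levels = lv), accessions))
}

#' Generate a complete synthetic two-group study
#'
#' Orchestrates every generator into one bundle: proteome records, the four
#' predictor tracks (disorder, backbone dynamics, early folding,
#' aggregation) with group-specific planted segment rates and baselines,
#' toy structures (helical traces for cytoplasmic proteins, hairpins for
#' secreted ones, planting the contact-order contrast), a planted fold
#' pool, an abundance matrix with a group-level mean shift, a
#' thermostability proxy scalar, and gatekeeper residues written into the
#' sequence flanks of planted aggregation-prone regions.  The returned
#' truth carries the planted coordinates and the direction-of-effect
#' ledger.
#'
#' @param n_per_group Proteins per group (default 400 each).
#' @param seed Integer seed; the study is deterministic given it.
#' @param config Named list overriding generator parameters: `idr_rate`,
#'   `foldon_rate`, `apr_rate` (per-100-residue segment rates per group),
#'   `backbone_baseline`, `disorder_baseline`, `early_baseline`,
#'   `aggregation_baseline`, `noise_sd` (per kind), `snr`,
#'   `thermostability_mean`, `abundance_mean_log2`, `gatekeeper_bias`,
#'   `structure_max_len`.
#' @return List: `bundle` (input to [compute_feature_table()]), `groups`
#'   (accession -> group), `truth` (planted segments per protein and
#'   kind, fold design, abundance classes, `effects` direction ledger).
#' @export
generate_synthetic_study <- function(n_per_group = 400L, seed = 1L,
                                     config = list()) {
  cfg <- utils::modifyList(list(
    idr_rate = c(cytoplasmome = 0.7, secretome = 1.1),
    foldon_rate = c(cytoplasmome = 1.4, secretome = 0.9),
    apr_rate = c(cytoplasmome = 1.0, secretome = 0.7),
    backbone_baseline = c(cytoplasmome = 0.68, secretome = 0.76),
    disorder_baseline = 0.25, early_baseline = 0.06,
    aggregation_baseline = 0,
    noise_sd = c(disorder = 0.05, backbone_dynamics = 0.03,
                 early_folding = 0.02, aggregation = 1.0),
    thresholds = c(disorder = 0.5, early_folding = 0.163, aggregation = 5.0),
    snr = 3,
    idr_len = 5:30, foldon_len = 5:12, apr_len = 5:8,
    thermostability_mean = c(cytoplasmome = 55, secretome = 62),
    thermostability_sd = 5,
    abundance_mean_log2 = c(cytoplasmome = 9, secretome = 7.5),
    gatekeeper_bias = list(
      cytoplasmome = c(E = 0.30, R = 0.30, K = 0.10, D = 0.10, P = 0.10,
                       G = 0.10),
      secretome = c(D = 0.40, E = 0.12, R = 0.08, K = 0.05, P = 0.175,
                    G = 0.175)),
    structure_max_len = 80L), config)

  rng <- local_rng(seed)
  on.exit(rng())
  prot <- generate_proteome(
    n_per_group = c(cytoplasmome = n_per_group, secretome = n_per_group),
    seed = sample.int(2^30, 1))
  records <- prot$records
  groups <- prot$truth$group
  acc <- names(records)

  tracks <- list(disorder = list(), backbone_dynamics = list(),
                 early_folding = list(), aggregation = list())
  planted <- list(disorder = list(), early_folding = list(),
                  aggregation = list())
  for (a in acc) {
    g <- groups[[a]]
    L <- nchar(mature_sequence(records[[a]]))
    ## disorder
    n_idr <- stats::rpois(1, cfg$idr_rate[[g]] * L / 100)
    seg <- plant_positions(L, n_idr, cfg$idr_len)
    planted$disorder[[a]] <- seg
    tracks$disorder[[a]] <- generate_track_with_segments(
      L, cfg$disorder_baseline, cfg$noise_sd[["disorder"]],
      cfg$thresholds[["disorder"]], seg, cfg$snr)
    ## early folding
    n_fo <- stats::rpois(1, cfg$foldon_rate[[g]] * L / 100)
    seg <- plant_positions(L, n_fo, cfg$foldon_len)
    planted$early_folding[[a]] <- seg
    tracks$early_folding[[a]] <- generate_track_with_segments(
      L, cfg$early_baseline, cfg$noise_sd[["early_folding"]],
      cfg$thresholds[["early_folding"]], seg, cfg$snr)
    ## aggregation + gatekeeper planting in the sequence flanks
    n_apr <- stats::rpois(1, cfg$apr_rate[[g]] * L / 100)
    seg <- plant_positions(L, n_apr, cfg$apr_len)
    planted$aggregation[[a]] <- seg
    tracks$aggregation[[a]] <- generate_track_with_segments(
      L, cfg$aggregation_baseline, cfg$noise_sd[["aggregation"]],
      cfg$thresholds[["aggregation"]], seg, cfg$snr)
    if (nrow(seg)) {
      bias <- cfg$gatekeeper_bias[[g]]
      s <- mature_sequence(records[[a]])
      ch <- seq_chars(s)
      gk <- unique(unlist(lapply(seq_len(nrow(seg)), function(i) {
        left <- seq.int(max(1L, seg$start[i] - 3L), seg$start[i] - 1L)
        right <- seq.int(seg$end[i] + 1L, min(L, seg$end[i] + 3L))
        c(left[left >= 1L & left < seg$start[i]],
          right[right <= L & right > seg$end[i]])
      })))
      gk <- setdiff(gk, unlist(lapply(seq_len(nrow(seg)),
                                      function(i) seg$start[i]:seg$end[i])))
      if (length(gk)) {
        ch[gk] <- sample(names(bias), length(gk), replace = TRUE, prob = bias)
        sp <- records[[a]]$sp_length
        full <- seq_chars(records[[a]]$sequence)
        full[sp + gk] <- ch[gk]
        records[[a]]$sequence <- paste(full, collapse = "")
      }
    }
    ## backbone dynamics: baseline shift only
    tracks$backbone_dynamics[[a]] <- generate_track_with_segments(
      L, cfg$backbone_baseline[[g]], cfg$noise_sd[["backbone_dynamics"]],
      cfg$backbone_baseline[[g]] + 1, NULL)
  }

  structures <- lapply(acc, function(a) {
    L <- min(nchar(mature_sequence(records[[a]])), cfg$structure_max_len)
    kind <- if (groups[[a]] == "cytoplasmome") "helix" else "hairpin"
    generate_toy_structure(kind, L, accession = a)
  })
  names(structures) <- acc

  design <- default_fold_design()
  fold_table <- generate_fold_table(
    design, accessions = split(acc, groups[acc]), seed = sample.int(2^30, 1))

  ab <- generate_abundance(
    acc, mean_log2 = cfg$abundance_mean_log2[groups[acc]],
    seed = sample.int(2^30, 1))

  thermo <- stats::rnorm(length(acc),
                         mean = cfg$thermostability_mean[groups[acc]],
                         sd = cfg$thermostability_sd)
  scalars <- data.frame(accession = acc, thermostability = thermo)

  effects <- data.frame(
    feature = c("polar", "small", "disorder_promoting", "hydrophobic",
                "charged", "aromatic", "aliphatic", "gravy", "cost",
                "length", "idrs_per_100", "idr_coverage", "disorder_mean",
                "backbone_dynamics_mean", "foldons_per_100",
                "early_folding_mean", "aprs_per_100", "aggregation_mean",
                "rco", "thermostability", "abundance_mean"),
    higher = c("secretome", "secretome", "secretome", "cytoplasmome",
               "cytoplasmome", "cytoplasmome", "cytoplasmome",
               "cytoplasmome", "cytoplasmome", "cytoplasmome",
               "secretome", "secretome", "secretome", "secretome",
               "cytoplasmome", "cytoplasmome", "cytoplasmome",
               "cytoplasmome", "secretome", "secretome", "cytoplasmome"))

  bundle <- list(records = records, tracks = tracks, structures = structures,
                 fold_table = fold_table, abundance = ab$abundance,
                 scalars = scalars)
  truth <- list(group = groups, planted = planted, fold_design = design,
                abundance_classes = ab$classes, effects = effects,
                config = cfg)
  list(bundle = bundle, groups = groups, truth = truth)
}
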