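## Segmentation of per-residue predictor tracks into called regions:
## intrinsically disordered regions (IDRs), early foldons and
## aggregation-prone regions (APRs) with gatekeeper analysis.
##
## Default thresholds follow the conventions of the tools whose output the
## tracks emulate: disorder >= 0.5 (IUPred2), early folding >= 0.163
## (EFoldMine), aggregation >= 5.0 on a 0-100 per-residue scale (TANGO).
## All are overridable.

#' Extract above-threshold segments from a score track
#'
#' Maximal runs of positions with score >= `threshold`, kept when at least
#' `min_len` residues long; 1-based inclusive coordinates on the mature
#' sequence, in left-to-right order.
#'
#' @param values Finite numeric track (or a [score_track()]).
#' @param threshold Score threshold (>= semantics).
#' @param min_len Minimum segment length (>= 1).
#' @param kind Optional segment kind label.
#' @return data.frame `start`, `end`, `length`, `mean_score` (and `kind`).
#' @export
extract_segments <- function(values, threshold, min_len = 1L, kind = NA_character_) {
  if (inherits(values, "score_track")) values <- values$values
  if (min_len < 1L) stop("extract_segments: min_len must be >= 1")
  if (any(!is.finite(values))) stop("extract_segments: non-finite scores")
  above <- values >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  seg <- data.frame(start = starts[keep], end = ends[keep])
  seg$length <- seg$end - seg$start + 1L
  seg$mean_score <- vapply(seq_len(nrow(seg)), function(i) {
    mean(values[seg$start[i]:seg$end[i]])
  }, numeric(1))
  seg$kind <- rep(kind, nrow(seg))
  seg
}

#' Merge overlapping or adjacent segments
#'
#' Segments that overlap or directly abut (next start <= previous end + 1)
#' are fused; the result is sorted and the operation is idempotent.
#'
#' @param segments data.frame with `start` and `end` columns.
#' @return data.frame `start`, `end`, `length` of the merged cover.
#' @export
merge_segments <- function(segments) {
  if (nrow(segments) == 0L) {
    return(data.frame(start = integer(), end = integer(), length = integer()))
  }
  red <- IRanges::reduce(IRanges::IRanges(segments$start, segments$end),
                         min.gapwidth = 1L)
  data.frame(start = IRanges::start(red), end = IRanges::end(red),
             length = IRanges::width(red))
}

#' Classify segment position within a protein
#'
#' N-terminal when the segment starts in the first 30 residues, C-terminal
#' when it extends into the last 30, middle otherwise.  For short proteins
#' where both conditions hold, N takes precedence.
#'
#' @param start,end Segment coordinates (vectorized).
#' @param L Mature protein length.
#' @param edge Terminal window size (default 30 residues).
#' @return Character vector over \{"N", "M", "C"\}.
#' @export
classify_segment_position <- function(start, end, L, edge = 30L) {
  if (any(start < 1L | end > L | start > end)) {
    stop("classify_segment_position: segment out of bounds")
  }
  ifelse(start <= edge, "N", ifelse(end >= L - edge + 1L, "C", "M"))
}

#' Summarize intrinsic disorder of a protein
#'
#' IDRs are above-threshold runs of at least 5 residues, split into short
#' (5-19) and long (>= 20) classes; coverage is computed on the merged IDR
#' cover; a protein is called an IDP when coverage reaches
#' `idp_threshold` (default 30%).
#'
#' @param values Disorder track (numeric or [score_track()]), one value per
#'   mature residue.
#' @param threshold Disorder call threshold (default 0.5).
#' @param min_len Minimum IDR length (default 5).
#' @param idp_threshold Coverage needed for an IDP call (default 0.30).
#' @param edge Terminal window for positional classes.
#' @return List: `segments` (with `length_class` and `position_class`),
#'   `idrs_per_100`, `n_short`, `n_long`, `longest`, `coverage`, `is_idp`,
#'   `mean_score`.
#' @export
idr_summary <- function(values, threshold = 0.5, min_len = 5L,
                        idp_threshold = 0.30, edge = 30L) {
  if (inherits(values, "score_track")) values <- values$values
  L <- length(values)
  seg <- extract_segments(values, threshold, min_len, kind = "IDR")
  seg$length_class <- ifelse(seg$length >= 20L, "long", "short")
  seg$position_class <- if (nrow(seg)) {
    classify_segment_position(seg$start, seg$end, L, edge)
  } else character(0)
  merged <- merge_segments(seg)
  coverage <- sum(merged$length) / L
  list(segments = seg,
       idrs_per_100 = nrow(seg) / L * 100,
       n_short = sum(seg$length_class == "short"),
       n_long = sum(seg$length_class == "long"),
       longest = if (nrow(seg)) max(seg$length) else 0L,
       coverage = coverage,
       is_idp = coverage >= idp_threshold,
       mean_score = mean(values))
}

#' Summarize early foldons of a protein
#'
#' Early foldons are above-threshold runs of at least `min_len` residues in
#' the early-folding propensity track, interpreted as folding-nucleation
#' elements.
#'
#' @param values Early-folding track (numeric or [score_track()]).
#' @param threshold Call threshold (default 0.163, the published
#'   EFoldMine operating point).
#' @param min_len Minimum foldon length (default 5).
#' @return List: `segments`, `foldons_per_100`, `mean_length`, `mean_score`
#'   (mean over per-segment means; NA when no foldon).
#' @export
foldon_summary <- function(values, threshold = 0.163, min_len = 5L) {
  if (inherits(values, "score_track")) values <- values$values
  L <- length(values)
  seg <- extract_segments(values, threshold, min_len, kind = "foldon")
  list(segments = seg,
       foldons_per_100 = nrow(seg) / L * 100,
       mean_length = if (nrow(seg)) mean(seg$length) else NA_real_,
       mean_score = if (nrow(seg)) mean(seg$mean_score) else NA_real_)
}

#' Aggregation-prone regions and their gatekeepers
#'
#' APRs are above-threshold runs of the per-residue aggregation propensity
#' track.  Gatekeepers are the up-to-`flank` residues on each side of each
#' APR (truncated at the termini), deduplicated across APRs and excluded
#' when they fall inside another APR; their residue composition is the
#' frequency of each residue among gatekeeper positions.
#'
#' @param values Aggregation track (numeric or [score_track()]); same length
#'   as `sequence`.
#' @param sequence Mature amino-acid sequence.
#' @param threshold Call threshold (default 5.0 on a 0-100 scale).
#' @param min_len Minimum APR length (default 5).
#' @param flank Gatekeeper flank width per side (default 3).
#' @return List: `segments`, `aprs_per_100`, `gatekeeper_positions` (sorted
#'   integer vector), `composition` (named frequencies summing to 1 over
#'   observed gatekeepers).
#' @export
apr_gatekeepers <- function(values, sequence, threshold = 5.0, min_len = 5L,
                            flank = 3L) {
  if (inherits(values, "score_track")) values <- values$values
  if (flank < 0L) stop("apr_gatekeepers: flank must be >= 0")
  L <- length(values)
  if (nchar(sequence) != L) {
    stop("apr_gatekeepers: track and sequence lengths differ")
  }
  seg <- extract_segments(values, threshold, min_len, kind = "APR")
  apr_pos <- if (nrow(seg)) {
    unlist(lapply(seq_len(nrow(seg)), function(i) seg$start[i]:seg$end[i]))
  } else integer(0)
  gk <- integer(0)
  if (flank > 0L) {
    for (i in seq_len(nrow(seg))) {
      left <- seq.int(max(1L, seg$start[i] - flank), seg$start[i] - 1L)
      left <- left[left >= 1L & left < seg$start[i]]
      right <- seq.int(seg$end[i] + 1L, min(L, seg$end[i] + flank))
      right <- right[right <= L & right > seg$end[i]]
      gk <- c(gk, left, right)
    }
  }
  gk <- sort(setdiff(unique(gk), apr_pos))
  ch <- seq_chars(sequence)
  comp <- if (length(gk)) {
    tab <- table(factor(ch[gk], levels = c(AMINO_ACIDS, "X")))
    prop <- as.numeric(tab) / length(gk)
    setNames(prop, names(tab))
  } else setNames(numeric(0), character(0))
  list(segments = seg,
       aprs_per_100 = nrow(seg) / L * 100,
       gatekeeper_positions = gk,
       composition = comp)
}
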