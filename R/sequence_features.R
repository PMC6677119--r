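## Primary-sequence features of mature proteins: residue-set composition,
## GRAVY hydropathy, isoelectric point, biosynthetic cost, continuous
## hydrophobic patches and their flanking peptides.  'X' residues are
## excluded from every numerator and denominator.

#' Residue-set composition profile
#'
#' Fraction of (non-X) residues belonging to each named residue set; sets
#' overlap, so fractions need not sum to 1.
#'
#' @param sequence Mature amino-acid sequence.
#' @param sets Named list of residue sets; default [residue_sets()].
#' @return Named numeric vector of fractions plus `length` (count of non-X
#'   residues).
#' @export
composition_profile <- function(sequence, sets = residue_sets()) {
  ch <- non_x_chars(sequence)
  if (length(ch) == 0L) {
    stop("composition_profile: empty or all-X sequence")
  }
  fr <- vapply(sets, function(s) mean(ch %in% s), numeric(1))
  c(fr, length = length(ch))
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of the Kyte-Doolittle hydropathy constants over the non-X
#' residues.
#'
#' @param sequence Mature amino-acid sequence.
#' @param scale Hydropathy scale; default [kyte_doolittle()].
#' @return GRAVY in \[-4.5, 4.5\].
#' @export
gravy <- function(sequence, scale = kyte_doolittle()) {
  ch <- non_x_chars(sequence)
  if (length(ch) == 0L) stop("gravy: empty or all-X sequence")
  mean(scale[ch])
}

## Henderson-Hasselbalch net charge at a given pH
net_charge <- function(counts, pH, pka) {
  pos_groups <- c(Nterm = 1, counts[c("K", "R", "H")])
  pos_pka <- pka[c("Nterm", "K", "R", "H")]
  neg_groups <- c(Cterm = 1, counts[c("D", "E", "C", "Y")])
  neg_pka <- pka[c("Cterm", "D", "E", "C", "Y")]
  sum(pos_groups / (1 + 10^(pH - pos_pka))) -
    sum(neg_groups / (1 + 10^(neg_pka - pH)))
}

#' Isoelectric point by bisection
#'
#' pH at which the Henderson-Hasselbalch net charge (N-terminus, C-terminus
#' and the D/E/C/Y/K/R/H side chains, EMBOSS pKa constants) crosses zero,
#' found by bisection on \[0, 14\] to |charge| < 1e-4.
#'
#' @param sequence Amino-acid sequence (nonempty).
#' @param pka pKa constants; default [emboss_pka()].
#' @return Isoelectric point (pH units).
#' @export
isoelectric_point <- function(sequence, pka = emboss_pka()) {
  ch <- non_x_chars(sequence)
  if (length(ch) == 0L) stop("isoelectric_point: empty or all-X sequence")
  counts <- vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                   function(a) sum(ch == a), numeric(1))
  lo <- 0; hi <- 14
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    q <- net_charge(counts, mid, pka)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Mean biosynthetic cost per residue
#'
#' Arithmetic mean of per-residue biosynthetic costs (ATP equivalents,
#' [biosynthetic_cost_table()]) over non-X residues.
#'
#' @param sequence Mature amino-acid sequence.
#' @param table Named cost vector.
#' @return Mean cost (ATP equivalents per residue).
#' @export
biosynthetic_cost <- function(sequence, table = biosynthetic_cost_table()) {
  ch <- non_x_chars(sequence)
  if (length(ch) == 0L) stop("biosynthetic_cost: empty or all-X sequence")
  miss <- setdiff(unique(ch), names(table))
  if (length(miss)) {
    stop("biosynthetic_cost: residue(s) missing from cost table: ",
         paste(miss, collapse = ","))
  }
  mean(table[ch])
}

#' Continuous hydrophobic patches
#'
#' Maximal runs of residues from the patch set (Kyte-Doolittle-positive core
#' A, C, F, I, L, M, V plus W; stricter than the composition "hydrophobic"
#' set) of at least `min_len` residues, reported left to right with summary
#' statistics.
#'
#' @param sequence Mature amino-acid sequence.
#' @param min_len Minimum patch length (default 5).
#' @param patch_set Residues allowed in a patch.
#' @param scale Hydropathy scale for per-patch mean scores.
#' @return List with `segments` (data.frame `start`, `end`, `length`,
#'   `mean_score`), `per_100` (patches per 100 residues), `mean_length` and
#'   `mean_score` (NA when no patch).
#' @export
hydrophobic_patches <- function(sequence, min_len = 5L,
                                patch_set = PATCH_SET,
                                scale = kyte_doolittle()) {
  if (min_len < 1L) stop("hydrophobic_patches: min_len must be >= 1")
  ch <- seq_chars(sequence)
  L <- length(ch)
  in_set <- ch %in% patch_set
  r <- rle(in_set)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  seg <- data.frame(start = starts[keep], end = ends[keep])
  seg$length <- seg$end - seg$start + 1L
  seg$mean_score <- vapply(seq_len(nrow(seg)), function(i) {
    mean(scale[ch[seg$start[i]:seg$end[i]]])
  }, numeric(1))
  list(segments = seg,
       per_100 = nrow(seg) / L * 100,
       mean_length = if (nrow(seg)) mean(seg$length) else NA_real_,
       mean_score = if (nrow(seg)) mean(seg$mean_score) else NA_real_)
}

#' Peptides flanking a segment
#'
#' Up to `width` residues immediately before the segment start and after the
#' segment end, truncated at the sequence termini (possibly empty).
#'
#' @param start,end 1-based inclusive segment coordinates.
#' @param sequence Mature amino-acid sequence.
#' @param width Flank width in residues (default 5, the quintapeptide
#'   convention).
#' @return List with `left` and `right` character scalars.
#' @export
flanking_peptides <- function(start, end, sequence, width = 5L) {
  L <- nchar(sequence)
  if (start < 1L || end > L || start > end) {
    stop("flanking_peptides: segment out of bounds")
  }
  left <- if (start > 1L) substr(sequence, max(1L, start - width), start - 1L) else ""
  right <- if (end < L) substr(sequence, end + 1L, min(L, end + width)) else ""
  list(left = left, right = right)
}
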