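## Structure-derived scalar features: residue contact maps, relative contact
## order (rCO), N-C termini distance and secondary-structure content.
##
## Contact definition (config-overridable): any heavy-atom pair of two
## residues closer than 6.0 Angstrom with sequence separation >= 1 -- the
## original contact-order convention.  A CA-only mode is provided for
## coordinate sets reduced to the backbone trace.

#' Residue contact pairs of a structure
#'
#' A pair (i, j), i < j, is a contact when any heavy-atom pair between
#' residues i and j is within `cutoff` and j - i >= `min_sep`.  Each pair is
#' counted once.  Unresolved residues contribute no contacts.
#'
#' @param model A [structure_model()].
#' @param cutoff Distance cutoff in Angstrom (default 6.0).
#' @param min_sep Minimum sequence separation (default 1).
#' @param ca_only Use only CA atoms.
#' @return data.frame with columns `i`, `j` (residue sequence numbers).
#' @export
contact_pairs <- function(model, cutoff = 6.0, min_sep = 1L, ca_only = FALSE) {
  stopifnot(inherits(model, "structure_model"))
  if (cutoff <= 0) stop("contact_pairs: cutoff must be positive")
  at <- model$atoms
  if (ca_only) at <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(at) < 2L) return(data.frame(i = integer(), j = integer()))
  d <- as.matrix(dist(at[, c("x", "y", "z")]))
  hit <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  ri <- at$resno[hit[, 1]]
  rj <- at$resno[hit[, 2]]
  i <- pmin(ri, rj); j <- pmax(ri, rj)
  keep <- (j - i) >= min_sep
  pairs <- unique(data.frame(i = i[keep], j = j[keep]))
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Relative contact order
#'
#' Absolute contact order is the mean sequence separation of residue pairs
#' in spatial contact, `co_abs = (1/N) * sum(j - i)`; the relative contact
#' order normalizes by the modeled chain length, `rco = co_abs / L`, where L
#' spans the first to last resolved residue inclusive (interior gaps count
#' toward L but contribute no contacts).  Low rCO correlates with fast
#' folding.
#'
#' @inheritParams contact_pairs
#' @return List: `rco`, `co_abs`, `n_contacts`, `modeled_length`.
#' @export
relative_contact_order <- function(model, cutoff = 6.0, min_sep = 1L,
                                   ca_only = FALSE) {
  pairs <- contact_pairs(model, cutoff, min_sep, ca_only)
  if (nrow(pairs) == 0L) {
    stop("relative_contact_order: no contacts; rCO undefined (",
         model$accession, ")")
  }
  co_abs <- mean(pairs$j - pairs$i)
  list(rco = co_abs / model$L, co_abs = co_abs,
       n_contacts = nrow(pairs), modeled_length = model$L)
}

#' Distance between protein termini
#'
#' Euclidean distance between the CA atoms of the first and last resolved
#' residues.
#'
#' @param model A [structure_model()].
#' @return Distance in Angstrom.
#' @export
termini_distance <- function(model) {
  ca <- model$atoms[model$atoms$elety == "CA", , drop = FALSE]
  a <- ca[ca$resno == model$first, , drop = FALSE]
  b <- ca[ca$resno == model$last, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("termini_distance: missing CA at a terminus (", model$accession, ")")
  }
  sqrt(sum((c(a$x[1], a$y[1], a$z[1]) - c(b$x[1], b$y[1], b$z[1]))^2))
}

#' Secondary-structure content from annotated segments
#'
#' Fraction of residues covered by helix and by strand segments (merged per
#' label, so duplicated annotations do not inflate the content).  A position
#' labeled both helix and strand is a conflict and raises an error.
#'
#' @param ss_segments data.frame with `start`, `end`, `label` in
#'   \{"helix", "strand"\}.
#' @param L Chain length.
#' @return Named vector: `helix_fraction`, `strand_fraction`.
#' @export
ss_content <- function(ss_segments, L) {
  if (nrow(ss_segments) == 0L) {
    return(c(helix_fraction = 0, strand_fraction = 0))
  }
  stopifnot(all(c("start", "end", "label") %in% names(ss_segments)))
  if (any(ss_segments$start < 1L | ss_segments$end > L)) {
    stop("ss_content: segment out of bounds")
  }
  cover <- function(lab) {
    d <- ss_segments[ss_segments$label == lab, , drop = FALSE]
    if (nrow(d) == 0L) return(integer(0))
    m <- merge_segments(d)
    unlist(lapply(seq_len(nrow(m)), function(i) m$start[i]:m$end[i]))
  }
  h <- cover("helix"); s <- cover("strand")
  if (length(intersect(h, s))) {
    stop("ss_content: conflicting helix/strand labels at position(s) ",
         paste(head(intersect(h, s), 3), collapse = ","))
  }
  c(helix_fraction = length(h) / L, strand_fraction = length(s) / L)
}
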