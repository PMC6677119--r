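#' Construct a protein record
#'
#' The central per-protein container: accession, amino-acid sequence (20
#' canonical residues plus 'X' for unknown), signal-peptide length, STEPdb
#' topology class letter, essentiality flag and free-form experimental tags.
#' All downstream feature coordinates are 1-based inclusive and refer to the
#' mature sequence (signal peptide removed, see [trim_to_mature()]).
#'
#' @param accession Character scalar identifier.
#' @param sequence Uppercase amino-acid sequence (nonempty).
#' @param sp_length Signal peptide length in residues; 0 means none; must be
#'   strictly less than the sequence length.
#' @param topology_class One of the STEPdb class letters
#'   A, B, C, E, F1, F2, F3, G, H, I, N, X, r; `NA` if not yet annotated.
#' @param essential Logical essentiality flag.
#' @param experimental_flags Character vector of tags (e.g.
#'   "IDP-experimental").
#' @return Object of class `protein_record`.
#' @export
protein_record <- function(accession, sequence, sp_length = 0L,
                           topology_class = NA_character_,
                           essential = FALSE,
                           experimental_flags = character()) {
  stopifnot(is.character(accession), length(accession) == 1L, nzchar(accession),
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) {
    stop("protein_record: empty sequence for '", accession, "'")
  }
  bad <- setdiff(unique(seq_chars(sequence)), c(AMINO_ACIDS, "X"))
  if (length(bad)) {
    stop("protein_record: invalid residue(s) ", paste(bad, collapse = ","),
         " in '", accession, "'")
  }
  sp_length <- as.integer(sp_length)
  if (is.na(sp_length) || sp_length < 0L || sp_length >= nchar(sequence)) {
    stop("protein_record: sp_length must be in [0, L) for '", accession, "'")
  }
  if (!is.na(topology_class) && !topology_class %in% TOPOLOGY_CLASSES) {
    stop("protein_record: unknown topology class '", topology_class,
         "' for '", accession, "'")
  }
  structure(
    list(accession = accession, sequence = sequence, sp_length = sp_length,
         topology_class = topology_class, essential = isTRUE(essential),
         experimental_flags = experimental_flags),
    class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record %s: L=%d, sp=%d, class=%s%s>\n",
              x$accession, nchar(x$sequence), x$sp_length,
              ifelse(is.na(x$topology_class), "?", x$topology_class),
              if (x$essential) ", essential" else ""))
  invisible(x)
}

#' Map topology class letters to analysis groups
#'
#' STEPdb single-letter classes are grouped into the analysis sets used
#' throughout: cytoplasmome (freely diffusing, nucleoid-, ribosome- and
#' peripherally IM-associated soluble proteins), membranome (inner-membrane
#' embedded), secretome (translocated across the inner membrane: periplasmic,
#' lipoproteins, outer-membrane proteins, surface/extracellular, imported
#' colicins), plus derived sets: OMP, secretome excluding OMPs, exportome
#' (membranome plus secretome) and the peripheral inner-membrane class.
#'
#' @param overrides Optional named list replacing the letter set of any
#'   group (derived groups are recomputed).
#' @return Named list mapping group name to a character vector of class
#'   letters.
#' @export
topology_group_map <- function(overrides = NULL) {
  base <- list(
    cytoplasmome = c("A", "N", "F1", "r"),
    membranome   = c("B"),
    secretome    = c("C", "E", "F2", "F3", "G", "H", "I", "X"),
    OMP          = c("H"),
    peripheral_IM = c("F1")
  )
  if (!is.null(overrides)) {
    for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  }
  base$secretome_no_OMP <- setdiff(base$secretome, base$OMP)
  base$exportome <- union(base$membranome, base$secretome)
  if (!all(base$OMP %in% base$secretome)) {
    stop("topology_group_map: OMP classes must be a subset of the secretome")
  }
  covered <- unique(unlist(base))
  missing <- setdiff(TOPOLOGY_CLASSES, covered)
  if (length(missing)) {
    stop("topology_group_map: class letter(s) not mapped to any group: ",
         paste(missing, collapse = ","))
  }
  base
}

#' Assign each record to one primary analysis group
#'
#' @param records List of [protein_record()] objects with topology classes.
#' @param map Output of [topology_group_map()].
#' @param groups Which (disjoint) groups to assign; first match wins.
#' @return Named character vector accession -> group (`NA` when the class
#'   belongs to none of the requested groups).
#' @export
assign_groups <- function(records, map = topology_group_map(),
                          groups = c("cytoplasmome", "membranome", "secretome")) {
  cls <- vapply(records, function(r) r$topology_class, character(1))
  acc <- vapply(records, function(r) r$accession, character(1))
  out <- rep(NA_character_, length(records))
  for (g in groups) {
    hit <- is.na(out) & !is.na(cls) & cls %in% map[[g]]
    out[hit] <- g
  }
  setNames(out, acc)
}

#' Remove the signal peptide from a record
#'
#' Returns the mature-domain record: residues `sp_length + 1 ... L` of the
#' input, with `sp_length` reset to 0.  All feature coordinates downstream
#' refer to this mature sequence.
#'
#' @param record A [protein_record()].
#' @return A `protein_record` carrying the mature sequence.
#' @export
trim_to_mature <- function(record) {
  stopifnot(inherits(record, "protein_record"))
  L <- nchar(record$sequence)
  if (record$sp_length >= L) {
    stop("trim_to_mature: sp_length >= sequence length for '",
         record$accession, "'")
  }
  if (record$sp_length == 0L) return(record)
  record$sequence <- substr(record$sequence, record$sp_length + 1L, L)
  record$sp_length <- 0L
  record
}

#' Mature sequence of a record
#' @param record A [protein_record()].
#' @return Character scalar: the sequence with any signal peptide removed.
#' @export
mature_sequence <- function(record) {
  substr(record$sequence, record$sp_length + 1L, nchar(record$sequence))
}
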