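## Shared residue-level constant tables.  All sequence arithmetic in the
## package excludes 'X' (unknown residue) from numerators and denominators;
## tracks still cover X positions.

AMINO_ACIDS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Residue-set definitions used for composition profiles
#'
#' The polar, hydrophobic and small sets follow the published composition
#' conventions for this analysis (note that these are composition sets, not
#' physical classifications: the "hydrophobic" set deliberately includes
#' G, T, H and K).  The charged, aromatic, aliphatic and disorder-promoting
#' sets are standard field definitions (TOP-IDP-style for disorder
#' promotion).  Override any set by passing a modified copy of this list to
#' [composition_profile()].
#'
#' @return Named list of character vectors of one-letter residue codes.
#' @export
residue_sets <- function() {
  list(
    polar              = c("D", "E", "K", "H", "R", "Q", "N", "S", "C", "T", "Y", "W"),
    hydrophobic        = c("I", "L", "V", "F", "Y", "W", "H", "T", "C", "G", "A", "M", "K"),
    small              = c("G", "S", "A", "C"),
    charged            = c("D", "E", "H", "K", "R"),
    aromatic           = c("F", "W", "Y"),
    aliphatic          = c("A", "I", "L", "V"),
    disorder_promoting = c("A", "R", "G", "Q", "S", "P", "E", "K")
  )
}

## Residues allowed to form a continuous hydrophobic patch.  Stricter than
## the composition "hydrophobic" set: the Kyte-Doolittle-positive core plus
## tryptophan.  Config-overridable in hydrophobic_patches().
PATCH_SET <- c("A", "C", "F", "I", "L", "M", "V", "W")

#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector, one value per canonical residue.
#' @export
kyte_doolittle <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
}

#' EMBOSS pKa constants for isoelectric-point calculation
#'
#' Terminal and side-chain dissociation constants of the EMBOSS set, used by
#' [isoelectric_point()] in the Henderson-Hasselbalch net-charge sum.
#'
#' @return Named numeric vector with entries `Nterm`, `Cterm` and the
#'   ionizable side chains C, D, E, H, K, R, Y.
#' @export
emboss_pka <- function() {
  c(Nterm = 8.6, Cterm = 3.6,
    C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
}

#' Biosynthetic cost of amino acids (ATP equivalents)
#'
#' Akashi-Gojobori per-residue biosynthetic opportunity costs in
#' high-energy phosphate bond (~ATP) equivalents, used by
#' [biosynthetic_cost()].
#'
#' @return Named numeric vector, one cost per canonical residue.
#' @export
biosynthetic_cost_table <- function() {
  c(A = 11.7, R = 27.3, N = 14.7, D = 12.7, C = 24.7,
    Q = 16.3, E = 15.3, G = 11.7, H = 38.3, I = 32.3,
    L = 27.3, K = 30.3, M = 34.3, F = 52.0, P = 20.3,
    S = 11.7, T = 18.7, W = 74.3, Y = 50.0, V = 23.3)
}

## STEPdb-style single-letter subcellular topology classes.
TOPOLOGY_CLASSES <- c("A", "B", "C", "E", "F1", "F2", "F3",
                      "G", "H", "I", "N", "X", "r")

## split a sequence string into residue vector
seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

## drop X before computing composition statistics
non_x_chars <- function(sequence) {
  ch <- seq_chars(sequence)
  ch[ch != "X"]
}
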