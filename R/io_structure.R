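#' Construct a structure model from heavy-atom coordinates
#'
#' @param accession Identifier.
#' @param atoms data.frame with columns `resno` (residue sequence index),
#'   `elety` (atom name, e.g. "CA"), `element` (element symbol), `x`, `y`,
#'   `z` (Angstrom).  Hydrogens are dropped.
#' @return Object of class `structure_model` with the modeled residue range
#'   (`first`..`last`), per-residue resolved flags and `L` = modeled span
#'   length including unresolved interior gaps.
#' @export
structure_model <- function(accession, atoms) {
  stopifnot(is.data.frame(atoms),
            all(c("resno", "elety", "element", "x", "y", "z") %in% names(atoms)))
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("structure_model: no heavy atoms (", accession, ")")
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("structure_model: non-finite coordinates (", accession, ")")
  }
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  first <- min(atoms$resno); last <- max(atoms$resno)
  resolved <- sort(unique(atoms$resno))
  structure(
    list(accession = accession, atoms = atoms,
         first = first, last = last,
         resolved = resolved, L = as.integer(last - first + 1L)),
    class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model %s: span %d-%d (L=%d), %d resolved, %d atoms>\n",
              x$accession, x$first, x$last, x$L, length(x$resolved),
              nrow(x$atoms)))
  invisible(x)
}

#' Read a structure model from PDB ATOM records
#'
#' Reads one chain of one model: the first model is used (with a warning if
#' more are present), hydrogens are dropped, only the first alternate
#' location ('A' or blank) is kept, and residue numbers missing from the
#' modeled range are marked unresolved.
#'
#' @param path PDB file.
#' @param chain Chain identifier; default: first chain in the file.
#' @param accession Identifier; defaults to the file base name.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, chain = NULL, accession = NULL) {
  if (is.null(accession)) accession <- sub("\\.pdb$", "", basename(path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("read_structure: no ATOM records in ", path)
  n_models <- length(grep("^MODEL", readLines(path, warn = FALSE)))
  if (n_models > 1L) {
    warning("read_structure: ", n_models, " models in ", path,
            "; using the first")
  }
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("read_structure: chain '", chain, "' not found")
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  atoms <- data.frame(resno = at$resno, elety = at$elety,
                      element = ifelse(is.na(at$elesy) | at$elesy == "",
                                       substr(gsub("[0-9]", "", at$elety), 1, 1),
                                       at$elesy),
                      x = at$x, y = at$y, z = at$z)
  structure_model(accession, atoms)
}

#' Write a structure model as PDB ATOM records
#' @param model A [structure_model()].
#' @param path Output file.
#' @param chain Chain identifier to write.
#' @export
write_structure <- function(model, path, chain = "A") {
  a <- model$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)),
    ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety),
    "ALA", chain, a$resno, a$x, a$y, a$z, 1, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
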