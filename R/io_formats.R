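## Readers and writers for the external plain-text formats: FASTA sequences,
## TSV annotation / track / fold / abundance tables, PDB ATOM records.
## Every reader has a writer whose round trip is the identity on valid input.

#' Read protein sequences from a FASTA file
#'
#' Sequence-only records: topology annotations are joined later with
#' [join_topology()].  Sequences are uppercased; entry order is preserved.
#'
#' @param path FASTA file.
#' @return List of [protein_record()]s (sp_length 0, class `NA`).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) return(list())
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) return(list())
  nm <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(nm))) stop("read_fasta: entry with empty header in ", path)
  w <- Biostrings::width(set)
  if (any(w == 0L)) {
    stop("read_fasta: empty sequence for entry '", nm[which(w == 0L)[1]], "'")
  }
  seqs <- toupper(as.character(set))
  mapply(function(a, s) protein_record(a, s), nm, seqs,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write protein records to FASTA
#' @param records List of [protein_record()]s.
#' @param path Output file.
#' @export
write_fasta <- function(records, path) {
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, `[[`, "", "accession")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a topology annotation table
#'
#' Tab-separated with header columns `accession`, `topology_class`,
#' `sp_length`, `essential`.  Class letters are validated against the STEPdb
#' set; duplicate accessions are an error.
#'
#' @param path TSV file.
#' @return data.frame with one row per accession.
#' @export
read_topology_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "topology_class", "sp_length", "essential")
  if (!all(need %in% names(df))) {
    stop("read_topology_table: missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ","))
  }
  if (anyDuplicated(df$accession)) {
    stop("read_topology_table: duplicate accession(s): ",
         paste(unique(df$accession[duplicated(df$accession)]), collapse = ","))
  }
  bad <- setdiff(unique(df$topology_class), TOPOLOGY_CLASSES)
  if (length(bad)) {
    stop("read_topology_table: unknown topology class(es): ",
         paste(bad, collapse = ","))
  }
  df$sp_length <- as.integer(df$sp_length)
  df$essential <- as.logical(as.integer(df$essential))
  df[need]
}

#' Write a topology annotation table
#' @param df data.frame as returned by [read_topology_table()].
#' @param path Output TSV.
#' @export
write_topology_table <- function(df, path) {
  out <- df
  out$essential <- as.integer(out$essential)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Join topology annotations onto sequence records
#'
#' @param records List of [protein_record()]s (typically from [read_fasta()]).
#' @param topology data.frame from [read_topology_table()].
#' @return List of annotated records; accessions absent from the table keep
#'   their defaults.
#' @export
join_topology <- function(records, topology) {
  idx <- match(vapply(records, `[[`, "", "accession"), topology$accession)
  lapply(seq_along(records), function(i) {
    r <- records[[i]]
    j <- idx[i]
    if (is.na(j)) return(r)
    protein_record(r$accession, r$sequence,
                   sp_length = topology$sp_length[j],
                   topology_class = topology$topology_class[j],
                   essential = topology$essential[j],
                   experimental_flags = r$experimental_flags)
  })
}

#' Construct a per-residue score track
#'
#' @param accession Protein accession.
#' @param kind One of disorder, backbone_dynamics, early_folding,
#'   aggregation, helix_propensity, sheet_propensity, hydropathy.
#' @param values Finite numeric vector, one value per mature-sequence
#'   residue.
#' @param provenance Free-text source tag.
#' @return Object of class `score_track`.
#' @export
score_track <- function(accession, kind, values, provenance = "unspecified") {
  kinds <- c("disorder", "backbone_dynamics", "early_folding", "aggregation",
             "helix_propensity", "sheet_propensity", "hydropathy")
  if (!kind %in% kinds) stop("score_track: unknown kind '", kind, "'")
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values))) {
    stop("score_track: values must be nonempty and finite (", accession, ")")
  }
  structure(list(accession = accession, kind = kind, values = values,
                 provenance = provenance),
            class = "score_track")
}

#' Read per-residue score tracks from a TSV file
#'
#' Long format with header `accession`, `position`, `residue`, `score`;
#' positions must be 1-based and contiguous within each protein.  When
#' `records` is supplied, each track length is checked against the mature
#' sequence length.
#'
#' @param path TSV file.
#' @param kind Track kind (see [score_track()]).
#' @param records Optional list of [protein_record()]s for length validation.
#' @return Named list of `score_track` objects (by accession).
#' @export
read_score_tracks <- function(path, kind, records = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "position", "residue", "score")
  if (!all(need %in% names(df))) {
    stop("read_score_tracks: missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ","))
  }
  lens <- NULL
  if (!is.null(records)) {
    lens <- setNames(vapply(records, function(r) nchar(mature_sequence(r)),
                            integer(1)),
                     vapply(records, `[[`, "", "accession"))
  }
  out <- lapply(split(df, df$accession), function(d) {
    d <- d[order(d$position), , drop = FALSE]
    if (!identical(as.integer(d$position), seq_len(nrow(d)))) {
      stop("read_score_tracks: non-contiguous positions for '",
           d$accession[1], "'")
    }
    if (!is.null(lens)) {
      L <- lens[[d$accession[1]]]
      if (!is.null(L) && !is.na(L) && L != nrow(d)) {
        stop("read_score_tracks: track length ", nrow(d),
             " != mature length ", L, " for '", d$accession[1], "'")
      }
    }
    score_track(d$accession[1], kind, d$score, provenance = path)
  })
  out[unique(df$accession)]
}

#' Write score tracks to TSV (round-trip inverse of [read_score_tracks()])
#'
#' @param tracks List of `score_track`s.
#' @param records List of matching [protein_record()]s supplying residues.
#' @param path Output TSV.
#' @export
write_score_tracks <- function(tracks, records, path) {
  seqs <- setNames(vapply(records, mature_sequence, ""),
                   vapply(records, `[[`, "", "accession"))
  rows <- lapply(tracks, function(tr) {
    s <- seqs[[tr$accession]]
    data.frame(accession = tr$accession,
               position = seq_along(tr$values),
               residue = seq_chars(s),
               score = tr$values)
  })
  df <- do.call(rbind, rows)
  write.table(format(df, digits = 10, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fold assignment table
#'
#' TSV with header `accession`, `fold_id`, `scop_class`, `start`, `end`.
#' SCOP-style classes a (all-alpha), b (all-beta), c (alpha/beta),
#' d (alpha+beta), f (membrane), other.
#'
#' @param path TSV file.
#' @return data.frame of domain assignments.
#' @export
read_fold_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "fold_id", "scop_class", "start", "end")
  if (!all(need %in% names(df))) {
    stop("read_fold_table: missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ","))
  }
  if (any(!nzchar(df$fold_id))) stop("read_fold_table: empty fold_id")
  bad <- setdiff(unique(df$scop_class), c("a", "b", "c", "d", "f", "other"))
  if (length(bad)) {
    stop("read_fold_table: invalid scop_class: ", paste(bad, collapse = ","))
  }
  df[need]
}

#' Write a fold assignment table
#' @param df Fold table data.frame.
#' @param path Output TSV.
#' @export
write_fold_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an abundance matrix (proteins x conditions)
#'
#' TSV with header; first column `accession`, remaining columns condition
#' names.  All entries must be positive (copies per cell).
#'
#' @param path TSV file.
#' @return Numeric matrix with accession rownames.
#' @export
read_abundance <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "accession") {
    stop("read_abundance: first column must be 'accession'")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$accession
  storage.mode(m) <- "double"
  if (ncol(m) < 2L) stop("read_abundance: need >= 2 conditions")
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("read_abundance: entries must be finite and positive")
  }
  m
}

#' Write an abundance matrix
#' @param m Matrix with accession rownames.
#' @param path Output TSV.
#' @export
write_abundance <- function(m, path) {
  df <- data.frame(accession = rownames(m), m, check.names = FALSE)
  write.table(format(df, digits = 10, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
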