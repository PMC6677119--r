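#' Global pairwise sequence identity
#'
#' Identity of a Needleman-Wunsch global alignment (match +1, mismatch -1,
#' linear gap -1, deterministic tie-break), defined as identical columns
#' divided by alignment length (gap columns included).
#'
#' @param a,b Amino-acid sequences (character scalars).
#' @return Identity in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  st <- .nw_align_stats(a, b)
  unname(st[["matches"]] / st[["columns"]])
}

#' Reduce sequence redundancy by greedy identity clustering
#'
#' CD-HIT-style greedy clustering: records are visited longest first (ties
#' keep input order); a record joins the first existing cluster whose
#' representative it matches at `identity_threshold` or above
#' ([pairwise_identity()]), otherwise it founds a new cluster.  Cluster
#' representatives are returned in the visiting (length) order, making the
#' procedure deterministic.
#'
#' @param records List of [protein_record()]s (nonempty).
#' @param identity_threshold Global identity threshold in (0, 1\];
#'   default 0.90.
#' @return List of representative records.
#' @export
reduce_redundancy <- function(records, identity_threshold = 0.90) {
  if (length(records) == 0L) stop("reduce_redundancy: no records")
  if (!is.numeric(identity_threshold) || identity_threshold <= 0 ||
      identity_threshold > 1) {
    stop("reduce_redundancy: identity_threshold must be in (0, 1]")
  }
  lens <- vapply(records, function(r) nchar(r$sequence), integer(1))
  ord <- order(-lens)                      # stable: ties keep input order
  reps <- list()
  for (i in ord) {
    r <- records[[i]]
    joined <- FALSE
    for (rep in reps) {
      if (pairwise_identity(r$sequence, rep$sequence) >= identity_threshold) {
        joined <- TRUE
        break
      }
    }
    if (!joined) reps[[length(reps) + 1L]] <- r
  }
  reps
}
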