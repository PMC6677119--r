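## Independent brute-force oracles used across the suite.  These are written
## against the definitions, not against the package implementations: simple
## exhaustive scans and dense-grid searches at sizes where correctness is
## obvious.

## Exhaustive position-by-position segment scan: a segment is a run whose
## every position clears the threshold, whose flanks (if any) do not, and
## whose length reaches min_len.
oracle_segments <- function(values, threshold, min_len) {
  L <- length(values)
  segs <- list()
  for (s in seq_len(L)) {
    if (values[s] < threshold) next
    if (s > 1 && values[s - 1] >= threshold) next   # not a run start
    e <- s
    while (e < L && values[e + 1L] >= threshold) e <- e + 1L
    if (e - s + 1L >= min_len) segs[[length(segs) + 1]] <- c(s, e)
  }
  if (!length(segs)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, segs)
  data.frame(start = m[, 1], end = m[, 2])
}

oracle_patches <- function(sequence, min_len, set) {
  ch <- strsplit(sequence, "")[[1]]
  oracle_segments(as.numeric(ch %in% set), 0.5, min_len)
}

## Dense-grid isoelectric point: minimize |net charge| over a fine pH grid,
## with the charge sum written out independently.
oracle_pi <- function(sequence, step = 0.001) {
  ch <- strsplit(sequence, "")[[1]]
  ch <- ch[ch != "X"]
  pk_pos <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
  pk_neg <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
  n_pos <- c(Nterm = 1, K = sum(ch == "K"), R = sum(ch == "R"),
             H = sum(ch == "H"))
  n_neg <- c(Cterm = 1, D = sum(ch == "D"), E = sum(ch == "E"),
             C = sum(ch == "C"), Y = sum(ch == "Y"))
  grid <- seq(0, 14, by = step)
  q <- vapply(grid, function(ph) {
    sum(n_pos / (1 + 10^(ph - pk_pos))) - sum(n_neg / (1 + 10^(pk_neg - ph)))
  }, numeric(1))
  grid[which.min(abs(q))]
}

## O(n^2) all-against-all residue contact scan over heavy atoms.
oracle_contacts <- function(model, cutoff, min_sep, ca_only = FALSE) {
  at <- model$atoms
  if (ca_only) at <- at[at$elety == "CA", , drop = FALSE]
  res <- sort(unique(at$resno))
  out <- list()
  for (a in seq_along(res)) {
    for (b in seq_along(res)) {
      if (b <= a) next
      i <- res[a]; j <- res[b]
      if (j - i < min_sep) next
      ai <- at[at$resno == i, , drop = FALSE]
      aj <- at[at$resno == j, , drop = FALSE]
      hit <- FALSE
      for (p in seq_len(nrow(ai))) {
        for (q in seq_len(nrow(aj))) {
          d <- sqrt((ai$x[p] - aj$x[q])^2 + (ai$y[p] - aj$y[q])^2 +
                      (ai$z[p] - aj$z[q])^2)
          if (d < cutoff) { hit <- TRUE; break }
        }
        if (hit) break
      }
      if (hit) out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer()))
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2])
}

## Exact Fisher p for a 2x2 table by enumerating the hypergeometric
## distribution over all tables with the observed margins and summing the
## probabilities no larger than the observed one.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  logp <- function(x) {
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  }
  p_obs <- logp(a)
  xs <- lo:hi
  ps <- logp(xs)
  sum(exp(ps[ps <= p_obs + 1e-7]))
}

## Random rigid-body motion (proper rotation + translation).
apply_rigid_motion <- function(model, seed) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3)
  qr_d <- qr(m)
  rot <- qr.Q(qr_d)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  tr <- rnorm(3, sd = 20)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% rot
  model$atoms$x <- xyz[, 1] + tr[1]
  model$atoms$y <- xyz[, 2] + tr[2]
  model$atoms$z <- xyz[, 3] + tr[3]
  model
}

random_sequence <- function(L, letters = c("A", "R", "N", "D", "C", "Q", "E",
                                           "G", "H", "I", "L", "K", "M", "F",
                                           "P", "S", "T", "W", "Y", "V")) {
  paste(sample(letters, L, replace = TRUE), collapse = "")
}

## Per-residue F1 of called segments against planted truth.
segment_f1 <- function(called, truth, L) {
  cov <- function(seg) {
    v <- logical(L)
    for (i in seq_len(nrow(seg))) v[seg$start[i]:seg$end[i]] <- TRUE
    v
  }
  a <- cov(called); b <- cov(truth)
  tp <- sum(a & b); fp <- sum(a & !b); fn <- sum(!a & b)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}
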