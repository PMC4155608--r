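# Mapping alignment columns onto structure residues, and measuring how
# close candidate mutations sit to a designated residue set (typically the
# active site) in 3D.

#' Map alignment columns to structure residues
#'
#' Aligns the degapped family row against the chain's residue sequence with
#' a semiglobal Needleman-Wunsch (match +1, mismatch -1, gap -2, terminal
#' gaps free — structures often truncate termini) and converts matched
#' positions into (alignment column, structure residue key) pairs.
#' Mismatched aligned positions are still mapped but flagged, covering
#' point mutations between the row and the deposited structure.
#'
#' @param row An aligned row (string) from the family.
#' @param chain A [read_structure()] chain.
#' @param min_identity Refuse to map below this fraction of identical
#'   aligned positions (default 0.3: below that the chain is likely the
#'   wrong protein).
#' @return A list of class `column_residue_map`: `map` (data.frame with
#'   `column`, `residue_pos`, `key`, `code`, `match`), `unmapped_columns`
#'   (alignment columns of row residues with no structure residue),
#'   `unmapped_keys` (structure residues with no row residue), `identity`.
#' @export
map_columns_to_structure <- function(row, chain, min_identity = 0.3) {
  seq_row <- degap(toupper(row))
  if (nchar(seq_row) == 0L) stop("row has no residues")
  cols <- which(chars(toupper(row)) != "-")   # degapped pos -> column
  a <- chars(seq_row)
  b <- chain$codes
  aln <- semiglobal_align(a, b)
  matched <- !is.na(aln$i) & !is.na(aln$j)
  ident <- sum(a[aln$i[matched]] == b[aln$j[matched]])
  identity <- if (any(matched)) ident / sum(matched) else 0
  if (identity < min_identity)
    stop(sprintf(
      "sequence/structure identity %.1f%% is below %.0f%%; wrong chain?",
      100 * identity, 100 * min_identity))
  i <- aln$i[matched]; j <- aln$j[matched]
  map <- data.frame(column = cols[i], residue_pos = i, key = chain$keys[j],
                    code = b[j], match = a[i] == b[j],
                    stringsAsFactors = FALSE)
  structure(list(map = map,
                 unmapped_columns = cols[setdiff(seq_along(a), i)],
                 unmapped_keys = chain$keys[setdiff(seq_along(b), j)],
                 identity = identity),
            class = "column_residue_map")
}

#' @export
print.column_residue_map <- function(x, ...) {
  cat("Column-to-residue map: ", nrow(x$map), " positions mapped (",
      round(100 * x$identity, 1), "% identity), ",
      length(x$unmapped_columns), " columns and ",
      length(x$unmapped_keys), " residues unmatched\n", sep = "")
  invisible(x)
}

#' Semiglobal alignment of two character vectors; terminal gaps free.
#' Returns aligned index pairs (NA = gap on that side).
#' @noRd
semiglobal_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1L, m + 1L)   # free leading gaps: first row/col 0
  P <- matrix(0L, n + 1L, m + 1L)  # 1 diag, 2 up (gap in b), 3 left (gap in a)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- S[i, j] + if (a[i] == b[j]) match else mismatch
      u <- S[i, j + 1L] + gap
      l <- S[i + 1L, j] + gap
      best <- max(d, u, l)
      S[i + 1L, j + 1L] <- best
      P[i + 1L, j + 1L] <- if (best == d) 1L else if (best == u) 2L else 3L
    }
  }
  # free trailing gaps: best cell on the last row or column
  last_col <- S[n + 1L, ]; last_row <- S[, m + 1L]
  if (max(last_col) >= max(last_row)) {
    i <- n; j <- which.max(last_col) - 1L
  } else {
    i <- which.max(last_row) - 1L; j <- m
  }
  ii <- integer(0); jj <- integer(0)
  # trailing unaligned tails are terminal gaps: record them unmatched
  if (i < n) { ii <- c((i + 1L):n, ii); jj <- c(rep(NA, n - i), jj) }
  if (j < m) { ii <- c(rep(NA, m - j), ii); jj <- c((j + 1L):m, jj) }
  while (i > 0L && j > 0L) {
    p <- P[i + 1L, j + 1L]
    if (p == 1L) { ii <- c(i, ii); jj <- c(j, jj); i <- i - 1L; j <- j - 1L }
    else if (p == 2L) { ii <- c(i, ii); jj <- c(NA, jj); i <- i - 1L }
    else { ii <- c(NA, ii); jj <- c(j, jj); j <- j - 1L }
  }
  if (i > 0L) { ii <- c(1L:i, ii); jj <- c(rep(NA, i), jj) }
  if (j > 0L) { ii <- c(rep(NA, j), ii); jj <- c(1L:j, jj) }
  list(i = ii, j = jj)
}

#' Distance of candidate residues to a site
#'
#' For each candidate residue, the minimum Euclidean distance between any
#' of its heavy atoms and any heavy atom of the site residue set. A
#' candidate that is itself a site member gets distance 0.
#'
#' @param candidates Character vector of residue keys (as in
#'   `chain$keys`).
#' @param site Character vector of site residue keys.
#' @param chain A [read_structure()] chain.
#' @param cutoff Distance cutoff in angstroms (> 0) for the `within` flag.
#' @return data.frame of class `proximity_result`: `key`, `distance`
#'   (angstroms), `within`.
#' @export
site_proximity <- function(candidates, site, chain, cutoff = 6) {
  if (cutoff <= 0) stop("cutoff must be positive")
  all_keys <- unique(c(candidates, site))
  missing <- setdiff(all_keys, chain$keys)
  if (length(missing))
    stop("residue key(s) not in chain ", chain$chain, ": ",
         paste(missing, collapse = ", "))
  site_atoms <- do.call(rbind, chain$coords[match(site, chain$keys)])
  dist_min <- vapply(candidates, function(k) {
    if (k %in% site) return(0)
    atoms <- chain$coords[[match(k, chain$keys)]]
    # all-pairs min distance via cross term
    d2 <- outer(rowSums(atoms^2), rowSums(site_atoms^2), "+") -
      2 * atoms %*% t(site_atoms)
    sqrt(max(0, min(d2)))
  }, numeric(1))
  out <- data.frame(key = candidates, distance = unname(dist_min),
                    within = unname(dist_min) <= cutoff,
                    stringsAsFactors = FALSE)
  class(out) <- c("proximity_result", "data.frame")
  out
}

#' Selection expression for external structure viewers
#'
#' Formats residue keys as a selection string usable in PyMOL-style
#' viewers, e.g. `"chain A and resi 107+138"`. Keys are sorted ascending
#' by residue number (insertion codes preserved verbatim and ordered after
#' the bare number).
#'
#' @param keys Nonempty character (or integer) vector of residue keys.
#' @param chain_id Chain identifier.
#' @return The selection string.
#' @export
selection_string <- function(keys, chain_id) {
  if (length(keys) == 0L) stop("empty residue key list")
  keys <- as.character(keys)
  num <- as.integer(sub("^(-?[0-9]+).*$", "\\1", keys))
  icode <- sub("^-?[0-9]+", "", keys)
  keys <- keys[order(num, icode)]
  paste0("chain ", chain_id, " and resi ", paste(keys, collapse = "+"))
}
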