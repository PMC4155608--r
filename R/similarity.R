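# The seven sorting weights of the trend-image panel and the row ordering
# they induce. Distances run over degapped sequences; the alignment is a
# display/selection artifact, not part of the string metric.

SIMILARITY_METRICS <- c("fragment_frequency", "edit", "weighted_edit",
                        "common_positional", "common_positional_pct",
                        "common_compositional", "common_compositional_pct",
                        "ngram_common", "selected_edit")

# metrics where smaller weight = more similar (reference weighs 0)
DISTANCE_METRICS <- c("edit", "weighted_edit", "selected_edit")

#' Specify a sorting metric
#'
#' Bundles a metric name with its parameters for [sort_family()].
#'
#' @param name One of `fragment_frequency`, `edit`, `weighted_edit`,
#'   `common_positional`, `common_positional_pct`, `common_compositional`,
#'   `common_compositional_pct`, `ngram_common`, `selected_edit`.
#' @param n n-gram length for `ngram_common` (default 3).
#' @param scheme Partition scheme name for `weighted_edit` (default
#'   `"polarity"`).
#' @param window Length-2 column range (1-based inclusive) for
#'   `fragment_frequency`; defaults to the full alignment width.
#' @param columns Selected column set for `selected_edit`.
#' @return A list of class `metric_spec`.
#' @export
metric_spec <- function(name, n = 3L, scheme = "polarity",
                        window = NULL, columns = NULL) {
  if (!name %in% SIMILARITY_METRICS)
    stop("unknown metric '", name, "'; valid metrics: ",
         paste(SIMILARITY_METRICS, collapse = ", "))
  if (n < 1L) stop("n-gram length must be >= 1")
  structure(list(name = name, n = as.integer(n), scheme = scheme,
                 window = window, columns = columns,
                 distance = name %in% DISTANCE_METRICS),
            class = "metric_spec")
}

#' Levenshtein edit distance between two sequences
#'
#' Unit insertion/deletion/substitution costs, computed on the degapped
#' sequences. `X` never matches any residue, itself included.
#'
#' @param a,b Residue strings (gaps are stripped first).
#' @return Integer edit distance.
#' @examples
#' edit_distance("KITTEN", "SITTING")  # 3
#' @export
edit_distance <- function(a, b) {
  .edit_distance_c(degap(a), degap(b))
}

#' Class-weighted edit distance
#'
#' Levenshtein distance where substituting two different residues of the
#' same scheme class costs 0.5 instead of 1; identical residues cost 0 and
#' insertions/deletions cost 1. An `X` on either side always costs 1. The
#' result never exceeds the plain [edit_distance()] and is symmetric.
#'
#' @param a,b Residue strings (gaps stripped).
#' @param scheme A partition scheme or its name (default `"polarity"`);
#'   `fragment_frequency` is not a partition and is rejected.
#' @return Numeric distance (multiples of 0.5).
#' @examples
#' weighted_edit_distance("L", "I", "polarity")  # 0.5: same class
#' @export
weighted_edit_distance <- function(a, b, scheme = "polarity") {
  if (is.character(scheme)) scheme <- get_scheme(scheme)
  if (scheme$name == "fragment_frequency")
    stop("weighted_edit_distance needs a partition scheme, ",
         "not fragment_frequency")
  class_of <- rep(-1L, 128L)
  cid <- 0L
  for (cl in names(scheme$classes)) {
    class_of[utf8ToInt(paste(scheme$classes[[cl]], collapse = "")) + 1L] <- cid
    cid <- cid + 1L
  }
  # class_of is 0-indexed by char code on the C++ side
  .weighted_edit_distance_c(degap(a), degap(b), class_of)
}

#' Common residues between two aligned rows
#'
#' Positional mode counts columns where both rows carry the identical
#' non-`X` residue (gap/gap columns never match). Compositional mode is the
#' multiset intersection of the two degapped residue compositions,
#' disregarding position (`X` excluded: it matches nothing). The percentage
#' divides by the shorter degapped sequence length (0 when that is 0).
#'
#' @param a_row,b_row Aligned rows of equal length.
#' @param positional `TRUE` for the positional count, `FALSE` for the
#'   composition-only count.
#' @return A list with `count` and `percentage`.
#' @export
common_residues <- function(a_row, b_row, positional = TRUE) {
  if (nchar(a_row) != nchar(b_row))
    stop("aligned rows differ in length (", nchar(a_row), " vs ",
         nchar(b_row), ")")
  ca <- chars(a_row); cb <- chars(b_row)
  if (positional) {
    count <- sum(ca == cb & ca %in% AA20)
  } else {
    ta <- table(factor(ca[ca %in% AA20], levels = AA20))
    tb <- table(factor(cb[cb %in% AA20], levels = AA20))
    count <- sum(pmin(ta, tb))
  }
  shorter <- min(nchar(degap(a_row)), nchar(degap(b_row)))
  pct <- if (shorter == 0L) 0 else 100 * count / shorter
  list(count = as.integer(count), percentage = pct)
}

#' Distinct n-grams shared by two sequences
#'
#' Counts the distinct contiguous length-`n` substrings present in both
#' degapped sequences. n-grams containing `X` are dropped (unknown residues
#' match nothing). A sequence shorter than `n` contributes the empty set.
#'
#' @param a,b Residue strings (gaps stripped).
#' @param n n-gram length, >= 1.
#' @return Integer count of shared distinct n-grams.
#' @export
ngram_common <- function(a, b, n = 3L) {
  if (n < 1L) stop("n must be >= 1")
  length(intersect(ngram_set(degap(a), n), ngram_set(degap(b), n)))
}

#' @noRd
ngram_set <- function(x, n) {
  L <- nchar(x)
  if (L < n) return(character(0))
  grams <- substring(x, 1:(L - n + 1L), n:L)
  unique(grams[!grepl("X", grams, fixed = TRUE)])
}

#' Edit distance on selected alignment columns
#'
#' Projects both rows onto the selected columns (in ascending column
#' order), drops gaps from each projection independently, and returns the
#' [edit_distance()] of the projections.
#'
#' @param a_row,b_row Aligned rows of equal length.
#' @param columns Nonempty set of 1-based column indices.
#' @return Integer edit distance over the selection.
#' @export
selected_edit_distance <- function(a_row, b_row, columns) {
  if (length(columns) == 0L) stop("empty column selection")
  L <- nchar(a_row)
  if (nchar(b_row) != L) stop("aligned rows differ in length")
  columns <- sort(unique(as.integer(columns)))
  if (columns[1L] < 1L || columns[length(columns)] > L)
    stop("selected columns must lie in [1, ", L, "]")
  pa <- paste(chars(a_row)[columns], collapse = "")
  pb <- paste(chars(b_row)[columns], collapse = "")
  edit_distance(pa, pb)
}

#' Fragment-frequency weight of a row
#'
#' The fraction of family rows whose aligned substring over the window is
#' character-identical (gaps included) to this row's substring. Always in
#' (0, 1]: the row matches itself.
#'
#' @param family An [aligned_family()].
#' @param row_index Row to weigh (1-based).
#' @param window Length-2 inclusive column range; defaults to the full
#'   width.
#' @return Numeric weight in (0, 1].
#' @export
fragment_frequency_weight <- function(family, row_index, window = NULL) {
  window <- window %||% c(1L, family$L)
  if (length(window) != 2L || window[1L] > window[2L])
    stop("window must be a nonempty column range a:b")
  if (window[1L] < 1L || window[2L] > family$L)
    stop("window must lie within [1, ", family$L, "]")
  frags <- substr(family$rows, window[1L], window[2L])
  sum(frags == frags[row_index]) / family$n
}

#' Rank a family against a reference sequence
#'
#' Computes one weight per row relative to the reference row and the
#' induced ordering: ascending for distance metrics (the reference weighs 0
#' and ranks first), descending for similarity counts. Ties keep input
#' order, so rendering is deterministic.
#'
#' @param family An [aligned_family()].
#' @param reference Id of the reference row.
#' @param spec A [metric_spec()] (or a metric name, taken with default
#'   parameters).
#' @return A list of class `sort_result`: `reference`, `spec`, `weights`
#'   (named by id, input order) and `order` (permutation of row indices).
#' @examples
#' fam <- aligned_family(c("r", "s", "t"), c("ACDE", "ACDE", "AAAA"))
#' sort_family(fam, "r", "edit")$order
#' @export
sort_family <- function(family, reference, spec = "edit") {
  if (is.character(spec)) spec <- metric_spec(spec)
  ref_row <- family_row(family, reference)
  w <- vapply(seq_len(family$n), function(i) {
    row <- family$rows[i]
    switch(spec$name,
      edit = edit_distance(row, ref_row),
      weighted_edit = weighted_edit_distance(row, ref_row, spec$scheme),
      common_positional = common_residues(row, ref_row, TRUE)$count,
      common_positional_pct = common_residues(row, ref_row, TRUE)$percentage,
      common_compositional = common_residues(row, ref_row, FALSE)$count,
      common_compositional_pct =
        common_residues(row, ref_row, FALSE)$percentage,
      ngram_common = ngram_common(row, ref_row, spec$n),
      selected_edit = selected_edit_distance(
        row, ref_row, spec$columns %||% seq_len(family$L)),
      fragment_frequency = fragment_frequency_weight(family, i, spec$window)
    ) * 1.0
  }, numeric(1))
  names(w) <- family$ids
  structure(list(reference = reference, spec = spec, weights = w,
                 order = stable_order(w, decreasing = !spec$distance)),
            class = "sort_result")
}

#' @export
print.sort_result <- function(x, ...) {
  cat("Family ranking by '", x$spec$name, "' vs reference '",
      x$reference, "'\n", sep = "")
  top <- utils::head(x$order, 8L)
  for (r in seq_along(top))
    cat(sprintf("  %2d. %-12s %g\n", r, names(x$weights)[top[r]],
                x$weights[top[r]]))
  if (length(x$order) > 8L)
    cat("  ... and ", length(x$order) - 8L, " more\n", sep = "")
  invisible(x)
}

#' Export a ranking as TSV (rank, id, weight)
#'
#' @param sr A [sort_family()] result.
#' @param path Output TSV path.
#' @return The exported data.frame, invisibly.
#' @export
write_sort_tsv <- function(sr, path) {
  df <- data.frame(rank = seq_along(sr$order),
                   id = names(sr$weights)[sr$order],
                   weight = unname(sr$weights[sr$order]),
                   stringsAsFactors = FALSE)
  write_tsv_report(df, path,
                   params = c(paste0("metric=", sr$spec$name),
                              paste0("reference=", sr$reference)))
  invisible(df)
}
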