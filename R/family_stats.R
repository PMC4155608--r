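# Per-column residue distributions, consensus and conservation statistics.

# residues counted in column distributions: 20 standard + unknown
COUNT_LEVELS <- c(AA20, "X")

#' Residue distribution of one alignment column
#'
#' Counts each residue letter (20 standard plus `X`) and gaps in the
#' column. Frequencies are computed over non-gap entries by default — the
#' view a consensus-design workflow needs — or over all rows with
#' `freq_over = "all"`.
#'
#' @param family An [aligned_family()].
#' @param column 1-based column index.
#' @param freq_over `"residues"` (default) or `"all"`: the denominator for
#'   the frequency column.
#' @return A list of class `column_distribution`: `column`, `counts` (named
#'   integer vector over residue letters), `gap_count`, `frequencies`,
#'   `modal_residue` (`NA` for an all-gap column; alphabetical tie-break)
#'   and `modal_frequency`.
#' @export
column_distribution <- function(family, column,
                                freq_over = c("residues", "all")) {
  freq_over <- match.arg(freq_over)
  column <- as.integer(column)
  if (length(column) != 1L || is.na(column) || column < 1L ||
      column > family$L)
    stop("column must lie in [1, ", family$L, "]")
  cc <- substr(family$rows, column, column)
  counts <- table(factor(cc, levels = COUNT_LEVELS))
  counts <- stats::setNames(as.integer(counts), COUNT_LEVELS)
  gap_count <- sum(cc == "-")
  denom <- if (freq_over == "residues") family$n - gap_count else family$n
  freqs <- if (denom > 0L) counts / denom else counts * NA_real_
  if (sum(counts) > 0L) {
    # which.max on the alphabetical level order gives the tie-break for free
    modal <- COUNT_LEVELS[which.max(counts)]
    modal_freq <- unname(freqs[modal])
  } else {
    modal <- NA_character_
    modal_freq <- NA_real_
  }
  structure(list(column = column, counts = counts, gap_count = gap_count,
                 frequencies = freqs, modal_residue = modal,
                 modal_frequency = modal_freq),
            class = "column_distribution")
}

#' @export
print.column_distribution <- function(x, ...) {
  cat("Column ", x$column, ": ", sum(x$counts), " residues, ",
      x$gap_count, " gaps", sep = "")
  if (!is.na(x$modal_residue))
    cat("; modal ", x$modal_residue, " (", round(100 * x$modal_frequency, 1),
        "%)", sep = "")
  cat("\n")
  nz <- x$counts[x$counts > 0L]
  if (length(nz))
    cat("  ", paste(sprintf("%s=%d", names(nz), nz), collapse = " "), "\n")
  invisible(x)
}

#' Family consensus sequence
#'
#' Per column, the most frequent non-gap residue, with ties broken
#' alphabetically by one-letter code; all-gap columns yield `-`. This is
#' the "most common residue at each location" a consensus-design mutation
#' moves a protein towards.
#'
#' @param family An [aligned_family()].
#' @return A list of class `consensus_sequence`: `sequence` (aligned string
#'   of length L) and `modal_frequency` (per-column modal frequency among
#'   non-gap entries; `NA` at all-gap columns).
#' @examples
#' consensus(aligned_family(c("a","b","c"), c("AAC","AAC","AGC")))$sequence
#' @export
consensus <- function(family) {
  m <- family_matrix(family)
  cons <- character(family$L)
  freq <- numeric(family$L)
  for (j in seq_len(family$L)) {
    counts <- tabulate(match(m[, j], COUNT_LEVELS), length(COUNT_LEVELS))
    if (sum(counts) == 0L) {
      cons[j] <- "-"
      freq[j] <- NA_real_
    } else {
      k <- which.max(counts)   # first max = alphabetical tie-break
      cons[j] <- COUNT_LEVELS[k]
      freq[j] <- counts[k] / sum(counts)
    }
  }
  structure(list(sequence = paste(cons, collapse = ""),
                 modal_frequency = freq),
            class = "consensus_sequence")
}

#' @export
print.consensus_sequence <- function(x, ...) {
  L <- nchar(x$sequence)
  cat("Consensus over ", L, " columns (mean modal frequency ",
      round(mean(x$modal_frequency, na.rm = TRUE), 3), ")\n", sep = "")
  cat("  ", if (L > 60L) paste0(substr(x$sequence, 1, 57), "...")
      else x$sequence, "\n", sep = "")
  invisible(x)
}

#' Fraction of the family sharing the reference residue, per column
#'
#' For each column where the reference carries a standard residue, the
#' fraction of family rows (reference included) carrying that same residue.
#' Columns where the reference has a gap — or an `X`, which matches nothing
#' — are `NA`.
#'
#' @param family An [aligned_family()].
#' @param reference Id of the reference row.
#' @return Numeric vector of length L with values in (0, 1] or `NA`.
#' @export
reference_match_profile <- function(family, reference) {
  ref <- chars(family_row(family, reference))
  m <- family_matrix(family)
  vapply(seq_len(family$L), function(j) {
    if (!ref[j] %in% AA20) return(NA_real_)
    sum(m[, j] == ref[j]) / family$n
  }, numeric(1))
}

#' Columns conserved above a threshold
#'
#' Reports columns whose modal non-gap residue reaches the given frequency
#' among non-gap entries. Mostly-gap columns (fewer than half the rows
#' carrying a residue) are excluded to avoid consensus artifacts at
#' filler-heavy termini.
#'
#' @param family An [aligned_family()].
#' @param threshold Modal-frequency cutoff in (0, 1]; default 0.9
#'   ("almost fully conserved").
#' @return data.frame with `column`, `residue` and `frequency`, ascending
#'   by column.
#' @export
conserved_columns <- function(family, threshold = 0.9) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  m <- family_matrix(family)
  out <- list()
  for (j in seq_len(family$L)) {
    counts <- tabulate(match(m[, j], COUNT_LEVELS), length(COUNT_LEVELS))
    non_gap <- sum(counts)
    if (2L * non_gap < family$n || non_gap == 0L) next
    k <- which.max(counts)
    f <- counts[k] / non_gap
    if (f >= threshold)
      out[[length(out) + 1L]] <- data.frame(
        column = j, residue = COUNT_LEVELS[k], frequency = f,
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(column = integer(0), residue = character(0),
                      frequency = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Export per-column residue distributions as TSV
#'
#' One row per (column, residue letter) with a positive count; columns
#' `column`, `residue`, `count`, `frequency`.
#'
#' @param family An [aligned_family()].
#' @param path Output TSV path.
#' @param columns Columns to export (default all).
#' @inheritParams column_distribution
#' @return The exported data.frame, invisibly.
#' @export
write_distribution_tsv <- function(family, path,
                                   columns = seq_len(family$L),
                                   freq_over = "residues") {
  rows <- lapply(columns, function(j) {
    d <- column_distribution(family, j, freq_over)
    keep <- d$counts > 0L
    if (!any(keep)) return(NULL)
    data.frame(column = j, residue = names(d$counts)[keep],
               count = unname(d$counts[keep]),
               frequency = unname(d$frequencies[keep]),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(column = integer(0), residue = character(0),
                     count = integer(0), frequency = numeric(0))
  write_tsv_report(df, path, params = paste0("freq_over=", freq_over))
  invisible(df)
}

#' Export the consensus as FASTA
#' @param family An [aligned_family()].
#' @param path Output FASTA path.
#' @return The consensus object, invisibly.
#' @export
write_consensus_fasta <- function(family, path) {
  cons <- consensus(family)
  write_sequence("consensus", cons$sequence, path)
  invisible(cons)
}
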