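# Parent-vs-mutant diffing and the consensus-candidate shortlist: columns
# where a mutant departs from its parent but agrees with the family, plus
# terminus-symmetric pairs of mutated positions.

#' Resolve a parent/mutant argument: an id in the family, or a pre-aligned
#' row of the family's width.
#' @noRd
resolve_row <- function(family, x, what) {
  if (x %in% family$ids) return(family_row(family, x))
  if (nchar(x) == family$L && first_bad_column(toupper(x)) == 0L)
    return(toupper(x))
  stop(what, " '", substr(x, 1L, 30L),
       "' is neither a family id nor an aligned row of width ", family$L)
}

#' Maximal runs of difference between two aligned rows
#'
#' A column differs when its two characters are unequal: residue/residue
#' (modified), gap/residue (created) or residue/gap (deleted); gap/gap
#' columns never differ. Runs are maximal contiguous blocks of differing
#' columns, so consecutive runs are never adjacent.
#'
#' @param ref_row,alt_row Aligned rows of equal length, in the same
#'   alignment coordinate system.
#' @return A list of class `diff_runs`: `runs` (data.frame with 1-based
#'   inclusive `start`, `end`, `ref_sub`, `alt_sub`, and per-run counts
#'   `n_sub`/`n_ins`/`n_del` of substituted, created and deleted columns),
#'   `n_runs` and `n_diff_cols`.
#' @examples
#' diff_runs("ACDEFG", "AXDYFG")$n_runs  # 2
#' @export
diff_runs <- function(ref_row, alt_row) {
  L <- nchar(ref_row)
  if (nchar(alt_row) != L)
    stop("aligned rows differ in length (", L, " vs ", nchar(alt_row), ")")
  cr <- chars(ref_row); ca <- chars(alt_row)
  differs <- cr != ca
  runs <- list()
  if (any(differs)) {
    r <- rle(differs)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      s <- starts[k]; e <- ends[k]
      seg_r <- cr[s:e]; seg_a <- ca[s:e]
      runs[[length(runs) + 1L]] <- data.frame(
        start = s, end = e,
        ref_sub = paste(seg_r, collapse = ""),
        alt_sub = paste(seg_a, collapse = ""),
        n_sub = sum(seg_r != "-" & seg_a != "-"),
        n_ins = sum(seg_r == "-"),
        n_del = sum(seg_a == "-"),
        stringsAsFactors = FALSE)
    }
  }
  runs <- if (length(runs)) do.call(rbind, runs) else
    data.frame(start = integer(0), end = integer(0),
               ref_sub = character(0), alt_sub = character(0),
               n_sub = integer(0), n_ins = integer(0), n_del = integer(0),
               stringsAsFactors = FALSE)
  structure(list(runs = runs, n_runs = nrow(runs),
                 n_diff_cols = sum(differs)),
            class = "diff_runs")
}

#' @export
print.diff_runs <- function(x, ...) {
  cat(x$n_runs, " differing runs covering ", x$n_diff_cols, " columns\n",
      sep = "")
  if (x$n_runs > 0L)
    print(utils::head(x$runs, 10L), row.names = FALSE)
  invisible(x)
}

#' Consensus-restoring candidate mutations
#'
#' Scans the columns where the parent and mutant rows carry different
#' residues (indel columns are skipped: candidates are substitutions) and
#' annotates each with the family consensus at that column: does the
#' mutant agree with the family where the parent does not, and how strongly
#' is the column conserved? The shortlist is sorted by descending consensus
#' frequency, then ascending column — the most conserved departures first.
#'
#' @param family An [aligned_family()] of the protein family.
#' @param parent,mutant Ids present in the family, or aligned rows of the
#'   family's width.
#' @param threshold Conservation threshold for the `highly_conserved` flag
#'   (modal frequency among non-gap entries; default 0.9).
#' @return data.frame of class `candidate_mutations`, one row per candidate
#'   column: `column`, `parent_pos` (1-based position in the parent's
#'   degapped sequence), `parent_res`, `mutant_res`, `consensus_res`,
#'   `consensus_freq`, `parent_matches_consensus`,
#'   `mutant_matches_consensus`, `highly_conserved`.
#' @export
consensus_candidates <- function(family, parent, mutant, threshold = 0.9) {
  p_row <- resolve_row(family, parent, "parent")
  m_row <- resolve_row(family, mutant, "mutant")
  cp <- chars(p_row); cm <- chars(m_row)
  cons <- consensus(family)
  cons_chars <- chars(cons$sequence)
  parent_pos <- cumsum(cp != "-")
  cols <- which(cp != cm & cp %in% c(AA20, "X") & cm %in% c(AA20, "X"))
  out <- data.frame(
    column = cols,
    parent_pos = parent_pos[cols],
    parent_res = cp[cols],
    mutant_res = cm[cols],
    consensus_res = cons_chars[cols],
    consensus_freq = cons$modal_frequency[cols],
    stringsAsFactors = FALSE)
  # X matches nothing, not even another X
  out$parent_matches_consensus <-
    out$parent_res == out$consensus_res & out$parent_res %in% AA20
  out$mutant_matches_consensus <-
    out$mutant_res == out$consensus_res & out$mutant_res %in% AA20
  out$highly_conserved <- !is.na(out$consensus_freq) &
    out$consensus_freq >= threshold
  out <- out[order(-out$consensus_freq, out$column), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_mutations", "data.frame")
  out
}

#' Terminus-symmetric pairs among candidate positions
#'
#' Two mutated positions i < j (in the parent's degapped residue numbering)
#' are symmetric when they sit at the same offset from either end of the
#' protein: i + j = L + 1, where L is the degapped parent length. Such
#' pairs were observed to be conserved family features rather than causes
#' of functional loss; they are annotated, never dropped.
#'
#' @param candidates A [consensus_candidates()] result, or any data.frame
#'   with a `parent_pos` column.
#' @param L_res Degapped length of the parent sequence.
#' @return data.frame with `pos_i`, `pos_j` (`pos_i < pos_j`) and `offset`
#'   (= `pos_i`, the common distance from the nearer terminus).
#' @examples
#' symmetric_pairs(data.frame(parent_pos = c(22, 219)), 240)
#' @export
symmetric_pairs <- function(candidates, L_res) {
  pos <- sort(unique(candidates$parent_pos))
  out <- data.frame(pos_i = integer(0), pos_j = integer(0),
                    offset = integer(0))
  for (i in pos) {
    j <- L_res + 1L - i
    if (j > i && j %in% pos)   # j > i also excludes the exact-center self pair
      out <- rbind(out, data.frame(pos_i = i, pos_j = j, offset = i))
  }
  out
}

#' Ranked candidate report
#'
#' Joins the candidate shortlist with its symmetric-pair annotation into
#' TSV-ready rows, keeping the candidate ranking (descending consensus
#' frequency). Symmetric-pair members carry their partner's position;
#' nothing is auto-excluded — whether a symmetric pair is benign is the
#' analyst's call.
#'
#' @param candidates A [consensus_candidates()] result.
#' @param pairs A [symmetric_pairs()] result.
#' @return data.frame: the candidate columns plus `symmetric_partner`
#'   (partner residue position or `NA`).
#' @export
candidate_report <- function(candidates, pairs) {
  df <- as.data.frame(candidates)
  df[["symmetric_partner"]] <- rep(NA_integer_, nrow(df))
  if (nrow(pairs) > 0L && nrow(df) > 0L) {
    for (k in seq_len(nrow(pairs))) {
      df$symmetric_partner[df$parent_pos == pairs$pos_i[k]] <- pairs$pos_j[k]
      df$symmetric_partner[df$parent_pos == pairs$pos_j[k]] <- pairs$pos_i[k]
    }
  }
  df
}

#' Write a candidate report as TSV
#' @param report A [candidate_report()] data.frame.
#' @param path Output TSV path.
#' @param params Optional character vector recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_candidate_tsv <- function(report, path, params = character(0)) {
  write_tsv_report(report, path, params)
}
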