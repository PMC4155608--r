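# Seeded synthetic-family generator: a stated world with a planted
# consensus, i.i.d. substitution noise, planted consensus-restoring
# candidate positions and terminus-symmetric pairs, plus the truth table
# that makes every downstream operation testable without external data.

#' Generate a synthetic protein family with planted ground truth
#'
#' Rows are drawn from a planted consensus with independent per-column
#' substitutions (uniform over the 19 other residues). The parent sequence
#' is the consensus with each planted candidate position reverted to its
#' "parent" residue; the mutant is the consensus at those positions —
#' exactly the consensus-design construction: the mutant departs from its
#' parent only where it was moved onto the family consensus. Symmetric
#' pairs plant candidates at positions `(k, L + 1 - k)` for each requested
#' offset `k`. The same seed reproduces the family byte for byte.
#'
#' The generated alignment is gap-free (all rows full length), emulating a
#' family of complete homologs; gap/filler behavior is exercised with
#' hand-built alignments instead.
#'
#' @param n Number of family rows (default 200).
#' @param L Sequence length in residues (default 250).
#' @param sub_rate Per-column substitution probability in `[0, 0.5)`
#'   (default 0.05).
#' @param candidates `NULL`, an integer vector of positions (parent and
#'   mutant residues then drawn), or a data.frame with columns `pos`,
#'   `parent_res`, `mutant_res`.
#' @param sym_offsets Integer offsets `k`; each plants a candidate pair at
#'   positions `k` and `L + 1 - k`.
#' @param consensus_seq Planted consensus string of length `L`, or `NULL`
#'   to draw one uniformly.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `family_fixture`: `family` (an
#'   [aligned_family()]), `parent` and `mutant` (`sequence_record`s),
#'   `consensus` (the planted string) and `truth` (data.frame `pos`,
#'   `parent_res`, `mutant_res`, `sym_partner`).
#' @examples
#' fx <- generate_family(n = 20, L = 40, sub_rate = 0.05,
#'                       candidates = c(7, 15), seed = 1)
#' fx$truth
#' @export
generate_family <- function(n = 200L, L = 250L, sub_rate = 0.05,
                            candidates = NULL, sym_offsets = integer(0),
                            consensus_seq = NULL, seed = 1L) {
  if (sub_rate < 0 || sub_rate >= 0.5)
    stop("sub_rate must lie in [0, 0.5)")
  if (n < 1L || L < 1L) stop("n and L must be positive")
  withr::with_seed(as.integer(seed), {
    cons <- consensus_seq %||%
      paste(sample(AA20, L, replace = TRUE), collapse = "")
    if (nchar(cons) != L) stop("consensus_seq must have length L = ", L)
    cons_chars <- chars(cons)
    if (any(!cons_chars %in% AA20))
      stop("consensus_seq must use the 20 standard residues")

    # assemble the planted-candidate truth table
    truth <- normalize_plants(candidates, sym_offsets, cons_chars, L)

    # family rows: consensus + i.i.d. substitution noise
    rows <- vapply(seq_len(n), function(i) {
      cc <- cons_chars
      hit <- which(stats::runif(L) < sub_rate)
      for (j in hit) cc[j] <- sample(setdiff(AA20, cc[j]), 1L)
      paste(cc, collapse = "")
    }, character(1))
    ids <- sprintf("seq%04d", seq_len(n))
    family <- aligned_family(ids, rows)

    parent_chars <- cons_chars
    parent_chars[truth$pos] <- truth$parent_res
    parent <- structure(list(id = "parent",
                             seq = paste(parent_chars, collapse = "")),
                        class = "sequence_record")
    mutant <- structure(list(id = "mutant", seq = cons),
                        class = "sequence_record")
    structure(list(family = family, parent = parent, mutant = mutant,
                   consensus = cons, truth = truth),
              class = "family_fixture")
  })
}

#' Merge explicit candidates and symmetric-offset plants; draw residues
#' where unspecified; reject overlapping plants.
#' @noRd
normalize_plants <- function(candidates, sym_offsets, cons_chars, L) {
  plants <- list()
  add <- function(pos, parent_res = NA, mutant_res = NA, partner = NA) {
    if (pos < 1L || pos > L) stop("planted position ", pos, " outside [1, ", L, "]")
    plants[[length(plants) + 1L]] <<- data.frame(
      pos = as.integer(pos), parent_res = parent_res,
      mutant_res = mutant_res, sym_partner = as.integer(partner),
      stringsAsFactors = FALSE)
  }
  if (is.data.frame(candidates)) {
    for (k in seq_len(nrow(candidates)))
      add(candidates$pos[k], candidates$parent_res[k],
          candidates$mutant_res[k])
  } else if (!is.null(candidates)) {
    for (p in candidates) add(p)
  }
  for (k in sym_offsets) {
    j <- L + 1L - k
    if (j <= k) stop("symmetric offset ", k, " has no distinct partner at L = ", L)
    add(k, partner = j)
    add(j, partner = k)
  }
  if (length(plants) == 0L)
    return(data.frame(pos = integer(0), parent_res = character(0),
                      mutant_res = character(0), sym_partner = integer(0),
                      stringsAsFactors = FALSE))
  truth <- do.call(rbind, plants)
  if (anyDuplicated(truth$pos))
    stop("overlapping planted positions: ",
         paste(truth$pos[duplicated(truth$pos)], collapse = ", "))
  # mutant residue defaults to the consensus (a consensus-design mutation);
  # parent residue defaults to a random different residue
  for (k in seq_len(nrow(truth))) {
    p <- truth$pos[k]
    if (is.na(truth$mutant_res[k])) truth$mutant_res[k] <- cons_chars[p]
    if (is.na(truth$parent_res[k]))
      truth$parent_res[k] <- sample(setdiff(AA20, truth$mutant_res[k]), 1L)
    if (truth$parent_res[k] == truth$mutant_res[k])
      stop("planted position ", p, " has identical parent and mutant residue")
  }
  # the planted consensus must equal the mutant residue at planted sites,
  # otherwise the plant is inconsistent with the stated construction
  bad <- truth$mutant_res != cons_chars[truth$pos]
  if (any(bad))
    stop("mutant residue differs from consensus at planted position(s) ",
         paste(truth$pos[bad], collapse = ", "))
  truth[order(truth$pos), , drop = FALSE]
}

#' @export
print.family_fixture <- function(x, ...) {
  cat("Synthetic family fixture: ", x$family$n, " rows x ", x$family$L,
      " residues, ", nrow(x$truth), " planted candidate(s)\n", sep = "")
  if (nrow(x$truth)) print(x$truth, row.names = FALSE)
  invisible(x)
}

#' Write a fixture to disk (family, parent, mutant, truth table)
#'
#' @param fx A [generate_family()] fixture.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_alignment(fx$family, file.path(dir, "family.fasta"))
  write_sequence(fx$parent$id, fx$parent$seq, file.path(dir, "parent.fasta"))
  write_sequence(fx$mutant$id, fx$mutant$seq, file.path(dir, "mutant.fasta"))
  utils::write.table(fx$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
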