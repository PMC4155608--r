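# Reading/writing sequence and structure formats, and the aligned-family
# container everything downstream operates on.

#' Construct an aligned protein family
#'
#' The central container of the package: a set of equal-length aligned rows
#' over the 20 standard amino-acid letters plus `X` (unknown) and `-` (gap).
#' Rows are stored as uppercase strings; `.` gap characters are normalized
#' to `-`.
#'
#' @param ids Character vector of unique, nonempty sequence identifiers.
#' @param rows Character vector of aligned residue strings, one per id.
#' @return An object of class `aligned_family` with fields `ids`, `rows`,
#'   `n` (number of rows) and `L` (alignment width in columns).
#' @examples
#' fam <- aligned_family(c("a", "b"), c("ACD-", "AC-E"))
#' fam$n; fam$L
#' @export
aligned_family <- function(ids, rows) {
  ids <- as.character(ids)
  rows <- toupper(gsub(".", "-", as.character(rows), fixed = TRUE))
  if (length(ids) != length(rows))
    stop("ids and rows must have the same length")
  if (length(ids) == 0L)
    stop("an aligned family needs at least one row")
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("sequence ids must be nonempty")
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[anyDuplicated(ids)])
  L <- nchar(rows[1L])
  widths <- nchar(rows)
  if (any(widths != L)) {
    off <- which(widths != L)[1L]
    stop("alignment shape error: record '", ids[off], "' has length ",
         widths[off], " but the alignment width is ", L)
  }
  for (i in seq_along(rows)) {
    bad <- first_bad_column(rows[i])
    if (bad > 0L)
      stop("parse error: illegal character '", substr(rows[i], bad, bad),
           "' in record '", ids[i], "' at column ", bad)
  }
  structure(list(ids = ids, rows = rows, n = length(ids), L = L),
            class = "aligned_family")
}

#' @export
print.aligned_family <- function(x, ...) {
  cat("Aligned protein family: ", x$n, " sequences x ", x$L, " columns\n",
      sep = "")
  show <- utils::head(seq_len(x$n), 6L)
  for (i in show) {
    row <- if (x$L > 60L) paste0(substr(x$rows[i], 1L, 57L), "...") else x$rows[i]
    cat(sprintf("  %-12s %s\n", x$ids[i], row))
  }
  if (x$n > 6L) cat("  ... and ", x$n - 6L, " more\n", sep = "")
  invisible(x)
}

#' Return the aligned row for an id, with a helpful error
#' @noRd
family_row <- function(family, id) {
  i <- match(id, family$ids)
  if (is.na(i)) stop("unknown sequence id '", id, "'")
  family$rows[i]
}

#' Read an aligned FASTA file into an aligned family
#'
#' All records must have identical aligned length. Lowercase letters are
#' uppercased and `.` gaps become `-`. Ids are the first whitespace-delimited
#' token of each FASTA header.
#'
#' @param path Path to an aligned FASTA file.
#' @return An [aligned_family()].
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("parse error: no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  aligned_family(ids, as.character(set))
}

#' Write an aligned family to FASTA
#'
#' @param family An [aligned_family()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(family, path) {
  set <- Biostrings::BStringSet(family$rows)
  names(set) <- family$ids
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read a single ungapped sequence record from FASTA
#'
#' Uses the first record (a warning is raised if the file holds more), strips
#' gap characters and uppercases.
#'
#' @param path Path to a FASTA file.
#' @return A list of class `sequence_record` with fields `id` and `seq`.
#' @export
read_sequence <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("parse error: no FASTA records in ", path)
  if (length(set) > 1L)
    warning("file has ", length(set), " records; using the first")
  id <- sub("\\s.*$", "", names(set)[1L])
  seq <- degap(toupper(gsub(".", "-", as.character(set[[1L]]), fixed = TRUE)))
  structure(list(id = id, seq = seq), class = "sequence_record")
}

#' Write a sequence record (or any id/sequence pair) to FASTA
#' @param id Sequence identifier.
#' @param seq Residue string.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(id, seq, path) {
  set <- Biostrings::BStringSet(seq)
  names(set) <- id
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

# Three-letter -> one-letter residue code table (PDB residue names).
AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
            MSE = "M", SEC = "U", PYL = "O")

#' Read one chain of a PDB coordinate file
#'
#' Parses `ATOM` records only (`HETATM` is ignored), keeps heavy atoms
#' (element H discarded), keeps the first alternate location of each atom,
#' and maps three-letter residue names to one-letter codes (unknown names
#' become `X`). Residue keys are the author residue number with any
#' insertion code appended, e.g. `"100"` or `"100A"`, in file order.
#'
#' @param path Path to a PDB-format file.
#' @param chain Single chain identifier, e.g. `"A"`.
#' @return A list of class `structure_chain` with fields `chain`, `keys`,
#'   `codes` (one-letter residue codes) and `coords` (list of numeric
#'   matrices, one `n_atoms x 3` matrix of angstrom coordinates per residue).
#' @export
read_structure <- function(path, chain) {
  stopifnot(length(chain) == 1L, nchar(chain) == 1L)
  lines <- readLines(path, warn = FALSE)
  atom <- lines[startsWith(lines, "ATOM  ")]
  if (length(atom) == 0L) stop("no ATOM records in ", path)
  ch <- substr(atom, 22L, 22L)
  avail <- sort(unique(ch))
  if (!chain %in% ch)
    stop("chain '", chain, "' not found; available chains: ",
         paste(avail, collapse = ", "))
  atom <- atom[ch == chain]
  altloc <- substr(atom, 17L, 17L)
  atom <- atom[altloc %in% c(" ", "A", "1")]
  elem <- trimws(substr(atom, 77L, 78L))
  # fall back on the atom-name column when the element field is blank
  name1 <- substr(trimws(substr(atom, 13L, 16L)), 1L, 1L)
  is_h <- ifelse(nzchar(elem), elem %in% c("H", "D"), name1 == "H")
  atom <- atom[!is_h]
  if (length(atom) == 0L) stop("chain '", chain, "' has no heavy atoms")
  resname <- trimws(substr(atom, 18L, 20L))
  key <- trimws(paste0(trimws(substr(atom, 23L, 26L)), substr(atom, 27L, 27L)))
  x <- as.numeric(substr(atom, 31L, 38L))
  y <- as.numeric(substr(atom, 39L, 46L))
  z <- as.numeric(substr(atom, 47L, 54L))
  keys <- unique(key)  # file order
  coords <- vector("list", length(keys))
  codes <- character(length(keys))
  for (i in seq_along(keys)) {
    sel <- key == keys[i]
    coords[[i]] <- cbind(x = x[sel], y = y[sel], z = z[sel])
    code <- AA3TO1[resname[sel][1L]]
    codes[i] <- if (is.na(code)) "X" else unname(code)
  }
  structure(list(chain = chain, keys = keys, codes = codes, coords = coords),
            class = "structure_chain")
}

#' @export
print.structure_chain <- function(x, ...) {
  cat("Structure chain ", x$chain, ": ", length(x$keys), " residues, ",
      sum(vapply(x$coords, nrow, 1L)), " heavy atoms\n", sep = "")
  cat("  sequence: ", paste(utils::head(x$codes, 40L), collapse = ""),
      if (length(x$codes) > 40L) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Terminal filler runs of an aligned family
#'
#' In a trend image the gap padding at the start and end of each row is
#' "filler" (drawn gray), distinct from internal alignment gaps (drawn
#' white). This reports, per row, the maximal leading and trailing runs of
#' `-` columns. An all-gap row is attributed entirely to the leading run.
#'
#' @param family An [aligned_family()].
#' @return A data.frame with one row per sequence: `id`, `lead` (number of
#'   leading filler columns) and `trail` (number of trailing filler columns).
#'   As half-open zero-based column ranges these are `[0, lead)` and
#'   `[L - trail, L)`.
#' @export
terminal_filler_mask <- function(family) {
  lead <- integer(family$n)
  trail <- integer(family$n)
  for (i in seq_len(family$n)) {
    cc <- chars(family$rows[i])
    res <- which(cc != "-")
    if (length(res) == 0L) {
      lead[i] <- family$L
      trail[i] <- 0L
    } else {
      lead[i] <- res[1L] - 1L
      trail[i] <- family$L - res[length(res)]
    }
  }
  data.frame(id = family$ids, lead = lead, trail = trail,
             stringsAsFactors = FALSE)
}

#' Logical n x L matrix marking filler cells
#' @noRd
filler_matrix <- function(family) {
  mask <- terminal_filler_mask(family)
  m <- matrix(FALSE, family$n, family$L)
  for (i in seq_len(family$n)) {
    if (mask$lead[i] > 0L) m[i, seq_len(mask$lead[i])] <- TRUE
    if (mask$trail[i] > 0L)
      m[i, (family$L - mask$trail[i] + 1L):family$L] <- TRUE
  }
  m
}

#' Character matrix view of a family (n x L)
#' @noRd
family_matrix <- function(family) {
  matrix(unlist(strsplit(family$rows, "", fixed = TRUE), use.names = FALSE),
         nrow = family$n, ncol = family$L, byrow = TRUE)
}
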