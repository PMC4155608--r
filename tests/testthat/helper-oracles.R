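# Independent oracles and small fixture builders shared across tests.
# The oracles are deliberately naive (pure-R dynamic programs, brute
# enumeration) and never call the code paths they check.

# Brute-force Levenshtein with a pluggable substitution cost. The
# implementation under test is C++; this is the independent R route.
edit_oracle <- function(a, b, sub_cost = NULL) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (is.null(sub_cost))
    sub_cost <- function(x, y) if (x == y && x != "X") 0 else 1
  n <- length(ca); m <- length(cb)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  if (n > 0 && m > 0)
    for (i in 1:n)
      for (j in 1:m)
        D[i + 1, j + 1] <- min(D[i, j] + sub_cost(ca[i], cb[j]),
                               D[i, j + 1] + 1, D[i + 1, j] + 1)
  D[n + 1, m + 1]
}

# Substitution cost of the class-weighted distance, routed through
# classify() rather than the C++ class table.
weighted_cost_fun <- function(scheme) {
  scheme <- get_scheme(scheme)
  function(x, y) {
    if (x == y && x != "X") return(0)
    cx <- classify(scheme, x); cy <- classify(scheme, y)
    if (cx == cy && !cx %in% c("unassigned", "gap")) 0.5 else 1
  }
}

# Random aligned family over the 20 residues plus gaps.
rand_family <- function(n, L, gap_prob = 0.1, alphabet = famtrend:::AA20) {
  rows <- vapply(seq_len(n), function(i) {
    cc <- sample(alphabet, L, replace = TRUE)
    cc[runif(L) < gap_prob] <- "-"
    paste(cc, collapse = "")
  }, character(1))
  aligned_family(sprintf("s%03d", seq_len(n)), rows)
}

# All strings of length 0..max_len over an alphabet.
all_strings <- function(alphabet, max_len) {
  out <- ""
  layer <- ""
  for (l in seq_len(max_len)) {
    layer <- as.vector(outer(layer, alphabet, paste0))
    out <- c(out, layer)
  }
  out
}

# Minimal PDB writer for toy structures. `residues` is a list of lists
# with fields: resn (3-letter), resi, icode (default ""), chain, atoms
# (matrix n x 3), elements (vector), names (atom names).
write_toy_pdb <- function(path, residues) {
  lines <- character(0)
  serial <- 0L
  for (r in residues) {
    icode <- r$icode %||% " "
    if (icode == "") icode <- " "
    atoms <- r$atoms
    for (k in seq_len(nrow(atoms))) {
      serial <- serial + 1L
      name <- (r$names %||% rep(" CA ", nrow(atoms)))[k]
      elem <- (r$elements %||% rep("C", nrow(atoms)))[k]
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s %s%4d%s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, name, r$resn, r$chain, r$resi, icode,
        atoms[k, 1], atoms[k, 2], atoms[k, 3], elem))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small handcrafted family with internal gaps and terminal filler on
# some rows; used by raster and IO tests.
gappy_family <- function() {
  aligned_family(
    c("full", "lead", "trail", "midgap", "short"),
    c("AKCDEFGHKL",
      "--CDEFGHKL",
      "AKCDEFGH--",
      "AKCD--GHKL",
      "---DEFGH--"))
}
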