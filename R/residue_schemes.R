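# Named amino-acid classification schemes and their display colors.
#
# Class memberships are the standard textbook groupings; palettes come from
# the Okabe-Ito colorblind-safe qualitative set. Gap cells are always white,
# terminal filler gray, and residues outside every class black.

# Okabe-Ito qualitative palette (RGB 0-255).
OKABE_ITO <- list(
  orange         = c(230, 159, 0),
  sky_blue       = c(86, 180, 233),
  bluish_green   = c(0, 158, 115),
  yellow         = c(240, 228, 66),
  blue           = c(0, 114, 178),
  vermillion     = c(213, 94, 0),
  reddish_purple = c(204, 121, 167)
)

GAP_COLOR <- c(255L, 255L, 255L)        # white: internal alignment gap
FILLER_COLOR <- c(190L, 190L, 190L)     # gray: terminal padding
UNASSIGNED_COLOR <- c(0L, 0L, 0L)       # black: residue in no class

# Sequential 5-bin palette for the fragment-frequency coloring
# (light -> dark blue; bin edges at 0.2/0.4/0.6/0.8).
FREQ_PALETTE <- rbind(c(239, 243, 255), c(189, 215, 231), c(107, 174, 214),
                      c(49, 130, 189), c(8, 81, 156))
FREQ_BIN_EDGES <- c(0.2, 0.4, 0.6, 0.8)

SCHEME_CLASSES <- list(
  chemical = list(
    aliphatic         = c("G", "A", "V", "L", "I", "P"),
    aromatic          = c("F", "Y", "W"),
    sulfur_containing = c("C", "M"),
    hydroxyl          = c("S", "T"),
    basic             = c("K", "R", "H"),
    acidic_amide      = c("D", "E", "N", "Q")
  ),
  polarity = list(
    nonpolar        = c("G", "A", "V", "L", "I", "P", "F", "M", "W"),
    polar_uncharged = c("S", "T", "C", "Y", "N", "Q"),
    polar_charged   = c("D", "E", "K", "R", "H")
  ),
  charge = list(
    positive = c("K", "R", "H"),
    negative = c("D", "E"),
    neutral  = c("A", "C", "F", "G", "I", "L", "M", "N", "P", "Q",
                 "S", "T", "V", "W", "Y")
  ),
  # hydrophobic side chains (positive Kyte-Doolittle hydropathy) are a
  # reproducible proxy for "buried, little polar-solvent contact"
  solvent_contact = list(
    hydrophobic_buried  = c("A", "V", "L", "I", "M", "F", "C"),
    hydrophilic_exposed = c("R", "N", "D", "E", "Q", "G", "H", "K",
                            "P", "S", "T", "W", "Y")
  )
)

SCHEME_NAMES <- c(names(SCHEME_CLASSES), "fragment_frequency")

#' Retrieve a residue classification scheme
#'
#' Five schemes are available: `chemical` (general chemical character),
#' `polarity` (side-chain polarity), `charge` (side-chain charge),
#' `solvent_contact` (hydropathy proxy for polar-solvent contact) and
#' `fragment_frequency`. The first four partition the 20 standard residues
#' into named classes with one display color each; `fragment_frequency` is
#' not a partition — it colors each trend-image cell by the binned frequency
#' of that cell's residue within its alignment column, using a 5-bin
#' sequential palette with bin edges at 0.2, 0.4, 0.6 and 0.8.
#'
#' In every scheme, gaps display white (255,255,255), terminal filler gray
#' (190,190,190) and unclassified residues (including `X`) black.
#'
#' @param name Scheme name, one of `r paste(SCHEME_NAMES, collapse = ", ")`.
#' @return A list of class `residue_scheme`: `name`, `classes` (named list
#'   of member residue vectors), `colors` (named list of RGB triples, plus
#'   `gap`, `filler`, `unassigned`), and for `fragment_frequency` the bin
#'   `palette` and `bin_edges`.
#' @examples
#' classify(get_scheme("charge"), "K")   # "positive"
#' @export
get_scheme <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% SCHEME_NAMES)
    stop("unknown scheme '", paste(name, collapse = ","),
         "'; valid schemes: ", paste(SCHEME_NAMES, collapse = ", "))
  if (name == "fragment_frequency") {
    sch <- list(name = name, classes = list(),
                colors = list(gap = GAP_COLOR, filler = FILLER_COLOR,
                              unassigned = UNASSIGNED_COLOR),
                palette = FREQ_PALETTE, bin_edges = FREQ_BIN_EDGES)
    return(structure(sch, class = "residue_scheme"))
  }
  classes <- SCHEME_CLASSES[[name]]
  colors <- stats::setNames(OKABE_ITO[seq_along(classes)], names(classes))
  colors$gap <- GAP_COLOR
  colors$filler <- FILLER_COLOR
  colors$unassigned <- UNASSIGNED_COLOR
  structure(list(name = name, classes = classes, colors = colors),
            class = "residue_scheme")
}

#' @export
print.residue_scheme <- function(x, ...) {
  cat("Residue scheme '", x$name, "'\n", sep = "")
  for (cl in names(x$classes))
    cat(sprintf("  %-20s %s\n", cl, paste(x$classes[[cl]], collapse = "")))
  if (x$name == "fragment_frequency")
    cat("  5-bin column-frequency coloring, edges at ",
        paste(x$bin_edges, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Classify one alignment character under a scheme
#'
#' @param scheme A [get_scheme()] result (or a scheme name).
#' @param residue A single alignment character.
#' @return The class name, `"gap"` for `-`, or `"unassigned"` for residues
#'   in no class (always the case for `X`, and for every residue under the
#'   `fragment_frequency` pseudo-scheme).
#' @export
classify <- function(scheme, residue) {
  if (is.character(scheme)) scheme <- get_scheme(scheme)
  if (!is.character(residue) || length(residue) != 1L || nchar(residue) != 1L)
    stop("residue must be a single character")
  if (residue == "-") return("gap")
  for (cl in names(scheme$classes))
    if (residue %in% scheme$classes[[cl]]) return(cl)
  "unassigned"
}

#' Class lookup table: named character vector over the full alphabet
#' @noRd
scheme_class_map <- function(scheme) {
  if (is.character(scheme)) scheme <- get_scheme(scheme)
  map <- stats::setNames(rep("unassigned", length(ALN_ALPHABET)), ALN_ALPHABET)
  map["-"] <- "gap"
  for (cl in names(scheme$classes)) map[scheme$classes[[cl]]] <- cl
  map
}

#' Export a scheme legend as TSV
#'
#' Writes one row per class plus the fixed `gap`, `filler` and `unassigned`
#' entries, with columns `scheme`, `class`, `members`, `R`, `G`, `B`.
#'
#' @param scheme A scheme or scheme name.
#' @param path Output TSV path.
#' @return The legend data.frame, invisibly.
#' @export
write_scheme_legend <- function(scheme, path) {
  df <- scheme_legend(scheme)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Legend rows for a scheme
#' @noRd
scheme_legend <- function(scheme) {
  if (is.character(scheme)) scheme <- get_scheme(scheme)
  rows <- list()
  for (cl in names(scheme$classes)) {
    rgb <- scheme$colors[[cl]]
    rows[[length(rows) + 1L]] <- data.frame(
      scheme = scheme$name, class = cl,
      members = paste(scheme$classes[[cl]], collapse = ""),
      R = rgb[1], G = rgb[2], B = rgb[3], stringsAsFactors = FALSE)
  }
  if (scheme$name == "fragment_frequency") {
    lo <- c(0, scheme$bin_edges)
    hi <- c(scheme$bin_edges, 1)
    for (b in seq_len(nrow(scheme$palette)))
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = scheme$name,
        class = sprintf("freq_bin_%d (%g,%g]", b, lo[b], hi[b]),
        members = "", R = scheme$palette[b, 1], G = scheme$palette[b, 2],
        B = scheme$palette[b, 3], stringsAsFactors = FALSE)
  }
  for (special in c("gap", "filler", "unassigned")) {
    rgb <- scheme$colors[[special]]
    rows[[length(rows) + 1L]] <- data.frame(
      scheme = scheme$name, class = special, members = "",
      R = rgb[1], G = rgb[2], B = rgb[3], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
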