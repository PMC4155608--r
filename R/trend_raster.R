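# The trend image: a pixel-per-residue raster summarizing a whole family.
# Each pixel row is one sequence (top to bottom in the chosen order), each
# pixel column one alignment position. Cell colors follow the scheme's
# class colors; internal gaps are white, terminal filler gray, residues
# outside every class black. Up to two "paddle" column windows can be
# overlaid by darkening.

PADDLE_DARKEN <- 0.7  # multiplicative darkening of paddle-covered pixels

#' Render a trend image
#'
#' @param family An [aligned_family()].
#' @param order A [sort_family()] result, an integer permutation of row
#'   indices, or `NULL` for input order. With a distance-metric
#'   `sort_result` the reference row lands on top.
#' @param scheme A [get_scheme()] scheme or its name (default
#'   `"chemical"`). Use [fragment_frequency_render()] for the
#'   frequency-based coloring.
#' @param row_scale,col_scale Integer pixel scales >= 1 per sequence row /
#'   alignment column.
#' @param paddles List of at most two length-2 inclusive column ranges to
#'   overlay.
#' @return A list of class `trend_raster`: `pixels` (integer array
#'   `height x width x 3`, values 0-255), `order` (row permutation),
#'   `ids` (top-to-bottom), `scheme`, `paddles`, `legend`.
#' @export
render <- function(family, order = NULL, scheme = "chemical",
                   row_scale = 1L, col_scale = 1L, paddles = NULL) {
  if (is.character(scheme)) scheme <- get_scheme(scheme)
  if (scheme$name == "fragment_frequency")
    stop("use fragment_frequency_render() for frequency coloring")
  cmap <- scheme_class_map(scheme)
  # per-character color lookup over the alignment alphabet
  col_of <- vapply(ALN_ALPHABET, function(ch) {
    cl <- cmap[[ch]]
    if (cl == "gap") GAP_COLOR
    else if (cl == "unassigned") UNASSIGNED_COLOR
    else scheme$colors[[cl]]
  }, numeric(3))
  render_grid(family, order, scheme, row_scale, col_scale, paddles,
              function(m, j) col_of[, m[, j], drop = FALSE])
}

#' Render a trend image colored by column residue frequency
#'
#' Each cell is colored by the frequency of its own residue within its
#' alignment column (among non-gap entries), binned into the 5-step
#' sequential palette of the `fragment_frequency` scheme. Gap and filler
#' cells keep the white/gray rules.
#'
#' @inheritParams render
#' @param window Optional length-2 column range overlaid like a paddle.
#' @return A `trend_raster`.
#' @export
fragment_frequency_render <- function(family, order = NULL, window = NULL,
                                      row_scale = 1L, col_scale = 1L) {
  scheme <- get_scheme("fragment_frequency")
  paddles <- if (is.null(window)) NULL else list(window)
  # per-column frequency of each alphabet character among non-gap entries
  freq_col <- function(m, j) {
    col <- m[, j]
    counts <- tabulate(match(col, COUNT_LEVELS), length(COUNT_LEVELS))
    non_gap <- sum(counts)
    out <- matrix(0, 3L, length(col))
    for (i in seq_along(col)) {
      ch <- col[i]
      if (ch == "-") { out[, i] <- GAP_COLOR; next }
      f <- counts[match(ch, COUNT_LEVELS)] / non_gap
      bin <- findInterval(f, scheme$bin_edges, left.open = TRUE) + 1L
      out[, i] <- scheme$palette[bin, ]
    }
    out
  }
  render_grid(family, order, scheme, row_scale, col_scale, paddles, freq_col)
}

#' Shared raster assembly: iterate columns, apply a color function, handle
#' filler, paddles and pixel scaling.
#' @noRd
render_grid <- function(family, order, scheme, row_scale, col_scale,
                        paddles, color_fun) {
  row_scale <- as.integer(row_scale); col_scale <- as.integer(col_scale)
  if (row_scale < 1L || col_scale < 1L) stop("pixel scales must be >= 1")
  perm <- resolve_order(family, order)
  if (!is.null(paddles)) {
    if (!is.list(paddles)) paddles <- list(paddles)
    if (length(paddles) > 2L)
      stop("at most two fragment paddles are supported")
    for (p in paddles)
      if (length(p) != 2L || p[1L] > p[2L] || p[1L] < 1L || p[2L] > family$L)
        stop("paddle windows must be inclusive column ranges within [1, ",
             family$L, "]")
  }
  ordered <- family
  ordered$rows <- family$rows[perm]
  ordered$ids <- family$ids[perm]
  m <- family_matrix(ordered)
  fill <- filler_matrix(ordered)
  grid <- array(0, dim = c(family$n, family$L, 3L))
  for (j in seq_len(family$L)) {
    cols <- color_fun(m, j)              # 3 x n
    f <- fill[, j]
    if (any(f)) cols[, f] <- FILLER_COLOR
    grid[, j, ] <- t(cols)
  }
  if (!is.null(paddles))
    for (p in paddles) {
      jj <- p[1L]:p[2L]
      grid[, jj, ] <- floor(grid[, jj, , drop = FALSE] * PADDLE_DARKEN)
    }
  # scale up to pixels
  px <- grid[rep(seq_len(family$n), each = row_scale),
             rep(seq_len(family$L), each = col_scale), , drop = FALSE]
  structure(list(pixels = px, order = perm, ids = ordered$ids,
                 scheme = scheme$name, paddles = paddles,
                 legend = scheme_legend(scheme)),
            class = "trend_raster")
}

#' @noRd
resolve_order <- function(family, order) {
  if (is.null(order)) return(seq_len(family$n))
  if (inherits(order, "sort_result")) order <- order$order
  order <- as.integer(order)
  if (length(order) != family$n || anyNA(order) ||
      !setequal(order, seq_len(family$n)))
    stop("order must be a permutation of the ", family$n, " row indices")
  order
}

#' @export
print.trend_raster <- function(x, ...) {
  d <- dim(x$pixels)
  cat("Trend raster ", d[1], "x", d[2], " px, scheme '", x$scheme, "'",
      if (!is.null(x$paddles)) paste0(", ", length(x$paddles), " paddle(s)"),
      "\n", sep = "")
  invisible(x)
}

#' Write a trend raster to PNG with sidecar legend and order tables
#'
#' The PNG's decoded pixels equal the raster grid exactly, and rendering is
#' bit-deterministic: the same family, order and scheme give byte-identical
#' files. Alongside `<path>` this writes `<path minus .png>_legend.tsv`
#' (scheme colors) and `<path minus .png>_order.tsv` (rank, id) so the
#' image rows stay interpretable without a GUI.
#'
#' @param raster A [render()] result.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  px <- raster$pixels / 255
  png::writePNG(px, path)
  base <- sub("\\.png$", "", path)
  utils::write.table(raster$legend, paste0(base, "_legend.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(rank = seq_along(raster$ids), id = raster$ids),
    paste0(base, "_order.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PNG back into a 0-255 integer pixel array (testing aid)
#' @param path PNG path.
#' @return Integer array `height x width x 3`.
#' @export
read_raster_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 1L))
  px <- px[, , 1:3, drop = FALSE]
  array(as.integer(round(px * 255)), dim = dim(px))
}
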