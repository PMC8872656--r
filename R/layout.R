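#' Channel layout of the 3 x 4 sensor array
#'
#' Describes how the 12 sensor channels map onto the array grid: three
#' transverse rows (passages) across the artery and four axial positions
#' along it. The default numbering places channels 1-4 on the radial
#' passage (RP), 5-8 on the intermediate passage (IP) and 9-12 on the
#' ulnar passage (UP), counted along the axial direction.
#'
#' @param channel_to_cell integer matrix with 12 rows and columns
#'   `row`, `col` (0-based grid coordinates); row `k` gives the cell of
#'   channel `k`. Defaults to row-major ordering described above.
#' @param row_labels character vector of length 3 naming the passages,
#'   outermost (row 0) first.
#' @return An object of class `channel_layout`.
#' @export
channel_layout <- function(channel_to_cell = NULL,
                           row_labels = c("RP", "IP", "UP")) {
  if (is.null(channel_to_cell)) {
    channel_to_cell <- cbind(row = rep(0:2, each = 4),
                             col = rep(0:3, times = 3))
  }
  channel_to_cell <- as.matrix(channel_to_cell)
  if (nrow(channel_to_cell) != 12L || ncol(channel_to_cell) != 2L)
    stop("channel_to_cell must be a 12 x 2 matrix of (row, col) cells")
  colnames(channel_to_cell) <- c("row", "col")
  key <- paste(channel_to_cell[, 1], channel_to_cell[, 2])
  if (anyDuplicated(key) ||
      !all(channel_to_cell[, 1] %in% 0:2) ||
      !all(channel_to_cell[, 2] %in% 0:3))
    stop("channel_to_cell must be a bijection onto {0,1,2} x {0,1,2,3}")
  row_labels <- as.character(row_labels)
  if (length(row_labels) != 3L || anyDuplicated(row_labels))
    stop("row_labels must be 3 unique passage names")
  structure(list(n_rows = 3L, n_cols = 4L,
                 channel_to_cell = channel_to_cell,
                 row_labels = row_labels),
            class = "channel_layout")
}

#' Channels belonging to one passage
#'
#' @param layout a [channel_layout()].
#' @param label a passage label from `layout$row_labels`.
#' @return Integer channel indices (1-12) on that passage, in axial order.
#' @export
passage_channels <- function(layout, label) {
  r <- match(label, layout$row_labels) - 1L
  if (is.na(r)) stop("unknown passage label: ", label)
  ch <- which(layout$channel_to_cell[, "row"] == r)
  ch[order(layout$channel_to_cell[ch, "col"])]
}

#' Physical footprint of the sensor array
#'
#' The rectangular contact area spanned by the array: `width` across the
#' artery (transverse, the 3 rows) and `length` along it (axial, the
#' 4 columns). The sensor pitch of the hardware is not standardised, so
#' the default is a unit square; physical dimensions scale all volume
#' values linearly and leave ratio features unchanged.
#'
#' @param width,length positive extents in arbitrary length units.
#' @return An object of class `footprint_spec` with the total area
#'   `a_total = width * length`.
#' @export
footprint_spec <- function(width = 1, length = 1) {
  stopifnot(is.finite(width), is.finite(length), width > 0, length > 0)
  structure(list(width = width, length = length, a_total = width * length),
            class = "footprint_spec")
}

#' Per-cell area of the interpolation grid
#'
#' @param footprint a [footprint_spec()].
#' @param n grid size N (the surface is evaluated on an N x N grid).
#' @return `a_total / n^2`, the area element that turns the grid sum into
#'   a Riemann-sum volume.
#' @export
cell_area <- function(footprint, n) {
  stopifnot(n >= 4)
  footprint$a_total / n^2
}

#' @export
print.channel_layout <- function(x, ...) {
  cat("3 x 4 sensor array layout; passages:",
      paste(x$row_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.footprint_spec <- function(x, ...) {
  cat(sprintf("array footprint %g x %g (area %g)\n",
              x$width, x$length, x$a_total))
  invisible(x)
}
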