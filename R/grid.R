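#' Unbiased grid subsampling of traced cells
#'
#' Reproduces the sampling design in which a lattice of 100 um x 100 um
#' squares is superimposed completely over each region tracing, every fourth
#' square is selected (about a quarter of the section), and cells touching a
#' selected square's top or left edge (the forbidden lines of an unbiased
#' counting frame) are excluded to avoid over-sampling.
#'
#' @name grid_sampling
NULL

#' Build a sampling grid over a region outline
#'
#' Lays a lattice of square sampling frames over the bounding box of a traced
#' region outline. Squares are indexed by (col, row) with columns increasing
#' rightwards and rows increasing downwards from the grid origin at the top
#' left, mirroring how a counting grid is read on a microscope section.
#'
#' @param region_outline a [contour] (the region tracing).
#' @param square_size side of a grid square in um (default 100).
#' @param origin_rule `"bbox"` anchors the grid at the bounding box's top-left
#'   corner (deterministic); `"random"` shifts the origin by a uniform
#'   sub-square offset (using the current RNG state), the convention used to
#'   demonstrate sampling unbiasedness.
#' @return an object of class `"sampling_grid"` with fields `origin` (top-left
#'   x, y), `square_size`, `n_cols`, `n_rows`, and (after [select_squares])
#'   `selected`, a two-column matrix of (col, row) indices.
#' @export
build_grid <- function(region_outline, square_size = 100,
                       origin_rule = c("bbox", "random")) {
  stopifnot(is_contour(region_outline), square_size > 0)
  origin_rule <- match.arg(origin_rule)
  xr <- range(region_outline[, 1L])
  yr <- range(region_outline[, 2L])
  x0 <- xr[1L]; y0 <- yr[2L]  # top-left of bounding box
  if (origin_rule == "random") {
    x0 <- x0 - stats::runif(1) * square_size
    y0 <- y0 + stats::runif(1) * square_size
  }
  n_cols <- max(1L, ceiling((xr[2L] - x0) / square_size - 1e-9))
  n_rows <- max(1L, ceiling((y0 - yr[1L]) / square_size - 1e-9))
  structure(
    list(origin = c(x = x0, y = y0), square_size = square_size,
         n_cols = n_cols, n_rows = n_rows, selected = NULL),
    class = "sampling_grid"
  )
}

#' @export
print.sampling_grid <- function(x, ...) {
  cat(sprintf("<sampling_grid: %d x %d squares of %g um, %s>\n",
              x$n_cols, x$n_rows, x$square_size,
              if (is.null(x$selected)) "none selected"
              else sprintf("%d selected", nrow(x$selected))))
  invisible(x)
}

#' Select every fourth square of a sampling grid
#'
#' Marks every fourth square in row-major order, with the row-start offset
#' cycling by one column per row so that selected squares fall on diagonals
#' rather than aligned columns: square (col, row) is selected when
#' `(col - 1) + (row - 1)` is divisible by 4. This samples ~25% of the grid
#' without stripe artifacts.
#'
#' @param grid a [build_grid] result.
#' @return the grid with `selected` filled in (always at least one square).
#' @export
select_squares <- function(grid) {
  stopifnot(inherits(grid, "sampling_grid"))
  idx <- expand.grid(col = seq_len(grid$n_cols), row = seq_len(grid$n_rows))
  sel <- ((idx$col - 1L) + (idx$row - 1L)) %% 4L == 0L
  grid$selected <- as.matrix(idx[sel, , drop = FALSE])
  if (nrow(grid$selected) == 0L) {
    grid$selected <- matrix(c(1L, 1L), 1L, dimnames = list(NULL, c("col", "row")))
  }
  rownames(grid$selected) <- NULL
  grid
}

# square index containing a point; boundary points fall in the square whose
# left/top edge they lie on (the square to the right / below the shared edge)
square_of <- function(x, y, grid) {
  s <- grid$square_size
  col <- floor((x - grid$origin[["x"]]) / s + 1e-12) + 1L
  row <- floor((grid$origin[["y"]] - y) / s + 1e-12) + 1L
  cbind(col = as.integer(col), row = as.integer(row))
}

# does a closed contour intersect or touch the segment (x1,y1)-(x2,y2)?
contour_touches_segment <- function(c, x1, y1, x2, y2) {
  n <- nrow(c)
  p <- unclass(c)
  q <- p[c(2:n, 1L), , drop = FALSE]
  a1 <- matrix(c(x1, y1), n, 2, byrow = TRUE)
  a2 <- matrix(c(x2, y2), n, 2, byrow = TRUE)
  if (any(segments_cross(a1, a2, p, q))) return(TRUE)
  # segment entirely inside the contour (no edge crossing)
  all(point_in_contour(c(x1, x2), c(y1, y2), c))
}

#' Apply the counting-frame rule to a set of cell markers
#'
#' Each marker is assigned to the single grid square containing its position.
#' A cell is sampled when that square is selected and, if contour-based
#' exclusion is on, its traced outline neither crosses nor touches the
#' square's top edge or left edge (the forbidden lines); the right and bottom
#' edges are acceptance edges, so cells straddling those are kept.
#'
#' @param markers a data frame with columns `x_um`, `y_um`, and (when
#'   `use_contours = TRUE`) a `contour` list-column of [contour] objects.
#' @param grid a [select_squares]-processed grid.
#' @param use_contours apply forbidden-line exclusion using the full traced
#'   outline (default). With `FALSE`, the marker point alone decides, the mode
#'   used for point-process unbiasedness checks.
#' @return the sampled rows of `markers`, with audit columns `sq_col`,
#'   `sq_row` appended.
#' @export
sample_cells <- function(markers, grid, use_contours = TRUE) {
  stopifnot(inherits(grid, "sampling_grid"))
  if (is.null(grid$selected)) stop("grid has no selected squares; call select_squares() first")
  markers <- tibble::as_tibble(markers)
  sq <- square_of(markers$x_um, markers$y_um, grid)
  key <- paste(sq[, "col"], sq[, "row"])
  sel_key <- paste(grid$selected[, "col"], grid$selected[, "row"])
  in_sel <- key %in% sel_key
  keep <- in_sel
  if (use_contours && any(in_sel)) {
    if (!"contour" %in% names(markers)) {
      stop("contour-based exclusion requested but markers have no 'contour' column")
    }
    s <- grid$square_size
    for (i in which(in_sel)) {
      cont <- markers$contour[[i]]
      if (is.null(cont)) stop("marker ", i, " has no contour; required for forbidden-line exclusion")
      xl <- grid$origin[["x"]] + (sq[i, "col"] - 1L) * s
      yt <- grid$origin[["y"]] - (sq[i, "row"] - 1L) * s
      hit_top <- contour_touches_segment(cont, xl, yt, xl + s, yt)
      hit_left <- contour_touches_segment(cont, xl, yt, xl, yt - s)
      if (hit_top || hit_left) keep[i] <- FALSE
    }
  }
  out <- markers[keep, , drop = FALSE]
  out$sq_col <- sq[keep, "col"]
  out$sq_row <- sq[keep, "row"]
  out
}
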