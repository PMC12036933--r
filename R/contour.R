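#' Closed planar contours for soma morphometry
#'
#' A contour is an ordered list of (x, y) vertices in micrometres describing a
#' closed, simple (non-self-intersecting) polygon: the outline of a traced cell
#' soma or of a tissue-region cross-section. Contours are stored *open* (the
#' closing edge from the last vertex back to the first is implicit) and with
#' positive (counter-clockwise) orientation.
#'
#' @name contour
NULL

#' Normalize raw traced vertices into a contour
#'
#' Takes raw tracing output (a two-column matrix or data frame of x/y
#' coordinates in um) and returns a validated contour: consecutive duplicate
#' vertices are dropped, a duplicated closing vertex (last == first) is
#' removed, and orientation is normalized counter-clockwise. Degenerate input
#' (fewer than 3 distinct vertices, zero area) and self-intersecting outlines
#' are rejected rather than repaired, since silent repair would bias the
#' downstream morphometrics.
#'
#' @param raw_vertices two-column matrix/data frame of vertex coordinates (um),
#'   ordered along the outline.
#' @param check_simple if `TRUE` (default) reject self-intersecting polygons.
#' @return an object of class `"contour"`: an n x 2 numeric matrix with
#'   columns `x`, `y`.
#' @examples
#' sq <- normalize_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' contour_area(sq)
#' @export
normalize_contour <- function(raw_vertices, check_simple = TRUE) {
  xy <- as.matrix(raw_vertices)
  if (ncol(xy) != 2L) stop("invalid contour: vertices must have two columns (x, y)")
  storage.mode(xy) <- "double"
  if (anyNA(xy) || any(!is.finite(xy))) stop("invalid contour: non-finite coordinates")

  # drop consecutive duplicates (including the wrap-around closing duplicate)
  n <- nrow(xy)
  if (n >= 2L) {
    keep <- c(TRUE, rowSums(abs(xy[-1L, , drop = FALSE] - xy[-n, , drop = FALSE])) > 0)
    xy <- xy[keep, , drop = FALSE]
  }
  n <- nrow(xy)
  if (n >= 2L && all(xy[n, ] == xy[1L, ])) xy <- xy[-n, , drop = FALSE]

  if (nrow(xy) < 3L) stop("invalid contour: fewer than 3 distinct vertices")

  a2 <- signed_area2(xy)
  if (abs(a2) < 1e-12 * max(1, max(abs(xy))^2)) {
    stop("invalid contour: degenerate (zero area)")
  }
  if (a2 < 0) xy <- xy[nrow(xy):1L, , drop = FALSE]

  if (check_simple && !is_simple_polygon(xy)) {
    stop("invalid contour: self-intersecting outline")
  }
  new_contour(xy)
}

# constructor without validation; for generated contours known to be simple
new_contour <- function(xy) {
  dimnames(xy) <- list(NULL, c("x", "y"))
  class(xy) <- c("contour", "matrix", "array")
  xy
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour: %d vertices, area %.2f um^2, perimeter %.2f um>\n",
              nrow(x), contour_area(x), contour_perimeter(x)))
  invisible(x)
}

is_contour <- function(x) inherits(x, "contour")

# twice the signed area (shoelace); positive for counter-clockwise
signed_area2 <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y)
}

# Simplicity test: no two non-adjacent edges intersect or touch. Edge pairs are
# pre-filtered by bounding-interval overlap on x (sorted sweep) so smooth
# outlines with thousands of vertices stay near-linear.
is_simple_polygon <- function(xy) {
  n <- nrow(xy)
  p <- xy
  q <- xy[c(2:n, 1L), , drop = FALSE]
  lo <- pmin(p[, 1L], q[, 1L]); hi <- pmax(p[, 1L], q[, 1L])
  ord <- order(lo)
  lo_s <- lo[ord]; hi_s <- hi[ord]
  # for each edge (in lo order), candidate partners are later edges whose lo
  # does not exceed this edge's hi
  upper <- findInterval(hi_s, lo_s)
  cnt <- pmax(0L, upper - seq_len(n))
  if (sum(cnt) == 0) return(TRUE)
  i_idx <- rep.int(seq_len(n), cnt)
  j_idx <- i_idx + sequence(cnt)
  ei <- ord[i_idx]; ej <- ord[j_idx]
  # drop adjacent edges (share a vertex), including the 1/n wrap pair
  d <- abs(ei - ej)
  keep <- d > 1L & d < (n - 1L)
  if (!any(keep)) return(TRUE)
  ei <- ei[keep]; ej <- ej[keep]
  # y-interval prefilter
  ylo <- pmin(p[, 2L], q[, 2L]); yhi <- pmax(p[, 2L], q[, 2L])
  keep <- ylo[ei] <= yhi[ej] & ylo[ej] <= yhi[ei]
  if (!any(keep)) return(TRUE)
  ei <- ei[keep]; ej <- ej[keep]
  !any(segments_cross(p[ei, , drop = FALSE], q[ei, , drop = FALSE],
                      p[ej, , drop = FALSE], q[ej, , drop = FALSE]))
}

# vectorized segment intersection (touching counts as crossing);
# a1->a2 and b1->b2 are matrices of endpoints, one segment per row
segments_cross <- function(a1, a2, b1, b2) {
  cr <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  d1 <- cr(a1[, 1], a1[, 2], a2[, 1], a2[, 2], b1[, 1], b1[, 2])
  d2 <- cr(a1[, 1], a1[, 2], a2[, 1], a2[, 2], b2[, 1], b2[, 2])
  d3 <- cr(b1[, 1], b1[, 2], b2[, 1], b2[, 2], a1[, 1], a1[, 2])
  d4 <- cr(b1[, 1], b1[, 2], b2[, 1], b2[, 2], a2[, 1], a2[, 2])
  proper <- (d1 * d2 < 0) & (d3 * d4 < 0)
  on_seg <- function(px, py, ax, ay, bx, by, d) {
    d == 0 & px >= pmin(ax, bx) & px <= pmax(ax, bx) &
      py >= pmin(ay, by) & py <= pmax(ay, by)
  }
  touch <- on_seg(b1[, 1], b1[, 2], a1[, 1], a1[, 2], a2[, 1], a2[, 2], d1) |
    on_seg(b2[, 1], b2[, 2], a1[, 1], a1[, 2], a2[, 1], a2[, 2], d2) |
    on_seg(a1[, 1], a1[, 2], b1[, 1], b1[, 2], b2[, 1], b2[, 2], d3) |
    on_seg(a2[, 1], a2[, 2], b1[, 1], b1[, 2], b2[, 1], b2[, 2], d4)
  proper | touch
}

#' Contour area
#'
#' Shoelace area of the closed polygon, in um^2.
#' @param c a [contour].
#' @return positive scalar area (um^2).
#' @export
contour_area <- function(c) {
  stopifnot(is_contour(c))
  signed_area2(c) / 2
}

#' Contour perimeter
#'
#' Sum of edge lengths including the implicit closing edge, in um.
#' @param c a [contour].
#' @return positive scalar perimeter (um).
#' @export
contour_perimeter <- function(c) {
  stopifnot(is_contour(c))
  n <- nrow(c)
  d <- c[c(2:n, 1L), , drop = FALSE] - c
  sum(sqrt(rowSums(d^2)))
}

# convex hull vertices in counter-clockwise order
convex_hull <- function(c) {
  h <- grDevices::chull(c[, 1L], c[, 2L])
  c[rev(h), , drop = FALSE]
}

# hull size below which the exact all-pairs / all-edges sweep (vectorized,
# O(h^2) but in C) beats the O(h) interpreted calipers scan
.CALIPER_SWITCH <- 400L

#' Maximum Feret diameter
#'
#' The maximum distance between any two points of the contour (the caliper
#' diameter), computed on the convex hull, where it is attained: for typical
#' hull sizes by an exact vectorized scan over hull vertex pairs, for very
#' fine hulls by a rotating-calipers pass over antipodal pairs (O(h)). Both
#' paths give the exact hull diameter.
#'
#' @param c a [contour].
#' @return maximum Feret diameter (um).
#' @export
feret_max <- function(c) {
  stopifnot(is_contour(c))
  H <- convex_hull(c)
  h <- nrow(H)
  if (h == 2L) return(sqrt(sum((H[1L, ] - H[2L, ])^2)))
  if (h <= .CALIPER_SWITCH) return(max(stats::dist(H)))
  x <- H[, 1L]; y <- H[, 2L]
  tri2 <- function(i, j, k) (x[j] - x[i]) * (y[k] - y[i]) - (y[j] - y[i]) * (x[k] - x[i])
  d2 <- function(i, j) (x[i] - x[j])^2 + (y[i] - y[j])^2
  best <- 0
  k <- 2L
  for (i in seq_len(h)) {
    ii <- if (i == h) 1L else i + 1L
    guard <- 0L
    repeat {
      kn <- if (k == h) 1L else k + 1L
      if (tri2(i, ii, kn) > tri2(i, ii, k) && guard < 2L * h) {
        k <- kn; guard <- guard + 1L
      } else break
    }
    best <- max(best, d2(i, k), d2(ii, k))
  }
  sqrt(best)
}

#' Minimum Feret diameter
#'
#' The minimum distance between two parallel supporting lines that enclose the
#' contour (the minimum width). The minimum is attained with one line flush
#' against a convex-hull edge; for typical hull sizes every edge's width (max
#' perpendicular distance of hull vertices from the edge line) is evaluated in
#' one vectorized sweep, and very fine hulls use a rotating-calipers scan.
#' Both paths give the exact hull width.
#'
#' @param c a [contour].
#' @return minimum Feret diameter (um).
#' @export
feret_min <- function(c) {
  stopifnot(is_contour(c))
  H <- convex_hull(c)
  h <- nrow(H)
  if (h == 2L) return(0)
  if (h <= .CALIPER_SWITCH) {
    x <- H[, 1L]; y <- H[, 2L]
    ex <- c(x[-1L], x[1L]) - x; ey <- c(y[-1L], y[1L]) - y
    len <- sqrt(ex^2 + ey^2)
    ok <- len > 0
    # cross(e_i, p_k - p_i) for all edges i x vertices k
    cr <- tcrossprod(ex, y) - tcrossprod(ey, x) + (ey * x - ex * y)
    cr <- cr[ok, , drop = FALSE]
    jmax <- max.col(cr, ties.method = "first")
    widths <- cr[cbind(seq_along(jmax), jmax)] / len[ok]
    return(min(widths))
  }
  x <- H[, 1L]; y <- H[, 2L]
  # perpendicular distance (times edge length) of hull point k from edge i->ii
  cross_e <- function(i, ii, k) (x[ii] - x[i]) * (y[k] - y[i]) - (y[ii] - y[i]) * (x[k] - x[i])
  width <- Inf
  j <- 2L
  for (i in seq_len(h)) {
    ii <- if (i == h) 1L else i + 1L
    elen <- sqrt((x[ii] - x[i])^2 + (y[ii] - y[i])^2)
    if (elen == 0) next
    guard <- 0L
    repeat {
      jn <- if (j == h) 1L else j + 1L
      if (cross_e(i, ii, jn) > cross_e(i, ii, j) && guard < 2L * h) {
        j <- jn; guard <- guard + 1L
      } else break
    }
    width <- min(width, cross_e(i, ii, j) / elen)
  }
  width
}

#' Soma shape descriptors
#'
#' Computes the nine per-cell morphometric measurements on a traced soma
#' contour: area (um^2), perimeter (um), maximum and minimum Feret diameters
#' (um), and five dimensionless descriptors:
#'
#' * `aspect_ratio = feret_min / feret_max` — flatness; 1 for a circle,
#'   smaller for flatter (more oval) somata.
#' * `compactness = sqrt(4 * area / pi) / feret_max` — 1 for a circle,
#'   smaller when the area is small relative to the maximum diameter.
#' * `roundness = 4 * area / (pi * feret_max^2)` — the square of compactness;
#'   spreads out contours with small compactness values.
#' * `shape_factor = perimeter / sqrt(area)` — large-scale outline
#'   convolution; minimal (2*sqrt(pi) ~ 3.54) for a circle.
#' * `form_factor = 4 * pi * area / perimeter^2` — fine-scale boundary
#'   roughness; 1 for a smooth circle, < 1 for rough outlines.
#'
#' @param c a [contour].
#' @return a one-row [tibble::tibble] with columns `area`, `perimeter`,
#'   `feret_max`, `feret_min`, `aspect_ratio`, `compactness`, `roundness`,
#'   `shape_factor`, `form_factor`.
#' @examples
#' soma_metrics(regular_polygon(256))
#' @export
soma_metrics <- function(c) {
  stopifnot(is_contour(c))
  a <- contour_area(c)
  if (!is.finite(a) || a <= 0) stop("invalid contour: degenerate (zero area)")
  p <- contour_perimeter(c)
  fmax <- feret_max(c)
  fmin <- feret_min(c)
  tibble::tibble(
    area = a,
    perimeter = p,
    feret_max = fmax,
    feret_min = fmin,
    aspect_ratio = fmin / fmax,
    compactness = sqrt(4 * a / pi) / fmax,
    roundness = 4 * a / (pi * fmax^2),
    shape_factor = p / sqrt(a),
    form_factor = 4 * pi * a / p^2
  )
}

#' Regular polygon contour
#'
#' Convenience constructor for a regular n-gon inscribed in a circle; with
#' large `n` this is the discretized-circle reference shape whose descriptors
#' approach the circular anchors (form factor 1, shape factor 2*sqrt(pi)).
#'
#' @param n number of vertices (>= 3).
#' @param radius circumradius in um.
#' @param center numeric length-2 center.
#' @return a [contour].
#' @export
regular_polygon <- function(n, radius = 1, center = c(0, 0)) {
  stopifnot(n >= 3, radius > 0)
  th <- 2 * pi * (seq_len(n) - 1L) / n
  new_contour(cbind(center[1] + radius * cos(th), center[2] + radius * sin(th)))
}

# vectorized even-odd point-in-polygon (ray casting); boundary points may fall
# either side at double precision — callers needing strict containment keep
# points away from the boundary
point_in_contour <- function(px, py, c) {
  x <- c[, 1L]; y <- c[, 2L]
  n <- length(x)
  xj <- c(x[n], x[-n]); yj <- c(y[n], y[-n])
  inside <- logical(length(px))
  for (k in seq_len(n)) {
    crosses <- ((y[k] > py) != (yj[k] > py)) &
      (px < (xj[k] - x[k]) * (py - y[k]) / (yj[k] - y[k]) + x[k])
    inside <- xor(inside, crosses)
  }
  inside
}
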