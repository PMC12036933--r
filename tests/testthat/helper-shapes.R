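# Shared fixtures and independent oracles for the geometry tests.
# Oracles are deliberately naive (brute force / enumeration) and never share
# code with the implementation paths they check.

# random star-shaped (hence simple) polygon around the origin; angular gaps
# are kept below pi so no chord can swing past the centre
random_star_polygon <- function(n_vertices, r_range = c(0.5, 1.5)) {
  th <- (seq_len(n_vertices) - stats::runif(n_vertices, 0, 0.95)) *
    2 * pi / n_vertices
  r <- stats::runif(n_vertices, r_range[1], r_range[2])
  normalize_contour(cbind(r * cos(th), r * sin(th)))
}

# O(n^2) all-vertex-pairs maximum distance
oracle_feret_max <- function(c) max(stats::dist(unclass(c)))

# minimum projection width over a fine angular sweep augmented with the exact
# hull edge-normal directions (the width minimum sits at an edge-flush
# direction, where the width function has a kink; a pure grid sweep has only
# first-order accuracy there)
oracle_feret_min <- function(c, n_angles = 3600) {
  xy <- unclass(c)
  h <- xy[grDevices::chull(xy[, 1], xy[, 2]), , drop = FALSE]
  e <- rbind(h[-1, , drop = FALSE], h[1, , drop = FALSE]) - h
  normals <- atan2(e[, 2], e[, 1]) + pi / 2
  ang <- c(seq(0, pi, length.out = n_angles), normals %% pi)
  min(vapply(ang, function(a) {
    diff(range(xy %*% c(cos(a), sin(a))))
  }, numeric(1)))
}

# fan-triangulation area from vertex 1 (valid for any simple polygon given
# positive orientation when summed with signs)
oracle_area <- function(c) {
  xy <- unclass(c)
  n <- nrow(xy)
  s <- 0
  for (i in 2:(n - 1)) {
    v1 <- xy[i, ] - xy[1, ]
    v2 <- xy[i + 1, ] - xy[1, ]
    s <- s + (v1[1] * v2[2] - v1[2] * v2[1]) / 2
  }
  unname(s)
}

# pairwise edge-length summation
oracle_perimeter <- function(c) {
  xy <- unclass(c)
  n <- nrow(xy)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + sqrt(sum((xy[i, ] - xy[j, ])^2))
  }
  s
}

# rigid motion of a contour
rotate_translate <- function(c, angle, shift) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  normalize_contour(sweep(unclass(c) %*% t(R), 2, shift, "+"), check_simple = FALSE)
}

# section areas of a sphere of radius r_mm sliced every (thickness * interval)
sphere_section_areas <- function(r_mm, thickness_um = 6, interval = 8,
                                 offset_frac = 0.5) {
  step <- thickness_um * interval / 1000  # mm
  z <- seq(-r_mm + offset_frac * step, r_mm, by = step)
  areas <- pi * (r_mm^2 - z^2)
  areas[areas > 0]
}
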