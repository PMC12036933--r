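# brute-force application of the counting rule used as the oracle in the
# toy-section test: marker in a selected square, contour clear of its top and
# left edges
manual_rule <- function(markers, grid) {
  s <- grid$square_size
  keep <- logical(nrow(markers))
  for (i in seq_len(nrow(markers))) {
    col <- floor((markers$x_um[i] - grid$origin[["x"]]) / s) + 1
    row <- floor((grid$origin[["y"]] - markers$y_um[i]) / s) + 1
    sel <- any(grid$selected[, "col"] == col & grid$selected[, "row"] == row)
    if (!sel) next
    xl <- grid$origin[["x"]] + (col - 1) * s
    yt <- grid$origin[["y"]] - (row - 1) * s
    v <- unclass(markers$contour[[i]])
    # dense resampling of the outline against the two forbidden edges
    n <- nrow(v)
    t <- seq(0, 1, length.out = 20)
    pts <- do.call(rbind, lapply(seq_len(n), function(k) {
      j <- if (k == n) 1 else k + 1
      cbind(v[k, 1] + t * (v[j, 1] - v[k, 1]), v[k, 2] + t * (v[j, 2] - v[k, 2]))
    }))
    hits_top <- any(abs(pts[, 2] - yt) < 1e-9 & pts[, 1] >= xl & pts[, 1] <= xl + s) ||
      any(pts[, 2] > yt & pts[, 1] >= xl & pts[, 1] <= xl + s)
    hits_left <- any(abs(pts[, 1] - xl) < 1e-9 & pts[, 2] <= yt & pts[, 2] >= yt - s) ||
      any(pts[, 1] < xl & pts[, 2] <= yt & pts[, 2] >= yt - s)
    keep[i] <- !(hits_top || hits_left)
  }
  keep
}

small_circle <- function(x, y, r = 3) {
  th <- 2 * pi * (0:23) / 24
  normalize_contour(cbind(x + r * cos(th), y + r * sin(th)), check_simple = FALSE)
}

test_that("grid dimensions cover the region bounding box", {
  box <- normalize_contour(cbind(c(0, 250, 250, 0), c(0, 0, 150, 150)))
  g <- build_grid(box, 100)
  expect_equal(c(g$n_cols, g$n_rows), c(3, 2))

  small <- normalize_contour(cbind(c(10, 60, 60, 10), c(10, 10, 70, 70)))
  g2 <- build_grid(small, 100)
  expect_equal(c(g2$n_cols, g2$n_rows), c(1, 1))

  big <- normalize_contour(cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000)))
  g3 <- select_squares(build_grid(big, 100))
  expect_equal(c(g3$n_cols, g3$n_rows), c(10, 10))
  expect_equal(nrow(g3$selected), 25)
})

test_that("every-fourth-square selection has the declared pattern", {
  box_of <- function(w, h) {
    normalize_contour(cbind(c(0, w, w, 0), c(0, 0, h, h)))
  }
  g41 <- select_squares(build_grid(box_of(400, 100), 100))
  expect_equal(nrow(g41$selected), 1)

  g21 <- select_squares(build_grid(box_of(200, 100), 100))
  expect_equal(nrow(g21$selected), 1)

  g82 <- select_squares(build_grid(box_of(800, 200), 100))
  expect_equal(nrow(g82$selected), 4)
  # per-row offsets prevent column alignment
  expect_gt(length(unique(g82$selected[, "col"])), 2)

  # selection fraction near a quarter on representative grids
  for (dims in list(c(4, 2), c(7, 3), c(10, 10), c(12, 5))) {
    g <- select_squares(build_grid(box_of(dims[1] * 100, dims[2] * 100), 100))
    frac <- nrow(g$selected) / (g$n_cols * g$n_rows)
    expect_gte(frac, 0.2)
    expect_lte(frac, 0.3)
  }
})

test_that("forbidden-line rule includes interior cells and excludes edge-touchers", {
  box <- normalize_contour(cbind(c(0, 400, 400, 0), c(0, 0, 400, 400)))
  g <- select_squares(build_grid(box, 100))
  # square (1,1) is selected: spans x 0-100, y 300-400
  inside <- tibble::tibble(cell_id = "a", x_um = 50, y_um = 350,
                           contour = list(small_circle(50, 350)))
  expect_equal(nrow(sample_cells(inside, g)), 1)

  crossing_top <- tibble::tibble(cell_id = "b", x_um = 50, y_um = 399,
                                 contour = list(small_circle(50, 399)))
  expect_equal(nrow(sample_cells(crossing_top, g)), 0)

  crossing_left <- tibble::tibble(cell_id = "c", x_um = 2, y_um = 350,
                                  contour = list(small_circle(2, 350)))
  expect_equal(nrow(sample_cells(crossing_left, g)), 0)

  # right/bottom are acceptance edges
  crossing_right <- tibble::tibble(cell_id = "d", x_um = 99, y_um = 350,
                                   contour = list(small_circle(99, 350)))
  expect_equal(nrow(sample_cells(crossing_right, g)), 1)

  expect_error(sample_cells(inside[, c("cell_id", "x_um", "y_um")], g),
               "no 'contour'")
})

test_that("sampled set equals exhaustive manual application of the rule", {
  box <- normalize_contour(cbind(c(0, 400, 400, 0), c(0, 0, 400, 400)))
  g <- select_squares(build_grid(box, 100))
  set.seed(55)
  mk <- tibble::tibble(
    cell_id = sprintf("c%02d", 1:12),
    x_um = runif(12, 5, 395), y_um = runif(12, 5, 395))
  mk$contour <- lapply(seq_len(12), function(i) {
    small_circle(mk$x_um[i], mk$y_um[i], r = runif(1, 2, 6))
  })
  got <- sample_cells(mk, g)
  expect_equal(got$cell_id, mk$cell_id[manual_rule(mk, g)])
  # determinism
  expect_identical(sample_cells(mk, g)$cell_id, got$cell_id)
})

test_that("point sampling is unbiased: sampled fraction matches selected fraction", {
  box <- normalize_contour(cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000)))
  set.seed(77)
  fracs <- replicate(500, {
    g <- select_squares(build_grid(box, 100, origin_rule = "random"))
    n <- 200
    mk <- tibble::tibble(x_um = runif(n, 0, 1000), y_um = runif(n, 0, 1000))
    sel_frac <- nrow(g$selected) / (g$n_cols * g$n_rows)
    nrow(sample_cells(mk, g, use_contours = FALSE)) / n - sel_frac
  })
  # mean deviation from the selected fraction is within Monte-Carlo error
  expect_lt(abs(mean(fracs)), 3 * sd(fracs) / sqrt(length(fracs)) + 0.005)
})

test_that("each cell is evaluated against exactly one square", {
  box <- normalize_contour(cbind(c(0, 400, 400, 0), c(0, 0, 400, 400)))
  g <- select_squares(build_grid(box, 100))
  # a marker exactly on an interior corner falls in exactly one square
  mk <- tibble::tibble(x_um = c(100, 200), y_um = c(300, 200))
  got <- sample_cells(mk, g, use_contours = FALSE)
  sq <- somamorph:::square_of(mk$x_um, mk$y_um, g)
  expect_equal(nrow(sq), 2)
  expect_true(all(sq[, "col"] %in% 1:4 & sq[, "row"] %in% 1:4))
})
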