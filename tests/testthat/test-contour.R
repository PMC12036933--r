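test_that("normalization closes, dedups and orients raw tracings", {
  # clockwise square becomes counter-clockwise (positive area)
  cw <- cbind(c(0, 0, 1, 1), c(0, 1, 1, 0))
  c1 <- normalize_contour(cw)
  expect_equal(nrow(c1), 4)
  expect_gt(somamorph:::signed_area2(c1), 0)

  # duplicated closing vertex and consecutive duplicates are dropped
  c2 <- normalize_contour(cbind(c(0, 1, 1, 1, 0, 0), c(0, 0, 0, 1, 1, 0)))
  expect_equal(nrow(c2), 4)

  expect_error(normalize_contour(cbind(c(0, 1), c(0, 1))), "fewer than 3")
  expect_error(normalize_contour(cbind(c(0, 1, 2), c(0, 0, 0))), "degenerate")
  # bow-tie quadrilaterals are rejected: the symmetric one degenerates to
  # zero net area, the skewed one is caught by the crossing test
  expect_error(normalize_contour(cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))),
               "invalid contour")
  expect_error(normalize_contour(cbind(c(0, 2, 2, 0), c(0, 2, 0, 1))),
               "self-intersect")
})

test_that("area and perimeter match closed forms and naive oracles", {
  sq <- normalize_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(contour_area(sq), 1)
  expect_equal(contour_perimeter(sq), 4)
  rect <- normalize_contour(cbind(c(0, 2, 2, 0), c(0, 0, 1, 1)))
  expect_equal(contour_area(rect), 2)

  # fine regular polygon approaches the circle perimeter
  expect_equal(contour_perimeter(regular_polygon(10000)), 2 * pi,
               tolerance = 1e-6)

  set.seed(101)
  for (i in 1:20) {
    c0 <- random_star_polygon(12)
    expect_equal(contour_area(c0), oracle_area(c0), tolerance = 1e-12)
    expect_equal(contour_perimeter(c0), oracle_perimeter(c0), tolerance = 1e-12)
  }
})

test_that("Feret diameters equal brute-force oracles on random polygons", {
  sq <- normalize_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(feret_max(sq), sqrt(2))
  expect_equal(feret_min(sq), 1)
  rect <- normalize_contour(cbind(c(0, 2, 2, 0), c(0, 0, 1, 1)))
  expect_equal(feret_min(rect), 1)
  expect_equal(feret_max(regular_polygon(2000, radius = 3)), 6, tolerance = 1e-5)

  set.seed(202)
  for (i in 1:50) {
    c0 <- random_star_polygon(sample(5:50, 1))
    expect_equal(feret_max(c0), oracle_feret_max(c0), tolerance = 1e-12)
    expect_equal(feret_min(c0), oracle_feret_min(c0), tolerance = 1e-9)
  }
})

test_that("caliper scan for fine hulls agrees with the vectorized hull sweep", {
  # hulls above the switch threshold take the O(h) rotating-calipers path;
  # compare both paths on the same shapes
  set.seed(7)
  for (i in 1:5) {
    th <- 2 * pi * (0:999) / 1000
    r <- 1 + 0.05 * cos(3 * th + runif(1, 0, 2 * pi))
    c0 <- normalize_contour(cbind(1.4 * r * cos(th), r * sin(th)),
                            check_simple = FALSE)
    expect_gt(nrow(unclass(c0)[grDevices::chull(c0), , drop = FALSE]),
              somamorph:::.CALIPER_SWITCH)
    expect_equal(feret_max(c0), oracle_feret_max(c0), tolerance = 1e-12)
    expect_equal(feret_min(c0), oracle_feret_min(c0), tolerance = 1e-9)
  }
})

test_that("descriptors reproduce the circle and square anchor values", {
  m <- soma_metrics(regular_polygon(12000, radius = 5.3))
  expect_equal(round(m$shape_factor, 2), 3.54)
  expect_equal(m$form_factor, 1, tolerance = 1e-3)
  expect_equal(m$compactness, 1, tolerance = 1e-3)
  expect_equal(m$roundness, 1, tolerance = 1e-3)
  expect_equal(m$aspect_ratio, 1, tolerance = 1e-3)

  sq <- normalize_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  ms <- soma_metrics(sq)
  expect_equal(ms$area, 1)
  expect_equal(ms$perimeter, 4)
  expect_equal(ms$feret_max, sqrt(2))
  expect_equal(ms$feret_min, 1)
  expect_equal(ms$aspect_ratio, 1 / sqrt(2))
  expect_equal(ms$compactness, sqrt(2 / pi))
  expect_equal(ms$roundness, 2 / pi)
  expect_equal(ms$shape_factor, 4)
  expect_equal(ms$form_factor, pi / 4)
})

test_that("metrics are rigid-motion invariant and scale covariant", {
  set.seed(303)
  for (i in 1:10) {
    c0 <- random_star_polygon(24)
    m0 <- soma_metrics(c0)
    m1 <- soma_metrics(rotate_translate(c0, runif(1, 0, 2 * pi),
                                        runif(2, -50, 50)))
    expect_equal(as.numeric(m1), as.numeric(m0), tolerance = 1e-9)

    s <- runif(1, 0.2, 5)
    m2 <- soma_metrics(normalize_contour(unclass(c0) * s, check_simple = FALSE))
    expect_equal(m2$area, m0$area * s^2, tolerance = 1e-12)
    expect_equal(m2$perimeter, m0$perimeter * s, tolerance = 1e-12)
    expect_equal(m2$feret_max, m0$feret_max * s, tolerance = 1e-12)
    expect_equal(m2$feret_min, m0$feret_min * s, tolerance = 1e-12)
    dimless <- c("aspect_ratio", "compactness", "roundness",
                 "shape_factor", "form_factor")
    expect_equal(as.numeric(m2[dimless]), as.numeric(m0[dimless]),
                 tolerance = 1e-9)
  }
})

test_that("descriptor identities and isoperimetric bounds hold", {
  set.seed(404)
  for (i in 1:30) {
    m <- soma_metrics(random_star_polygon(sample(6:40, 1)))
    expect_equal(m$roundness, m$compactness^2, tolerance = 1e-9)
    expect_lte(m$form_factor, 1)
    expect_gte(m$shape_factor, 2 * sqrt(pi))
    expect_lte(m$feret_min, m$feret_max)
    expect_gt(m$feret_min, 0)
    expect_true(m$aspect_ratio > 0 && m$aspect_ratio <= 1)
    expect_true(m$compactness > 0 && m$compactness <= 1 + 1e-12)
  }
})

test_that("radial roughness raises shape factor and lowers form factor", {
  # paired draws at increasing high-frequency amplitude, fixed seeds
  amps <- c(0, 0.02, 0.05)
  mean_sf <- numeric(length(amps))
  mean_ff <- numeric(length(amps))
  for (a in seq_along(amps)) {
    sf <- ff <- numeric(100)
    for (s in 1:100) {
      p <- morph_params(axis_ratio = 1, convolution_amp = 0,
                        roughness_amp = amps[a])
      m <- soma_metrics(gen_contour(p, seed = 1000 + s))
      sf[s] <- m$shape_factor; ff[s] <- m$form_factor
    }
    mean_sf[a] <- mean(sf); mean_ff[a] <- mean(ff)
  }
  expect_true(all(diff(mean_sf) > 0))
  expect_true(all(diff(mean_ff) < 0))
})
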