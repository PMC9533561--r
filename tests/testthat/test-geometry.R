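# Boundary estimation, signed distances, and TC/TF/PT assignment.

test_that("signed distance to a square boundary matches hand geometry", {
  b <- square_boundary(100)
  expect_equal(distance_to_boundary(50, 50, b), -50)
  expect_equal(distance_to_boundary(150, 50, b), 50)
  expect_equal(distance_to_boundary(200, 200, b), sqrt(100^2 + 100^2))
  expect_equal(distance_to_boundary(100, 50, b), 0)   # on the edge
})

test_that("boundary estimated from a lattice-filled disc recovers its area", {
  g <- expand.grid(x = seq(100, 1100, by = 10), y = seq(100, 1100, by = 10))
  keep <- (g$x - 600)^2 + (g$y - 600)^2 <= 500^2
  cells <- data.frame(cell_id = paste0("c", seq_len(sum(keep))), roi_id = "r1",
                      x = g$x[keep], y = g$y[keep], compartment = "tumor",
                      stringsAsFactors = FALSE)
  roi <- data.frame(roi_id = "r1", xmin = 0, ymin = 0, xmax = 1200, ymax = 1200,
                    area_mm2 = 1.44, stringsAsFactors = FALSE)
  b <- estimate_boundary(cells, roi, grid_resolution = 10, closing_radius = 30)
  expect_lt(abs(boundary_area_um2(b) - pi * 500^2) / (pi * 500^2), 0.10)
  # estimated boundary encloses (or nearly touches) every tumor cell
  d <- distance_to_boundary(cells$x, cells$y, b)
  expect_true(all(d <= b$grid_resolution))
})

test_that("a single tumor cell yields one small positive-area polygon", {
  cells <- data.frame(cell_id = "c1", roi_id = "r1", x = 200, y = 200,
                      compartment = "tumor", stringsAsFactors = FALSE)
  roi <- data.frame(roi_id = "r1", xmin = 0, ymin = 0, xmax = 400, ymax = 400,
                    area_mm2 = 0.16, stringsAsFactors = FALSE)
  b <- estimate_boundary(cells, roi, grid_resolution = 5, closing_radius = 30)
  expect_gt(boundary_area_um2(b), 0)
  expect_lt(boundary_area_um2(b), (2 * 30 + 10)^2)  # about one closed neighborhood
})

test_that("two distant tumor clusters give two disjoint polygons", {
  mk <- function(cx) {
    g <- expand.grid(x = seq(cx - 60, cx + 60, 10), y = seq(440, 560, 10))
    g[(g$x - cx)^2 + (g$y - 500)^2 <= 60^2, ]
  }
  g <- rbind(mk(300), mk(1300))
  cells <- data.frame(cell_id = paste0("c", seq_len(nrow(g))), roi_id = "r1",
                      x = g$x, y = g$y, compartment = "tumor",
                      stringsAsFactors = FALSE)
  roi <- data.frame(roi_id = "r1", xmin = 0, ymin = 0, xmax = 1600, ymax = 1000,
                    area_mm2 = 1.6, stringsAsFactors = FALSE)
  b <- estimate_boundary(cells, roi, grid_resolution = 10, closing_radius = 30)
  expect_equal(length(b$rings), 2)
})

test_that("no tumor cells raises a 'no tumor region' error", {
  cells <- data.frame(cell_id = "c1", roi_id = "r1", x = 10, y = 10,
                      compartment = "stroma", stringsAsFactors = FALSE)
  roi <- data.frame(roi_id = "r1", xmin = 0, ymin = 0, xmax = 100, ymax = 100,
                    area_mm2 = 0.01, stringsAsFactors = FALSE)
  expect_error(estimate_boundary(cells, roi), "no tumor region")
})

test_that("band-edge semantics honour 'less than' / 'at or beyond' 150 um", {
  b <- square_boundary(1000)  # edge at x = 1000 for points to its right
  pts <- cbind(1000 + c(-0.001, 0, 149.999, 150), rep(500, 4))
  s <- make_point_sample(pts)
  p <- assign_regions(s, list(r1 = b), band_width = 150)
  expect_equal(p$cells$region, c("TC", "TF", "TF", "PT"))
})

test_that("a zero band width leaves no cell in TF", {
  set.seed(2)
  pts <- cbind(runif(200, 0, 2000), runif(200, 0, 2000))
  s <- make_point_sample(pts)
  p <- assign_regions(s, list(r1 = square_boundary(1000)), band_width = 0)
  expect_false(any(p$cells$region == "TF"))
  expect_equal(p$areas_mm2[["TF"]], 0)
})

test_that("labels match the brute-force per-edge oracle on random polygons", {
  set.seed(19)
  for (i in 1:25) {
    ring <- rand_polygon(sample(5:20, 1), cx = runif(1, 400, 1600),
                         cy = runif(1, 400, 1600))
    b <- structure(list(rings = list(ring), grid_resolution = 5),
                   class = "tumor_boundary")
    n <- sample(50:500, 1)
    pts <- cbind(runif(n, 0, 2000), runif(n, 0, 2000))
    band <- sample(c(50, 150, 300), 1)
    s <- make_point_sample(pts)
    p <- assign_regions(s, list(r1 = b), band_width = band)
    d_oracle <- oracle_signed_distance(pts[, 1], pts[, 2], list(ring))
    expect_identical(p$cells$region, oracle_region(d_oracle, band))
    # partition: every cell exactly one label; areas sum to the ROI
    expect_false(anyNA(p$cells$region))
    expect_lt(abs(sum(p$areas_mm2) - sum(s$rois$area_mm2)) / sum(s$rois$area_mm2),
              0.005)
  }
})

test_that("widening the band only moves PT cells into TF", {
  set.seed(23)
  ring <- rand_polygon(12)
  b <- structure(list(rings = list(ring)), class = "tumor_boundary")
  pts <- cbind(runif(300, 0, 2000), runif(300, 0, 2000))
  s <- make_point_sample(pts)
  p1 <- assign_regions(s, list(r1 = b), band_width = 100)
  p2 <- assign_regions(s, list(r1 = b), band_width = 250)
  expect_identical(p1$cells$region == "TC", p2$cells$region == "TC")
  moved <- p1$cells$region != p2$cells$region
  expect_true(all(p1$cells$region[moved] == "PT" & p2$cells$region[moved] == "TF"))
})

test_that("region labels are scale-equivariant and areas scale as k^2", {
  set.seed(29)
  ring <- rand_polygon(10)
  pts <- cbind(runif(200, 0, 2000), runif(200, 0, 2000))
  k <- 3.5
  s1 <- make_point_sample(pts)
  s2 <- make_point_sample(pts * k, roi_side = 2000 * k)
  b1 <- structure(list(rings = list(ring)), class = "tumor_boundary")
  b2 <- structure(list(rings = list(ring * k)), class = "tumor_boundary")
  p1 <- assign_regions(s1, list(r1 = b1), band_width = 150, grid_resolution = 5)
  p2 <- assign_regions(s2, list(r1 = b2), band_width = 150 * k,
                       grid_resolution = 5 * k)
  expect_identical(p1$cells$region, p2$cells$region)
  expect_equal(unname(p2$areas_mm2), unname(p1$areas_mm2) * k^2)
})

test_that("the all-PT policy covers ROIs without tumor cells", {
  set.seed(31)
  s <- rand_sample_map(n_cells = 20, n_rois = 1)
  s$cells$compartment <- "stroma"
  expect_error(estimate_boundaries(s), "no tumor region")
  b <- estimate_boundaries(s, no_tumor_policy = "all_pt")
  p <- assign_regions(s, b)
  expect_true(all(p$cells$region == "PT"))
  expect_equal(p$areas_mm2[["PT"]], sum(p$areas_mm2))
})
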