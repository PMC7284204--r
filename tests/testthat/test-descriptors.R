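test_that("shape records match analytic values for simple shapes", {
  # circle: the form-factor maximum
  circ <- compute_feature_descriptors(
    render_design(manual_design(circle_prim(10, 14.5, 14.5)), 10), 10)
  expect_equal(nrow(circ), 1)
  expect_gt(circ$form_factor, 0.95)
  expect_lt(circ$form_factor, 1.02)
  expect_lt(abs(circ$area - pi * 25) / (pi * 25), 0.005)
  expect_lt(abs(circ$max_feret - 10), 0.3)
  expect_gt(circ$solidity, 0.97)
  expect_lt(circ$eccentricity, 0.2)

  # square: area exact, form factor ~ pi/4, Feret diameters side/diagonal
  sq <- compute_feature_descriptors(
    render_design(manual_design(rect_prim(10, 10, 14.5, 14.5)), 10), 10)
  expect_equal(sq$area, 100)
  expect_lt(abs(sq$form_factor - pi / 4), 0.05)
  expect_lt(abs(sq$min_feret - 10), 0.3)
  expect_lt(abs(sq$max_feret - 10 * sqrt(2)), 0.4)

  # elongated rectangle: high eccentricity, Feret extremes
  re <- compute_feature_descriptors(
    render_design(manual_design(rect_prim(20, 4, 14.5, 14.5)), 10), 10)
  expect_gt(re$eccentricity, 0.9)
  expect_lt(abs(re$min_feret - 4), 0.3)
})

test_that("disjoint features yield one record each; empty rasters none", {
  two <- dplyr::bind_rows(circle_prim(5, 7, 7), circle_prim(5, 22, 22))
  rec <- compute_feature_descriptors(render_design(manual_design(two), 10), 10)
  expect_equal(nrow(rec), 2)
  expect_equal(nrow(compute_feature_descriptors(render_design(flat_design()), 10)), 0)
})

test_that("overlapping primitives merge into a single 8-connected feature", {
  two <- dplyr::bind_rows(circle_prim(10, 12, 12), circle_prim(10, 18, 12))
  rec <- compute_feature_descriptors(render_design(manual_design(two), 10), 10)
  expect_equal(nrow(rec), 1)
})

test_that("descriptors in micrometers are scale-equivariant", {
  des <- manual_design(dplyr::bind_rows(circle_prim(6, 8, 8),
                                        rect_prim(9, 5, 19, 19, 25)))
  a <- compute_feature_descriptors(render_design(des, 10), 10)
  b <- compute_feature_descriptors(render_design(des, 20), 20)
  for (f in c("area", "perimeter", "min_feret", "max_feret")) {
    expect_lt(max(abs(a[[f]] - b[[f]]) / b[[f]]), 0.015)
  }
})

test_that("design summaries aggregate per-feature statistics correctly", {
  two <- dplyr::bind_rows(circle_prim(5.05, 7, 7), circle_prim(10.09, 20, 20))
  des <- manual_design(two)
  shp <- compute_feature_descriptors(render_design(des, 10), 10)
  circ <- max_inscribed_circles(tile_unit(des, 58, 10))
  sv <- summarize_design(des, shp, circ)
  expect_true("Pattern_Area_min" %in% names(sv))
  expect_equal(sv$Pattern_Area_mean, mean(shp$area))
  expect_equal(sv$Pattern_Area_min, min(shp$area))
  expect_equal(sv$Pillar_Count, 2)
  # single-feature design: every statistic collapses to the same value
  one <- manual_design(circle_prim(8, 14, 14))
  shp1 <- compute_feature_descriptors(render_design(one, 10), 10)
  sv1 <- summarize_design(one, shp1, max_inscribed_circles(tile_unit(one, 58, 10)))
  expect_equal(sv1$Pattern_Area_mean, sv1$Pattern_Area_median)
  expect_equal(sv1$Pattern_Area_min, sv1$Pattern_Area_max)
})

test_that("flat designs map to zero pattern descriptors and maximal spacing", {
  lib <- dplyr::bind_rows(flat_design(), manual_design(circle_prim(8, 14, 14), id = "D1"))
  class(lib) <- c("topo_library", class(lib))
  dm <- compute_descriptor_matrix(lib)
  fl <- dm[dm$design_id == "FLAT_D", ]
  pat <- dm[dm$design_id == "D1", ]
  expect_equal(fl$Pattern_Area_mean, 0)
  expect_equal(fl$Pillar_Count, 0)
  expect_equal(fl$Pattern_Coverage, 0)
  expect_gt(fl$Inscribed_Circle_Diameter_max, pat$Inscribed_Circle_Diameter_max)
  # no missing values anywhere, flats included
  expect_false(any(is.na(as.matrix(dm[, -1]))))
})
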