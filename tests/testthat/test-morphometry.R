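# Descriptor battery: geometry, size/shape/intensity/texture descriptors.

test_that("toy masks match the exhaustive pixel-enumeration oracle exactly", {
  shapes <- list(
    rect = {m <- matrix(FALSE, 6, 7); m[2:4, 2:5] <- TRUE; m},
    square = {m <- matrix(FALSE, 8, 8); m[2:6, 3:7] <- TRUE; m},
    blob = {m <- matrix(FALSE, 12, 12); m[3:9, 3:9] <- TRUE;
            m[3, 3] <- m[9, 9] <- FALSE; m})
  for (nm in names(shapes)) {
    m <- shapes[[nm]]
    sc <- scene_from_mask(m, pixel_size_um = 1)
    g <- extract_geometry(sc, 1)
    # enumeration oracle: area, centroid, bounding box
    idx <- which(m, arr.ind = TRUE)
    expect_identical(g$n_px, nrow(idx))
    expect_equal(unname(g$centroid), c(mean(idx[, 2]), mean(idx[, 1])))
    s <- size_features(g)
    expect_equal(s$box_width, diff(range(idx[, 2])) + 1)
    expect_equal(s$box_height, diff(range(idx[, 1])) + 1)
    # chain length against an independent contour tracer, same step weights
    expect_equal(s$perimeter3, ocontour_chain_length(m), tolerance = 1e-12)
  }
})

test_that("geometry extraction rejects absent, split and degenerate labels", {
  m <- matrix(FALSE, 10, 10); m[2:5, 2:5] <- TRUE
  sc <- scene_from_mask(m)
  expect_error(extract_geometry(sc, 7), "label 7")
  two <- matrix(0L, 12, 12); two[2:5, 2:5] <- 1L; two[8:11, 8:11] <- 1L
  sc2 <- scene_from_mask(two)
  expect_error(extract_geometry(sc2, 1), "component")
  small <- matrix(0L, 8, 8); small[3:4, 3:4] <- 1L
  sc3 <- scene_from_mask(small)
  expect_error(extract_geometry(sc3, 1), "degenerate")
})

test_that("disk descriptors match analytic values", {
  sc <- scene_from_mask(disk_mask(10), pixel_size_um = 0.25)
  g <- extract_geometry(sc, 1)
  s <- size_features(g)
  expect_equal(g$n_px, pi * 100, tolerance = 0.02)
  expect_equal(s$radius_max, 2.5, tolerance = 0.25)  # +/- 1 px
  expect_equal(s$radius_min, 2.5, tolerance = 0.25)
  expect_equal(s$diameter_mean, 5, tolerance = 0.25)
  expect_equal(s$feret_mean, 5, tolerance = 0.25)
  expect_equal(s$perimeter3, 2 * pi * 10 * 0.25, tolerance = 0.02 * 5 * pi)
  sh <- shape_features(g)
  expect_equal(sh$aspect, 1, tolerance = 0.02)
  expect_equal(sh$radius_ratio, 1, tolerance = 0.12)
})

test_that("disk of radius 30 px is smooth: roundness and FD in [1, 1.05]", {
  sc <- scene_from_mask(disk_mask(30))
  sh <- shape_features(extract_geometry(sc, 1))
  expect_gte(sh$roundness, 1); expect_lte(sh$roundness, 1.05)
  expect_gte(sh$fractal_dimension, 1); expect_lte(sh$fractal_dimension, 1.05)
})

test_that("rectangle moments give the expected equivalent-ellipse axes", {
  m <- matrix(FALSE, 16, 26); m[4:13, 4:23] <- TRUE  # 10 rows x 20 cols
  sc <- scene_from_mask(m, pixel_size_um = 1)
  s <- size_features(extract_geometry(sc, 1))
  expect_equal(s$box_width, 20)
  expect_equal(s$box_height, 10)
  # moment oracle for a w x h rectangle of pixels: var = w^2/12 (footprint
  # corrected), axis = 4 * sqrt(var)
  expect_equal(s$axis_major, 4 * sqrt(20^2 / 12), tolerance = 1e-8)
  expect_equal(s$axis_minor, 4 * sqrt(10^2 / 12), tolerance = 1e-8)
  sh <- shape_features(extract_geometry(sc, 1))
  expect_equal(sh$aspect, 2, tolerance = 1e-8)
  expect_equal(sh$area_per_box, 1)  # rectangle fills its bounding box
})

test_that("convex perimeter never exceeds the outer chain materially", {
  for (seed in 1:5) {
    sc <- scene_from_boundary(make_boundary(15, 0.25, seed = seed))
    s <- size_features(extract_geometry(sc, 1))
    expect_lte(s$perimeter_convex, s$perimeter3 + 2 * 0.25)
    expect_lte(s$perimeter_ratio, 1.02)
    expect_gt(s$perimeter_ratio, 0)
  }
})

test_that("length features scale with calibration, dimensionless ones do not", {
  m <- ellipse_mask(12, 7, 0.4)
  f1 <- extract_features(scene_from_mask(m, pixel_size_um = 0.25), 1)
  f2 <- extract_features(scene_from_mask(m, pixel_size_um = 0.5), 1)
  lengths <- c("axis_major", "axis_minor", "diameter_max", "diameter_min",
               "diameter_mean", "radius_max", "radius_min", "length", "width",
               "perimeter2", "perimeter3", "perimeter_convex",
               "perimeter_ellipse", "perimeter_length", "box_width",
               "box_height", "feret_min", "feret_mean")
  areas <- c("nuclear_area", "iod", "total_chromatin")
  unitless <- c("aspect", "area_per_box", "radius_ratio", "roundness",
                "perimeter_ratio", "fractal_dimension", "holes", "gray_mean",
                "gray_min", "gray_max", "gray_std", "gray_red", "gray_green",
                "gray_blue", "gray_sum", "margination", "heterogeneity",
                "clumpiness", "od_mean")
  for (v in lengths) expect_equal(f2[[v]], 2 * f1[[v]], tolerance = 1e-9)
  for (v in areas) expect_equal(f2[[v]], 4 * f1[[v]], tolerance = 1e-9)
  for (v in unitless) expect_equal(f2[[v]], f1[[v]], tolerance = 1e-9)
})

test_that("disk features are exactly invariant under 90-degree rotation and
          ellipse features stable under arbitrary rotation", {
  m <- disk_mask(9)
  f0 <- extract_features(scene_from_mask(m), 1)
  f90 <- extract_features(scene_from_mask(t(m)[, rev(seq_len(ncol(m)))]), 1)
  for (v in setdiff(names(f0), c("holes"))) {
    expect_equal(f90[[v]], f0[[v]], tolerance = 1e-9)
  }
  e0 <- extract_features(scene_from_mask(ellipse_mask(14, 8, 0)), 1)
  e1 <- extract_features(scene_from_mask(ellipse_mask(14, 8, 0.6)), 1)
  for (v in c("nuclear_area", "axis_major", "axis_minor", "aspect",
              "perimeter3", "perimeter_ellipse", "diameter_max",
              "diameter_min", "feret_mean")) {
    expect_equal(e1[[v]], e0[[v]], tolerance = 0.02 * abs(e0[[v]]))
  }
})

test_that("uniform-intensity nuclei give the textbook intensity descriptors", {
  f <- extract_features(scene_from_mask(disk_mask(8), channels = 100), 1)
  expect_equal(f$gray_mean, 100)
  expect_equal(f$gray_min, 100)
  expect_equal(f$gray_max, 100)
  expect_equal(f$gray_std, 0)
  expect_equal(f$od_mean, 156)
  expect_equal(f$heterogeneity, 0)
  expect_equal(f$clumpiness, 0)
  expect_equal(f$margination, 1 / 3)
  expect_equal(f$holes, 0)
  expect_equal(f$gray_sum, 100 * sum(disk_mask(8)))
  expect_equal(f$iod, 156 * f$nuclear_area)
})

test_that("chromatin quantity arithmetic reproduces the printed per-grade rows", {
  # grade-3 row: green mean 97, area 54 um^2; grade-5 row: 89, 71 um^2
  m <- disk_mask(8)
  sc <- scene_from_mask(m, channels = c(120, 97, 130), pixel_size_um = 1)
  g <- extract_geometry(sc, 1)
  f <- intensity_features(sc, g)
  expect_equal(f$total_chromatin, (256 - 97) * g$n_px)
  # direct arithmetic at the printed inputs
  expect_equal((256 - 97) * 54, 8586)
  expect_equal((256 - 89) * 71, 11857)
})

test_that("a bright interior blob is counted as one hole", {
  m <- disk_mask(8)
  lum <- matrix(100, nrow(m), ncol(m))
  ctr <- (nrow(m) + 1) / 2
  lum[ctr + (-1:1), ctr] <- 220  # 3-px bright spot
  sc <- scene_from_mask(m, channels = list(lum, lum, lum))
  sh <- shape_features(extract_geometry(sc, 1),
                       luminance = nucmorph:::luminance_crop(
                         sc, extract_geometry(sc, 1)))
  expect_equal(sh$holes, 1)
})

test_that("margination reflects peripheral chromatin concentration", {
  # OD doubled in the peripheral band (relative radius >= 2/3): the band
  # holds 5/9 of the area, so margination = 2m / (3 * (4/9 m + 5/9 * 2m))
  # = 3/7, close to the idealized 50/50-split value 4/9
  R <- 20
  m <- disk_mask(R)
  ctr <- (nrow(m) + 1) / 2
  rr <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  cc <- t(rr)
  d <- sqrt((rr - ctr)^2 + (cc - ctr)^2)
  lum <- matrix(NA_real_, nrow(m), ncol(m))
  lum[m] <- ifelse(d[m] >= 2 / 3 * R, 256 - 120, 256 - 60)  # OD 120 vs 60
  sc <- scene_from_mask(m, channels = list(lum, lum, lum))
  g <- extract_geometry(sc, 1)
  tex <- texture_features(sc, g)
  # pixel-sum oracle on the same pixels, using the implementation's own
  # boundary-radius definition only through the analytic disk radius
  od <- 256 - lum[m]
  periph <- d[m] >= 2 / 3 * R
  oracle <- mean(od[periph]) / (3 * mean(od))
  expect_equal(tex$margination, oracle, tolerance = 0.04)
  expect_equal(oracle, 3 / 7, tolerance = 0.02)
  expect_equal(tex$margination, 4 / 9, tolerance = 0.05)
})

test_that("feature tables assemble one complete row per nucleus", {
  co <- generate_cohort(cohort_spec(c(1, 1, 1), nuclei_per_sample = 5, seed = 21))
  tab <- extract_table(co)
  expect_equal(nrow(tab), 15)
  expect_true(all(feature_names() %in% names(tab)))
  expect_false(any(duplicated(tab[c("sample_id", "nucleus_id")])))
  # determinism of the whole extraction path
  expect_identical(tab, extract_table(co))
  # per-nucleus invariants
  expect_true(all(tab$radius_min <= tab$radius_max))
  expect_true(all(tab$diameter_min <= tab$diameter_mean &
                    tab$diameter_mean <= tab$diameter_max))
  expect_true(all(tab$gray_min <= tab$gray_mean & tab$gray_mean <= tab$gray_max))
  expect_true(all(tab$nuclear_area > 0))
  expect_true(all(tab$radius_ratio >= 1))
  expect_true(all(tab$aspect >= 1))
  expect_true(all(tab$roundness >= 1))
  expect_true(all(is.na(tab$fractal_dimension) |
                    (tab$fractal_dimension >= 1 & tab$fractal_dimension <= 2)))
  expect_true(all(tab$heterogeneity >= 0 & tab$heterogeneity <= 1))
  expect_true(all(tab$area_per_box > 0 & tab$area_per_box <= 1))
})
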