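# The morphometric descriptor battery: size, shape, intensity and chromatin
# texture descriptors per nucleus, in calibrated units (um, um^2, 8-bit
# intensity levels, or dimensionless).

#' Names of the 38 morphometric descriptors, in canonical column order
#' @export
feature_names <- function() {
  c("nuclear_area", "aspect", "area_per_box", "gray_mean", "axis_major",
    "axis_minor", "diameter_max", "diameter_min", "diameter_mean",
    "radius_max", "radius_min", "holes", "radius_ratio", "roundness",
    "gray_red", "gray_green", "gray_blue", "length", "width", "perimeter2",
    "iod", "perimeter_convex", "perimeter_ellipse", "perimeter_ratio",
    "fractal_dimension", "box_width", "box_height", "feret_min",
    "feret_mean", "gray_min", "gray_max", "gray_std", "margination",
    "heterogeneity", "clumpiness", "gray_sum", "perimeter3",
    "perimeter_length")
}

# boundary pixel coordinates as (x = col, y = row) numeric matrix
boundary_xy <- function(geom) {
  cbind(x = as.numeric(geom$boundary[, "col"]),
        y = as.numeric(geom$boundary[, "row"]))
}

# periodic 1-degree radial profile r(theta) of the boundary about the
# centroid; returns a function of angle (radians, any range)
radial_profile <- function(geom) {
  b <- boundary_xy(geom)
  dx <- b[, 1] - geom$centroid["x"]
  dy <- b[, 2] - geom$centroid["y"]
  th <- atan2(dy, dx) %% (2 * pi)
  r <- sqrt(dx^2 + dy^2)
  o <- order(th)
  th <- th[o]; r <- r[o]
  keep <- c(TRUE, diff(th) > 1e-12)
  th <- th[keep]; r <- r[keep]
  thp <- c(th[length(th)] - 2 * pi, th, th[1] + 2 * pi)
  rp <- c(r[length(r)], r, r[1])
  function(ang) stats::approx(thp, rp, xout = ang %% (2 * pi), rule = 2)$y
}

#' Size descriptors of one nucleus
#'
#' All lengths in micrometres, areas in square micrometres. `perimeter2`
#' counts the outer chain plus any enclosed-hole boundaries; `perimeter3` is
#' the outer chain only; `perimeter_length` is the semi-perimeter of the
#' outer chain. Diameters are measured through the centroid and Feret
#' (caliper) extents over a 1-degree angular grid; `length`/`width` are the
#' maximal Feret and its orthogonal caliper.
#'
#' @param geom a `nucleus_geometry` from [extract_geometry()].
#' @param angular_step angular grid spacing in degrees (default 1).
#' @return named list of size descriptors.
#' @export
size_features <- function(geom, angular_step = 1) {
  cal <- geom$pixel_size_um
  b <- boundary_xy(geom)
  cx <- geom$centroid["x"]; cy <- geom$centroid["y"]
  area <- geom$n_px * cal^2

  rad <- sqrt((b[, 1] - cx)^2 + (b[, 2] - cy)^2)
  radius_max <- max(rad) * cal
  radius_min <- min(rad) * cal

  rfun <- radial_profile(geom)
  th <- seq(0, pi, by = angular_step * pi / 180)
  th <- th[th < pi]
  diam <- (rfun(th) + rfun(th + pi)) * cal
  # Feret extents over the same directions (+1 px for the pixel footprint)
  ft <- vapply(th, function(a) {
    p <- b[, 1] * cos(a) + b[, 2] * sin(a)
    diff(range(p)) + 1
  }, numeric(1))
  ft <- ft * cal
  i_max <- which.max(ft)
  len <- ft[i_max]
  orth <- (th[i_max] + pi / 2) %% pi
  p_orth <- b[, 1] * cos(orth) + b[, 2] * sin(orth)
  wid <- (diff(range(p_orth)) + 1) * cal

  box_w <- (diff(range(b[, 1])) + 1) * cal
  box_h <- (diff(range(b[, 2])) + 1) * cal

  # axis lengths of the moment-equivalent ellipse (pixel-footprint corrected)
  rows <- rep(geom$rows, times = length(geom$cols))[as.vector(geom$mask)]
  cols <- rep(geom$cols, each = length(geom$rows))[as.vector(geom$mask)]
  vx <- stats::var(cols) * (length(cols) - 1) / length(cols) + 1 / 12
  vy <- stats::var(rows) * (length(rows) - 1) / length(rows) + 1 / 12
  vxy <- stats::cov(cols, rows) * (length(rows) - 1) / length(rows)
  tr2 <- (vx + vy) / 2
  det_root <- sqrt(max(0, ((vx - vy) / 2)^2 + vxy^2))
  l1 <- tr2 + det_root; l2 <- max(tr2 - det_root, 1e-9)
  axis_major <- 4 * sqrt(l1) * cal
  axis_minor <- 4 * sqrt(l2) * cal

  per3 <- geom$outer_chain_px * cal
  per2 <- (geom$outer_chain_px + geom$hole_chain_px) * cal
  hull <- grDevices::chull(b)
  per_convex <- polygon_perimeter(b[hull, , drop = FALSE]) * cal
  a_e <- axis_major / 2; b_e <- axis_minor / 2
  per_ellipse <- pi * (3 * (a_e + b_e) - sqrt((3 * a_e + b_e) * (a_e + 3 * b_e)))

  list(nuclear_area = area,
       perimeter2 = per2, perimeter3 = per3,
       perimeter_length = per3 / 2,
       perimeter_convex = per_convex,
       perimeter_ellipse = per_ellipse,
       perimeter_ratio = per_convex / per3,
       diameter_max = max(diam), diameter_min = min(diam),
       diameter_mean = mean(diam),
       radius_max = radius_max, radius_min = radius_min,
       box_width = box_w, box_height = box_h,
       feret_min = min(ft), feret_mean = mean(ft),
       length = len, width = wid,
       axis_major = axis_major, axis_minor = axis_minor)
}

# Box-counting dimension of a boundary pixel chain. Dyadic box sizes from
# 1 px up to min(64, max(bbox/4, 8)); least-squares slope of log N(s) on
# log(1/s), clamped to the geometrically attainable range [1, 2]. At least
# four scales are required, otherwise NA (boundary too short).
box_count_dimension <- function(boundary) {
  x <- boundary[, "col"]; y <- boundary[, "row"]
  bbox <- max(diff(range(x)), diff(range(y))) + 1
  smax <- min(64, max(bbox / 4, 8))
  sizes <- 2^(0:6)
  sizes <- sizes[sizes <= smax]
  if (length(sizes) < 4L) return(NA_real_)
  n <- vapply(sizes, function(s) {
    length(unique((floor((x - min(x)) / s)) * 1e6 + floor((y - min(y)) / s)))
  }, numeric(1))
  if (n[1] <= n[length(n)]) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, log(1 / sizes)), log(n))
  min(2, max(1, fit$coefficients[2]))
}

#' Shape descriptors of one nucleus
#'
#' `roundness` is the squared-perimeter-to-area contour index
#' `perimeter3^2 / (4 pi area)` (1 for a disk, larger for irregular
#' outlines); `fractal_dimension` is the box-counting dimension of the
#' boundary chain; `holes` counts bright intranuclear vesicles: connected
#' regions brighter than `gray_mean + gray_std` that are fully enclosed by
#' the nucleus (requires the luminance crop; NA otherwise).
#'
#' @param geom a `nucleus_geometry`.
#' @param luminance optional luminance matrix matching `geom$mask` (used for
#'   the vesicle/hole count).
#' @param size optional precomputed [size_features()] list (avoids rework).
#' @return named list of shape descriptors.
#' @export
shape_features <- function(geom, luminance = NULL, size = NULL) {
  if (is.null(size)) size <- size_features(geom)
  holes <- NA_real_
  if (!is.null(luminance)) {
    lum <- luminance[geom$mask]
    thr <- mean(lum) + stats::sd(lum)
    bright <- geom$mask & luminance > thr
    if (any(bright)) {
      lab <- label_components(bright, 8L)
      on_boundary <- matrix(FALSE, nrow(geom$mask), ncol(geom$mask))
      on_boundary[cbind(geom$boundary[, "row"] - min(geom$rows) + 1L,
                        geom$boundary[, "col"] - min(geom$cols) + 1L)] <- TRUE
      ids <- setdiff(unique(as.vector(lab)), 0L)
      holes <- sum(vapply(ids, function(i) !any(on_boundary[lab == i]),
                          logical(1)))
    } else {
      holes <- 0
    }
  }
  list(aspect = size$axis_major / size$axis_minor,
       # clamped at the isoperimetric floor: rasterization can push the raw
       # ratio marginally below the continuous-shape minimum of 1
       roundness = max(1, size$perimeter3^2 / (4 * pi * size$nuclear_area)),
       area_per_box = size$nuclear_area / (size$box_width * size$box_height),
       radius_ratio = size$radius_max / size$radius_min,
       fractal_dimension = box_count_dimension(geom$boundary),
       holes = holes)
}

# luminance crop (unweighted RGB mean) for a geometry's bounding box
luminance_crop <- function(scene, geom) {
  (scene$image[geom$rows, geom$cols, 1] +
     scene$image[geom$rows, geom$cols, 2] +
     scene$image[geom$rows, geom$cols, 3]) / 3
}

#' Intensity and optical-density descriptors of one nucleus
#'
#' Gray statistics are computed on the luminance channel (unweighted mean of
#' R, G, B) over nucleus pixels; `od_mean = 256 - gray_mean` follows the
#' optical-density convention of the grading study this package models;
#' `iod = od_mean * nuclear_area` (integrated optical density, a proxy for
#' total chromatin), and `total_chromatin = (256 - gray_green) *
#' nuclear_area` is its green-channel analogue.
#'
#' @param scene a `labeled_scene`.
#' @param geom a `nucleus_geometry`.
#' @param size optional precomputed [size_features()] list.
#' @return named list of intensity descriptors.
#' @export
intensity_features <- function(scene, geom, size = NULL) {
  if (is.null(size)) size <- size_features(geom)
  sel <- geom$mask
  r <- scene$image[geom$rows, geom$cols, 1][sel]
  g <- scene$image[geom$rows, geom$cols, 2][sel]
  b <- scene$image[geom$rows, geom$cols, 3][sel]
  lum <- (r + g + b) / 3
  gray_mean <- mean(lum)
  od_mean <- 256 - gray_mean
  gray_green <- mean(g)
  list(gray_mean = gray_mean,
       gray_min = min(lum), gray_max = max(lum),
       gray_std = stats::sd(lum),
       gray_red = mean(r), gray_green = gray_green, gray_blue = mean(b),
       gray_sum = sum(lum),
       od_mean = od_mean,
       iod = od_mean * size$nuclear_area,
       total_chromatin = (256 - gray_green) * size$nuclear_area)
}

#' Chromatin texture descriptors of one nucleus
#'
#' `heterogeneity`: fraction of nucleus pixels whose luminance deviates from
#' the nuclear mean by more than 10% of that mean. `clumpiness`: fraction of
#' those deviating pixels that survive one pass of 3x3 majority erosion
#' (a pixel survives if at least 5 of the 9 pixels in its neighbourhood
#' deviate), i.e. how much of the heterogeneity sits in spatial clumps
#' rather than isolated pixels. `margination`: mean optical density of the
#' peripheral band (relative radial position >= 2/3 of the local
#' centre-to-boundary distance) divided by three times the whole-nucleus
#' mean OD, so a radially uniform chromatin distribution scores 1/3.
#'
#' @param scene a `labeled_scene`.
#' @param geom a `nucleus_geometry` with at least 30 pixels (NA flags
#'   otherwise).
#' @return named list with `margination`, `heterogeneity`, `clumpiness`.
#' @export
texture_features <- function(scene, geom) {
  if (geom$n_px < 30L) {
    return(list(margination = NA_real_, heterogeneity = NA_real_,
                clumpiness = NA_real_))
  }
  lum <- luminance_crop(scene, geom)
  sel <- geom$mask
  m <- mean(lum[sel])
  dev <- sel & abs(lum - m) > 0.1 * m
  het <- sum(dev) / sum(sel)
  clump <- 0
  if (any(dev)) {
    # 3x3 deviant-neighbour count via shifted sums on a padded matrix
    nr <- nrow(dev); nc <- ncol(dev)
    pad <- matrix(0L, nr + 2L, nc + 2L)
    pad[2:(nr + 1L), 2:(nc + 1L)] <- dev
    cnt <- matrix(0L, nr, nc)
    for (i in 0:2) for (j in 0:2) {
      cnt <- cnt + pad[(1:nr) + i, (1:nc) + j]
    }
    clump <- sum(dev & cnt >= 5L) / sum(dev)
  }
  od <- 256 - lum
  cx <- geom$centroid["x"]; cy <- geom$centroid["y"]
  px <- rep(geom$cols, each = length(geom$rows))[as.vector(sel)]
  py <- rep(geom$rows, times = length(geom$cols))[as.vector(sel)]
  rfun <- radial_profile(geom)
  d <- sqrt((px - cx)^2 + (py - cy)^2)
  rel <- d / pmax(rfun(atan2(py - cy, px - cx)), 1e-9)
  periph <- rel >= 2 / 3
  odv <- od[sel]
  marg <- if (any(periph)) mean(odv[periph]) / (3 * mean(odv)) else NA_real_
  list(margination = marg, heterogeneity = het, clumpiness = clump)
}

#' Extract the full descriptor vector for one nucleus
#'
#' Composes [extract_geometry()], [size_features()], [shape_features()],
#' [intensity_features()] and [texture_features()] into a single one-row
#' data.frame with the 38 descriptors of [feature_names()] plus `od_mean`
#' and `total_chromatin`.
#'
#' @param scene a `labeled_scene`.
#' @param label nucleus label in the mask.
#' @return one-row data.frame of named descriptors.
#' @examples
#' sc <- render_scene(grade_profile("G13"), n_nuclei = 3, seed = 2)
#' extract_features(sc, 1)[, c("nuclear_area", "roundness", "gray_green")]
#' @export
extract_features <- function(scene, label) {
  geom <- extract_geometry(scene, label)
  size <- size_features(geom)
  lum <- luminance_crop(scene, geom)
  shape <- shape_features(geom, luminance = lum, size = size)
  intens <- intensity_features(scene, geom, size = size)
  tex <- texture_features(scene, geom)
  out <- c(size, shape, intens, tex)
  as.data.frame(out[c(feature_names(), "od_mean", "total_chromatin")])
}

#' Extract the per-nucleus feature table for a whole cohort
#'
#' One row per nucleus; nuclei whose extraction fails (absent label,
#' multi-component region, degenerate size) are logged via `message()` and
#' skipped, never imputed.
#'
#' @param cohort an `nm_cohort` from [generate_cohort()].
#' @return data.frame with `sample_id`, `nucleus_id`, `grade_group` and the
#'   descriptor columns.
#' @export
extract_table <- function(cohort) {
  stopifnot(inherits(cohort, "nm_cohort"))
  rows <- list()
  for (i in seq_along(cohort$scenes)) {
    sc <- cohort$scenes[[i]]
    labs <- sort(setdiff(unique(as.vector(sc$labels)), 0L))
    for (lb in labs) {
      f <- tryCatch(extract_features(sc, lb), error = function(e) {
        message(sprintf("skipping %s nucleus %d: %s",
                        cohort$sample_id[i], lb, conditionMessage(e)))
        NULL
      })
      if (!is.null(f)) {
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(sample_id = cohort$sample_id[i], nucleus_id = lb,
                     grade_group = cohort$grade_group[i]), f)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
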