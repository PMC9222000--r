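# Scene rendering: rasterized nuclei with correlated chromatin texture on a
# light background, plus per-nucleus ground-truth records.

# Row-normalized Gaussian smoothing matrix for 1-D convolution by product.
smoothing_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
  K / rowSums(K)
}

# Zero-mean, unit-SD spatially correlated Gaussian field on an nr x nc grid.
correlated_field <- function(nr, nc, grain_px) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (grain_px > 0) {
    z <- smoothing_matrix(nr, grain_px) %*% z %*% t(smoothing_matrix(nc, grain_px))
  }
  s <- stats::sd(as.vector(z))
  if (s > 0) z <- (z - mean(z)) / s
  z
}

#' Render one synthetic field of labeled nuclei
#'
#' Simulates a brightfield-like RGB image of `n_nuclei` darkly stained nuclei
#' on a light background together with its integer label mask and per-nucleus
#' ground truth. One call corresponds to one biopsy sample: a sample-level
#' mean radius, roughness and RGB intensity triple are drawn first from the
#' profile's between-sample distributions, then individual nuclei scatter
#' around those sample means.
#'
#' Nuclei are placed on a jittered grid, so labels can never collide; if a
#' caller-supplied `image_size` is too small for the grid, sequential random
#' placement with bounded retries is attempted and an error naming the
#' achieved count is raised on failure.
#'
#' @param profile a [grade_profile()].
#' @param n_nuclei number of nuclei to place.
#' @param image_size side length in pixels (`NULL` = smallest jittered grid
#'   that fits).
#' @param pixel_size_um calibration, micrometres per pixel.
#' @param seed RNG seed; identical arguments give byte-identical scenes.
#' @return an object of class `labeled_scene`: list with `image`
#'   (H x W x 3 integer array, 0-255), `labels` (H x W integer matrix, 0 =
#'   background), `pixel_size_um`, `truth` (data.frame of per-nucleus
#'   generative parameters) and `sample` (the sample-level draws).
#' @examples
#' sc <- render_scene(grade_profile("G13"), n_nuclei = 5, seed = 1)
#' table(sc$labels > 0)
#' @export
render_scene <- function(profile, n_nuclei, image_size = NULL,
                         pixel_size_um = 0.25, seed = NULL) {
  stopifnot(inherits(profile, "grade_profile"), n_nuclei >= 1,
            pixel_size_um > 0)
  with_seed(seed, {
    # sample-level draws (between-sample variation)
    s_radius <- max(3.2 * pixel_size_um,
                    stats::rnorm(1, profile$radius_mean_um, profile$radius_sd_um))
    s_rough <- clip01(stats::rnorm(1, profile$boundary_roughness,
                                   profile$roughness_sd), 0, 0.5)
    s_rgb <- clip01(stats::rnorm(3, profile$gray_mean_rgb, profile$gray_sd_rgb))

    # radius_um is the target *minimal* radius of each nucleus; the base
    # radius of the star-convex boundary is larger by 1/(1 - roughness)
    radius_um <- pmax(3.1 * pixel_size_um,
                      stats::rnorm(n_nuclei, s_radius,
                                   profile$radius_cv_within * s_radius))
    radius_px <- radius_um / pixel_size_um / (1 - s_rough)
    reach_px <- radius_px * (1 + s_rough)

    g <- ceiling(sqrt(n_nuclei))
    cell <- ceiling(2 * max(reach_px)) + 4L
    need <- g * cell + 2L
    grid_ok <- is.null(image_size) || image_size >= need
    if (is.null(image_size)) image_size <- need
    H <- W <- as.integer(image_size)

    labels <- matrix(0L, H, W)
    image <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) image[, , ch] <- clip01(stats::rnorm(H * W, 230, 5))

    truth <- data.frame(nucleus_id = seq_len(n_nuclei), cx = NA_real_,
                        cy = NA_real_, radius_um = radius_um,
                        roughness = s_rough, mean_r = NA_real_,
                        mean_g = NA_real_, mean_b = NA_real_,
                        n_vesicles = NA_integer_)
    placed <- 0L
    for (k in seq_len(n_nuclei)) {
      if (grid_ok) {
        gi <- (k - 1L) %/% g; gj <- (k - 1L) %% g
        slack <- cell - 2 * reach_px[k] - 2
        cx <- 1 + gj * cell + reach_px[k] + 1 + stats::runif(1, 0, max(0, slack))
        cy <- 1 + gi * cell + reach_px[k] + 1 + stats::runif(1, 0, max(0, slack))
      } else {
        ok <- FALSE
        for (try in seq_len(200L)) {
          cx <- stats::runif(1, reach_px[k] + 2, W - reach_px[k] - 1)
          cy <- stats::runif(1, reach_px[k] + 2, H - reach_px[k] - 1)
          rr <- (max(1, floor(cy - reach_px[k] - 1))):(min(H, ceiling(cy + reach_px[k] + 1)))
          cc <- (max(1, floor(cx - reach_px[k] - 1))):(min(W, ceiling(cx + reach_px[k] + 1)))
          if (all(labels[rr, cc] == 0L)) { ok <- TRUE; break }
        }
        if (!ok) {
          stop(sprintf("could not place %d nuclei without overlap; achieved %d",
                       n_nuclei, placed), call. = FALSE)
        }
      }
      poly <- make_boundary(radius_px[k], s_rough)
      ras <- rasterize_boundary(poly, cx, cy, H, W)
      sel <- ras$mask
      if (!any(sel)) next
      sub_lab <- labels[ras$rows, ras$cols, drop = FALSE]
      sub_lab[sel] <- k
      labels[ras$rows, ras$cols] <- sub_lab

      nuc_rgb <- clip01(s_rgb + stats::rnorm(3, 0, 4))
      nr <- length(ras$rows); nc <- length(ras$cols)
      field <- correlated_field(nr, nc, profile$texture_grain_px) *
        profile$texture_sd
      # bright vesicles: small discs within the inner 60% of the radius
      n_ves <- stats::rpois(1, profile$vesicle_rate)
      ves <- matrix(0, nr, nc)
      if (n_ves > 0) {
        for (v in seq_len(n_ves)) {
          va <- stats::runif(1, 0, 2 * pi)
          vd <- stats::runif(1, 0, 0.6 * radius_px[k])
          vx <- cx + vd * cos(va); vy <- cy + vd * sin(va)
          vr <- stats::runif(1, 1, 2.5)
          dy2 <- outer((ras$rows - vy)^2, rep(1, nc))
          dx2 <- outer(rep(1, nr), (ras$cols - vx)^2)
          ves[dy2 + dx2 <= vr^2] <- 70
        }
      }
      for (ch in 1:3) {
        sub <- image[ras$rows, ras$cols, ch]
        sub[sel] <- clip01(nuc_rgb[ch] + field[sel] + ves[sel])
        image[ras$rows, ras$cols, ch] <- sub
      }
      placed <- placed + 1L
      truth$cx[k] <- cx; truth$cy[k] <- cy
      truth$mean_r[k] <- nuc_rgb[1]; truth$mean_g[k] <- nuc_rgb[2]
      truth$mean_b[k] <- nuc_rgb[3]
      truth$n_vesicles[k] <- n_ves
    }
    image[] <- round(image)
    storage.mode(image) <- "integer"
    structure(list(image = image, labels = labels,
                   pixel_size_um = pixel_size_um, truth = truth,
                   sample = list(radius_um = s_radius, roughness = s_rough,
                                 rgb = s_rgb),
                   seed = seed),
              class = "labeled_scene")
  })
}

#' @export
print.labeled_scene <- function(x, ...) {
  cat(sprintf("<labeled_scene> %d x %d px, %d nuclei, %.3g um/px\n",
              nrow(x$labels), ncol(x$labels), max(x$labels),
              x$pixel_size_um))
  invisible(x)
}

#' Generate a synthetic multi-sample cohort
#'
#' Renders one [labeled_scene()] per sample for the grade composition in
#' `spec`, using per-scene RNG streams derived from the root seed so the
#' whole cohort is reproducible.
#'
#' @param spec a [cohort_spec()].
#' @param profiles named list of [grade_profile()]s covering every grade with
#'   a positive sample count.
#' @return an object of class `nm_cohort`: list with `scenes` (list of
#'   `labeled_scene`), `sample_id`, `grade_group` and `spec`.
#' @examples
#' co <- generate_cohort(cohort_spec(c(1, 1, 1), nuclei_per_sample = 5, seed = 3))
#' table(co$grade_group)
#' @export
generate_cohort <- function(spec, profiles = default_profiles()) {
  stopifnot(inherits(spec, "cohort_spec"))
  grades <- names(spec$n_samples_per_grade)
  missing_p <- setdiff(grades[spec$n_samples_per_grade > 0], names(profiles))
  if (length(missing_p)) {
    stop("profiles missing for grade(s): ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  n_total <- sum(spec$n_samples_per_grade)
  seeds <- derive_seeds(spec$seed, n_total)
  scenes <- vector("list", n_total)
  sample_id <- character(n_total)
  grade_group <- character(n_total)
  i <- 0L
  for (g in grades) {
    for (j in seq_len(spec$n_samples_per_grade[[g]])) {
      i <- i + 1L
      scenes[[i]] <- render_scene(profiles[[g]], spec$nuclei_per_sample,
                                  image_size = spec$image_size,
                                  pixel_size_um = spec$pixel_size_um,
                                  seed = seeds[i])
      sample_id[i] <- sprintf("%s_S%02d", g, j)
      grade_group[i] <- g
    }
  }
  structure(list(scenes = scenes, sample_id = sample_id,
                 grade_group = grade_group, spec = spec),
            class = "nm_cohort")
}

#' @export
print.nm_cohort <- function(x, ...) {
  cat(sprintf("<nm_cohort> %d samples (%s), %d nuclei/sample\n",
              length(x$scenes),
              paste(sprintf("%s:%d", names(table(x$grade_group)),
                            as.integer(table(x$grade_group))), collapse = ", "),
              x$spec$nuclei_per_sample))
  invisible(x)
}

#' Write a cohort to disk as TIFF images, masks and a manifest
#'
#' Images are written as 8-bit RGB TIFF, label masks as 16-bit single-channel
#' TIFF, and a `manifest.csv` records sample ids, grades, paths, calibration
#' and seeds. Per-nucleus ground truth goes to `truth.csv`.
#'
#' @param cohort an `nm_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "nm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(cohort$scenes)
  manifest <- data.frame(sample_id = cohort$sample_id,
                         grade_group = cohort$grade_group,
                         scene_path = file.path(dir, paste0(cohort$sample_id, "_img.tif")),
                         mask_path = file.path(dir, paste0(cohort$sample_id, "_mask.tif")),
                         pixel_size_um = cohort$spec$pixel_size_um,
                         seed = vapply(cohort$scenes, function(s)
                           if (is.null(s$seed)) NA_integer_ else as.integer(s$seed),
                           integer(1)))
  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(sample_id = cohort$sample_id[i], cohort$scenes[[i]]$truth)
  }))
  for (i in seq_len(n)) {
    sc <- cohort$scenes[[i]]
    tiff::writeTIFF(sc$image / 255, manifest$scene_path[i],
                    bits.per.sample = 8L)
    tiff::writeTIFF(sc$labels / 65535, manifest$mask_path[i],
                    bits.per.sample = 16L)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read one scene back from image + mask files
#'
#' @param scene_path RGB TIFF/PNG path (8-bit).
#' @param mask_path 16-bit label TIFF path.
#' @param pixel_size_um calibration to attach.
#' @return a `labeled_scene` (without ground truth).
#' @export
read_scene <- function(scene_path, mask_path, pixel_size_um) {
  img <- tiff::readTIFF(scene_path)
  msk <- tiff::readTIFF(mask_path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  image <- array(as.integer(round(img * 255)), dim = dim(img))
  labels <- matrix(as.integer(round(msk * 65535)), nrow(msk), ncol(msk))
  structure(list(image = image, labels = labels,
                 pixel_size_um = pixel_size_um, truth = NULL,
                 sample = NULL, seed = NULL),
            class = "labeled_scene")
}
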