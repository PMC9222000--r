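# Fixture builders: analytic masks wrapped into labeled scenes, so every
# geometric expectation has a closed form.

# Wrap a logical/integer mask into a labeled_scene with given channel values.
# `channels` may be a single number (uniform), length-3 (per channel), or a
# list of three matrices the size of the mask.
scene_from_mask <- function(mask, channels = 120, pixel_size_um = 0.25) {
  mask <- mask != 0
  H <- nrow(mask); W <- ncol(mask)
  img <- array(230L, dim = c(H, W, 3))
  if (is.list(channels)) {
    for (ch in 1:3) {
      sub <- img[, , ch]
      sub[mask] <- as.integer(round(channels[[ch]][mask]))
      img[, , ch] <- sub
    }
  } else {
    vals <- rep_len(channels, 3)
    for (ch in 1:3) {
      sub <- img[, , ch]
      sub[mask] <- as.integer(round(vals[ch]))
      img[, , ch] <- sub
    }
  }
  structure(list(image = img, labels = matrix(as.integer(mask), H, W),
                 pixel_size_um = pixel_size_um, truth = NULL,
                 sample = NULL, seed = NULL),
            class = "labeled_scene")
}

# Disk of radius R pixels (pixel-centre inclusion), centred in a padded frame.
disk_mask <- function(R, pad = 3) {
  n <- 2 * (R + pad) + 1
  ctr <- R + pad + 1
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  (rr - ctr)^2 + (cc - ctr)^2 <= R^2
}

# Axis-aligned ellipse with semi-axes a, b rotated by phi (radians).
ellipse_mask <- function(a, b, phi = 0, pad = 3) {
  n <- 2 * ceiling(max(a, b) + pad) + 1
  ctr <- (n + 1) / 2
  rr <- matrix(seq_len(n), n, n) - ctr
  cc <- t(matrix(seq_len(n), n, n)) - ctr
  x <- cc * cos(phi) + rr * sin(phi)
  y <- -cc * sin(phi) + rr * cos(phi)
  (x / a)^2 + (y / b)^2 <= 1
}

# Rasterize one make_boundary() polygon into a scene (for fractal-dimension
# and roughness experiments).
scene_from_boundary <- function(poly, channels = 120, pixel_size_um = 0.25) {
  rmax <- max(attr(poly, "radial"))
  n <- 2 * ceiling(rmax + 3) + 1
  ctr <- (n + 1) / 2
  ras <- nucmorph:::rasterize_boundary(poly, ctr, ctr, n, n)
  mask <- matrix(FALSE, n, n)
  mask[ras$rows, ras$cols] <- ras$mask
  scene_from_mask(mask, channels, pixel_size_um)
}

# Independent chain-length oracle: EBImage's oriented contour tracer with the
# same bias-corrected step weights.
ocontour_chain_length <- function(mask) {
  oc <- EBImage::ocontour(matrix(as.integer(mask), nrow(mask), ncol(mask)))[[1]]
  d <- diff(rbind(oc, oc[1, , drop = FALSE]))
  diag_step <- d[, 1] != 0 & d[, 2] != 0
  sum(ifelse(diag_step, 1.340, 0.948))
}

# From-scratch one-way ANOVA F via explicit sums of squares.
anova_f_oracle <- function(x, g) {
  g <- factor(g)
  gm <- mean(x)
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(g) - 1
  dfw <- length(x) - nlevels(g)
  (ssb / dfb) / (ssw / dfw)
}

# Feature-level two-class simulator for stepwise experiments: n per class,
# p candidates, the first `k` informative with `delta`-SD class separation.
simulate_candidates <- function(n_per_class, p, k, delta, seed) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
    colnames(X) <- paste0("f", seq_len(p))
    cls <- rep(c("G13", "G4"), each = n_per_class)
    for (i in seq_len(k)) X[cls == "G4", i] <- X[cls == "G4", i] + delta
    cbind(data.frame(sample_id = seq_len(2 * n_per_class),
                     grade_group = cls), as.data.frame(X))
  })
}
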