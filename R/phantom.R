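# Seeded synthetic fixtures: curvilinear vessel phantoms with known
# ground truth, smooth multiplicative bias fields (intensity
# inhomogeneity) and additive Gaussian noise, plus a simple two-phase disk
# fixture.  Ground truth always reflects geometry alone: it is captured
# before bias and noise are applied.

#' Phantom specification
#'
#' Describes a vessel phantom: grid shape, a set of tubes (each a smooth
#' centerline through quadratic-spline control points with a width in
#' pixels and a contrast against the background), background level, bias
#' field amplitude/scale, noise standard deviation, and the seed driving
#' bias and noise.
#'
#' @param shape `c(rows, cols)`.
#' @param tubes List of tubes, each
#'   `list(control = matrix of (row, col) control points, width, contrast)`;
#'   widths in 1-10 px, contrast nonzero (on the 0-255 scale).
#' @param background Background intensity level.
#' @param bias_amplitude Multiplicative bias amplitude in \[0, 1).
#' @param bias_scale Spatial scale (pixels) of the bias field; default
#'   half the smaller grid side.
#' @param noise_std Additive Gaussian noise standard deviation.
#' @param seed Integer seed for bias and noise.
#' @return List of class `mgdf_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L), tubes = list(),
                         background = 80, bias_amplitude = 0.25,
                         bias_scale = NULL, noise_std = 3, seed = 1L) {
  if (length(shape) != 2L || any(shape < 3))
    stop_mgdf("shape must be two integers >= 3", class = "mgdf_validation_error")
  for (tb in tubes) {
    if (tb$width < 1)
      stop_mgdf("tube widths must be >= 1", class = "mgdf_validation_error")
    if (tb$contrast == 0)
      stop_mgdf("tube contrast must be nonzero", class = "mgdf_validation_error")
    if (any(tb$control[, 1] < 0) || any(tb$control[, 1] > shape[1] - 1) ||
        any(tb$control[, 2] < 0) || any(tb$control[, 2] > shape[2] - 1))
      stop_mgdf("tube control points outside the grid",
                class = "mgdf_validation_error")
  }
  if (bias_amplitude < 0 || bias_amplitude >= 1)
    stop_mgdf("bias_amplitude must lie in [0, 1)",
              class = "mgdf_validation_error")
  if (noise_std < 0)
    stop_mgdf("noise_std must be nonnegative", class = "mgdf_validation_error")
  if (is.null(bias_scale)) bias_scale <- min(shape) / 2
  structure(list(shape = as.integer(shape), tubes = tubes,
                 background = background, bias_amplitude = bias_amplitude,
                 bias_scale = bias_scale, noise_std = noise_std,
                 seed = as.integer(seed)),
            class = "mgdf_phantom_spec")
}

#' Default vessel phantom specification
#'
#' A 128 x 128 phantom with three curved tubes of widths 2, 4 and 7 px
#' (the thin one crossing the middle one), background 80, contrast +60,
#' bias amplitude 0.25 and noise std 3 — the conditions under which
#' thin-vessel behaviour and intensity inhomogeneity are exercised.
#'
#' @param seed Integer seed for bias and noise.
#' @param noise_std Noise standard deviation override.
#' @param bias_amplitude Bias amplitude override.
#' @return An `mgdf_phantom_spec`.
#' @export
default_phantom_spec <- function(seed = 1L, noise_std = 3,
                                 bias_amplitude = 0.25) {
  tubes <- list(
    list(control = rbind(c(18, 4), c(40, 60), c(20, 123)),
         width = 7, contrast = 60),
    list(control = rbind(c(70, 4), c(58, 50), c(80, 90), c(64, 123)),
         width = 4, contrast = 60),
    list(control = rbind(c(120, 20), c(70, 70), c(8, 88)),
         width = 2, contrast = 60))
  phantom_spec(shape = c(128L, 128L), tubes = tubes, background = 80,
               bias_amplitude = bias_amplitude, noise_std = noise_std,
               seed = seed)
}

#' Low-contrast ordering phantom
#'
#' A harder variant of the default phantom used for model-comparison
#' studies: bias amplitude 0.35 (strong enough that the intensity ranges
#' of vessel and background overlap globally, defeating any single
#' intensity threshold) and tubes of decreasing contrast (60, 30, 12),
#' the faintest of which is close to the noise floor so intensity-only
#' local models tend to lose it while the local-phase vesselness channel
#' still marks it.
#'
#' @param seed Integer seed for bias and noise.
#' @param noise_std Noise standard deviation.
#' @return An `mgdf_phantom_spec`.
#' @export
ordering_phantom_spec <- function(seed = 1L, noise_std = 3) {
  tubes <- list(
    list(control = rbind(c(18, 4), c(40, 60), c(20, 123)),
         width = 7, contrast = 60),
    list(control = rbind(c(70, 4), c(58, 50), c(80, 90), c(64, 123)),
         width = 4, contrast = 30),
    list(control = rbind(c(120, 20), c(70, 70), c(8, 88)),
         width = 3, contrast = 12))
  phantom_spec(shape = c(128L, 128L), tubes = tubes, background = 80,
               bias_amplitude = 0.35, noise_std = noise_std, seed = seed)
}

# Sample a quadratic spline through the control points.  With 3 points
# this is the quadratic Bezier; with more, successive overlapping Bezier
# segments through midpoints (standard open quadratic B-spline walk).
sample_centerline <- function(control, n_per_seg = 160L) {
  k <- nrow(control)
  if (k < 2) stop_mgdf("a tube needs >= 2 control points",
                       class = "mgdf_validation_error")
  if (k == 2) {
    t <- seq(0, 1, length.out = n_per_seg)
    return(cbind(control[1, 1] + t * (control[2, 1] - control[1, 1]),
                 control[1, 2] + t * (control[2, 2] - control[1, 2])))
  }
  bezier <- function(p0, p1, p2) {
    t <- seq(0, 1, length.out = n_per_seg)
    cbind((1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
          (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2])
  }
  pts <- NULL
  # endpoints interpolated; interior control points act as Bezier handles
  starts <- control[1, ]
  for (s in 2:(k - 1)) {
    ctrl <- control[s, ]
    ends <- if (s == k - 1) control[k, ] else (control[s, ] + control[s + 1, ]) / 2
    pts <- rbind(pts, bezier(starts, ctrl, ends))
    starts <- ends
  }
  pts
}

#' Generate a vessel phantom
#'
#' Rasterises each tube as the set of pixels within `width / 2` of its
#' sampled centerline, paints tube pixels at `background + contrast`,
#' captures the exact truth mask, and then applies the multiplicative
#' bias field and additive Gaussian noise (in that order — sensor noise on
#' an inhomogeneously illuminated scene).
#'
#' @param spec An [phantom_spec()] / [default_phantom_spec()].
#' @return List of class `mgdf_phantom`: `image`, `truth` ({0,1} mask),
#'   `spec`.
#' @export
generate_vessel_phantom <- function(spec = default_phantom_spec()) {
  if (!inherits(spec, "mgdf_phantom_spec"))
    stop_mgdf("spec must be an mgdf_phantom_spec", class = "mgdf_validation_error")
  nr <- spec$shape[1]; nc <- spec$shape[2]
  img <- matrix(spec$background, nr, nc)
  truth <- matrix(0, nr, nc)
  for (tb in spec$tubes) {
    pts <- sample_centerline(tb$control)
    d <- polyline_dist(nr, nc, pts[, 1], pts[, 2])
    sel <- d <= tb$width / 2
    truth[sel] <- 1
    img[sel] <- spec$background + tb$contrast
  }
  with_seed(spec$seed, {
    if (spec$bias_amplitude > 0)
      img <- add_bias_field(img, spec$bias_amplitude, spec$bias_scale,
                            seed = NULL)
    if (spec$noise_std > 0)
      img <- add_gaussian_noise(img, spec$noise_std, seed = NULL)
  })
  structure(list(image = img, truth = truth, spec = spec),
            class = "mgdf_phantom")
}

#' Multiplicative bias field
#'
#' Multiplies the image by a smooth positive field built from a few
#' seeded low-frequency cosine components, centred to mean exactly 1 and
#' scaled so the field stays within `[1 - amplitude, 1 + amplitude]`.
#' Amplitude 0 returns the image unchanged.
#'
#' @param image Numeric matrix.
#' @param amplitude Bias amplitude in \[0, 1).
#' @param scale Spatial wavelength scale in pixels (default: half the
#'   smaller image side).
#' @param seed Integer seed, or NULL to draw from the current RNG state.
#' @return Matrix of the same shape.
#' @export
add_bias_field <- function(image, amplitude, scale = NULL, seed = NULL) {
  check_image(image)
  if (amplitude >= 1 || amplitude < 0)
    stop_mgdf("amplitude must lie in [0, 1)", class = "mgdf_validation_error")
  if (amplitude == 0) return(image)
  if (is.null(scale)) scale <- min(dim(image)) / 2
  with_seed(seed, {
    nr <- nrow(image); nc <- ncol(image)
    rr <- matrix(0:(nr - 1), nr, nc)
    cc <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
    g <- matrix(0, nr, nc)
    for (k in 1:4) {
      th <- runif(1, 0, 2 * pi)
      wl <- scale * runif(1, 0.8, 2)
      ph <- runif(1, 0, 2 * pi)
      g <- g + runif(1, 0.5, 1) *
        cos(2 * pi * (rr * sin(th) + cc * cos(th)) / wl + ph)
    }
    g <- g - mean(g)
    field <- 1 + amplitude * g / max(abs(g))
    image * field
  })
}

#' Additive Gaussian noise
#'
#' Adds i.i.d. zero-mean Gaussian noise of the given standard deviation.
#'
#' @param image Numeric matrix.
#' @param std Noise standard deviation, >= 0.
#' @param seed Integer seed, or NULL to draw from the current RNG state.
#' @return Matrix of the same shape.
#' @export
add_gaussian_noise <- function(image, std, seed = NULL) {
  check_image(image)
  if (std < 0)
    stop_mgdf("std must be nonnegative", class = "mgdf_validation_error")
  if (std == 0) return(image)
  with_seed(seed,
            image + matrix(rnorm(length(image), 0, std),
                           nrow(image), ncol(image)))
}

#' Two-phase disk fixture
#'
#' Piecewise-constant image: `inside` value on a disk, `outside`
#' elsewhere, with exact truth mask and optional additive noise.  Used by
#' the statistic-recovery and global-mean tests.
#'
#' @param shape `c(rows, cols)`.
#' @param inside,outside Region intensities.
#' @param disk `list(center = c(row, col), radius)` (0-based).
#' @param noise_std Additive Gaussian noise std.
#' @param seed Integer seed for the noise.
#' @return List of class `mgdf_phantom`: `image`, `truth`, `spec`.
#' @export
two_phase_fixture <- function(shape, inside, outside, disk,
                              noise_std = 0, seed = 1L) {
  if (length(shape) != 2L || any(shape < 3))
    stop_mgdf("shape must be two integers >= 3", class = "mgdf_validation_error")
  nr <- shape[1]; nc <- shape[2]
  if (disk$center[1] < 0 || disk$center[1] > nr - 1 ||
      disk$center[2] < 0 || disk$center[2] > nc - 1 || disk$radius < 0)
    stop_mgdf("disk outside the grid", class = "mgdf_validation_error")
  rr <- matrix(0:(nr - 1), nr, nc)
  cc <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  truth <- ((rr - disk$center[1])^2 + (cc - disk$center[2])^2 <=
              disk$radius^2) * 1
  img <- ifelse(truth == 1, inside, outside)
  if (noise_std > 0) img <- add_gaussian_noise(img, noise_std, seed)
  structure(list(image = img, truth = truth,
                 spec = list(shape = shape, inside = inside,
                             outside = outside, disk = disk,
                             noise_std = noise_std, seed = seed)),
            class = "mgdf_phantom")
}
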