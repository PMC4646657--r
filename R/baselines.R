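# Baseline region-based active contours on the shared evolution engine.
# Only the data force differs between models; initialisation,
# Heaviside/Dirac, curvature, regularisation and the stopping rule are the
# code paths used by the MGDF evolution.

#' Chan-Vese segmentation
#'
#' Global two-phase piecewise-constant model: at every iteration the
#' region means `c1` (interior, phi < 0) and `c2` (exterior) are refreshed
#' as membership-weighted global averages and the contour evolves under
#' the data force `lambda1 (I - c1)^2 - lambda2 (I - c2)^2` plus the
#' shared regularisation terms.  Fails by design when the two regions
#' share their mean (its documented limitation).
#'
#' @param I Intensity matrix on the 0-255 scale.
#' @param cfg An [mgdf_config()]; `lambda1_i`/`lambda2_i` are the CV
#'   weights.
#' @param seeds Seed disks, see [initialize_level_set()].
#' @param init Optional {0,1} matrix giving the initial interior
#'   explicitly (e.g. from [vesselness_init()]), overriding `seeds`.
#' @return An `mgdf_segmentation`.
#' @export
segment_cv <- function(I, cfg = mgdf_config(), seeds = NULL, init = NULL) {
  check_image(I, "I")
  phi0 <- resolve_init(dim(I), cfg, seeds, NULL, init)
  force_fn <- function(phi, iter) {
    h1 <- membership_inside(phi, cfg$epsilon)
    a1 <- sum(h1); a2 <- sum(1 - h1)
    c1 <- sum(I * h1) / (a1 + 1e-10)
    c2 <- sum(I * (1 - h1)) / (a2 + 1e-10)
    e1 <- (I - c1)^2
    e2 <- (I - c2)^2
    en <- list(data_intensity =
                 sum(cfg$lambda1_i * e1 * h1 + cfg$lambda2_i * e2 * (1 - h1)),
               c1 = c1, c2 = c2)
    list(force = cfg$lambda1_i * e1 - cfg$lambda2_i * e2, energy = en)
  }
  evolve_engine(I, force_fn, cfg, seeds, model = "cv", phi = phi0)
}

#' Local binary fitting segmentation
#'
#' Replaces the global means of the Chan-Vese model with Gaussian-window
#' local fitted intensities `f1(x)` (interior) and `f2(x)` (exterior),
#' computed with the same window machinery as the MGDF statistics, and
#' evolves under the force
#' `lambda1 e1 - lambda2 e2` with
#' `e_i(x) = integral K(y - x) (I(x) - f_i(y))^2 dy`.
#'
#' @inheritParams segment_cv
#' @return An `mgdf_segmentation`.
#' @export
segment_lbf <- function(I, cfg = mgdf_config(), seeds = NULL, init = NULL) {
  check_image(I, "I")
  phi0 <- resolve_init(dim(I), cfg, seeds, NULL, init)
  w <- make_window_kernel(cfg$sigma)
  KI2 <- I^2                      # K * 1 == 1 for the normalised window
  force_fn <- function(phi, iter) {
    f <- lbf_fitting(I, phi, w, cfg$epsilon)
    e1 <- KI2 - 2 * I * wconv(f$f1, w) + wconv(f$f1^2, w)
    e2 <- KI2 - 2 * I * wconv(f$f2, w) + wconv(f$f2^2, w)
    h1 <- membership_inside(phi, cfg$epsilon)
    en <- list(data_intensity =
                 sum(cfg$lambda1_i * e1 * h1 + cfg$lambda2_i * e2 * (1 - h1)))
    list(force = cfg$lambda1_i * e1 - cfg$lambda2_i * e2, energy = en)
  }
  evolve_engine(I, force_fn, cfg, seeds, model = "lbf", phi = phi0)
}

#' Local fitted intensities of the LBF model
#'
#' `f_i(x) = (K * (I H_i)) / (K * H_i)` with `H_1` the interior
#' membership; in the large-window limit these approach the global means
#' of the Chan-Vese model.
#'
#' @param I Intensity matrix.
#' @param phi Level-set field.
#' @param w An `mgdf_window`.
#' @param epsilon Heaviside width.
#' @return List of matrices `f1`, `f2`.
#' @export
lbf_fitting <- function(I, phi, w, epsilon = 0.1) {
  h1 <- membership_inside(phi, epsilon)
  list(f1 = wconv(I * h1, w) / (wconv(h1, w) + 1e-10),
       f2 = wconv(I * (1 - h1), w) / (wconv(1 - h1, w) + 1e-10))
}

#' Local Gaussian distribution fitting segmentation
#'
#' The single-feature special case of the MGDF evolution: delegates to
#' [evolve()] with both vesselness weights forced to zero, so the result
#' is identical, bit for bit, to an MGDF run with `lambda1_v = lambda2_v
#' = 0` regardless of any vesselness input.
#'
#' @inheritParams segment_cv
#' @return An `mgdf_segmentation` (model tag `"lgdf"`).
#' @export
segment_lgdf <- function(I, cfg = mgdf_config(), seeds = NULL, init = NULL) {
  cfg$lambda1_v <- 0
  cfg$lambda2_v <- 0
  evolve(I, NULL, cfg, seeds, init)
}

#' Segment with a chosen model
#'
#' Dispatcher used by the command line: runs one of `"mgdf"`, `"cv"`,
#' `"lbf"`, `"lgdf"`.  The vesselness map `V` is required for `"mgdf"`
#' (computed from `I` via [enhance()] when NULL) and ignored by the
#' baselines.
#'
#' @param I Intensity matrix.
#' @param model One of `"mgdf"`, `"cv"`, `"lbf"`, `"lgdf"`.
#' @param V Optional precomputed vesselness map.
#' @param cfg An [mgdf_config()].
#' @param seeds Seed disks.
#' @param init Optional explicit initial interior mask shared by all
#'   models (useful for like-for-like model comparisons).
#' @return An `mgdf_segmentation`.
#' @export
segment_model <- function(I, model = c("mgdf", "cv", "lbf", "lgdf"),
                          V = NULL, cfg = mgdf_config(), seeds = NULL,
                          init = NULL) {
  model <- match.arg(model)
  switch(model,
         mgdf = {
           if (is.null(V)) V <- enhance(I, cfg)
           evolve(I, V, cfg, seeds, init)
         },
         cv = segment_cv(I, cfg, seeds, init),
         lbf = segment_lbf(I, cfg, seeds, init),
         lgdf = segment_lgdf(I, cfg, seeds, init))
}
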