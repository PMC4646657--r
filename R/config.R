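#' Model and filter configuration
#'
#' Builds the full set of tunable parameters used by the vesselness filter
#' bank, the MGDF energy and the level-set evolution.  All intensities are
#' kept on the 0-255 scale; the default length weight
#' \code{upsilon = 0.00065 * 255^2} assumes that scale and is meaningless on
#' images normalised to \[0, 1\].
#'
#' @param center_frequency Radial centre frequency (radians per pixel) of the
#'   finest filter scale.  Default \code{5 * pi / 7}.
#' @param bandwidth_octaves Radial bandwidth of each log-Gabor filter, in
#'   octaves.  Default 2.
#' @param filter_size Side of the square spatial quadrature kernels; odd,
#'   >= 3.  Default 15.
#' @param n_scales Number of filter scales M (centre frequency halves per
#'   scale).  Default 3.
#' @param n_orientations Number of filter orientations J, evenly spaced over
#'   180 degrees.  Default 6.
#' @param beta Scale-combination sharpness (>= 1) weighting each scale by
#'   \code{|q_m|^beta}.  Default 2.
#' @param alpha Vesselness normalisation constant (> 0).  \code{NA} (the
#'   default) resolves per image to \code{alpha_rel * max|P|}.
#' @param alpha_rel Relative normalisation used when \code{alpha} is
#'   \code{NA}.  Default 0.1.
#' @param sigma Standard deviation (pixels) of the Gaussian window carrying
#'   the local statistics.  Default 3; the window is truncated at
#'   half-width tau = smallest odd integer >= 2 * sigma (15 x 15 by default).
#' @param lambda1_i,lambda2_i Intensity-term weights for the interior /
#'   exterior region.  Defaults 1.05 and 1.0.
#' @param lambda1_v,lambda2_v Vesselness-term weights for the interior /
#'   exterior region.  Defaults 1.05 and 1.0.
#' @param dt Time step of the forward-Euler evolution.  Default 0.1.
#' @param upsilon Contour-length weight.  Default 2, calibrated to the
#'   scale of the data force, which is a log-likelihood (order 1-30 at
#'   structure boundaries): the length force `upsilon * delta * curvature`
#'   then stays a few percent of the edge data force, smoothing noise
#'   without eroding vessels a few pixels wide.  Values quoted for models
#'   whose data terms are squared intensities (order `255^2`), such as
#'   \code{0.00065 * 255^2} for 0-255 images, are three orders of
#'   magnitude too large on this scale and shrink thin structures faster
#'   than any data term can hold them (see the methods vignette).
#' @param mu Distance-regularisation weight.  Default 1.
#' @param eta Small-component (gamma-neighbourhood) weight.  Default 1.
#' @param epsilon Width of the regularised Heaviside/Dirac.  Default 0.1:
#'   region memberships must be close to crisp, otherwise the local
#'   within-region variances absorb cross-region mixing near the contour
#'   and the data force collapses (see the methods vignette).
#' @param lp_init Vesselness threshold used by the vesselness-guided
#'   initialisation: pixels with normalised vesselness above it start
#'   inside the contour.  On the saturating normalised scale, 0.5 marks
#'   responses at the normalisation constant alpha.  Default 0.5.
#' @param init_mode `"auto"` (default): initialise from the thresholded
#'   vesselness map when one is available, unioned with any seed disks;
#'   `"disks"`: seed disks only (single centred disk when none given).
#' @param c0 Magnitude of the binary-step initial level set.  Default 2.
#' @param gamma Spatial scale (pixels) of the gamma-neighbourhood term.
#'   Default 3.
#' @param kappa Sensitivity exponent of the gamma-neighbourhood term
#'   (>= 1).  Default 2.
#' @param sigma_floor Lower bound for every local standard deviation (on
#'   the 0-255 intensity scale and, identically, on the vesselness scale).
#'   Default 0.01.
#' @param max_iters Iteration cap of the evolution loop.  Default 400.
#' @param tolerance Convergence threshold on the fractional change of the
#'   interior pixel count over a 10-iteration window.  Default 1e-4.
#' @param seed Optional integer seed echoed into results (the evolution
#'   itself is deterministic).
#'
#' @return A named list of class \code{mgdf_config}.
#' @export
#' @examples
#' cfg <- mgdf_config()
#' cfg$center_frequency   # 5*pi/7
mgdf_config <- function(center_frequency = 5 * pi / 7,
                        bandwidth_octaves = 2,
                        filter_size = 15L,
                        n_scales = 3L,
                        n_orientations = 6L,
                        beta = 2,
                        alpha = NA_real_,
                        alpha_rel = 0.1,
                        sigma = 3,
                        lambda1_i = 1.05, lambda2_i = 1.0,
                        lambda1_v = 1.05, lambda2_v = 1.0,
                        dt = 0.1,
                        upsilon = 2,
                        mu = 1,
                        eta = 1,
                        epsilon = 0.1,
                        lp_init = 0.5,
                        init_mode = c("auto", "disks"),
                        c0 = 2,
                        gamma = 3,
                        kappa = 2,
                        sigma_floor = 1e-2,
                        max_iters = 400L,
                        tolerance = 1e-4,
                        seed = NULL) {
  cfg <- list(center_frequency = center_frequency,
              bandwidth_octaves = bandwidth_octaves,
              filter_size = as.integer(filter_size),
              n_scales = as.integer(n_scales),
              n_orientations = as.integer(n_orientations),
              beta = beta, alpha = alpha, alpha_rel = alpha_rel,
              sigma = sigma,
              lambda1_i = lambda1_i, lambda2_i = lambda2_i,
              lambda1_v = lambda1_v, lambda2_v = lambda2_v,
              dt = dt, upsilon = upsilon, mu = mu, eta = eta,
              epsilon = epsilon, lp_init = lp_init,
              init_mode = match.arg(init_mode),
              c0 = c0, gamma = gamma, kappa = kappa,
              sigma_floor = sigma_floor,
              max_iters = as.integer(max_iters), tolerance = tolerance,
              seed = seed)
  class(cfg) <- "mgdf_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  ck <- function(ok, msg) if (!ok) stop_mgdf("invalid config: ", msg,
                                             class = "mgdf_validation_error")
  ck(cfg$center_frequency > 0 && cfg$center_frequency <= pi,
     "center_frequency must lie in (0, pi]")
  ck(cfg$filter_size >= 3L && cfg$filter_size %% 2L == 1L,
     "filter_size must be odd and >= 3")
  ck(cfg$n_scales >= 1L, "n_scales must be >= 1")
  ck(cfg$n_orientations >= 1L, "n_orientations must be >= 1")
  ck(cfg$beta >= 1, "beta must be >= 1")
  ck(is.na(cfg$alpha) || cfg$alpha > 0, "alpha must be positive (or NA)")
  ck(cfg$alpha_rel > 0, "alpha_rel must be positive")
  ck(cfg$sigma > 0, "sigma must be positive")
  ck(all(c(cfg$lambda1_i, cfg$lambda2_i, cfg$lambda1_v, cfg$lambda2_v) >= 0),
     "lambda weights must be nonnegative")
  ck(cfg$dt > 0, "dt must be positive")
  ck(cfg$epsilon > 0, "epsilon must be positive")
  ck(abs(cfg$lp_init) < 1, "lp_init must lie in (-1, 1)")
  ck(cfg$init_mode %in% c("auto", "disks"), "init_mode must be auto or disks")
  ck(cfg$c0 > 0, "c0 must be positive")
  ck(cfg$gamma > 0, "gamma must be positive")
  ck(cfg$kappa >= 1, "kappa must be >= 1")
  ck(cfg$sigma_floor > 0, "sigma_floor must be positive")
  ck(cfg$max_iters >= 1L, "max_iters must be >= 1")
  ck(cfg$tolerance >= 0, "tolerance must be nonnegative")
  invisible(cfg)
}

#' Read a configuration file
#'
#' Reads a flat key-value YAML file whose keys match the arguments of
#' [mgdf_config()]; keys absent from the file keep their defaults and
#' unknown keys are an error.  `overrides` (e.g. from command-line flags)
#' win over file values.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @param overrides Named list applied on top of the file contents.
#' @return An `mgdf_config` object.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop_mgdf("config file not found: ", path, class = "mgdf_io_error")
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(mgdf_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop_mgdf("unknown config keys: ", paste(bad, collapse = ", "),
              class = "mgdf_validation_error")
  do.call(mgdf_config, vals)
}

#' @export
print.mgdf_config <- function(x, ...) {
  cat("MGDF configuration:\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-18s %s\n", k,
                if (is.null(v)) "NULL" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}

# Serialise the fully-resolved config for run logs / echo files.
config_as_yaml <- function(cfg) {
  yaml::as.yaml(lapply(unclass(cfg), function(v) if (is.null(v)) NA else v))
}
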