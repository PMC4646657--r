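# The MGDF data model: local two-feature Gaussian statistics and the data
# energy they induce.
#
# Region convention used throughout the package: region 1 is the contour
# interior (the vessel, where phi < 0) with weight H1 = 1 - H_eps(phi);
# region 2 is the exterior with H2 = H_eps(phi).  lambda1_* weight the
# interior terms, matching the convention that phi is initialised to -c0
# inside the seed region.  All window integrals are correlations with the
# truncated Gaussian kernel under reflective padding.

#' Local statistics window
#'
#' Gaussian window `exp(-d^2 / (2 sigma^2))` truncated to a
#' `(2 tau + 1) x (2 tau + 1)` mask, where `tau` is the smallest odd
#' integer >= `2 sigma`, renormalised to sum exactly 1.  With the default
#' `sigma = 3`, `tau = 7` and the window is 15 x 15.
#'
#' @param sigma Positive Gaussian scale in pixels.
#' @return Object of class `mgdf_window`: list with `weights` (2-D, sums
#'   to 1), `k1d` (the separable 1-D factor), `sigma`, `tau`.
#' @export
make_window_kernel <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop_mgdf("sigma must be a positive number", class = "mgdf_validation_error")
  tau <- ceiling(2 * sigma)
  if (tau %% 2 == 0) tau <- tau + 1
  d <- (-tau):tau
  k1 <- exp(-d^2 / (2 * sigma^2))
  w <- outer(k1, k1)
  w <- w / sum(w)
  structure(list(weights = w, k1d = k1 / sum(k1), sigma = sigma,
                 tau = as.integer(tau)),
            class = "mgdf_window")
}

# Window correlation (separable fast path), reflective boundary.
wconv <- function(x, w) conv2_sep_reflect(x, w$k1d)

check_window <- function(w) {
  if (!inherits(w, "mgdf_window"))
    stop_mgdf("expected an mgdf_window (see make_window_kernel)",
              class = "mgdf_validation_error")
  invisible(w)
}

# Interior membership weight H1 = 1 - H_eps(phi) (phi < 0 inside).
membership_inside <- function(phi, epsilon) 1 - heaviside_eps(phi, epsilon)

#' Local Gaussian statistics of both features
#'
#' For each feature F in {intensity I, vesselness V} and region i in
#' {1 = interior, 2 = exterior}, computes the spatially varying local mean
#' and standard deviation
#' `u_i(x) = (w * (F H_i)) / (w * H_i)` and
#' `s_i(x)^2 = (w * ((u_i(x) - F)^2 H_i)) / (w * H_i)`,
#' with `H_1 = 1 - H_eps(phi)` (interior), `H_2 = H_eps(phi)`.
#' Denominators are floored by 1e-10 (inert: wherever they vanish the
#' statistics are multiplied by a vanishing membership) and standard
#' deviations are floored at `sigma_floor`.
#'
#' @param I Intensity matrix (0-255 scale).
#' @param V Vesselness matrix, same shape (may be NULL when only the
#'   intensity channel is used; the V fields are then omitted).
#' @param phi Level-set field, same shape; negative inside.
#' @param w An `mgdf_window`.
#' @param epsilon Heaviside regularisation width.
#' @param sigma_floor Lower bound on the standard deviations.
#' @return Object of class `mgdf_local_stats`: list of matrices
#'   `u1I, u2I, s1I, s2I` and (if `V` given) `u1V, u2V, s1V, s2V`.
#' @export
update_local_stats <- function(I, V, phi, w, epsilon = 1, sigma_floor = 1e-2) {
  check_image(I, "I")
  check_window(w)
  check_same_shape(I, phi, "I", "phi")
  if (!is.null(V)) check_same_shape(I, V, "I", "V")
  h1 <- membership_inside(phi, epsilon)
  wh1 <- wconv(h1, w)
  wh2 <- wconv(1 - h1, w)
  den1 <- wh1 + 1e-10
  den2 <- wh2 + 1e-10
  one_feature <- function(F) {
    wf1 <- wconv(F * h1, w);  wf2 <- wconv(F * (1 - h1), w)
    wf1sq <- wconv(F^2 * h1, w); wf2sq <- wconv(F^2 * (1 - h1), w)
    u1 <- wf1 / den1; u2 <- wf2 / den2
    v1 <- wf1sq / den1 - 2 * u1 * (wf1 / den1) + u1^2 * (wh1 / den1)
    v2 <- wf2sq / den2 - 2 * u2 * (wf2 / den2) + u2^2 * (wh2 / den2)
    list(u1 = u1, u2 = u2,
         s1 = pmax(sqrt(pmax(v1, 0)), sigma_floor),
         s2 = pmax(sqrt(pmax(v2, 0)), sigma_floor))
  }
  si <- one_feature(I)
  out <- list(u1I = si$u1, u2I = si$u2, s1I = si$s1, s2I = si$s2)
  if (!is.null(V)) {
    sv <- one_feature(V)
    out <- c(out, list(u1V = sv$u1, u2V = sv$u2, s1V = sv$s1, s2V = sv$s2))
  }
  structure(out, class = "mgdf_local_stats")
}

# Per-region negative log-likelihood field for one feature:
#   e_i(x) = w * [ log(2*pi) + log s_i + (u_i - F(x))^2 / (2 s_i^2) ](x),
# the window integral running over the neighbouring statistics.  The
# additive constant is kept as the flow equations print it (log(2*pi)
# rather than the density's log(sqrt(2*pi))); the energy subtracts the
# difference, see total_energy.  Expanded into three window correlations
# so the mixed (u_i(y) - F(x))^2 term is exact.
loglik_field <- function(F, u, s, w) {
  A <- wconv(log(2 * pi) + log(s) + u^2 / (2 * s^2), w)
  B <- wconv(u / s^2, w)
  C <- wconv(1 / (2 * s^2), w)
  list(e = A - F * B + F^2 * C)
}

LOG_CONST_EXCESS <- 0.5 * log(2 * pi)  # printed log(2*pi) minus density's half

data_force_fields <- function(I, V, stats, w, lambda) {
  use_v <- (lambda$l1v != 0 || lambda$l2v != 0)
  e1I <- loglik_field(I, stats$u1I, stats$s1I, w)$e
  e2I <- loglik_field(I, stats$u2I, stats$s2I, w)$e
  force <- lambda$l1i * e1I - lambda$l2i * e2I
  e1V <- e2V <- NULL
  if (use_v) {
    if (is.null(V) || is.null(stats$u1V))
      stop_mgdf("vesselness weights are nonzero but no vesselness channel given",
                class = "mgdf_validation_error")
    e1V <- loglik_field(V, stats$u1V, stats$s1V, w)$e
    e2V <- loglik_field(V, stats$u2V, stats$s2V, w)$e
    force <- force + lambda$l1v * e1V - lambda$l2v * e2V
  }
  list(force = force, e1I = e1I, e2I = e2I, e1V = e1V, e2V = e2V,
       use_v = use_v)
}

lambda_from_cfg <- function(cfg) {
  list(l1i = cfg$lambda1_i, l2i = cfg$lambda2_i,
       l1v = cfg$lambda1_v, l2v = cfg$lambda2_v)
}

#' MGDF data force
#'
#' The pixel-wise data term of the gradient flow,
#' `F_data = lambda1I e1I - lambda2I e2I + lambda1V e1V - lambda2V e2V`,
#' where `e_i^F` is the window-integrated negative log-likelihood of the
#' feature under region i's local Gaussians.  Positive where the exterior
#' model fits better (pushing phi positive), negative inside well-fitted
#' vessel, so the evolution applies it as `+ delta_eps(phi) * F_data`.
#' With both vesselness weights zero this is exactly the single-feature
#' (LGDF) force and the vesselness channel is ignored.
#'
#' @param I Intensity matrix.
#' @param V Vesselness matrix or NULL.
#' @param stats An `mgdf_local_stats` from [update_local_stats()].
#' @param w An `mgdf_window`.
#' @param lambda Named list `l1i, l2i, l1v, l2v` of nonnegative weights.
#' @return Real matrix of the data force.
#' @export
data_force <- function(I, V, stats, w, lambda) {
  check_image(I, "I")
  check_window(w)
  if (!inherits(stats, "mgdf_local_stats"))
    stop_mgdf("stats must come from update_local_stats",
              class = "mgdf_validation_error")
  if (any(unlist(lambda) < 0))
    stop_mgdf("lambda weights must be nonnegative",
              class = "mgdf_validation_error")
  data_force_fields(I, V, stats, w, lambda)$force
}

#' Total MGDF energy
#'
#' Evaluates the full energy of the current state: the two data terms
#' (window-integrated negative log-likelihoods weighted by region
#' membership, using the exact Gaussian constant `log(sqrt(2*pi))`), the
#' contour-length term `upsilon * sum |grad H_eps(phi)|`, the
#' distance-regularisation term `mu * sum (|grad phi| - 1)^2 / 2`, and the
#' gamma-neighbourhood term `eta * sum gamma^kappa / (gamma^kappa +
#' |phi|^kappa)` penalising small-|phi| (isolated-component-prone)
#' regions.
#'
#' @inheritParams data_force
#' @param phi Level-set field.
#' @param cfg An [mgdf_config()] (uses `upsilon, mu, eta, epsilon, gamma,
#'   kappa`).
#' @return Object of class `mgdf_energy`: named list
#'   `data_intensity, data_vesselness, length_term, distance_term,
#'   gamma_term, total`.
#' @export
total_energy <- function(I, V, phi, stats, w, lambda, cfg) {
  check_image(I, "I")
  check_same_shape(I, phi, "I", "phi")
  ff <- data_force_fields(I, V, stats, w, lambda)
  energy_from_fields(phi, ff, lambda, cfg)
}

# Energy evaluated from precomputed log-likelihood fields (shared with the
# evolution loop so logged energies match total_energy bitwise).
energy_from_fields <- function(phi, ff, lambda, cfg) {
  h1 <- membership_inside(phi, cfg$epsilon)
  e1I <- ff$e1I - LOG_CONST_EXCESS
  e2I <- ff$e2I - LOG_CONST_EXCESS
  data_i <- sum(lambda$l1i * e1I * h1 + lambda$l2i * e2I * (1 - h1))
  data_v <- 0
  if (ff$use_v) {
    e1V <- ff$e1V - LOG_CONST_EXCESS
    e2V <- ff$e2V - LOG_CONST_EXCESS
    data_v <- sum(lambda$l1v * e1V * h1 + lambda$l2v * e2V * (1 - h1))
  }
  H <- heaviside_eps(phi, cfg$epsilon)
  gH <- grad_central(H)
  length_term <- cfg$upsilon * sum(sqrt(gH$dr^2 + gH$dc^2))
  gp <- grad_central(phi)
  distance_term <- cfg$mu * sum(0.5 * (sqrt(gp$dr^2 + gp$dc^2) - 1)^2)
  gk <- cfg$gamma^cfg$kappa
  gamma_term <- cfg$eta * sum(gk / (gk + abs(phi)^cfg$kappa))
  structure(list(data_intensity = data_i, data_vesselness = data_v,
                 length_term = length_term, distance_term = distance_term,
                 gamma_term = gamma_term,
                 total = data_i + data_v + length_term + distance_term +
                   gamma_term),
            class = "mgdf_energy")
}
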