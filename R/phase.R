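# Local-phase vesselness enhancement.
#
# A bank of oriented quadrature pairs (even line filter, odd edge filter,
# 90 degrees out of phase) is realised as log-Gabor filters designed in
# the frequency domain and cropped to small spatial kernels.  Per-scale
# complex responses are combined across orientations and scales and
# normalised to a bounded, signed vesselness map: positive inside bright
# tubular structures, near zero at their edges, negative in background.

#' Build the quadrature filter bank
#'
#' Constructs `n_scales * n_orientations` even/odd kernel pairs of size
#' `filter_size` x `filter_size`.  Each pair is an oriented log-Gabor
#' filter: a radial log-Gaussian at the scale's centre frequency with the
#' configured octave bandwidth, an angular Gaussian matched to the number
#' of orientations, inverse-transformed to the spatial domain and cropped.
#' The real (even, point-symmetric) part responds to lines, the imaginary
#' (odd, antisymmetric) part to edges.  Centre frequency halves per scale.
#' Even kernels are made exactly DC-free so constant images yield zero
#' response.
#'
#' @param cfg An [mgdf_config()] object (uses `center_frequency`,
#'   `bandwidth_octaves`, `filter_size`, `n_scales`, `n_orientations`).
#' @return An object of class `mgdf_filter_bank`: list with `kernels`
#'   (a list indexed `[[scale]][[orientation]]` of `list(even, odd)`),
#'   `frequencies`, `angles`.
#' @export
build_filter_bank <- function(cfg = mgdf_config()) {
  validate_config(cfg)
  fs <- cfg$filter_size
  M <- cfg$n_scales
  J <- cfg$n_orientations
  # frequency-domain design grid: odd-sized so the grid is symmetric under
  # quarter-turn rotations and the crop is exactly centred
  N <- max(4L * fs + 1L, 63L)
  if (N %% 2L == 0L) N <- N + 1L
  half <- (N - 1L) / 2L
  f1 <- 2 * pi * c(0:half, -(half:1)) / N     # unshifted FFT frequencies
  U <- matrix(f1, N, N)                        # row frequency
  V <- matrix(f1, N, N, byrow = TRUE)          # column frequency
  R <- sqrt(U^2 + V^2)
  TH <- atan2(U, V)
  s_log <- cfg$bandwidth_octaves * log(2) / (2 * sqrt(2 * log(2)))
  sigma_theta <- (pi / J) / 1.2
  freqs <- cfg$center_frequency / 2^(seq_len(M) - 1)
  angles <- (seq_len(J) - 1) * pi / J
  ctr <- half + 1L
  keep <- (ctr - (fs - 1L) / 2L):(ctr + (fs - 1L) / 2L)
  kernels <- vector("list", M)
  for (m in seq_len(M)) {
    fm <- freqs[m]
    radial <- exp(-(log(pmax(R, .Machine$double.eps) / fm))^2 / (2 * s_log^2))
    radial[R == 0] <- 0
    kernels[[m]] <- vector("list", J)
    for (j in seq_len(J)) {
      dth <- atan2(sin(TH - angles[j]), cos(TH - angles[j]))
      Fj <- radial * exp(-dth^2 / (2 * sigma_theta^2))
      h <- fft(Fj, inverse = TRUE) / length(Fj)
      # bring the kernel centre to the middle of the grid
      h <- h[c((ctr + 1L):N, 1:ctr), c((ctr + 1L):N, 1:ctr)]
      h <- h[keep, keep]
      even <- Re(h); odd <- Im(h)
      even <- (even + rot180(even)) / 2       # enforce exact symmetry
      odd <- (odd - rot180(odd)) / 2          # enforce exact antisymmetry
      even <- even - mean(even)               # DC-free line filter
      nrm <- sqrt(sum(even^2 + odd^2))
      kernels[[m]][[j]] <- list(even = even / nrm, odd = odd / nrm)
    }
  }
  structure(list(kernels = kernels, frequencies = freqs, angles = angles,
                 filter_size = fs, n_scales = M, n_orientations = J),
            class = "mgdf_filter_bank")
}

#' Per-scale quadrature responses
#'
#' Convolves the image with every kernel pair (reflective boundary) and
#' combines orientations at each scale into a single complex response
#' `q_m = sum_j (e_m_j + |o_m_j| * i)`: the even responses add signed, the
#' odd responses add by absolute value so the phase map is orientation
#' invariant.  The imaginary part is therefore nonnegative everywhere.
#'
#' @param image Numeric matrix (0-255 scale).
#' @param bank An `mgdf_filter_bank`.
#' @return List of complex matrices, one per scale.
#' @export
scale_responses <- function(image, bank) {
  check_image(image)
  if (!inherits(bank, "mgdf_filter_bank"))
    stop_mgdf("bank must be an mgdf_filter_bank", class = "mgdf_validation_error")
  fs <- bank$filter_size
  if (nrow(image) < fs || ncol(image) < fs)
    stop_mgdf("image (", nrow(image), "x", ncol(image),
              ") is smaller than the filter kernels (", fs, "x", fs, ")",
              class = "mgdf_validation_error")
  lapply(bank$kernels, function(scale_kernels) {
    re <- matrix(0, nrow(image), ncol(image))
    im <- matrix(0, nrow(image), ncol(image))
    for (pair in scale_kernels) {
      re <- re + conv2_reflect(image, pair$even)
      im <- im + abs(conv2_reflect(image, pair$odd))
    }
    complex(real = re, imaginary = im) |> matrix(nrow(image), ncol(image))
  })
}

#' Combine responses across scales
#'
#' Per pixel, the overall response is the `|q_m|^beta`-weighted mean of the
#' complex per-scale responses,
#' `P = sum_m q_m |q_m|^beta / sum_m |q_m|^beta`, reduced to its real
#' (line-filter) part, which is the channel that highlights vessel
#' interiors.  Pixels with zero total weight yield 0.
#'
#' @param responses List of complex matrices from [scale_responses()].
#' @param beta Weighting exponent, >= 1.
#' @return Real matrix `P`.
#' @export
combine_scales <- function(responses, beta = 2) {
  if (beta < 1)
    stop_mgdf("beta must be >= 1", class = "mgdf_validation_error")
  if (!length(responses))
    stop_mgdf("empty response list", class = "mgdf_validation_error")
  d <- dim(responses[[1]])
  num <- matrix(complex(real = 0, imaginary = 0), d[1], d[2])
  den <- matrix(0, d[1], d[2])
  for (q in responses) {
    if (!identical(dim(q), d))
      stop_mgdf("scale responses have mismatched shapes",
                class = "mgdf_validation_error")
    w <- Mod(q)^beta
    num <- num + q * w
    den <- den + w
  }
  P <- matrix(0, d[1], d[2])
  nz <- den > 0
  P[nz] <- Re(num[nz] / den[nz])
  P
}

#' Normalise the overall response to a bounded vesselness map
#'
#' `LP = P * |P| / (P^2 + alpha^2)`: sign-preserving, zero at zero, and
#' strictly inside (-1, 1) for every `alpha > 0`; responses much larger
#' than `alpha` saturate toward +/-1.
#'
#' @param P Real response matrix.
#' @param alpha Positive normalisation constant.
#' @return Matrix of class `mgdf_vesselness` with attribute `alpha`.
#' @export
normalize_vesselness <- function(P, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stop_mgdf("alpha must be a positive number", class = "mgdf_validation_error")
  v <- P * abs(P) / (P^2 + alpha^2)
  structure(v, alpha = alpha, class = c("mgdf_vesselness", class(v)))
}

#' Local-phase vesselness enhancement
#'
#' Full enhancement pipeline: build the filter bank, compute per-scale
#' quadrature responses, combine scales, and normalise.  When
#' `cfg$alpha` is `NA` the normalisation constant is resolved per image as
#' `cfg$alpha_rel * max|P|` (falling back to 1 on identically-zero
#' response), so the map is comparable across images of different
#' contrast.
#'
#' @param image Numeric matrix on the 0-255 scale.
#' @param cfg An [mgdf_config()] object.
#' @return `mgdf_vesselness` matrix with values in (-1, 1).
#' @export
#' @examples
#' ph <- two_phase_fixture(c(48, 48), 140, 80,
#'                         disk = list(center = c(24, 24), radius = 10),
#'                         noise_std = 0, seed = 1)
#' v <- enhance(ph$image, mgdf_config(n_orientations = 4))
#' range(v)   # strictly inside (-1, 1)
enhance <- function(image, cfg = mgdf_config()) {
  bank <- build_filter_bank(cfg)
  qs <- scale_responses(image, bank)
  P <- combine_scales(qs, cfg$beta)
  alpha <- cfg$alpha
  if (is.na(alpha)) {
    # floored in absolute terms so structure-free images (max response at
    # rounding level) normalise to zero instead of saturating noise
    alpha <- max(cfg$alpha_rel * max(abs(P)), 1e-6)
  }
  normalize_vesselness(P, alpha)
}
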