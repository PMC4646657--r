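# Shared fixtures, built in code at test time.

# Clean two-phase disk on a 64x64 grid (values 100 / 20, radius 15).
disk_fixture <- function(noise_std = 0, seed = 2) {
  two_phase_fixture(c(64, 64), 100, 20,
                    disk = list(center = c(31.5, 31.5), radius = 15),
                    noise_std = noise_std, seed = seed)
}

# Exact signed binary-step field for a fixture's truth mask.
truth_phi <- function(truth, c0 = 2) ifelse(truth == 1, -c0, c0)

# A single bright horizontal tube across a square grid.
tube_fixture <- function(n = 64, row = NULL, width = 3, contrast = 60,
                         background = 80) {
  if (is.null(row)) row <- (n - 1) / 2
  spec <- phantom_spec(shape = c(n, n),
                       tubes = list(list(control = rbind(c(row, 0),
                                                         c(row, n - 1)),
                                         width = width,
                                         contrast = contrast)),
                       background = background, bias_amplitude = 0,
                       noise_std = 0, seed = 1)
  generate_vessel_phantom(spec)
}

# Small config for fast evolutions in unit tests.
fast_config <- function(...) mgdf_config(max_iters = 60L, ...)
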