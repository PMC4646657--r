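# Internal helpers shared across modules.

stop_mgdf <- function(..., class = "mgdf_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_image <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_mgdf(name, " must be a numeric matrix", class = "mgdf_validation_error")
  if (nrow(x) < 3L || ncol(x) < 3L)
    stop_mgdf(name, " must be at least 3x3", class = "mgdf_validation_error")
  if (!all(is.finite(x)))
    stop_mgdf(name, " contains non-finite values", class = "mgdf_validation_error")
  invisible(x)
}

check_same_shape <- function(a, b, name_a = "first", name_b = "second") {
  if (!identical(dim(a), dim(b)))
    stop_mgdf("shape mismatch: ", name_a, " is ", paste(dim(a), collapse = "x"),
              " but ", name_b, " is ", paste(dim(b), collapse = "x"),
              class = "mgdf_validation_error")
  invisible(NULL)
}

check_binary_mask <- function(m, name = "mask") {
  if (!is.matrix(m) || !is.numeric(m))
    stop_mgdf(name, " must be a numeric matrix", class = "mgdf_validation_error")
  if (!all(m %in% c(0, 1)))
    stop_mgdf(name, " must contain only 0 and 1", class = "mgdf_validation_error")
  invisible(m)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.  seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rot180 <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]

# Shift a matrix by one pixel with symmetric (reflective) boundary; used by
# the finite-difference operators.  dr/dc in {-1, 0, 1}.
shift_reflect <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- seq_len(nr) + dr
  ci <- seq_len(nc) + dc
  ri[ri < 1L] <- 1L; ri[ri > nr] <- nr
  ci[ci < 1L] <- 1L; ci[ci > nc] <- nc
  m[ri, ci, drop = FALSE]
}

# Central differences with reflective boundary (Neumann: zero normal
# derivative at the border).
grad_central <- function(m) {
  list(dr = (shift_reflect(m, 1, 0) - shift_reflect(m, -1, 0)) / 2,
       dc = (shift_reflect(m, 0, 1) - shift_reflect(m, 0, -1)) / 2)
}

laplacian5 <- function(m) {
  shift_reflect(m, 1, 0) + shift_reflect(m, -1, 0) +
    shift_reflect(m, 0, 1) + shift_reflect(m, 0, -1) - 4 * m
}

# Display rounding used for report tables: half-up at `digits` decimals.
# The 1e-9 guard keeps values that are exact halves in decimal (but sit
# just below .5 in binary floating point) rounding upward.
round_half_up <- function(x, digits = 3L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
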