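# Raster I/O.  Images live in memory as numeric matrices, (row, col)
# indexed, on the nominal 0-255 intensity scale regardless of the on-disk
# bit depth.  Masks are {0,1} matrices stored as single-channel {0,255}
# PNG.  Vesselness maps carry signed values in (-1, 1) and are stored as
# 32-bit float TIFF through the affine map v -> (v + 1) / 2 (near-lossless:
# float32 quantisation only).

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext %in% c("ppm", "pgm", "pnm")) return("pnm")
  stop_mgdf("unsupported raster format: ", path, class = "mgdf_format_error")
}

read_raster <- function(path) {
  if (!file.exists(path))
    stop_mgdf("cannot read image, file not found: ", path,
              class = "mgdf_io_error")
  fmt <- img_format(path)
  a <- tryCatch(switch(fmt,
                       png = png::readPNG(path),
                       tiff = tiff::readTIFF(path),
                       pnm = read_pnm(path)),
                error = function(e)
                  stop_mgdf("failed to decode ", path, ": ",
                            conditionMessage(e), class = "mgdf_io_error"))
  a
}

#' Load a grayscale or RGB image
#'
#' Reads a PNG, TIFF, or PPM/PGM raster and returns a numeric matrix on the
#' 0-255 scale.  Multi-channel images are reduced according to
#' `channel_policy`: `"green"` (the default; fundus vessels are imaged on
#' the green channel), `"luminance"` (Rec. 601 weights), or `"as_is"`,
#' which accepts only single-channel input.  Values are mapped linearly
#' from the file's bit depth to 0-255; no per-image contrast normalisation
#' is applied.
#'
#' @param path Path to the image file.
#' @param channel_policy One of `"green"`, `"luminance"`, `"as_is"`.
#' @return Numeric matrix (rows x cols) with values on the 0-255 scale.
#' @export
load_image <- function(path, channel_policy = c("green", "luminance", "as_is")) {
  channel_policy <- match.arg(channel_policy)
  a <- read_raster(path)
  if (is.matrix(a)) {
    g <- a
  } else if (length(dim(a)) == 3L) {
    nch <- dim(a)[3]
    if (nch == 2L) {            # gray + alpha
      g <- a[, , 1]
    } else if (nch %in% c(3L, 4L)) {
      g <- switch(channel_policy,
                  green = a[, , 2],
                  luminance = 0.299 * a[, , 1] + 0.587 * a[, , 2] +
                    0.114 * a[, , 3],
                  as_is = stop_mgdf(
                    "channel_policy 'as_is' requires a single-channel image: ",
                    path, class = "mgdf_format_error"))
    } else {
      stop_mgdf("unsupported channel count (", nch, ") in ", path,
                class = "mgdf_format_error")
    }
  } else {
    stop_mgdf("unsupported raster layout in ", path, class = "mgdf_format_error")
  }
  img <- g * 255
  check_image(img, "loaded image")
  img
}

#' Save an image
#'
#' Writes a numeric matrix (0-255 scale) to PNG, TIFF or PGM.  PNG and PGM
#' are 8-bit (values clamped to \[0, 255\] and quantised); TIFF is written
#' as 32-bit float of `pmin(pmax(img/255, 0), 1)`.
#'
#' @param img Numeric matrix on the 0-255 scale.
#' @param path Output path; format chosen by extension.
#' @return Invisibly, `path`.
#' @export
save_image <- function(img, path) {
  check_image(img)
  fmt <- img_format(path)
  v <- pmin(pmax(img / 255, 0), 1)
  switch(fmt,
         png = png::writePNG(v, path),
         tiff = suppressWarnings(tiff::writeTIFF(v, path, bits.per.sample = 32L)),
         pnm = write_pgm(round(v * 255), path))
  invisible(path)
}

#' Save / load a binary mask
#'
#' Masks are {0,1} matrices sharing the image grid; on disk they are
#' single-channel PNG with values {0, 255}.  The round-trip
#' `load_mask(save_mask(m))` is exact.
#'
#' @param mask Numeric matrix with values in {0, 1}.
#' @param path PNG path.
#' @return `save_mask` invisibly returns `path`; `load_mask` returns the
#'   {0,1} matrix.
#' @export
save_mask <- function(mask, path) {
  check_binary_mask(mask)
  ok <- tryCatch({png::writePNG(mask, path); TRUE},
                 error = function(e) FALSE)
  if (!ok)
    stop_mgdf("cannot write mask to ", path, class = "mgdf_io_error")
  invisible(path)
}

#' @rdname save_mask
#' @export
load_mask <- function(path) {
  a <- read_raster(path)
  if (!is.matrix(a)) {
    if (length(dim(a)) == 3L) a <- a[, , 1] else
      stop_mgdf("mask file has unsupported layout: ", path,
                class = "mgdf_format_error")
  }
  m <- (a >= 0.5) * 1
  m
}

#' Save / load a vesselness map
#'
#' Vesselness maps hold signed values in (-1, 1) and are persisted as
#' 32-bit float TIFF via the affine map `(v + 1) / 2`; loading inverts the
#' map.  Quantisation is that of IEEE float32 (relative error ~1e-7).
#'
#' @param v Numeric matrix with values in (-1, 1).
#' @param path TIFF path.
#' @return `save_vesselness` invisibly returns `path`; `load_vesselness`
#'   returns the signed matrix.
#' @export
save_vesselness <- function(v, path) {
  if (!is.matrix(v) || !all(is.finite(v)))
    stop_mgdf("vesselness map must be a finite numeric matrix",
              class = "mgdf_validation_error")
  if (any(abs(v) >= 1))
    stop_mgdf("vesselness values must lie in (-1, 1)",
              class = "mgdf_validation_error")
  suppressWarnings(tiff::writeTIFF((v + 1) / 2, path, bits.per.sample = 32L))
  invisible(path)
}

#' @rdname save_vesselness
#' @export
load_vesselness <- function(path) {
  a <- read_raster(path)
  if (!is.matrix(a))
    stop_mgdf("vesselness file must be single-channel: ", path,
              class = "mgdf_format_error")
  2 * a - 1
}

# --- minimal PNM (PGM/PPM) support ------------------------------------
# Binary (P5/P6) and ASCII (P2/P3), maxval <= 65535.  No installed R
# package reads PNM, hence this small reader/writer.

read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0 || ch == "")
        stop("unexpected end of PNM header")
      if (ch == "#") {                       # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0 || ch == "" || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok) else next
      }
      tok <- paste0(tok, ch)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported PNM magic: ", magic)
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  if (magic %in% c("P5", "P6")) {
    if (maxval < 256) {
      vals <- as.integer(readBin(con, "raw", n))
    } else {
      vals <- readBin(con, "integer", n, size = 2L, signed = FALSE,
                      endian = "big")
    }
  } else {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    vals <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])[seq_len(n)]
  }
  if (length(vals) < n || anyNA(vals)) stop("truncated PNM payload")
  v <- vals / maxval
  if (nch == 1L) {
    matrix(v, nrow = h, ncol = w, byrow = TRUE)
  } else {
    a <- array(0, c(h, w, 3L))
    for (k in 1:3)
      a[, , k] <- matrix(v[seq(k, n, by = 3L)], nrow = h, ncol = w, byrow = TRUE)
    a
  }
}

write_pgm <- function(img, path) {
  img <- pmin(pmax(round(img), 0), 255)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(img), nrow(img)), con,
            eos = NULL, useBytes = TRUE)
  writeBin(as.raw(as.integer(t(img))), con)
  invisible(path)
}
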