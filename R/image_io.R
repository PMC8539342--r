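#' Construct a calibrated grayscale micrograph
#'
#' A `gray_image` bundles a 2-D intensity matrix with the pixel-size
#' calibration and the contrast polarity of the imaging modality:
#' `"dark_particles"` for bright-field TEM (particles darker than the
#' support film) and `"bright_particles"` for ADF-STEM (particles brighter
#' than the background).
#'
#' @param pixels Numeric matrix of intensities, `[row, col]`, row 1 at the
#'   top. Values are kept as-is; no rescaling is applied.
#' @param nm_per_px Pixel size calibration in nanometres per pixel (> 0).
#' @param polarity `"dark_particles"` or `"bright_particles"`.
#' @return An object of class `gray_image` with elements `pixels`,
#'   `nm_per_px`, `polarity`.
#' @export
gray_image <- function(pixels, nm_per_px, polarity = "dark_particles") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop_input("pixels must be a numeric matrix")
  }
  if (nrow(pixels) < 16 || ncol(pixels) < 16) {
    stop_input("image must be at least 16 x 16 pixels")
  }
  if (!all(is.finite(pixels))) stop_input("all intensities must be finite")
  if (!is.numeric(nm_per_px) || length(nm_per_px) != 1 || nm_per_px <= 0) {
    stop_input("nm_per_px must be a positive scalar")
  }
  assert_polarity(polarity)
  structure(
    list(pixels = pixels * 1.0, nm_per_px = as.numeric(nm_per_px),
         polarity = polarity),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d px, %.4g nm/px, %s, intensity [%.4g, %.4g]\n",
    nrow(x$pixels), ncol(x$pixels), x$nm_per_px, x$polarity,
    min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

png_bit_depth <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 25L)
  if (length(header) < 25L) stop_input("not a PNG file: ", path)
  as.integer(header[25L])
}

#' Read a micrograph from a TIFF or PNG file
#'
#' Reads a single-frame 8- or 16-bit grayscale raster. RGB images whose
#' channels are identical (or near-identical) are collapsed to grayscale by
#' the channel mean. Intensities are returned on their native integer scale
#' (a 16-bit image keeps its 0..65535 range) but stored as floating point.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @inheritParams gray_image
#' @return A [gray_image].
#' @export
read_micrograph <- function(path, nm_per_px, polarity = "dark_particles") {
  if (!file.exists(path)) stop_input("file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- tryCatch(tiff::readTIFF(path, as.is = TRUE, all = TRUE),
                    error = function(e) {
                      stop_input("unreadable TIFF file: ", path)
                    })
    if (is.list(raw)) {
      if (length(raw) != 1L) {
        stop_input("multi-frame TIFF not supported: ", path)
      }
      raw <- raw[[1L]]
    }
    px <- raw
  } else if (ext == "png") {
    raw <- tryCatch(png::readPNG(path),
                    error = function(e) {
                      stop_input("unreadable PNG file: ", path)
                    })
    depth <- png_bit_depth(path)
    px <- round(raw * (2^depth - 1))  # PNG stores integer samples
  } else {
    stop_input("unsupported image format '", ext, "': ", path)
  }
  if (length(dim(px)) == 3L) {
    nch <- dim(px)[3L]
    ch <- if (nch >= 3L) 3L else nch          # drop any alpha channel
    px <- apply(px[, , seq_len(ch), drop = FALSE], c(1, 2), mean)
  }
  storage.mode(px) <- "double"
  gray_image(px, nm_per_px = nm_per_px, polarity = polarity)
}

#' Write a binary mask to an 8-bit image file
#'
#' Foreground (1) pixels are written as 255, background as 0, so the file
#' round-trips losslessly through [read_mask()].
#'
#' @param mask Integer/numeric matrix of 0/1.
#' @param path Output `.png` or `.tif`/`.tiff` path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  ext <- tolower(tools::file_ext(path))
  img <- mask * 1.0  # writePNG/writeTIFF expect [0,1]; 1 -> 255 at 8 bit
  ok <- tryCatch({
    if (ext == "png") {
      png::writePNG(img, target = path)
    } else if (ext %in% c("tif", "tiff")) {
      tiff::writeTIFF(img, where = path, bits.per.sample = 8L)
    } else {
      stop_input("unsupported mask format '", ext, "'")
    }
    TRUE
  }, error = function(e) stop_input("cannot write mask to ", path,
                                    ": ", conditionMessage(e)))
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#'
#' @param path Path to the mask image.
#' @return Integer matrix of 0/1.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop_input("file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  m <- matrix(as.integer(raw > 0.5), nrow(raw), ncol(raw))
  m
}

#' Write a 16-bit label raster to TIFF
#'
#' Used for the synthetic ground-truth channel: pixel value = particle id,
#' 0 = background. Supports up to 65535 labels.
#'
#' @param labels Integer matrix of non-negative labels.
#' @param path Output `.tif` path.
#' @return Invisibly, `path`.
#' @export
write_label_tiff <- function(labels, path) {
  if (!is.matrix(labels) || any(labels < 0) || any(labels > 65535)) {
    stop_input("labels must be a matrix of ids in 0..65535")
  }
  tiff::writeTIFF(labels / 65535, where = path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit label raster written by [write_label_tiff()]
#'
#' @param path Path to the label TIFF.
#' @return Integer matrix of labels.
#' @export
read_label_tiff <- function(path) {
  raw <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(raw) <- "integer"
  raw
}
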