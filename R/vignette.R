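#' Construct a particle vignette
#'
#' A vignette is the cut-out greyscale image of a single detected particle,
#' as stored by profiling cameras such as the Underwater Vision Profiler
#' (UVP). Grey values run from 0 (black) to 255 (white); particles are dark
#' objects on a light background.
#'
#' @param pixels Numeric matrix of grey values in `[0, 255]`.
#' @param object_id Opaque identifier for the particle (character scalar).
#' @param pixel_size_mm Physical length of one pixel edge, in millimetres.
#'   Instrument-specific; there is no universal default.
#' @return An object of class `snow_vignette`.
#' @examples
#' v <- snow_vignette(matrix(255, 9, 9), "obj1", pixel_size_mm = 0.08)
#' @export
snow_vignette <- function(pixels, object_id, pixel_size_mm) {
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    abort("`pixels` must be a non-empty matrix of grey values.")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    abort("grey values must lie in [0, 255] with no missing entries.")
  }
  if (!is.numeric(pixel_size_mm) || length(pixel_size_mm) != 1L ||
      is.na(pixel_size_mm) || pixel_size_mm <= 0) {
    abort("`pixel_size_mm` must be a single positive number.")
  }
  structure(
    list(
      pixels = pixels,
      object_id = as.character(object_id),
      pixel_size_mm = pixel_size_mm
    ),
    class = "snow_vignette"
  )
}

#' @export
print.snow_vignette <- function(x, ...) {
  cat(
    "<snow_vignette> ", x$object_id, ": ",
    nrow(x$pixels), "x", ncol(x$pixels), " px, ",
    format(x$pixel_size_mm), " mm/px\n",
    sep = ""
  )
  invisible(x)
}

#' Read and write greyscale vignette images
#'
#' Vignettes are stored as 8-bit greyscale PNG files named
#' `<object_id>.png`. RGB(A) input is converted to grey by averaging
#' channels.
#'
#' @param path Path to a PNG file (for reading) or target path (writing).
#' @param pixel_size_mm Pixel size in millimetres to attach on read.
#' @param object_id Identifier; defaults to the file name without extension.
#' @return `read_vignette()` returns a [snow_vignette()];
#'   `write_vignette()` returns `path` invisibly.
#' @export
read_vignette <- function(path, pixel_size_mm, object_id = NULL) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    img <- apply(img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE],
                 c(1, 2), mean)
  }
  if (is.null(object_id)) {
    object_id <- sub("\\.png$", "", basename(path), ignore.case = TRUE)
  }
  snow_vignette(round(img * 255), object_id, pixel_size_mm)
}

#' @rdname read_vignette
#' @param vignette A [snow_vignette()] to write.
#' @export
write_vignette <- function(vignette, path) {
  png::writePNG(vignette$pixels / 255, path)
  invisible(path)
}
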