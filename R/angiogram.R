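#' Scan-geometry specification for an en-face angiogram
#'
#' Describes the square en-face acquisition grid. The default matches a 3 x 3 mm
#' macular scan sampled by 245 A-scans per B-scan and 245 B-scans, so the pixel
#' pitch is `field_mm / width_px` mm.
#'
#' @param width_px,height_px Grid size in pixels; must be equal (square grid).
#' @param field_mm Physical side length of the field of view, in mm.
#' @param bit_depth Pixel bit depth; only 8-bit images are supported.
#' @return An object of class `image_spec` with the derived
#'   `scale_mm_per_px`.
#' @examples
#' sp <- image_spec()
#' sp$scale_mm_per_px   # 3/245 mm per pixel
#' @export
image_spec <- function(width_px = 245L, height_px = width_px,
                       field_mm = 3.0, bit_depth = 8L) {
  width_px <- as.integer(width_px); height_px <- as.integer(height_px)
  if (width_px < 8L || height_px < 8L) stop("grid too small", call. = FALSE)
  if (width_px != height_px) stop("scan grid must be square (width_px == height_px)", call. = FALSE)
  if (bit_depth != 8L) stop("only 8-bit images are supported", call. = FALSE)
  if (field_mm <= 0) stop("field_mm must be positive", call. = FALSE)
  structure(list(width_px = width_px, height_px = height_px,
                 field_mm = field_mm, bit_depth = 8L,
                 scale_mm_per_px = field_mm / width_px),
            class = "image_spec")
}

#' Construct an angiogram object
#'
#' Wraps an 8-bit pixel matrix (values 0-255, first index = x, second = y)
#' together with its physical scale, slab label and processing provenance.
#' The `processed` flag records whether the pixels have been thresholded or
#' re-rendered; mean-gray-value analysis refuses processed input.
#'
#' @param pixels Integer/numeric matrix with values in \[0, 255\].
#' @param scale_mm_per_px Pixel pitch in mm.
#' @param slab One of `"SCP"`, `"DCP"`, `"choriocapillaris"`.
#' @param source_path Optional provenance string.
#' @param processed Logical; `TRUE` if the image is no longer raw grayscale.
#' @return An `angiogram` object.
#' @export
angiogram <- function(pixels, scale_mm_per_px, slab = c("SCP", "DCP", "choriocapillaris"),
                      source_path = NA_character_, processed = FALSE) {
  slab <- match.arg(slab)
  if (!is.matrix(pixels)) stop("pixels must be a matrix", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  if (scale_mm_per_px <= 0) stop("scale_mm_per_px must be positive", call. = FALSE)
  structure(list(pixels = matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels)),
                 scale_mm_per_px = scale_mm_per_px, slab = slab,
                 source_path = source_path, processed = isTRUE(processed)),
            class = "angiogram")
}

#' @export
print.angiogram <- function(x, ...) {
  cat(sprintf("<angiogram> %dx%d px, %.4f mm/px, slab=%s, %s\n",
              nrow(x$pixels), ncol(x$pixels), x$scale_mm_per_px, x$slab,
              if (x$processed) "processed" else "raw"))
  invisible(x)
}

#' Read an angiogram image from disk
#'
#' Reads PNG, TIFF or JPEG via EBImage. RGB images are reduced to their red
#' channel with [extract_red_channel()]; JPEG input triggers a warning that
#' lossy compression may shift the automatic threshold.
#'
#' @param path Image file path.
#' @param scale_mm_per_px Pixel pitch in mm (e.g. `3/245`).
#' @param slab Slab label, see [angiogram()].
#' @param channel `"red"` to take the red plane of RGB input, `"gray"` to
#'   average the planes.
#' @return An `angiogram`.
#' @export
read_angiogram <- function(path, scale_mm_per_px, slab = "SCP", channel = c("red", "gray")) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  if (grepl("\\.jpe?g$", path, ignore.case = TRUE))
    warning("JPEG input: lossy compression may shift threshold values", call. = FALSE)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img) * 255
  if (length(dim(dat)) == 3 && channel == "gray")
    dat <- apply(dat[, , 1:3, drop = FALSE], c(1, 2), mean)
  a <- extract_red_channel(dat, scale_mm_per_px = scale_mm_per_px, slab = slab)
  a$source_path <- path
  a
}

#' Write an angiogram (or raw matrix) to an image file
#'
#' @param x An `angiogram`, or a matrix/array with values in \[0,255\].
#' @param path Output path; format chosen from the extension (.png/.tif/.jpg).
#' @param quality JPEG quality (ignored for lossless formats).
#' @return `path`, invisibly.
#' @export
write_angiogram <- function(x, path, quality = 92) {
  dat <- if (inherits(x, "angiogram")) x$pixels else x
  img <- EBImage::Image(dat / 255,
                        colormode = if (length(dim(dat)) == 3) "Color" else "Grayscale")
  EBImage::writeImage(img, path, quality = quality)
  invisible(path)
}
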