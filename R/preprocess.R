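#' Select the red channel of a loaded image
#'
#' En-face angiograms exported as RGB are reduced to a single reference plane
#' before thresholding; the red channel is used. Grayscale input passes
#' through unchanged (with a message). Input must already be 8-bit scaled
#' (values in \[0, 255\]); higher bit depths must be converted explicitly.
#'
#' @param img A matrix (grayscale) or 3-d array (RGB planes last) with values
#'   in \[0, 255\], or an `angiogram`.
#' @param scale_mm_per_px Pixel pitch, required when `img` is not already an
#'   `angiogram`.
#' @param slab Slab label for the result.
#' @return An `angiogram` holding the selected plane.
#' @export
extract_red_channel <- function(img, scale_mm_per_px = NULL, slab = "SCP") {
  if (inherits(img, "angiogram")) return(img)
  if (is.null(scale_mm_per_px)) stop("scale_mm_per_px is required", call. = FALSE)
  d <- dim(img)
  if (anyNA(img)) stop("image contains missing values", call. = FALSE)
  if (max(img) > 255 || min(img) < 0)
    stop("input is not 8-bit scaled: convert to [0, 255] explicitly first", call. = FALSE)
  if (max(img) <= 1 && max(img) > 0 && any(img != round(img)))
    stop("input looks float-scaled [0,1]: convert to [0, 255] explicitly first", call. = FALSE)
  if (length(d) == 2) {
    message("grayscale input: passed through unchanged")
    plane <- img
  } else if (length(d) == 3 && d[3] %in% c(3L, 4L)) {
    plane <- img[, , 1]
  } else stop("expected a 1- or 3-channel image", call. = FALSE)
  angiogram(plane, scale_mm_per_px, slab)
}

#' Threshold bounds
#'
#' Lower/upper gray-level bounds for binarization, with a record of whether
#' they came from the automatic default rule or were fixed by the user.
#'
#' @param lower,upper Gray levels, `0 <= lower <= upper <= 255`.
#' @param mode `"auto_default"` or `"fixed"`.
#' @return A `threshold_bounds` object.
#' @export
threshold_bounds <- function(lower, upper = 255L, mode = c("fixed", "auto_default")) {
  mode <- match.arg(mode)
  lower <- as.integer(lower); upper <- as.integer(upper)
  if (lower < 0L || upper > 255L || lower > upper)
    stop("require 0 <= lower <= upper <= 255", call. = FALSE)
  structure(list(lower = lower, upper = upper, mode = mode), class = "threshold_bounds")
}

#' Automatic default threshold (iterative intermeans / IsoData variant)
#'
#' Reproduces the default dark-background auto-threshold: starting from the
#' image mean, iterate `t <- floor((mean(pixels <= t) + mean(pixels > t)) / 2)`
#' on the 256-bin histogram until `t` is unchanged. Under the dark-background
#' convention the foreground (vessels) is bright, so the returned bounds are
#' `(t + 1, 255)`.
#'
#' @param a An `angiogram` (non-constant).
#' @return A `threshold_bounds` with `mode = "auto_default"`.
#' @examples
#' px <- matrix(c(rep(50, 50), rep(200, 50)), 10, 10)
#' a <- angiogram(px, 3 / 245)
#' auto_threshold_default(a)  # lower = 126
#' @export
auto_threshold_default <- function(a) {
  stopifnot(inherits(a, "angiogram"))
  px <- as.vector(a$pixels)
  if (min(px) == max(px)) stop("degenerate histogram: constant image", call. = FALSE)
  h <- tabulate(px + 1L, nbins = 256L)        # counts of levels 0..255
  lev <- 0:255
  csum_n <- cumsum(h)
  csum_s <- cumsum(h * lev)
  n <- length(px); s <- csum_s[256]
  t <- floor(s / n)
  lo <- min(px); hi <- max(px)
  for (it in seq_len(256L)) {
    t <- min(max(t, lo), hi - 1L)             # keep both classes non-empty
    n1 <- csum_n[t + 1L]; s1 <- csum_s[t + 1L]
    m1 <- s1 / n1
    m2 <- (s - s1) / (n - n1)
    t_new <- floor((m1 + m2) / 2)
    if (t_new == t) break
    t <- t_new
  }
  threshold_bounds(t + 1L, 255L, mode = "auto_default")
}

#' Binarize an angiogram into a vessel mask
#'
#' A pixel is classified as vessel when `lower <= value <= upper` (both bounds
#' inclusive, matching the in-range semantics of the thresholding tool the
#' bounds emulate). Idempotent: re-binarizing a rendered mask under the same
#' bounds reproduces it.
#'
#' @param a An `angiogram`.
#' @param b A `threshold_bounds`.
#' @return A `vessel_mask`: logical matrix (`TRUE` = vessel) with the parent
#'   scale and the bounds used.
#' @export
binarize <- function(a, b) {
  stopifnot(inherits(a, "angiogram"), inherits(b, "threshold_bounds"))
  m <- a$pixels >= b$lower & a$pixels <= b$upper
  structure(list(mask = m, scale_mm_per_px = a$scale_mm_per_px,
                 slab = a$slab, bounds_used = b),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %dx%d px, %.1f%% vessel, bounds [%d, %d] (%s)\n",
              nrow(x$mask), ncol(x$mask), 100 * mean(x$mask),
              x$bounds_used$lower, x$bounds_used$upper, x$bounds_used$mode))
  invisible(x)
}

#' Render a processed tri-color image
#'
#' Renders the analysis convention: vessels black, background white, FAZ
#' pixels blue. FAZ takes precedence where it overlaps a vessel pixel (the
#' FAZ region is excluded from both counts of the perfusion-density ratio).
#'
#' @param mask A `vessel_mask`.
#' @param faz Optional `faz_mask` on the same grid.
#' @return An 8-bit RGB array (x, y, 3) with values in \{0, 255\}.
#' @export
render_processed <- function(mask, faz = NULL) {
  stopifnot(inherits(mask, "vessel_mask"))
  m <- mask$mask
  if (!is.null(faz)) {
    stopifnot(inherits(faz, "faz_mask"))
    if (!all(dim(faz$mask) == dim(m))) stop("mask dimensions differ", call. = FALSE)
  }
  r <- g <- b <- matrix(255L, nrow(m), ncol(m))
  r[m] <- 0L; g[m] <- 0L; b[m] <- 0L
  if (!is.null(faz)) {
    f <- faz$mask
    r[f] <- 0L; g[f] <- 0L; b[f] <- 255L
  }
  out <- array(0L, c(dim(m), 3L))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}
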