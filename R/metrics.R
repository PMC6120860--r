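#' Perfusion density with FAZ exclusion
#'
#' Percentage of analyzed pixels classified as perfused vessel. FAZ pixels
#' are excluded from both the numerator and the denominator: vessel-labeled
#' pixels inside the FAZ do not count as vessel, and FAZ pixels do not count
#' toward the analyzed area.
#'
#' @param v A `vessel_mask`.
#' @param f Optional `faz_mask` on the same grid; `NULL` for the plain vessel
#'   fraction.
#' @return Perfusion density in percent.
#' @examples
#' m <- matrix(FALSE, 10, 10); m[1:30] <- TRUE
#' vm <- structure(list(mask = m, scale_mm_per_px = 3/245), class = "vessel_mask")
#' perfusion_density(vm)   # 30%
#' @export
perfusion_density <- function(v, f = NULL) {
  stopifnot(inherits(v, "vessel_mask"))
  m <- v$mask
  if (is.null(f)) return(100 * sum(m) / length(m))
  stopifnot(inherits(f, "faz_mask"))
  if (!all(dim(f$mask) == dim(m))) stop("mask dimensions differ", call. = FALSE)
  denom <- length(m) - sum(f$mask)
  if (denom <= 0) stop("empty denominator: FAZ covers the whole image", call. = FALSE)
  100 * sum(m & !f$mask) / denom
}

#' Choriocapillaris mean gray value
#'
#' Arithmetic mean gray level of the unprocessed 8-bit choriocapillaris
#' en-face image, used as a proxy for choroidal blood flow. Refuses images
#' whose provenance flag marks them as thresholded/processed, and images from
#' other slabs.
#'
#' @param a An `angiogram` with `slab = "choriocapillaris"`, unprocessed.
#' @return Mean gray value (full precision).
#' @export
choriocapillaris_mgv <- function(a) {
  stopifnot(inherits(a, "angiogram"))
  if (a$slab != "choriocapillaris")
    stop("MGV is defined on the choriocapillaris slab", call. = FALSE)
  if (isTRUE(a$processed))
    stop("MGV requires unprocessed image", call. = FALSE)
  mean(a$pixels)
}

#' Ellipsoid-zone line width from a reflectivity profile
#'
#' Automated width of the EZ band on a horizontal foveal B-scan reflectivity
#' profile: the profile is smoothed with a moving average (window 5), and the
#' widest contiguous run above half-maximum contrast that contains the
#' profile peak is converted to micrometers at `scan_mm * 1000 / length(px)`
#' um per pixel.
#'
#' @param profile Numeric vector of reflectivities (length >= 16).
#' @param scan_mm Physical scan length in mm (default 9).
#' @return Width in micrometers; 0 (with a warning) for a flat profile.
#' @export
ez_width <- function(profile, scan_mm = 9.0) {
  profile <- as.numeric(profile)
  n <- length(profile)
  if (n < 16) stop("profile too short (need >= 16 samples)", call. = FALSE)
  um_per_px <- scan_mm * 1000 / n
  k <- 5L
  sm <- stats::filter(profile, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)
  # moving average is NA at the ends; pad with edge values
  sm[is.na(sm)] <- profile[is.na(sm)]
  lo <- min(sm); hi <- max(sm)
  if (hi - lo < 1e-6 * max(1, abs(hi))) {
    warning("flat profile: EZ width 0", call. = FALSE)
    return(0)
  }
  level <- lo + 0.5 * (hi - lo)
  above <- sm >= level
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peak <- which.max(sm)
  run <- which(r$values & starts <= peak & ends >= peak)
  if (length(run) == 0) return(0)
  r$lengths[run] * um_per_px
}

#' Manual EZ width from boundary columns
#'
#' Width between two manually placed boundary columns, inclusive of both:
#' `(right - left + 1)` pixels converted at `scan_mm * 1000 / length_px`
#' micrometers per pixel.
#'
#' @param left_px,right_px Boundary columns, `0 <= left < right < length_px`
#'   (0-based, as read off a measurement caliper).
#' @param length_px Profile length in pixels.
#' @param scan_mm Physical scan length in mm.
#' @return Width in micrometers.
#' @examples
#' ez_width_manual(360, 663, 1024)  # ~2671.9 um
#' @export
ez_width_manual <- function(left_px, right_px, length_px, scan_mm = 9.0) {
  if (left_px < 0 || right_px <= left_px || right_px >= length_px)
    stop("require 0 <= left < right < length_px", call. = FALSE)
  (right_px - left_px + 1) * scan_mm * 1000 / length_px
}

#' Change over time
#'
#' The study's progression-rate estimator: difference between the follow-up
#' and baseline values divided by the follow-up length in years. Negative
#' values indicate decline.
#'
#' @param visit1_value,visit2_value Baseline and follow-up measurements.
#' @param dt_years Follow-up interval in years, `> 0`.
#' @return Rate in units per year.
#' @examples
#' change_over_time(33.4, 30.4, 1.24)   # -2.42 %/yr
#' @export
change_over_time <- function(visit1_value, visit2_value, dt_years) {
  if (any(dt_years <= 0)) stop("dt_years must be positive", call. = FALSE)
  (visit2_value - visit1_value) / dt_years
}
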