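new_faz_mask <- function(mask, scale_mm_per_px, method) {
  structure(list(mask = mask, scale_mm_per_px = scale_mm_per_px,
                 area_mm2 = sum(mask) * scale_mm_per_px^2, method = method),
            class = "faz_mask")
}

#' @export
print.faz_mask <- function(x, ...) {
  cat(sprintf("<faz_mask> %dx%d px, %d px / %.4f mm^2, method=%s\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$area_mm2, x$method))
  invisible(x)
}

# TRUE where the pixel center (px, py) lies inside or on the closed polygon,
# even-odd rule. Vectorised crossing-number test with an explicit on-boundary
# check so boundary pixels are included.
point_in_polygon_ <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # on-segment test
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    within <- px >= pmin(xi, xj) - 1e-9 & px <= pmax(xi, xj) + 1e-9 &
      py >= pmin(yi, yj) - 1e-9 & py <= pmax(yi, yj) + 1e-9
    onedge <- onedge | (abs(cross) < 1e-9 & within)
    # crossing-number update (half-open in y to count each crossing once)
    crosses <- ((yi > py) != (yj > py)) &
      (px < xi + (py - yi) * (xj - xi) / (yj - yi))
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onedge
}

# TRUE if any two non-adjacent edges of the closed polygon properly intersect.
polygon_self_intersects_ <- function(vx, vy) {
  n <- length(vx)
  seg <- cbind(vx, vy, c(vx[-1], vx[1]), c(vy[-1], vy[1]))
  orient <- function(ax, ay, bx, by, cx, cy) sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  for (i in seq_len(n - 2L)) {
    for (j in seq.int(i + 2L, n)) {
      if (i == 1L && j == n) next   # closing edge is adjacent to the first
      a <- seg[i, ]; b <- seg[j, ]
      o1 <- orient(a[1], a[2], a[3], a[4], b[1], b[2])
      o2 <- orient(a[1], a[2], a[3], a[4], b[3], b[4])
      o3 <- orient(b[1], b[2], b[3], b[4], a[1], a[2])
      o4 <- orient(b[1], b[2], b[3], b[4], a[3], a[4])
      if (o1 != o2 && o3 != o4 && all(c(o1, o2, o3, o4) != 0)) return(TRUE)
    }
  }
  FALSE
}

#' FAZ mask from a free-hand polygon outline
#'
#' Rasterizes a closed polygon of pixel coordinates (the manual free-hand
#' outline) into a FAZ mask using the even-odd fill rule with pixel-center
#' inclusion; boundary pixels count as inside. Area is the filled pixel count
#' times the squared pixel pitch.
#'
#' @param vertices Two-column matrix or data.frame of (x_px, y_px) vertices in
#'   order; the polygon is closed automatically. At least 3 non-collinear
#'   vertices; must be simple (non-self-intersecting).
#' @param grid An [image_spec()] describing the raster.
#' @return A `faz_mask` with `method = "manual_polygon"`.
#' @examples
#' sp <- image_spec()
#' sq <- cbind(c(100, 148, 148, 100), c(100, 100, 148, 148))
#' faz_from_polygon(sq, sp)$area_mm2  # 49*49 px -> ~0.360 mm^2
#' @export
faz_from_polygon <- function(vertices, grid) {
  stopifnot(inherits(grid, "image_spec"))
  v <- as.matrix(vertices)
  if (ncol(v) != 2 || nrow(v) < 3) stop("need >= 3 (x, y) vertices", call. = FALSE)
  vx <- as.numeric(v[, 1]); vy <- as.numeric(v[, 2])
  # degenerate (zero-area / collinear) outline
  shoelace <- abs(sum(vx * c(vy[-1], vy[1]) - c(vx[-1], vx[1]) * vy)) / 2
  if (shoelace < 1e-9) stop("degenerate outline: vertices are collinear", call. = FALSE)
  if (polygon_self_intersects_(vx, vy)) stop("polygon is self-intersecting", call. = FALSE)
  W <- grid$width_px; H <- grid$height_px
  if (min(vx) < 1 || max(vx) > W || min(vy) < 1 || max(vy) > H)
    warning("polygon exits image bounds; clipped to the raster", call. = FALSE)
  xr <- max(1L, floor(min(vx))):min(W, ceiling(max(vx)))
  yr <- max(1L, floor(min(vy))):min(H, ceiling(max(vy)))
  gx <- rep(xr, times = length(yr))
  gy <- rep(yr, each = length(xr))
  inside <- point_in_polygon_(gx, gy, vx, vy)
  mask <- matrix(FALSE, W, H)
  mask[cbind(gx[inside], gy[inside])] <- TRUE
  new_faz_mask(mask, grid$scale_mm_per_px, "manual_polygon")
}

#' FAZ mask from a binary raster file or matrix
#'
#' Ingests a manually drawn binary mask (e.g. a PNG where FAZ pixels are
#' non-zero). If the mask has several 4-connected components the largest is
#' kept with a warning.
#'
#' @param x Path to a binary image, or a logical/0-1 matrix.
#' @param scale_mm_per_px Pixel pitch in mm.
#' @return A `faz_mask` with `method = "manual_mask"`.
#' @export
faz_from_mask <- function(x, scale_mm_per_px) {
  if (is.character(x)) {
    dat <- EBImage::imageData(EBImage::readImage(x))
    if (length(dim(dat)) == 3) dat <- dat[, , 1]
    m <- dat > 0.5
  } else m <- x > 0
  if (!any(m)) stop("mask is empty", call. = FALSE)
  lab <- EBImage::bwlabel(m)
  if (max(lab) > 1) {
    warning("mask has multiple components; keeping the largest", call. = FALSE)
    sizes <- tabulate(lab[lab > 0])
    m <- lab == which.max(sizes)
  }
  new_faz_mask(m, scale_mm_per_px, "manual_mask")
}

#' Automated FAZ surrogate by morphological closing and flood fill
#'
#' Automated stand-in for the manual free-hand outline, enabling unattended
#' cohort runs: the binarized vessel mask is morphologically closed (disc of
#' radius `r_close`) to seal inter-capillary gaps, then the avascular region
#' is grown by 4-connected flood fill from a seed at the image center (scans
#' are fovea-centered). The filled component is the FAZ.
#'
#' @param mask A `vessel_mask`.
#' @param seed_point Optional `(x, y)` pixel seed; default is the image
#'   center. If the seed lands on a (closed) vessel pixel, a 5x5
#'   neighborhood is searched for a background seed.
#' @param r_close Closing disc radius in px (default 2, ~24 um at 3 mm/245 px).
#' @return A `faz_mask` with `method = "auto_region_grow"`.
#' @export
faz_auto <- function(mask, seed_point = NULL, r_close = 2L) {
  stopifnot(inherits(mask, "vessel_mask"))
  m <- mask$mask
  W <- nrow(m); H <- ncol(m)
  closed <- if (r_close > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(r_close) + 1L, shape = "disc")
    EBImage::closing(m * 1, brush) > 0.5
  } else m
  open <- !closed
  if (is.null(seed_point)) seed_point <- c(round((W + 1) / 2), round((H + 1) / 2))
  sx <- as.integer(seed_point[1]); sy <- as.integer(seed_point[2])
  if (sx < 1 || sx > W || sy < 1 || sy > H) stop("seed outside image", call. = FALSE)
  if (!open[sx, sy]) {
    nb <- expand.grid(x = pmax(1, sx - 2):pmin(W, sx + 2),
                      y = pmax(1, sy - 2):pmin(H, sy + 2))
    ok <- open[cbind(nb$x, nb$y)]
    if (!any(ok)) stop("no avascular seed near center", call. = FALSE)
    d2 <- (nb$x - sx)^2 + (nb$y - sy)^2
    d2[!ok] <- Inf
    k <- which.min(d2)
    sx <- nb$x[k]; sy <- nb$y[k]
  }
  filled <- flood_fill4_(open, cbind(sx, sy), leak_frac = 0.5)
  if (isTRUE(attr(filled, "leaked")) || sum(filled) > 0.5 * length(filled))
    stop("unbounded FAZ (vessel ring broken)", call. = FALSE)
  attr(filled, "leaked") <- NULL
  new_faz_mask(filled, mask$scale_mm_per_px, "auto_region_grow")
}

#' FAZ area growth rate between two visits
#'
#' Change over time of the FAZ area: the difference between follow-up and
#' baseline areas divided by the follow-up length in years.
#'
#' @param visit1,visit2 `faz_mask` objects (or numbers in mm^2).
#' @param dt_years Follow-up interval in years, `> 0`.
#' @return Growth rate in mm^2 per year.
#' @export
faz_growth <- function(visit1, visit2, dt_years) {
  a1 <- if (inherits(visit1, "faz_mask")) visit1$area_mm2 else as.numeric(visit1)
  a2 <- if (inherits(visit2, "faz_mask")) visit2$area_mm2 else as.numeric(visit2)
  change_over_time(a1, a2, dt_years)
}
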