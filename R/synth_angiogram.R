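new_vessel_truth <- function(vessel, faz, spec) {
  n_faz <- sum(faz)
  denom <- length(vessel) - n_faz
  structure(list(vessel_mask = vessel, faz_mask = faz,
                 true_pd_pct = 100 * sum(vessel) / denom,
                 true_faz_mm2 = n_faz * spec$scale_mm_per_px^2,
                 spec = spec),
            class = "vessel_truth")
}

#' @export
print.vessel_truth <- function(x, ...) {
  cat(sprintf("<vessel_truth> PD %.2f%%, FAZ %.4f mm^2 (%d px)\n",
              x$true_pd_pct, x$true_faz_mm2, sum(x$faz_mask)))
  invisible(x)
}

# Star-convex avascular region: a disk whose radius is modulated by a smooth
# random periodic perturbation, carved to exactly `n_px` pixels by taking the
# pixels with the smallest (distance / boundary-radius) ratio.
faz_region_ <- function(spec, n_px, center = NULL) {
  W <- spec$width_px; H <- spec$height_px
  mask <- matrix(FALSE, W, H)
  if (n_px <= 0) return(mask)
  if (is.null(center))
    center <- c((W + 1) / 2 + runif(1, -3, 3), (H + 1) / 2 + runif(1, -3, 3))
  r0 <- sqrt(n_px / pi)
  if (r0 + 4 > min(center[1], center[2], W - center[1], H - center[2]))
    stop("target FAZ does not fit inside the field", call. = FALSE)
  a <- runif(4, -0.12, 0.12) / (1:4)
  ph <- runif(4, 0, 2 * pi)
  x <- rep(seq_len(W), times = H) - center[1]
  y <- rep(seq_len(H), each = W) - center[2]
  th <- atan2(y, x)
  rb <- r0 * (1 + a[1] * cos(2 * th + ph[1]) + a[2] * cos(3 * th + ph[2]) +
                a[3] * cos(4 * th + ph[3]) + a[4] * cos(5 * th + ph[4]))
  ratio <- sqrt(x^2 + y^2) / pmax(rb, 1e-6)
  keep <- order(ratio)[seq_len(n_px)]
  mask[keep] <- TRUE
  mask
}

# Capillary ring hugging the FAZ boundary: a band immediately outside the
# region, so the avascular zone is sealed against 4-connected flood fill.
faz_ring_ <- function(faz, thickness = 2L) {
  if (!any(faz)) return(faz)
  g <- faz
  for (k in seq_len(thickness)) g <- grow4_(g)
  g & !faz
}

# Thickest ring (2 px preferred, 1 px fallback) that fits the vessel budget.
faz_ring_budgeted_ <- function(faz, n_v) {
  ring <- faz_ring_(faz, 2L)
  if (sum(ring) > n_v) ring <- faz_ring_(faz, 1L)
  if (sum(ring) > n_v)
    stop("unreachable target: target_pd too low to maintain the perifoveal ring",
         call. = FALSE)
  ring
}

# Seeded branching random-walk vasculature: trunks enter from the field edge,
# walk with direction persistence toward/past the center, and branch with a
# fixed probability; each walker has a stroke width of 1-3 px.
vessel_network_ <- function(spec, faz, n_trunks = 16L, branch_p = 0.10,
                            max_walkers = 90L, max_steps = 420L) {
  W <- spec$width_px; H <- spec$height_px
  side <- sample(4L, n_trunks, replace = TRUE)
  u <- runif(n_trunks, 0.05, 0.95)
  px <- ifelse(side == 1L, 1, ifelse(side == 2L, W, u * W))
  py <- ifelse(side == 3L, 1, ifelse(side == 4L, H, u * H))
  ang <- atan2(H / 2 - py, W / 2 - px) + runif(n_trunks, -0.5, 0.5)
  wdt <- sample(1:3, n_trunks, replace = TRUE, prob = c(0.3, 0.45, 0.25))
  alive <- rep(TRUE, n_trunks)
  pts_x <- vector("list", max_steps); pts_y <- pts_x; pts_w <- pts_x
  for (s in seq_len(max_steps)) {
    if (!any(alive)) break
    i <- which(alive)
    px[i] <- px[i] + cos(ang[i]); py[i] <- py[i] + sin(ang[i])
    ang[i] <- ang[i] + rnorm(length(i), 0, 0.22)
    out <- px < 1 | px > W | py < 1 | py > H
    alive <- alive & !out
    i <- which(alive)
    if (length(i) == 0) break
    ix <- round(px[i]); iy <- round(py[i])
    infaz <- faz[cbind(ix, iy)]
    if (any(infaz)) { alive[i[infaz]] <- FALSE; i <- i[!infaz] }
    if (length(i) == 0) next
    pts_x[[s]] <- round(px[i]); pts_y[[s]] <- round(py[i]); pts_w[[s]] <- wdt[i]
    # branching
    nb <- i[runif(length(i)) < branch_p]
    nb <- head(nb, max_walkers - length(px))
    if (length(nb) > 0) {
      px <- c(px, px[nb]); py <- c(py, py[nb])
      ang <- c(ang, ang[nb] + sample(c(-1, 1), length(nb), TRUE) * runif(length(nb), 0.4, 1.0))
      wdt <- c(wdt, pmax(1L, wdt[nb] - sample(0:1, length(nb), TRUE)))
      alive <- c(alive, rep(TRUE, length(nb)))
    }
  }
  xs <- unlist(pts_x); ys <- unlist(pts_y); ws <- unlist(pts_w)
  v <- matrix(FALSE, W, H)
  if (length(xs) == 0) return(v)
  stamp <- function(dx, dy, sel) {
    x2 <- xs[sel] + dx; y2 <- ys[sel] + dy
    ok <- x2 >= 1 & x2 <= W & y2 >= 1 & y2 <= H
    v[cbind(x2[ok], y2[ok])] <<- TRUE
  }
  stamp(0L, 0L, TRUE)
  w2 <- ws >= 2L
  if (any(w2)) { stamp(1L, 0L, w2); stamp(0L, 1L, w2) }
  w3 <- ws >= 3L
  if (any(w3)) { stamp(-1L, 0L, w3); stamp(0L, -1L, w3); stamp(1L, 1L, w3) }
  v
}

# Add or prune vessel pixels until the mask holds exactly `target_n` pixels.
# Additions thicken existing vessels (background pixels 4-adjacent to vessel,
# `prefer` candidates first); removals thin vessel boundaries, never touching
# `protect` (the sealing ring) or placing vessels in `forbid`; pixels in
# `avoid` (the wider perifoveal margin) are pruned only once everything else
# is exhausted.
adjust_vessel_count_ <- function(v, target_n, forbid, protect, prefer = NULL,
                                 avoid = NULL) {
  for (iter in seq_len(500L)) {
    need <- target_n - sum(v)
    if (need == 0L) return(v)
    if (need > 0L) {
      cand <- which(grow4_(v) & !v & !forbid)
      if (!is.null(prefer)) {
        pref <- cand[prefer[cand]]
        rest <- setdiff(cand, pref)
        cand <- c(pref, resample_(rest, length(rest)))
      }
      if (length(cand) == 0L) {
        if (!any(v)) { cand <- which(!forbid) } else
          stop("unreachable perfusion-density target: no room to add vessel pixels",
               call. = FALSE)
      }
      if (length(cand) <= need) v[cand] <- TRUE
      else {
        take <- if (is.null(prefer)) resample_(cand, need)
        else cand[seq_len(need)]         # preferred candidates are pre-ordered
        v[take] <- TRUE
      }
    } else {
      boundary <- v & grow4_(!v) & !protect
      cand <- which(if (is.null(avoid)) boundary else boundary & !avoid)
      if (length(cand) == 0L && !is.null(avoid)) cand <- which(boundary)
      if (length(cand) == 0L) cand <- which(v & !protect)
      if (length(cand) == 0L)
        stop("unreachable perfusion-density target: only protected vessel pixels remain",
             call. = FALSE)
      if (length(cand) <= -need) v[cand] <- FALSE
      else v[resample_(cand, -need)] <- FALSE
    }
  }
  stop("vessel count adjustment did not converge", call. = FALSE)
}

# Render a binary vessel layout as an 8-bit angiogram: bright vessels on a
# dark background with additive speckle-like Gaussian noise, per-image
# brightness jitter so automatic thresholds vary realistically across scans.
render_angiogram_ <- function(vessel, spec, slab, noise_sd = 6) {
  bg <- runif(1, 8, 16)
  vl <- min(max(rnorm(1, 110, 12), 75), 160)
  px <- bg + (vl - bg) * vessel + rnorm(length(vessel), 0, noise_sd)
  px <- matrix(pmin(255, pmax(0, round(px))), nrow(vessel), ncol(vessel))
  angiogram(px, spec$scale_mm_per_px, slab)
}

#' Generate a synthetic en-face angiogram with known ground truth
#'
#' Builds a branching vascular network by seeded biased random walks (trunks
#' entering from the field edge, branching, stroke width 1-3 px), carves an
#' irregular star-convex central avascular zone of exactly the requested
#' pixel area ringed by a hugging capillary band, and then adds/prunes vessel
#' pixels until the ground-truth perfusion density matches the target. The
#' mask is rendered as bright-vessels-on-dark with speckle noise.
#'
#' @param spec An [image_spec()].
#' @param target_pd Target perfusion density in percent, `0 <= target_pd < 100`
#'   (0 produces an all-background image with no vessels).
#' @param target_faz_mm2 Target FAZ area in mm^2 (0 for no FAZ).
#' @param seed Integer seed; identical inputs give bit-identical output.
#' @param slab Slab label for the rendered image.
#' @param noise_sd Additive Gaussian noise SD in gray levels.
#' @return A list with `image` (an `angiogram`) and `truth` (a
#'   `vessel_truth` holding the vessel/FAZ masks and achieved PD/area).
#' @examples
#' g <- generate_angiogram(image_spec(128), 30, 0.1, seed = 1)
#' g$truth
#' @export
generate_angiogram <- function(spec, target_pd, target_faz_mm2, seed,
                               slab = "SCP", noise_sd = 6) {
  stopifnot(inherits(spec, "image_spec"))
  if (target_pd < 0 || target_pd >= 100)
    stop("target_pd must lie in [0, 100)", call. = FALSE)
  if (target_faz_mm2 < 0) stop("target_faz_mm2 must be >= 0", call. = FALSE)
  with_seed_(seed, {
    N <- spec$width_px * spec$height_px
    n_faz <- as.integer(round(target_faz_mm2 / spec$scale_mm_per_px^2))
    faz <- faz_region_(spec, n_faz)
    n_v <- as.integer(round(target_pd / 100 * (N - n_faz)))
    if (n_v > N - n_faz)
      stop("unreachable target: target_pd exceeds available non-FAZ area", call. = FALSE)
    if (n_v == 0L) {
      v <- matrix(FALSE, spec$width_px, spec$height_px)
    } else {
      ring <- faz_ring_budgeted_(faz, n_v)
      v <- vessel_network_(spec, faz) | ring
      v <- v & !faz
      margin <- if (n_faz > 0) grow4_(grow4_(grow4_(faz))) & !faz
      else matrix(FALSE, spec$width_px, spec$height_px)
      v <- adjust_vessel_count_(v, n_v, forbid = faz, protect = ring,
                                avoid = margin)
    }
    list(image = render_angiogram_(v, spec, slab, noise_sd),
         truth = new_vessel_truth(v, faz, spec))
  })
}

# Grow (or shrink) a FAZ region to exactly `n_target` pixels, one boundary
# shell at a time, preferring pixels that keep the region compact.
resize_faz_ <- function(faz, n_target, spec) {
  n_target <- as.integer(n_target)
  if (n_target < 0L) stop("FAZ area cannot be negative", call. = FALSE)
  if (n_target > 0L && !any(faz))
    return(faz_region_(spec, n_target))
  W <- nrow(faz); H <- ncol(faz)
  if (any(faz)) {
    idx <- which(faz)
    cx <- mean((idx - 1L) %% W + 1L); cy <- mean((idx - 1L) %/% W + 1L)
  } else { cx <- (W + 1) / 2; cy <- (H + 1) / 2 }
  dist_from_center <- function(ii) {
    x <- (ii - 1L) %% W + 1L; y <- (ii - 1L) %/% W + 1L
    sqrt((x - cx)^2 + (y - cy)^2)
  }
  for (it in seq_len(2000L)) {
    need <- n_target - sum(faz)
    if (need == 0L) return(faz)
    if (need > 0L) {
      band <- which(grow4_(faz) & !faz)
      if (length(band) == 0L) stop("FAZ growth has no room", call. = FALSE)
      if (any(dist_from_center(band) > min(cx, cy, W - cx, H - cy) - 4))
        stop("grown FAZ does not fit inside the field", call. = FALSE)
      if (length(band) <= need) faz[band] <- TRUE
      else {
        ord <- order(dist_from_center(band) + runif(length(band), 0, 0.75))
        faz[band[ord[seq_len(need)]]] <- TRUE
      }
    } else {
      band <- which(faz & grow4_(!faz))
      if (length(band) <= -need) faz[band] <- FALSE
      else {
        ord <- order(-(dist_from_center(band) + runif(length(band), 0, 0.75)))
        faz[band[ord[seq_len(-need)]]] <- FALSE
      }
    }
  }
  stop("FAZ resizing did not converge", call. = FALSE)
}

#' Derive a follow-up angiogram by degrading a baseline truth
#'
#' Realizes the follow-up visit of a longitudinal pair: the avascular zone is
#' dilated (or, for negative deltas, contracted) to the requested area change
#' and vessel pixels are pruned (or added, for positive density deltas) until
#' the perfusion-density change matches the request. The capillary margin is
#' re-formed as a tight ring at the new FAZ boundary so the zone remains
#' measurable by the flood-fill segmenter; apart from that <= 3 px boundary
#' band, a negative density delta only removes vessel pixels, and a
#' non-negative area delta never removes FAZ pixels.
#'
#' @param base A `vessel_truth` from [generate_angiogram()] (visit 1).
#' @param pd_delta_pct Signed change in perfusion density, percentage points.
#' @param faz_delta_mm2 Signed change in FAZ area, mm^2.
#' @param seed Integer seed.
#' @param slab,noise_sd Rendering parameters, see [generate_angiogram()].
#' @return A list with `image` and `truth` for the follow-up visit.
#' @export
degrade_angiogram <- function(base, pd_delta_pct, faz_delta_mm2, seed,
                              slab = "SCP", noise_sd = 6) {
  stopifnot(inherits(base, "vessel_truth"))
  spec <- base$spec
  N <- spec$width_px * spec$height_px
  pd2 <- base$true_pd_pct + pd_delta_pct
  if (pd2 <= 0 || pd2 >= 100)
    stop("resulting perfusion density must lie in (0, 100)", call. = FALSE)
  with_seed_(seed, {
    n_faz1 <- sum(base$faz_mask)
    n_faz2 <- n_faz1 + as.integer(round(faz_delta_mm2 / spec$scale_mm_per_px^2))
    if (n_faz2 < 0L) stop("resulting FAZ area cannot be negative", call. = FALSE)
    faz2 <- resize_faz_(base$faz_mask, n_faz2, spec)
    vacated <- base$faz_mask & !faz2
    v <- (base$vessel_mask | vacated) & !faz2
    n_v2 <- as.integer(round(pd2 / 100 * (N - n_faz2)))
    ring2 <- tryCatch(faz_ring_budgeted_(faz2, n_v2), error = function(e)
      stop("requested density delta exceeds available vessel pixels", call. = FALSE))
    v <- v | ring2
    margin <- if (n_faz2 > 0) grow4_(grow4_(grow4_(faz2))) & !faz2
    else matrix(FALSE, spec$width_px, spec$height_px)
    v <- adjust_vessel_count_(v, n_v2, forbid = faz2, protect = ring2,
                              prefer = margin, avoid = margin)
    list(image = render_angiogram_(v, spec, slab, noise_sd),
         truth = new_vessel_truth(v, faz2, spec))
  })
}

#' Generate a synthetic choriocapillaris texture
#'
#' Homogeneous granular 8-bit texture: i.i.d. Gaussian gray levels about the
#' target mean, rounded to integers and clipped to \[0, 255\]. With
#' `noise_sd = 0` the image is constant at the nearest representable 8-bit
#' level (so a target of 99.5 rounds to 100).
#'
#' @param spec An [image_spec()].
#' @param target_mgv Target mean gray value in \[0, 255\].
#' @param noise_sd Gaussian texture SD in gray levels.
#' @param seed Integer seed.
#' @return An `angiogram` with `slab = "choriocapillaris"`.
#' @export
generate_choriocapillaris <- function(spec, target_mgv, noise_sd = 10, seed = 1L) {
  stopifnot(inherits(spec, "image_spec"))
  if (target_mgv < 0 || target_mgv > 255)
    stop("target_mgv must lie in [0, 255]", call. = FALSE)
  with_seed_(seed, {
    N <- spec$width_px * spec$height_px
    px <- if (noise_sd == 0) rep(round(target_mgv), N)
    else pmin(255, pmax(0, round(rnorm(N, target_mgv, noise_sd))))
    angiogram(matrix(px, spec$width_px, spec$height_px),
              spec$scale_mm_per_px, slab = "choriocapillaris")
  })
}

#' Generate a synthetic foveal reflectivity profile with an EZ band
#'
#' 1-D stand-in for a horizontal foveal B-scan: an elevated plateau of the
#' requested physical width (converted at `scan_mm * 1000 / length_px` um per
#' pixel), with smoothed shoulders (Gaussian kernel) and additive noise.
#'
#' @param length_px Number of A-scan columns (default 1024).
#' @param scan_mm Physical scan length in mm (default 9).
#' @param band_center_px Plateau center column.
#' @param band_width_um Plateau width in micrometers; must fit in the scan.
#' @param contrast Plateau elevation above baseline, in reflectivity units.
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Integer seed.
#' @param baseline Baseline reflectivity level.
#' @return Numeric profile of length `length_px`, with attributes
#'   `true_width_um` (the realized plateau width after pixel rounding) and
#'   `true_width_px`.
#' @export
generate_ez_profile <- function(length_px = 1024L, scan_mm = 9.0,
                                band_center_px = (length_px + 1) / 2,
                                band_width_um, contrast = 120, noise_sd = 0,
                                seed = 1L, baseline = 40) {
  length_px <- as.integer(length_px)
  um_per_px <- scan_mm * 1000 / length_px
  if (band_width_um < 0) stop("band_width_um must be >= 0", call. = FALSE)
  if (band_width_um > scan_mm * 1000)
    stop("band wider than the scan length", call. = FALSE)
  w_px <- as.integer(round(band_width_um / um_per_px))
  with_seed_(seed, {
    prof <- rep(baseline, length_px)
    if (w_px > 0) {
      c0 <- as.integer(round(band_center_px - (w_px - 1) / 2))
      c1 <- c0 + w_px - 1L
      if (c0 < 1L || c1 > length_px)
        stop("band does not fit within the scan at this center", call. = FALSE)
      prof[c0:c1] <- baseline + contrast
      # smooth shoulders: symmetric Gaussian kernel keeps the half-maximum
      # crossings at the plateau edges
      kk <- dnorm(-4:4, sd = 1.3); kk <- kk / sum(kk)
      padded <- c(rep(prof[1], 4), prof, rep(prof[length_px], 4))
      prof <- as.numeric(stats::filter(padded, kk, sides = 2))[5:(length_px + 4)]
    }
    if (noise_sd > 0) prof <- prof + rnorm(length_px, 0, noise_sd)
    attr(prof, "true_width_px") <- w_px
    attr(prof, "true_width_um") <- w_px * um_per_px
    prof
  })
}
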