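#' Default per-metric population parameters for a simulated RP cohort
#'
#' Baseline (visit-1) means and between-eye SDs, and yearly progression-rate
#' means and dispersions, for the seven per-eye metrics: SCP/DCP perfusion
#' density (%), SCP/DCP FAZ area (mm^2), choriocapillaris mean gray value,
#' EZ line width (um), and BCVA (logMAR). The printed dispersion of a
#' progression rate is the standard error of the cohort mean (the rate
#' P-values are only consistent with that reading), so the between-eye SD of
#' the per-eye rates is `rate_sem * sqrt(28)` -- a property of the study
#' population, kept fixed regardless of the simulated sample size.
#' `baseline_lo/hi` truncate baseline draws to physiologically sensible
#' values; `feas_lo/hi` clamp realized visit values to what an image can
#' encode.
#'
#' @return A data.frame with one row per metric.
#' @export
default_metric_params <- function() {
  n_ref <- 28
  data.frame(
    metric        = c("scp_pd", "dcp_pd", "scp_faz", "dcp_faz", "cc_mgv", "ez_um", "bcva"),
    baseline_mean = c(33.4, 24.5, 0.345, 0.784, 99.5, 2674.9, 0.28),
    baseline_sd   = c(11.1, 9.69, 0.226, 0.389, 11.1, 1766.8, 0.30),
    baseline_lo   = c(8, 5, 0.05, 0.08, 40, 300, -0.15),
    baseline_hi   = c(60, 55, 1.5, 2.2, 180, 8500, 1.6),
    rate_mean     = c(-2.42, -2.41, 0.078, 0.152, 1.36, -107.03, 0.049),
    rate_sem      = c(0.62, 0.76, 0.021, 0.039, 1.23, 13.67, 0.021),
    rate_sd       = c(0.62, 0.76, 0.021, 0.039, 1.23, 13.67, 0.021) * sqrt(n_ref),
    feas_lo       = c(2, 2, 0.04, 0.04, 2, 0, -0.3),
    feas_hi       = c(95, 95, 2.5, 2.5, 253, 8900, 2.5),
    stringsAsFactors = FALSE
  )
}

#' Default cross-metric correlation matrix for baseline values
#'
#' Correlations among the seven baseline metrics. Ten entries are the study's
#' visit-1 correlation grid (EZ width and BCVA against each OCT-A metric);
#' the remaining pairs are not reported and are filled with clinically
#' plausible values chosen once so that the matrix is positive definite:
#' plexus densities track each other, FAZ areas track each other, density
#' and FAZ area oppose each other, and the choriocapillaris is essentially
#' uncorrelated with the retinal metrics.
#'
#' @return A symmetric 7x7 correlation matrix (positive definite).
#' @export
default_correlations <- function() {
  nm <- c("scp_pd", "dcp_pd", "scp_faz", "dcp_faz", "cc_mgv", "ez_um", "bcva")
  m <- diag(7)
  dimnames(m) <- list(nm, nm)
  set <- function(a, b, v) { m[a, b] <<- v; m[b, a] <<- v }
  # study visit-1 grid
  set("ez_um", "scp_pd", 0.660); set("ez_um", "scp_faz", -0.277)
  set("ez_um", "dcp_pd", 0.537); set("ez_um", "dcp_faz", 0.073)
  set("ez_um", "cc_mgv", -0.105)
  set("bcva", "scp_pd", -0.434); set("bcva", "scp_faz", 0.679)
  set("bcva", "dcp_pd", -0.472); set("bcva", "dcp_faz", 0.383)
  set("bcva", "cc_mgv", -0.031)
  # unreported pairs, filled for positive definiteness
  set("ez_um", "bcva", -0.45)
  set("scp_pd", "dcp_pd", 0.65); set("scp_faz", "dcp_faz", 0.60)
  set("scp_pd", "scp_faz", -0.45); set("dcp_pd", "dcp_faz", -0.40)
  set("scp_pd", "dcp_faz", -0.30); set("dcp_pd", "scp_faz", -0.35)
  set("cc_mgv", "scp_pd", 0.05); set("cc_mgv", "dcp_pd", 0.05)
  m
}

#' Specification of a synthetic longitudinal cohort
#'
#' Holds everything the cohort generator needs: sample size, the follow-up
#' interval distribution (years, truncated at a minimum), per-metric
#' population parameters, the baseline correlation structure and the seed.
#'
#' @param n_eyes Number of eyes (one per patient); `>= 2`. Default 28.
#' @param followup_mean_yr,followup_sd_yr Follow-up interval distribution in
#'   years (default 1.3 +/- 0.46).
#' @param followup_min_yr Truncation floor for the interval (default 0.5).
#' @param metrics Per-metric parameter table, see [default_metric_params()].
#' @param correlations Baseline correlation matrix, see
#'   [default_correlations()]; must be positive semidefinite.
#' @param rng_seed Integer seed.
#' @param image An [image_spec()] for rendered angiograms.
#' @param profile_px EZ profile length in pixels.
#' @param ez_scan_mm EZ scan physical length in mm.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_eyes = 28L, followup_mean_yr = 1.3, followup_sd_yr = 0.46,
                        followup_min_yr = 0.5, metrics = default_metric_params(),
                        correlations = default_correlations(), rng_seed = 1L,
                        image = image_spec(), profile_px = 1024L, ez_scan_mm = 9.0) {
  n_eyes <- as.integer(n_eyes)
  if (n_eyes < 2L) stop("n_eyes must be >= 2", call. = FALSE)
  if (followup_min_yr <= 0) stop("followup_min_yr must be positive", call. = FALSE)
  if (!all(metrics$metric %in% rownames(correlations)))
    stop("correlation matrix must cover every metric", call. = FALSE)
  R <- correlations[metrics$metric, metrics$metric]
  if (max(abs(R - t(R))) > 1e-8 || any(abs(diag(R) - 1) > 1e-8))
    stop("correlations must be a symmetric correlation matrix", call. = FALSE)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("correlation matrix is not positive semidefinite", call. = FALSE)
  structure(list(n_eyes = n_eyes, followup_mean_yr = followup_mean_yr,
                 followup_sd_yr = followup_sd_yr, followup_min_yr = followup_min_yr,
                 metrics = metrics, correlations = R, rng_seed = as.integer(rng_seed),
                 image = image, profile_px = as.integer(profile_px),
                 ez_scan_mm = ez_scan_mm),
            class = "cohort_spec")
}

# Normal draws truncated below at `lo` by rejection.
rtruncnorm_ <- function(n, mean, sd, lo) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Draw the ground-truth parameter table for a cohort
#'
#' Table-only cohort generation: draws follow-up intervals, correlated
#' baseline values (joint Gaussian with the configured correlation matrix),
#' and per-eye yearly progression rates (`N(rate_mean, rate_sd^2)`,
#' independent across metrics), and derives visit-2 values as
#' `visit1 + rate * dt`. Raw (untruncated) Gaussian draws are kept in
#' `*_v1_raw` columns for distributional calibration; the `*_v1` / `*_v2`
#' columns are clipped to the physiological/encodable ranges and are what the
#' image renderer realizes. `*_rate` is the drawn rate; `*_rate_real` is the
#' rate implied by the clipped visit values (identical except at the clip
#' boundaries).
#'
#' @param cs A [cohort_spec()].
#' @return A data.frame with one row per eye.
#' @export
draw_cohort_truth <- function(cs) {
  stopifnot(inherits(cs, "cohort_spec"))
  with_seed_(cs$rng_seed, {
    n <- cs$n_eyes
    mp <- cs$metrics
    k <- nrow(mp)
    dt <- rtruncnorm_(n, cs$followup_mean_yr, cs$followup_sd_yr, cs$followup_min_yr)
    L <- chol(cs$correlations + diag(1e-10, k))
    z <- matrix(rnorm(n * k), n, k) %*% L
    raw <- sweep(sweep(z, 2, mp$baseline_sd, `*`), 2, mp$baseline_mean, `+`)
    colnames(raw) <- mp$metric
    out <- data.frame(eye_id = sprintf("eye%03d", seq_len(n)),
                      patient_id = sprintf("pat%03d", seq_len(n)),
                      date_v1 = format(as.Date("2016-03-01") + 7L * seq_len(n), "%Y-%m-%d"),
                      dt_years = dt, stringsAsFactors = FALSE)
    out$date_v2 <- format(as.Date(out$date_v1) + round(dt * 365.25), "%Y-%m-%d")
    for (j in seq_len(k)) {
      m <- mp$metric[j]
      v1_raw <- raw[, j]
      v1 <- pmin(pmax(v1_raw, mp$baseline_lo[j]), mp$baseline_hi[j])
      rate <- rnorm(n, mp$rate_mean[j], mp$rate_sd[j])
      v2 <- pmin(pmax(v1 + rate * dt, mp$feas_lo[j]), mp$feas_hi[j])
      out[[paste0(m, "_v1_raw")]] <- v1_raw
      out[[paste0(m, "_v1")]] <- v1
      out[[paste0(m, "_v2")]] <- v2
      out[[paste0(m, "_rate")]] <- rate
      out[[paste0(m, "_rate_real")]] <- (v2 - v1) / dt
    }
    out$quality_v1 <- 10L
    out$quality_v2 <- 10L
    out
  })
}

#' Draw correlated bivariate-normal metric pairs
#'
#' Large-n table-only generator for correlation-recovery checks: `n` pairs
#' from a bivariate normal with the requested Pearson correlation and
#' marginal means/SDs.
#'
#' @param n Number of pairs.
#' @param rho Target correlation in (-1, 1).
#' @param mean_x,sd_x,mean_y,sd_y Marginal parameters.
#' @param seed Integer seed.
#' @return A data.frame with columns `x` and `y`.
#' @export
draw_correlated_pair <- function(n, rho, mean_x = 0, sd_x = 1, mean_y = 0, sd_y = 1,
                                 seed = 1L) {
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)", call. = FALSE)
  with_seed_(seed, {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    data.frame(x = mean_x + sd_x * z1, y = mean_y + sd_y * z2)
  })
}

#' Generate a full synthetic cohort with images on disk
#'
#' Realizes the truth table from [draw_cohort_truth()] as files: per eye and
#' visit, SCP and DCP angiogram pairs (visit 2 derived from visit 1 by
#' [degrade_angiogram()]), choriocapillaris textures, and EZ reflectivity
#' profiles (written as single-column CSVs). Ground truth achieved by the
#' masks (exact pixel counts) is recorded in `*_img` columns. Writes
#' `truth.csv`, a `manifest.csv` of paths, and a YAML echo of the spec.
#'
#' @param cs A [cohort_spec()].
#' @param out_dir Output directory; created if missing. `NULL` for
#'   table-only mode (returns the truth table, writes nothing).
#' @param slabs Angiogram slabs to render (default SCP and DCP).
#' @param force Overwrite a non-empty `out_dir`.
#' @return Invisibly, a list with `truth` (data.frame), `manifest`
#'   (data.frame; `NULL` in table-only mode) and `out_dir`.
#' @export
generate_cohort <- function(cs, out_dir = NULL, slabs = c("SCP", "DCP"), force = FALSE) {
  stopifnot(inherits(cs, "cohort_spec"))
  truth <- draw_cohort_truth(cs)
  if (is.null(out_dir))
    return(invisible(list(truth = truth, manifest = NULL, out_dir = NULL)))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop("output directory is not empty (use force = TRUE)", call. = FALSE)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "profiles"), recursive = TRUE, showWarnings = FALSE)
  man <- list()
  slab_key <- c(SCP = "scp", DCP = "dcp")
  for (i in seq_len(cs$n_eyes)) {
    eye <- truth$eye_id[i]
    for (sl in slabs) {
      key <- slab_key[[sl]]
      s1 <- child_seed_(cs$rng_seed, i * 10L + match(sl, slabs))
      g1 <- generate_angiogram(cs$image,
                               truth[[paste0(key, "_pd_v1")]][i],
                               truth[[paste0(key, "_faz_v1")]][i],
                               seed = s1, slab = sl)
      g2 <- degrade_angiogram(g1$truth,
                              pd_delta_pct = truth[[paste0(key, "_pd_v2")]][i] -
                                truth[[paste0(key, "_pd_v1")]][i],
                              faz_delta_mm2 = truth[[paste0(key, "_faz_v2")]][i] -
                                truth[[paste0(key, "_faz_v1")]][i],
                              seed = child_seed_(s1, 1L), slab = sl)
      for (v in 1:2) {
        g <- if (v == 1) g1 else g2
        p <- file.path(out_dir, "images", sprintf("%s_v%d_%s.png", eye, v, key))
        write_angiogram(g$image, p)
        truth[i, sprintf("%s_pd_v%d_img", key, v)] <- g$truth$true_pd_pct
        truth[i, sprintf("%s_faz_v%d_img", key, v)] <- g$truth$true_faz_mm2
        man[[length(man) + 1L]] <- data.frame(
          eye_id = eye, patient_id = truth$patient_id[i], visit = v, type = sl,
          path = p, quality = truth[[paste0("quality_v", v)]][i],
          stringsAsFactors = FALSE)
      }
    }
    # choriocapillaris textures and EZ profiles
    for (v in 1:2) {
      cc <- generate_choriocapillaris(cs$image, truth[[paste0("cc_mgv_v", v)]][i],
                                      noise_sd = 10,
                                      seed = child_seed_(cs$rng_seed, i * 10L + 5L + v))
      p <- file.path(out_dir, "images", sprintf("%s_v%d_cc.png", eye, v))
      write_angiogram(cc, p)
      man[[length(man) + 1L]] <- data.frame(
        eye_id = eye, patient_id = truth$patient_id[i], visit = v,
        type = "choriocapillaris", path = p,
        quality = truth[[paste0("quality_v", v)]][i], stringsAsFactors = FALSE)
      prof <- generate_ez_profile(cs$profile_px, cs$ez_scan_mm,
                                  band_width_um = truth[[paste0("ez_um_v", v)]][i],
                                  contrast = 120, noise_sd = 4,
                                  seed = child_seed_(cs$rng_seed, i * 10L + 7L + v))
      pp <- file.path(out_dir, "profiles", sprintf("%s_v%d_ez.csv", eye, v))
      write.csv(data.frame(reflectivity = as.numeric(prof)), pp, row.names = FALSE)
      man[[length(man) + 1L]] <- data.frame(
        eye_id = eye, patient_id = truth$patient_id[i], visit = v, type = "ez_profile",
        path = pp, quality = truth[[paste0("quality_v", v)]][i], stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, man)
  write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  yaml::write_yaml(list(n_eyes = cs$n_eyes, followup_mean_yr = cs$followup_mean_yr,
                        followup_sd_yr = cs$followup_sd_yr,
                        followup_min_yr = cs$followup_min_yr,
                        rng_seed = cs$rng_seed,
                        image = list(width_px = cs$image$width_px,
                                     field_mm = cs$image$field_mm),
                        metrics = cs$metrics,
                        correlations = as.data.frame(cs$correlations)),
                   file.path(out_dir, "config.yaml"))
  invisible(list(truth = truth, manifest = manifest, out_dir = out_dir))
}
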