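#' Parameter-recovery simulation of cohort progression rates
#'
#' The package's core validation study: for each of `n_seeds` replicate
#' cohorts, draw a 28-eye (by default) truth table, realize it as data, run
#' the measurement pipeline, and return the recovered cohort-mean yearly
#' progression rate per metric. Three realization routes are used, matching
#' what each metric is measured from:
#' \describe{
#'   \item{imaging metrics (`scp_pd`, `dcp_pd`, `scp_faz`, `dcp_faz`)}{visit
#'     pairs of synthetic angiograms are rendered in memory
#'     ([generate_angiogram()] / [degrade_angiogram()]), binarized with the
#'     automatic default threshold, the FAZ segmented with the flood-fill
#'     surrogate, and perfusion density / FAZ area measured per visit.}
#'   \item{`ez_um`}{foveal reflectivity profile pairs are generated and
#'     measured with [ez_width()].}
#'   \item{`bcva`, `cc_mgv`}{metadata-only: drawn visit values pass straight
#'     to the change-over-time estimator (BCVA has no image; the
#'     choriocapillaris route through [choriocapillaris_mgv()] is exercised
#'     when `render_cc = TRUE`).}
#' }
#'
#' @param metrics Character vector of metrics to recover.
#' @param n_seeds Number of replicate cohorts.
#' @param base_seed Integer seed; replicate s uses a child seed derived from
#'   it.
#' @param n_eyes Eyes per cohort.
#' @param image An [image_spec()] for the rendered angiograms.
#' @param render_cc Render choriocapillaris textures and measure their MGV
#'   (slower); otherwise `cc_mgv` is metadata-only.
#' @param progress Print one line per replicate.
#' @return A data.frame with one row per replicate and one column per metric
#'   holding the recovered cohort-mean rate (units/yr), plus a `seed` column.
#' @export
simulate_rate_recovery <- function(metrics = c("scp_pd", "dcp_pd", "scp_faz",
                                               "dcp_faz", "ez_um", "bcva"),
                                   n_seeds = 10L, base_seed = 1L, n_eyes = 28L,
                                   image = image_spec(), render_cc = FALSE,
                                   progress = FALSE) {
  imaging <- intersect(metrics, c("scp_pd", "dcp_pd", "scp_faz", "dcp_faz"))
  slabs <- unique(sub("_.*", "", imaging))
  out <- vector("list", n_seeds)
  n_failed <- 0L
  for (s in seq_len(n_seeds)) {
    cs <- cohort_spec(n_eyes = n_eyes, rng_seed = child_seed_(base_seed, s),
                      image = image)
    tt <- draw_cohort_truth(cs)
    row <- list(seed = cs$rng_seed)
    rates <- matrix(NA_real_, n_eyes, length(metrics),
                    dimnames = list(NULL, metrics))
    for (i in seq_len(n_eyes)) {
      dt <- tt$dt_years[i]
      for (sl in slabs) {
        key <- sl   # "scp" or "dcp"
        seed_i <- child_seed_(cs$rng_seed, i * 10L + match(sl, slabs))
        g1 <- generate_angiogram(image, tt[[paste0(key, "_pd_v1")]][i],
                                 tt[[paste0(key, "_faz_v1")]][i], seed = seed_i,
                                 slab = toupper(sl))
        g2 <- degrade_angiogram(g1$truth,
                                tt[[paste0(key, "_pd_v2")]][i] - tt[[paste0(key, "_pd_v1")]][i],
                                tt[[paste0(key, "_faz_v2")]][i] - tt[[paste0(key, "_faz_v1")]][i],
                                seed = child_seed_(seed_i, 1L), slab = toupper(sl))
        # measurement failures (e.g. no avascular seed on an extreme eye) are
        # row-level events: the eye's metric goes missing and the cohort mean
        # is complete-case, mirroring cmd_quantify()
        q12 <- tryCatch(list(quantify_angiogram(g1$image), quantify_angiogram(g2$image)),
                        error = function(e) { n_failed <<- n_failed + 1L; NULL })
        if (!is.null(q12)) {
          if (paste0(key, "_pd") %in% metrics)
            rates[i, paste0(key, "_pd")] <- change_over_time(q12[[1]]$pd_pct,
                                                             q12[[2]]$pd_pct, dt)
          if (paste0(key, "_faz") %in% metrics)
            rates[i, paste0(key, "_faz")] <- change_over_time(q12[[1]]$faz_mm2,
                                                              q12[[2]]$faz_mm2, dt)
        }
      }
      if ("ez_um" %in% metrics) {
        w <- sapply(1:2, function(v) {
          prof <- generate_ez_profile(1024L, 9.0,
                                      band_width_um = tt[[paste0("ez_um_v", v)]][i],
                                      contrast = 120, noise_sd = 4,
                                      seed = child_seed_(cs$rng_seed, i * 10L + 6L + v))
          ez_width(prof, 9.0)
        })
        rates[i, "ez_um"] <- change_over_time(w[1], w[2], dt)
      }
      if ("cc_mgv" %in% metrics) {
        if (render_cc) {
          m <- sapply(1:2, function(v) {
            cc <- generate_choriocapillaris(image, tt[[paste0("cc_mgv_v", v)]][i],
                                            noise_sd = 10,
                                            seed = child_seed_(cs$rng_seed, i * 10L + 4L + v))
            choriocapillaris_mgv(cc)
          })
          rates[i, "cc_mgv"] <- change_over_time(m[1], m[2], dt)
        } else
          rates[i, "cc_mgv"] <- change_over_time(tt$cc_mgv_v1[i], tt$cc_mgv_v2[i], dt)
      }
      if ("bcva" %in% metrics)
        rates[i, "bcva"] <- change_over_time(tt$bcva_v1[i], tt$bcva_v2[i], dt)
    }
    for (m in metrics) row[[m]] <- mean(rates[, m], na.rm = TRUE)
    out[[s]] <- as.data.frame(row)
    if (progress)
      message(sprintf("replicate %d/%d done", s, n_seeds))
  }
  res <- do.call(rbind, out)
  if (n_failed > 0)
    message(n_failed, " eye-visit pair(s) had measurement failures (complete-case)")
  attr(res, "n_failed") <- n_failed
  res
}
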