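#' Quantify a single en-face angiogram
#'
#' Chains the per-image analysis: red-channel selection, automatic default
#' (or fixed) thresholding, binarization, FAZ delineation and perfusion
#' density. For the choriocapillaris slab only the mean gray value of the
#' raw image is computed.
#'
#' @param a An `angiogram` (or a path, read with [read_angiogram()]).
#' @param threshold `"auto"` or a `threshold_bounds` (e.g.
#'   `threshold_bounds(60, 255)`).
#' @param faz `"auto"`, a `faz_mask`, or `NULL` to skip FAZ exclusion.
#' @param scale_mm_per_px,slab Passed to [read_angiogram()] when `a` is a path.
#' @return A list with `pd_pct`, `faz_mm2`, `mgv`, `bounds`, and the masks.
#' @export
quantify_angiogram <- function(a, threshold = "auto", faz = "auto",
                               scale_mm_per_px = 3 / 245, slab = "SCP") {
  if (is.character(a)) a <- read_angiogram(a, scale_mm_per_px, slab)
  stopifnot(inherits(a, "angiogram"))
  if (a$slab == "choriocapillaris")
    return(list(pd_pct = NA_real_, faz_mm2 = NA_real_,
                mgv = choriocapillaris_mgv(a), bounds = NULL,
                vessel_mask = NULL, faz_mask = NULL))
  b <- if (identical(threshold, "auto")) auto_threshold_default(a) else threshold
  vm <- binarize(a, b)
  fm <- if (identical(faz, "auto")) faz_auto(vm) else faz
  pd <- perfusion_density(vm, fm)
  list(pd_pct = pd,
       faz_mm2 = if (is.null(fm)) NA_real_ else fm$area_mm2,
       mgv = NA_real_, bounds = b, vessel_mask = vm, faz_mask = fm)
}

#' Simulate a synthetic cohort (pipeline step 1)
#'
#' Thin orchestration over [generate_cohort()]: writes the image tree, truth
#' table and manifest into `out_dir`.
#'
#' @param cs A [cohort_spec()].
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty directory.
#' @return Invisibly, the [generate_cohort()] result.
#' @export
cmd_simulate <- function(cs, out_dir, force = FALSE) {
  generate_cohort(cs, out_dir = out_dir, force = force)
}

#' Quantify a simulated or real image manifest (pipeline step 2)
#'
#' Runs the per-image pipeline over every row of a manifest
#' (`eye_id, patient_id, visit, type, path, quality`) and assembles one row
#' per eye and visit. Eyes whose scan quality score is below `min_quality`
#' (the signal-strength cutoff of 7 out of 10) are excluded and logged. When
#' a patient contributes several eyes, one eye per patient is kept: the eye
#' with the best mean quality, ties broken toward the lexicographically last
#' eye id (the right eye under OD/OS naming). Row-level read failures are
#' recorded and skipped; the run fails if more than half the rows fail.
#'
#' @param manifest Data.frame or path to `manifest.csv`.
#' @param out_csv Optional path for the per-eye-visit CSV.
#' @param threshold `"auto"` or `threshold_bounds`.
#' @param scale_mm_per_px Pixel pitch of the angiograms.
#' @param ez_scan_mm EZ profile scan length (mm).
#' @param min_quality Exclusion cutoff on the quality column (default 7).
#' @return A data.frame, one row per retained eye-visit, with attributes
#'   `excluded` (eye ids dropped for quality) and `errors`.
#' @export
cmd_quantify <- function(manifest, out_csv = NULL, threshold = "auto",
                         scale_mm_per_px = 3 / 245, ez_scan_mm = 9.0,
                         min_quality = 7) {
  if (is.character(manifest)) manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  if (nrow(manifest) == 0) stop("empty manifest", call. = FALSE)
  need <- c("eye_id", "visit", "type", "path")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (is.null(manifest$quality)) manifest$quality <- 10
  if (is.null(manifest$patient_id)) manifest$patient_id <- manifest$eye_id

  # quality exclusion: an eye is dropped if any of its scans is below cutoff
  qual <- stats::aggregate(quality ~ eye_id, manifest, min)
  excluded <- qual$eye_id[qual$quality < min_quality]
  # one eye per patient: best mean quality, tie -> last eye id
  mq <- stats::aggregate(quality ~ eye_id + patient_id,
                         manifest[!manifest$eye_id %in% excluded, ], mean)
  keep <- character(0)
  for (p in unique(mq$patient_id)) {
    sub <- mq[mq$patient_id == p, ]
    best <- sub[sub$quality == max(sub$quality), ]
    keep <- c(keep, min(best$eye_id))   # tie -> right eye (OD sorts before OS)
  }
  rows <- manifest[manifest$eye_id %in% keep, ]
  errors <- character(0)
  res <- list()
  for (i in seq_len(nrow(rows))) {
    rr <- rows[i, ]
    key <- paste(rr$eye_id, rr$visit, sep = "|")
    if (is.null(res[[key]]))
      res[[key]] <- list(eye_id = rr$eye_id, patient_id = rr$patient_id,
                         visit = rr$visit)
    out <- tryCatch({
      if (rr$type %in% c("SCP", "DCP")) {
        a <- suppressMessages(read_angiogram(rr$path, scale_mm_per_px, slab = rr$type))
        q <- quantify_angiogram(a, threshold = threshold)
        pre <- if (rr$type == "SCP") "scp" else "dcp"
        res[[key]][[paste0(pre, "_pd")]] <- q$pd_pct
        res[[key]][[paste0(pre, "_faz")]] <- q$faz_mm2
      } else if (rr$type == "choriocapillaris") {
        a <- suppressMessages(read_angiogram(rr$path, scale_mm_per_px,
                                             slab = "choriocapillaris"))
        res[[key]]$cc_mgv <- choriocapillaris_mgv(a)
      } else if (rr$type == "ez_profile") {
        prof <- suppressWarnings(read.csv(rr$path))$reflectivity
        res[[key]]$ez_um <- ez_width(prof, scan_mm = ez_scan_mm)
      }
      TRUE
    }, error = function(e) {
      errors <<- c(errors, paste0(rr$path, ": ", conditionMessage(e)))
      FALSE
    })
  }
  if (length(errors) > nrow(rows) / 2)
    stop("more than half of the manifest rows failed:\n",
         paste(head(errors, 5), collapse = "\n"), call. = FALSE)
  cols <- c("eye_id", "patient_id", "visit", "scp_pd", "scp_faz", "dcp_pd",
            "dcp_faz", "cc_mgv", "ez_um")
  df <- do.call(rbind, lapply(res, function(r) {
    for (cn in cols) if (is.null(r[[cn]])) r[[cn]] <- NA
    as.data.frame(r[cols], stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df <- df[order(df$eye_id, df$visit), ]
  attr(df, "excluded") <- excluded
  attr(df, "errors") <- errors
  if (length(excluded))
    message("excluded for quality < ", min_quality, ": ",
            paste(excluded, collapse = ", "))
  if (!is.null(out_csv)) write.csv(df, out_csv, row.names = FALSE)
  df
}

#' Reshape quantified eye-visit rows into longitudinal records
#'
#' Joins the visit-1 and visit-2 rows per eye into one wide record and
#' computes per-metric change-over-time rates. Follow-up intervals come
#' either from a `dt_years` column in `visit_dates` or from ISO-8601 visit
#' dates (days / 365.25).
#'
#' @param eyevisits Output of [cmd_quantify()] (or a compatible data.frame;
#'   columns `bcva` per visit are carried through when present).
#' @param visit_dates Data.frame with `eye_id` and either `dt_years` or
#'   `date_v1`/`date_v2`; may also carry `bcva_v1`/`bcva_v2` metadata.
#' @return A records data.frame suitable for [build_tables()].
#' @export
longitudinal_records <- function(eyevisits, visit_dates) {
  v1 <- eyevisits[eyevisits$visit == 1, ]
  v2 <- eyevisits[eyevisits$visit == 2, ]
  rec <- merge(v1, v2, by = "eye_id", suffixes = c("_v1", "_v2"))
  if (!"dt_years" %in% names(visit_dates)) {
    visit_dates$dt_years <- as.numeric(as.Date(visit_dates$date_v2) -
                                         as.Date(visit_dates$date_v1)) / 365.25
  }
  keep <- intersect(c("eye_id", "dt_years", "bcva_v1", "bcva_v2"), names(visit_dates))
  rec <- merge(rec, visit_dates[, keep, drop = FALSE], by = "eye_id")
  if (any(rec$dt_years <= 0)) stop("non-positive follow-up interval", call. = FALSE)
  for (m in c("scp_pd", "dcp_pd", "scp_faz", "dcp_faz", "cc_mgv", "ez_um", "bcva")) {
    c1 <- paste0(m, "_v1"); c2 <- paste0(m, "_v2")
    if (all(c(c1, c2) %in% names(rec)))
      rec[[paste0(m, "_rate")]] <- (rec[[c2]] - rec[[c1]]) / rec$dt_years
  }
  rec
}

#' Compute the summary statistics tables (pipeline step 3)
#'
#' Delegates to [build_tables()] and optionally writes the per-visit/rate
#' table, the SCP-vs-DCP comparisons and the correlation grid as CSVs.
#'
#' @param records Output of [longitudinal_records()].
#' @param out_dir Optional directory for `table_visits.csv`,
#'   `table_comparisons.csv`, `table_correlations.csv`.
#' @param alpha,fdr Passed to [build_tables()].
#' @return The [build_tables()] list.
#' @export
cmd_stats <- function(records, out_dir = NULL, alpha = 0.05, fdr = "none") {
  tb <- build_tables(records, alpha = alpha, fdr = fdr)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tb$visits, file.path(out_dir, "table_visits.csv"), row.names = FALSE)
    if (!is.null(tb$comparisons))
      write.csv(tb$comparisons, file.path(out_dir, "table_comparisons.csv"),
                row.names = FALSE)
    if (!is.null(tb$correlations))
      write.csv(tb$correlations, file.path(out_dir, "table_correlations.csv"),
                row.names = FALSE)
  }
  tb
}

#' Run simulate, quantify and stats end to end
#'
#' Convenience wrapper: generates a cohort under `out_dir`, quantifies every
#' image through the automatic pipeline, joins with the simulated follow-up
#' intervals and BCVA metadata, and writes the summary tables.
#'
#' @param cs A [cohort_spec()].
#' @param out_dir Working directory for all outputs.
#' @param force Overwrite a non-empty directory.
#' @return A list with `truth`, `eyevisits`, `records` and `tables`.
#' @export
run_pipeline <- function(cs, out_dir, force = FALSE) {
  sim <- cmd_simulate(cs, out_dir, force = force)
  ev <- cmd_quantify(file.path(out_dir, "manifest.csv"),
                     out_csv = file.path(out_dir, "eyevisits.csv"),
                     scale_mm_per_px = cs$image$scale_mm_per_px,
                     ez_scan_mm = cs$ez_scan_mm)
  meta <- sim$truth[, c("eye_id", "dt_years", "bcva_v1", "bcva_v2")]
  rec <- longitudinal_records(ev, meta)
  tb <- cmd_stats(rec, out_dir = file.path(out_dir, "tables"))
  list(truth = sim$truth, eyevisits = ev, records = rec, tables = tb)
}
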