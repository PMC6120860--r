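#' One-sample Student's t-test
#'
#' Tests whether the mean of `values` differs from `null_mean`:
#' `t = (mean - null_mean) / (sd / sqrt(n))`, two-sided p from the t
#' distribution with `n - 1` degrees of freedom. Used to test whether mean
#' change-over-time rates differ from zero.
#'
#' @param values Numeric vector, `n >= 2`, non-constant.
#' @param null_mean Null hypothesis mean (default 0).
#' @return A list with `t`, `df`, `p`, `mean`, `sem` and `n`.
#' @examples
#' one_sample_t(c(1, 2, 3))   # t = 3.464, p = 0.0742
#' @export
one_sample_t <- function(values, null_mean = 0) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  if (sd(values) == 0)
    stop("zero variance: all values equal ", values[1], call. = FALSE)
  ht <- stats::t.test(values, mu = null_mean)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean = mean(values), sem = sd(values) / sqrt(n), n = n)
}

#' Paired Student's t-test
#'
#' Equivalent to a one-sample t-test on the element-wise differences
#' `values_a - values_b` (tested as an invariant of the package).
#'
#' @param values_a,values_b Paired numeric vectors of equal length.
#' @return As [one_sample_t()], plus `mean_diff`.
#' @export
paired_t <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("paired vectors must have equal length", call. = FALSE)
  ok <- !is.na(values_a) & !is.na(values_b)
  r <- one_sample_t(values_a[ok] - values_b[ok])
  r$mean_diff <- r$mean
  r
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson correlation; significance via
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, non-constant.
#' @return A list with `r`, `p`, `df` and `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("constant input has no correlation", call. = FALSE)
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, df = unname(ht$parameter), n = n)
}

#' Merge two graders' measurements
#'
#' Inter-grader reliability and averaging: returns the Pearson correlation
#' between the two graders' series and their element-wise mean, which is the
#' series used for all downstream analyses.
#'
#' @param a,b Numeric vectors of the same measurements by two independent
#'   graders.
#' @return A `grader_pair` list with `pearson_r`, `p`, `averaged`, and the
#'   input series.
#' @export
grader_merge <- function(a, b) {
  if (length(a) != length(b)) stop("grader series must have equal length", call. = FALSE)
  r <- if (sd(a) == 0 && sd(b) == 0 && all(a == b)) list(r = 1, p = NA_real_)
  else pearson_r(a, b)
  structure(list(grader_a = a, grader_b = b, pearson_r = r$r, p = r$p,
                 averaged = (a + b) / 2),
            class = "grader_pair")
}

# metric label -> pretty row name used in the summary tables
metric_labels_ <- c(scp_pd = "Perfusion density SCP (%)",
                    dcp_pd = "Perfusion density DCP (%)",
                    scp_faz = "FAZ area SCP (mm2)",
                    dcp_faz = "FAZ area DCP (mm2)",
                    cc_mgv = "Choriocapillaris mean gray value",
                    ez_um = "EZ line width (um)",
                    bcva = "BCVA (logMAR)")

#' Build the per-visit / progression-rate and correlation summary tables
#'
#' From a per-eye longitudinal record table, reproduces the study's two
#' summary layouts:
#' \describe{
#'   \item{visits}{per metric: visit means with SD, a paired t-test between
#'     visits, the mean yearly rate with its SEM and the one-sample t-test of
#'     the rates against zero; plus paired SCP-vs-DCP comparisons of the
#'     perfusion-density and FAZ means at each visit and of their rates.}
#'   \item{correlations}{the EZ-width and BCVA correlation grid against every
#'     OCT-A metric at each visit, with two-sided Pearson p-values and a
#'     significance flag at `alpha`.}
#' }
#' Metrics with fewer than 2 complete records are dropped with a warning;
#' each analysis uses its complete cases and reports the `n` used. With
#' `fdr = "bh"` an extra Benjamini-Hochberg-adjusted p column is added to the
#' correlation grid (off by default; the study applied no correction).
#'
#' @param records Data.frame with columns `eye_id`, `dt_years` and, per
#'   metric `m` in `names(metric_labels_)`, `m_v1`, `m_v2` (and optionally
#'   `m_rate`; recomputed as `(v2 - v1) / dt` when absent).
#' @param alpha Significance level (default 0.05).
#' @param fdr `"none"` or `"bh"`.
#' @return A list of data.frames `visits`, `comparisons` and `correlations`.
#' @export
build_tables <- function(records, alpha = 0.05, fdr = c("none", "bh")) {
  fdr <- match.arg(fdr)
  stopifnot(is.data.frame(records), all(c("dt_years") %in% names(records)))
  if (nrow(records) < 2) stop("need at least 2 records", call. = FALSE)
  metrics <- names(metric_labels_)[vapply(names(metric_labels_), function(m)
    all(paste0(m, c("_v1", "_v2")) %in% names(records)), logical(1))]
  if (length(metrics) == 0) stop("no metric columns found", call. = FALSE)

  safe_t <- function(expr) tryCatch(expr, error = function(e) {
    warning(conditionMessage(e), call. = FALSE)
    list(t = NA_real_, df = NA_real_, p = NA_real_, mean = NA_real_,
         sem = NA_real_, n = NA_integer_, mean_diff = NA_real_)
  })

  rows <- lapply(metrics, function(m) {
    v1 <- records[[paste0(m, "_v1")]]
    v2 <- records[[paste0(m, "_v2")]]
    rate <- if (paste0(m, "_rate") %in% names(records)) records[[paste0(m, "_rate")]]
    else (v2 - v1) / records$dt_years
    ok <- !is.na(v1) & !is.na(v2) & !is.na(rate)
    if (sum(ok) < 2) {
      warning("metric ", m, " dropped: fewer than 2 complete records", call. = FALSE)
      return(NULL)
    }
    pt_ <- safe_t(paired_t(v2[ok], v1[ok]))
    ot <- safe_t(one_sample_t(rate[ok]))
    data.frame(metric = m, label = metric_labels_[[m]], n = sum(ok),
               v1_mean = mean(v1[ok]), v1_sd = sd(v1[ok]),
               v2_mean = mean(v2[ok]), v2_sd = sd(v2[ok]),
               p_visits = pt_$p,
               rate_mean = ot$mean, rate_sem = ot$sem, rate_sd = sd(rate[ok]),
               t_rate = ot$t, df_rate = ot$df, p_rate = ot$p,
               stringsAsFactors = FALSE)
  })
  visits <- do.call(rbind, rows)
  rownames(visits) <- NULL

  # paired SCP-vs-DCP comparisons on complete cases
  cmp_rows <- list()
  add_cmp <- function(lab, a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2) return()
    ct <- safe_t(paired_t(a[ok], b[ok]))
    cmp_rows[[length(cmp_rows) + 1L]] <<- data.frame(
      comparison = lab, n = sum(ok), mean_diff = ct$mean_diff,
      t = ct$t, df = ct$df, p = ct$p, stringsAsFactors = FALSE)
  }
  has <- function(cols) all(cols %in% names(records))
  rate_of <- function(m) {
    if (paste0(m, "_rate") %in% names(records)) records[[paste0(m, "_rate")]]
    else (records[[paste0(m, "_v2")]] - records[[paste0(m, "_v1")]]) / records$dt_years
  }
  if (has(c("scp_pd_v1", "dcp_pd_v1"))) {
    add_cmp("PD SCP vs DCP, visit 1", records$scp_pd_v1, records$dcp_pd_v1)
    add_cmp("PD SCP vs DCP, visit 2", records$scp_pd_v2, records$dcp_pd_v2)
    add_cmp("PD rate SCP vs DCP", rate_of("scp_pd"), rate_of("dcp_pd"))
  }
  if (has(c("scp_faz_v1", "dcp_faz_v1"))) {
    add_cmp("FAZ SCP vs DCP, visit 1", records$scp_faz_v1, records$dcp_faz_v1)
    add_cmp("FAZ SCP vs DCP, visit 2", records$scp_faz_v2, records$dcp_faz_v2)
    add_cmp("FAZ rate SCP vs DCP", rate_of("scp_faz"), rate_of("dcp_faz"))
  }
  comparisons <- if (length(cmp_rows)) do.call(rbind, cmp_rows) else NULL

  # correlation grid: EZ width and BCVA against each OCT-A metric per visit
  octa <- intersect(c("scp_pd", "scp_faz", "dcp_pd", "dcp_faz", "cc_mgv"), metrics)
  func <- intersect(c("ez_um", "bcva"), metrics)
  cor_rows <- list()
  for (f in func) for (m in octa) for (v in 1:2) {
    x <- records[[paste0(f, "_v", v)]]
    y <- records[[paste0(m, "_v", v)]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) next
    pr <- tryCatch(pearson_r(x[ok], y[ok]), error = function(e) NULL)
    if (is.null(pr)) next
    cor_rows[[length(cor_rows) + 1L]] <- data.frame(
      functional = f, metric = m, visit = v, n = pr$n, r = pr$r, p = pr$p,
      significant = pr$p < alpha, stringsAsFactors = FALSE)
  }
  correlations <- if (length(cor_rows)) do.call(rbind, cor_rows) else NULL
  if (!is.null(correlations) && fdr == "bh")
    correlations$p_bh <- stats::p.adjust(correlations$p, method = "BH")

  list(visits = visits, comparisons = comparisons, correlations = correlations)
}
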