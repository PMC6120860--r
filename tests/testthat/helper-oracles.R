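# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct arithmetic, nested loops, closed forms.

# All intermeans fixed points of a pixel vector, by brute-force scan over
# every candidate threshold t in 0..254: t is a fixed point iff
# floor((mean(px <= t) + mean(px > t)) / 2) == t.
intermeans_fixed_points <- function(px) {
  out <- integer(0)
  for (t in 0:254) {
    lo <- px[px <= t]; hi <- px[px > t]
    if (length(lo) == 0 || length(hi) == 0) next
    if (floor((mean(lo) + mean(hi)) / 2) == t) out <- c(out, t)
  }
  out
}

# Brute-force perfusion density by nested-loop pixel counting.
pd_bruteforce <- function(vmask, fmask = NULL) {
  n_v <- 0L; n_f <- 0L
  for (i in seq_len(nrow(vmask))) for (j in seq_len(ncol(vmask))) {
    in_f <- !is.null(fmask) && fmask[i, j]
    if (in_f) n_f <- n_f + 1L
    else if (vmask[i, j]) n_v <- n_v + 1L
  }
  100 * n_v / (length(vmask) - n_f)
}

# Shoelace (analytic) polygon area in px^2.
shoelace_area <- function(vx, vy) {
  n <- length(vx)
  abs(sum(vx * vy[c(2:n, 1)] - vx[c(2:n, 1)] * vy)) / 2
}

# Construct y with an exact sample Pearson correlation r against x.
exact_cor_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  e <- rnorm(n)
  e <- residuals(lm(e ~ x))
  x <- (x - mean(x)) / sd(x)
  e <- e / sd(e)
  list(x = x, y = r * x + sqrt(1 - r^2) * e)
}

# A tiny synthetic longitudinal record table with known rates.
make_records <- function(n = 8, seed = 42) {
  set.seed(seed)
  dt <- runif(n, 0.8, 1.8)
  rec <- data.frame(eye_id = sprintf("e%02d", 1:n), dt_years = dt)
  for (m in c("scp_pd", "dcp_pd", "scp_faz", "dcp_faz", "cc_mgv", "ez_um", "bcva")) {
    v1 <- rnorm(n, 30, 5)
    v2 <- v1 + rnorm(n, -2, 1) * dt
    rec[[paste0(m, "_v1")]] <- v1
    rec[[paste0(m, "_v2")]] <- v2
  }
  rec
}
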