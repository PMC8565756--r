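# Independent oracles used across the test files. Each is a deliberately
# naive re-derivation (sums of squares, grids, enumeration) kept separate
# from the package's own code paths.

# One-way ANOVA + Tukey-Kramer limitation labels from first principles:
# sums of squares by hand, studentized-range p-values via ptukey().
oracle_tukey_labels <- function(ldm, rate, alpha = 0.05) {
  rate <- as.character(rate)
  levs <- unique(rate)
  k <- length(levs)
  means <- vapply(levs, function(l) mean(ldm[rate == l]), numeric(1))
  ns <- vapply(levs, function(l) sum(rate == l), numeric(1))
  grand <- mean(ldm)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(levs, function(l) {
    sum((ldm[rate == l] - means[l])^2)
  }, numeric(1)))
  df_b <- k - 1
  df_w <- length(ldm) - k
  ms_w <- ss_within / df_w
  f <- (ss_between / df_b) / ms_w
  p_global <- stats::pf(f, df_b, df_w, lower.tail = FALSE)

  labels <- setNames(rep("non_limited", k), levs)
  if (is.finite(p_global) && p_global < alpha) {
    top <- levs[means == max(means)][1]
    for (l in setdiff(levs, levs[means == max(means)])) {
      se <- sqrt(ms_w * (1 / ns[top] + 1 / ns[l]) / 2)
      q <- abs(means[top] - means[l]) / se
      p <- stats::ptukey(q, nmeans = k, df = df_w, lower.tail = FALSE)
      if (p < alpha && means[l] < max(means)) labels[l] <- "limited"
    }
  }
  labels
}

# Closed-form simple OLS via the normal equations.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Grid-search minimizer of the log-scale SSE of nc = a * ldm^-b,
# iteratively refined around the incumbent.
oracle_powerfit_grid <- function(ldm, nc, passes = 6) {
  lna <- 0; b <- 0.5
  half_lna <- 2; half_b <- 2
  sse <- function(lna, b) sum((log(nc) - (lna - b * log(ldm)))^2)
  for (i in seq_len(passes)) {
    lnas <- seq(lna - half_lna, lna + half_lna, length.out = 41)
    bs <- seq(b - half_b, b + half_b, length.out = 41)
    grid <- expand.grid(lna = lnas, b = bs)
    vals <- mapply(sse, grid$lna, grid$b)
    best <- grid[which.min(vals), ]
    lna <- best$lna; b <- best$b
    half_lna <- half_lna / 8; half_b <- half_b / 8
  }
  c(a = exp(lna), b = b)
}

# Fine-grid argmax of a fitted quadratic over an interval.
oracle_quad_argmax <- function(c0, c1, c2, lo, hi) {
  x <- seq(lo, hi, length.out = 2e5)
  y <- c0 + c1 * x + c2 * x^2
  x[which.max(y)]
}

# A small replicate-level data frame shaped like one sampling date.
make_date <- function(means, reps = 3, jitter = 0.01,
                      rates = c(0, 75, 150, 225), stage = "TS") {
  stopifnot(length(means) == length(rates))
  # deterministic +/- jitter pattern, no RNG
  off <- rep_len(c(-1, 0, 1), reps)
  tibble::tibble(
    variety = "T", season = "early", year = 1L, stage = stage,
    n_rate = rep(rates, each = reps),
    replicate = rep(seq_len(reps), times = length(rates)),
    ldm = rep(means, each = reps) + rep(off, length(rates)) * jitter,
    pnc = 2
  )
}
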