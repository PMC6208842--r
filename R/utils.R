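# Small numerical helpers shared across modules.

# Centered moving average with shrinking windows at the edges, so the
# output has the same length as the input and no NA padding.
moving_average <- function(x, k = 5L) {
  n <- length(x)
  if (k <= 1L || n < 3L) return(x)
  half <- (k - 1L) %/% 2L
  # cumulative sum with NA treated as missing contribution
  isna <- is.na(x)
  x0 <- ifelse(isna, 0, x)
  cs <- c(0, cumsum(x0))
  cn <- c(0, cumsum(!isna))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cnt <- cn[hi + 1L] - cn[lo]
  out <- (cs[hi + 1L] - cs[lo]) / cnt
  out[cnt == 0] <- NA_real_
  out[isna] <- NA_real_  # do not invent samples where the input is missing
  out
}

# Ordinary least-squares slope of y against time, returned per second.
# t_ms in milliseconds; NAs dropped pairwise.
ols_slope_per_s <- function(t_ms, y) {
  ok <- !is.na(t_ms) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  t <- t_ms[ok]; yy <- y[ok]
  tc <- t - mean(t)
  denom <- sum(tc^2)
  if (denom == 0) return(NA_real_)
  1000 * sum(tc * (yy - mean(yy))) / denom
}

euclid <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)

# Minimum-jerk position profile on [0, 1].
min_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  tau^3 * (10 - 15 * tau + 6 * tau^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
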