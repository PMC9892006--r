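#' @keywords internal
"_PACKAGE"

# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Centred rolling quantile with edge truncation
#'
#' The window is centred on each sample and truncated at the series edges, so
#' the output has the same length as the input with no padding artefacts.
#'
#' @param x numeric vector.
#' @param half_width integer, samples on each side of the centre.
#' @param prob quantile probability.
#' @return numeric vector, `length(x)`.
#' @keywords internal
rolling_quantile <- function(x, half_width, prob) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half_width)
    hi <- min(n, i + half_width)
    out[i] <- stats::quantile(x[lo:hi], probs = prob, names = FALSE, type = 7)
  }
  out
}

# O(n) centred rolling mean and sd via cumulative sums, edge-truncated.
rolling_mean_sd <- function(x, half_width) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_width)
  hi <- pmin(n, i + half_width)
  cnt <- hi - lo + 1
  s <- cs[hi + 1] - cs[lo]
  s2 <- cs2[hi + 1] - cs2[lo]
  mu <- s / cnt
  v <- (s2 - cnt * mu^2) / pmax(cnt - 1, 1)
  v[v < 0] <- 0
  list(mean = mu, sd = sqrt(v), n = cnt)
}

#' Centred boxcar smoothing with edge truncation
#'
#' @param x numeric vector.
#' @param width boxcar width in samples.
#' @return smoothed vector of the same length.
#' @export
boxcar_smooth <- function(x, width) {
  half <- floor(width / 2)
  rolling_mean_sd(x, half)$mean
}

#' Find local maxima with height and prominence constraints
#'
#' A sample is a peak when it strictly exceeds both neighbours (plateaus take
#' the first sample). Prominence is the height above the higher of the two
#' bounding minima, computed by walking outward to the nearest higher samples.
#'
#' @param x numeric vector.
#' @param height minimum peak value.
#' @param prominence minimum prominence.
#' @param min_distance minimum separation between kept peaks (samples);
#'   taller peaks win.
#' @return integer vector of peak indices, increasing.
#' @keywords internal
find_peaks <- function(x, height = -Inf, prominence = 0, min_distance = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= height]
  if (length(cand) == 0) return(integer(0))
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    # walk left until a sample higher than the peak (or the edge)
    lmin <- x[i]
    j <- i - 1L
    while (j >= 1 && x[j] <= x[i]) {
      lmin <- min(lmin, x[j]); j <- j - 1L
    }
    if (j < 1) lmin <- min(x[1:i])
    rmin <- x[i]
    j <- i + 1L
    while (j <= n && x[j] <= x[i]) {
      rmin <- min(rmin, x[j]); j <- j + 1L
    }
    if (j > n) rmin <- min(x[i:n])
    prom <- x[i] - max(lmin, rmin)
    keep[k] <- prom >= prominence
  }
  cand <- cand[keep]
  if (min_distance > 1 && length(cand) > 1) {
    ord <- order(x[cand], decreasing = TRUE)
    taken <- integer(0)
    for (i in cand[ord]) {
      if (all(abs(i - taken) >= min_distance)) taken <- c(taken, i)
    }
    cand <- sort(taken)
  }
  cand
}

# Circularly shift a vector by k (positive = later values move forward).
circ_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(n - k + 1):n], x[1:(n - k)])
}

# Derive a child integer seed from a master seed and a stream index,
# keeping the result inside 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 16807) %% 2147483647)
}

# Shannon entropy (nats) of a probability vector; zero entries contribute 0.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# z-score a vector; zero-variance input maps to zeros.
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
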