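#' Centred moving average with shrinking edge windows
#'
#' Boxcar smoother whose window shrinks near the trace edges so that the
#' output has the same length as the input. For even widths the window
#' extends one sample further to the right.
#'
#' @param x numeric vector.
#' @param w window width in samples (>= 1).
#' @return numeric vector of the same length as \code{x}.
#' @keywords internal
moving_average <- function(x, w) {
  n <- length(x)
  w <- as.integer(w)
  if (w <= 1L || n == 0L) return(x)
  hl <- (w - 1L) %/% 2L
  hr <- w - 1L - hl
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - hl)
  hi <- pmin(n, i + hr)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' EPSP-like kernel with a smooth foot
#'
#' Unit-amplitude postsynaptic-potential waveform: raised-cosine rise up to
#' the time-to-peak followed by an exponential decay. The raised-cosine foot
#' has zero derivative at onset, which matters for onset-latency detection.
#'
#' @param ttp_ms time from onset to peak, ms.
#' @param decay_ms exponential decay time constant, ms.
#' @param fs sampling rate, Hz.
#' @param length_ms total kernel length, ms.
#' @return numeric vector starting at the event onset, peak value 1.
#' @keywords internal
epsp_kernel <- function(ttp_ms, decay_ms = 15, fs = 1e5, length_ms = 80) {
  t <- seq(0, length_ms, by = 1000 / fs)
  y <- ifelse(t <= ttp_ms,
              0.5 - 0.5 * cos(pi * t / ttp_ms),
              exp(-(t - ttp_ms) / decay_ms))
  y
}

#' Adjusted Rand index between two labelings
#'
#' Measures agreement between two partitions of the same items, corrected
#' for chance. Used to compare recovered response-type assignments against
#' planted ground truth.
#'
#' @param a,b vectors of equal length; any label coding.
#' @return numeric scalar in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# Small deterministic string hash (FNV-1a, 32 bit) used for provenance
# stamps in run reports; avoids external digest dependencies.
fnv1a32 <- function(s) {
  xor32 <- function(a, b) {
    bitwXor(a %/% 65536, b %/% 65536) * 65536 +
      bitwXor(a %% 65536, b %% 65536)
  }
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# Derive component sub-seeds from a master seed so that partial
# reconfiguration leaves unrelated components reproducible.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  sample.int(2^30, n)
}
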