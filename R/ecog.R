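#' Segment an ECoG trace into synchronized and desynchronized states
#'
#' The trace is cut into 1000-ms segments hopping by 875 ms (125-ms
#' overlap). Each segment is mean-detrended and its periodogram power is
#' summed over the delta, theta and alpha bands ((0, 12] Hz). A segment is
#' desynchronized only when its compound power lies strictly below the
#' median of all segments for at least two segments in sequence; everything
#' else, including median ties and isolated below-median segments, is
#' synchronized.
#'
#' @param ecog numeric ECoG vector.
#' @param fs sampling rate, Hz (default 1000).
#' @param seg_ms segment length, ms.
#' @param hop_ms hop between segment starts, ms.
#' @param band frequency band whose power is summed, Hz (half-open
#'   \code{(band[1], band[2]]}).
#' @return object of class \code{ecog_state_track}: data frame
#'   \code{segments} (\code{start_s}, \code{power}, \code{below},
#'   \code{state}), \code{median_power}, \code{fs}, \code{seg_ms},
#'   \code{hop_ms}.
#' @export
segment_ecog <- function(ecog, fs = 1000, seg_ms = 1000, hop_ms = 875,
                         band = c(0, 12)) {
  nseg_len <- round(seg_ms / 1000 * fs)
  hop <- round(hop_ms / 1000 * fs)
  n <- length(ecog)
  starts <- seq(1L, n - nseg_len + 1L, by = hop)
  if (length(starts) < 2L) stop("ECoG shorter than two segments")
  freqs <- (seq_len(nseg_len) - 1L) * fs / nseg_len
  sel <- freqs > band[1] & freqs <= band[2]
  power <- vapply(starts, function(s) {
    x <- ecog[s:(s + nseg_len - 1L)]
    x <- x - mean(x)                      # constant (mean) detrending
    px <- Mod(stats::fft(x))^2 / (nseg_len * fs)
    sum(px[sel])
  }, numeric(1))
  med <- stats::median(power)
  below <- power < med                    # strictly below
  r <- rle(below)
  runs <- rep(r$lengths, r$lengths)
  state <- ifelse(below & runs >= 2L, "desynchronized", "synchronized")
  structure(list(segments = data.frame(start_s = (starts - 1L) / fs,
                                       power = power, below = below,
                                       state = state),
                 median_power = med, fs = fs, seg_ms = seg_ms,
                 hop_ms = hop_ms),
            class = "ecog_state_track")
}

#' @export
print.ecog_state_track <- function(x, ...) {
  cat(sprintf("ECoG state track: %d segment(s), %.1f%% desynchronized\n",
              nrow(x$segments),
              100 * mean(x$segments$state == "desynchronized")))
  invisible(x)
}

#' @export
plot.ecog_state_track <- function(x, ...) {
  s <- x$segments
  graphics::plot(s$start_s, s$power, type = "l",
                 xlab = "time (s)", ylab = "0-12 Hz power", ...)
  graphics::abline(h = x$median_power, lty = 2)
  de <- s$state == "desynchronized"
  graphics::points(s$start_s[de], s$power[de], col = 2, pch = 16, cex = 0.6)
  invisible(x)
}

#' ECoG state at given times
#'
#' Each time is mapped to the latest segment starting at or before it (in
#' the 125-ms overlap of two segments the later segment wins) and that
#' segment's state is returned.
#'
#' @param track an \code{ecog_state_track}.
#' @param times numeric times, s.
#' @return character vector of states.
#' @export
state_at_times <- function(track, times) {
  s <- track$segments
  idx <- findInterval(times, s$start_s)
  if (any(idx < 1L)) stop("times before the first ECoG segment")
  s$state[idx]
}

#' Association between response types and the desynchronized state
#'
#' For every response type the fraction of its member presentations that
#' fell in the desynchronized ECoG state is paired with the overall
#' desynchronized fraction of its own (neuron, pattern) cell, and the pairs
#' are compared with a two-sided paired t-test. A second test restricted to
#' types with more than \code{big_min} members is also run, since the
#' fraction of a small type moves in coarse steps.
#'
#' @param cells list of cells, each with \code{assignment} (integer type
#'   labels per repetition, 0 = ungrouped) and \code{onset_states}
#'   (character state per repetition, from \code{\link{state_at_times}}).
#' @param big_min membership cut for the restricted test (default 9:
#'   "more than nine members").
#' @return object of class \code{type_state_association}: \code{per_type}
#'   data frame (cell, type, n members, desync fraction, cell fraction),
#'   \code{p_all}, \code{p_big}, \code{n_types}, \code{n_big}.
#' @export
type_state_association <- function(cells, big_min = 9) {
  rows <- list()
  for (ci in seq_along(cells)) {
    cl <- cells[[ci]]
    de <- cl$onset_states == "desynchronized"
    cell_frac <- mean(de)
    for (t_ in sort(unique(cl$assignment[cl$assignment > 0L]))) {
      m <- cl$assignment == t_
      rows[[length(rows) + 1L]] <- data.frame(
        cell = ci, type = t_, n = sum(m),
        type_desync = mean(de[m]), cell_desync = cell_frac)
    }
  }
  per <- do.call(rbind, rows)
  if (is.null(per) || nrow(per) < 2L) stop("fewer than 2 response types")
  tt <- stats::t.test(per$type_desync, per$cell_desync, paired = TRUE)
  big <- per[per$n > big_min, ]
  p_big <- if (nrow(big) >= 2L && stats::sd(big$type_desync - big$cell_desync) > 0) {
    stats::t.test(big$type_desync, big$cell_desync, paired = TRUE)$p.value
  } else {
    NA_real_
  }
  structure(list(per_type = per, p_all = tt$p.value, p_big = p_big,
                 n_types = nrow(per), n_big = nrow(big), big_min = big_min),
            class = "type_state_association")
}

#' @export
print.type_state_association <- function(x, ...) {
  cat(sprintf("Response type vs ECoG state: paired t-test p = %.3f over %d type(s)\n",
              x$p_all, x$n_types))
  cat(sprintf("  restricted to types with > %d members: p = %.3f (%d type(s))\n",
              x$big_min, x$p_big, x$n_big))
  invisible(x)
}
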