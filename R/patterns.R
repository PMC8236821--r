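#' Pattern labels used throughout
#'
#' The eight spatiotemporal stimulation patterns are named by the sensor
#' tuning (F = fast-adapting, S = slow-adapting) and the sharpness exponent
#' of the probe (5, 10, 20, inf).
#' @keywords internal
pattern_labels <- function(n) {
  base <- c("F5", "S5", "F10", "S10", "F20", "S20", "Finf", "Sinf")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, paste0("P", seq(length(base) + 1L, n)))
}

#' Generate spatiotemporal stimulation patterns
#'
#' Each pattern is an ordered list of pulse times (ms from pattern onset)
#' with a skin channel per pulse. Pulse counts are 5-33 per pattern,
#' inter-pulse intervals are drawn log-uniform on [1, 123] ms and, when a
#' draw overruns the maximal pattern duration, the intervals are compressed
#' proportionally (clipping at the 1 ms floor) so the last pulse stays below
#' 340 ms. Across the default eight patterns the total pulse count is close
#' to the configurable target of 152.
#'
#' @param n_patterns number of patterns (default 8).
#' @param n_channels number of skin channels (default 4).
#' @param seed integer seed; identical seeds give identical pulse lists.
#' @param total_pulses target for the summed pulse count across patterns.
#' @param max_duration_ms pattern duration bound; last pulse offset is kept
#'   strictly below this.
#' @param ipi_range_ms allowed inter-pulse interval range, ms.
#' @return a list of \code{stim_pattern} objects, each with \code{label} and
#'   a \code{pulses} data frame (\code{offset_ms}, \code{channel}).
#' @export
generate_patterns <- function(n_patterns = 8, n_channels = 4, seed = 1,
                              total_pulses = 152, max_duration_ms = 340,
                              ipi_range_ms = c(1, 123)) {
  if (n_patterns < 1) stop("n_patterns must be >= 1")
  if (n_channels < 1) stop("n_channels must be >= 1")
  if (max_duration_ms <= 5 * ipi_range_ms[1]) {
    stop("pattern duration constraints unsatisfiable")
  }
  set.seed(seed)
  labels <- pattern_labels(n_patterns)
  per <- total_pulses / n_patterns
  counts <- pmin(33L, pmax(5L, as.integer(round(stats::rnorm(n_patterns, per, 4)))))
  out <- vector("list", n_patterns)
  for (i in seq_len(n_patterns)) {
    k <- counts[i]
    ipi <- exp(stats::runif(k - 1L, log(ipi_range_ms[1]), log(ipi_range_ms[2])))
    # compress to fit strictly inside the duration bound
    limit <- max_duration_ms - 1
    if (sum(ipi) > limit) {
      ipi <- ipi * limit / sum(ipi)
      ipi <- pmax(ipi, ipi_range_ms[1])
      while (sum(ipi) > limit && k > 5L) {  # floor clipping can re-overflow
        k <- k - 1L
        ipi <- ipi[seq_len(k - 1L)]
      }
    }
    offsets <- c(0, cumsum(ipi))
    channels <- sample.int(n_channels, length(offsets), replace = TRUE)
    out[[i]] <- structure(
      list(label = labels[i],
           pulses = data.frame(offset_ms = offsets, channel = channels)),
      class = "stim_pattern")
  }
  out
}

#' @export
print.stim_pattern <- function(x, ...) {
  cat(sprintf("Stimulation pattern %s: %d pulses over %.0f ms on %d channel(s)\n",
              x$label, nrow(x$pulses), max(x$pulses$offset_ms),
              length(unique(x$pulses$channel))))
  invisible(x)
}

#' Select within-pattern pulses eligible for single-pulse response analysis
#'
#' A pulse inside a pattern is eligible when it is separated from both its
#' previous and next pulse by at least \code{min_sep_ms}; the first and last
#' pulses only have one neighbouring gap and are judged on that gap alone.
#'
#' @param patterns list of \code{stim_pattern} objects.
#' @param min_sep_ms minimum separation from neighbouring pulses, ms.
#' @return data frame with columns \code{label}, \code{pulse_index},
#'   \code{offset_ms}, \code{channel}, \code{eligible}.
#' @export
select_in_pattern_pulses <- function(patterns, min_sep_ms = 10) {
  if (inherits(patterns, "stim_pattern")) patterns <- list(patterns)
  rows <- lapply(patterns, function(p) {
    off <- p$pulses$offset_ms
    k <- length(off)
    gap_prev <- c(Inf, diff(off))
    gap_next <- c(diff(off), Inf)
    data.frame(label = p$label, pulse_index = seq_len(k),
               offset_ms = off, channel = p$pulses$channel,
               eligible = gap_prev >= min_sep_ms & gap_next >= min_sep_ms)
  })
  do.call(rbind, rows)
}
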