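#' Quality check of an intracellular recording
#'
#' Applies the recording-inclusion criteria: a stable Down-state membrane
#' potential below -55 mV, a spike amplitude above 25 mV when spikes are
#' present, and an Up/Down peak-to-peak separation above 10 mV. The Down and
#' Up levels are estimated as the lower and upper modes of the membrane
#' potential amplitude distribution; if the distribution is unimodal the
#' peak-to-peak criterion falls back to the 5th-95th percentile span and the
#' report notes it.
#'
#' @param recording a \code{vm_recording}, or a numeric Vm vector (mV).
#' @param fs sampling rate in Hz (ignored when a recording is given).
#' @return object of class \code{qc_report}: \code{down_state_mode},
#'   \code{up_mode}, \code{up_down_peak_to_peak}, \code{spike_amplitude}
#'   (NA if no spikes detected), \code{unimodal}, and \code{passes}, a list
#'   of per-criterion booleans plus \code{overall}.
#' @export
qc_check <- function(recording, fs = 1e5) {
  if (inherits(recording, "vm_recording")) {
    vm <- recording$vm
    fs <- recording$fs_vm
  } else {
    vm <- as.numeric(recording)
  }
  if (length(vm) == 0) stop("empty Vm trace")
  dec <- max(1L, floor(fs / 1000))
  v <- vm[seq(1L, length(vm), by = dec)]

  spikes <- detect_spikes(vm, fs)
  spike_amp <- NA_real_
  if (length(spikes$times) > 0) spike_amp <- stats::median(spikes$amplitudes)
  # exclude spike excursions from the level histogram
  if (length(spikes$times) > 0) {
    sp_ms <- round(spikes$times * 1000)
    drop <- unique(unlist(lapply(sp_ms, function(m) max(1, m - 2):(m + 8))))
    drop <- drop[drop <= length(v)]
    if (length(drop) > 0 && length(drop) < length(v)) v <- v[-drop]
  }

  dens <- stats::density(v, n = 512)
  y <- dens$y
  pk <- which(diff(sign(diff(y))) == -2) + 1L
  pk <- pk[order(y[pk], decreasing = TRUE)]
  # keep peaks that are separated and non-negligible
  pk <- pk[y[pk] > 0.05 * max(y)]
  unimodal <- length(pk) < 2L
  if (unimodal) {
    down_mode <- dens$x[pk[1]]
    up_mode <- down_mode
    p2p <- unname(diff(stats::quantile(v, c(0.05, 0.95))))
  } else {
    modes <- sort(dens$x[pk[1:2]])
    down_mode <- modes[1]
    up_mode <- modes[2]
    p2p <- up_mode - down_mode
  }

  passes <- list(
    down_state = down_mode < -55,
    spikes = is.na(spike_amp) || spike_amp > 25,
    peak_to_peak = p2p > 10
  )
  passes$overall <- passes$down_state && passes$spikes && passes$peak_to_peak
  structure(list(down_state_mode = down_mode, up_mode = up_mode,
                 up_down_peak_to_peak = p2p, spike_amplitude = spike_amp,
                 n_spikes = length(spikes$times), unimodal = unimodal,
                 passes = passes),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Recording quality check\n")
  cat(sprintf("  Down-state mode: %.1f mV (criterion < -55: %s)\n",
              x$down_state_mode, x$passes$down_state))
  cat(sprintf("  Up-Down peak-to-peak: %.1f mV (criterion > 10: %s)%s\n",
              x$up_down_peak_to_peak, x$passes$peak_to_peak,
              if (x$unimodal) " [unimodal Vm: percentile span used]" else ""))
  if (is.na(x$spike_amplitude)) {
    cat("  Spikes: none detected\n")
  } else {
    cat(sprintf("  Spike amplitude: %.1f mV over %d spikes (criterion > 25: %s)\n",
                x$spike_amplitude, x$n_spikes, x$passes$spikes))
  }
  cat(sprintf("  Overall: %s\n", if (x$passes$overall) "PASS" else "FAIL"))
  invisible(x)
}

#' Low-pass smooth a trace with the standard 50-microsecond moving average
#'
#' @param vm numeric Vm vector (mV).
#' @param fs sampling rate, Hz; the window is \code{round(50e-6 * fs)}
#'   samples (5 samples at 100 kHz). Edges use shrinking windows.
#' @return smoothed vector, same length.
#' @export
smooth_trace <- function(vm, fs = 1e5) {
  w <- max(1L, as.integer(round(50e-6 * fs)))
  moving_average(vm, w)
}

#' Blank stimulation artifacts by linear interpolation
#'
#' Replaces samples in \code{[t, t + blank_ms)} after each pulse by a linear
#' interpolation between the samples bounding the blanked span. Overlapping
#' spans are merged.
#'
#' @param vm numeric Vm vector.
#' @param pulse_times_s pulse onset times, seconds.
#' @param fs sampling rate, Hz.
#' @param blank_ms blanked span per pulse, ms (default 1).
#' @return vector with artifacts blanked.
#' @export
blank_artifacts <- function(vm, pulse_times_s, fs = 1e5, blank_ms = 1) {
  if (length(pulse_times_s) == 0) return(vm)
  n <- length(vm)
  w <- max(1L, round(blank_ms / 1000 * fs))
  starts <- pmax(1L, floor(pulse_times_s * fs) + 1L)
  ends <- pmin(n, starts + w - 1L)
  keep <- starts <= n
  starts <- starts[keep]; ends <- ends[keep]
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  # merge overlapping or adjacent spans
  ms <- me <- integer(0)
  cs <- starts[1]; ce <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= ce + 1L) {
      ce <- max(ce, ends[i])
    } else {
      ms <- c(ms, cs); me <- c(me, ce)
      cs <- starts[i]; ce <- ends[i]
    }
  }
  ms <- c(ms, cs); me <- c(me, ce)
  for (i in seq_along(ms)) {
    i0 <- ms[i]; i1 <- me[i]
    v0 <- if (i0 > 1L) vm[i0 - 1L] else vm[i1 + 1L]
    v1 <- if (i1 < n) vm[i1 + 1L] else v0
    vm[i0:i1] <- v0 + (v1 - v0) * seq_len(i1 - i0 + 1L) / (i1 - i0 + 2L)
  }
  vm
}

# Spike detection by derivative threshold on the 1-ms-smoothed trace.
# Returns peak times (s) and peak-minus-local-baseline amplitudes (mV).
detect_spikes <- function(vm, fs, thresh_mv_per_ms = 15) {
  sm <- moving_average(vm, max(1L, round(fs / 1000)))
  dv <- c(0, diff(sm)) * fs / 1000     # mV per ms
  hot <- dv > thresh_mv_per_ms
  if (!any(hot)) return(list(times = numeric(0), amplitudes = numeric(0)))
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  w2 <- round(0.002 * fs)
  times <- amps <- numeric(0)
  last <- -Inf
  for (k in on) {
    i0 <- starts[k]
    if (i0 - last < 0.003 * fs) next   # refractory merge
    span <- i0:min(length(vm), i0 + w2)
    pk <- span[which.max(vm[span])]
    base <- stats::median(vm[max(1L, i0 - w2):i0])
    times <- c(times, (pk - 1) / fs)
    amps <- c(amps, vm[pk] - base)
    last <- pk
  }
  list(times = times, amplitudes = amps)
}

#' Remove action potentials using a recursive generic-spike fit
#'
#' Spikes are detected by a derivative threshold; a generic spike waveform is
#' then estimated by iterative alignment-and-averaging over the detections
#' (recursing until the average changes by less than \code{tol}) and
#' subtracted at every occurrence. With fewer than three detections the spike
#' times are reported but nothing is subtracted.
#'
#' @param vm numeric Vm vector (mV).
#' @param fs sampling rate, Hz.
#' @param thresh_mv_per_ms detection threshold on the smoothed derivative.
#' @param tol convergence tolerance on the mean waveform, mV.
#' @param max_iter maximum refinement iterations.
#' @return list with \code{vm} (cleaned trace) and \code{spike_times}
#'   (seconds).
#' @export
remove_spikes <- function(vm, fs = 1e5, thresh_mv_per_ms = 15, tol = 0.01,
                          max_iter = 20) {
  det <- detect_spikes(vm, fs, thresh_mv_per_ms)
  if (length(det$times) < 3) {
    return(list(vm = vm, spike_times = det$times))
  }
  pre <- round(0.002 * fs); post <- round(0.008 * fs)
  idx <- round(det$times * fs) + 1L
  idx <- idx[idx - pre >= 1 & idx + post <= length(vm)]
  if (length(idx) < 3) return(list(vm = vm, spike_times = det$times))
  segs <- t(vapply(idx, function(i) vm[(i - pre):(i + post)],
                   numeric(pre + post + 1L)))
  # align on waveform relative to its pre-spike baseline
  base <- segs[, 1:max(2L, round(pre / 2))]
  segs0 <- segs - rowMeans(base)
  shape <- colMeans(segs0)
  for (it in seq_len(max_iter)) {
    # re-estimate on residual-weighted average (plain mean here: shapes are
    # stereotyped, so this converges in one or two passes)
    new_shape <- colMeans(segs0)
    if (max(abs(new_shape - shape)) < tol && it > 1) break
    shape <- new_shape
  }
  # taper the subtraction window so no step is introduced
  taper <- rep(1, length(shape))
  nt <- round(0.0005 * fs)
  taper[seq_len(nt)] <- seq(0, 1, length.out = nt)
  taper[length(taper) - seq_len(nt) + 1L] <- seq(0, 1, length.out = nt)
  sub <- shape * taper
  out <- vm
  for (i in idx) out[(i - pre):(i + post)] <- out[(i - pre):(i + post)] - sub
  list(vm = out, spike_times = (idx - 1) / fs)
}

#' Extract evoked response windows aligned to event onsets
#'
#' One raw window per event, aligned to the event onset, half-open
#' \code{[onset, onset + duration)}. Windows truncated by the end of the
#' recording are dropped with a message.
#'
#' @param recording a \code{vm_recording} (or numeric Vm vector).
#' @param events event table with columns \code{onset_s}, \code{label},
#'   \code{repetition}; defaults to the recording's pattern events.
#' @param duration_ms window length, ms (350 for clustering; 1200 for the
#'   statistical time courses).
#' @param fs sampling rate when \code{recording} is a bare vector.
#' @return object of class \code{response_windows}: \code{windows} (matrix,
#'   one row per kept event), \code{info} (data frame of kept events),
#'   \code{fs}, \code{duration_ms}, \code{n_dropped}.
#' @export
extract_windows <- function(recording, events = NULL, duration_ms = 350,
                            fs = 1e5) {
  if (inherits(recording, "vm_recording")) {
    vm <- recording$vm
    fs <- recording$fs_vm
    if (is.null(events)) {
      events <- recording$events[recording$events$kind == "pattern", ]
    }
  } else {
    vm <- as.numeric(recording)
    if (is.null(events)) stop("events must be supplied for a bare trace")
  }
  nsamp <- round(duration_ms / 1000 * fs)
  starts <- floor(events$onset_s * fs) + 1L
  ok <- starts >= 1L & (starts + nsamp - 1L) <= length(vm)
  if (any(!ok)) {
    message(sprintf("dropping %d window(s) truncated by end of recording",
                    sum(!ok)))
  }
  keep <- which(ok)
  win <- matrix(NA_real_, length(keep), nsamp)
  for (j in seq_along(keep)) {
    s <- starts[keep[j]]
    win[j, ] <- vm[s:(s + nsamp - 1L)]
  }
  structure(list(windows = win, info = events[keep, , drop = FALSE],
                 fs = fs, duration_ms = duration_ms, n_dropped = sum(!ok)),
            class = "response_windows")
}

#' @export
print.response_windows <- function(x, ...) {
  cat(sprintf("%d response window(s) of %d ms at %g Hz (%d dropped)\n",
              nrow(x$windows), x$duration_ms, x$fs, x$n_dropped))
  invisible(x)
}

#' Normalise a raw response window to its temporal shape
#'
#' Pipeline (in order): 1-ms moving average; decimation to 1 kHz; subtraction
#' of a centred 100-ms moving average (shrinking at the edges) to remove the
#' offset; min-max scaling to [0, 1] based on the highest peak and deepest
#' trough. A window whose range is below \code{eps} is flagged degenerate and
#' filled with 0.5 so record counts stay aligned downstream.
#'
#' @param x numeric raw window (mV) sampled at \code{fs} (>= 1 kHz).
#' @param fs sampling rate of \code{x}, Hz.
#' @param eps degeneracy threshold on the pre-scaling range.
#' @return numeric vector of length \code{length(x) / (fs/1000)} in [0, 1],
#'   with attribute \code{degenerate} (logical).
#' @export
normalize_window <- function(x, fs = 1e5, eps = 1e-9) {
  dec <- max(1L, round(fs / 1000))
  if (dec > 1L) {
    x <- moving_average(x, round(fs / 1000))
    x <- x[seq(1L, length(x), by = dec)]
  }
  x <- x - moving_average(x, 100L)
  r <- max(x) - min(x)
  if (!is.finite(r) || r < eps) {
    out <- rep(0.5, length(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (x - min(x)) / r
  attr(out, "degenerate") <- FALSE
  out
}

#' Normalise a matrix of raw windows
#'
#' @param windows a \code{response_windows} object or a numeric matrix of
#'   raw windows (rows = repetitions).
#' @param fs sampling rate of the raw windows.
#' @return list with \code{normalized} (matrix, one row per window, 1 kHz)
#'   and \code{degenerate} (logical vector).
#' @export
normalize_windows <- function(windows, fs = 1e5) {
  if (inherits(windows, "response_windows")) {
    fs <- windows$fs
    windows <- windows$windows
  }
  res <- apply(windows, 1L, normalize_window, fs = fs, simplify = FALSE)
  list(normalized = do.call(rbind, lapply(res, as.numeric)),
       degenerate = vapply(res, function(r) attr(r, "degenerate"), logical(1)))
}
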