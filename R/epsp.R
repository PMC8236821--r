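# Smoothed derivative in mV/ms.
vm_derivative <- function(vm, fs) {
  sm <- moving_average(vm, max(1L, round(fs / 1000)))
  c(0, diff(sm)) * fs / 1000
}

#' Measure the EPSP evoked by one stimulation pulse
#'
#' Automated stand-in for manual cursor measurements: the response onset is
#' the first time after the pulse at which the 1-ms-smoothed derivative
#' exceeds the mean plus \code{thresh_sd} SDs of the pre-pulse derivative
#' (computed over the \code{pre_ms} before the pulse) for at least
#' \code{persist_ms}; the peak is the Vm maximum within \code{peak_win_ms}
#' of onset; the amplitude is Vm(peak) - Vm(onset). Returns \code{NULL}
#' when no onset is found within \code{max_latency_ms} or the post-pulse
#' window is truncated. Stimulation artifacts must be blanked beforehand
#' (see \code{\link{blank_artifacts}}); the onset search starts at
#' \code{min_latency_ms} after the pulse to stay clear of the blanked span.
#'
#' @param vm numeric Vm vector (artifact-blanked), mV.
#' @param pulse_time_s pulse onset, s.
#' @param fs sampling rate, Hz.
#' @param pre_ms baseline span for the derivative statistics.
#' @param min_latency_ms,max_latency_ms onset search bounds after the pulse.
#' @param peak_win_ms peak search span after onset.
#' @param persist_ms required supra-threshold run length.
#' @param thresh_sd threshold in baseline-derivative SDs.
#' @return list with \code{latency_ms}, \code{amplitude_mv}, \code{ttp_ms},
#'   \code{onset_s}, \code{peak_s}; or \code{NULL}.
#' @export
measure_pulse_response <- function(vm, pulse_time_s, fs = 1e5, pre_ms = 100,
                                   min_latency_ms = 1, max_latency_ms = 25,
                                   peak_win_ms = 30, persist_ms = 0.5,
                                   thresh_sd = 3) {
  ip <- floor(pulse_time_s * fs) + 1L
  post <- round((max_latency_ms + peak_win_ms + 5) / 1000 * fs)
  if (ip + round(0.04 * fs) > length(vm)) return(NULL)  # need >= 40 ms
  i0 <- max(1L, ip - round(pre_ms / 1000 * fs))
  i1 <- min(length(vm), ip + post)
  d <- vm_derivative(vm[i0:i1], fs)
  ip_loc <- ip - i0 + 1L
  base <- d[seq_len(max(2L, ip_loc - 1L))]
  thr <- mean(base) + thresh_sd * stats::sd(base)
  lo <- ip_loc + round(min_latency_ms / 1000 * fs)
  hi <- min(length(d), ip_loc + round(max_latency_ms / 1000 * fs))
  if (lo >= hi) return(NULL)
  hot <- d[lo:hi] > thr
  need <- max(1L, round(persist_ms / 1000 * fs))
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  k <- which(r$values & r$lengths >= need)
  if (length(k) == 0L) return(NULL)
  onset_loc <- lo + (ends[k[1]] - r$lengths[k[1]])
  pk_hi <- min(length(d), onset_loc + round(peak_win_ms / 1000 * fs))
  seg <- vm[(i0 + onset_loc - 1L):(i0 + pk_hi - 1L)]
  pk_rel <- which.max(seg)
  list(latency_ms = (onset_loc - ip_loc) * 1000 / fs,
       amplitude_mv = seg[pk_rel] - vm[i0 + onset_loc - 1L],
       ttp_ms = (pk_rel - 1L) * 1000 / fs,
       onset_s = (i0 + onset_loc - 2L) / fs,
       peak_s = (i0 + onset_loc + pk_rel - 3L) / fs)
}

#' Build an EPSP detection template from detected events
#'
#' Aligns at least 100 EPSP-like events at their onsets, averages them, and
#' places \code{n_checkpoints} equally spaced time-voltage checkpoints over
#' the rise and early decay. Each checkpoint's tolerance is \code{c_tol}
#' times the across-event SD at that offset, floored at \code{floor_mv}.
#' The checkpoint count is clamped to 5-20.
#'
#' @param vm numeric Vm vector.
#' @param event_times_s event onset times, s (>= 100 events).
#' @param fs sampling rate, Hz.
#' @param n_checkpoints requested checkpoints (clamped to [5, 20]).
#' @param c_tol tolerance multiplier (default 2).
#' @param span_ms template span after onset, ms.
#' @param floor_mv tolerance floor, mV.
#' @return object of class \code{epsp_template}: data frame
#'   \code{checkpoints} (\code{offset_ms}, \code{value_mv},
#'   \code{tol_mv}), \code{span_ms}, \code{n_events}.
#' @export
build_epsp_template <- function(vm, event_times_s, fs = 1e5,
                                n_checkpoints = 12, c_tol = 2,
                                span_ms = 25, floor_mv = 0.2) {
  if (length(event_times_s) < 100L) {
    stop("at least 100 events required to build a template")
  }
  n_checkpoints <- max(5L, min(20L, as.integer(n_checkpoints)))
  offs_ms <- seq(1, span_ms, length.out = n_checkpoints)
  idx0 <- floor(event_times_s * fs) + 1L
  offs_i <- round(offs_ms / 1000 * fs)
  keep <- idx0 + max(offs_i) <= length(vm) & idx0 >= 1L
  idx0 <- idx0[keep]
  segs <- vapply(offs_i, function(o) vm[idx0 + o] - vm[idx0],
                 numeric(length(idx0)))
  structure(list(checkpoints = data.frame(
    offset_ms = offs_ms,
    value_mv = colMeans(segs),
    tol_mv = pmax(floor_mv, c_tol * apply(segs, 2L, stats::sd))),
    span_ms = span_ms, n_events = length(idx0)),
    class = "epsp_template")
}

#' @export
print.epsp_template <- function(x, ...) {
  cat(sprintf("EPSP template: %d checkpoint(s) over %g ms, built on %d event(s)\n",
              nrow(x$checkpoints), x$span_ms, x$n_events))
  cat(sprintf("  peak checkpoint %.1f mV, tolerances %.2f-%.2f mV\n",
              max(x$checkpoints$value_mv), min(x$checkpoints$tol_mv),
              max(x$checkpoints$tol_mv)))
  invisible(x)
}

# Derivative-triggered candidate onsets over a whole trace: robust global
# threshold (median + thresh_sd * MAD), runs of at least persist_ms.
candidate_onsets <- function(vm, fs, thresh_sd = 3, persist_ms = 0.5) {
  d <- vm_derivative(vm, fs)
  thr <- stats::median(d) + thresh_sd * stats::mad(d)
  hot <- d > thr
  need <- max(1L, round(persist_ms / 1000 * fs))
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  k <- which(r$values & r$lengths >= need)
  ends[k] - r$lengths[k] + 1L
}

#' Detect EPSP-like events by template matching
#'
#' Slides the template over derivative-triggered candidate onsets and
#' reports a match when every checkpoint of the offset-corrected trace
#' falls within its tolerance. Matches closer than \code{merge_ms} are
#' merged to the earliest.
#'
#' @param vm numeric Vm vector (artifact-blanked).
#' @param template an \code{epsp_template}.
#' @param fs sampling rate, Hz.
#' @param merge_ms merge distance, ms.
#' @param thresh_sd,persist_ms candidate-onset detector settings.
#' @return numeric vector of match onset times, s.
#' @export
match_template <- function(vm, template, fs = 1e5, merge_ms = 4,
                           thresh_sd = 3, persist_ms = 0.5) {
  cand <- candidate_onsets(vm, fs, thresh_sd, persist_ms)
  if (length(cand) == 0L) return(numeric(0))
  cp <- template$checkpoints
  offs_i <- round(cp$offset_ms / 1000 * fs)
  cand <- cand[cand + max(offs_i) <= length(vm)]
  if (length(cand) == 0L) return(numeric(0))
  ok <- rep(TRUE, length(cand))
  base <- vm[cand]
  for (j in seq_len(nrow(cp))) {
    dev <- vm[cand + offs_i[j]] - base - cp$value_mv[j]
    ok <- ok & abs(dev) <= cp$tol_mv[j]
  }
  t_match <- (cand[ok] - 1L) / fs
  if (length(t_match) <= 1L) return(t_match)
  keep <- c(TRUE, diff(t_match) >= merge_ms / 1000)
  # merge chains: keep the earliest of each run of close matches
  t_match[keep]
}

#' Response fraction of a stimulation pulse with significance gating
#'
#' The response fraction is the proportion of a pulse's occurrences with at
#' least one template-matched EPSP in the 4-18 ms window after the pulse.
#' The spontaneous baseline is measured in 12 consecutive 14-ms bins
#' preceding each pattern onset: the per-presentation spontaneous fraction
#' is the proportion of matched bins, and its mean and SD across
#' presentations form the gate. A pulse response is significant only when
#' its fraction exceeds the baseline mean plus two SDs and at least
#' \code{min_events} occurrences evoked a matched event. With no pattern
#' onsets the baseline is undefined and the gate fails closed.
#'
#' @param match_times matched EPSP onset times, s (from
#'   \code{\link{match_template}}), or a list with \code{vm} to match on
#'   the fly.
#' @param pulse_times occurrence times of the pulse, s.
#' @param pattern_onsets pattern onset times used for the baseline, s.
#' @param resp_window_ms response window after the pulse, ms.
#' @param bin_ms,n_bins baseline binning before each onset.
#' @param min_events minimum matched occurrences.
#' @return list: \code{fraction}, \code{baseline_mean}, \code{baseline_sd},
#'   \code{n_events}, \code{significant}.
#' @export
response_fraction_and_gate <- function(match_times, pulse_times,
                                       pattern_onsets,
                                       resp_window_ms = c(4, 18),
                                       bin_ms = 14, n_bins = 12,
                                       min_events = 5) {
  if (length(pulse_times) == 0L) stop("at least one pulse occurrence required")
  hit <- vapply(pulse_times, function(t0) {
    any(match_times > t0 + resp_window_ms[1] / 1000 &
          match_times <= t0 + resp_window_ms[2] / 1000)
  }, logical(1))
  fraction <- mean(hit)
  n_events <- sum(hit)
  if (length(pattern_onsets) == 0L) {
    return(list(fraction = fraction, baseline_mean = NA_real_,
                baseline_sd = NA_real_, n_events = n_events,
                significant = FALSE))
  }
  per_onset <- vapply(pattern_onsets, function(t0) {
    edges <- t0 - (n_bins:0) * bin_ms / 1000
    binhit <- vapply(seq_len(n_bins), function(b) {
      any(match_times > edges[b] & match_times <= edges[b + 1L])
    }, logical(1))
    mean(binhit)
  }, numeric(1))
  bm <- mean(per_onset)
  bs <- stats::sd(per_onset)
  list(fraction = fraction, baseline_mean = bm, baseline_sd = bs,
       n_events = n_events,
       significant = fraction > bm + 2 * bs && n_events >= min_events)
}

#' Order effect of single-pulse rank within stimulation chunks
#'
#' Isolated single-pulse responses are delivered in chunks of five pulses;
#' this tests whether the within-chunk rank (1-5) affects the response
#' amplitude, by pairwise two-sided Wilcoxon rank-sum tests between rank
#' groups.
#'
#' @param amplitudes response amplitudes, mV.
#' @param ranks within-chunk rank (integer, same length).
#' @param min_group minimum values per rank group (smaller groups are
#'   skipped, yielding NA).
#' @return p-value matrix (rank x rank, NA diagonal).
#' @export
order_effect_test <- function(amplitudes, ranks, min_group = 3) {
  ranks <- as.integer(ranks)
  lv <- sort(unique(ranks))
  p <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (a in seq_along(lv)) for (b in seq_along(lv)) {
    if (a >= b) next
    xa <- amplitudes[ranks == lv[a]]
    xb <- amplitudes[ranks == lv[b]]
    if (length(xa) < min_group || length(xb) < min_group) next
    p[a, b] <- p[b, a] <- suppressWarnings(
      stats::wilcox.test(xa, xb, exact = FALSE)$p.value)
  }
  p
}

#' Pairwise between-neuron comparisons of pulse-response metrics
#'
#' For one eligible within-pattern pulse, compares the per-repetition
#' response values between every pair of neurons with two-sided Wilcoxon
#' rank-sum tests.
#'
#' @param values_by_neuron named list of numeric vectors (one per neuron
#'   with a significant, gated response at this pulse).
#' @return list: \code{p} (neuron x neuron matrix, NA diagonal),
#'   \code{frac_significant} (fraction of pairwise comparisons with
#'   p < 0.05), \code{n_comparisons}.
#' @export
pairwise_neuron_tests <- function(values_by_neuron) {
  k <- length(values_by_neuron)
  nm <- names(values_by_neuron)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  if (k >= 2L) {
    for (a in seq_len(k - 1L)) for (b in seq(a + 1L, k)) {
      p[a, b] <- p[b, a] <- suppressWarnings(
        stats::wilcox.test(values_by_neuron[[a]], values_by_neuron[[b]],
                           exact = FALSE)$p.value)
    }
  }
  lower <- p[lower.tri(p)]
  list(p = p,
       frac_significant = if (any(!is.na(lower))) mean(lower < 0.05, na.rm = TRUE) else NA_real_,
       n_comparisons = sum(!is.na(lower)))
}
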