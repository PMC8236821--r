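#' Configuration for a synthetic recording session
#'
#' Collects every tunable of the synthetic-session generator with defaults
#' matching the study conditions the pipeline is meant to analyse: eight
#' spatiotemporal patterns over four skin channels delivered 100 times each
#' with 1.8-s gaps, isolated single-pulse chunks (20 per channel, five pulses
#' 300 ms apart), a bistable Up/Down membrane potential with the Down state
#' below -55 mV and more than 10 mV Up-Down separation, single-pulse EPSP
#' statistics with population mean/SD 7.7/4.8 mV amplitude, 11.1/3.1 ms
#' onset latency and 9.8/5.6 ms time-to-peak, and an ECoG spending about 20
#' percent of the time in the desynchronized state.
#'
#' Amplitude and timing statistics are hierarchical: each neuron has its own
#' mean amplitude and time-to-peak (drawn from between-neuron distributions
#' whose spread is chosen so the pooled population SD matches the defaults),
#' while within-neuron variability is controlled by the coefficients of
#' variation (\code{sp_amp_cv} 0.43, \code{sp_latency_cv} 0.28,
#' \code{sp_ttp_cv} 0.29). For a single simulated neuron the per-neuron
#' means default to the population values.
#'
#' @param n_patterns,n_channels,reps_per_pattern pattern set geometry;
#'   \code{reps_per_pattern} may be a vector (one entry per pattern) to
#'   emulate recordings truncated after fewer repetitions.
#' @param inter_trial_gap gap between consecutive deliveries, s.
#' @param k_types number of planted response types per pattern: a single
#'   integer or an inclusive range to sample from.
#' @param ungrouped_fraction probability that a repetition is drawn from the
#'   diffuse (ungrouped) process instead of a planted type.
#' @param template_separation minimum pairwise mean absolute difference
#'   between planted type templates (normalized units).
#' @param within_type_noise_sd SD of the smooth within-type variability, in
#'   normalized template units.
#' @param evoked_amp_mv peak-to-peak amplitude of the evoked network drive, mV.
#' @param single_pulse_chunks,pulses_per_chunk,chunk_interval isolated
#'   single-pulse protocol (chunks per channel, pulses per chunk, s between
#'   pulses in a chunk).
#' @param vm_rate,ecog_rate sampling rates, Hz.
#' @param down_mv,up_mv Down and Up state levels, mV.
#' @param dwell_down_s,dwell_up_s mean Up/Down dwell times, s.
#' @param noise_sd_mv,noise_tau_ms membrane noise SD (mV) and correlation
#'   time (ms).
#' @param spont_epsp_rate,spont_epsp_amp_mv spontaneous EPSP shot-noise rate
#'   (Hz) and mean amplitude (mV).
#' @param sp_amp_mean,sp_amp_sd,sp_amp_cv single-pulse EPSP amplitude:
#'   population mean and SD (mV) and within-neuron CV.
#' @param sp_latency_mean,sp_latency_sd,sp_latency_cv onset latency (ms).
#' @param sp_ttp_mean,sp_ttp_sd,sp_ttp_cv time-to-peak (ms).
#' @param artifact_mv,artifact_ms stimulus artifact amplitude (mV) and
#'   biphasic transient width (ms).
#' @param spike_rate,spike_amp_mv spontaneous spike rate (Hz) and amplitude
#'   (mV); the recorded neurons are held just below threshold, so the rate
#'   is low.
#' @param desync_fraction,desync_dwell_s target fraction of time in the
#'   desynchronized ECoG state and its mean dwell, s.
#' @param seed master seed; all randomness flows from it.
#' @return a validated list of class \code{session_config}.
#' @export
session_config <- function(n_patterns = 8, n_channels = 4,
                           reps_per_pattern = 100, inter_trial_gap = 1.8,
                           k_types = c(3, 5), ungrouped_fraction = 0.2,
                           template_separation = 0.24,
                           within_type_noise_sd = 0.02,
                           evoked_amp_mv = 22,
                           single_pulse_chunks = 20, pulses_per_chunk = 5,
                           chunk_interval = 0.3,
                           vm_rate = 1e5, ecog_rate = 1000,
                           down_mv = -72, up_mv = -60,
                           dwell_down_s = 1.2, dwell_up_s = 0.8,
                           noise_sd_mv = 0.4, noise_tau_ms = 10,
                           spont_epsp_rate = 2, spont_epsp_amp_mv = 3.5,
                           sp_amp_mean = 7.7, sp_amp_sd = 4.8,
                           sp_amp_cv = 0.43,
                           sp_latency_mean = 11.1, sp_latency_sd = 3.1,
                           sp_latency_cv = 0.28,
                           sp_ttp_mean = 9.8, sp_ttp_sd = 5.6,
                           sp_ttp_cv = 0.29,
                           artifact_mv = 30, artifact_ms = 1,
                           spike_rate = 0.05, spike_amp_mv = 40,
                           desync_fraction = 0.2, desync_dwell_s = 4,
                           seed = 1) {
  cfg <- as.list(environment())
  if (cfg$vm_rate <= 0 || cfg$ecog_rate <= 0) stop("rates must be positive")
  if (any(cfg$reps_per_pattern < 1)) stop("reps_per_pattern must be >= 1")
  if (cfg$down_mv >= -55) stop("Down level must be below -55 mV")
  if (cfg$up_mv - cfg$down_mv <= 10) {
    stop("Up-Down separation must exceed 10 mV")
  }
  if (cfg$ungrouped_fraction < 0 || cfg$ungrouped_fraction > 1) {
    stop("ungrouped_fraction must be in [0, 1]")
  }
  structure(cfg, class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf("Synthetic session config: %d pattern(s) x %s rep(s), %d channel(s), seed %d\n",
              x$n_patterns, paste(unique(x$reps_per_pattern), collapse = "/"),
              x$n_channels, x$seed))
  invisible(x)
}

# Planted response types differ mildly in prevalence (the clustering
# extracts the largest first). The profile is kept close to uniform: very
# small types are statistically fragile in the per-timepoint rank tests,
# and the study's cells had no dominant type either.
type_size_profile <- function(k) {
  p <- 2^(-(seq_len(k) - 1L) / 2.5)
  p / sum(p)
}

# Between-neuron parameter draws consistent with the pooled population
# statistics (see session_config): neuron mean amplitude and time-to-peak
# vary across neurons; latency does not (its pooled SD already equals the
# within-neuron SD).
draw_neuron_params <- function(config, n_neurons = 1) {
  amp_within_sd <- config$sp_amp_cv * config$sp_amp_mean
  amp_between <- sqrt(max(0, config$sp_amp_sd^2 - amp_within_sd^2))
  ttp_within_sd <- config$sp_ttp_cv * config$sp_ttp_mean
  ttp_between <- sqrt(max(0, config$sp_ttp_sd^2 - ttp_within_sd^2))
  data.frame(
    neuron = seq_len(n_neurons),
    amp_mean = pmax(1.5, stats::rnorm(n_neurons, config$sp_amp_mean, amp_between)),
    lat_mean = rep(config$sp_latency_mean, n_neurons),
    ttp_mean = pmax(3, stats::rnorm(n_neurons, config$sp_ttp_mean, ttp_between))
  )
}

# Within-neuron event parameter draws (gamma-distributed, CV-controlled).
rgamma_cv <- function(n, mean, cv) {
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

draw_epsp_events <- function(n, neuron, config) {
  data.frame(
    amplitude_mv = rgamma_cv(n, neuron$amp_mean, config$sp_amp_cv),
    latency_ms = rgamma_cv(n, neuron$lat_mean, config$sp_latency_cv),
    ttp_ms = rgamma_cv(n, neuron$ttp_mean, config$sp_ttp_cv)
  )
}

# Sum many kernel-shaped transients into one trace in a single scope, so
# the subassignments stay in place instead of copying the full trace per
# event.
events_trace <- function(n, idx, kernels) {
  out <- numeric(n)
  for (j in seq_along(idx)) {
    i0 <- idx[j]
    if (is.na(i0) || i0 > n) next
    k <- kernels[[j]]
    if (i0 < 1L) {
      k <- k[(2L - i0):length(k)]
      i0 <- 1L
    }
    i1 <- min(n, i0 + length(k) - 1L)
    out[i0:i1] <- out[i0:i1] + k[seq_len(i1 - i0 + 1L)]
  }
  out
}

# Smooth correlated membrane noise: OU-like process generated at 2 kHz and
# linearly interpolated to the target rate, plus a small white component.
membrane_noise <- function(n, fs, sd_mv, tau_ms, white_sd = 0.05) {
  fs_lo <- 2000
  n_lo <- ceiling(n / fs * fs_lo) + 2L
  phi <- exp(-1000 / fs_lo / tau_ms)
  z <- stats::filter(stats::rnorm(n_lo, 0, sqrt(1 - phi^2)), phi,
                     method = "recursive")
  z <- as.numeric(z) * sd_mv
  idx <- (seq_len(n) - 1L) * (fs_lo / fs)
  lo <- floor(idx) + 1L
  frac <- idx - (lo - 1L)
  out <- z[lo] * (1 - frac) + z[pmin(n_lo, lo + 1L)] * frac
  out + stats::rnorm(n, 0, white_sd)
}

# Alternating two-state dwell sequence; returns transition times (s) and the
# state after each transition, starting in state 1 at time 0.
dwell_sequence <- function(total_s, mean1, mean2, shape = 2) {
  times <- numeric(0)
  t <- 0
  s <- 1L
  repeat {
    d <- stats::rgamma(1, shape = shape, rate = shape / if (s == 1L) mean1 else mean2)
    t <- t + d
    if (t >= total_s) break
    times <- c(times, t)
    s <- 3L - s
  }
  times
}

#' Simulate one synthetic recording session with ground truth
#'
#' Generates a full intracellular session: an Up/Down bistable membrane
#' potential with correlated noise and spontaneous EPSP shot noise;
#' randomly interleaved pattern presentations (each drawing a planted
#' response type or the diffuse ungrouped process) and isolated single-pulse
#' chunks; per-pulse EPSPs, biphasic stimulus artifacts and occasional
#' stereotyped spikes; and a parallel ECoG whose low-frequency power
#' alternates between synchronized and desynchronized epochs. Slow Up/Down
#' transitions are deferred until just after each evoked window, emulating
#' the stimulus-locked state reset of the cortical slow oscillation, so the
#' planted response shape is not confounded by a mid-window state flip.
#'
#' @param config a \code{session_config}.
#' @param neuron_id integer label for the simulated neuron; also offsets the
#'   neuron-specific parameter draws so different neurons differ.
#' @return list with \code{recording} (class \code{vm_recording}: \code{vm},
#'   \code{ecog}, \code{events}, \code{fs_vm}, \code{fs_ecog},
#'   \code{neuron_id}) and \code{truth} (class \code{session_truth}: planted
#'   \code{types}, \code{epsp} events, ECoG \code{states}, \code{spikes},
#'   \code{templates}, \code{patterns}, \code{neuron_params}).
#' @export
simulate_session <- function(config = session_config(), neuron_id = 1L) {
  stopifnot(inherits(config, "session_config"))
  seeds <- derive_seeds(config$seed + 7919L * neuron_id, 6L)

  patterns <- generate_patterns(config$n_patterns, config$n_channels,
                                seed = seeds[1])
  reps <- rep(config$reps_per_pattern, length.out = config$n_patterns)

  # planted templates per pattern (each call reseeds the RNG internally)
  kr <- range(config$k_types)
  set.seed(seeds[2])
  kvec <- sample(seq(kr[1], kr[2]), config$n_patterns, replace = TRUE)
  templates <- lapply(seq_len(config$n_patterns), function(i) {
    generate_type_templates(patterns[[i]], kvec[i],
                            separation = config$template_separation,
                            seed = seeds[2] + i)
  })

  set.seed(seeds[3])
  neuron <- draw_neuron_params(config, 1L)
  if (neuron_id > 1L) {
    set.seed(seeds[3] + neuron_id)
    neuron <- draw_neuron_params(config, 1L)
  }

  # ---- schedule ------------------------------------------------------------
  pat_items <- data.frame(
    kind = "pattern",
    label = rep(vapply(patterns, `[[`, "", "label"), reps),
    pattern_index = rep(seq_len(config$n_patterns), reps),
    channel = NA_integer_,
    repetition = unlist(lapply(reps, seq_len)),
    dur = 0.46
  )
  n_chunks <- config$single_pulse_chunks * config$n_channels
  chunk_items <- if (n_chunks > 0) data.frame(
    kind = "single",
    label = "single",
    pattern_index = NA_integer_,
    channel = rep(seq_len(config$n_channels), each = config$single_pulse_chunks),
    repetition = rep(seq_len(config$single_pulse_chunks), config$n_channels),
    dur = (config$pulses_per_chunk - 1) * config$chunk_interval + 0.12
  ) else pat_items[0, ]
  items <- rbind(pat_items, chunk_items)
  items <- items[sample.int(nrow(items)), ]
  # repetition index = chronological presentation count within its group
  grp <- paste(items$kind, items$label, items$channel)
  items$repetition <- stats::ave(seq_len(nrow(items)), grp,
                                 FUN = seq_along)
  onsets <- 5 + cumsum(c(0, utils::head(items$dur + config$inter_trial_gap, -1)))
  items$onset_s <- onsets
  total_s <- max(onsets + items$dur) + 2
  fs <- config$vm_rate
  n <- ceiling(total_s * fs)

  # ---- membrane potential --------------------------------------------------
  # Up/Down telegraph with transitions deferred out of evoked windows
  trans <- dwell_sequence(total_s, config$dwell_down_s, config$dwell_up_s)
  pat_onsets <- items$onset_s[items$kind == "pattern"]
  for (i in seq_along(trans)) {
    inwin <- pat_onsets[pat_onsets <= trans[i] & trans[i] < pat_onsets + 0.46]
    if (length(inwin)) trans[i] <- max(inwin) + 0.46
  }
  trans <- sort(trans)
  lvl_idx <- pmax(1L, pmin(n, floor(trans * fs) + 1L))
  state <- integer(n)
  cur <- 1L  # 1 = Down, 2 = Up
  bounds <- c(1L, lvl_idx, n + 1L)
  for (i in seq_len(length(bounds) - 1L)) {
    if (bounds[i] <= n && bounds[i + 1L] > bounds[i]) {
      state[bounds[i]:(bounds[i + 1L] - 1L)] <- cur
    }
    cur <- 3L - cur
  }
  lv <- ifelse(state == 2L, config$up_mv, config$down_mv)
  lv <- moving_average(lv, round(0.03 * fs))
  vm <- lv + membrane_noise(n, fs, config$noise_sd_mv, config$noise_tau_ms)
  rm(lv, state)

  # transient events are accumulated and summed into the trace in one pass
  ev_idx <- integer(0)
  ev_kern <- list()
  push_events <- function(at_idx, kerns) {
    ev_idx <<- c(ev_idx, at_idx)
    ev_kern <<- c(ev_kern, kerns)
  }

  # spontaneous EPSP shot noise
  n_spont <- stats::rpois(1, config$spont_epsp_rate * total_s)
  spont_t <- sort(stats::runif(n_spont, 0, total_s - 0.1))
  spont <- draw_epsp_events(n_spont, neuron, config)
  spont$amplitude_mv <- rgamma_cv(n_spont, config$spont_epsp_amp_mv, 0.6)
  push_events(floor(spont_t * fs) + 1L,
              lapply(seq_len(n_spont), function(e) {
                spont$amplitude_mv[e] *
                  epsp_kernel(spont$ttp_ms[e], 15, fs, length_ms = 70)
              }))

  # evoked responses, per-pulse EPSPs and artifacts
  truth_types <- items[items$kind == "pattern",
                       c("label", "repetition", "pattern_index", "onset_s")]
  truth_types$type_id <- NA_integer_
  epsp_rows <- list()
  artifact_times <- numeric(0)
  art_kern <- artifact_kernel(config$artifact_mv, config$artifact_ms, fs)
  # Neuron-specific relative gain per within-pattern pulse (the "mosaic").
  # In-pattern pulses evoke considerably smaller EPSPs than isolated
  # single pulses; keeping their mean contribution well below the slow
  # network drive also keeps the drive the dominant determinant of the
  # response shape.
  pulse_rel <- lapply(patterns, function(p) {
    exp(stats::rnorm(nrow(p$pulses), log(0.22), 0.4))
  })
  noise_len_ms <- 460L
  for (r in which(items$kind == "pattern")) {
    pi_ <- items$pattern_index[r]
    tpl <- templates[[pi_]]
    if (stats::runif(1) < config$ungrouped_fraction) {
      type_id <- 0L
      drive <- tpl$draw_ungrouped(1L)$drive[1L, ]
    } else {
      type_id <- sample.int(nrow(tpl$drive), 1L,
                            prob = type_size_profile(nrow(tpl$drive)))
      drive <- tpl$drive[type_id, ]
    }
    truth_types$type_id[truth_types$pattern_index == pi_ &
                          truth_types$repetition == items$repetition[r]] <- type_id
    ext <- extend_drive(drive, noise_len_ms)
    wn <- moving_average(stats::rnorm(noise_len_ms), 10L)
    wn <- wn / stats::sd(wn) * config$within_type_noise_sd
    # lead-in and lead-out ramps so the drive joins the background smoothly
    # (the analysis window [onset, onset+duration) sees exactly `ext`)
    lead <- 30L
    tail_ms <- 60L
    curve_1k <- config$evoked_amp_mv *
      c(ext[1] * (0.5 - 0.5 * cos(pi * seq_len(lead) / lead)),
        ext + wn,
        ext[noise_len_ms] * (0.5 + 0.5 * cos(pi * seq_len(tail_ms) / tail_ms)))
    noise_len_tot <- noise_len_ms + lead + tail_ms
    i0 <- floor((items$onset_s[r] - lead / 1000) * fs) + 1L
    up <- fs / 1000
    m <- (noise_len_tot - 1L) * up
    xi <- (seq_len(m) - 1L) / up
    loi <- floor(xi) + 1L
    fr <- xi - (loi - 1L)
    seg <- curve_1k[loi] * (1 - fr) +
      curve_1k[pmin(noise_len_tot, loi + 1L)] * fr
    push_events(i0, list(seg))
    # per-pulse EPSPs and artifacts; the in-pattern amplitude is mostly a
    # fixed property of the (neuron, pulse) pair, with modest
    # trial-to-trial jitter
    pl <- patterns[[pi_]]$pulses
    ev <- draw_epsp_events(nrow(pl), neuron, config)
    ev$amplitude_mv <- neuron$amp_mean * pulse_rel[[pi_]] *
      exp(stats::rnorm(nrow(pl), 0, 0.25))
    ev$latency_ms <- neuron$lat_mean * exp(stats::rnorm(nrow(pl), 0, 0.12))
    pt <- items$onset_s[r] + pl$offset_ms / 1000
    push_events(floor((pt + ev$latency_ms / 1000) * fs) + 1L,
                lapply(seq_len(nrow(pl)), function(j) {
                  # in-pattern EPSPs decay faster than isolated ones (the
                  # network is in a driven, high-conductance regime)
                  ev$amplitude_mv[j] * epsp_kernel(ev$ttp_ms[j], 8, fs, 45)
                }))
    push_events(floor(pt * fs) + 1L,
                rep(list(art_kern), length(pt)))
    artifact_times <- c(artifact_times, pt)
    epsp_rows[[length(epsp_rows) + 1L]] <- data.frame(
      time_s = pt, kind = "pattern", label = items$label[r],
      repetition = items$repetition[r], channel = pl$channel,
      pulse_index = seq_len(nrow(pl)), rank = NA_integer_, ev)
  }
  # isolated single-pulse chunks
  for (r in which(items$kind == "single")) {
    pt <- items$onset_s[r] +
      (seq_len(config$pulses_per_chunk) - 1L) * config$chunk_interval
    ev <- draw_epsp_events(config$pulses_per_chunk, neuron, config)
    push_events(floor((pt + ev$latency_ms / 1000) * fs) + 1L,
                lapply(seq_along(pt), function(j) {
                  ev$amplitude_mv[j] * epsp_kernel(ev$ttp_ms[j], 15, fs, 60)
                }))
    push_events(floor(pt * fs) + 1L, rep(list(art_kern), length(pt)))
    artifact_times <- c(artifact_times, pt)
    epsp_rows[[length(epsp_rows) + 1L]] <- data.frame(
      time_s = pt, kind = "single", label = "single",
      repetition = items$repetition[r], channel = items$channel[r],
      pulse_index = NA_integer_, rank = seq_along(pt), ev)
  }
  truth_epsp <- do.call(rbind, epsp_rows)

  # occasional stereotyped spikes
  n_spk <- stats::rpois(1, config$spike_rate * total_s)
  spike_times <- sort(stats::runif(n_spk, 0, total_s - 0.05))
  if (n_spk > 0) {
    spk <- spike_kernel(config$spike_amp_mv, fs)
    push_events(floor(spike_times * fs) + 1L, rep(list(spk), n_spk))
  }
  vm <- vm + events_trace(n, ev_idx, ev_kern)

  # ---- ECoG ----------------------------------------------------------------
  set.seed(seeds[4])
  ec <- simulate_ecog(total_s, config)

  events <- items[, c("onset_s", "kind", "label", "channel", "repetition")]
  rownames(events) <- NULL
  recording <- structure(
    list(vm = vm, ecog = ec$signal, events = events,
         patterns = patterns, pulses_per_chunk = config$pulses_per_chunk,
         chunk_interval = config$chunk_interval,
         fs_vm = fs, fs_ecog = config$ecog_rate, neuron_id = neuron_id),
    class = "vm_recording")
  truth <- structure(
    list(types = truth_types[order(truth_types$pattern_index,
                                   truth_types$repetition),
                             c("label", "repetition", "type_id")],
         epsp = truth_epsp, states = ec$states,
         spikes = spike_times, templates = templates,
         patterns = patterns, neuron_params = neuron,
         artifact_times = sort(artifact_times), k_types = kvec),
    class = "session_truth")
  list(recording = recording, truth = truth)
}

# biphasic 1-ms stimulus artifact
artifact_kernel <- function(amp_mv, width_ms, fs) {
  half <- max(1L, round(width_ms / 2000 * fs))
  c(rep(amp_mv, half), rep(-amp_mv, half))
}

# stereotyped action potential: fast rise, fast fall, shallow AHP
spike_kernel <- function(amp_mv, fs) {
  rise <- round(0.0004 * fs)
  fall <- round(0.0010 * fs)
  ahp <- round(0.004 * fs)
  c(seq(0, amp_mv, length.out = rise),
    seq(amp_mv, -0.1 * amp_mv, length.out = fall),
    seq(-0.1 * amp_mv, 0, length.out = ahp))
}

# ECoG synthesis: synchronized epochs carry a large-amplitude 1-4 Hz
# oscillation (amplitude-modulated per half second) over broadband noise;
# desynchronized epochs are attenuated broadband noise only.
simulate_ecog <- function(total_s, config) {
  fs <- config$ecog_rate
  n <- ceiling(total_s * fs)
  f <- config$desync_fraction
  mean_sync <- config$desync_dwell_s * (1 - f) / f
  trans <- dwell_sequence(total_s, mean_sync, config$desync_dwell_s, shape = 3)
  k <- length(trans)
  starts <- c(0, trans)
  ends <- c(trans, total_s)
  st <- rep(c("synchronized", "desynchronized"), length.out = k + 1L)
  states <- data.frame(start_s = starts, end_s = ends, state = st)

  base <- as.numeric(stats::filter(stats::rnorm(n), 0.9, method = "recursive"))
  base <- base / stats::sd(base)
  t <- (seq_len(n) - 1L) / fs
  freq <- stats::runif(1, 1.5, 3.5)
  # the slow-wave amplitude waxes and wanes with a ~1.8-s period (the
  # periodic grouping of slow-wave/spindle activity under ketamine), with
  # a slowly varying random component on top
  am_noise <- as.numeric(stats::filter(stats::rnorm(n, 0, 0.03), 0.98,
                                       method = "recursive"))
  am <- pmax(0.15, 1 + 0.45 * sin(2 * pi * t / 1.75 +
                                    stats::runif(1, 0, 2 * pi)) + am_noise)
  osc <- am * sin(2 * pi * freq * t + stats::runif(1, 0, 2 * pi))
  sync_mask <- rep(TRUE, n)
  for (i in which(states$state == "desynchronized")) {
    i0 <- max(1L, floor(states$start_s[i] * fs) + 1L)
    i1 <- min(n, ceiling(states$end_s[i] * fs))
    if (i1 >= i0) sync_mask[i0:i1] <- FALSE
  }
  sig <- ifelse(sync_mask, base + 2.6 * osc, 0.4 * base)
  list(signal = sig, states = states)
}

#' @export
print.vm_recording <- function(x, ...) {
  cat(sprintf("Intracellular recording, neuron %s: %.1f s Vm at %g Hz, ECoG at %g Hz\n",
              x$neuron_id, length(x$vm) / x$fs_vm, x$fs_vm, x$fs_ecog))
  cat(sprintf("  %d pattern presentation(s), %d single-pulse chunk(s)\n",
              sum(x$events$kind == "pattern"), sum(x$events$kind == "single")))
  invisible(x)
}

#' @export
print.session_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d labelled repetition(s), %d planted EPSP event(s), %d ECoG state interval(s)\n",
              nrow(x$types), nrow(x$epsp), nrow(x$states)))
  invisible(x)
}

#' Simulate evoked response windows directly (window-level generator)
#'
#' The window-level counterpart of \code{\link{simulate_session}} for
#' studies of the clustering and statistics stages: it generates the evoked
#' 1200-ms response windows of several (neuron, pattern) cells at 1 kHz in
#' mV, skipping the full 100-kHz trace synthesis. Each cell has its own
#' stimulation pattern, planted type templates and ground-truth labels;
#' windows are the planted drive (or an ungrouped draw) scaled to
#' \code{evoked_amp_mv}, riding on the resting potential and the Up/Down
#' background, with smooth within-type noise. As in the full generator the
#' background state is held during the evoked window (stimulus-locked state
#' reset) and resumes its spontaneous switching afterwards, and templates
#' decay to a common baseline within about 100 ms after the 350-ms
#' stimulation window, so separability collapses after stimulation offset.
#'
#' @param n_cells number of (neuron, pattern) cells.
#' @param k_types planted types per cell (scalar or range).
#' @param reps repetitions per cell.
#' @param config a \code{session_config}; the template, noise, amplitude and
#'   ungrouped-fraction settings are taken from it.
#' @param duration_ms window length, ms.
#' @param seed integer seed.
#' @return object of class \code{window_set}: a list of cells, each with
#'   \code{windows} (reps x duration matrix, mV at 1 kHz), \code{truth}
#'   (planted type id per repetition, 0 = ungrouped), \code{pattern},
#'   \code{templates}, \code{neuron}, \code{label}.
#' @export
simulate_window_set <- function(n_cells = 4, k_types = 4, reps = 100,
                                config = session_config(),
                                duration_ms = 1200, seed = 1) {
  kr <- range(k_types)
  cells <- vector("list", n_cells)
  for (ci in seq_len(n_cells)) {
    pat <- generate_patterns(1, config$n_channels,
                             seed = seed + 1000L * ci)[[1]]
    set.seed(seed + 31L * ci)
    k <- if (kr[1] == kr[2]) kr[1] else sample(seq(kr[1], kr[2]), 1L)
    tpl <- generate_type_templates(pat, k,
                                   separation = config$template_separation,
                                   seed = seed + 31L * ci + 1L)
    set.seed(seed + 31L * ci + 2L)
    labels <- ifelse(stats::runif(reps) < config$ungrouped_fraction, 0L,
                     sample.int(k, reps, replace = TRUE,
                                prob = type_size_profile(k)))
    up_shift <- config$up_mv - config$down_mv
    hold_ms <- 460L
    win <- matrix(0, reps, duration_ms)
    for (r in seq_len(reps)) {
      drive <- if (labels[r] == 0L) tpl$draw_ungrouped(1L)$drive[1L, ]
               else tpl$drive[labels[r], ]
      ext <- extend_drive(drive, duration_ms)
      wn <- moving_average(stats::rnorm(duration_ms), 10L)
      wn <- wn / stats::sd(wn) * config$within_type_noise_sd
      # Up/Down background: constant level while the evoked response is
      # held, then the spontaneous slow-wave regime in the window tail
      # (irregular Up/Down alternation at roughly 1 Hz, so no window has a
      # quiescent flat tail)
      bg <- numeric(duration_ms)
      lvl <- if (stats::runif(1) < 0.35) up_shift else 0
      bg[] <- lvl
      if (duration_ms > hold_ms) {
        t_ <- hold_ms + stats::runif(1, 0, 200)
        repeat {
          if (t_ >= duration_ms) break
          lvl <- up_shift - lvl
          bg[ceiling(t_):duration_ms] <- lvl
          t_ <- t_ + stats::rgamma(1, 2, 2 / (if (lvl > 0) 400 else 500))
        }
        bg <- moving_average(bg, 30L)
      }
      win[r, ] <- config$down_mv + bg +
        config$evoked_amp_mv * (ext + wn) +
        stats::rnorm(duration_ms, 0, 0.05)
    }
    cells[[ci]] <- list(windows = win, truth = labels, pattern = pat,
                        templates = tpl, neuron = 1L + (ci - 1L) %/% 8L,
                        label = paste0(pat$label, "#", ci))
  }
  structure(list(cells = cells, duration_ms = duration_ms, seed = seed),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("Window set: %d cell(s) of %d x %d ms evoked windows\n",
              length(x$cells), nrow(x$cells[[1]]$windows), x$duration_ms))
  invisible(x)
}

#' Simulate isolated single-pulse EPSP trials
#'
#' One long quiescent-baseline trace (Down-state level plus correlated
#' membrane noise) carrying one stimulated EPSP per trial, with the biphasic
#' stimulus artifact included. Event parameters are drawn from the
#' generator's default single-pulse distributions (hierarchical, see
#' \code{\link{session_config}}).
#'
#' @param n_trials number of trials.
#' @param config a \code{session_config}.
#' @param seed integer seed.
#' @param trial_s trial spacing, s.
#' @param pulse_offset_s pulse time within each trial, s.
#' @return list with \code{vm}, \code{fs}, \code{pulse_times} (s) and
#'   \code{truth} (planted amplitude/latency/time-to-peak per trial).
#' @export
simulate_single_pulse_trials <- function(n_trials = 400,
                                         config = session_config(),
                                         seed = 1, trial_s = 0.25,
                                         pulse_offset_s = 0.1) {
  set.seed(seed)
  fs <- config$vm_rate
  total_s <- n_trials * trial_s + 0.2
  n <- ceiling(total_s * fs)
  vm <- config$down_mv +
    membrane_noise(n, fs, config$noise_sd_mv, config$noise_tau_ms)
  neuron <- draw_neuron_params(config, 1L)
  neuron$amp_mean <- config$sp_amp_mean   # defaults for a single neuron
  neuron$ttp_mean <- config$sp_ttp_mean
  ev <- draw_epsp_events(n_trials, neuron, config)
  pulse_times <- (seq_len(n_trials) - 1L) * trial_s + pulse_offset_s
  art <- artifact_kernel(config$artifact_mv, config$artifact_ms, fs)
  idx <- c(floor((pulse_times + ev$latency_ms / 1000) * fs) + 1L,
           floor(pulse_times * fs) + 1L)
  kerns <- c(lapply(seq_len(n_trials), function(j) {
    ev$amplitude_mv[j] * epsp_kernel(ev$ttp_ms[j], 15, fs, 60)
  }), rep(list(art), n_trials))
  vm <- vm + events_trace(n, idx, kerns)
  list(vm = vm, fs = fs, pulse_times = pulse_times, truth = ev)
}
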