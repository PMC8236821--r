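#' All stimulus pulse times of a recording
#'
#' Reconstructs the delivery time, channel and identity of every stimulation
#' pulse from the event table and the pattern definitions carried by the
#' recording.
#'
#' @param recording a \code{vm_recording}.
#' @return data frame with \code{time_s}, \code{kind}, \code{label},
#'   \code{channel}, \code{repetition}, \code{pulse_index}.
#' @export
stimulus_pulse_times <- function(recording) {
  ev <- recording$events
  pat_by_label <- stats::setNames(recording$patterns,
                                  vapply(recording$patterns, `[[`, "", "label"))
  rows <- list()
  for (i in seq_len(nrow(ev))) {
    if (ev$kind[i] == "pattern") {
      p <- pat_by_label[[ev$label[i]]]
      rows[[i]] <- data.frame(
        time_s = ev$onset_s[i] + p$pulses$offset_ms / 1000,
        kind = "pattern", label = ev$label[i], channel = p$pulses$channel,
        repetition = ev$repetition[i],
        pulse_index = seq_len(nrow(p$pulses)))
    } else {
      k <- recording$pulses_per_chunk
      rows[[i]] <- data.frame(
        time_s = ev$onset_s[i] + (seq_len(k) - 1L) * recording$chunk_interval,
        kind = "single", label = "single", channel = ev$channel[i],
        repetition = ev$repetition[i], pulse_index = seq_len(k))
    }
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline on simulated sessions
#'
#' Orchestrates all stages end to end for one or more simulated neurons:
#' simulation, artifact blanking, spike removal, quality control (failing
#' recordings are excluded and listed), window extraction and
#' normalisation, response-type clustering per (neuron, pattern) cell,
#' Kruskal-Wallis specificity time courses with a label-shuffle null,
#' within-pattern and cross-pattern PCA + kNN decoding, ECoG state
#' segmentation with the type-state association test, and single-pulse
#' EPSP analysis (measurement, template matching, response-fraction gating,
#' chunk-order tests). Re-running with the same configuration reproduces
#' identical results.
#'
#' @param config a \code{session_config}.
#' @param n_neurons number of simulated neurons.
#' @param kw_shuffles label shuffles for the null curve (0 skips it).
#' @param with_ecog,with_epsp stage switches.
#' @param stat_window_ms length of the statistics windows, ms.
#' @return object of class \code{vm_run_report}.
#' @export
run_all <- function(config = session_config(), n_neurons = 2,
                    kw_shuffles = 20, with_ecog = TRUE, with_epsp = TRUE,
                    stat_window_ms = 1200) {
  stopifnot(inherits(config, "session_config"))
  cells <- list()
  cell_rows <- list()
  excluded <- list()
  cross_pattern <- list()
  ecog_assoc <- NULL
  epsp_rows <- list()
  order_tests <- list()
  sp_values <- list()

  for (nid in seq_len(n_neurons)) {
    message(sprintf("neuron %d: simulating session", nid))
    sim <- simulate_session(config, neuron_id = nid)
    rec <- sim$recording
    pulses <- stimulus_pulse_times(rec)

    message(sprintf("neuron %d: preprocessing (%d pulses)", nid, nrow(pulses)))
    vm <- blank_artifacts(rec$vm, pulses$time_s, rec$fs_vm,
                          blank_ms = config$artifact_ms)
    qc <- qc_check(vm, fs = rec$fs_vm)
    if (!qc$passes$overall) {
      excluded[[length(excluded) + 1L]] <- list(neuron = nid, qc = qc)
      message(sprintf("neuron %d: excluded by quality check", nid))
      next
    }
    sp <- remove_spikes(vm, rec$fs_vm)
    vm <- smooth_trace(sp$vm, rec$fs_vm)

    # ECoG segmentation once per neuron
    track <- if (with_ecog) segment_ecog(rec$ecog, rec$fs_ecog) else NULL

    pat_events <- rec$events[rec$events$kind == "pattern", ]
    for (p in rec$patterns) {
      ev <- pat_events[pat_events$label == p$label, ]
      w350 <- extract_windows(vm, ev, duration_ms = 350, fs = rec$fs_vm)
      w_long <- extract_windows(vm, ev, duration_ms = stat_window_ms,
                                fs = rec$fs_vm)
      n350 <- normalize_windows(w350)
      ts <- response_types(n350)
      nlong <- normalize_windows(w_long)
      # decoding within pattern
      acc <- f1_ung <- NA_real_
      if (ts$n_types >= 1L && sum(ts$assignment == 0L) >= 2L &&
          all(table(ts$assignment) >= 2L)) {
        task <- assemble_decoding_task(
          list(list(windows = n350$normalized, typeset = ts,
                    neuron = nid, label = p$label)), "within_pattern")
        dec <- try(decode_task(task, n_iter = 20,
                               seed = config$seed + nid), silent = TRUE)
        if (!inherits(dec, "try-error")) {
          acc <- dec$accuracy
          f1_ung <- unname(dec$f1["ungrouped"])
        }
      }
      onset_states <- if (with_ecog) {
        state_at_times(track, w_long$info$onset_s)
      } else {
        NULL
      }
      cells[[length(cells) + 1L]] <- list(
        neuron = nid, label = p$label,
        windows350 = n350$normalized, typeset = ts,
        windows_long = nlong$normalized,
        assignment = ts$assignment, onset_states = onset_states)
      cell_rows[[length(cell_rows) + 1L]] <- data.frame(
        neuron = nid, label = p$label, n_windows = ts$n_windows,
        n_types = ts$n_types, prop_ungrouped = ts$prop_ungrouped,
        accuracy = acc, f1_ungrouped = f1_ung)
    }

    # cross-pattern decoding for this neuron
    this <- cells[vapply(cells, function(cl) cl$neuron == nid, logical(1))]
    cp <- try(decode_task(assemble_decoding_task(
      lapply(this, function(cl) list(windows = cl$windows350,
                                     typeset = cl$typeset,
                                     neuron = cl$neuron, label = cl$label)),
      "cross_pattern"), n_iter = 20, seed = config$seed + nid),
      silent = TRUE)
    if (!inherits(cp, "try-error")) {
      cross_pattern[[as.character(nid)]] <- cp
    }

    # single-pulse EPSP stage
    if (with_epsp) {
      message(sprintf("neuron %d: EPSP analysis", nid))
      singles <- pulses[pulses$kind == "single", ]
      meas <- lapply(singles$time_s, function(t_)
        measure_pulse_response(vm, t_, rec$fs_vm))
      ok <- !vapply(meas, is.null, logical(1))
      if (any(ok)) {
        sp_values[[as.character(nid)]] <- data.frame(
          neuron = nid, channel = singles$channel[ok],
          rank = singles$pulse_index[ok],
          amplitude_mv = vapply(meas[ok], `[[`, numeric(1), "amplitude_mv"),
          latency_ms = vapply(meas[ok], `[[`, numeric(1), "latency_ms"),
          ttp_ms = vapply(meas[ok], `[[`, numeric(1), "ttp_ms"),
          onset_s = vapply(meas[ok], `[[`, numeric(1), "onset_s"))
        # order effect per channel
        spv <- sp_values[[as.character(nid)]]
        for (ch in sort(unique(spv$channel))) {
          m <- spv[spv$channel == ch, ]
          order_tests[[paste(nid, ch)]] <-
            order_effect_test(m$amplitude_mv, m$rank)
        }
        # template matching and response-fraction gating
        if (sum(ok) >= 100L) {
          tmpl <- build_epsp_template(vm, spv$onset_s, rec$fs_vm)
          matches <- match_template(vm, tmpl, rec$fs_vm)
          elig <- select_in_pattern_pulses(rec$patterns)
          iso_mean <- tapply(spv$amplitude_mv, spv$channel, mean)
          iso_lat <- tapply(spv$latency_ms, spv$channel, mean)
          for (r in which(elig$eligible)) {
            pp <- pulses[pulses$kind == "pattern" &
                           pulses$label == elig$label[r] &
                           pulses$pulse_index == elig$pulse_index[r], ]
            onsets <- pat_events$onset_s[pat_events$label == elig$label[r]]
            gate <- response_fraction_and_gate(matches, pp$time_s, onsets)
            rel_amp <- rel_lat <- NA_real_
            if (gate$significant) {
              pm <- lapply(pp$time_s, function(t_)
                measure_pulse_response(vm, t_, rec$fs_vm))
              pok <- !vapply(pm, is.null, logical(1))
              if (any(pok)) {
                amps <- vapply(pm[pok], `[[`, numeric(1), "amplitude_mv")
                lats <- vapply(pm[pok], `[[`, numeric(1), "latency_ms")
                ch <- as.character(elig$channel[r])
                rel_amp <- mean(amps) / iso_mean[[ch]]
                rel_lat <- mean(lats) / iso_lat[[ch]]
              }
            }
            epsp_rows[[length(epsp_rows) + 1L]] <- data.frame(
              neuron = nid, label = elig$label[r],
              pulse_index = elig$pulse_index[r],
              channel = elig$channel[r], fraction = gate$fraction,
              baseline_mean = gate$baseline_mean,
              baseline_sd = gate$baseline_sd, n_events = gate$n_events,
              significant = gate$significant,
              rel_amplitude = rel_amp, rel_latency = rel_lat)
          }
        }
      }
    }
  }
  if (length(cells) == 0L) stop("all recordings excluded by quality control")

  message("Kruskal-Wallis specificity and shuffle control")
  kw_cells <- lapply(cells, function(cl)
    list(windows = cl$windows_long, assignment = cl$assignment))
  tcs <- lapply(kw_cells, function(cl)
    try(type_specificity_timecourse(cl$windows, cl$assignment),
        silent = TRUE))
  tcs <- tcs[!vapply(tcs, inherits, logical(1), "try-error")]
  tcs <- tcs[vapply(tcs, function(tc) nrow(tc$p) > 0, logical(1))]
  fraction <- if (length(tcs)) significant_fraction(tcs) else NULL
  null_curve <- if (kw_shuffles > 0) {
    shuffle_control(kw_cells, n_shuffles = kw_shuffles,
                    seed = config$seed + 101L)
  } else {
    NULL
  }

  assoc <- NULL
  if (with_ecog) {
    assoc <- try(type_state_association(cells), silent = TRUE)
    if (inherits(assoc, "try-error")) assoc <- NULL
  }

  cfg_string <- paste(deparse(unclass(config)), collapse = "")
  structure(list(
    cells = do.call(rbind, cell_rows),
    cell_data = cells,
    kw = list(fraction = fraction, null = null_curve,
              timecourses = tcs),
    cross_pattern = cross_pattern,
    ecog_association = assoc,
    epsp = if (length(epsp_rows)) do.call(rbind, epsp_rows) else NULL,
    single_pulse = if (length(sp_values)) do.call(rbind, sp_values) else NULL,
    order_tests = order_tests,
    excluded = excluded,
    provenance = list(seed = config$seed, n_neurons = n_neurons,
                      config_hash = fnv1a32(cfg_string),
                      package_version = tryCatch(
                        as.character(utils::packageVersion("vmtypes")),
                        error = function(e) "unversioned"))),
    class = "vm_run_report")
}

#' @export
print.vm_run_report <- function(x, ...) {
  cat(sprintf("Pipeline run: %d (neuron, pattern) cell(s), %d excluded recording(s) [config %s, seed %s]\n",
              nrow(x$cells), length(x$excluded),
              x$provenance$config_hash, x$provenance$seed))
  cat(sprintf("  response types per cell: %.1f (SD %.1f); ungrouped %.0f%%\n",
              mean(x$cells$n_types), stats::sd(x$cells$n_types),
              100 * mean(x$cells$prop_ungrouped)))
  if (!is.null(x$kw$fraction)) {
    cat(sprintf("  KW significant fraction, stimulation window: mean %.2f (min %.2f)\n",
                mean(x$kw$fraction[1:341]), min(x$kw$fraction[1:341])))
  }
  if (!is.null(x$kw$null)) {
    cat(sprintf("  label-shuffle null, time-averaged: %.3f\n",
                x$kw$null$time_avg))
  }
  if (!is.null(x$ecog_association)) {
    cat(sprintf("  type vs ECoG state: paired t-test p = %.2f\n",
                x$ecog_association$p_all))
  }
  invisible(x)
}

#' Summary tables of a pipeline run
#'
#' Produces the per-pattern summary (mean and SD across neurons of the
#' number of identified response types, the type-separation accuracy, the
#' ungrouped fraction and the ungrouped F1 score, with a grand-average
#' column) and the single-pulse quantification (CV and values of the peak
#' amplitude, onset latency and time-to-peak).
#'
#' @param object a \code{vm_run_report}.
#' @param ... unused.
#' @return list of class \code{summary.vm_run_report} with data frames
#'   \code{type_separation} and \code{single_pulse}.
#' @export
summary.vm_run_report <- function(object, ...) {
  cl <- object$cells
  labels <- unique(cl$label)
  metrics <- list(
    n_types = cl$n_types,
    accuracy_pct = 100 * cl$accuracy,
    ungrouped_pct = 100 * cl$prop_ungrouped,
    f1_ungrouped = cl$f1_ungrouped)
  fmt <- function(v) {
    if (sum(!is.na(v)) == 0) return("-")
    s <- stats::sd(v, na.rm = TRUE)
    sprintf("%.1f (%.1f)", mean(v, na.rm = TRUE),
            if (is.na(s)) 0 else s)
  }
  tab1 <- data.frame(metric = names(metrics))
  tab1[["Grand average"]] <- vapply(metrics, fmt, "")
  for (lb in labels) {
    tab1[[lb]] <- vapply(metrics, function(v) fmt(v[cl$label == lb]), "")
  }
  tab2 <- NULL
  if (!is.null(object$single_pulse)) {
    spv <- object$single_pulse
    per_neuron_cv <- function(col) {
      vapply(split(spv[[col]], spv$neuron),
             function(v) stats::sd(v) / mean(v), numeric(1))
    }
    tab2 <- data.frame(
      metric = c("peak amplitude", "onset latency", "time to peak"),
      cv = vapply(c("amplitude_mv", "latency_ms", "ttp_ms"),
                  function(cn) {
                    v <- per_neuron_cv(cn)
                    sprintf("%.2f +/- %.2f", mean(v),
                            ifelse(is.na(stats::sd(v)), 0, stats::sd(v)))
                  }, ""),
      value = c(sprintf("%.1f +/- %.1f mV", mean(spv$amplitude_mv),
                        stats::sd(spv$amplitude_mv)),
                sprintf("%.1f +/- %.1f ms", mean(spv$latency_ms),
                        stats::sd(spv$latency_ms)),
                sprintf("%.1f +/- %.1f ms", mean(spv$ttp_ms),
                        stats::sd(spv$ttp_ms))))
  }
  structure(list(type_separation = tab1, single_pulse = tab2,
                 n_cells = nrow(cl), excluded = length(object$excluded)),
            class = "summary.vm_run_report")
}

#' @export
print.summary.vm_run_report <- function(x, ...) {
  cat(sprintf("Type separation per stimulation pattern (%d cells, %d excluded recordings):\n",
              x$n_cells, x$excluded))
  print(x$type_separation, row.names = FALSE)
  if (!is.null(x$single_pulse)) {
    cat("\nSingle-pulse response quantification:\n")
    print(x$single_pulse, row.names = FALSE)
  }
  invisible(x)
}
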