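#' Generate latent response-type templates for one stimulation pattern
#'
#' Builds \code{k_types} smooth 350-ms "drive" curves (1 kHz, min-max scaled
#' to [0, 1]) that play the role of the latent response types a neuron
#' expresses for one pattern, plus a diffuse generator for ungrouped
#' responses. Each drive is the sum of four components:
#' \itemize{
#'   \item a slow network-drive envelope taking a type-specific level in
#'     each of eight ~44-ms blocks; in every block the types split into a
#'     depolarised and a quiescent cluster (mirroring the bimodal Up/Down
#'     organisation of cortical membrane potential) with distinct
#'     sub-levels inside each cluster, and the split reshuffles from block
#'     to block, so any two types differ at essentially every sample away
#'     from block transitions,
#'   \item a spindle-band (11-14 Hz) oscillation with a type-specific phase,
#'     evenly spaced across types, emulating type-specific locking to the
#'     spindle activity prominent under ketamine anesthesia,
#'   \item pulse-triggered EPSP-like kernels whose gains co-vary with the
#'     envelope (a depolarised subnetwork responds more strongly),
#'   \item a type-specific smooth random perturbation so that no two types
#'     coincide exactly at any time point.
#' }
#' Construction is re-drawn until the minimum pairwise mean absolute
#' difference between the template curves reaches \code{separation} (and a
#' secondary internal margin on the offset-removed, window-normalised
#' counterparts holds, so the clustering stage sees well-separated shapes);
#' it fails after \code{attempts} tries.
#'
#' @param pattern a \code{stim_pattern} object.
#' @param k_types number of response types (>= 1, at most 14).
#' @param separation minimum pairwise mean absolute difference between
#'   template curves, normalized units (default 0.24; the geometric ceiling
#'   for smooth multi-component curves in [0, 1] is about 0.4, and the
#'   operative clustering margin is enforced separately via the inter-type
#'   mean overshoot).
#' @param seed integer seed.
#' @param w_pulse weight of the pulse-locked component.
#' @param h_env weight of the slow envelope component.
#' @param a_osc weight of the spindle-band component.
#' @param perturb_sd SD of the smooth type-specific perturbation.
#' @param duration_ms template length, ms (samples at 1 kHz).
#' @param attempts maximum number of construction attempts.
#' @return an object of class \code{type_templates} with elements
#'   \code{drive} (k x duration matrix in [0,1]; these are the template
#'   curves), \code{templates} (their offset-removed window-normalised
#'   counterparts, i.e. what a noise-free response window normalises to),
#'   \code{label}, \code{separation_achieved}, and
#'   \code{draw_ungrouped(n)}, a function drawing \code{n} diffuse drive
#'   curves from the same construction with fresh random codes, phases and
#'   gains.
#' @export
generate_type_templates <- function(pattern, k_types, separation = 0.24,
                                    seed = 1, w_pulse = 0.15, h_env = 1,
                                    a_osc = 0.25, perturb_sd = 0.05,
                                    duration_ms = 350, attempts = 1000) {
  stopifnot(inherits(pattern, "stim_pattern"), k_types >= 1)
  set.seed(seed)
  n <- as.integer(duration_ms)
  blocks <- 8L
  if (k_types > 14L) {
    stop("at most 14 types supported per pattern")
  }
  # The clustering stage must still separate the types after offset removal:
  # require the pairwise mean overshoot (the clustering's decision statistic,
  # at the default 0.13 per-sample threshold) between window-normalised
  # templates to clear the default 0.08 decision bound with a 50% margin.
  # (Bridging of two types by a response lying between them is prevented
  # separately, by the repulsion built into the diffuse draw process.)
  min_type_overshoot <- 0.12
  overshoot_ref <- 0.13

  for (att in seq_len(attempts)) {
    # Per-block network-drive levels: in every block the k types take k
    # distinct, equally spaced levels in a fresh random order (a Latin-
    # square-like design). Any two types therefore differ by at least one
    # level gap at every sample away from block transitions, which is what
    # gives the per-timepoint statistics their power, and the orderings
    # reshuffle from block to block so no type is systematically extremal.
    rows <- level_design(k_types, blocks)
    # types lock to a type-specific spindle phase; with more than four
    # types they split over two spindle frequencies so that phase
    # neighbours stay well separated
    if (k_types <= 4L) {
      freqs <- rep(stats::runif(1, 11, 14), k_types)
      phases <- 2 * pi * (seq_len(k_types) - 1L) / max(k_types, 2L)
    } else {
      k1 <- ceiling(k_types / 2)
      k2 <- k_types - k1
      f1 <- stats::runif(1, 10.5, 12)
      f2 <- f1 + stats::runif(1, 2.5, 3.5)
      freqs <- c(rep(f1, k1), rep(f2, k2))
      phases <- c(2 * pi * (seq_len(k1) - 1L) / k1,
                  2 * pi * (seq_len(k2) - 1L) / k2)
    }
    phases <- phases + stats::runif(1, 0, 2 * pi) +
      stats::runif(k_types, -0.12, 0.12)
    grid_shift <- stats::runif(1, 0, n / blocks)
    drive <- t(vapply(seq_len(k_types), function(i) {
      build_drive(pattern,
                  envelope_from_code(rows[i, ], n, shift_ms = grid_shift),
                  n, w_pulse, h_env, a_osc, freqs[i], phases[i], perturb_sd)
    }, numeric(n)))
    sep <- Inf
    if (k_types > 1L) {
      prs <- utils::combn(k_types, 2L)
      pairsep <- function(m) {
        min(apply(prs, 2L, function(p) mean(abs(m[p[1], ] - m[p[2], ]))))
      }
      sep <- pairsep(drive)
      if (sep < separation) next
      tpl <- t(apply(drive, 1L, function(d)
        as.numeric(normalize_window(d, fs = 1000))))
      hinge <- min(apply(prs, 2L, function(p) {
        mean(pmax(abs(tpl[p[1], ] - tpl[p[2], ]) - overshoot_ref, 0))
      }))
      if (hinge < min_type_overshoot) next
      # Equalise the offset-removed amplitude range of the extended (1200 ms)
      # curves across types, so the per-window normalisation constants of
      # long statistics windows carry no type information. Window
      # normalisation is affine-invariant, so this leaves the templates,
      # their separation and the clustering unchanged.
      for (it in 1:6) {
        rng <- apply(drive, 1L, function(d) {
          e <- extend_drive(d, 1200L)
          diff(range(e - moving_average(e, 100L)))
        })
        if (max(rng) / min(rng) - 1 < 0.02) break
        drive <- drive * (exp(mean(log(rng))) / rng)
      }
      if (max(rng) / min(rng) - 1 >= 0.04) next
      sep <- pairsep(drive)       # the rescale changes pairwise distances
      if (sep < separation) next
    } else {
      tpl <- matrix(as.numeric(normalize_window(drive[1, ], fs = 1000)),
                    nrow = 1L)
    }
    # The diffuse (ungrouped) process is repulsive: every draw must differ
    # both from the planted types (or the ground-truth labels would be
    # incoherent, and a between-types draw could bridge two types during
    # greedy extraction) and from recent previous draws (so that diffuse
    # responses do not themselves condense into spurious small types).
    tpl_local <- tpl
    ung_memory <- matrix(numeric(0), 0L, n)
    draw_ungrouped <- function(m) {
      drv <- matrix(0, m, n)
      tps <- matrix(0, m, n)
      for (i in seq_len(m)) {
        best <- NULL
        best_h <- -Inf
        for (try_ in seq_len(100L)) {
          code <- stats::runif(blocks, 0, 1)
          d <- build_drive(pattern, envelope_from_code(code, n,
                                                       shift_ms = grid_shift),
                           n, w_pulse, h_env, a_osc,
                           stats::runif(1, 9, 16),
                           stats::runif(1, 0, 2 * pi), perturb_sd)
          u <- as.numeric(normalize_window(d, fs = 1000))
          ref <- rbind(tpl_local, ung_memory)
          h <- min(apply(ref, 1L, function(t_) {
            mean(pmax(abs(u - t_) - overshoot_ref, 0))
          }))
          if (h > best_h) {
            best <- list(d = d, u = u)
            best_h <- h
          }
          if (h >= 0.10) break
        }
        drv[i, ] <- best$d
        tps[i, ] <- best$u
        ung_memory <<- rbind(ung_memory, best$u)
        if (nrow(ung_memory) > 60L) {
          ung_memory <<- ung_memory[-1L, , drop = FALSE]
        }
      }
      list(drive = drv, templates = tps)
    }
    return(structure(list(drive = drive, templates = tpl,
                          label = pattern$label, codes = rows,
                          spindle_hz = freqs, phases = phases,
                          separation_achieved = sep,
                          separation = separation,
                          duration_ms = n,
                          draw_ungrouped = draw_ungrouped),
                     class = "type_templates"))
  }
  stop(sprintf("could not reach template separation %.2f in %d attempts",
               separation, attempts))
}

# Per-block network-drive levels. In every block the types split into a
# depolarised and a quiescent cluster (the bimodal Up/Down organisation of
# cortical membrane potential), with small distinct sub-levels inside each
# cluster so no two types ever coincide exactly. The split is chosen so the
# expected membership mass of the two clusters is as balanced as possible:
# the pooled across-type median then falls between the clusters, which is
# what gives every single type a rank shift against the pooled rest at
# every sample (a type sitting exactly at the pooled median would be
# undetectable by a rank test however well separated the types are).
level_design <- function(k, blocks, sub_spread = 0.2) {
  if (k == 1L) return(matrix(stats::runif(blocks, 0.3, 0.7), 1L))
  w <- type_size_profile(k)
  subsets <- utils::combn(k, floor(k / 2), simplify = FALSE)
  if (k > 2L) {
    subsets <- c(subsets, utils::combn(k, ceiling(k / 2), simplify = FALSE))
  }
  imbalance <- vapply(subsets, function(s) abs(sum(w[s]) - 0.5), numeric(1))
  good <- subsets[imbalance <= pmax(0.08, min(imbalance) + 1e-9)]
  vapply(seq_len(blocks), function(b) {
    hi <- good[[sample.int(length(good), 1L)]]
    lv <- numeric(k)
    nh <- length(hi); nl <- k - nh
    lv[hi] <- 1 - sub_spread *
      (sample.int(nh) - 1L) / max(1L, nh - 1L)
    lv[-hi] <- sub_spread * (sample.int(nl) - 1L) / max(1L, nl - 1L)
    lv
  }, numeric(k))
}

# Smooth block envelope: value ~1 inside active blocks, 0 elsewhere, with
# boxcar-smoothed edges. `shift_ms` rotates the block grid (the same shift
# is used for every type of one pattern so code distances are preserved,
# but different patterns place their block boundaries at different times).
envelope_from_code <- function(code, n, ramp_ms = 7, shift_ms = 0) {
  blocks <- length(code)
  width <- n / blocks
  idx <- (floor((seq_len(n) - 1L + shift_ms) / width)) %% blocks + 1L
  lv <- code[idx]
  pad <- 2L * ramp_ms
  sm <- moving_average(c(rep(lv[1], pad), lv, rep(lv[n], pad)), pad)
  sm[pad + seq_len(n)]
}

# One drive curve: slow envelope + phase-tagged spindle oscillation +
# pulse kernels (gain tied to envelope) + smooth perturbation,
# min-max scaled to [0, 1].
build_drive <- function(pattern, env, n, w_pulse, h_env, a_osc,
                        osc_hz, osc_phase, perturb_sd) {
  kern <- epsp_kernel(ttp_ms = 9, decay_ms = 18, fs = 1000, length_ms = 70)
  pc <- numeric(n + length(kern))
  off <- pattern$pulses$offset_ms
  for (j in seq_along(off)) {
    i0 <- floor(off[j]) + 1L
    e <- env[min(n, i0)]
    gain <- (0.35 + 0.9 * e) * exp(stats::rnorm(1, 0, 0.18))
    idx <- i0:(i0 + length(kern) - 1L)
    pc[idx] <- pc[idx] + gain * kern
  }
  pc <- pc[seq_len(n)]
  if (max(pc) > 0) pc <- pc / max(pc)
  t_ms <- seq_len(n) - 1L
  osc <- 0.5 * (1 + sin(2 * pi * osc_hz * t_ms / 1000 + osc_phase))
  pert <- stats::rnorm(n)
  pert <- moving_average(pert, 30)
  pert <- pert / stats::sd(pert) * perturb_sd
  d <- w_pulse * pc + h_env * env + a_osc * osc + pert
  d <- (d - min(d)) / (max(d) - min(d))
  # blend the final 25 ms toward a common end anchor so the off-response
  # appended by extend_drive starts from the same value for every curve
  # (otherwise the offset-removal stage would couple type identity into
  # the shared off-response transient)
  nb <- 25L
  w <- (0.5 - 0.5 * cos(pi * seq_len(nb) / nb))
  tail_idx <- (n - nb + 1L):n
  d[tail_idx] <- d[tail_idx] * (1 - w) + 0.5 * w
  d
}

#' @export
print.type_templates <- function(x, ...) {
  cat(sprintf("%d response-type template(s) for pattern %s (%d ms)\n",
              nrow(x$templates), x$label, x$duration_ms))
  cat(sprintf("  min pairwise mean |difference|: %s\n",
              if (is.finite(x$separation_achieved))
                sprintf("%.3f", x$separation_achieved) else "n/a (single type)"))
  invisible(x)
}

# Extend a 350-ms drive to a longer window: a stereotyped biphasic
# off-response (brief rebound depolarisation followed by a deep
# post-stimulation hyperpolarisation) shared by all types, recovering to a
# common baseline, then flat. The off-response is fast enough to survive
# the 100-ms offset removal and more extreme than the drives themselves,
# so the min-max normalisation constants of long statistics windows are
# set by this shared transient rather than by the type-specific
# stimulation epoch, and separability collapses after stimulation offset.
extend_drive <- function(drive, total_ms, baseline = 0.3,
                         rebound_hi = 1.35, rebound_lo = -0.5) {
  n0 <- length(drive)
  if (total_ms <= n0) return(drive[seq_len(total_ms)])
  ramp <- function(from, to, ms) {
    from + (to - from) * (0.5 - 0.5 * cos(pi * seq_len(ms) / ms))
  }
  off <- c(ramp(drive[n0], rebound_hi, 40L),
           ramp(rebound_hi, rebound_lo, 60L),
           ramp(rebound_lo, baseline, 120L))
  out <- c(drive, off, rep(baseline, max(0L, total_ms - n0 - length(off))))
  out[seq_len(total_ms)]
}
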