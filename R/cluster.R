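#' Clustering parameters for response-type separation
#'
#' @param threshold_diff per-sample difference below which two normalised
#'   curves are considered identical at that sample, normalized units
#'   (default 0.13).
#' @param overshoot_thresh threshold on the mean overshoot above
#'   \code{threshold_diff} across the window, normalized units (default
#'   0.08); two curves with mean overshoot below it are the same type.
#' @param min_members minimum members for a valid response type (default 5);
#'   smaller groups dissolve into the ungrouped class.
#' @return list of class \code{cluster_params}.
#' @export
cluster_params <- function(threshold_diff = 0.13, overshoot_thresh = 0.08,
                           min_members = 5) {
  if (threshold_diff <= 0 || overshoot_thresh <= 0 || min_members <= 0) {
    stop("all clustering parameters must be positive")
  }
  structure(list(threshold_diff = threshold_diff,
                 overshoot_thresh = overshoot_thresh,
                 min_members = as.integer(min_members)),
            class = "cluster_params")
}

#' Pairwise same-type decision between two normalised response curves
#'
#' For each sample the absolute difference is reduced by
#' \code{threshold_diff} (clipped at zero); the mean of these overshoots
#' across all samples (zeros included) is compared against
#' \code{overshoot_thresh}. This emphasises persistent low-amplitude shape
#' differences while tolerating brief high-amplitude transients.
#'
#' @param a,b normalised curves of equal length.
#' @param params a \code{cluster_params}.
#' @return list with \code{same} (logical) and \code{mean_overshoot}.
#' @export
pair_same_type <- function(a, b, params = cluster_params()) {
  if (length(a) != length(b)) stop("curves must have equal length")
  ov <- mean(pmax(0, abs(a - b) - params$threshold_diff))
  list(same = ov < params$overshoot_thresh, mean_overshoot = ov)
}

# Full pairwise mean-overshoot matrix for a set of normalised windows.
overshoot_matrix <- function(w, threshold_diff) {
  n <- nrow(w)
  o <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- abs(sweep(w, 2L, w[i, ]))
    o[i, ] <- rowMeans(pmax(d - threshold_diff, 0))
  }
  (o + t(o)) / 2   # symmetrise against floating-point asymmetry
}

#' Sort response windows of one (neuron, pattern) into response types
#'
#' The central fitting routine. All pairwise same-type relations are
#' evaluated first; then types are extracted greedily: every remaining
#' window is a candidate leader whose group is itself plus its direct
#' same-type partners among the remaining windows, the largest candidate
#' group (ties broken towards the lowest repetition index) is removed as
#' the next type, and the procedure repeats until no windows remain.
#' Finally every type with fewer than \code{min_members} members dissolves
#' into the ungrouped class. Degenerate (flat) windows never cluster and
#' are ungrouped from the start.
#'
#' @param windows matrix of normalised response curves (rows = repetitions)
#'   or the list returned by \code{\link{normalize_windows}}.
#' @param params a \code{cluster_params}.
#' @param degenerate optional logical vector flagging degenerate windows.
#' @return object of class \code{response_typeset}: \code{assignment}
#'   (integer per repetition; 1, 2, ... in order of extraction with 1 the
#'   largest type, 0 = ungrouped), \code{n_types}, \code{sizes},
#'   \code{means} (type mean curves), \code{params},
#'   \code{prop_ungrouped}.
#' @export
response_types <- function(windows, params = cluster_params(),
                           degenerate = NULL) {
  if (is.list(windows) && !is.null(windows$normalized)) {
    degenerate <- windows$degenerate
    windows <- windows$normalized
  }
  if (is.null(dim(windows))) windows <- matrix(windows, nrow = 1L)
  n <- nrow(windows)
  if (n < 1L) stop("at least one window required")
  if (is.null(degenerate)) degenerate <- rep(FALSE, n)

  assignment <- integer(n)   # 0 = ungrouped
  active <- which(!degenerate)
  if (length(active) > 0L) {
    ov <- overshoot_matrix(windows[active, , drop = FALSE],
                           params$threshold_diff)
    same <- ov < params$overshoot_thresh
    diag(same) <- TRUE
    remaining <- seq_along(active)
    tid <- 0L
    while (length(remaining) > 0L) {
      sizes <- rowSums(same[remaining, remaining, drop = FALSE])
      leader <- remaining[which.max(sizes)]   # first max = lowest index
      grp <- remaining[same[leader, remaining]]
      tid <- tid + 1L
      assignment[active[grp]] <- tid
      remaining <- setdiff(remaining, grp)
    }
  }
  # dissolve undersized types, then renumber survivors by extraction order
  tab <- table(assignment[assignment > 0L])
  small <- as.integer(names(tab)[tab < params$min_members])
  assignment[assignment %in% small] <- 0L
  kept <- sort(unique(assignment[assignment > 0L]))
  assignment <- match(assignment, kept, nomatch = 0L)
  assignment[is.na(assignment)] <- 0L

  k <- length(kept)
  means <- if (k > 0L) {
    t(vapply(seq_len(k), function(t_) {
      colMeans(windows[assignment == t_, , drop = FALSE])
    }, numeric(ncol(windows))))
  } else {
    matrix(numeric(0), 0L, ncol(windows))
  }
  structure(list(assignment = assignment, n_types = k,
                 sizes = as.integer(table(factor(assignment,
                                                 levels = seq_len(k)))),
                 means = means, params = params,
                 prop_ungrouped = mean(assignment == 0L),
                 n_windows = n, degenerate = degenerate),
            class = "response_typeset")
}

#' @export
print.response_typeset <- function(x, ...) {
  cat(sprintf("Response typeset: %d type(s) over %d window(s), %.0f%% ungrouped\n",
              x$n_types, x$n_windows, 100 * x$prop_ungrouped))
  if (x$n_types > 0) {
    cat("  type sizes:", paste(x$sizes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.response_typeset <- function(object, ...) {
  out <- list(
    n_types = object$n_types,
    sizes = object$sizes,
    n_windows = object$n_windows,
    prop_ungrouped = object$prop_ungrouped,
    params = object$params
  )
  class(out) <- "summary.response_typeset"
  out
}

#' @export
print.summary.response_typeset <- function(x, ...) {
  cat("Response-type clustering\n")
  cat(sprintf("  windows: %d; threshold %.2f, overshoot %.2f, min members %d\n",
              x$n_windows, x$params$threshold_diff, x$params$overshoot_thresh,
              x$params$min_members))
  cat(sprintf("  types found: %d (sizes %s)\n", x$n_types,
              paste(x$sizes, collapse = ", ")))
  cat(sprintf("  ungrouped: %.1f%%\n", 100 * x$prop_ungrouped))
  invisible(x)
}

#' Plot type mean curves of a response typeset
#'
#' @param x a \code{response_typeset}.
#' @param ... passed to \code{matplot}.
#' @export
plot.response_typeset <- function(x, ...) {
  if (x$n_types == 0) {
    graphics::plot.new()
    graphics::title("No response types identified")
    return(invisible(x))
  }
  graphics::matplot(t(x$means), type = "l", lty = 1,
                    xlab = "time (ms)", ylab = "normalized Vm",
                    main = sprintf("%d response type(s)", x$n_types), ...)
  invisible(x)
}

#' Assign new normalised windows to fitted response types
#'
#' Each new window is compared against every type mean with the same-type
#' rule used in fitting; it is assigned to the type with the smallest mean
#' overshoot among the matches, or to the ungrouped class (0) when no type
#' mean matches.
#'
#' @param object a \code{response_typeset}.
#' @param newdata matrix of normalised windows.
#' @param ... unused.
#' @return integer vector of type assignments (0 = ungrouped).
#' @export
predict.response_typeset <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (object$n_types == 0L) return(rep(0L, nrow(newdata)))
  thr <- object$params$threshold_diff
  vapply(seq_len(nrow(newdata)), function(i) {
    ov <- vapply(seq_len(object$n_types), function(t_) {
      mean(pmax(0, abs(newdata[i, ] - object$means[t_, ]) - thr))
    }, numeric(1))
    if (min(ov) < object$params$overshoot_thresh) which.min(ov) else 0L
  }, integer(1))
}
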