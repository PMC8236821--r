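#' Agreement between two clusterings of the same responses
#'
#' Directional agreement used for neighbouring parameter-grid cells: for
#' every cluster of the center clustering, the proportion of its members
#' contained in the single best-matching cluster of the neighbour is
#' computed; the comparison value is the mean of these proportions over the
#' center's clusters (\code{mean}), and \code{best} is the largest
#' per-cluster proportion. Ungrouped responses are excluded on both sides.
#'
#' @param center,neighbor lists of integer member-index vectors (one per
#'   cluster), or \code{response_typeset} objects.
#' @return list with \code{mean} and \code{best}; \code{NULL} if either side
#'   has no clusters.
#' @export
agreement_pair <- function(center, neighbor) {
  to_clusters <- function(x) {
    if (inherits(x, "response_typeset")) {
      lapply(seq_len(x$n_types), function(t_) which(x$assignment == t_))
    } else {
      x
    }
  }
  center <- to_clusters(center)
  neighbor <- to_clusters(neighbor)
  if (length(center) == 0L || length(neighbor) == 0L) return(NULL)
  per <- vapply(center, function(k) {
    max(vapply(neighbor, function(d) length(intersect(k, d)) / length(k),
               numeric(1)))
  }, numeric(1))
  list(mean = mean(per), best = max(per))
}

#' Explore clustering outcomes across the parameter grid
#'
#' Re-runs the response-type clustering for every combination of threshold
#' and overshoot values and summarises each cell: number of types,
#' proportion ungrouped, proportion grouped (types relative to the grid
#' maximum) and the mean/max cluster-agreement with the up-to-eight
#' neighbouring cells.
#'
#' @param windows matrix of normalised windows (or
#'   \code{\link{normalize_windows}} output).
#' @param threshold_values,overshoot_values grid axes.
#' @param min_members passed to the clustering.
#' @param degenerate optional degeneracy flags.
#' @return object of class \code{sensitivity_grid} with matrices
#'   \code{n_types}, \code{prop_ungrouped}, \code{prop_grouped},
#'   \code{mean_agreement}, \code{max_agreement} (rows = threshold values,
#'   columns = overshoot values) and the per-cell \code{typesets}.
#' @export
sensitivity_grid <- function(windows, threshold_values, overshoot_values,
                             min_members = 5, degenerate = NULL) {
  if (length(threshold_values) == 0L || length(overshoot_values) == 0L) {
    stop("grid axes must be nonempty")
  }
  if (is.list(windows) && !is.null(windows$normalized)) {
    degenerate <- windows$degenerate
    windows <- windows$normalized
  }
  nt <- length(threshold_values)
  no <- length(overshoot_values)
  typesets <- vector("list", nt * no)
  dim(typesets) <- c(nt, no)
  n_types <- prop_ung <- matrix(NA_real_, nt, no)
  for (i in seq_len(nt)) for (j in seq_len(no)) {
    ts <- response_types(windows,
                         cluster_params(threshold_values[i],
                                        overshoot_values[j], min_members),
                         degenerate = degenerate)
    typesets[[i, j]] <- ts
    n_types[i, j] <- ts$n_types
    prop_ung[i, j] <- ts$prop_ungrouped
  }
  agr <- cluster_agreement(typesets)
  structure(list(threshold_values = threshold_values,
                 overshoot_values = overshoot_values,
                 n_types = n_types, prop_ungrouped = prop_ung,
                 prop_grouped = n_types / max(n_types, 1),
                 mean_agreement = agr$mean_agreement,
                 max_agreement = agr$max_agreement,
                 typesets = typesets),
            class = "sensitivity_grid")
}

#' Cluster agreement across a grid of clusterings
#'
#' For every cell the clustering is compared against each of its up to
#' eight neighbouring cells (fewer at edges and corners) with
#' \code{\link{agreement_pair}}. \code{mean_agreement} averages the
#' comparison means over the available neighbours; \code{max_agreement}
#' averages the per-comparison best values. Comparisons against cells with
#' no clusters are skipped; a cell with no valid comparison gets NA.
#'
#' @param typesets a list-matrix of \code{response_typeset} objects (as
#'   stored in a \code{sensitivity_grid}).
#' @return list with matrices \code{mean_agreement} and
#'   \code{max_agreement}.
#' @export
cluster_agreement <- function(typesets) {
  d <- dim(typesets)
  if (is.null(d) || any(d < 1L)) stop("typesets must be a list-matrix")
  nt <- d[1]; no <- d[2]
  mean_a <- max_a <- matrix(NA_real_, nt, no)
  for (i in seq_len(nt)) for (j in seq_len(no)) {
    ms <- bs <- numeric(0)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      ii <- i + di; jj <- j + dj
      if (ii < 1L || ii > nt || jj < 1L || jj > no) next
      cmp <- agreement_pair(typesets[[i, j]], typesets[[ii, jj]])
      if (is.null(cmp)) next
      ms <- c(ms, cmp$mean)
      bs <- c(bs, cmp$best)
    }
    if (length(ms) > 0L) {
      mean_a[i, j] <- mean(ms)
      max_a[i, j] <- mean(bs)
    }
  }
  list(mean_agreement = mean_a, max_agreement = max_a)
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat(sprintf("Sensitivity grid: %d threshold x %d overshoot cells\n",
              length(x$threshold_values), length(x$overshoot_values)))
  cat(sprintf("  types found: %d-%d; ungrouped %.0f%%-%.0f%%\n",
              min(x$n_types), max(x$n_types),
              100 * min(x$prop_ungrouped), 100 * max(x$prop_ungrouped)))
  invisible(x)
}

#' @export
plot.sensitivity_grid <- function(x, what = c("prop_ungrouped",
                                              "prop_grouped",
                                              "mean_agreement",
                                              "max_agreement",
                                              "n_types"), ...) {
  what <- match.arg(what)
  z <- x[[what]]
  graphics::image(x$threshold_values, x$overshoot_values, z,
                  xlab = "threshold difference", ylab = "overshoot threshold",
                  main = what, ...)
  invisible(x)
}
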