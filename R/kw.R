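# ---- vectorised per-timepoint Kruskal-Wallis machinery ---------------------
# Ranks and tie corrections depend only on the data, not on the group
# labels, so they are computed once per window matrix and reused across
# types and label shuffles.

kw_engine <- function(x) {
  n <- nrow(x)
  r <- apply(x, 2L, rank)
  tie <- apply(x, 2L, function(col) {
    t <- table(col)
    sum(t^3 - t)
  })
  corr <- 1 - tie / (n^3 - n)
  list(r = r, corr = corr, n = n)
}

# Two-group KW (equivalent to a tie-corrected rank-sum chi-square test)
# for one member set against the rest, across all columns at once.
kw_two_group <- function(eng, members) {
  n1 <- sum(members)
  n2 <- eng$n - n1
  if (n1 < 2L || n2 < 2L) return(NULL)
  s1 <- colSums(eng$r[members, , drop = FALSE])
  s2 <- eng$n * (eng$n + 1) / 2 - s1
  h <- 12 / (eng$n * (eng$n + 1)) * (s1^2 / n1 + s2^2 / n2) - 3 * (eng$n + 1)
  h <- ifelse(eng$corr > 0, h / eng$corr, 0)
  h <- pmax(h, 0)
  p <- stats::pchisq(h, df = 1L, lower.tail = FALSE)
  p[eng$corr <= 0] <- 1       # all observations tied at this sample
  list(p = p, h = h)
}

# Omnibus KW across all classes of `g`, per column.
kw_omnibus <- function(eng, g) {
  g <- factor(g)
  if (nlevels(g) < 2L) return(NULL)
  gm <- t(stats::model.matrix(~ g - 1))   # classes x n indicator
  ns <- as.numeric(table(g))
  s <- gm %*% eng$r                        # class rank sums per column
  h <- 12 / (eng$n * (eng$n + 1)) * colSums(s^2 / ns) - 3 * (eng$n + 1)
  h <- ifelse(eng$corr > 0, h / eng$corr, 0)
  h <- pmax(h, 0)
  p <- stats::pchisq(h, df = nlevels(g) - 1L, lower.tail = FALSE)
  p[eng$corr <= 0] <- 1
  list(p = p, h = h)
}

#' Per-timepoint Kruskal-Wallis specificity of each response type
#'
#' For each response type and each 1-ms sample of the (typically 1200-ms)
#' normalised windows, tests whether the amplitude distribution of the
#' type's members differs from that of all other responses to the same
#' stimulation pattern in the same neuron (ungrouped responses count among
#' the others). The per-type test is the two-group Kruskal-Wallis
#' (tie-corrected); the omnibus statistic across all classes is also
#' returned.
#'
#' @param windows matrix of normalised windows (rows = repetitions, columns
#'   = 1-ms samples), or \code{\link{normalize_windows}} output.
#' @param typeset a \code{response_typeset}, or an integer assignment
#'   vector (0 = ungrouped).
#' @param alpha significance level recorded with the result.
#' @return object of class \code{kw_timecourse}: \code{p} and \code{h}
#'   (type x sample matrices; types with fewer than 2 members are skipped),
#'   \code{type_ids}, \code{omnibus_p}, \code{omnibus_h}, \code{alpha},
#'   \code{time_ms}.
#' @export
type_specificity_timecourse <- function(windows, typeset, alpha = 0.05) {
  if (is.list(windows) && !is.null(windows$normalized)) {
    windows <- windows$normalized
  }
  assignment <- if (inherits(typeset, "response_typeset")) {
    typeset$assignment
  } else {
    as.integer(typeset)
  }
  stopifnot(nrow(windows) == length(assignment))
  eng <- kw_engine(windows)
  types <- sort(unique(assignment[assignment > 0L]))
  res_p <- list(); res_h <- list(); kept <- integer(0)
  for (t_ in types) {
    two <- kw_two_group(eng, assignment == t_)
    if (is.null(two)) next
    kept <- c(kept, t_)
    res_p[[length(res_p) + 1L]] <- two$p
    res_h[[length(res_h) + 1L]] <- two$h
  }
  omni <- kw_omnibus(eng, assignment)
  structure(list(
    p = if (length(res_p)) do.call(rbind, res_p) else matrix(numeric(0), 0L, ncol(windows)),
    h = if (length(res_h)) do.call(rbind, res_h) else matrix(numeric(0), 0L, ncol(windows)),
    type_ids = kept,
    omnibus_p = if (is.null(omni)) rep(NA_real_, ncol(windows)) else omni$p,
    omnibus_h = if (is.null(omni)) rep(NA_real_, ncol(windows)) else omni$h,
    alpha = alpha, time_ms = seq_len(ncol(windows)) - 1L),
    class = "kw_timecourse")
}

#' @export
print.kw_timecourse <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis time course: %d type(s) x %d sample(s)\n",
              nrow(x$p), ncol(x$p)))
  if (nrow(x$p) > 0) {
    cat(sprintf("  fraction significant at alpha %.2f (time-averaged): %.3f\n",
                x$alpha, mean(x$p < x$alpha)))
  }
  invisible(x)
}

#' Fraction of response types significant per timepoint
#'
#' @param timecourses a \code{kw_timecourse} or a list of them (one per
#'   (neuron, pattern) cell).
#' @param alpha significance level.
#' @return numeric vector over samples: the fraction of all response types
#'   with p below \code{alpha}; attribute \code{n_types} carries the count.
#' @export
significant_fraction <- function(timecourses, alpha = 0.05) {
  if (inherits(timecourses, "kw_timecourse")) timecourses <- list(timecourses)
  ps <- do.call(rbind, lapply(timecourses, `[[`, "p"))
  if (is.null(ps) || nrow(ps) == 0L) stop("no defined response types")
  out <- colMeans(ps < alpha)
  attr(out, "n_types") <- nrow(ps)
  out
}

#' Label-shuffle null for the significant-fraction curve
#'
#' Response-type labels are permuted within each (neuron, pattern) cell,
#' the per-type Kruskal-Wallis time courses and the significant fraction
#' are recomputed, and the curve is averaged over shuffles. Under the null
#' the time-averaged fraction sits at the significance level, which is the
#' control the per-timepoint analysis relies on in place of a
#' multiple-comparisons correction.
#'
#' @param cells list of cells, each a list with \code{windows} (normalised
#'   matrix) and \code{assignment} (integer labels, 0 = ungrouped), e.g.
#'   built from clustering output.
#' @param n_shuffles number of label permutations (default 50).
#' @param alpha significance level.
#' @param seed integer seed for the permutations.
#' @return list of class \code{kw_shuffle_null}: \code{fraction} (averaged
#'   null curve), \code{time_avg} (its time average), \code{per_shuffle}
#'   (time-averaged fraction per shuffle), \code{n_shuffles}, \code{alpha}.
#' @export
shuffle_control <- function(cells, n_shuffles = 50, alpha = 0.05, seed = 1) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  set.seed(seed)
  engines <- lapply(cells, function(cl) kw_engine(cl$windows))
  tcols <- ncol(cells[[1]]$windows)
  acc <- matrix(0, n_shuffles, tcols)
  per_mean <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    ps <- list()
    for (ci in seq_along(cells)) {
      a <- sample(cells[[ci]]$assignment)
      eng <- engines[[ci]]
      for (t_ in sort(unique(a[a > 0L]))) {
        two <- kw_two_group(eng, a == t_)
        if (!is.null(two)) ps[[length(ps) + 1L]] <- two$p
      }
    }
    if (length(ps) == 0L) {
      acc[s, ] <- NA_real_
      per_mean[s] <- NA_real_
      next
    }
    pm <- do.call(rbind, ps)
    acc[s, ] <- colMeans(pm < alpha)
    per_mean[s] <- mean(acc[s, ])
  }
  structure(list(fraction = colMeans(acc, na.rm = TRUE),
                 time_avg = mean(acc, na.rm = TRUE),
                 per_shuffle = per_mean, n_shuffles = n_shuffles,
                 alpha = alpha),
            class = "kw_shuffle_null")
}

#' @export
print.kw_shuffle_null <- function(x, ...) {
  cat(sprintf("Shuffle null over %d permutation(s): time-averaged significant fraction %.3f (alpha %.2f)\n",
              x$n_shuffles, x$time_avg, x$alpha))
  invisible(x)
}
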