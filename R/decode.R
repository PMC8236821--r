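#' Analytic chance level of a uniform classifier
#'
#' @param n_classes number of classes (>= 1).
#' @return 1 / n_classes.
#' @export
chance_level <- function(n_classes) {
  if (n_classes < 1) stop("n_classes must be >= 1")
  1 / n_classes
}

#' Fit a principal-component basis on response-type mean curves
#'
#' The basis is computed from the type mean curves only (centred on their
#' mean), and the number of components is the smallest one explaining at
#' least \code{var_frac} of the total variance of the mean signals.
#' Individual responses are then projected onto this low-dimensional basis
#' for decoding.
#'
#' @param mean_curves matrix (one row per type mean curve).
#' @param var_frac explained-variance requirement (default 0.95).
#' @return object of class \code{pc_basis}: \code{center}, \code{rotation}
#'   (curve length x n_components), \code{n_components},
#'   \code{var_explained} (cumulative fractions per component).
#' @export
fit_pc_basis <- function(mean_curves, var_frac = 0.95) {
  if (nrow(mean_curves) < 2L) stop("at least two mean curves required")
  center <- colMeans(mean_curves)
  xc <- sweep(mean_curves, 2L, center)
  sv <- svd(xc)
  ev <- sv$d^2
  ev <- ev[ev > max(ev) * 1e-12]
  cum <- cumsum(ev) / sum(ev)
  nc <- which(cum >= var_frac)[1]
  structure(list(center = center,
                 rotation = sv$v[, seq_len(nc), drop = FALSE],
                 n_components = nc, var_explained = cum,
                 var_frac = var_frac),
            class = "pc_basis")
}

#' @export
print.pc_basis <- function(x, ...) {
  cat(sprintf("PC basis: %d component(s) explaining %.1f%% of mean-curve variance\n",
              x$n_components, 100 * x$var_explained[x$n_components]))
  invisible(x)
}

#' Project responses onto a fitted principal-component basis
#'
#' @param windows matrix of responses (rows), same length as the basis.
#' @param basis a \code{pc_basis}.
#' @return coordinate matrix (n x n_components).
#' @export
project_responses <- function(windows, basis) {
  if (is.null(dim(windows))) windows <- matrix(windows, nrow = 1L)
  if (ncol(windows) != length(basis$center)) {
    stop("window length does not match basis input length")
  }
  sweep(windows, 2L, basis$center) %*% basis$rotation
}

#' k-nearest-neighbour decoding with repeated random half splits
#'
#' Per iteration half of the responses are drawn as the training set; each
#' test response is classified by the relative majority among its k nearest
#' training responses (Euclidean distance in PC space), with class ties
#' resolved by the class of the single nearest neighbour. Splits leaving a
#' class absent from either half are redrawn (and counted). Confusion
#' counts are accumulated over iterations; the confusion matrix is
#' row-normalised over true classes, the mean accuracy is the diagonal
#' mean, and per-class F1 scores are computed from the summed counts.
#'
#' @param coords coordinate matrix (responses x dimensions).
#' @param labels class labels (coerced to factor).
#' @param k neighbours (default 4).
#' @param n_iter iterations (default 40).
#' @param split training fraction (default 0.5).
#' @param seed integer seed.
#' @return object of class \code{decoding_result}: \code{confusion}
#'   (row-normalised), \code{counts}, \code{accuracy}, \code{f1}
#'   (per class), \code{chance}, \code{k}, \code{n_iterations},
#'   \code{n_resampled}.
#' @export
knn_decode <- function(coords, labels, k = 4, n_iter = 40, split = 0.5,
                       seed = 1) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1L)
  labels <- factor(labels)
  n <- nrow(coords)
  stopifnot(length(labels) == n, k >= 1)
  if (any(table(labels) < 2L)) {
    stop("every class needs at least 2 members")
  }
  set.seed(seed)
  ncl <- nlevels(labels)
  counts <- matrix(0, ncl, ncl, dimnames = list(levels(labels), levels(labels)))
  n_res <- 0L
  n_train <- floor(n * split)
  for (it in seq_len(n_iter)) {
    for (try_ in seq_len(100L)) {
      tr <- sample.int(n, n_train)
      if (nlevels(droplevels(labels[tr])) == ncl &&
          nlevels(droplevels(labels[-tr])) == ncl) break
      n_res <- n_res + 1L
      if (try_ == 100L) stop("could not draw a split containing every class")
    }
    te <- setdiff(seq_len(n), tr)
    pred <- knn_predict(coords[tr, , drop = FALSE], labels[tr],
                        coords[te, , drop = FALSE], k)
    tab <- table(factor(labels[te], levels = levels(labels)),
                 factor(pred, levels = levels(labels)))
    counts <- counts + tab
  }
  confusion <- counts / rowSums(counts)
  tp <- diag(counts)
  prec <- ifelse(colSums(counts) > 0, tp / colSums(counts), 0)
  rec <- tp / rowSums(counts)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(confusion = confusion, counts = counts,
                 accuracy = mean(diag(confusion)), f1 = f1,
                 chance = chance_level(ncl), k = k, n_iterations = n_iter,
                 n_resampled = n_res, labels = levels(labels)),
            class = "decoding_result")
}

# Majority-vote kNN with nearest-neighbour tie break.
knn_predict <- function(train, train_labels, test, k) {
  k <- min(k, nrow(train))
  lv <- levels(train_labels)
  out <- character(nrow(test))
  tt <- rowSums(train^2)
  for (i in seq_len(nrow(test))) {
    d2 <- tt - 2 * as.numeric(train %*% test[i, ])
    nb <- order(d2)[seq_len(k)]
    votes <- table(train_labels[nb])
    top <- names(votes)[votes == max(votes)]
    out[i] <- if (length(top) == 1L) top else {
      # tie among classes: fall back to the single nearest neighbour
      as.character(train_labels[nb[1L]])
    }
  }
  factor(out, levels = lv)
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("kNN decoding (k=%d, %d iteration(s)): accuracy %.1f%% over %d classes (chance %.1f%%)\n",
              x$k, x$n_iterations, 100 * x$accuracy, nrow(x$confusion),
              100 * x$chance))
  invisible(x)
}

#' @export
plot.decoding_result <- function(x, ...) {
  ncl <- nrow(x$confusion)
  graphics::image(seq_len(ncl), seq_len(ncl),
                  t(x$confusion[rev(seq_len(ncl)), , drop = FALSE]),
                  xlab = "decoded class", ylab = "true class", axes = FALSE,
                  main = sprintf("Confusion matrix (accuracy %.1f%%)",
                                 100 * x$accuracy), ...)
  graphics::axis(1, at = seq_len(ncl), labels = x$labels, las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(ncl), labels = rev(x$labels), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Assemble a decoding task at one of the three scopes
#'
#' \describe{
#'   \item{within_pattern}{classes are the response types of one
#'     (neuron, pattern) cell plus the ungrouped class; k = 4.}
#'   \item{cross_pattern}{classes are all response types across the
#'     patterns of one neuron (ungrouped excluded); k = 9.}
#'   \item{cross_neuron}{classes are all response types across neurons for
#'     one pattern (ungrouped excluded); k = 9.}
#' }
#'
#' @param cells list of clustered cells; each needs \code{windows}
#'   (normalised 350-ms matrix), \code{typeset} (a
#'   \code{response_typeset}), and identifiers \code{neuron},
#'   \code{label}.
#' @param scope one of \code{"within_pattern"}, \code{"cross_pattern"},
#'   \code{"cross_neuron"}.
#' @return list with \code{windows}, \code{labels} (factor), \code{k},
#'   and \code{mean_curves} (one row per class, for the PC basis).
#' @export
assemble_decoding_task <- function(cells,
                                   scope = c("within_pattern",
                                             "cross_pattern",
                                             "cross_neuron")) {
  scope <- match.arg(scope)
  if (length(cells) == 0L) stop("no cells supplied")
  if (scope == "within_pattern") {
    if (length(cells) != 1L) stop("within_pattern scope expects one cell")
    cl <- cells[[1]]
    lab <- ifelse(cl$typeset$assignment == 0L, "ungrouped",
                  paste0("type", cl$typeset$assignment))
    windows <- cl$windows
    labels <- factor(lab)
    k <- 4L
  } else {
    win <- list(); lab <- character(0)
    for (cl in cells) {
      keep <- cl$typeset$assignment > 0L
      if (!any(keep)) next
      win[[length(win) + 1L]] <- cl$windows[keep, , drop = FALSE]
      lab <- c(lab, paste0(if (scope == "cross_pattern") cl$label
                           else paste0("n", cl$neuron),
                           ".T", cl$typeset$assignment[keep]))
    }
    windows <- do.call(rbind, win)
    labels <- factor(lab)
    k <- 9L
  }
  if (nlevels(labels) < 2L) stop("scope yields fewer than 2 classes")
  mean_curves <- t(vapply(levels(labels), function(l) {
    colMeans(windows[labels == l, , drop = FALSE])
  }, numeric(ncol(windows))))
  list(windows = windows, labels = labels, k = k, mean_curves = mean_curves,
       scope = scope)
}

#' Run PCA + kNN decoding for an assembled task
#'
#' Convenience wrapper: fits the PC basis on the class mean curves,
#' projects all responses, and runs the repeated-half-split kNN decoder.
#'
#' @param task output of \code{\link{assemble_decoding_task}}.
#' @param var_frac explained-variance requirement for the basis.
#' @param n_iter,seed passed to \code{\link{knn_decode}}.
#' @return a \code{decoding_result} with the fitted \code{basis} attached.
#' @export
decode_task <- function(task, var_frac = 0.95, n_iter = 40, seed = 1) {
  basis <- fit_pc_basis(task$mean_curves, var_frac)
  coords <- project_responses(task$windows, basis)
  res <- knn_decode(coords, task$labels, k = task$k, n_iter = n_iter,
                    seed = seed)
  res$basis <- basis
  res$scope <- task$scope
  res
}
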