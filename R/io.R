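#' Save a simulated session to a directory
#'
#' Writes the event table and ground truth as TSV files (\code{events.tsv},
#' \code{truth_types.tsv}, \code{truth_states.tsv}, \code{truth_epsp.tsv})
#' and the raw traces plus metadata as RDS (\code{traces.rds}), so a
#' session can be regenerated once and re-analysed from disk.
#'
#' @param session list with \code{recording} and \code{truth} as returned
#'   by \code{\link{simulate_session}}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(session$recording$events, "events.tsv")
  w(session$truth$types, "truth_types.tsv")
  w(session$truth$states, "truth_states.tsv")
  w(session$truth$epsp, "truth_epsp.tsv")
  saveRDS(session$recording, file.path(dir, "traces.rds"))
  invisible(dir)
}

#' Load a session saved by \code{write_session}
#'
#' @param dir session directory.
#' @return list with \code{recording} and partial \code{truth} (the tables;
#'   templates are not persisted).
#' @export
read_session <- function(dir) {
  r <- function(f) utils::read.delim(file.path(dir, f))
  list(recording = readRDS(file.path(dir, "traces.rds")),
       truth = structure(list(types = r("truth_types.tsv"),
                              states = r("truth_states.tsv"),
                              epsp = r("truth_epsp.tsv")),
                         class = "session_truth"))
}

#' Write normalised response windows as a long TSV table
#'
#' One row per (repetition, sample): columns \code{neuron}, \code{label},
#' \code{repetition}, \code{sample_ms}, \code{value}.
#'
#' @param windows matrix of normalised windows (rows = repetitions).
#' @param file output path.
#' @param neuron,label identifiers written with every row.
#' @param repetitions optional repetition indices (default row numbers).
#' @return \code{file}, invisibly.
#' @export
write_windows_tsv <- function(windows, file, neuron = 1L, label = "",
                              repetitions = seq_len(nrow(windows))) {
  long <- data.frame(
    neuron = neuron, label = label,
    repetition = rep(repetitions, each = ncol(windows)),
    sample_ms = rep(seq_len(ncol(windows)) - 1L, nrow(windows)),
    value = as.vector(t(windows)))
  utils::write.table(long, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a long window table written by \code{write_windows_tsv}
#'
#' @param file path to the TSV.
#' @return list with \code{windows} (matrix) and \code{info} (data frame of
#'   neuron/label/repetition per row).
#' @export
read_windows_tsv <- function(file) {
  long <- utils::read.delim(file)
  key <- interaction(long$neuron, long$label, long$repetition,
                     drop = TRUE, lex.order = TRUE)
  parts <- split(long, key)
  windows <- t(vapply(parts, function(p) p$value[order(p$sample_ms)],
                      numeric(max(long$sample_ms) + 1L)))
  info <- do.call(rbind, lapply(parts, function(p)
    p[1L, c("neuron", "label", "repetition")]))
  rownames(windows) <- rownames(info) <- NULL
  list(windows = windows, info = info)
}
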