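#' Construct an EEG recording
#'
#' The raw input of the connectivity stage: a channels x samples matrix
#' (microvolts) with a sampling rate and 10-20 sensor labels.
#'
#' @param data Numeric channels x samples matrix.
#' @param rate Sampling rate in Hz (> 0).
#' @param labels Character vector of unique channel labels (one per row).
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, rate, labels = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) param_error("data must be numeric")
  if (!all(is.finite(data))) param_error("data contains non-finite samples")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    param_error("rate must be a single positive number")
  if (is.null(labels))
    labels <- paste0("ch", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (length(labels) != nrow(data))
    param_error("need one label per channel (%d labels, %d channels)",
                length(labels), nrow(data))
  if (anyDuplicated(labels)) param_error("channel labels must be unique")
  rownames(data) <- labels
  structure(list(data = data, rate = rate, labels = labels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  cat("  channels:", paste(head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "..." else "", "\n")
  invisible(x)
}

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)
duration_seconds <- function(rec) ncol(rec$data) / rec$rate

#' Write an EEG recording as delimited text
#'
#' Tab-separated samples x channels table with a header row of channel
#' labels, preceded by a `# rate_hz: <rate>` comment line. This plain-text
#' interchange format replaces a binary EDF writer (no EDF library is
#' available in the target environment); headers carry the same metadata
#' an EDF header would.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eeg_text <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz: %.10g", rec$rate), con)
  writeLines(paste(rec$labels, collapse = "\t"), con)
  utils::write.table(t(rec$data), con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read an EEG recording from delimited text
#'
#' Counterpart of [write_eeg_text()]; `rate` may be given explicitly when
#' the file lacks the `# rate_hz:` header line.
#'
#' @param path Input file path.
#' @param rate Sampling rate override in Hz.
#' @return An `eeg_recording`.
#' @export
read_eeg_text <- function(path, rate = NULL) {
  if (!file.exists(path)) param_error("file not found: %s", path)
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (grepl("^#\\s*rate_hz:", first)) {
    hdr_rate <- as.numeric(sub("^#\\s*rate_hz:\\s*", "", first))
    if (is.null(rate)) rate <- hdr_rate
    skip <- 1L
  }
  if (is.null(rate))
    param_error("no rate in header of %s and none supplied", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = skip,
                           check.names = FALSE)
  eeg_recording(t(as.matrix(tab)), rate = rate, labels = colnames(tab))
}
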