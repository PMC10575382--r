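#' Fixed-length ECG beat dataset
#'
#' Bundles a matrix of fixed-length beat windows with integer class labels.
#' Rows are beats, columns are sample positions within the window; amplitudes
#' are dimensionless (raw ADC-derived or standardised). Labels are 0-based
#' class indices, as written by [write_beat_csv()].
#'
#' @param beats Numeric matrix, `n_beats x window_length`; all values finite.
#' @param labels Integer vector of length `n_beats`, values in `0..C-1`.
#' @return An object of class `beat_dataset`: a list with elements `beats`,
#'   `labels` and `window_length`.
#' @seealso [read_beat_csv()], [generate_dataset()], [stratified_split()]
#' @export
beat_dataset <- function(beats, labels) {
  beats <- as.matrix(beats)
  if (nrow(beats) == 0L || length(labels) == 0L) stop("empty input")
  if (!is.numeric(beats) || !all(is.finite(beats))) stop("non-finite sample")
  if (ncol(beats) < 8L) stop("window too short")
  if (nrow(beats) != length(labels)) stop("beats row count must equal labels length")
  if (any(!is.finite(labels)) || any(abs(labels - round(labels)) > 1e-9) ||
      any(labels < 0)) {
    stop("bad label")
  }
  dimnames(beats) <- NULL
  structure(
    list(beats = beats, labels = as.integer(round(labels)),
         window_length = ncol(beats)),
    class = "beat_dataset"
  )
}

#' @export
print.beat_dataset <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:max(x$labels)))
  cat(sprintf("<beat_dataset> %d beats x %d samples; classes: %s\n",
              nrow(x$beats), x$window_length,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

n_beats <- function(data) nrow(data$beats)

n_classes <- function(data) max(data$labels) + 1L

## Every class 0..C-1 must appear at least once for supervised operations.
check_supervised <- function(data) {
  C <- n_classes(data)
  present <- sort(unique(data$labels))
  if (!identical(present, 0:(C - 1L)))
    stop("degenerate labels")
  invisible(C)
}

#' Read a beat dataset from a header-less CSV file
#'
#' Expects one beat per row: `window_length` real sample columns followed by
#' one integer class-label column; no header. The inverse of
#' [write_beat_csv()]; a write/read round trip reproduces amplitudes to well
#' below 1e-9.
#'
#' @param path Path to an existing CSV file.
#' @return A [beat_dataset()].
#' @export
read_beat_csv <- function(path) {
  if (!file.exists(path)) stop("record not found")
  widths <- tryCatch(utils::count.fields(path, sep = ",", quote = ""),
                     error = function(e) stop("malformed beat file"))
  if (length(widths) == 0L) stop("empty input")
  if (length(unique(widths)) != 1L) stop("malformed beat file")
  if (widths[1L] < 2L) stop("malformed beat file")
  dt <- data.table::fread(path, header = FALSE, sep = ",", data.table = FALSE)
  m <- as.matrix(dt)
  if (!is.numeric(m)) stop("malformed beat file")
  lab <- m[, ncol(m)]
  if (any(abs(lab - round(lab)) > 1e-9)) stop("bad label")
  beat_dataset(m[, -ncol(m), drop = FALSE], as.integer(round(lab)))
}

#' Write a beat dataset to a header-less CSV file
#'
#' @param data A [beat_dataset()].
#' @param path Output path; overwritten if present.
#' @return `path`, invisibly.
#' @rdname read_beat_csv
#' @export
write_beat_csv <- function(data, path) {
  stopifnot(inherits(data, "beat_dataset"))
  out <- data.table::as.data.table(cbind(data$beats, data$labels))
  data.table::fwrite(out, path, col.names = FALSE, sep = ",")
  invisible(path)
}
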