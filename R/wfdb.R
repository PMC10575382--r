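# Minimal WFDB adapter: enough of the header (.hea), signal (.dat, formats
# 16 and 212) and MIT annotation (.atr) formats to pull annotated beat
# windows out of Holter-style records. Only single-segment records are
# handled; samples are returned in physical units via (adc - baseline)/gain.

## Standard MIT annotation code -> symbol table (beat and rhythm codes).
wfdb_code_symbols <- c(
  "1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V", "6" = "F",
  "7" = "J", "8" = "A", "9" = "S", "10" = "E", "11" = "j", "12" = "/",
  "13" = "Q", "14" = "~", "16" = "|", "18" = "s", "19" = "T", "20" = "*",
  "21" = "D", "22" = "\"", "23" = "=", "24" = "p", "25" = "B", "26" = "^",
  "27" = "t", "28" = "+", "29" = "u", "30" = "?", "31" = "!", "32" = "[",
  "33" = "]", "34" = "e", "35" = "n", "36" = "@", "37" = "x", "38" = "f",
  "39" = "(", "40" = ")", "41" = "r")

parse_hea_gain <- function(tok) {
  # token like "200", "200(0)/mV", "200/mV"
  gain <- as.numeric(sub("^([-0-9.eE+]+).*$", "\\1", tok))
  baseline <- 0
  if (grepl("\\(", tok))
    baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", tok))
  if (!is.finite(gain) || gain == 0) gain <- 200
  list(gain = gain, baseline = baseline)
}

#' Read a WFDB record (header + signal)
#'
#' Parses `<record>.hea` and the referenced `.dat` file. Signal formats 16
#' (16-bit little-endian) and 212 (packed 12-bit pairs) are supported;
#' samples are converted to physical units using each signal's gain and
#' baseline.
#'
#' @param record_path Record path without extension (e.g. `"dir/100"`).
#' @return List with `signal` (samples x channels numeric matrix), `fs`
#'   (sampling frequency, Hz), `n_samples` and `record_name`.
#' @export
read_wfdb_record <- function(record_path) {
  hea <- paste0(record_path, ".hea")
  if (!file.exists(hea)) stop("record not found")
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  head_tok <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  nsig <- as.integer(head_tok[2L])
  fs <- if (length(head_tok) >= 3L) as.numeric(head_tok[3L]) else 250
  nsamp <- if (length(head_tok) >= 4L) as.integer(head_tok[4L]) else NA_integer_
  sig_lines <- lines[2:(1L + nsig)]
  sig_tok <- lapply(sig_lines, function(l) strsplit(trimws(l), "\\s+")[[1L]])
  dat_file <- sig_tok[[1L]][1L]
  fmt <- as.integer(sub("^([0-9]+).*$", "\\1", sig_tok[[1L]][2L]))
  dat <- file.path(dirname(hea), dat_file)
  if (!file.exists(dat)) stop("record not found")
  raw_bytes <- readBin(dat, "raw", n = file.size(dat))
  if (fmt == 16L) {
    vals <- readBin(raw_bytes, "integer", n = length(raw_bytes) %/% 2L,
                    size = 2L, signed = TRUE, endian = "little")
    ns <- length(vals) %/% nsig
    adc <- matrix(vals[seq_len(ns * nsig)], ns, nsig, byrow = TRUE)
  } else if (fmt == 212L) {
    b <- as.integer(raw_bytes)
    ntrip <- length(b) %/% 3L
    i <- 3L * (seq_len(ntrip) - 1L)
    x1 <- b[i + 1L] + bitwAnd(b[i + 2L], 0x0FL) * 256L
    x2 <- b[i + 3L] + bitwAnd(bitwShiftR(b[i + 2L], 4L), 0x0FL) * 256L
    x1 <- ifelse(x1 > 2047L, x1 - 4096L, x1)
    x2 <- ifelse(x2 > 2047L, x2 - 4096L, x2)
    vals <- as.vector(rbind(x1, x2))
    ns <- length(vals) %/% nsig
    adc <- matrix(vals[seq_len(ns * nsig)], ns, nsig, byrow = TRUE)
  } else {
    stop(sprintf("unsupported WFDB signal format %d", fmt))
  }
  if (!is.na(nsamp) && nsamp <= nrow(adc)) adc <- adc[seq_len(nsamp), , drop = FALSE]
  phys <- adc
  for (s in seq_len(nsig)) {
    g <- parse_hea_gain(sig_tok[[s]][3L])
    phys[, s] <- (adc[, s] - g$baseline) / g$gain
  }
  list(signal = phys, fs = fs, n_samples = nrow(phys),
       record_name = basename(record_path))
}

#' Read a WFDB annotation file
#'
#' Decodes the MIT annotation format: 16-bit words carrying a 6-bit
#' annotation code and a 10-bit sample increment, with the SKIP, NUM,
#' SUBTYP, CHAN and AUX pseudo-codes handled (AUX payloads skipped).
#'
#' @param path Path to the annotation file (e.g. `"dir/100.atr"`).
#' @return Data frame with columns `sample` (0-based) and `symbol`.
#' @export
read_wfdb_annotation <- function(path) {
  if (!file.exists(path)) stop("record not found")
  b <- as.integer(readBin(path, "raw", n = file.size(path)))
  i <- 1L
  time <- 0
  samples <- numeric(0)
  symbols <- character(0)
  while (i + 1L <= length(b)) {
    lo <- b[i]; hi <- b[i + 1L]
    i <- i + 2L
    code <- bitwShiftR(hi, 2L)
    incr <- bitwAnd(hi, 3L) * 256L + lo
    if (code == 0L && incr == 0L) break  # EOF marker
    if (code == 59L) {            # SKIP: 4 extra bytes, high word first
      if (i + 3L > length(b)) break
      interval <- (b[i] + 256 * b[i + 1L]) * 65536 + (b[i + 2L] + 256 * b[i + 3L])
      i <- i + 4L
      time <- time + interval
    } else if (code %in% c(60L, 61L, 62L)) {
      # NUM / SUBTYP / CHAN: field modifiers, no time advance
    } else if (code == 63L) {     # AUX: incr = payload byte count
      skip <- incr + (incr %% 2L)
      i <- i + skip
    } else {
      time <- time + incr
      samples <- c(samples, time)
      sym <- wfdb_code_symbols[as.character(code)]
      symbols <- c(symbols, if (is.na(sym)) "?" else unname(sym))
    }
  }
  data.frame(sample = samples, symbol = symbols, stringsAsFactors = FALSE)
}

## Writers (format 16 signals, plain annotation stream). Used to build
## synthetic records for tests and examples; not part of the spec surface.
write_wfdb_record <- function(record_path, signal, fs = 360, gain = 200) {
  signal <- as.matrix(signal)
  nsig <- ncol(signal)
  rec <- basename(record_path)
  hea <- paste0(record_path, ".hea")
  dat <- paste0(record_path, ".dat")
  writeLines(c(
    sprintf("%s %d %g %d", rec, nsig, fs, nrow(signal)),
    sprintf("%s.dat 16 %g(0)/mV 16 0 0 0 0 ch%d", rec, gain, seq_len(nsig))
  ), hea)
  adc <- round(signal * gain)
  adc <- pmin(pmax(adc, -32768), 32767)
  writeBin(as.integer(t(adc)), dat, size = 2L, endian = "little")
  invisible(record_path)
}

write_wfdb_annotation <- function(path, samples, symbols) {
  ord <- order(samples)
  samples <- samples[ord]; symbols <- symbols[ord]
  sym_codes <- stats::setNames(as.integer(names(wfdb_code_symbols)),
                               wfdb_code_symbols)
  con <- file(path, "wb")
  on.exit(close(con))
  prev <- 0
  for (j in seq_along(samples)) {
    code <- sym_codes[[symbols[j]]]
    incr <- samples[j] - prev
    prev <- samples[j]
    if (incr > 1023) {
      # SKIP word then the 32-bit interval, high word first, words LE
      writeBin(as.integer(c(0L, bitwShiftL(59L, 2L))), con, size = 1L)
      hiw <- incr %/% 65536; low <- incr %% 65536
      writeBin(as.integer(c(hiw %% 256, hiw %/% 256,
                            low %% 256, low %/% 256)), con, size = 1L)
      incr <- 0
    }
    writeBin(as.integer(c(incr %% 256,
                          bitwShiftL(code, 2L) + incr %/% 256)), con,
             size = 1L)
  }
  writeBin(as.integer(c(0L, 0L)), con, size = 1L)  # EOF
  invisible(path)
}

#' Extract annotated beat windows from a signal
#'
#' Cuts one window of `window_length` samples centred on each annotated
#' beat: with `half = floor(window_length / 2)` the window covers 0-based
#' samples `c - half .. c - half + window_length - 1`. Annotations whose
#' symbol is absent from `label_map` are dropped, as are windows
#' overlapping the record boundaries.
#'
#' @param signal Numeric vector (single channel).
#' @param ann_samples 0-based annotation sample positions.
#' @param ann_symbols Annotation symbols, same length.
#' @param window_length Window length in samples. Default 180.
#' @param label_map Named integer vector mapping symbols to 0-based class
#'   labels, e.g. `c(N = 0, V = 1)`.
#' @return A [beat_dataset()].
#' @export
extract_beats <- function(signal, ann_samples, ann_symbols,
                          window_length = 180L, label_map) {
  if (window_length < 8L) stop("window too short")
  stopifnot(length(ann_samples) == length(ann_symbols))
  half <- window_length %/% 2L
  keep <- ann_symbols %in% names(label_map)
  starts <- ann_samples[keep] - half
  syms <- ann_symbols[keep]
  ok <- starts >= 0 & (starts + window_length - 1L) <= (length(signal) - 1L)
  starts <- starts[ok]; syms <- syms[ok]
  if (length(starts) == 0L) stop("no beats extracted")
  beats <- t(vapply(starts, function(s)
    signal[(s + 1L):(s + window_length)], numeric(window_length)))
  beat_dataset(beats, as.integer(label_map[syms]))
}

#' Extract beat windows from a WFDB record
#'
#' Reads the record and its annotation file and applies [extract_beats()]
#' to the first signal channel.
#'
#' @param record_path Record path without extension.
#' @param window_length Window length in samples. Default 180.
#' @param label_map Named integer vector mapping annotation symbols to
#'   0-based class labels; unmapped symbols are dropped.
#' @param annotator Annotation file extension. Default `"atr"`.
#' @param channel Signal channel to use (1-based). Default 1.
#' @return A [beat_dataset()].
#' @export
extract_beats_wfdb <- function(record_path, window_length = 180L, label_map,
                               annotator = "atr", channel = 1L) {
  rec <- read_wfdb_record(record_path)
  ann <- read_wfdb_annotation(paste0(record_path, ".", annotator))
  extract_beats(rec$signal[, channel], ann$sample, ann$symbol,
                window_length, label_map)
}
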