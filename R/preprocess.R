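#' Fit a per-position standard scaler
#'
#' Computes, for every sample position (column) across beats, the arithmetic
#' mean and the population standard deviation (divisor `n`, the usual
#' "standard scaler" convention), so that [apply_standard_scaler()] maps the
#' fitted data to mean 0 and variance 1 per column, z = (x - mu) / sd.
#' Columns whose spread falls below `1e-12` (constant channels) get their sd
#' replaced by 1, so degenerate columns pass through centred but unscaled
#' rather than dividing by zero.
#'
#' @param data A [beat_dataset()] with at least two beats.
#' @return An object of class `scaler_params`: list with numeric vectors
#'   `mean` and `sd`, each of length `window_length`.
#' @examples
#' d <- generate_dataset(beat_gen_params(n_beats = 20, window_length = 32, seed = 1))
#' sc <- fit_standard_scaler(d)
#' z <- apply_standard_scaler(d, sc)
#' max(abs(colMeans(z$beats)))  # ~ 0
#' @export
fit_standard_scaler <- function(data) {
  stopifnot(inherits(data, "beat_dataset"))
  x <- data$beats
  if (nrow(x) < 2L) stop("empty input")
  if (!all(is.finite(x))) stop("non-finite sample")
  mu <- colMeans(x)
  sd_pop <- sqrt(colMeans(sweep(x, 2L, mu)^2))  # population (divisor n)
  sd_pop[sd_pop < 1e-12] <- 1
  structure(list(mean = mu, sd = sd_pop), class = "scaler_params")
}

#' Apply a fitted standard scaler
#'
#' @param data A [beat_dataset()] whose window length matches `params`.
#' @param params A `scaler_params` object from [fit_standard_scaler()].
#' @return A [beat_dataset()] with standardised amplitudes; labels unchanged.
#' @rdname fit_standard_scaler
#' @export
apply_standard_scaler <- function(data, params) {
  stopifnot(inherits(data, "beat_dataset"), inherits(params, "scaler_params"))
  if (ncol(data$beats) != length(params$mean)) stop("scaler shape mismatch")
  z <- sweep(sweep(data$beats, 2L, params$mean, "-"), 2L, params$sd, "/")
  beat_dataset(z, data$labels)
}

## JSON persistence for scaler parameters (used by the CLI).
write_scaler_json <- function(params, path) {
  jsonlite::write_json(list(mean = params$mean, sd = params$sd), path,
                       digits = NA)
  invisible(path)
}

read_scaler_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = as.numeric(obj$mean), sd = as.numeric(obj$sd)),
            class = "scaler_params")
}

#' Stratified train/test split
#'
#' Splits a beat dataset into disjoint, exhaustive train and test subsets,
#' preserving class proportions: each class contributes
#' `round(train_fraction * class_count)` beats to the training set (rounding
#' half away from zero), the remainder to the test set. Membership is drawn
#' by a seeded permutation, so a fixed seed reproduces the identical
#' partition.
#'
#' @param data A [beat_dataset()]; every class needs at least 2 members.
#' @param train_fraction Fraction of each class assigned to training,
#'   strictly between 0 and 1.
#' @param seed Integer seed for the permutation.
#' @return A list of class `beat_split`: `train` and `test`
#'   ([beat_dataset()]s) plus the integer index vectors `train_idx`,
#'   `test_idx` into the original rows.
#' @export
stratified_split <- function(data, train_fraction, seed) {
  stopifnot(inherits(data, "beat_dataset"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0,1)")
  check_supervised(data)
  classes <- sort(unique(data$labels))
  counts <- table(data$labels)
  if (any(counts < 2L)) stop("class too small to stratify")
  set.seed(as.integer(seed))
  train_idx <- integer(0)
  for (cl in classes) {
    idx <- which(data$labels == cl)
    idx <- idx[sample.int(length(idx))]
    k <- round_half_away(train_fraction * length(idx))
    k <- max(1L, min(length(idx) - 1L, k))  # keep both sides non-empty
    train_idx <- c(train_idx, idx[seq_len(k)])
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n_beats(data)), train_idx)
  structure(
    list(train = beat_dataset(data$beats[train_idx, , drop = FALSE],
                              data$labels[train_idx]),
         test = beat_dataset(data$beats[test_idx, , drop = FALSE],
                             data$labels[test_idx]),
         train_idx = train_idx, test_idx = test_idx),
    class = "beat_split"
  )
}
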