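# Shared fixtures, built in code at test time.

## Standardised separable synthetic dataset.
make_sep_data <- function(n = 100L, L = 64L, separation = 2, noise = 0.05,
                          seed = 1L) {
  d <- generate_dataset(beat_gen_params(
    window_length = L, n_beats = n, noise_sd = noise,
    separation = separation, seed = seed))
  apply_standard_scaler(d, fit_standard_scaler(d))
}

## Independent brute-force evaluation of the four GRU update formulas,
## written as explicit per-unit scalar loops (plogis as the sigmoid) so it
## shares no code path with gru_step().
oracle_gru_step <- function(x, h, w) {
  H <- length(w$br)
  r <- z <- hb <- numeric(H)
  for (j in seq_len(H)) {
    r[j] <- stats::plogis(sum(x * w$Wxr[, j]) + sum(h * w$Whr[, j]) + w$br[j])
    z[j] <- stats::plogis(sum(x * w$Wxz[, j]) + sum(h * w$Whz[, j]) + w$bz[j])
  }
  for (j in seq_len(H)) {
    hb[j] <- tanh(sum(x * w$Wxh[, j]) + sum((r * h) * w$Whh[, j]) + w$bh[j])
  }
  z * h + (1 - z) * hb
}

## Deterministic nearest-centroid fitting hook for exercising the CV
## plumbing without neural-network training.
centroid_fit_fun <- function(train_data, hp, train_cfg, seed) {
  classes <- sort(unique(train_data$labels))
  centroids <- t(vapply(classes, function(cl)
    colMeans(train_data$beats[train_data$labels == cl, , drop = FALSE]),
    numeric(ncol(train_data$beats))))
  function(test_data) {
    d2 <- vapply(seq_len(nrow(centroids)), function(i)
      rowSums(sweep(test_data$beats, 2L, centroids[i, ])^2),
      numeric(nrow(test_data$beats)))
    classes[max.col(-d2, ties.method = "first")]
  }
}

## Tiny topology + compact search space used by the desk-scale tuning runs.
tiny_base_spec <- function(L = 64L) {
  model_spec(window_length = L, conv_layers = 1L, gru_layers = 1L,
             hidden_units = 8L)
}

tiny_space <- function() {
  hyper_space(
    learning_rate = hp_logreal(1e-3, 1e-1),
    dropout = hp_real(0, 0.5),
    gru_units = hp_int(4L, 16L),
    conv_filters = hp_int(4L, 8L))
}
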