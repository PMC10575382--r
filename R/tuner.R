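#' Hyperparameter search space
#'
#' A named collection of tunable settings, each declared as a log-scaled
#' real, linear real, integer or categorical entry. The optimiser searches
#' the continuous unit hypercube `[0,1]^D` (one gene per entry);
#' [decode_genome()] maps genes onto concrete values. The default space
#' covers learning rate (log-scaled 1e-4..1e-1), dropout (0..0.7), batch
#' size (4..64), convolution filters (8..64), GRU units (8..128) and kernel
#' size (3..9).
#'
#' @param ... Named entries created with [hp_real()], [hp_logreal()],
#'   [hp_int()] or [hp_cat()].
#' @return An object of class `hyper_space`.
#' @export
hyper_space <- function(...) {
  entries <- list(...)
  if (length(entries) == 0L) stop("empty hyperparameter space")
  if (is.null(names(entries)) || any(names(entries) == ""))
    stop("hyperparameter entries must be named")
  for (e in entries) {
    if (!inherits(e, "hp_entry")) stop("entries must be hp_* objects")
  }
  structure(entries, class = "hyper_space")
}

hp_entry <- function(kind, lower = NULL, upper = NULL, choices = NULL) {
  if (kind %in% c("real", "log-real", "integer")) {
    if (!is.numeric(lower) || !is.numeric(upper) || lower >= upper)
      stop("degenerate range")
    if (kind == "log-real" && lower <= 0) stop("log range must be positive")
  } else if (length(choices) < 2L) stop("degenerate range")
  structure(list(kind = kind, lower = lower, upper = upper,
                 choices = choices), class = "hp_entry")
}

#' @rdname hyper_space
#' @param lower,upper Range bounds (inclusive).
#' @export
hp_real <- function(lower, upper) hp_entry("real", lower, upper)

#' @rdname hyper_space
#' @export
hp_logreal <- function(lower, upper) hp_entry("log-real", lower, upper)

#' @rdname hyper_space
#' @export
hp_int <- function(lower, upper) hp_entry("integer", as.integer(lower),
                                          as.integer(upper))

#' @rdname hyper_space
#' @param choices Vector of categorical choices.
#' @export
hp_cat <- function(choices) hp_entry("categorical", choices = choices)

#' @rdname hyper_space
#' @export
default_hyper_space <- function() {
  hyper_space(
    learning_rate = hp_logreal(1e-4, 1e-1),
    dropout = hp_real(0, 0.7),
    batch_size = hp_int(4L, 64L),
    conv_filters = hp_int(8L, 64L),
    gru_units = hp_int(8L, 128L),
    kernel_size = hp_int(3L, 9L)
  )
}

#' Decode a unit-cube genome into hyperparameter values
#'
#' Per entry kind: log-real interpolates in log10 space,
#' `10^(log10(lo) + g*(log10(hi)-log10(lo)))`; real interpolates linearly;
#' integer maps `lo + floor(g*(hi-lo+1))` capped at `hi`; categorical picks
#' `choices[floor(g*m)+1]` capped at the last choice.
#'
#' @param genome Numeric vector in `[0,1]^D`, `D = length(space)`.
#' @param space A [hyper_space()].
#' @param clip Clip out-of-range genes into `[0,1]` instead of erroring.
#' @return Named list of decoded hyperparameter values.
#' @examples
#' decode_genome(rep(0.5, 6), default_hyper_space())
#' @export
decode_genome <- function(genome, space, clip = FALSE) {
  stopifnot(inherits(space, "hyper_space"))
  if (length(genome) != length(space)) stop("genome length mismatch")
  if (clip) genome <- pmin(pmax(genome, 0), 1)
  if (any(genome < 0 | genome > 1)) stop("genome out of range")
  out <- vector("list", length(space))
  names(out) <- names(space)
  for (i in seq_along(space)) {
    e <- space[[i]]
    g <- genome[i]
    out[[i]] <- switch(
      e$kind,
      "log-real" = 10^(log10(e$lower) + g * (log10(e$upper) - log10(e$lower))),
      "real" = e$lower + g * (e$upper - e$lower),
      "integer" = min(e$upper, e$lower + as.integer(floor(g * (e$upper - e$lower + 1)))),
      "categorical" = e$choices[[min(length(e$choices),
                                     floor(g * length(e$choices)) + 1L)]]
    )
  }
  out
}

#' Classification error rate
#'
#' Percentage of misclassified instances,
#' `100 * #mismatches / total` -- the quantity the tuner minimises.
#'
#' @param truth,predicted Equal-length label vectors.
#' @return Error percentage in `[0, 100]`.
#' @export
error_rate <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("label length mismatch")
  if (length(truth) == 0L) stop("empty input")
  100 * sum(truth != predicted) / length(truth)
}

## Stratified fold assignment that is invariant to dataset row order: rows
## are first put into a canonical order (label, then beat values), then
## permuted by the seeded generator and dealt round-robin into folds.
## Returns a fold id per original row.
stratified_folds <- function(data, folds, seed) {
  C <- check_supervised(data)
  counts <- table(data$labels)
  if (any(counts < folds)) stop("class too small for CV")
  canon <- do.call(order, c(list(data$labels),
                            lapply(seq_len(ncol(data$beats)),
                                   function(j) data$beats[, j])))
  fold_of <- integer(n_beats(data))
  set.seed(as.integer(seed))
  for (cl in 0:(C - 1L)) {
    rows <- canon[data$labels[canon] == cl]
    rows <- rows[sample.int(length(rows))]
    fold_of[rows] <- rep_len(seq_len(folds), length(rows))
  }
  fold_of
}

## Default model-fitting hook for cv_fitness(): merge decoded
## hyperparameters into the base spec / train config, build and train a
## CNN-GRU, and return a predictor closure.
default_fit_fun <- function(train_data, hp, train_cfg, seed, base_spec) {
  spec_args <- list(window_length = train_data$window_length,
                    n_classes = max(2L, n_classes(train_data)))
  if (!is.null(base_spec)) {
    spec_args <- utils::modifyList(unclass(base_spec), spec_args)
  }
  for (nm in intersect(names(hp), c("conv_filters", "gru_units",
                                    "kernel_size", "dropout",
                                    "conv_layers", "gru_layers",
                                    "hidden_units"))) {
    spec_args[[nm]] <- hp[[nm]]
  }
  spec <- do.call(model_spec, spec_args)
  cfg_args <- unclass(train_cfg)
  for (nm in intersect(names(hp), c("learning_rate", "batch_size")))
    cfg_args[[nm]] <- hp[[nm]]
  cfg_args$seed <- seed
  cfg <- do.call(train_config, cfg_args)
  model <- train_model(build_model(spec, seed = seed), train_data, cfg)
  function(test_data) predict(model, test_data)$labels
}

#' Cross-validated classification-error fitness
#'
#' The tuning objective: decode the genome, and for each of `folds`
#' stratified folds train a classifier on the remaining folds and score the
#' held-out fold with [error_rate()]; the fitness is the mean held-out
#' error percentage. Fold assignment comes from a seeded permutation of a
#' canonical row ordering, so the value is invariant to dataset row order;
#' per-fold training seeds are derived by hashing the global seed, the
#' genome and the fold index, so concurrent candidate evaluations are not
#' confounded by shared initialisation noise.
#'
#' @param genome Unit-cube genome (see [decode_genome()]).
#' @param data A standardised [beat_dataset()]; every class needs at least
#'   `folds` members.
#' @param space A [hyper_space()].
#' @param folds Number of CV folds (>= 2). Default 3.
#' @param train_cfg A [train_config()]; during tuning keep `epochs` small
#'   (the default tuning cap is 5) independently of the final-training
#'   epoch count.
#' @param seed Integer seed.
#' @param base_spec Optional [model_spec()] supplying the non-tuned
#'   topology fields.
#' @param fit_fun Optional replacement fitting hook
#'   `function(train_data, hp, train_cfg, seed)` returning a predictor
#'   `function(test_data) -> labels`; used for testing the CV plumbing.
#' @return Mean held-out error percentage.
#' @export
cv_fitness <- function(genome, data, space, folds = 3L,
                       train_cfg = train_config(epochs = 5L), seed = 1L,
                       base_spec = NULL, fit_fun = NULL) {
  stopifnot(inherits(data, "beat_dataset"))
  if (folds < 2L) stop("folds must be at least 2")
  hp <- decode_genome(genome, space)
  fold_of <- stratified_folds(data, folds, hash_seed(seed, 17L, vec = genome))
  errs <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f)
    te <- which(fold_of == f)
    train_data <- beat_dataset(data$beats[tr, , drop = FALSE],
                               data$labels[tr])
    test_data <- beat_dataset(data$beats[te, , drop = FALSE],
                              data$labels[te])
    fold_seed <- hash_seed(seed, f, vec = genome)
    pred <- if (is.null(fit_fun)) {
      default_fit_fun(train_data, hp, train_cfg, fold_seed, base_spec)
    } else {
      fit_fun(train_data, hp, train_cfg, fold_seed)
    }
    errs[f] <- error_rate(test_data$labels, pred(test_data))
  }
  mean(errs)
}

#' Tune CNN-GRU hyperparameters with the Farmland Fertility Algorithm
#'
#' Runs [ffa_optimize()] over the unit hypercube of the hyperparameter
#' space with [cv_fitness()] as the objective, then decodes the best
#' genome. Optionally retrains a final model on all supplied data with the
#' tuned settings and the full-length training configuration.
#'
#' @param data A standardised [beat_dataset()].
#' @param space A [hyper_space()]; default [default_hyper_space()].
#' @param ffa_cfg An [ffa_config()] (its `seed` also seeds the CV folds).
#' @param train_cfg A [train_config()] used for the optional final fit.
#' @param folds CV folds for the fitness. Default 3.
#' @param base_spec Optional [model_spec()] with the non-tuned topology.
#' @param tune_epochs Epoch cap per fitness evaluation (default 5),
#'   deliberately smaller than the final-training epochs.
#' @param final_fit Retrain on all data with the tuned settings.
#' @param fit_fun Optional fitting hook forwarded to [cv_fitness()].
#' @return List of class `ffa_tune_result`: `hyperparameters` (decoded
#'   best), `fitness`, `trace`, `initial_fitness`, the raw `ffa` result and
#'   (if `final_fit`) the trained `model`.
#' @export
ffa_tune <- function(data, space = default_hyper_space(), ffa_cfg,
                     train_cfg = train_config(), folds = 3L,
                     base_spec = NULL, tune_epochs = 5L, final_fit = FALSE,
                     fit_fun = NULL) {
  stopifnot(inherits(space, "hyper_space"), inherits(ffa_cfg, "ffa_config"))
  cv_cfg <- train_config(learning_rate = train_cfg$learning_rate,
                         batch_size = train_cfg$batch_size,
                         epochs = tune_epochs, seed = train_cfg$seed)
  objective <- function(g) {
    cv_fitness(g, data, space, folds = folds, train_cfg = cv_cfg,
               seed = ffa_cfg$seed, base_spec = base_spec, fit_fun = fit_fun)
  }
  domain <- search_domain(rep(0, length(space)), rep(1, length(space)))
  res <- ffa_optimize(objective, domain, ffa_cfg)
  out <- list(hyperparameters = decode_genome(res$best, space),
              fitness = res$fitness, trace = res$trace,
              initial_fitness = res$initial_fitness, ffa = res)
  if (final_fit) {
    hp <- out$hyperparameters
    fold_seed <- hash_seed(ffa_cfg$seed, 0L, vec = res$best)
    fitted <- default_fit_fun(data, hp, train_cfg, fold_seed, base_spec)
    out$model <- environment(fitted)$model
  }
  structure(out, class = "ffa_tune_result")
}

#' @export
print.ffa_tune_result <- function(x, ...) {
  cat(sprintf("<ffa_tune_result> tuned CV error %.2f%% (initial population median %.2f%%)\n",
              x$fitness, stats::median(x$initial_fitness)))
  hp <- vapply(x$hyperparameters, function(v) format(v, digits = 4), "")
  cat("  ", paste(names(hp), hp, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Confusion matrix and classification metrics
#'
#' Builds the `C x C` confusion matrix (rows = truth, columns =
#' prediction) and reports accuracy, sensitivity and specificity as
#' percentages. For binary labels the rates are taken with respect to
#' `positive_class`; for more than two classes sensitivity and specificity
#' are macro-averages of the one-vs-rest rates. A rate with an empty
#' denominator is reported as 0 and flagged in `$undefined_rates`.
#'
#' @param truth,predicted Equal-length 0-based label vectors.
#' @param positive_class Positive class for binary rates. Default 1.
#' @param n_classes Number of classes; inferred from the labels if omitted.
#' @return An object of class `beat_metrics`: list with `confusion`,
#'   `accuracy`, `sensitivity`, `specificity` and `undefined_rates`.
#' @examples
#' m <- evaluate_metrics(c(0, 0, 1, 1), c(0, 1, 1, 1))
#' m$accuracy
#' @export
evaluate_metrics <- function(truth, predicted, positive_class = 1L,
                             n_classes = NULL) {
  if (length(truth) != length(predicted)) stop("label length mismatch")
  if (length(truth) == 0L) stop("empty input")
  C <- if (is.null(n_classes)) max(truth, predicted) + 1L
       else as.integer(n_classes)
  lev <- 0:(C - 1L)
  cm <- table(factor(truth, levels = lev), factor(predicted, levels = lev))
  cm <- matrix(as.integer(cm), C, C, dimnames = list(truth = lev, predicted = lev))
  n <- length(truth)
  accuracy <- 100 * sum(diag(cm)) / n
  undefined <- FALSE
  rate <- function(num, den) {
    if (den == 0) {
      undefined <<- TRUE
      0
    } else 100 * num / den
  }
  one_vs_rest <- function(pos) {
    tp <- cm[pos + 1L, pos + 1L]
    fn <- sum(cm[pos + 1L, ]) - tp
    fp <- sum(cm[, pos + 1L]) - tp
    tn <- n - tp - fn - fp
    c(sens = rate(tp, tp + fn), spec = rate(tn, tn + fp))
  }
  if (C == 2L) {
    r <- one_vs_rest(as.integer(positive_class))
    sens <- r[["sens"]]; spec <- r[["spec"]]
  } else {
    rs <- vapply(lev, one_vs_rest, numeric(2))
    sens <- mean(rs["sens", ]); spec <- mean(rs["spec", ])
  }
  if (undefined) warning("rate with empty denominator reported as 0")
  structure(list(confusion = cm, accuracy = accuracy, sensitivity = sens,
                 specificity = spec, undefined_rates = undefined),
            class = "beat_metrics")
}

#' @export
print.beat_metrics <- function(x, ...) {
  cat(sprintf("Accuracy (%%): %.2f\nSensitivity (%%): %.2f\nSpecificity (%%): %.2f\n",
              x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}
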