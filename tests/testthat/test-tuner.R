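test_that("genome decoding maps each entry kind correctly", {
  space <- default_hyper_space()
  hp <- decode_genome(c(0.5, 0, 0.999, 0, 1, 0.5), space)
  expect_equal(hp$learning_rate, 10^-2.5, tolerance = 1e-12)  # log midpoint
  expect_equal(hp$dropout, 0)                                 # lower bound
  expect_equal(hp$batch_size, 64L)                            # upper cap
  expect_equal(hp$conv_filters, 8L)
  expect_equal(hp$gru_units, 128L)
  expect_error(decode_genome(c(0.5, -0.1, 0, 0, 0, 0), space),
               "genome out of range")
  expect_equal(decode_genome(c(0.5, -0.1, 0, 0, 0, 0), space, clip = TRUE)$dropout, 0)

  cats <- hyper_space(act = hp_cat(c("relu", "tanh", "elu")))
  expect_equal(decode_genome(0.99, cats)$act, "elu")
  expect_equal(decode_genome(0, cats)$act, "relu")
})

test_that("decoding is monotone per coordinate for real and log-real entries", {
  space <- default_hyper_space()
  g <- seq(0, 1, length.out = 11)
  lr <- vapply(g, function(x)
    decode_genome(c(x, 0, 0, 0, 0, 0), space)$learning_rate, numeric(1))
  dr <- vapply(g, function(x)
    decode_genome(c(0, x, 0, 0, 0, 0), space)$dropout, numeric(1))
  expect_true(all(diff(lr) > 0))
  expect_true(all(diff(dr) > 0))
})

test_that("error rate is the misclassification percentage", {
  expect_equal(error_rate(rep(0, 10), c(rep(0, 8), 1, 1)), 20.0)
  expect_equal(error_rate(1:5, 1:5), 0.0)
  expect_equal(error_rate(rep(0, 4), rep(1, 4)), 100.0)
  expect_error(error_rate(1:3, 1:4), "label length mismatch")
})

test_that("accuracy always equals 100 minus the error rate", {
  set.seed(14)
  for (C in c(2L, 4L)) {
    truth <- sample(0:(C - 1L), 60, replace = TRUE)
    pred <- ifelse(runif(60) < 0.3, sample(0:(C - 1L), 60, replace = TRUE),
                   truth)
    m <- suppressWarnings(evaluate_metrics(truth, pred, n_classes = C))
    expect_equal(m$accuracy, 100 - error_rate(truth, pred), tolerance = 1e-9)
  }
})

test_that("binary metrics match the confusion-matrix arithmetic", {
  truth <- c(rep(0L, 50), rep(1L, 50))
  pred <- c(rep(0L, 45), rep(1L, 5), rep(0L, 10), rep(1L, 40))
  m <- evaluate_metrics(truth, pred, positive_class = 1L)
  expect_equal(m$accuracy, 85.0)
  expect_equal(m$sensitivity, 80.0)
  expect_equal(m$specificity, 90.0)
  expect_equal(as.integer(m$confusion), c(45L, 10L, 5L, 40L))
  expect_false(m$undefined_rates)

  perfect <- evaluate_metrics(truth, truth)
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity),
               c(100, 100, 100))

  # no positives in truth: sensitivity undefined -> 0 with a warning flag
  expect_warning(m0 <- evaluate_metrics(rep(0L, 5), rep(0L, 5),
                                        n_classes = 2L),
                 "empty denominator")
  expect_equal(m0$sensitivity, 0)
  expect_true(m0$undefined_rates)
})

test_that("cv_fitness hits the perfect and majority limits with stub fits", {
  d <- make_sep_data(n = 100L, L = 16L, seed = 4)
  space <- tiny_space()
  g <- rep(0.5, 4)
  memorise <- function(train_data, hp, cfg, seed)
    function(test_data) test_data$labels
  expect_equal(cv_fitness(g, d, space, folds = 5, seed = 1,
                          fit_fun = memorise), 0.0)
  constant <- function(train_data, hp, cfg, seed)
    function(test_data) rep(0L, nrow(test_data$beats))
  expect_equal(cv_fitness(g, d, space, folds = 5, seed = 1,
                          fit_fun = constant), 50.0)
  # every class must fill each fold
  tiny <- beat_dataset(matrix(rnorm(4 * 8), 4, 8), c(0L, 0L, 0L, 1L))
  expect_equal(nrow(tiny$beats), 4L)
  expect_error(cv_fitness(g, tiny, space, folds = 3, seed = 1,
                          fit_fun = memorise), "class too small for CV")
})

test_that("cv_fitness is invariant to dataset row order", {
  d <- make_sep_data(n = 60L, L = 16L, seed = 8)
  space <- tiny_space()
  g <- rep(0.3, 4)
  f1 <- cv_fitness(g, d, space, folds = 3, seed = 5,
                   fit_fun = centroid_fit_fun)
  set.seed(123)
  perm <- sample.int(60)
  dperm <- beat_dataset(d$beats[perm, ], d$labels[perm])
  f2 <- cv_fitness(g, dperm, space, folds = 3, seed = 5,
                   fit_fun = centroid_fit_fun)
  expect_equal(f1, f2)
  # and deterministic across calls
  expect_equal(f1, cv_fitness(g, d, space, folds = 3, seed = 5,
                              fit_fun = centroid_fit_fun))
})

test_that("separable data gives low CV error with a tiny real fit", {
  d <- make_sep_data(n = 90L, L = 64L, separation = 3, noise = 0.02,
                     seed = 13)
  fit <- cv_fitness(rep(0.5, 4), d, tiny_space(), folds = 3,
                    train_cfg = train_config(batch_size = 8, epochs = 3),
                    seed = 2, base_spec = tiny_base_spec())
  expect_lte(fit, 10.0)
})

test_that("ffa_tune improves on the initial population and keeps the trace monotone", {
  d <- make_sep_data(n = 60L, L = 16L, seed = 17)
  res <- ffa_tune(d, space = tiny_space(),
                  ffa_cfg = suppressWarnings(
                    ffa_config(k = 2, n = 2, max_iters = 2, seed = 3)),
                  folds = 3, fit_fun = centroid_fit_fun)
  expect_true(all(diff(res$trace) <= 0))
  expect_lte(res$fitness, stats::median(res$initial_fitness))
  expect_named(res$hyperparameters,
               c("learning_rate", "dropout", "gru_units", "conv_filters"))
  # max_iters = 0 returns the best of the random initial genomes
  res0 <- ffa_tune(d, space = tiny_space(),
                   ffa_cfg = suppressWarnings(
                     ffa_config(k = 2, n = 2, max_iters = 0, seed = 3)),
                   folds = 3, fit_fun = centroid_fit_fun)
  expect_equal(res0$fitness, min(res0$initial_fitness))
})
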