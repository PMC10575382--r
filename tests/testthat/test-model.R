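test_that("softmax matches closed forms and is shift invariant", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(1000, 1000)), c(0.5, 0.5))
  expect_equal(softmax(c(log(1), log(3))), c(0.25, 0.75), tolerance = 1e-12)
  expect_error(softmax(numeric(0)), "empty input")
  set.seed(2)
  for (rep in 1:10) {
    v <- rnorm(5) * 10
    cshift <- rnorm(1) * 100
    expect_lt(max(abs(softmax(v + cshift) - softmax(v))), 1e-9)
    expect_equal(sum(softmax(v)), 1, tolerance = 1e-9)
  }
})

test_that("build_model honours the spec and is seed-deterministic", {
  spec <- model_spec(window_length = 180, n_classes = 2)
  m <- build_model(spec, seed = 5)
  expect_length(m$params$conv, 3L)
  expect_length(m$params$gru, 2L)
  pr <- predict(m, matrix(rnorm(3 * 180), 3, 180))
  expect_equal(dim(pr$prob), c(3L, 2L))
  expect_equal(rowSums(pr$prob), rep(1, 3), tolerance = 1e-6)

  m2 <- build_model(spec, seed = 5)
  expect_identical(m$params, m2$params)
  m3 <- build_model(spec, seed = 6)
  expect_false(identical(m$params, m3$params))
})

test_that("infeasible conv/pool stacks are rejected", {
  expect_error(model_spec(window_length = 4, conv_layers = 3,
                          use_pooling = TRUE),
               "architecture infeasible")
  # same depth without pooling is fine at small L
  expect_s3_class(model_spec(window_length = 8, conv_layers = 3,
                             use_pooling = FALSE), "model_spec")
})

test_that("analytic gradients match finite differences", {
  spec <- model_spec(window_length = 12, n_classes = 2, conv_layers = 2,
                     conv_filters = 3, kernel_size = 4, gru_layers = 2,
                     gru_units = 3, hidden_units = 4, dropout = 0)
  m <- build_model(spec, seed = 8)
  set.seed(8)
  X <- matrix(rnorm(3 * 12), 3, 12)
  y <- c(0L, 1L, 1L)
  lg <- ffatune:::nn_loss_grads(m$params, spec, X, y)
  eps <- 1e-6
  probe <- function(path, idx) {
    f <- function(delta) {
      p <- m$params
      if (length(path) == 3L) {
        p[[path[[1]]]][[path[[2]]]][[path[[3]]]][idx] <-
          p[[path[[1]]]][[path[[2]]]][[path[[3]]]][idx] + delta
      } else {
        p[[path[[1]]]][[path[[2]]]][idx] <-
          p[[path[[1]]]][[path[[2]]]][idx] + delta
      }
      ffatune:::nn_loss_grads(p, spec, X, y)$loss
    }
    (f(eps) - f(-eps)) / (2 * eps)
  }
  cases <- list(list(list("conv", 1L, "W"), 2), list(list("conv", 2L, "b"), 1),
                list(list("gru", 1L, "Whh"), 3), list(list("gru", 2L, "Wxr"), 1),
                list(list("gru", 2L, "bh"), 2), list(list("dense", "W"), 4),
                list(list("out", "W"), 1), list(list("out", "b"), 2))
  for (cs in cases) {
    g_an <- lg$grads
    for (k in cs[[1]]) g_an <- g_an[[k]]
    expect_equal(g_an[cs[[2]]], probe(cs[[1]], cs[[2]]), tolerance = 1e-5)
  }
})

test_that("training separates the synthetic classes and records its loss", {
  d <- make_sep_data(n = 80L, L = 64L, separation = 3, noise = 0.02,
                     seed = 5)
  spec <- model_spec(window_length = 64, conv_layers = 1, conv_filters = 8,
                     gru_layers = 1, gru_units = 8, hidden_units = 8,
                     dropout = 0)
  cfg <- train_config(epochs = 10, seed = 1)
  m <- train_model(build_model(spec, seed = 1), d, cfg)
  expect_length(m$loss_trace, 10L)
  expect_lt(m$loss_trace[10], m$loss_trace[1])
  acc <- mean(predict(m, d)$labels == d$labels)
  expect_gte(acc, 0.95)

  # fixed seed reproduces the trace
  m2 <- train_model(build_model(spec, seed = 1), d, cfg)
  expect_identical(m$loss_trace, m2$loss_trace)
})

test_that("training rejects degenerate inputs", {
  d <- make_sep_data(n = 20L, L = 16L, seed = 2)
  one_class <- beat_dataset(d$beats, rep(0L, 20))
  spec <- model_spec(window_length = 16, conv_layers = 1, gru_layers = 1,
                     gru_units = 4, hidden_units = 4)
  m <- build_model(spec, seed = 1)
  expect_error(train_model(m, one_class, train_config(epochs = 1)),
               "degenerate labels")
  expect_error(train_config(epochs = 0), "epochs")
  wrong <- make_sep_data(n = 10L, L = 32L, seed = 3)
  expect_error(train_model(m, wrong, train_config(epochs = 1)),
               "input shape mismatch")
  expect_error(predict(m, matrix(0, 2, 8)), "input shape mismatch")
})

test_that("prediction breaks probability ties toward the lower class", {
  spec <- model_spec(window_length = 16, conv_layers = 1, conv_filters = 2,
                     gru_layers = 1, gru_units = 2, hidden_units = 2)
  m <- build_model(spec, seed = 1)
  m$params$out$W[] <- 0
  m$params$out$b[] <- 0  # all scores equal -> exact tie
  pr <- predict(m, matrix(rnorm(4 * 16), 4, 16))
  expect_true(all(pr$prob == 0.5))
  expect_true(all(pr$labels == 0L))
})

test_that("checkpoints round-trip through JSON", {
  d <- make_sep_data(n = 20L, L = 16L, seed = 6)
  spec <- model_spec(window_length = 16, conv_layers = 1, conv_filters = 3,
                     gru_layers = 1, gru_units = 4, hidden_units = 4)
  m <- train_model(build_model(spec, seed = 2), d, train_config(epochs = 2))
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  X <- matrix(rnorm(5 * 16), 5, 16)
  expect_lt(max(abs(predict(m, X)$prob - predict(m2, X)$prob)), 1e-12)
  expect_identical(m2$trained, TRUE)
  expect_equal(m2$loss_trace, m$loss_trace)
})
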