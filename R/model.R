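#' CNN-GRU model specification
#'
#' Describes the hybrid classifier topology: a stack of 1-D convolutional
#' layers (ReLU, optional width-2 max pooling after each), feeding the
#' filter activations as a sequence of feature vectors into stacked GRU
#' layers; the final GRU hidden state passes through a ReLU dense hidden
#' layer with dropout into a softmax output. Defaults follow the reference
#' topology: three convolutional layers of 32 filters, two GRU layers of 64
#' units, one hidden layer, dropout 0.5.
#'
#' @param window_length Input window length in samples.
#' @param n_classes Number of output classes (>= 2).
#' @param conv_layers,conv_filters,kernel_size Convolution stack shape.
#' @param gru_layers,gru_units Recurrent stack shape.
#' @param hidden_units Width of the dense hidden layer.
#' @param dropout Dropout rate in `[0, 1)` applied after the hidden layer
#'   during training.
#' @param use_pooling Max-pool (width 2) after each convolution; halves the
#'   sequence length each time.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(window_length, n_classes = 2L, conv_layers = 3L,
                       conv_filters = 32L, kernel_size = 5L, gru_layers = 2L,
                       gru_units = 64L, hidden_units = 64L, dropout = 0.5,
                       use_pooling = TRUE) {
  spec <- list(window_length = as.integer(window_length),
               n_classes = as.integer(n_classes),
               conv_layers = as.integer(conv_layers),
               conv_filters = as.integer(conv_filters),
               kernel_size = as.integer(kernel_size),
               gru_layers = as.integer(gru_layers),
               gru_units = as.integer(gru_units),
               hidden_units = as.integer(hidden_units),
               dropout = as.numeric(dropout),
               use_pooling = isTRUE(use_pooling))
  stopifnot(spec$n_classes >= 2L, spec$conv_layers >= 1L,
            spec$conv_filters >= 1L, spec$kernel_size >= 1L,
            spec$gru_layers >= 1L, spec$gru_units >= 1L,
            spec$hidden_units >= 1L, spec$dropout >= 0, spec$dropout < 1)
  if (conv_out_length(spec) < 1L) stop("architecture infeasible")
  structure(spec, class = "model_spec")
}

conv_out_length <- function(spec) {
  Lp <- spec$window_length
  for (i in seq_len(spec$conv_layers))
    if (spec$use_pooling) Lp <- Lp %/% 2L
  Lp
}

#' Training configuration
#'
#' Defaults match the reference settings: learning rate 0.01, batch size 5,
#' 50 epochs. Optimisation is mini-batch Adam on the categorical
#' cross-entropy.
#'
#' @param learning_rate Positive step size.
#' @param batch_size Mini-batch size (>= 1).
#' @param epochs Number of passes over the training data (>= 1).
#' @param seed Integer seed controlling shuffling and dropout draws.
#' @param clip_norm Global gradient-norm ceiling per mini-batch (the usual
#'   stabiliser for recurrent nets at aggressive learning rates); `Inf`
#'   disables clipping. Default 5.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, batch_size = 5L, epochs = 50L,
                         seed = 1L, clip_norm = 5) {
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop("learning_rate must be positive")
  if (epochs < 1L) stop("epochs must be at least 1")
  if (batch_size < 1L) stop("batch_size must be at least 1")
  if (!is.numeric(clip_norm) || clip_norm <= 0)
    stop("clip_norm must be positive")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 clip_norm = clip_norm),
            class = "train_config")
}

glorot <- function(a, b) {
  lim <- sqrt(6 / (a + b))
  matrix(stats::runif(a * b, -lim, lim), a, b)
}

glorot_gru <- function(input_size, H) {
  gw <- function(a, b) glorot(a, b)
  gru_weights(gw(input_size, H), gw(H, H), gw(input_size, H), gw(H, H),
              gw(input_size, H), gw(H, H),
              numeric(H), numeric(H), numeric(H))
}

#' Build an untrained CNN-GRU classifier
#'
#' Allocates and initialises all weights (Glorot-uniform, biases zero) from
#' a seeded stream: two builds with the same spec and seed have identical
#' parameters.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `cnn_gru`.
#' @export
build_model <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "model_spec"))
  if (conv_out_length(spec) < 1L) stop("architecture infeasible")
  set.seed(as.integer(seed))
  params <- list(conv = list(), gru = list())
  cin <- 1L
  for (i in seq_len(spec$conv_layers)) {
    params$conv[[i]] <- list(
      W = glorot(spec$kernel_size * cin, spec$conv_filters),
      b = numeric(spec$conv_filters))
    cin <- spec$conv_filters
  }
  gin <- spec$conv_filters
  for (i in seq_len(spec$gru_layers)) {
    params$gru[[i]] <- glorot_gru(gin, spec$gru_units)
    gin <- spec$gru_units
  }
  params$dense <- list(W = glorot(spec$gru_units, spec$hidden_units),
                       b = numeric(spec$hidden_units))
  params$out <- list(W = glorot(spec$hidden_units, spec$n_classes),
                     b = numeric(spec$n_classes))
  structure(list(spec = spec, params = params, trained = FALSE,
                 loss_trace = numeric(0), seed = as.integer(seed)),
            class = "cnn_gru")
}

#' @export
print.cnn_gru <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<cnn_gru> L=%d -> conv x%d (%d filters, kernel %d%s) -> GRU x%d (%d units) -> dense %d -> softmax %d [%s]\n",
    s$window_length, s$conv_layers, s$conv_filters, s$kernel_size,
    if (s$use_pooling) ", pool 2" else "", s$gru_layers, s$gru_units,
    s$hidden_units, s$n_classes,
    if (x$trained) "trained" else "untrained"))
  invisible(x)
}

## Full forward pass. Returns class probabilities; with `y` also the
## cross-entropy loss and all layer caches needed by nn_loss_grads().
nn_forward <- function(params, spec, X, dropout_mask = NULL) {
  B <- nrow(X)
  A <- array(X, c(B, spec$window_length, 1L))
  conv_caches <- vector("list", spec$conv_layers)
  for (i in seq_len(spec$conv_layers)) {
    cf <- conv1d_forward(A, params$conv[[i]]$W, params$conv[[i]]$b,
                         spec$kernel_size)
    rf <- relu_forward(cf$out)
    if (spec$use_pooling) {
      pf <- maxpool2_forward(rf$out)
      A <- pf$out
    } else {
      pf <- NULL
      A <- rf$out
    }
    conv_caches[[i]] <- list(cf = cf, rf = rf, pf = pf)
  }
  gru_caches <- vector("list", spec$gru_layers)
  for (i in seq_len(spec$gru_layers)) {
    gf <- gru_layer_forward(A, params$gru[[i]])
    gru_caches[[i]] <- gf
    A <- gf$out
  }
  h <- gru_caches[[spec$gru_layers]]$h_final
  d1 <- dense_forward(h, params$dense$W, params$dense$b)
  r1 <- relu_forward(d1$out)
  hdrop <- if (is.null(dropout_mask)) r1$out else r1$out * dropout_mask
  d2 <- dense_forward(hdrop, params$out$W, params$out$b)
  list(scores = d2$out, conv_caches = conv_caches, gru_caches = gru_caches,
       h = h, r1 = r1, hdrop = hdrop)
}

## Loss and full gradient for one mini-batch (y is 0-based).
nn_loss_grads <- function(params, spec, X, y, dropout_mask = NULL) {
  fw <- nn_forward(params, spec, X, dropout_mask)
  sx <- softmax_xent(fw$scores, y)
  grads <- list(conv = vector("list", spec$conv_layers),
                gru = vector("list", spec$gru_layers))
  b2 <- dense_backward(sx$dZ, list(X = fw$hdrop), params$out$W)
  grads$out <- list(W = b2$dW, b = b2$db)
  dhdrop <- b2$dX
  if (!is.null(dropout_mask)) dhdrop <- dhdrop * dropout_mask
  dr1 <- relu_backward(dhdrop, fw$r1)
  b1 <- dense_backward(dr1, list(X = fw$h), params$dense$W)
  grads$dense <- list(W = b1$dW, b = b1$db)
  dh_final <- b1$dX
  dH_all <- NULL
  for (i in rev(seq_len(spec$gru_layers))) {
    gb <- gru_layer_backward(dH_all, dh_final, fw$gru_caches[[i]],
                             params$gru[[i]])
    grads$gru[[i]] <- gb[c("Wxr", "Whr", "Wxz", "Whz", "Wxh", "Whh",
                           "br", "bz", "bh")]
    dH_all <- gb$dX
    dh_final <- NULL
  }
  dA <- dH_all
  for (i in rev(seq_len(spec$conv_layers))) {
    cc <- fw$conv_caches[[i]]
    if (spec$use_pooling) dA <- maxpool2_backward(dA, cc$pf)
    dA <- relu_backward(dA, cc$rf)
    cb <- conv1d_backward(dA, cc$cf, params$conv[[i]]$W)
    grads$conv[[i]] <- list(W = cb$dW, b = cb$db)
    dA <- cb$dX
  }
  list(loss = sx$loss, grads = grads, prob = sx$prob)
}

## Recursive Adam step over the nested parameter list.
adam_step <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(p)) {
    keys <- if (!is.null(names(p)) && all(nzchar(names(p)))) names(p)
            else seq_along(p)
    for (i in keys) {
      r <- adam_step(p[[i]], g[[i]], m[[i]], v[[i]], lr, t, b1, b2, eps)
      p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
    }
  } else {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    p <- p - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
  }
  list(p = p, m = m, v = v)
}

tree_sumsq <- function(p) {
  if (is.list(p)) sum(vapply(p, tree_sumsq, numeric(1))) else sum(p^2)
}

tree_scale <- function(p, s) {
  if (is.list(p)) {
    out <- lapply(p, tree_scale, s = s)
    attributes(out) <- attributes(p)
    out
  } else p * s
}

zero_like <- function(p) {
  if (is.list(p)) {
    out <- lapply(p, zero_like)
    attributes(out) <- attributes(p)
    out
  } else p * 0
}

#' Train a CNN-GRU classifier
#'
#' Minimises the categorical cross-entropy by mini-batch Adam at the
#' configured learning rate. Shuffling and dropout draws come from the
#' config seed, so a fixed seed reproduces the loss trace on a fixed
#' platform. Expects standardised inputs (see [fit_standard_scaler()]).
#'
#' @param model An untrained (or previously trained) [build_model()] object.
#' @param data A [beat_dataset()] with every class present.
#' @param cfg A [train_config()].
#' @return The trained model; `$loss_trace` holds the mean training loss per
#'   epoch (length `cfg$epochs`).
#' @export
train_model <- function(model, data, cfg) {
  stopifnot(inherits(model, "cnn_gru"), inherits(data, "beat_dataset"),
            inherits(cfg, "train_config"))
  if (ncol(data$beats) != model$spec$window_length)
    stop("input shape mismatch")
  C <- check_supervised(data)
  if (C < 2L) stop("degenerate labels")
  if (C > model$spec$n_classes) stop("more classes than model outputs")
  spec <- model$spec
  params <- model$params
  m <- zero_like(params); v <- zero_like(params)
  set.seed(cfg$seed)
  n <- n_beats(data)
  tstep <- 0L
  trace <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    tot <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
      X <- data$beats[idx, , drop = FALSE]
      y <- data$labels[idx]
      mask <- NULL
      if (spec$dropout > 0) {
        keep <- 1 - spec$dropout
        mask <- (matrix(stats::runif(length(idx) * spec$hidden_units),
                        length(idx), spec$hidden_units) < keep) / keep
      }
      lg <- nn_loss_grads(params, spec, X, y, mask)
      gnorm <- sqrt(tree_sumsq(lg$grads))
      if (is.finite(cfg$clip_norm) && gnorm > cfg$clip_norm)
        lg$grads <- tree_scale(lg$grads, cfg$clip_norm / gnorm)
      tstep <- tstep + 1L
      r <- adam_step(params, lg$grads, m, v, cfg$learning_rate, tstep)
      params <- r$p; m <- r$m; v <- r$v
      tot <- tot + lg$loss * length(idx)
    }
    trace[epoch] <- tot / n
  }
  model$params <- params
  model$trained <- TRUE
  model$loss_trace <- trace
  model$train_cfg <- cfg
  model
}

#' Predict beat classes
#'
#' Runs the forward pass in evaluation mode (no dropout) and returns the
#' argmax class per beat; exact ties break toward the lower class index.
#'
#' @param object A `cnn_gru` model.
#' @param data A [beat_dataset()] or a numeric beat matrix with matching
#'   window length.
#' @param ... Unused.
#' @return A list: `labels` (0-based integer vector) and `prob`
#'   (`n x n_classes` probability matrix, rows summing to 1).
#' @export
predict.cnn_gru <- function(object, data, ...) {
  X <- if (inherits(data, "beat_dataset")) data$beats else as.matrix(data)
  if (ncol(X) != object$spec$window_length) stop("input shape mismatch")
  n <- nrow(X)
  prob <- matrix(0, n, object$spec$n_classes)
  for (start in seq(1L, n, by = 256L)) {
    idx <- start:min(start + 255L, n)
    fw <- nn_forward(object$params, object$spec, X[idx, , drop = FALSE])
    prob[idx, ] <- softmax_rows(fw$scores)
  }
  labels <- max.col(prob, ties.method = "first") - 1L
  list(labels = labels, prob = prob)
}

## ---- JSON checkpointing ----

serialize_arrays <- function(p) {
  if (is.list(p)) lapply(p, serialize_arrays)
  else list(dim = if (is.matrix(p)) dim(p) else length(p), data = as.numeric(p))
}

deserialize_arrays <- function(s) {
  if (!is.null(s$dim) && !is.null(s$data)) {
    d <- unlist(s$dim)
    x <- as.numeric(unlist(s$data))
    if (length(d) == 2L) matrix(x, d[1L], d[2L]) else x
  } else lapply(s, deserialize_arrays)
}

#' Save / load a CNN-GRU checkpoint
#'
#' Writes the model spec, training configuration and every weight array to
#' a single JSON file at full double precision.
#'
#' @param model A `cnn_gru` model.
#' @param path Checkpoint path (`.json`).
#' @return `write_model()` returns `path` invisibly; `read_model()` the
#'   reconstructed model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cnn_gru"))
  obj <- list(spec = unclass(model$spec),
              train_cfg = if (!is.null(model$train_cfg))
                unclass(model$train_cfg) else NULL,
              trained = model$trained,
              loss_trace = model$loss_trace,
              params = serialize_arrays(model$params))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("record not found")
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  spec <- do.call(model_spec, lapply(obj$spec, unlist))
  params <- deserialize_arrays(obj$params)
  params$gru <- lapply(params$gru, function(w) do.call(gru_weights, w))
  model <- structure(list(spec = spec, params = params,
                          trained = isTRUE(obj$trained),
                          loss_trace = as.numeric(unlist(obj$loss_trace))),
                     class = "cnn_gru")
  if (!is.null(obj$train_cfg))
    model$train_cfg <- do.call(train_config, lapply(obj$train_cfg, unlist))
  model
}
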