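#' GRU cell weights
#'
#' Container for the six weight matrices and three bias vectors of a gated
#' recurrent unit. Input-to-gate maps (`Wxr`, `Wxz`, `Wxh`) are
#' `input_size x hidden_size`; hidden-to-gate maps (`Whr`, `Whz`, `Whh`) are
#' `hidden_size x hidden_size`; biases have length `hidden_size`.
#'
#' @param Wxr,Wxz,Wxh Input-to-reset/update/candidate weight matrices.
#' @param Whr,Whz,Whh Hidden-to-reset/update/candidate weight matrices.
#' @param br,bz,bh Bias vectors.
#' @return An object of class `gru_weights`.
#' @export
gru_weights <- function(Wxr, Whr, Wxz, Whz, Wxh, Whh, br, bz, bh) {
  w <- list(Wxr = as.matrix(Wxr), Whr = as.matrix(Whr),
            Wxz = as.matrix(Wxz), Whz = as.matrix(Whz),
            Wxh = as.matrix(Wxh), Whh = as.matrix(Whh),
            br = as.numeric(br), bz = as.numeric(bz), bh = as.numeric(bh))
  H <- length(w$br)
  D <- nrow(w$Wxr)
  ok <- all(vapply(w[c("Wxr", "Wxz", "Wxh")], function(m)
    identical(dim(m), c(D, H)), TRUE)) &&
    all(vapply(w[c("Whr", "Whz", "Whh")], function(m)
      identical(dim(m), c(H, H)), TRUE)) &&
    length(w$bz) == H && length(w$bh) == H
  if (!ok) stop("GRU shape mismatch")
  if (!all(vapply(w, function(m) all(is.finite(m)), TRUE)))
    stop("non-finite sample")
  structure(w, class = "gru_weights")
}

random_gru_weights <- function(input_size, hidden_size, scale = 0.5) {
  m <- function(a, b) matrix(stats::runif(a * b, -scale, scale), a, b)
  gru_weights(m(input_size, hidden_size), m(hidden_size, hidden_size),
              m(input_size, hidden_size), m(hidden_size, hidden_size),
              m(input_size, hidden_size), m(hidden_size, hidden_size),
              stats::runif(hidden_size, -scale, scale),
              stats::runif(hidden_size, -scale, scale),
              stats::runif(hidden_size, -scale, scale))
}

#' One reference GRU step
#'
#' Direct evaluation of the four printed GRU update formulas, used as the
#' conformance reference for the trainable recurrent layer:
#' \deqn{r_t = \sigma(W_{xr} x_t + W_{hr} h_{t-1} + b_r)}
#' \deqn{z_t = \sigma(W_{xz} x_t + W_{hz} h_{t-1} + b_z)}
#' \deqn{\tilde h_t = \tanh(W_{xh} x_t + W_{hh} (r_t \odot h_{t-1}) + b_h)}
#' \deqn{h_t = z_t \odot h_{t-1} + (1 - z_t) \odot \tilde h_t}
#' Note the update-gate convention: `z_t` weights the carried-over hidden
#' state, `1 - z_t` the candidate.
#'
#' @param x_t Input vector at time t (length `input_size`).
#' @param h_prev Hidden state at time t-1 (length `hidden_size`).
#' @param w A [gru_weights()] object.
#' @return The new hidden state `h_t` (length `hidden_size`).
#' @export
gru_step <- function(x_t, h_prev, w) {
  stopifnot(inherits(w, "gru_weights"))
  x_t <- as.numeric(x_t); h_prev <- as.numeric(h_prev)
  if (length(x_t) != nrow(w$Wxr) || length(h_prev) != length(w$br))
    stop("GRU shape mismatch")
  r <- sigmoid(drop(x_t %*% w$Wxr) + drop(h_prev %*% w$Whr) + w$br)
  z <- sigmoid(drop(x_t %*% w$Wxz) + drop(h_prev %*% w$Whz) + w$bz)
  hb <- tanh(drop(x_t %*% w$Wxh) + drop((r * h_prev) %*% w$Whh) + w$bh)
  z * h_prev + (1 - z) * hb
}
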