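#' Initialise the attention-MIL parameter set
#'
#' The aggregation head applied on top of frozen tile features: two fully
#' connected layers (D -> 512 -> 128 by default) with rectified-linear
#' activations, a self-attention layer with query/key maps `W_f`, `W_g`
#' (128 -> d_attn) and a trainable scalar `gamma` (initialised to 1), and a
#' final 128 -> 2 classification layer. Weights are He-initialised for the
#' rectified layers and Xavier-initialised elsewhere; biases start at zero.
#'
#' @param input_dim tile feature dimension D.
#' @param hidden widths of the two fully connected layers.
#' @param d_attn width of the attention query/key maps.
#' @param seed seed for the initialisation.
#' @return Object of class `mil_params`: list with `W1`, `b1`, `W2`, `b2`,
#'   `Wf`, `Wg`, `gamma`, `Wo`, `bo`.
#' @export
mil_params <- function(input_dim, hidden = c(512L, 128L), d_attn = 16L,
                       seed = 1L) {
  input_dim <- check_scalar_int(input_dim, "input_dim")
  d_attn <- check_scalar_int(d_attn, "d_attn")
  stopifnot(length(hidden) == 2L)
  withr::with_seed(seed, {
    p <- list(
      W1 = matrix(stats::rnorm(input_dim * hidden[1], sd = sqrt(2 / input_dim)),
                  input_dim, hidden[1]),
      b1 = numeric(hidden[1]),
      W2 = matrix(stats::rnorm(hidden[1] * hidden[2], sd = sqrt(2 / hidden[1])),
                  hidden[1], hidden[2]),
      b2 = numeric(hidden[2]),
      Wf = matrix(stats::rnorm(hidden[2] * d_attn, sd = sqrt(1 / hidden[2])),
                  hidden[2], d_attn),
      Wg = matrix(stats::rnorm(hidden[2] * d_attn, sd = sqrt(1 / hidden[2])),
                  hidden[2], d_attn),
      gamma = 1,
      Wo = matrix(stats::rnorm(hidden[2] * 2L, sd = sqrt(1 / hidden[2])),
                  hidden[2], 2L),
      bo = numeric(2L)
    )
  })
  structure(p, class = "mil_params")
}

#' Self-attention forward pass over a bag's hidden features
#'
#' Given the N x 128 hidden representation h, computes queries `f = h W_f`
#' and keys `g = h W_g`, pairwise scores `s[j, i] = f(h_i) . g(h_j)`, and the
#' attention matrix `alpha` by softmax over the input index i within each
#' output row j (each output attends over all tiles, so rows of `alpha` sum
#' to 1). Per-tile outputs are `o_j = sum_i alpha[j, i] h_i`, residual tile
#' features `y = h + gamma * o`, and the pooled global vector is the mean of
#' the residual rows.
#'
#' @param h N x d numeric matrix of per-tile hidden features.
#' @param params a [mil_params()] (only `Wf`, `Wg`, `gamma` are used).
#' @return Object of class `attention_state`: `alpha` (N x N,
#'   row-stochastic), `o` (N x d), `y_tiles` (N x d), `y_global` (d-vector).
#' @export
attention_forward <- function(h, params) {
  h <- as.matrix(h)
  if (!all(is.finite(h))) stop_arg("non-finite values in attention input")
  f <- h %*% params$Wf
  g <- h %*% params$Wg
  s <- g %*% t(f)                      # s[j, i] = f(h_i) . g(h_j)
  alpha <- softmax_rows(s)
  o <- alpha %*% h
  y_tiles <- h + params$gamma * o
  structure(list(alpha = alpha, o = o, y_tiles = y_tiles,
                 y_global = colMeans(y_tiles)),
            class = "attention_state")
}

# full forward pass keeping intermediates for backprop
mil_forward_full <- function(x, p) {
  if (!all(is.finite(x))) stop_arg("non-finite values in bag features")
  if (ncol(x) != nrow(p$W1))
    stop_arg(sprintf("bag feature dimension %d does not match model input %d",
                     ncol(x), nrow(p$W1)))
  z1 <- sweep(x %*% p$W1, 2L, p$b1, "+")
  a1 <- relu(z1)
  z2 <- sweep(a1 %*% p$W2, 2L, p$b2, "+")
  h <- relu(z2)
  f <- h %*% p$Wf
  g <- h %*% p$Wg
  alpha <- softmax_rows(g %*% t(f))
  o <- alpha %*% h
  y_tiles <- h + p$gamma * o
  y <- colMeans(y_tiles)
  logits <- drop(y %*% p$Wo) + p$bo
  prob <- exp(logits - max(logits))
  prob <- prob / sum(prob)
  list(z1 = z1, a1 = a1, z2 = z2, h = h, f = f, g = g, alpha = alpha, o = o,
       y_tiles = y_tiles, y = y, logits = logits, prob = prob)
}

#' Forward pass of the full model on one bag
#'
#' Per-tile features pass through the two rectified fully connected layers,
#' the self-attention layer, mean pooling, and the final classification
#' layer with a two-class softmax. The prediction is invariant to the order
#' of tiles within the bag.
#'
#' @param bag a [feature_bag()] or bare N x D feature matrix.
#' @param params a [mil_params()] with matching input dimension.
#' @return List with `prob` (named 2-vector, classes "negative"/"positive"),
#'   `logits`, and `state` (the [attention_forward()] result).
#' @export
model_forward <- function(bag, params) {
  x <- if (inherits(bag, "feature_bag")) bag$features else as.matrix(bag)
  fw <- mil_forward_full(x, params)
  list(prob = stats::setNames(fw$prob, c("negative", "positive")),
       logits = fw$logits,
       state = structure(list(alpha = fw$alpha, o = fw$o,
                              y_tiles = fw$y_tiles, y_global = fw$y),
                         class = "attention_state"))
}

#' Per-tile importance weights from an attention state
#'
#' The weight of tile i is `beta_i = 1 + gamma * sum_j alpha[j, i]` — one
#' plus gamma times the attention the tile receives from all outputs (the
#' column sum of the row-stochastic attention matrix). The weights total
#' `N * (1 + gamma)`.
#'
#' @param state an `attention_state` (or a bare row-stochastic alpha matrix).
#' @param gamma the model's attention scale.
#' @return Object of class `tile_weights`: numeric `beta` vector plus the
#'   `gamma` used.
#' @export
tile_weights <- function(state, gamma) {
  alpha <- if (inherits(state, "attention_state")) state$alpha else as.matrix(state)
  structure(list(beta = 1 + gamma * colSums(alpha), gamma = gamma),
            class = "tile_weights")
}

# analytic gradients of the cross-entropy loss for one bag
mil_backward <- function(x, label, fw, p) {
  N <- nrow(x)
  target <- c(1 - label, label)
  dlogits <- fw$prob - target
  dWo <- outer(fw$y, dlogits)
  dbo <- dlogits
  dy <- drop(p$Wo %*% dlogits)
  dYt <- matrix(dy / N, N, length(dy), byrow = TRUE)   # y = colMeans(y_tiles)
  dh <- dYt
  dO <- p$gamma * dYt
  dgamma <- sum(dYt * fw$o)
  dalpha <- dO %*% t(fw$h)
  dh <- dh + t(fw$alpha) %*% dO
  # softmax rows: ds[j,] = alpha[j,] * (dalpha[j,] - sum_i alpha[j,i] dalpha[j,i])
  ds <- fw$alpha * (dalpha - rowSums(fw$alpha * dalpha))
  dg <- ds %*% fw$f                                    # s = g f^T
  df <- t(ds) %*% fw$g
  dWf <- t(fw$h) %*% df
  dWg <- t(fw$h) %*% dg
  dh <- dh + df %*% t(p$Wf) + dg %*% t(p$Wg)
  dz2 <- dh * (fw$z2 > 0)
  dW2 <- t(fw$a1) %*% dz2
  db2 <- colSums(dz2)
  dz1 <- (dz2 %*% t(p$W2)) * (fw$z1 > 0)
  dW1 <- t(x) %*% dz1
  db1 <- colSums(dz1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, Wf = dWf, Wg = dWg,
       gamma = dgamma, Wo = dWo, bo = dbo)
}
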