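#' Single GRU cell update (reference implementation)
#'
#' The standard gated-recurrent-unit update used as the basic unit of the
#' recurrent feature extractor:
#' \deqn{z_t = \sigma(W_z x_t + U_z h_{prev} + b_z)}
#' \deqn{r_t = \sigma(W_r x_t + U_r h_{prev} + b_r)}
#' \deqn{\tilde h_t = \tanh(W_c x_t + U_c (r_t \odot h_{prev}) + b_c)}
#' \deqn{h_t = (1 - z_t) \odot h_{prev} + z_t \odot \tilde h_t}
#' The update gate `z` controls how much of the previous state is replaced;
#' the reset gate `r` controls how much of it feeds the candidate state.
#'
#' This plain-R implementation defines the cell semantics; the batched
#' compiled extractor is required to agree with compositions of it.
#'
#' @param x Input vector (length `in_dim`) or matrix (`in_dim` x batch).
#' @param h_prev Previous hidden state, vector (length `H`) or matrix
#'   (`H` x batch).
#' @param params List with `W` (`3H` x `in_dim`), `U` (`3H` x `H`), `b`
#'   (length `3H`), gate rows stacked in the order z, r, candidate.
#' @return The new hidden state, same shape as `h_prev`.
#' @export
gru_step <- function(x, h_prev, params) {
  x <- as.matrix(x)
  h_prev <- as.matrix(h_prev)
  H <- nrow(h_prev)
  if (nrow(params$W) != 3 * H || ncol(params$W) != nrow(x) ||
      nrow(params$U) != 3 * H || ncol(params$U) != H ||
      length(params$b) != 3 * H || ncol(x) != ncol(h_prev)) {
    stop("parameter/input shapes are inconsistent", call. = FALSE)
  }
  a <- params$W %*% x + params$b
  zi <- 1:H; ri <- (H + 1):(2 * H); ci <- (2 * H + 1):(3 * H)
  z <- plogis(a[zi, , drop = FALSE] + params$U[zi, , drop = FALSE] %*% h_prev)
  r <- plogis(a[ri, , drop = FALSE] + params$U[ri, , drop = FALSE] %*% h_prev)
  cand <- tanh(a[ci, , drop = FALSE] +
               params$U[ci, , drop = FALSE] %*% (r * h_prev))
  (1 - z) * h_prev + z * cand
}

#' Dilated recurrent network configuration
#'
#' Architecture of the feature extractor: a 4-layer GRU stack with 50
#' neurons per layer by default, exponentially increasing dilations
#' (1, 2, 4, 8) so deeper layers skip further back in time, and a linear
#' readout of the last layer's final state to `feature_dim` dimensions.
#'
#' @param n_layers Number of layers.
#' @param hidden_size Neurons per layer.
#' @param dilations Integer dilations, one per layer (>= 1).
#' @param feature_dim Dimension of the deep feature space (default 32; use
#'   2 for direct feature-space visualization).
#' @param pool Number of final top-layer states averaged by the readout.
#'   The default, the top layer's dilation, covers each of its recurrence
#'   chains exactly once.
#' @return An object of class `drnn_config`.
#' @export
drnn_config <- function(n_layers = 4, hidden_size = 50,
                        dilations = 2^(seq_len(n_layers) - 1),
                        feature_dim = 32,
                        pool = dilations[length(dilations)]) {
  stop_if_not_scalar_num(n_layers, "n_layers", 1)
  stop_if_not_scalar_num(hidden_size, "hidden_size", 1)
  stop_if_not_scalar_num(feature_dim, "feature_dim", 1)
  stop_if_not_scalar_num(pool, "pool", 1)
  dilations <- as.integer(dilations)
  if (length(dilations) != n_layers || any(dilations < 1)) {
    stop("`dilations` must have one entry >= 1 per layer", call. = FALSE)
  }
  structure(list(n_layers = as.integer(n_layers),
                 hidden_size = as.integer(hidden_size),
                 dilations = dilations,
                 feature_dim = as.integer(feature_dim),
                 pool = as.integer(pool)),
            class = "drnn_config")
}

# Uniform(-a, a) initialization with a = 1/sqrt(hidden), drawn from the
# current RNG stream so training is reproducible from one seed.
init_drnn_params <- function(config, input_dim = 1) {
  H <- config$hidden_size
  a <- 1 / sqrt(H)
  lay <- function(in_dim) {
    list(W = matrix(stats::runif(3 * H * in_dim, -a, a), 3 * H, in_dim),
         U = matrix(stats::runif(3 * H * H, -a, a), 3 * H, H),
         b = numeric(3 * H))
  }
  layers <- vector("list", config$n_layers)
  layers[[1]] <- lay(input_dim)
  if (config$n_layers > 1) {
    for (l in 2:config$n_layers) layers[[l]] <- lay(H)
  }
  readout <- list(
    W_out = matrix(stats::runif(config$feature_dim * H, -a, a),
                   config$feature_dim, H),
    b_out = numeric(config$feature_dim))
  list(layers = layers, readout = readout)
}

#' Forward pass of the dilated recurrent feature extractor
#'
#' Runs the batched compiled extractor: layer `l` updates its hidden state
#' from the state `dilations[l]` steps back, and the feature vector is the
#' linear readout of the last layer's final state. With all dilations equal
#' to 1 this is an ordinary stacked GRU.
#'
#' @param X Sequence matrix, `T` x `batch` (a single sequence may be given
#'   as a vector).
#' @param params Parameter list from the internal initializer or a trained
#'   model (`$layers`, `$readout`).
#' @param dilations Integer dilations per layer.
#' @param pool Number of final top-layer states averaged before the linear
#'   readout (1 = plain final state).
#' @return List with `features` (`feature_dim` x batch) and `h_last`
#'   (`hidden` x batch, pooled).
#' @export
dilated_forward <- function(X, params, dilations, pool = 1) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  out <- cpp_drnn_forward(params$layers, X, as.integer(dilations), FALSE,
                          as.integer(pool))
  f <- params$readout$W_out %*% out$h_last + params$readout$b_out
  list(features = f, h_last = out$h_last)
}

#' Number of trainable parameters of a dilated RNN
#'
#' Dilation changes only the recurrent connectivity pattern, not the number
#' of weights, so the count depends only on layer sizes.
#'
#' @param config A [drnn_config()].
#' @param input_dim Input dimension per time step (1 for raw signals).
#' @param n_classes Classes of the softmax head (0 to count the extractor
#'   plus readout only).
#' @return Integer parameter count.
#' @export
drnn_n_params <- function(config, input_dim = 1, n_classes = 0) {
  H <- config$hidden_size
  n <- 3 * H * (input_dim + H + 1)
  if (config$n_layers > 1) n <- n + (config$n_layers - 1) * 3 * H * (2 * H + 1)
  n <- n + config$feature_dim * (H + 1)
  if (n_classes > 0) n <- n + n_classes * (config$feature_dim + 1)
  as.integer(n)
}
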