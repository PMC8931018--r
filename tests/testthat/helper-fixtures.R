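# Shared fixtures, memoised so expensive objects are built once per run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small, well-separated 3-class dataset for fast model tests
tiny_dataset <- function() {
  fixture("tiny_dataset", function() {
    make_dataset(n_classes = 3, n_per_class = 12,
                 templates = builtin_templates("fruits")[c("Date", "Banana", "Lemon")],
                 base_seed = 11)
  })
}

tiny_net <- function(feature_dim = 4) {
  drnn_config(n_layers = 2, hidden_size = 8, dilations = c(1, 2),
              feature_dim = feature_dim)
}

tiny_config <- function(epochs = 30, ...) {
  train_config(epochs = epochs, input_len = 48, seed = 5, batch_size = 8,
               learning_rate = 3e-3, ...)
}

# model trained to convergence on the tiny separable dataset
tiny_trained <- function() {
  fixture("tiny_trained", function() {
    train_lip_model(tiny_dataset(), tiny_config(epochs = 50), tiny_net())
  })
}

# elementwise scalar recomputation of the GRU update: the independent
# oracle against which gru_step and the compiled extractor are checked
gru_step_scalar <- function(x, h_prev, params) {
  H <- length(h_prev)
  h_new <- numeric(H)
  # gates first: the candidate needs the whole reset vector
  z <- r <- numeric(H)
  for (i in seq_len(H)) {
    z[i] <- 1 / (1 + exp(-(sum(params$W[i, ] * x) +
                           sum(params$U[i, ] * h_prev) + params$b[i])))
    r[i] <- 1 / (1 + exp(-(sum(params$W[H + i, ] * x) +
                           sum(params$U[H + i, ] * h_prev) + params$b[H + i])))
  }
  for (i in seq_len(H)) {
    cand <- tanh(sum(params$W[2 * H + i, ] * x) +
                 sum(params$U[2 * H + i, ] * (r * h_prev)) + params$b[2 * H + i])
    h_new[i] <- (1 - z[i]) * h_prev[i] + z[i] * cand
  }
  h_new
}

# naive stacked/dilated GRU assembled from gru_step calls
naive_drnn_forward <- function(X, params, dilations, hidden) {
  X <- as.matrix(X)
  inp <- lapply(seq_len(nrow(X)), function(t) matrix(X[t, ], 1, ncol(X)))
  for (l in seq_along(params$layers)) {
    Hs <- vector("list", nrow(X))
    for (t in seq_len(nrow(X))) {
      hp <- if (t - dilations[l] >= 1) Hs[[t - dilations[l]]]
            else matrix(0, hidden, ncol(X))
      Hs[[t]] <- gru_step(inp[[t]], hp, params$layers[[l]])
    }
    inp <- Hs
  }
  params$readout$W_out %*% Hs[[nrow(X)]] + params$readout$b_out
}
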