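#' Training configuration
#'
#' Hyperparameters of the end-to-end classifier training: the study
#' protocol trains for 500 epochs on an 80/20 split with either the
#' prototype-learning head or the softmax baseline. Optimization uses
#' adaptive moment estimation (learning rate 1e-3, batch 32). `lambda`
#' weights the prototype pull term and `gamma` scales the distance-based
#' logits.
#'
#' @param epochs Training epochs (default 500).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param lambda Prototype-loss weight (default 0.01).
#' @param gamma Distance scale of the prototype logits (default 1).
#' @param head `"prototype"` or `"softmax"`.
#' @param seed RNG seed controlling initialization and batching.
#' @param input_len Fixed sequence length fed to the network (see
#'   [to_model_input()]).
#' @param cutoff_hz Low-pass cut-off of the conditioning chain.
#' @param eval_every Evaluate test accuracy every this many epochs (the
#'   final epoch is always evaluated; other epochs record `NA`).
#' @param trim Trim each signal to its active span before resampling (see
#'   `condition_signal`); `FALSE` resamples the whole record.
#' @param lr_decay `"cosine"` anneals the learning rate to 10% of its
#'   initial value over the run; `"none"` keeps it constant.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 500, batch_size = 32, learning_rate = 1e-3,
                         lambda = 0.01, gamma = 1,
                         head = c("prototype", "softmax"), seed = 1,
                         input_len = 1000, cutoff_hz = 20, eval_every = 1,
                         trim = FALSE, lr_decay = c("cosine", "none")) {
  stop_if_not_scalar_num(epochs, "epochs", 1)
  stop_if_not_scalar_num(batch_size, "batch_size", 1)
  stop_if_not_scalar_num(learning_rate, "learning_rate", lower = 1e-12)
  stop_if_not_scalar_num(lambda, "lambda", 0)
  stop_if_not_scalar_num(gamma, "gamma", lower = 1e-12)
  head <- match.arg(head)
  lr_decay <- match.arg(lr_decay)
  stop_if_not_scalar_num(eval_every, "eval_every", 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lambda = lambda, gamma = gamma,
                 head = head, seed = as.integer(seed),
                 input_len = as.integer(input_len), cutoff_hz = cutoff_hz,
                 eval_every = as.integer(eval_every), trim = isTRUE(trim),
                 lr_decay = lr_decay),
            class = "train_config")
}

#' Prototype-matching class probabilities
#'
#' Distance-based classification: the probability of class `k` is
#' proportional to `exp(-gamma * ||f - m_k||^2)`, so the most probable
#' class is the one whose prototype is nearest in feature space (ties go to
#' the lowest class index in `which.max`).
#'
#' @param features Feature vector (length `feature_dim`) or matrix
#'   (`feature_dim` x batch).
#' @param prototypes `K` x `feature_dim` matrix of class prototypes.
#' @param gamma Positive distance scale.
#' @return `K` x batch matrix of class probabilities (columns sum to 1).
#' @export
prototype_logits <- function(features, prototypes, gamma = 1) {
  f <- as.matrix(features)
  if (!is.matrix(prototypes) || nrow(prototypes) == 0) {
    stop("`prototypes` must be a non-empty K x feature_dim matrix", call. = FALSE)
  }
  if (ncol(prototypes) != nrow(f)) stop("feature dimension mismatch", call. = FALSE)
  stop_if_not_scalar_num(gamma, "gamma", lower = 1e-12)
  d2 <- sq_dists(f, prototypes)
  softmax_cols(-gamma * d2)
}

# K x B matrix of squared Euclidean distances ||f_b - m_k||^2
sq_dists <- function(f, M) {
  d2 <- matrix(colSums(f^2), nrow(M), ncol(f), byrow = TRUE) +
    rowSums(M^2) - 2 * (M %*% f)
  pmax(d2, 0)
}

softmax_cols <- function(logits) {
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  sweep(e, 2, colSums(e), "/")
}

# Prototype head: distance-based cross-entropy plus the prototype pull term
# lambda * ||f - m_y||^2. Returns loss, dL/df, head-parameter grads, preds.
proto_head <- function(f, y, M, gamma, lambda) {
  B <- ncol(f)
  K <- nrow(M)
  d2 <- sq_dists(f, M)
  p <- softmax_cols(-gamma * d2)
  Y <- matrix(0, K, B)
  Y[cbind(y, seq_len(B))] <- 1
  loss <- -mean(log(pmax(p[cbind(y, seq_len(B))], 1e-300))) +
    lambda * mean(d2[cbind(y, seq_len(B))])
  dlogits <- (p - Y) / B
  dD2 <- -gamma * dlogits + (lambda / B) * Y
  s <- colSums(dD2)
  dF <- 2 * (sweep(f, 2, s, "*") - t(M) %*% dD2)
  dM <- -2 * (dD2 %*% t(f) - rowSums(dD2) * M)
  list(loss = loss, dF = dF, dhead = list(M = dM),
       preds = max.col(t(-d2), ties.method = "first"))
}

# Softmax baseline head: linear layer + cross-entropy.
softmax_head <- function(f, y, W, b) {
  B <- ncol(f)
  K <- nrow(W)
  logits <- W %*% f + b
  p <- softmax_cols(logits)
  Y <- matrix(0, K, B)
  Y[cbind(y, seq_len(B))] <- 1
  loss <- -mean(log(pmax(p[cbind(y, seq_len(B))], 1e-300)))
  dlogits <- (p - Y) / B
  list(loss = loss, dF = t(W) %*% dlogits,
       dhead = list(W = dlogits %*% t(f), b = rowSums(dlogits)),
       preds = max.col(t(logits), ties.method = "first"))
}

# Loss and full analytic gradient for one batch; the single code path used
# by both training and the finite-difference gradient checks.
loss_and_grad <- function(params, Xb, yb, config, net, want_grad = TRUE) {
  fwd <- cpp_drnn_forward(params$layers, Xb, net$dilations, want_grad, net$pool)
  h <- fwd$h_last
  f <- params$readout$W_out %*% h + params$readout$b_out
  hd <- if (config$head == "prototype") {
    proto_head(f, yb, params$head$M, config$gamma, config$lambda)
  } else {
    softmax_head(f, yb, params$head$W, params$head$b)
  }
  if (!want_grad) {
    return(list(loss = hd$loss, preds = hd$preds, features = f))
  }
  dh <- t(params$readout$W_out) %*% hd$dF
  grad <- list(layers = cpp_drnn_backward(params$layers, Xb, fwd$cache, dh,
                                          net$dilations, net$pool),
               readout = list(W_out = hd$dF %*% t(h), b_out = rowSums(hd$dF)),
               head = hd$dhead)
  list(loss = hd$loss, grad = grad, preds = hd$preds, features = f)
}

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(flesh, skel) {
  i <- 0L
  rec <- function(s) {
    if (is.list(s)) return(lapply(s, rec))
    n <- length(s)
    v <- flesh[(i + 1L):(i + n)]
    i <<- i + n
    if (is.matrix(s)) matrix(v, nrow(s), ncol(s)) else v
  }
  rec(skel)
}

# forward-only features/predictions in memory-bounded chunks
forward_in_chunks <- function(params, X, net, chunk = 512L) {
  n <- ncol(X)
  feats <- NULL
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    f <- dilated_forward(X[, i0:i1, drop = FALSE], params, net$dilations,
                         net$pool)$features
    feats <- if (is.null(feats)) f else cbind(feats, f)
  }
  feats
}

head_predict <- function(params, feats, config) {
  if (config$head == "prototype") {
    d2 <- sq_dists(feats, params$head$M)
    max.col(t(-d2), ties.method = "first")
  } else {
    logits <- params$head$W %*% feats + params$head$b
    max.col(t(logits), ties.method = "first")
  }
}

#' Train the lip-motion classifier
#'
#' End-to-end seeded training of the dilated GRU feature extractor with
#' either the prototype-learning head (distance-based cross-entropy plus a
#' prototype pull term) or the softmax baseline. Prototypes are initialized
#' to the class means of the untrained features and then optimized jointly
#' with the extractor by Adam. Per-epoch train accuracy (over the epoch's
#' minibatch predictions) and test accuracy are recorded.
#'
#' @param dataset A `lip_dataset` from [make_dataset()] (uses its
#'   train/test split tags), or a list with elements `X` (input matrix
#'   `input_len` x n, already conditioned), `y` (integer labels), `split`
#'   (character vector of `"train"`/`"test"`), `labels` (class names).
#' @param config A [train_config()].
#' @param net A [drnn_config()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `lip_model`: parameters, configs, label set,
#'   and `curves` (data frame `epoch`, `train_acc`, `test_acc`, `loss`).
#' @export
train_lip_model <- function(dataset, config = train_config(),
                            net = drnn_config(), verbose = FALSE) {
  prep <- prepare_training_data(dataset, config)
  X <- prep$X; y <- prep$y; split <- prep$split; labels <- prep$labels
  K <- length(labels)
  tr <- which(split == "train")
  te <- which(split == "test")
  if (length(tr) == 0 || length(te) == 0) {
    stop("dataset must contain both train and test entries", call. = FALSE)
  }
  with_seed(config$seed, {
    params <- init_drnn_params(net, input_dim = 1)
    params$head <- if (config$head == "prototype") {
      # class-mean initialization in the untrained feature space
      f0 <- forward_in_chunks(params, X[, tr, drop = FALSE], net)
      M0 <- t(vapply(seq_len(K), function(k) {
        rowMeans(f0[, y[tr] == k, drop = FALSE])
      }, numeric(net$feature_dim)))
      list(M = M0)
    } else {
      a <- 1 / sqrt(net$feature_dim)
      list(W = matrix(stats::runif(K * net$feature_dim, -a, a), K, net$feature_dim),
           b = numeric(K))
    }
    skel <- params
    theta <- flatten_params(params)
    m <- numeric(length(theta)); v <- numeric(length(theta))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0L
    curves <- data.frame(epoch = integer(0), train_acc = numeric(0),
                         test_acc = numeric(0), loss = numeric(0))
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr)
      correct <- 0L
      ep_loss <- 0
      nb <- 0L
      for (i0 in seq(1L, length(ord), by = config$batch_size)) {
        i1 <- min(i0 + config$batch_size - 1L, length(ord))
        ix <- ord[i0:i1]
        lg <- loss_and_grad(params, X[, ix, drop = FALSE], y[ix], config, net)
        correct <- correct + sum(lg$preds == y[ix])
        ep_loss <- ep_loss + lg$loss
        nb <- nb + 1L
        g <- flatten_params(lg$grad)
        step <- step + 1L
        lr <- config$learning_rate
        if (config$lr_decay == "cosine") {
          frac <- (ep - 1) / max(1L, config$epochs - 1L)
          lr <- lr * (0.1 + 0.9 * 0.5 * (1 + cos(pi * frac)))
        }
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g^2
        mhat <- m / (1 - b1^step)
        vhat <- v / (1 - b2^step)
        theta <- theta - lr * mhat / (sqrt(vhat) + eps)
        params <- unflatten_params(theta, skel)
      }
      test_acc <- NA_real_
      if (ep %% config$eval_every == 0L || ep == config$epochs) {
        feats_te <- forward_in_chunks(params, X[, te, drop = FALSE], net)
        test_acc <- mean(head_predict(params, feats_te, config) == y[te])
      }
      curves <- rbind(curves, data.frame(
        epoch = ep, train_acc = correct / length(ord),
        test_acc = test_acc, loss = ep_loss / nb))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  train %.3f  test %.3f",
                        ep, ep_loss / nb, correct / length(ord), test_acc))
      }
    }
    structure(list(params = params, config = config, net = net,
                   labels = labels, curves = curves, trained = TRUE),
              class = "lip_model")
  })
}

# Accepts a lip_dataset or a pre-conditioned list(X, y, split, labels).
prepare_training_data <- function(dataset, config) {
  if (inherits(dataset, "lip_dataset")) {
    X <- vapply(dataset$utterances, function(u) {
      condition_signal(u$lip, config$cutoff_hz, config$input_len,
                       trim = config$trim)
    }, numeric(config$input_len))
    labels <- dataset$params$labels
    y <- match(dataset$manifest$label, labels)
    list(X = X, y = y, split = dataset$manifest$split, labels = labels)
  } else if (is.list(dataset) && all(c("X", "y", "split") %in% names(dataset))) {
    labels <- if (!is.null(dataset$labels)) dataset$labels
              else as.character(sort(unique(dataset$y)))
    list(X = as.matrix(dataset$X), y = as.integer(dataset$y),
         split = dataset$split, labels = labels)
  } else {
    stop("`dataset` must be a lip_dataset or a list(X, y, split)", call. = FALSE)
  }
}

#' @export
print.lip_model <- function(x, ...) {
  n <- nrow(x$curves)
  cat(sprintf("<lip_model> %s head, %d classes, %d epochs, final test accuracy %.2f%%\n",
              x$config$head, length(x$labels), n,
              100 * x$curves$test_acc[n]))
  invisible(x)
}

#' Classify lip-motion waveforms with a trained model
#'
#' Applies the model's own conditioning chain (low-pass, normalize, fixed
#' length), runs the feature extractor and classifies with the trained
#' head. With a prototype head and a `reject_threshold`, inputs whose
#' nearest-prototype distance exceeds the threshold are flagged as rejected
#' (open-set decision).
#'
#' @param object A trained `lip_model`.
#' @param newdata A [waveform()], an `utterance`, a `lip_dataset`, or a
#'   list of waveforms/utterances.
#' @param reject_threshold Optional open-set distance threshold (prototype
#'   head only).
#' @param ... Unused.
#' @return Data frame with one row per input: `label`, `prob` (probability
#'   of the predicted class), `dist` (nearest-prototype distance; `NA` for
#'   the softmax head) and `rejected`. The feature matrix is attached as
#'   attribute `"features"`.
#' @export
predict.lip_model <- function(object, newdata, reject_threshold = NULL, ...) {
  if (is.null(object$trained) || !object$trained) {
    stop("model has not been trained", call. = FALSE)
  }
  ws <- as_waveform_list(newdata)
  X <- vapply(ws, function(w) {
    condition_signal(w, object$config$cutoff_hz, object$config$input_len,
                     trim = object$config$trim)
  }, numeric(object$config$input_len))
  X <- matrix(X, nrow = object$config$input_len)
  feats <- forward_in_chunks(object$params, X, object$net)
  if (object$config$head == "prototype") {
    d2 <- sq_dists(feats, object$params$head$M)
    p <- softmax_cols(-object$config$gamma * d2)
    ix <- max.col(t(-d2), ties.method = "first")
    dmin <- sqrt(d2[cbind(ix, seq_len(ncol(d2)))])
    rejected <- if (is.null(reject_threshold)) rep(FALSE, length(ix))
                else dmin > reject_threshold
  } else {
    logits <- object$params$head$W %*% feats + object$params$head$b
    p <- softmax_cols(logits)
    ix <- max.col(t(logits), ties.method = "first")
    dmin <- rep(NA_real_, length(ix))
    rejected <- rep(FALSE, length(ix))
  }
  out <- data.frame(label = object$labels[ix],
                    prob = p[cbind(ix, seq_along(ix))],
                    dist = dmin, rejected = rejected)
  attr(out, "features") <- feats
  out
}

as_waveform_list <- function(newdata) {
  if (inherits(newdata, "waveform")) return(list(newdata))
  if (inherits(newdata, "utterance")) return(list(newdata$lip))
  if (inherits(newdata, "lip_dataset")) {
    return(lapply(newdata$utterances, function(u) u$lip))
  }
  if (is.list(newdata)) {
    return(lapply(newdata, function(x) {
      if (inherits(x, "utterance")) x$lip
      else if (inherits(x, "waveform")) x
      else stop("list entries must be waveforms or utterances", call. = FALSE)
    }))
  }
  stop("unsupported `newdata` type", call. = FALSE)
}
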