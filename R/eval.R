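#' Confusion analysis of a trained classifier
#'
#' Row-normalized confusion matrix on a labeled evaluation set, with the
#' summary statistics used to read it: overall accuracy, per-class
#' accuracies (the diagonal) and the fractions of classes recognized with
#' exactly 100%, above 90% and above 80% accuracy. Rows are exact ratios
#' of counts, so each row sums to 1.
#'
#' @param model A trained `lip_model`.
#' @param dataset A `lip_dataset`.
#' @param split Which split tag to evaluate (default `"test"`).
#' @return An object of class `eval_report`: list with `confusion`
#'   (K x K, rows = true class), `accuracy`, `per_class`,
#'   `frac_100`, `frac_gt90`, `frac_gt80`, `n`.
#' @export
confusion_report <- function(model, dataset, split = "test") {
  stopifnot(inherits(model, "lip_model"), inherits(dataset, "lip_dataset"))
  ix <- which(dataset$manifest$split == split)
  if (length(ix) == 0) stop("no samples carry the requested split tag", call. = FALSE)
  truth <- factor(dataset$manifest$label[ix], levels = model$labels)
  if (anyNA(truth)) stop("dataset labels outside the model's label set", call. = FALSE)
  pred <- predict(model, dataset$utterances[ix])
  pred <- factor(pred$label, levels = model$labels)
  counts <- table(truth, pred)
  rs <- rowSums(counts)
  if (any(rs == 0)) stop("every class needs at least one evaluation sample", call. = FALSE)
  conf <- sweep(unclass(counts), 1, rs, "/")
  per_class <- diag(conf)
  structure(list(confusion = conf,
                 accuracy = sum(diag(counts)) / sum(counts),
                 per_class = per_class,
                 frac_100 = mean(per_class == 1),
                 frac_gt90 = mean(per_class > 0.9),
                 frac_gt80 = mean(per_class > 0.8),
                 n = length(ix)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> %d samples, overall accuracy %.2f%%\n",
                     "  classes at 100%% / >90%% / >80%% accuracy: ",
                     "%.0f%% / %.0f%% / %.0f%%\n"),
              x$n, 100 * x$accuracy, 100 * x$frac_100, 100 * x$frac_gt90,
              100 * x$frac_gt80))
  invisible(x)
}

#' Small-sample training sweep
#'
#' Probes data efficiency by retraining with the training split subsampled
#' to fixed fractions (stratified per class, seeded) while the test split
#' is untouched, for one or both classification heads. Each
#' (fraction, head) cell is run for several seeds; the median is the
#' headline number.
#'
#' @param dataset A `lip_dataset`.
#' @param fractions Training fractions in (0, 1], default
#'   `c(1, 0.8, 0.6, 0.4, 0.2)`.
#' @param config A [train_config()]; its `head` field is ignored.
#' @param net A [drnn_config()].
#' @param heads Heads to run (default both).
#' @param seeds Seeds to aggregate over (default 3).
#' @return An object of class `sweep_result`: `$runs` (data frame
#'   `fraction`, `head`, `seed`, `accuracy`) and `$summary` (median over
#'   seeds per fraction and head).
#' @export
small_sample_sweep <- function(dataset, fractions = c(1, 0.8, 0.6, 0.4, 0.2),
                               config = train_config(),
                               net = drnn_config(),
                               heads = c("prototype", "softmax"),
                               seeds = 1:3) {
  stopifnot(inherits(dataset, "lip_dataset"))
  if (any(fractions <= 0 | fractions > 1)) {
    stop("`fractions` must lie in (0, 1]", call. = FALSE)
  }
  heads <- match.arg(heads, c("prototype", "softmax"), several.ok = TRUE)
  prep <- prepare_training_data(dataset, config)
  tr <- which(prep$split == "train")
  runs <- expand.grid(fraction = fractions, head = heads, seed = seeds,
                      stringsAsFactors = FALSE)
  runs$accuracy <- NA_real_
  for (i in seq_len(nrow(runs))) {
    fr <- runs$fraction[i]
    keep <- if (fr == 1) tr else {
      with_seed(config$seed + 1000L * runs$seed[i], {
        unlist(lapply(split(tr, prep$y[tr]), function(ix) {
          n_keep <- max(1L, round(fr * length(ix)))
          sample(ix, n_keep)
        }), use.names = FALSE)
      })
    }
    if (min(table(prep$y[keep])) < 1) stop("fraction leaves a class empty", call. = FALSE)
    sub <- list(X = prep$X[, c(keep, which(prep$split == "test"))],
                y = prep$y[c(keep, which(prep$split == "test"))],
                split = rep(c("train", "test"),
                            c(length(keep), sum(prep$split == "test"))),
                labels = prep$labels)
    cfg <- config
    cfg$head <- runs$head[i]
    cfg$seed <- config$seed + runs$seed[i]
    fit <- train_lip_model(sub, cfg, net)
    runs$accuracy[i] <- fit$curves$test_acc[nrow(fit$curves)]
  }
  summary <- stats::aggregate(accuracy ~ fraction + head, data = runs,
                              FUN = stats::median)
  structure(list(runs = runs, summary = summary), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> median test accuracy by training fraction:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Two-dimensional feature map and class separability
#'
#' Extracts the per-sample feature vectors of a model trained with
#' `feature_dim = 2` (so the deep feature space can be plotted directly)
#' and summarizes class structure as the ratio of the mean between-class
#' to the mean within-class pairwise feature distance. Ratios well above 1
#' indicate interclass separability with intraclass compactness; an
#' untrained extractor sits near 1.
#'
#' @param model A `lip_model` (any feature dimension is accepted; 2 is the
#'   intended use).
#' @param dataset A `lip_dataset`.
#' @param split Split tag to embed (default `"train"`).
#' @return List with `points` (data frame `f1`, `f2`, ... , `label`) and
#'   `separability` (between/within distance ratio; `NA` with a warning if
#'   fewer than two classes are present).
#' @export
feature_map_2d <- function(model, dataset, split = "train") {
  stopifnot(inherits(model, "lip_model"), inherits(dataset, "lip_dataset"))
  ix <- which(dataset$manifest$split == split)
  pred <- predict(model, dataset$utterances[ix])
  feats <- attr(pred, "features")
  labels <- dataset$manifest$label[ix]
  pts <- as.data.frame(t(feats))
  names(pts) <- paste0("f", seq_len(ncol(pts)))
  pts$label <- labels
  ratio <- separability_ratio(feats, labels)
  list(points = pts, separability = ratio)
}

#' Between/within class distance ratio
#'
#' @param features `feature_dim` x n matrix.
#' @param labels Class label per column.
#' @return Mean between-class pairwise distance divided by mean
#'   within-class pairwise distance; `NA` (with a warning) if only one
#'   class is present.
#' @export
separability_ratio <- function(features, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    warning("separability undefined for a single class")
    return(NA_real_)
  }
  d <- as.matrix(stats::dist(t(features)))
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  mean(d[!is.na(same) & !same]) / mean(d[!is.na(same) & same])
}

#' Enroll a speaker for identity verification
#'
#' Builds the open-set verification policy from a speaker's enrollment
#' utterances of the pass phrase: the enrolled prototype is the mean
#' feature vector, and the acceptance threshold is calibrated on the
#' enrollment data as `q` times the 95th-percentile genuine distance (so
#' genuine attempts are accepted with high probability without any
#' impostor data).
#'
#' @param model A trained `lip_model` (feature extractor is reused; the
#'   classification head is not).
#' @param utterances List of the enrolled speaker's utterances (>= 2).
#' @param quantile_level Quantile of genuine distances used for the
#'   threshold (default 0.95).
#' @param margin Multiplier on the calibrated threshold (default 1.5,
#'   leaving headroom for held-out genuine attempts).
#' @return An object of class `verification_policy`: `prototype`, `tau`,
#'   `genuine_distances`.
#' @export
enroll_speaker <- function(model, utterances, quantile_level = 0.95,
                           margin = 1.5) {
  stopifnot(inherits(model, "lip_model"))
  if (!is.list(utterances) || length(utterances) < 2) {
    stop("enrollment needs at least two utterances", call. = FALSE)
  }
  pred <- predict(model, utterances)
  feats <- attr(pred, "features")
  proto <- rowMeans(feats)
  dists <- sqrt(colSums((feats - proto)^2))
  tau <- margin * stats::quantile(dists, quantile_level, names = FALSE)
  structure(list(prototype = proto, tau = tau, genuine_distances = dists),
            class = "verification_policy")
}

#' Verify a claimed identity from one utterance
#'
#' Open-set decision: accept iff the utterance's feature distance to the
#' enrolled prototype is at most the policy threshold `tau`. Acceptance is
#' monotone in `tau` (never accepts at `tau = 0`, always accepts as
#' `tau` grows beyond the observed distance).
#'
#' @param model The `lip_model` used at enrollment.
#' @param policy A `verification_policy` from [enroll_speaker()].
#' @param utterance An `utterance` or [waveform()].
#' @param tau Optional threshold override.
#' @return List with `accept` (logical) and `distance`.
#' @export
verify_identity <- function(model, policy, utterance, tau = NULL) {
  stopifnot(inherits(policy, "verification_policy"))
  tau <- if (is.null(tau)) policy$tau else tau
  if (tau < 0) stop("`tau` must be non-negative", call. = FALSE)
  pred <- predict(model, list(utterance))
  f <- attr(pred, "features")[, 1]
  d <- sqrt(sum((f - policy$prototype)^2))
  list(accept = d <= tau, distance = d)
}

#' Map a recognized command word to an action token
#'
#' Bijective mapping from the four directional instruction words to the
#' action tokens emitted for downstream hardware.
#'
#' @param label Command word, e.g. `"Go forwards"`.
#' @return Action token string.
#' @export
command_map <- function(label) {
  map <- command_table()
  if (!is.character(label) || length(label) != 1L || !label %in% names(map)) {
    stop(sprintf("unknown command word: %s", paste(label, collapse = ", ")),
         call. = FALSE)
  }
  unname(map[label])
}

#' Inverse command mapping (action token to command word)
#' @param action Action token, e.g. `"FORWARD"`.
#' @return The command word.
#' @export
command_unmap <- function(action) {
  map <- command_table()
  hit <- names(map)[map == action]
  if (length(hit) != 1L) {
    stop(sprintf("unknown action token: %s", paste(action, collapse = ", ")),
         call. = FALSE)
  }
  hit
}

command_table <- function() {
  c(`Go forwards` = "FORWARD", `Go backwards` = "BACKWARD",
    Left = "LEFT", Right = "RIGHT")
}
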