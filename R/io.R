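#' Write a waveform as CSV plus JSON sidecar
#'
#' The on-disk dialect for all waveforms: a two-column CSV
#' (`time_s,value`) next to a JSON sidecar `<path>.json` carrying the
#' metadata needed to interpret and regenerate the file (units, kind,
#' sampling rate, optional provenance such as generator parameters, and a
#' schema version).
#'
#' @param w A [waveform()].
#' @param path Output CSV path; the sidecar is written to `<path>.json`.
#' @param provenance Optional named list recorded verbatim in the sidecar.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(w, path, provenance = NULL) {
  stopifnot(inherits(w, "waveform"))
  df <- data.frame(time_s = time_axis(w), value = w$samples)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(schema_version = "1.0", units = w$units, kind = w$kind,
               sampling_rate = w$rate, n_samples = length(w$samples),
               provenance = provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a waveform written by [write_waveform()]
#'
#' Validates that the sidecar is present and that the CSV time column is a
#' uniform, monotone grid consistent with the sidecar's sampling rate.
#' Round-trips samples to better than 1e-12 (values are written in full
#' precision by `write.csv`).
#'
#' @param path CSV path (sidecar expected at `<path>.json`).
#' @return A [waveform()]; the sidecar metadata is attached as attribute
#'   `"meta"`.
#' @export
read_waveform <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop("waveform file not found: ", path, call. = FALSE)
  if (!file.exists(sidecar)) {
    stop("missing JSON sidecar: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df))) {
    stop("waveform CSV must have columns time_s,value", call. = FALSE)
  }
  dt <- diff(df$time_s)
  if (length(dt) > 0) {
    if (any(dt <= 0)) stop("non-monotone time grid", call. = FALSE)
    if (max(abs(dt - 1 / meta$sampling_rate)) > 1e-9 / meta$sampling_rate + 1e-12) {
      stop("non-uniform time grid", call. = FALSE)
    }
  }
  w <- waveform(df$value, rate = meta$sampling_rate,
                units = if (is.null(meta$units)) "V" else meta$units,
                kind = meta$kind)
  attr(w, "meta") <- meta
  w
}

#' Write a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer used to render sound envelopes as audio-rate
#' files. Samples are clipped to \[-1, 1\] and quantized to 16 bits.
#'
#' @param samples Numeric samples in \[-1, 1\].
#' @param rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  x <- as.integer(round(pmin(1, pmax(-1, samples)) * 32767))
  n <- length(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(1), con, size = 2, endian = "little")   # PCM
  writeBin(as.integer(1), con, size = 2, endian = "little")   # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2), con, size = 4, endian = "little")
  writeBin(as.integer(2), con, size = 2, endian = "little")   # block align
  writeBin(as.integer(16), con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono WAV file as a sound envelope
#'
#' Reads 16-bit PCM mono WAV audio, rectifies and smooths it into an
#' amplitude envelope and resamples the envelope to the lip-motion
#' sampling rate, so audio recorded alongside the sensors can be compared
#' with the lip waveforms (onsets and durations).
#'
#' @param path WAV path.
#' @param target_rate Output envelope sampling rate in Hz (default 1000).
#' @param smooth_ms Envelope moving-average width in ms (default 10).
#' @return A normalized-envelope [waveform()] at `target_rate` (zero
#'   waveform for silent input).
#' @export
read_wav_envelope <- function(path, target_rate = 1000, smooth_ms = 10) {
  if (!file.exists(path)) stop("WAV file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file", call. = FALSE)
  }
  rate <- NULL; bits <- NULL; channels <- NULL; x <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), 2, size = 2, endian = "little")
      channels <- fmt[2]
      rate <- readBin(con, integer(), 1, size = 4, endian = "little")
      invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
      invisible(readBin(con, integer(), 1, size = 2, endian = "little"))
      bits <- readBin(con, integer(), 1, size = 2, endian = "little")
      if (sz > 16) invisible(readBin(con, raw(), sz - 16))
    } else if (id == "data") {
      if (is.null(bits)) stop("malformed WAV: data before fmt", call. = FALSE)
      x <- readBin(con, integer(), sz / 2, size = 2, endian = "little")
      break
    } else {
      invisible(readBin(con, raw(), sz))
    }
  }
  if (is.null(x)) stop("no data chunk in WAV", call. = FALSE)
  if (channels != 1) stop("only mono WAV is supported", call. = FALSE)
  if (bits != 16) stop("only 16-bit PCM WAV is supported", call. = FALSE)
  env <- smooth_ma(abs(x / 32768), max(1L, round(smooth_ms * rate / 1000)))
  n_out <- max(2L, round(length(env) * target_rate / rate))
  pos <- 1 + (seq_len(n_out) - 1) * (length(env) / n_out)
  y <- stats::approx(seq_along(env), env, xout = pos, rule = 2)$y
  if (max(y) > 0) y <- y / max(y)
  waveform(y, target_rate, units = "normalized", kind = "sound")
}

#' Write a dataset to disk
#'
#' Writes every utterance as a CSV waveform (with sidecar recording label,
#' speaker, seed and split) under `dir`, plus a `manifest.json` from which
#' the dataset can be reloaded or regenerated.
#'
#' @param dataset A `lip_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "lip_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- dataset$manifest
  man$file <- sprintf("utt_%04d.csv", man$id)
  for (i in seq_len(nrow(man))) {
    u <- dataset$utterances[[i]]
    write_waveform(u$lip, file.path(dir, man$file[i]),
                   provenance = list(label = u$label, speaker = u$speaker,
                                     seed = u$seed))
  }
  jsonlite::write_json(
    list(schema_version = "1.0", params = dataset$params, entries = man),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#' @param dir Dataset directory containing `manifest.json`.
#' @return A `lip_dataset` (without ground-truth bookkeeping).
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("missing manifest.json in ", dir, call. = FALSE)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  entries <- as.data.frame(man$entries)
  utterances <- lapply(seq_len(nrow(entries)), function(i) {
    w <- read_waveform(file.path(dir, entries$file[i]))
    new_utterance(w, entries$label[i], entries$speaker[i],
                  as.integer(entries$seed[i]), truth = NULL,
                  profile = NULL)
  })
  params <- man$params
  structure(list(utterances = utterances,
                 manifest = entries[, c("id", "label", "speaker", "split", "seed")],
                 params = params),
            class = "lip_dataset")
}

#' Save a trained model as a JSON checkpoint
#'
#' Serializes all weights (as arrays) together with the architecture,
#' training configuration, label set and accuracy curves into a single
#' JSON file, from which [read_lip_model()] restores a working model.
#'
#' @param model A `lip_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lip_model <- function(model, path) {
  stopifnot(inherits(model, "lip_model"))
  enc_mat <- function(m) {
    if (is.matrix(m)) list(dim = dim(m), data = as.numeric(m))
    else list(dim = length(m), data = as.numeric(m))
  }
  params <- model$params
  # name the layers so the JSON stays an object (arrays of objects would
  # round-trip as data frames)
  names(params$layers) <- paste0("layer", seq_along(params$layers))
  enc <- rapply(params, enc_mat, how = "replace",
                classes = c("matrix", "numeric", "array"))
  obj <- list(schema_version = "1.0",
              config = unclass(model$config), net = unclass(model$net),
              labels = model$labels, curves = model$curves, params = enc)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a model saved by [write_lip_model()]
#' @param path Checkpoint path.
#' @return A `lip_model`.
#' @export
read_lip_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(x) {
    if (is.list(x) && !is.null(x$dim) && !is.null(x$data)) {
      if (length(x$dim) == 2) matrix(x$data, x$dim[1], x$dim[2])
      else as.numeric(x$data)
    } else if (is.list(x)) {
      lapply(x, dec)
    } else {
      x
    }
  }
  cfg <- obj$config
  config <- train_config(epochs = cfg$epochs, batch_size = cfg$batch_size,
                         learning_rate = cfg$learning_rate, lambda = cfg$lambda,
                         gamma = cfg$gamma, head = cfg$head, seed = cfg$seed,
                         input_len = cfg$input_len, cutoff_hz = cfg$cutoff_hz,
                         eval_every = if (is.null(cfg$eval_every)) 1 else cfg$eval_every,
                         trim = isTRUE(cfg$trim),
                         lr_decay = if (is.null(cfg$lr_decay)) "cosine" else cfg$lr_decay)
  net <- drnn_config(n_layers = obj$net$n_layers, hidden_size = obj$net$hidden_size,
                     dilations = obj$net$dilations, feature_dim = obj$net$feature_dim,
                     pool = if (is.null(obj$net$pool)) 1 else obj$net$pool)
  params <- dec(obj$params)
  params$layers <- unname(params$layers)
  structure(list(params = params, config = config, net = net,
                 labels = obj$labels, curves = as.data.frame(obj$curves),
                 trained = TRUE),
            class = "lip_model")
}
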