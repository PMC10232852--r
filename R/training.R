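#' Training configuration (published regime)
#'
#' Adam with learning rate 0.001, 20 epochs, batch size 64, binary
#' cross-entropy loss, and 5 training repeats whose averaged probability is
#' the ensemble prediction.  There is no early stopping or learning-rate
#' schedule; training always runs the configured number of epochs.  Class
#' weighting is available (`class_weighting = "balanced"`) but off by default,
#' also under 1:10 imbalance.
#'
#' @param learning_rate Adam learning rate.
#' @param epochs number of epochs.
#' @param batch_size minibatch size.
#' @param repeats ensemble members to train.
#' @param seed base seed; member `m` trains under `seed + m`.
#' @param shuffle reshuffle the training stream every epoch.
#' @param class_weighting `"none"` (default) or `"balanced"`.
#' @export
training_config <- function(learning_rate = 0.001, epochs = 20L,
                            batch_size = 64L, repeats = 5L, seed = 1L,
                            shuffle = TRUE, class_weighting = "none") {
  stopifnot(epochs >= 1L, batch_size >= 1L, repeats >= 1L, learning_rate > 0)
  class_weighting <- match.arg(class_weighting, c("none", "balanced"))
  structure(list(optimizer = "adam", loss = "binary_crossentropy",
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 shuffle = isTRUE(shuffle), class_weighting = class_weighting),
            class = "training_config")
}

#' Train one model on a train/validation split
#'
#' Runs exactly `config$epochs` epochs of minibatch Adam on the split's
#' training fraction, evaluating binary cross-entropy on the validation
#' fraction after each epoch.  Fully deterministic given
#' `config$seed + member`.
#'
#' @param spec an `architecture_spec`.
#' @param split a `dataset_split` (its `test` partition is never touched).
#' @param config a [training_config()].
#' @param member member index added to the seed (0 for a single model).
#' @param verbose print per-epoch losses.
#' @return A trained `predictive_model` with `history` (per-epoch `train_loss`
#'   and `val_loss`).
#' @export
train_once <- function(spec, split, config = training_config(), member = 0L,
                       verbose = FALSE) {
  stopifnot(inherits(spec, "architecture_spec"),
            inherits(config, "training_config"))
  if (is.null(split$train) || nrow(split$train) == 0L) {
    stop("training partition is empty", call. = FALSE)
  }
  seed <- config$seed + as.integer(member)
  tr <- one_hot_encode(split$train)
  has_val <- !is.null(split$validation) && nrow(split$validation) > 0L
  va <- if (has_val) one_hot_encode(split$validation) else NULL
  es <- engine_spec(spec)
  w0 <- nn_init(es, spec$input_shape, seed)
  sw <- numeric(0)
  if (config$class_weighting == "balanced") {
    tab <- table(factor(tr$y, levels = 0:1))
    sw <- length(tr$y) / (2 * as.numeric(tab[as.character(tr$y)]))
  }
  fit <- nn_train(es, spec$input_shape, w0,
                  tr$x, as.numeric(tr$y),
                  if (has_val) va$x else numeric(0),
                  if (has_val) as.numeric(va$y) else numeric(0),
                  config$epochs, config$batch_size, config$learning_rate,
                  seed, config$shuffle, verbose, sw)
  structure(list(spec = spec, weights = fit$weights,
                 shapes = nn_shapes(es, spec$input_shape),
                 seed = seed, trained = TRUE,
                 history = list(train_loss = fit$train_loss,
                                val_loss = if (has_val) fit$val_loss else NULL),
                 split_ids = list(train = split$train$id,
                                  validation = if (has_val) split$validation$id
                                               else character(0))),
            class = "predictive_model")
}

#' Train a 5-member averaged ensemble
#'
#' Repeats training `config$repeats` times.  The test partition is fixed once;
#' each member re-shuffles the remaining training-plus-validation pool into
#' its own train/validation split (seeded by `config$seed + member`) and
#' re-initialises its weights, so members differ reproducibly.  The ensemble
#' prediction is the arithmetic mean of the member probabilities.
#'
#' @param spec an `architecture_spec`.
#' @param data labelled records data frame, or an existing `dataset_split`
#'   whose test partition is kept as-is.
#' @param config a [training_config()].
#' @param fractions train/validation/test fractions used when `data` is a
#'   record data frame.
#' @param verbose print per-epoch losses.
#' @return An `ensemble_model` with `members`, `histories`, the fixed `test`
#'   records and `member_seeds`.
#' @export
train_ensemble <- function(spec, data, config = training_config(),
                           fractions = c(0.70, 0.10, 0.20), verbose = FALSE) {
  if (inherits(data, "dataset_split")) {
    split0 <- data
  } else {
    split0 <- three_way_split(data, fractions, seed = config$seed)
  }
  pool <- rbind(split0$train, split0$validation)
  train_frac <- nrow(split0$train) / nrow(pool)
  members <- vector("list", config$repeats)
  histories <- vector("list", config$repeats)
  member_seeds <- config$seed + seq_len(config$repeats)
  for (m in seq_len(config$repeats)) {
    ms <- stratified_split(pool, train_frac, seed = member_seeds[m],
                           shuffle = config$shuffle)
    msplit <- structure(list(train = ms$train, validation = ms$test,
                             test = split0$test),
                        class = "dataset_split")
    members[[m]] <- train_once(spec, msplit, config, member = m,
                               verbose = verbose)
    histories[[m]] <- members[[m]]$history
  }
  structure(list(spec = spec, members = members, histories = histories,
                 config = config, test = split0$test,
                 member_seeds = member_seeds),
            class = "ensemble_model")
}

#' Averaged ensemble probabilities
#'
#' The final prediction: the arithmetic mean of the member models' output
#' probabilities, invariant to member order.
#'
#' @param ensemble an `ensemble_model` (a single `predictive_model` is also
#'   accepted).
#' @param newdata an `encoded_batch`, record data frame, or character vector.
#' @param batch_size forward-pass batch size.
#' @return Named numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(ensemble, newdata, batch_size = 256L) {
  batch <- as_encoded_batch(newdata)
  pred <- as_predictor(ensemble)
  pred(batch, batch_size = batch_size)
}

# Normalise the many predictor flavours (single model, ensemble, plain
# function) to one interface: f(encoded_batch) -> probability vector.
as_predictor <- function(object) {
  if (inherits(object, "ensemble_model")) {
    function(batch, batch_size = 256L) {
      ps <- lapply(object$members, function(m) {
        predict(m, batch, batch_size = batch_size)
      })
      p <- Reduce(`+`, ps) / length(ps)
      names(p) <- batch$ids
      p
    }
  } else if (inherits(object, "predictive_model")) {
    function(batch, batch_size = 256L) predict(object, batch,
                                               batch_size = batch_size)
  } else if (is.function(object)) {
    function(batch, batch_size = 256L) object(batch)
  } else {
    stop("cannot interpret object of class '", class(object)[1],
         "' as a predictor", call. = FALSE)
  }
}

#' Threshold probabilities into class labels
#'
#' Scores at or above the threshold are called positive (ties go to the
#' positive class).
#'
#' @param probs numeric probabilities.
#' @param threshold decision threshold, default 0.5.
#' @return Integer vector of 0/1 labels, order-preserving.
#' @export
predict_class <- function(probs, threshold = 0.5) {
  stopifnot(is.numeric(probs), threshold >= 0, threshold <= 1)
  as.integer(probs >= threshold)
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %s, %d members (seeds %s)\n", x$spec$name,
              length(x$members), paste(x$member_seeds, collapse = ",")))
  invisible(x)
}

#' Save / load a trained ensemble
#'
#' Writes each member's weights plus a YAML manifest (architecture, training
#' configuration, member seeds) into a directory; `load_ensemble()` restores a
#' bit-identical predictor.
#'
#' @param ensemble an `ensemble_model`.
#' @param dir output directory (created if absent).
#' @export
save_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "ensemble_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_architecture_spec(ensemble$spec, file.path(dir, "architecture.yml"))
  member_files <- sprintf("member_%d.rds", seq_along(ensemble$members))
  for (m in seq_along(ensemble$members)) {
    saveRDS(ensemble$members[[m]], file.path(dir, member_files[m]))
  }
  manifest <- list(
    package = "deepm5U",
    architecture = ensemble$spec$name,
    members = member_files,
    member_seeds = as.integer(ensemble$member_seeds),
    config = unclass(ensemble$config)
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  if (!is.null(ensemble$test)) {
    utils::write.table(ensemble$test, file.path(dir, "test_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yml"))
  spec <- read_architecture_spec(file.path(dir, "architecture.yml"))
  members <- lapply(manifest$members, function(f) readRDS(file.path(dir, f)))
  test <- NULL
  tf <- file.path(dir, "test_records.tsv")
  if (file.exists(tf)) {
    test <- utils::read.table(tf, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  }
  cfg <- do.call(training_config,
                 manifest$config[setdiff(names(manifest$config),
                                         c("optimizer", "loss"))])
  structure(list(spec = spec, members = members,
                 histories = lapply(members, `[[`, "history"),
                 config = cfg, test = test,
                 member_seeds = manifest$member_seeds),
            class = "ensemble_model")
}
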