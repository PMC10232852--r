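#' Layer specifications
#'
#' Declarative building blocks for sequence-classifier stacks.  Convolutions
#' are valid (no padding) with stride 1 by default; recurrent layer `units`
#' count units per direction, so a bidirectional layer outputs `2 * units`
#' features; the output layer is always a 1-unit sigmoid.
#'
#' @param filters,kernel_size,stride,activation convolution parameters.
#' @param pool_size,units,return_sequences,rate,fun other layer parameters.
#' @name layer_spec
NULL

new_layer <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "layer_spec")
}

#' @rdname layer_spec
#' @export
layer_conv1d <- function(filters, kernel_size, stride = 1L,
                         activation = "relu") {
  stopifnot(filters >= 1L, kernel_size >= 1L, stride >= 1L)
  new_layer("conv1d", filters = as.integer(filters),
            kernel_size = as.integer(kernel_size), stride = as.integer(stride),
            activation = activation)
}

#' @rdname layer_spec
#' @export
layer_maxpool1d <- function(pool_size, stride = pool_size) {
  stopifnot(pool_size >= 1L, stride >= 1L)
  new_layer("maxpool1d", pool_size = as.integer(pool_size),
            stride = as.integer(stride))
}

#' @rdname layer_spec
#' @export
layer_bilstm <- function(units, return_sequences = FALSE) {
  stopifnot(units >= 1L)
  new_layer("bilstm", units = as.integer(units),
            return_sequences = isTRUE(return_sequences))
}

#' @rdname layer_spec
#' @export
layer_bigru <- function(units, return_sequences = FALSE) {
  stopifnot(units >= 1L)
  new_layer("bigru", units = as.integer(units),
            return_sequences = isTRUE(return_sequences))
}

#' @rdname layer_spec
#' @export
layer_dense <- function(units, activation = "linear") {
  stopifnot(units >= 1L)
  new_layer("dense", units = as.integer(units), activation = activation)
}

#' @rdname layer_spec
#' @export
layer_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  new_layer("dropout", rate = rate)
}

#' @rdname layer_spec
#' @export
layer_activation <- function(fun) {
  stopifnot(fun %in% c("relu", "sigmoid"))
  new_layer("activation", fun = fun)
}

#' @rdname layer_spec
#' @export
layer_output <- function() {
  new_layer("output", units = 1L, activation = "sigmoid")
}

ARCH_NAMES <- c("CNN", "BiLSTM", "BiGRU", "CNN_BiLSTM", "CNN_BiGRU")

new_architecture <- function(name, layers, input_shape = c(41L, 4L)) {
  structure(list(name = name, layers = layers,
                 input_shape = as.integer(input_shape)),
            class = "architecture_spec")
}

#' The five published model architectures
#'
#' Returns the exact layer stack of one of the five benchmark architectures
#' (CNN, BiLSTM, BiGRU, CNN-BiLSTM, CNN-BiGRU) for one-hot encoded 41 x 4
#' input.  Recurrent units are per direction; every stack ends in
#' dense(256) -> dropout(0.2) -> ReLU -> output(1, sigmoid).
#'
#' @param name one of `"CNN"`, `"BiLSTM"`, `"BiGRU"`, `"CNN_BiLSTM"`,
#'   `"CNN_BiGRU"` (case-insensitive; `-` accepted for `_`).
#' @return An `architecture_spec`.
#' @export
architecture_spec <- function(name) {
  key <- toupper(gsub("-", "_", name))
  key <- unname(c(CNN = "CNN", BILSTM = "BiLSTM", BIGRU = "BiGRU",
                  CNN_BILSTM = "CNN_BiLSTM", CNN_BIGRU = "CNN_BiGRU")[key])
  if (is.na(key)) {
    stop("unknown architecture '", name, "'; choose one of ",
         paste(ARCH_NAMES, collapse = ", "), call. = FALSE)
  }
  head_layers <- list(layer_dense(256L), layer_dropout(0.2),
                      layer_activation("relu"), layer_output())
  body <- switch(key,
    CNN = list(layer_conv1d(250L, 11L), layer_conv1d(250L, 11L),
               layer_maxpool1d(10L, 10L)),
    BiLSTM = list(layer_bilstm(256L, return_sequences = TRUE),
                  layer_bilstm(256L)),
    BiGRU = list(layer_bigru(256L)),
    CNN_BiLSTM = list(layer_conv1d(250L, 7L), layer_conv1d(250L, 7L),
                      layer_maxpool1d(4L, 4L), layer_bilstm(64L)),
    CNN_BiGRU = list(layer_conv1d(250L, 11L), layer_maxpool1d(10L, 10L),
                     layer_bigru(256L))
  )
  new_architecture(key, c(body, head_layers))
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec> %s, input (%d, %d)\n", x$name,
              x$input_shape[1], x$input_shape[2]))
  for (l in x$layers) {
    ps <- l[setdiff(names(l), "kind")]
    cat(sprintf("  %-11s %s\n", l$kind,
                paste(names(ps), unlist(ps), sep = "=", collapse = ", ")))
  }
  invisible(x)
}

#' Output length of a valid 1-D convolution or pooling window
#'
#' `floor((L - kernel) / stride) + 1` under the valid (no-padding) convention.
#' Used as the symbolic shape trace that every built model must reproduce.
#'
#' @param L input length.
#' @param kernel window size.
#' @param stride step size.
#' @export
conv_output_length <- function(L, kernel, stride = 1L) {
  if (kernel > L) {
    stop(sprintf("window size %d exceeds input length %d (architecture infeasible)",
                 kernel, L), call. = FALSE)
  }
  as.integer((L - kernel) %/% stride + 1L)
}

#' Symbolic shape trace of an architecture
#'
#' Walks the layer stack with [conv_output_length()] arithmetic only (no
#' weights, no engine) and returns each layer's output shape: `c(L, C)` for
#' sequence-shaped outputs, a single integer for flat outputs.
#'
#' @param spec an `architecture_spec`.
#' @export
shape_trace <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  cur <- spec$input_shape
  seq_shaped <- TRUE
  out <- list()
  for (l in spec$layers) {
    cur <- switch(l$kind,
      conv1d = {
        if (!seq_shaped) stop("conv1d after flat output", call. = FALSE)
        c(conv_output_length(cur[1], l$kernel_size, l$stride), l$filters)
      },
      maxpool1d = {
        if (!seq_shaped) stop("maxpool1d after flat output", call. = FALSE)
        c(conv_output_length(cur[1], l$pool_size, l$stride), cur[2])
      },
      bilstm = ,
      bigru = {
        if (!seq_shaped) stop("recurrent layer after flat output", call. = FALSE)
        if (l$return_sequences) c(cur[1], 2L * l$units) else {
          seq_shaped <- FALSE
          2L * l$units
        }
      },
      dense = {
        seq_shaped <- FALSE
        l$units
      },
      output = {
        seq_shaped <- FALSE
        1L
      },
      cur  # dropout, activation: shape-preserving
    )
    out[[length(out) + 1L]] <- as.integer(cur)
  }
  names(out) <- engine_layer_names(spec)
  out
}

# Convert an architecture_spec into the plain list the C++ engine consumes.
engine_spec <- function(spec) {
  lapply(spec$layers, function(l) unclass(l))
}

engine_layer_names <- function(spec) {
  nn_layer_names(engine_spec(spec), spec$input_shape)
}

#' Build a predictive model from an architecture
#'
#' Validates the layer stack against the input shape (an infeasible
#' convolution/pooling chain raises an error naming the offending layer) and
#' initialises weights (Glorot-uniform, LSTM forget-gate bias 1) under `seed`.
#'
#' @param spec an `architecture_spec`.
#' @param seed integer seed for weight initialisation.
#' @return A `predictive_model` usable with [predict()][predict.predictive_model].
#' @export
build_model <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "architecture_spec"))
  es <- engine_spec(spec)
  shapes <- nn_shapes(es, spec$input_shape)  # throws on infeasible chains
  weights <- nn_init(es, spec$input_shape, as.integer(seed))
  structure(list(spec = spec, weights = weights, shapes = shapes,
                 seed = as.integer(seed), trained = FALSE, history = NULL),
            class = "predictive_model")
}

#' Predict class probabilities with a single model
#'
#' The network emits the output unit's pre-activation and the final sigmoid
#' is applied in double precision, so near-saturated probabilities remain
#' distinguishable (which saturation-mutagenesis deltas rely on).
#'
#' @param object a `predictive_model`.
#' @param newdata an `encoded_batch`, record data frame, or character vector
#'   of sequences.
#' @param batch_size forward-pass batch size.
#' @param type `"response"` for probabilities (default) or `"logit"`.
#' @param ... unused.
#' @export
predict.predictive_model <- function(object, newdata, batch_size = 256L,
                                     type = c("response", "logit"), ...) {
  type <- match.arg(type)
  batch <- as_encoded_batch(newdata)
  z <- nn_predict(engine_spec(object$spec), object$spec$input_shape,
                  object$weights, batch$x, batch_size, TRUE)
  p <- if (type == "logit") z else stats::plogis(z)
  names(p) <- batch$ids
  p
}

as_encoded_batch <- function(x) {
  if (inherits(x, "encoded_batch")) return(x)
  one_hot_encode(x)
}

#' @export
print.predictive_model <- function(x, ...) {
  cat(sprintf("<predictive_model> %s (%s), %d parameters\n", x$spec$name,
              if (x$trained) "trained" else "untrained", n_parameters(x)))
  invisible(x)
}

n_parameters <- function(model) {
  sum(vapply(model$weights, function(wl) {
    sum(vapply(wl, length, 0L))
  }, 0L))
}

#' The published hyperparameter grid
#'
#' The exact value sets explored when selecting the five architectures:
#' convolution layers (1,2,3), kernel size (3,5,7,9,11), filters (50,150,250),
#' pool size (2,4,6,8,10), LSTM/GRU layers (1,2,3), LSTM/GRU units
#' (32,64,128,256).
#'
#' @export
grid_search_space <- function() {
  structure(list(
    conv_layers = c(1L, 2L, 3L),
    kernel_size = c(3L, 5L, 7L, 9L, 11L),
    filters = c(50L, 150L, 250L),
    pool_size = c(2L, 4L, 6L, 8L, 10L),
    lstm_layers = c(1L, 2L, 3L),
    lstm_units = c(32L, 64L, 128L, 256L),
    gru_layers = c(1L, 2L, 3L),
    gru_units = c(32L, 64L, 128L, 256L)
  ), class = "grid_search_space")
}

# Assemble one candidate architecture of a family from grid values.
assemble_candidate <- function(family, p) {
  body <- list()
  if (family %in% c("CNN", "CNN_BiLSTM", "CNN_BiGRU")) {
    for (i in seq_len(p$conv_layers)) {
      body <- c(body, list(layer_conv1d(p$filters, p$kernel_size)))
    }
    body <- c(body, list(layer_maxpool1d(p$pool_size, p$pool_size)))
  }
  if (family %in% c("BiLSTM", "CNN_BiLSTM")) {
    nl <- p$lstm_layers
    for (i in seq_len(nl)) {
      body <- c(body, list(layer_bilstm(p$lstm_units,
                                        return_sequences = i < nl)))
    }
  }
  if (family %in% c("BiGRU", "CNN_BiGRU")) {
    nl <- p$gru_layers
    for (i in seq_len(nl)) {
      body <- c(body, list(layer_bigru(p$gru_units,
                                       return_sequences = i < nl)))
    }
  }
  new_architecture(family, c(body, list(layer_dense(256L), layer_dropout(0.2),
                                        layer_activation("relu"),
                                        layer_output())))
}

grid_dimensions <- function(family, space) {
  switch(family,
    CNN = c("conv_layers", "kernel_size", "filters", "pool_size"),
    BiLSTM = c("lstm_layers", "lstm_units"),
    BiGRU = c("gru_layers", "gru_units"),
    CNN_BiLSTM = c("conv_layers", "kernel_size", "filters", "pool_size",
                   "lstm_layers", "lstm_units"),
    CNN_BiGRU = c("conv_layers", "kernel_size", "filters", "pool_size",
                  "gru_layers", "gru_units"),
    stop("unknown family '", family, "'", call. = FALSE)
  )
}

#' Grid search over architecture hyperparameters
#'
#' Enumerates the family's slice of the grid, trains each candidate once on
#' the split's training fraction, and selects the configuration with the
#' highest validation accuracy (ties broken by fewer parameters).  Candidates
#' whose convolution/pooling chain is infeasible for the input length are
#' recorded as infeasible and skipped.  `budget` subsamples the grid
#' reproducibly under `seed`.
#'
#' @param family architecture family name (as in [architecture_spec()]).
#' @param split a `dataset_split`.
#' @param space a [grid_search_space()]; restrict its vectors to narrow the
#'   search.
#' @param config a [training_config()]; grid search typically uses fewer
#'   epochs than final training.
#' @param budget maximum number of configurations to evaluate (NULL = all).
#' @param seed seed for the budget subsample.
#' @param out_file optional path for the tab-separated results table.
#' @return list with `best` (an `architecture_spec`), `results` (data frame of
#'   all evaluated configurations and validation accuracies).
#' @export
grid_search <- function(family, split, space = grid_search_space(),
                        config = training_config(epochs = 3L, repeats = 1L),
                        budget = NULL, seed = 1L, out_file = NULL) {
  family <- architecture_spec(family)$name
  dims <- grid_dimensions(family, space)
  vals <- space[dims]
  if (any(vapply(vals, length, 0L) == 0L)) {
    stop("grid search space is empty", call. = FALSE)
  }
  grid <- expand.grid(vals, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (!is.null(budget) && budget < nrow(grid)) {
    keep <- with_seed(seed, sample(nrow(grid), budget))
    grid <- grid[sort(keep), , drop = FALSE]
  }
  res <- grid
  res$feasible <- TRUE
  res$n_parameters <- NA_integer_
  res$val_acc <- NA_real_
  best <- NULL
  best_key <- c(-Inf, Inf)
  for (i in seq_len(nrow(grid))) {
    cand <- assemble_candidate(family, as.list(grid[i, , drop = FALSE]))
    ok <- tryCatch({ shape_trace(cand); TRUE }, error = function(e) FALSE)
    if (!ok) {
      res$feasible[i] <- FALSE
      next
    }
    fit <- train_once(cand, split, config)
    acc <- accuracy(confusion(split$validation$label,
                              predict_class(predict(fit, split$validation))))
    res$val_acc[i] <- acc
    res$n_parameters[i] <- n_parameters(fit)
    if (acc > best_key[1] ||
        (acc == best_key[1] && res$n_parameters[i] < best_key[2])) {
      best <- cand
      best_key <- c(acc, res$n_parameters[i])
    }
  }
  if (is.null(best)) stop("no feasible configuration in the grid", call. = FALSE)
  if (!is.null(out_file)) {
    utils::write.table(res, out_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(best = best, results = res)
}

#' Read or write an architecture spec as a structured text file
#'
#' Architectures serialise to YAML so users can define variants outside R.
#'
#' @param spec an `architecture_spec`.
#' @param path file path.
#' @export
write_architecture_spec <- function(spec, path) {
  stopifnot(inherits(spec, "architecture_spec"))
  yaml::write_yaml(list(name = spec$name,
                        input_shape = as.integer(spec$input_shape),
                        layers = lapply(spec$layers, unclass)), path)
  invisible(path)
}

#' @rdname write_architecture_spec
#' @export
read_architecture_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  layers <- lapply(obj$layers, function(l) {
    do.call(new_layer, c(list(kind = l$kind), l[setdiff(names(l), "kind")]))
  })
  new_architecture(obj$name, layers, obj$input_shape)
}
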