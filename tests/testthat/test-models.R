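test_that("the five published stacks have the stated layers", {
  cb <- architecture_spec("CNN_BiLSTM")
  l1 <- cb$layers[[1]]
  expect_equal(l1[c("kind", "filters", "kernel_size", "stride", "activation")],
               list(kind = "conv1d", filters = 250L, kernel_size = 7L,
                    stride = 1L, activation = "relu"))
  rec_layer <- Filter(function(l) l$kind == "bilstm", cb$layers)[[1]]
  expect_equal(rec_layer$units, 64L)

  cnn <- architecture_spec("CNN")
  expect_equal(vapply(cnn$layers, `[[`, "", "kind"),
               c("conv1d", "conv1d", "maxpool1d", "dense", "dropout",
                 "activation", "output"))
  expect_equal(cnn$layers[[1]]$kernel_size, 11L)
  expect_equal(cnn$layers[[3]]$pool_size, 10L)

  bl <- architecture_spec("BiLSTM")
  expect_true(bl$layers[[1]]$return_sequences)
  expect_false(bl$layers[[2]]$return_sequences)
  expect_equal(bl$layers[[1]]$units, 256L)

  expect_equal(architecture_spec("BiGRU")$layers[[1]]$units, 256L)
  cg <- architecture_spec("cnn-bigru")  # name normalization
  expect_equal(cg$name, "CNN_BiGRU")
  expect_equal(cg$layers[[1]]$kernel_size, 11L)

  for (nm in c("CNN", "BiLSTM", "BiGRU", "CNN_BiLSTM", "CNN_BiGRU")) {
    last <- tail(architecture_spec(nm)$layers, 1)[[1]]
    expect_equal(last$kind, "output")
    expect_equal(last$units, 1L)
    expect_equal(last$activation, "sigmoid")
    dense <- Filter(function(l) l$kind == "dense",
                    architecture_spec(nm)$layers)[[1]]
    expect_equal(dense$units, 256L)
  }
  expect_error(architecture_spec("transformer"), "unknown architecture")
})

test_that("valid-convolution length arithmetic matches the known traces", {
  expect_equal(conv_output_length(41, 11, 1), 31L)
  expect_equal(conv_output_length(41, 7, 1), 35L)
  expect_equal(conv_output_length(35, 7, 1), 29L)
  expect_equal(conv_output_length(29, 4, 4), 7L)
  expect_equal(conv_output_length(31, 11, 1), 21L)
  expect_equal(conv_output_length(21, 10, 10), 2L)
  expect_error(conv_output_length(5, 7), "infeasible")
})

test_that("built models reproduce the symbolic shape trace", {
  for (nm in c("CNN", "BiLSTM", "BiGRU", "CNN_BiLSTM", "CNN_BiGRU")) {
    spec <- architecture_spec(nm)
    trace <- shape_trace(spec)
    model <- build_model(spec, seed = 1)
    expect_identical(unname(model$shapes), unname(trace), label = nm)
  }
  # spot-check the printed traces
  tr <- shape_trace(architecture_spec("CNN"))
  expect_equal(tr$conv1d_1[1], 31L)
  expect_equal(tr$conv1d_2[1], 21L)
  expect_equal(tr$maxpool1d_1[1], 2L)
  tr2 <- shape_trace(architecture_spec("CNN_BiLSTM"))
  expect_equal(vapply(tr2[1:3], `[[`, 0L, 1L),
               c(conv1d_1 = 35L, conv1d_2 = 29L, maxpool1d_1 = 7L))
})

test_that("infeasible shape chains fail naming the offending layer", {
  bad <- deepm5U:::new_architecture("bad", list(
    layer_conv1d(4L, 30L), layer_conv1d(4L, 30L), layer_output()
  ))
  expect_error(build_model(bad), "conv1d_2")
  expect_error(shape_trace(bad), "infeasible")
})

test_that("untrained models output probabilities, order-preserving", {
  model <- build_model(tiny_arch("bigru"), seed = 3)
  seqs <- random_windows(20, seed = 5)
  p <- predict(model, seqs)
  expect_length(p, 20L)
  expect_true(all(p >= 0 & p <= 1))
  # batch order: predicting a subset gives the same values
  expect_equal(unname(p[3:5]), unname(predict(model, seqs[3:5])),
               tolerance = 1e-6)
  # init determinism
  m2 <- build_model(tiny_arch("bigru"), seed = 3)
  expect_identical(model$weights, m2$weights)
})

test_that("architecture specs round-trip through the YAML file format", {
  spec <- architecture_spec("CNN_BiLSTM")
  path <- withr::local_tempfile(fileext = ".yml")
  write_architecture_spec(spec, path)
  back <- read_architecture_spec(path)
  expect_equal(back$name, spec$name)
  expect_equal(back$input_shape, spec$input_shape)
  expect_equal(lapply(back$layers, unclass), lapply(spec$layers, unclass))
})

test_that("grid search space holds the printed value sets", {
  sp <- grid_search_space()
  expect_equal(sp$conv_layers, c(1L, 2L, 3L))
  expect_equal(sp$kernel_size, c(3L, 5L, 7L, 9L, 11L))
  expect_equal(sp$filters, c(50L, 150L, 250L))
  expect_equal(sp$pool_size, c(2L, 4L, 6L, 8L, 10L))
  expect_equal(sp$lstm_units, c(32L, 64L, 128L, 256L))
  expect_equal(sp$gru_units, c(32L, 64L, 128L, 256L))
})

test_that("grid search evaluates candidates and picks the best by val ACC", {
  fix <- tiny_trained()
  space <- grid_search_space()
  space$lstm_layers <- 1L
  space$lstm_units <- c(4L, 8L)
  cfg <- training_config(epochs = 2L, repeats = 1L, seed = 9L)
  res <- grid_search("BiLSTM", fix$split, space, cfg)
  expect_equal(nrow(res$results), 2L)
  expect_s3_class(res$best, "architecture_spec")
  best_row <- which.max(res$results$val_acc)
  expect_equal(res$best$layers[[1]]$units, res$results$lstm_units[best_row])

  # a single-configuration space returns that configuration
  space$lstm_units <- 8L
  res1 <- grid_search("BiLSTM", fix$split, space, cfg)
  expect_equal(nrow(res1$results), 1L)
  expect_equal(res1$best$layers[[1]]$units, 8L)

  space$lstm_units <- integer(0)
  expect_error(grid_search("BiLSTM", fix$split, space, cfg), "empty")
})

test_that("grid search marks infeasible convolution chains and skips them", {
  fix <- tiny_trained()
  space <- grid_search_space()
  space$conv_layers <- 3L
  space$kernel_size <- c(3L, 11L)
  space$filters <- 4L
  space$pool_size <- c(10L, 2L)
  cfg <- training_config(epochs = 1L, repeats = 1L, seed = 9L)
  res <- grid_search("CNN", fix$split, space, cfg)
  # kernel 11 three times: 41 -> 31 -> 21 -> 11, pool 10 feasible; but the
  # budget/feasibility bookkeeping must match the trace oracle
  feas <- vapply(seq_len(nrow(res$results)), function(i) {
    p <- as.list(res$results[i, c("conv_layers", "kernel_size", "filters",
                                  "pool_size")])
    ok <- TRUE
    L <- 41L
    for (k in seq_len(p$conv_layers)) {
      ok <- ok && p$kernel_size <= L
      if (ok) L <- conv_output_length(L, p$kernel_size)
    }
    ok && p$pool_size <= L
  }, TRUE)
  expect_equal(res$results$feasible, feas)
  expect_true(all(is.na(res$results$val_acc[!feas])))
  expect_true(all(!is.na(res$results$val_acc[feas])))
})
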