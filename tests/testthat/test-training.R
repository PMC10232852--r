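test_that("training runs the configured epochs and learns separable data", {
  fix <- tiny_trained()
  h <- fix$model$history
  expect_length(h$train_loss, fix$config$epochs)
  expect_length(h$val_loss, fix$config$epochs)
  expect_lt(tail(h$train_loss, 1), h$train_loss[1])
  # planted motifs with plant_prob 1 are near-perfectly learnable
  p <- predict(fix$model, fix$split$test)
  expect_gt(accuracy(confusion(fix$split$test$label, predict_class(p))), 0.95)
})

test_that("training is deterministic under a fixed seed", {
  rec <- generate_dataset(synthetic_config(n_pos = 40, n_neg = 40, seed = 3))
  split <- three_way_split(rec, seed = 1)
  cfg <- training_config(epochs = 2L, repeats = 1L, seed = 4L)
  m1 <- train_once(tiny_arch("none"), split, cfg)
  m2 <- train_once(tiny_arch("none"), split, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
  m3 <- train_once(tiny_arch("none"), split, cfg, member = 1L)
  expect_false(identical(m1$weights, m3$weights))
})

test_that("training config validates the published regime", {
  cfg <- training_config()
  expect_equal(cfg$learning_rate, 0.001)
  expect_equal(cfg$epochs, 20L)
  expect_equal(cfg$batch_size, 64L)
  expect_equal(cfg$repeats, 5L)
  expect_equal(cfg$optimizer, "adam")
  expect_equal(cfg$loss, "binary_crossentropy")
  expect_error(training_config(epochs = 0), "epochs")
  expect_error(train_once(tiny_arch("none"),
                          list(train = data.frame(), validation = NULL),
                          training_config()),
               "empty")
})

test_that("ensembles train one member per repeat without test leakage", {
  rec <- generate_dataset(synthetic_config(n_pos = 60, n_neg = 60, seed = 6))
  cfg <- training_config(epochs = 2L, repeats = 3L, seed = 10L)
  ens <- train_ensemble(tiny_arch("none"), rec, cfg)
  expect_length(ens$members, 3L)
  expect_length(ens$histories, 3L)
  expect_false(identical(ens$histories[[1]], ens$histories[[2]]))
  for (m in ens$members) {
    expect_length(intersect(c(m$split_ids$train, m$split_ids$validation),
                            ens$test$id), 0L)
  }
  # member splits differ (per-repeat reshuffling)
  expect_false(identical(ens$members[[1]]$split_ids$train,
                         ens$members[[2]]$split_ids$train))
})

test_that("ensemble prediction is the member mean and permutation-invariant", {
  # members with zeroed weights and chosen output biases give exact constant
  # probabilities
  make_const_member <- function(logit) {
    m <- build_model(tiny_arch("none"), seed = 1)
    for (l in names(m$weights)) {
      for (k in seq_along(m$weights[[l]])) {
        m$weights[[l]][[k]][] <- 0
      }
    }
    m$weights$output[[2]][] <- logit
    m
  }
  probs <- c(0.2, 0.4, 0.6)
  members <- lapply(log(probs / (1 - probs)), make_const_member)
  ens <- structure(list(spec = tiny_arch("none"), members = members,
                        config = training_config(repeats = 3L)),
                   class = "ensemble_model")
  seqs <- random_windows(5, seed = 1)
  expect_equal(unname(predict_proba(ens, seqs)), rep(0.4, 5), tolerance = 1e-6)
  ens$members <- rev(ens$members)
  expect_equal(unname(predict_proba(ens, seqs)), rep(0.4, 5), tolerance = 1e-6)

  # an ensemble of one behaves as its single member
  ens1 <- structure(list(spec = tiny_arch("none"), members = members[1],
                         config = training_config(repeats = 1L)),
                    class = "ensemble_model")
  expect_equal(unname(predict_proba(ens1, seqs)),
               unname(predict(members[[1]], seqs)))
})

test_that("class thresholding is vectorized with ties to positive", {
  expect_identical(predict_class(c(0.51, 0.49, 0.5, 0, 1)),
                   c(1L, 0L, 1L, 0L, 1L))
  p <- withr::with_seed(2, runif(50))
  expect_identical(predict_class(p)[7], as.integer(p[7] >= 0.5))
})

test_that("balanced class weighting changes training on imbalanced data", {
  rec <- generate_dataset(synthetic_config(n_pos = 20, n_neg = 200, seed = 9))
  split <- three_way_split(rec, seed = 2)
  m_plain <- train_once(tiny_arch("none"), split,
                        training_config(epochs = 2L, seed = 3L))
  m_bal <- train_once(tiny_arch("none"), split,
                      training_config(epochs = 2L, seed = 3L,
                                      class_weighting = "balanced"))
  expect_false(identical(m_plain$weights, m_bal$weights))
})

test_that("saved ensembles reload with bit-identical predictions", {
  fix <- tiny_trained()
  ens <- structure(list(spec = fix$model$spec, members = list(fix$model),
                        histories = list(fix$model$history),
                        config = fix$config, test = fix$split$test,
                        member_seeds = fix$config$seed + 1L),
                   class = "ensemble_model")
  dir <- withr::local_tempdir()
  save_ensemble(ens, dir)
  back <- load_ensemble(dir)
  seqs <- random_windows(10, seed = 20)
  expect_identical(predict_proba(back, seqs), predict_proba(ens, seqs))
  expect_equal(back$spec$name, ens$spec$name)
})
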