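# Shared fixtures, all generated in code.

random_windows <- function(n, seed = 1, L = 41L) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      s <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
      s[21L] <- "U"
      paste(s, collapse = "")
    }, "")
  })
}

random_records <- function(n_pos, n_neg, seed = 1) {
  data.frame(
    id = c(sprintf("p%03d", seq_len(n_pos)), sprintf("n%03d", seq_len(n_neg))),
    seq = random_windows(n_pos + n_neg, seed = seed),
    label = rep(c(1L, 0L), c(n_pos, n_neg)),
    stringsAsFactors = FALSE
  )
}

write_fasta_pair <- function(records, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  pos <- file.path(dir, "pos.fasta")
  neg <- file.path(dir, "neg.fasta")
  write_dataset_fasta(records, pos, neg)
  list(pos = pos, neg = neg, dir = dir)
}

# A deliberately small stack exercising conv + pool + recurrent + dense paths
# without the cost of the published widths.
tiny_arch <- function(recurrent = c("bilstm", "bigru", "none")) {
  recurrent <- match.arg(recurrent)
  body <- list(layer_conv1d(8L, 5L), layer_maxpool1d(3L, 3L))
  if (recurrent == "bilstm") body <- c(body, list(layer_bilstm(6L)))
  if (recurrent == "bigru") body <- c(body, list(layer_bigru(6L)))
  deepm5U:::new_architecture(
    "tiny", c(body, list(layer_dense(16L), layer_dropout(0.2),
                         layer_activation("relu"), layer_output()))
  )
}

# Small separable dataset + trained tiny model, cached across tests.
tiny_trained <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rec <- generate_dataset(synthetic_config(n_pos = 300L, n_neg = 300L,
                                               plant_prob = 1, seed = 11L))
      split <- three_way_split(rec, seed = 2L)
      cfg <- training_config(learning_rate = 0.003, epochs = 30L,
                             batch_size = 32L, repeats = 1L, seed = 5L)
      model <- train_once(tiny_arch("bilstm"), split, cfg)
      cache <<- list(records = rec, split = split, model = model, config = cfg)
    }
    cache
  }
})
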