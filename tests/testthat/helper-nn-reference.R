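# Independent double-precision reference forward pass, written with plain R
# loops against the layer definitions (valid convolution, max pooling, LSTM
# gates i/f/c~/o with the candidate tanh, classic GRU with reset-gated
# candidate, time-major flattening).  Used to validate the compiled engine.

ref_sigmoid <- function(x) 1 / (1 + exp(-x))

ref_conv1d <- function(x, W, b, kernel, stride = 1L, relu = TRUE) {
  # x: L x C; W: (K*C) x F (offset-major rows); b: F
  L <- nrow(x); C <- ncol(x); F_ <- ncol(W)
  Lo <- (L - kernel) %/% stride + 1L
  out <- matrix(0, Lo, F_)
  for (i in seq_len(Lo)) {
    patch <- as.numeric(t(x[(i - 1L) * stride + seq_len(kernel), , drop = FALSE]))
    # t() gives channel-fastest order matching row index m*C + c
    out[i, ] <- patch %*% W + b
  }
  if (relu) out <- pmax(out, 0)
  out
}

ref_maxpool1d <- function(x, pool, stride) {
  L <- nrow(x); C <- ncol(x)
  Lo <- (L - pool) %/% stride + 1L
  out <- matrix(0, Lo, C)
  for (i in seq_len(Lo)) {
    out[i, ] <- apply(x[(i - 1L) * stride + seq_len(pool), , drop = FALSE], 2L, max)
  }
  out
}

ref_lstm_dir <- function(x, Wx, Wh, b, reverse = FALSE) {
  L <- nrow(x); H <- ncol(Wh) / 4L
  ord <- if (reverse) rev(seq_len(L)) else seq_len(L)
  h <- numeric(H); cs <- numeric(H)
  hs <- matrix(0, L, H)
  for (s in seq_along(ord)) {
    z <- as.numeric(x[ord[s], ] %*% Wx + h %*% Wh) + as.numeric(b)
    i_ <- ref_sigmoid(z[1:H])
    f_ <- ref_sigmoid(z[(H + 1):(2 * H)])
    ct <- tanh(z[(2 * H + 1):(3 * H)])
    o_ <- ref_sigmoid(z[(3 * H + 1):(4 * H)])
    cs <- f_ * cs + i_ * ct
    h <- o_ * tanh(cs)
    hs[s, ] <- h
  }
  hs  # processing-step order
}

ref_gru_dir <- function(x, Wx, Wh, b, reverse = FALSE) {
  L <- nrow(x); H <- ncol(Wh) / 3L
  ord <- if (reverse) rev(seq_len(L)) else seq_len(L)
  h <- numeric(H)
  hs <- matrix(0, L, H)
  ixr <- 1:H; ixz <- (H + 1):(2 * H); ixh <- (2 * H + 1):(3 * H)
  for (s in seq_along(ord)) {
    xt <- x[ord[s], ]
    r <- ref_sigmoid(as.numeric(xt %*% Wx[, ixr] + h %*% Wh[, ixr]) + b[ixr])
    z <- ref_sigmoid(as.numeric(xt %*% Wx[, ixz] + h %*% Wh[, ixz]) + b[ixz])
    ht <- tanh(as.numeric(xt %*% Wx[, ixh] + (r * h) %*% Wh[, ixh]) + b[ixh])
    h <- (1 - z) * ht + z * h
    hs[s, ] <- h
  }
  hs
}

ref_flatten <- function(x) as.numeric(t(x))  # time-major

# Full forward pass for one sample; spec/weights in the package's engine
# layout.  Returns the output probability.
ref_forward <- function(arch, weights, xmat, dims = c(41L, 4L)) {
  cur <- xmat  # L x C
  flat <- NULL
  names_seen <- list()
  for (l in arch$layers) {
    kind <- l$kind
    n <- (names_seen[[kind]] <- (names_seen[[kind]] %||% 0L) + 1L)
    nm <- if (kind == "output") "output" else sprintf("%s_%d", kind, n)
    w <- weights[[nm]]
    if (kind == "conv1d") {
      cur <- ref_conv1d(cur, w[[1]], as.numeric(w[[2]]), l$kernel_size,
                        l$stride, relu = identical(l$activation, "relu"))
    } else if (kind == "maxpool1d") {
      cur <- ref_maxpool1d(cur, l$pool_size, l$stride)
    } else if (kind %in% c("bilstm", "bigru")) {
      dirfun <- if (kind == "bilstm") ref_lstm_dir else ref_gru_dir
      hf <- dirfun(cur, w[[1]], w[[2]], as.numeric(w[[3]]), reverse = FALSE)
      hb <- dirfun(cur, w[[4]], w[[5]], as.numeric(w[[6]]), reverse = TRUE)
      L <- nrow(cur)
      if (isTRUE(l$return_sequences)) {
        cur <- cbind(hf, hb[rev(seq_len(L)), , drop = FALSE])
      } else {
        flat <- c(hf[L, ], hb[L, ])
        cur <- NULL
      }
    } else if (kind %in% c("dense", "output")) {
      v <- if (is.null(cur)) flat else ref_flatten(cur)
      out <- as.numeric(v %*% w[[1]]) + as.numeric(w[[2]])
      act <- if (kind == "output") "sigmoid" else (l$activation %||% "linear")
      if (act == "relu") out <- pmax(out, 0)
      if (act == "sigmoid") out <- ref_sigmoid(out)
      flat <- out
      cur <- NULL
    } else if (kind == "dropout") {
      # identity at inference
    } else if (kind == "activation") {
      apply_act <- function(v) if (l$fun == "relu") pmax(v, 0) else ref_sigmoid(v)
      if (is.null(cur)) flat <- apply_act(flat) else cur <- apply_act(cur)
    }
  }
  flat
}

`%||%` <- function(a, b) if (is.null(a)) b else a
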