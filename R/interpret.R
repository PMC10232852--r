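#' Extract a hidden layer's activations
#'
#' Runs the forward pass up to the selected layer and returns one flattened
#' row per sample.  Sequence-shaped outputs are flattened time-major: the
#' feature vector is position 1's channels, then position 2's, and so on.
#' Layer 0 (or `"input"`) is the flattened one-hot input itself, the "reshape"
#' view of the data.
#'
#' @param model a `predictive_model` or `ensemble_model` (for an ensemble the
#'   indicated member is dissected).
#' @param layer layer name, or index with 0 = input; unknown selectors raise
#'   an error listing the available layer names.
#' @param newdata an `encoded_batch`, record data frame, or character vector.
#' @param member ensemble member to dissect (default 1).
#' @param batch_size forward-pass batch size.
#' @return A `layer_activation`: list with `layer_name`, `matrix` (N x D),
#'   `ids`, `labels`.
#' @export
extract_layer_output <- function(model, layer, newdata, member = 1L,
                                 batch_size = 256L) {
  if (inherits(model, "ensemble_model")) model <- model$members[[member]]
  stopifnot(inherits(model, "predictive_model"))
  batch <- as_encoded_batch(newdata)
  nms <- engine_layer_names(model$spec)
  if (is.character(layer)) {
    if (layer %in% c("input", "reshape")) {
      idx <- 0L
    } else {
      idx <- match(layer, nms)
      if (is.na(idx)) {
        stop("unknown layer '", layer, "'; available layers: input, ",
             paste(nms, collapse = ", "), call. = FALSE)
      }
    }
  } else {
    idx <- as.integer(layer)
    if (idx < 0L || idx > length(nms)) {
      stop("layer index out of range; available layers: 0 (input) .. ",
           length(nms), " (", paste(nms, collapse = ", "), ")", call. = FALSE)
    }
  }
  mat <- nn_layer_output(engine_spec(model$spec), model$spec$input_shape,
                         model$weights, batch$x, idx, batch_size)
  structure(list(layer_name = if (idx == 0L) "input" else nms[idx],
                 matrix = mat, ids = batch$ids, labels = batch$y),
            class = "layer_activation")
}

has_python_umap <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ok <- tryCatch({
        status <- suppressWarnings(system2(
          "python", c("-c", shQuote("import umap, numpy")),
          stdout = FALSE, stderr = FALSE))
        identical(status, 0L)
      }, error = function(e) FALSE)
      cache <<- ok
    }
    cache
  }
})

#' Project layer activations to 2-D with UMAP
#'
#' Embeds the activation matrix with uniform manifold approximation and
#' projection (via the bundled python/umap-learn runner), preserving local
#' neighbourhood structure.  Deterministic under `seed`.
#'
#' @param activation a `layer_activation` (or plain numeric matrix).
#' @param n_neighbors UMAP neighbourhood size (default 15).
#' @param min_dist UMAP minimum embedding distance (default 0.1).
#' @param seed random state passed to UMAP.
#' @return An `embedding_2d`: list with `coords` (N x 2), `layer_name`,
#'   `umap_params`, `ids`, `labels`.
#' @export
umap_project <- function(activation, n_neighbors = 15L, min_dist = 0.1,
                         seed = 42L) {
  mat <- if (inherits(activation, "layer_activation")) activation$matrix
         else as.matrix(activation)
  if (nrow(mat) < n_neighbors + 1L) {
    stop("need at least n_neighbors + 1 samples for UMAP", call. = FALSE)
  }
  if (!has_python_umap()) {
    stop("umap_project requires `python` with the umap-learn package on the PATH",
         call. = FALSE)
  }
  infile <- tempfile(fileext = ".csv")
  outfile <- tempfile(fileext = ".csv")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  utils::write.table(mat, infile, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  script <- system.file("python", "run_umap.py", package = "deepm5U",
                        mustWork = TRUE)
  status <- system2("python",
                    c(shQuote(script), shQuote(infile), shQuote(outfile),
                      as.integer(n_neighbors), format(min_dist),
                      as.integer(seed)),
                    stdout = FALSE, stderr = "")
  if (!identical(status, 0L) || !file.exists(outfile)) {
    stop("UMAP runner failed (exit status ", status, ")", call. = FALSE)
  }
  coords <- as.matrix(utils::read.table(outfile, sep = ","))
  dimnames(coords) <- list(NULL, c("umap1", "umap2"))
  structure(list(coords = coords,
                 layer_name = if (inherits(activation, "layer_activation"))
                   activation$layer_name else "matrix",
                 umap_params = list(n_neighbors = n_neighbors,
                                    min_dist = min_dist, seed = seed),
                 ids = if (inherits(activation, "layer_activation"))
                   activation$ids else NULL,
                 labels = if (inherits(activation, "layer_activation"))
                   activation$labels else NULL),
            class = "embedding_2d")
}

#' Quantify class separation of an embedding
#'
#' Mean silhouette width of the 2-D embedding (or any coordinate matrix)
#' under the class labels; 1 = perfectly separated clusters, 0 = no structure.
#'
#' @param embedding an `embedding_2d` or numeric matrix of coordinates.
#' @param labels class labels (taken from the embedding when omitted).
#' @export
class_separation <- function(embedding, labels = NULL) {
  coords <- if (inherits(embedding, "embedding_2d")) embedding$coords
            else as.matrix(embedding)
  if (is.null(labels) && inherits(embedding, "embedding_2d")) {
    labels <- embedding$labels
  }
  if (is.null(labels)) stop("labels are required", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("need at least two classes", call. = FALSE)
  }
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(coords))
  mean(sil[, "sil_width"])
}

#' Write embedding coordinates as CSV
#'
#' @param embedding an `embedding_2d`.
#' @param path output path (columns id, x, y, label).
#' @export
write_embedding <- function(embedding, path) {
  df <- data.frame(id = embedding$ids %||% seq_len(nrow(embedding$coords)),
                   x = embedding$coords[, 1L], y = embedding$coords[, 2L],
                   label = embedding$labels %||% NA)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Shapley machinery.  Features are groups of input coordinates (for sequences,
# one group per position).  The value function is
#   v(S) = mean over background rows b of f(composite(x, b, S)),
# the interventional conditional expectation: coordinates in S come from x,
# the rest from the background sample.

# All permutations of 1..m (m <= 8 in practice).
all_permutations <- function(m) {
  if (m == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(m - 1L)
  out <- matrix(0L, m * nrow(sub), m)
  r <- 1L
  for (k in seq_len(m)) {
    block <- cbind(k, sub + (sub >= k))
    out[r:(r + nrow(sub) - 1L), ] <- block
    r <- r + nrow(sub)
  }
  out
}

# Value table over all 2^m subsets (bitmask-indexed, v[mask+1]).
subset_value_table <- function(f, x, background, groups) {
  m <- length(groups)
  n_sub <- 2L^m
  bg_n <- nrow(background)
  d <- length(x)
  comp <- matrix(0, n_sub * bg_n, d)
  for (mask in 0:(n_sub - 1L)) {
    sel <- logical(d)
    for (g in seq_len(m)) {
      if (bitwAnd(mask, bitwShiftL(1L, g - 1L)) != 0L) sel[groups[[g]]] <- TRUE
    }
    rows <- mask * bg_n + seq_len(bg_n)
    comp[rows, ] <- background
    comp[rows, sel] <- matrix(rep(x[sel], each = bg_n), nrow = bg_n)
  }
  fv <- f(comp)
  stopifnot(length(fv) == n_sub * bg_n)
  as.numeric(tapply(fv, rep(0:(n_sub - 1L), each = bg_n), mean))
}

shapley_exact <- function(f, x, background, groups) {
  m <- length(groups)
  if (m > 8L) stop("exact Shapley is limited to 8 feature groups",
                   call. = FALSE)
  v <- subset_value_table(f, x, background, groups)
  phi <- numeric(m)
  # average marginal contribution over all m! orderings, reusing the
  # subset-value table
  perms <- all_permutations(m)
  bits <- bitwShiftL(1L, seq_len(m) - 1L)
  for (r in seq_len(nrow(perms))) {
    mask <- 0L
    for (g in perms[r, ]) {
      nxt <- bitwOr(mask, bits[g])
      phi[g] <- phi[g] + v[nxt + 1L] - v[mask + 1L]
      mask <- nxt
    }
  }
  phi <- phi / nrow(perms)
  list(phi = phi, phi0 = v[1L], f_x = v[length(v)])
}

shapley_sampling <- function(f, x, background, groups, nsim, seed) {
  m <- length(groups)
  d <- length(x)
  bg_n <- nrow(background)
  phi <- numeric(m)
  perms <- with_seed(seed, {
    matrix(unlist(lapply(seq_len(nsim), function(i) sample.int(m))),
           nrow = nsim, byrow = TRUE)
  })
  # one batched evaluation per permutation: (m+1) prefixes x bg_n backgrounds
  for (p in seq_len(nsim)) {
    ord <- perms[p, ]
    comp <- matrix(0, (m + 1L) * bg_n, d)
    sel <- logical(d)
    for (step in 0:m) {
      if (step > 0L) sel[groups[[ord[step]]]] <- TRUE
      rows <- step * bg_n + seq_len(bg_n)
      comp[rows, ] <- background
      if (any(sel)) comp[rows, sel] <- matrix(rep(x[sel], each = bg_n),
                                              nrow = bg_n)
    }
    fv <- f(comp)
    vbar <- as.numeric(tapply(fv, rep(0:m, each = bg_n), mean))
    phi[ord] <- phi[ord] + diff(vbar)
  }
  phi <- phi / nsim
  list(phi = phi, phi0 = mean(f(background)),
       f_x = mean(f(matrix(rep(x, each = bg_n), nrow = bg_n))))
}

#' Shapley values of grouped input features
#'
#' Computes per-group Shapley values of `f(x)` against a background reference
#' set.  The value of a coalition is the mean model output when coalition
#' coordinates come from `x` and the rest from a background sample.  With
#' `method = "exact"` (feasible up to 12 groups) all coalitions are evaluated
#' and combined by averaging marginal contributions over every feature
#' ordering; `"sampling"` draws `nsim` random orderings (Castro-style
#' permutation sampling).  Both estimators satisfy the additivity identity
#' `f(x) = phi0 + sum(phi)` exactly.
#'
#' @param f vectorised function: numeric matrix of rows -> numeric outputs.
#' @param x numeric vector, the sample to explain.
#' @param background numeric matrix of reference rows (same width as `x`).
#' @param groups list of coordinate-index vectors, one per feature group;
#'   default one group per coordinate.
#' @param method `"auto"` (exact when feasible), `"exact"`, or `"sampling"`.
#' @param nsim permutations for sampling mode.
#' @param seed seed for sampling mode.
#' @return list with `phi` (per group), `phi0`, `f_x`, `residual`.
#' @export
shapley_values <- function(f, x, background,
                           groups = as.list(seq_along(x)),
                           method = c("auto", "exact", "sampling"),
                           nsim = 32L, seed = 1L) {
  method <- match.arg(method)
  background <- as.matrix(background)
  if (nrow(background) == 0L) stop("background must be non-empty", call. = FALSE)
  stopifnot(ncol(background) == length(x))
  m <- length(groups)
  if (method == "auto") method <- if (m <= 8L) "exact" else "sampling"
  res <- if (method == "exact") shapley_exact(f, x, background, groups)
         else shapley_sampling(f, x, background, groups, nsim, seed)
  res$residual <- res$f_x - res$phi0 - sum(res$phi)
  res$method <- method
  res
}

#' Shapley attribution of a sequence prediction
#'
#' Explains one sequence window's predicted m5U probability by Shapley values
#' with one feature group per position: a position is "present" when its base
#' comes from the explained sequence and "absent" when it comes from a
#' background sequence.  The per-position value is assigned to the observed
#' base's channel of the 41 x 4 attribution matrix (other channels 0).  A
#' position whose base is constant across the explained sequence and the
#' whole background (the center U) is a null player and receives exactly 0.
#'
#' @param model an `ensemble_model`, `predictive_model`, or probability
#'   function over encoded batches; ensembles are explained as their averaged
#'   probability, the deployed predictor.
#' @param x the sequence to explain: a 1-row record data frame, sequence
#'   string, or single-sequence `encoded_batch`.
#' @param background reference sequences (records, character vector or
#'   `encoded_batch`), typically a seeded subsample of ~100 training
#'   sequences.
#' @param method,nsim,seed passed to [shapley_values()].
#' @return An `attribution_matrix`: list with `phi` (L x 4), `phi0`, `f_x`,
#'   `residual`, `seq`, `id`.
#' @export
shap_attributions <- function(model, x, background,
                              method = c("auto", "exact", "sampling"),
                              nsim = 32L, seed = 1L) {
  method <- match.arg(method)
  xb <- as_encoded_batch(x)
  if (dim(xb$x)[1L] != 1L) stop("explain one sequence at a time", call. = FALSE)
  bg <- as_encoded_batch(background)
  nb <- dim(bg$x)[1L]
  if (nb == 0L) stop("background must be non-empty", call. = FALSE)
  L <- dim(xb$x)[2L]
  pred <- as_predictor(model)
  f <- function(rows) {
    arr <- array(rows, dim = c(nrow(rows), L, 4L),
                 dimnames = list(NULL, NULL, BASES))
    pred(structure(list(x = arr, y = NULL, ids = seq_len(nrow(rows))),
                   class = "encoded_batch"))
  }
  xvec <- as.numeric(xb$x[1L, , ])            # (L*4), position-major in cols
  bgmat <- matrix(bg$x, nrow = nb)
  groups <- lapply(seq_len(L), function(i) i + L * (0:3))
  if (method == "auto") method <- if (L <= 8L) "exact" else "sampling"
  res <- shapley_values(f, xvec, bgmat, groups, method = method,
                        nsim = nsim, seed = seed)
  seq_chr <- decode_one_hot(xb)
  obs <- match(strsplit(seq_chr, "")[[1L]], BASES)
  phi <- matrix(0, L, 4L, dimnames = list(NULL, BASES))
  phi[cbind(seq_len(L), obs)] <- res$phi
  structure(list(phi = phi, phi0 = res$phi0, f_x = res$f_x,
                 residual = res$residual, seq = seq_chr,
                 id = xb$ids[[1L]], method = res$method),
            class = "attribution_matrix")
}

#' Per-position importance (logo letter heights)
#'
#' Value at position i is the attribution of the base observed there,
#' the letter height in a SHAP sequence logo.
#'
#' @param attr an `attribution_matrix`.
#' @param seq sequence (defaults to the explained sequence).
#' @return Numeric vector of length L.
#' @export
per_base_importance <- function(attr, seq = attr$seq) {
  stopifnot(inherits(attr, "attribution_matrix"))
  obs <- match(strsplit(seq, "")[[1L]], BASES)
  stopifnot(length(obs) == nrow(attr$phi))
  attr$phi[cbind(seq_len(nrow(attr$phi)), obs)]
}

#' Scale attributions to \[-0.25, 0.25\] and accumulate by position and base
#'
#' Each sequence's attribution matrix is scaled by `0.25 / max(abs(phi))`
#' (an all-zero matrix stays zero), so single-base magnitudes lie in
#' \[-0.25, 0.25\]; the scaled values are then summed over sequences into a
#' position-by-base accumulation matrix restricted to each sequence's
#' observed bases.  Positive accumulated values mark favoured features,
#' negative values disfavoured ones.  Scaling is per sequence and never flips
#' a sign.  Sequences whose scaled values sum outside \[-1, 1\] are flagged.
#'
#' @param attrs list of `attribution_matrix` objects.
#' @param seqs optional character vector overriding the stored sequences.
#' @return A `normalized_attribution`: list with `scaled` (list of L x 4
#'   matrices), `accumulated` (L x 4), `sums` and `sum_in_range` per sequence.
#' @export
normalize_and_accumulate <- function(attrs, seqs = NULL) {
  if (length(attrs) == 0L) stop("no attributions to accumulate", call. = FALSE)
  L <- nrow(attrs[[1L]]$phi)
  acc <- matrix(0, L, 4L, dimnames = list(NULL, BASES))
  scaled <- vector("list", length(attrs))
  sums <- numeric(length(attrs))
  for (k in seq_along(attrs)) {
    a <- attrs[[k]]
    s <- if (is.null(seqs)) a$seq else seqs[[k]]
    mx <- max(abs(a$phi))
    sc <- if (mx > 0) a$phi * (0.25 / mx) else a$phi
    scaled[[k]] <- sc
    sums[k] <- sum(sc)
    obs <- match(strsplit(s, "")[[1L]], BASES)
    mask <- matrix(0, L, 4L)
    mask[cbind(seq_len(L), obs)] <- 1
    acc <- acc + sc * mask
  }
  in_range <- abs(sums) <= 1 + 1e-12
  if (!all(in_range)) {
    warning(sprintf("%d sequence(s) have scaled attribution sums outside [-1, 1]",
                    sum(!in_range)), call. = FALSE)
  }
  structure(list(scaled = scaled, accumulated = acc, sums = sums,
                 sum_in_range = in_range, n = length(attrs)),
            class = "normalized_attribution")
}

#' Write an attribution or accumulation matrix as tabular text
#'
#' Position, A, C, G, U columns - the layout consumed by logo-plotting tools.
#'
#' @param mat an `attribution_matrix`, `normalized_attribution` (its
#'   accumulated matrix), or plain L x 4 matrix.
#' @param path output path.
#' @export
write_attribution_table <- function(mat, path) {
  m <- if (inherits(mat, "attribution_matrix")) mat$phi
       else if (inherits(mat, "normalized_attribution")) mat$accumulated
       else as.matrix(mat)
  df <- data.frame(position = seq_len(nrow(m)), m)
  colnames(df) <- c("position", BASES)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
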