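#' Enumerate all single-base substitutions of a window
#'
#' Converts every position of the 41-nt window to every other base, yielding
#' exactly 41 x 3 = 123 mutants at Hamming distance 1, in position-major order
#' with bases ordered A, C, G, U.
#'
#' @param seq a valid 41-nt sequence over `{A,C,G,U}` (T accepted).
#' @return Data frame with columns `position`, `base`, `seq`.
#' @export
saturation_mutants <- function(seq) {
  seq <- normalize_rna(seq)
  L <- nchar(seq)
  if (L != WINDOW_LENGTH || grepl("[^ACGU]", seq)) {
    stop("need a valid 41-nt sequence over {A,C,G,U}", call. = FALSE)
  }
  chars <- strsplit(seq, "")[[1L]]
  out <- vector("list", L)
  for (i in seq_len(L)) {
    alts <- setdiff(BASES, chars[i])
    muts <- vapply(alts, function(b) {
      s <- chars
      s[i] <- b
      paste(s, collapse = "")
    }, "")
    out[[i]] <- data.frame(position = i, base = alts, seq = unname(muts),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mutation effect scores from in-silico saturation mutagenesis
#'
#' Predicts the wild type and all 123 single-base mutants in one batch and
#' records the probability change `delta[i, b] = p(mutant with base b at i) -
#' p(wild type)`.  Wild-type cells are 0 by construction; a positive score
#' means the substitution pushes the prediction toward the m5U class.  The
#' center position is mutated like any other; mask it downstream when the
#' center U is definitional.
#'
#' @param model trained `ensemble_model`, `predictive_model`, or probability
#'   function.
#' @param seq the wild-type 41-nt sequence.
#' @param seq_id identifier stored in the result.
#' @return A `mutation_effect_matrix`: list with `delta` (41 x 4, in
#'   `[-1, 1]`), `wt_prob`, `seq`, `seq_id`.
#' @export
effect_scores <- function(model, seq, seq_id = "seq") {
  seq <- normalize_rna(seq)
  muts <- saturation_mutants(seq)
  pred <- as_predictor(model)
  p <- pred(one_hot_encode(c(seq, muts$seq)))
  wt_prob <- p[[1L]]
  delta <- matrix(0, WINDOW_LENGTH, 4L, dimnames = list(NULL, BASES))
  delta[cbind(muts$position, match(muts$base, BASES))] <- p[-1L] - wt_prob
  structure(list(delta = delta, wt_prob = wt_prob, seq = seq,
                 seq_id = seq_id),
            class = "mutation_effect_matrix")
}

#' Positions with the largest mutation effects
#'
#' Ranks positions by their largest absolute probability change over the
#' three substitutions.  The window center is masked by default: a non-U
#' center is out of distribution for models trained on centered-U windows
#' (every training example of either class has U there), so its effect
#' scores reflect extrapolation rather than learned sequence determinants.
#'
#' @param mem a `mutation_effect_matrix`.
#' @param n how many positions to return.
#' @param mask_center exclude the definitional center position (default TRUE).
#' @return Integer vector of positions, strongest first.
#' @export
top_effect_positions <- function(mem, n = 3L, mask_center = TRUE) {
  stopifnot(inherits(mem, "mutation_effect_matrix"))
  per_pos <- apply(abs(mem$delta), 1L, max)
  if (mask_center) per_pos[CENTER_POS] <- -Inf
  order(per_pos, decreasing = TRUE)[seq_len(n)]
}

#' Heatmap-ready table of mutation effects
#'
#' The 4 x 41 layout used for mutagenesis heatmaps: rows A, C, G, U, columns
#' positions 1-41, with wild-type cells marked by the companion `wildtype`
#' logical matrix.
#'
#' @param mem a `mutation_effect_matrix`.
#' @return list with `table` (4 x 41 numeric), `wildtype` (4 x 41 logical),
#'   `seq`, `seq_id`, `wt_prob`.
#' @export
effect_heatmap_table <- function(mem) {
  stopifnot(inherits(mem, "mutation_effect_matrix"))
  tab <- t(mem$delta)
  colnames(tab) <- seq_len(ncol(tab))
  chars <- strsplit(mem$seq, "")[[1L]]
  wt <- matrix(FALSE, 4L, WINDOW_LENGTH, dimnames = dimnames(tab))
  wt[cbind(match(chars, BASES), seq_len(WINDOW_LENGTH))] <- TRUE
  list(table = tab, wildtype = wt, seq = mem$seq, seq_id = mem$seq_id,
       wt_prob = mem$wt_prob)
}

#' Write / read a mutation-effect table
#'
#' Tab-separated 4 x 41 table with a header comment carrying the wild-type
#' sequence and probability, so the file round-trips losslessly.
#'
#' @param mem a `mutation_effect_matrix`.
#' @param path file path.
#' @export
write_effect_table <- function(mem, path) {
  ht <- effect_heatmap_table(mem)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seq_id: %s", ht$seq_id), con)
  writeLines(sprintf("# seq: %s", ht$seq), con)
  writeLines(sprintf("# wt_prob: %s",
                     format(ht$wt_prob, digits = 17)), con)
  df <- data.frame(base = rownames(ht$table), ht$table, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_effect_table
#' @export
read_effect_table <- function(path) {
  lines <- readLines(path)
  meta <- function(key) {
    sub(sprintf("^# %s: ", key), "",
        grep(sprintf("^# %s: ", key), lines, value = TRUE)[[1L]])
  }
  df <- utils::read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                          sep = "\t", check.names = FALSE)
  tab <- as.matrix(df[, -1L, drop = FALSE])
  rownames(tab) <- df$base
  delta <- t(tab)
  rownames(delta) <- NULL
  structure(list(delta = delta, wt_prob = as.numeric(meta("wt_prob")),
                 seq = meta("seq"), seq_id = meta("seq_id")),
            class = "mutation_effect_matrix")
}
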