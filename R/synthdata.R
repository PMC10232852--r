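#' Specify a motif planted into positive windows
#'
#' A motif is a pattern over `{A,C,G,U,X}` written at a fixed 1-based start
#' position of the 41-nt window; `X` positions are wildcards left to the
#' background.  Motifs may not touch the window center (position 21), which is
#' the queried uridine in both classes.
#'
#' @param pattern pattern string over `{A,C,G,U,X}`.
#' @param start 1-based start position in the window.
#' @export
motif_spec <- function(pattern, start) {
  pattern <- toupper(pattern)
  if (grepl("[^ACGUX]", pattern)) {
    stop("motif pattern may only contain A, C, G, U, X", call. = FALSE)
  }
  start <- as.integer(start)
  end <- start + nchar(pattern) - 1L
  if (start < 1L || end > WINDOW_LENGTH) {
    stop("motif must fit inside the 41-nt window", call. = FALSE)
  }
  if (start <= CENTER_POS && end >= CENTER_POS) {
    stop("motif may not overlap the center position (21)", call. = FALSE)
  }
  structure(list(pattern = pattern, start = start, end = end),
            class = "motif_spec")
}

#' Default planted motifs: GGU upstream, CXAXCCC downstream
#'
#' The defaults plant `GGU` at positions 18-20 and `CXAXCCC` at positions
#' 23-29, the sequence determinants the m5U classifier is expected to recover.
#'
#' @export
default_motifs <- function() {
  list(motif_spec("GGU", 18L), motif_spec("CXAXCCC", 23L))
}

#' Configuration of the planted-motif synthetic benchmark
#'
#' Emulates the structure of the m5U benchmark: 41-nt windows with U fixed at
#' the center in both classes, negatives drawn i.i.d. from the background
#' composition, and positives identical to negatives except that each motif is
#' written at its position with probability `plant_prob`.
#'
#' @param n_pos,n_neg class sizes; set e.g. `n_neg = 10 * n_pos` for the 1:10
#'   imbalanced regime.
#' @param background length-4 base probabilities (A,C,G,U), summing to 1.
#' @param motifs list of [motif_spec()]s; default [default_motifs()].
#' @param plant_prob probability that a positive carries each motif
#'   (default 0.9, so the task has irreducible error and confusion tables are
#'   non-degenerate).
#' @param seed integer seed; generation is fully reproducible.
#' @export
synthetic_config <- function(n_pos = 2000L, n_neg = 2000L,
                             background = rep(0.25, 4L),
                             motifs = default_motifs(),
                             plant_prob = 0.9, seed = 1L) {
  if (length(background) != 4L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-8) {
    stop("background must be 4 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  if (plant_prob < 0 || plant_prob > 1) {
    stop("plant_prob must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_pos >= 1L, n_neg >= 1L)
  for (m in motifs) stopifnot(inherits(m, "motif_spec"))
  if (length(motifs) > 1L) {
    spans <- lapply(motifs, function(m) m$start:m$end)
    if (any(duplicated(unlist(spans)))) {
      stop("motifs overlap each other", call. = FALSE)
    }
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 background = background, motifs = motifs,
                 plant_prob = plant_prob, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' A background preset with upstream G and downstream C enrichment
#'
#' Mimics the composition bias seen around real m5U sites (guanine
#' over-represented upstream, cytosine downstream) for logo-rendering demos.
#' Returns a 41 x 4 matrix of per-position background probabilities usable via
#' the `position_background` argument of [generate_dataset()].
#'
#' @export
biased_background <- function() {
  bg <- matrix(0.25, WINDOW_LENGTH, 4L, dimnames = list(NULL, BASES))
  up <- seq_len(CENTER_POS - 1L)
  dn <- (CENTER_POS + 1L):WINDOW_LENGTH
  bg[up, ] <- matrix(rep(c(0.20, 0.20, 0.40, 0.20), each = length(up)),
                     ncol = 4L)
  bg[dn, ] <- matrix(rep(c(0.20, 0.40, 0.20, 0.20), each = length(dn)),
                     ncol = 4L)
  bg
}

#' Generate a planted-motif synthetic dataset
#'
#' All windows are 41 nt with U at position 21.  Negatives are i.i.d.
#' background at every non-center position; positives additionally carry each
#' configured motif with probability `plant_prob`.
#'
#' @param config a [synthetic_config()].
#' @param position_background optional 41 x 4 matrix of per-position
#'   probabilities overriding the flat background (e.g. [biased_background()]).
#' @return Record data frame (`id`, `seq`, `label`).
#' @export
generate_dataset <- function(config, position_background = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  L <- WINDOW_LENGTH
  bg <- position_background
  if (is.null(bg)) {
    bg <- matrix(rep(config$background, each = L), nrow = L)
  }
  stopifnot(nrow(bg) == L, ncol(bg) == 4L)
  n_tot <- config$n_pos + config$n_neg
  with_seed(config$seed, {
    m <- matrix("", n_tot, L)
    for (p in seq_len(L)) {
      m[, p] <- sample(BASES, n_tot, replace = TRUE, prob = bg[p, ])
    }
    m[, CENTER_POS] <- "U"
    for (mo in config$motifs) {
      carry <- stats::runif(config$n_pos) < config$plant_prob
      pat <- strsplit(mo$pattern, "")[[1L]]
      for (k in seq_along(pat)) {
        if (pat[k] != "X") m[which(carry), mo$start + k - 1L] <- pat[k]
      }
    }
  })
  seqs <- apply(m, 1L, paste, collapse = "")
  data.frame(
    id = c(sprintf("pos_%05d", seq_len(config$n_pos)),
           sprintf("neg_%05d", seq_len(config$n_neg))),
    seq = seqs,
    label = rep(c(1L, 0L), c(config$n_pos, config$n_neg)),
    stringsAsFactors = FALSE
  )
}

#' Per-position nucleotide composition
#'
#' Computes the 41 x 4 matrix of per-position base frequencies used for
#' classical sequence logos (each row sums to 1).
#'
#' @param records record data frame or character vector of equal-length
#'   sequences.
#' @return A `composition_matrix`: numeric matrix `L x 4` with columns
#'   A, C, G, U and attribute `n` (number of sequences).
#' @export
composition_matrix <- function(records) {
  seqs <- if (is.character(records)) records else records$seq
  if (length(seqs) == 0L) stop("no sequences", call. = FALSE)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences have mixed lengths", call. = FALSE)
  chars <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs), byrow = TRUE)
  freq <- t(apply(chars, 2L, function(col) {
    tabulate(match(col, BASES), nbins = 4L) / length(col)
  }))
  dimnames(freq) <- list(NULL, BASES)
  structure(freq, n = length(seqs), class = c("composition_matrix", "matrix"))
}

#' Write a dataset as the two-file per-class FASTA layout
#'
#' Writes positives and negatives to separate FASTA files, the layout consumed
#' by [read_labeled_sequences()].  Output is byte-identical for identical
#' input, so simulation under a fixed seed is reproducible on disk.
#'
#' @param records record data frame.
#' @param pos_path,neg_path output FASTA paths.
#' @export
write_dataset_fasta <- function(records, pos_path, neg_path) {
  write_one <- function(df, path) {
    lines <- character(2L * nrow(df))
    lines[c(TRUE, FALSE)] <- paste0(">", df$id)
    lines[c(FALSE, TRUE)] <- df$seq
    writeLines(lines, path)
  }
  write_one(records[records$label == 1L, , drop = FALSE], pos_path)
  write_one(records[records$label == 0L, , drop = FALSE], neg_path)
  invisible(c(pos = pos_path, neg = neg_path))
}
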