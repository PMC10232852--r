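#' Read labelled sequence windows from per-class files
#'
#' Reads one file of positive (m5U) windows and one file of negative windows.
#' Each file is either FASTA (detected by a leading `>`) or plain text with one
#' sequence per line.  Sequences are upper-cased and `T` is mapped to `U`, so
#' DNA-alphabet site lists are accepted.  Windows must be exactly 41 nt over
#' `{A,C,G,U}`; offending records abort the run (or are dropped with
#' `skip_invalid = TRUE`), and their ids are reported.  A non-U base at the
#' window center (position 21) raises a warning, not an error, so the reader
#' also serves marks other than m5U.
#'
#' @param pos_path,neg_path paths to the positive- and negative-class files.
#' @param skip_invalid drop invalid records (with a warning) instead of
#'   aborting.
#' @param expected_length required window length (default 41).
#' @param check_center warn when the center base is not U.
#' @return A data frame with columns `id`, `seq`, `label` (1 = positive).
#'   Duplicated sequences appearing in both classes are reported in the
#'   `"duplicates"` attribute.
#' @export
read_labeled_sequences <- function(pos_path, neg_path, skip_invalid = FALSE,
                                   expected_length = WINDOW_LENGTH,
                                   check_center = TRUE) {
  pos <- read_sequence_file(pos_path)
  neg <- read_sequence_file(neg_path)
  rec <- data.frame(
    id = c(names(pos), names(neg)),
    seq = c(unname(pos), unname(neg)),
    label = rep(c(1L, 0L), c(length(pos), length(neg))),
    stringsAsFactors = FALSE
  )
  rec$seq <- normalize_rna(rec$seq)

  bad_len <- nchar(rec$seq) != expected_length
  bad_chr <- grepl(sprintf("[^%s]", paste(BASES, collapse = "")), rec$seq)
  bad <- bad_len | bad_chr
  if (any(bad)) {
    report <- paste(utils::head(rec$id[bad], 20L), collapse = ", ")
    msg <- sprintf(
      "%d record(s) failed validation (wrong length or non-ACGU/T character): %s%s",
      sum(bad), report, if (sum(bad) > 20L) ", ..." else ""
    )
    if (!skip_invalid) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    rec <- rec[!bad, , drop = FALSE]
  }
  if (nrow(rec) == 0L) stop("no valid sequence records", call. = FALSE)

  if (check_center && expected_length >= CENTER_POS) {
    off <- substr(rec$seq, CENTER_POS, CENTER_POS) != "U"
    if (any(off)) {
      warning(sprintf(
        "%d record(s) do not have U at the center position (%d); continuing",
        sum(off), CENTER_POS
      ), call. = FALSE)
    }
  }

  dup <- intersect(rec$seq[rec$label == 1L], rec$seq[rec$label == 0L])
  if (length(dup) > 0L) {
    warning(sprintf(
      "%d sequence(s) occur in both classes; see attr(x, 'duplicates')",
      length(dup)
    ), call. = FALSE)
  }
  attr(rec, "duplicates") <- dup
  rownames(rec) <- NULL
  rec
}

read_sequence_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty sequence file: ", path, call. = FALSE)
  if (startsWith(trimws(lines[[1L]]), ">")) {
    set <- Biostrings::readBStringSet(path)
    seqs <- as.character(set)
    names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  } else {
    seqs <- trimws(lines)
    names(seqs) <- sprintf("%s_%d", tools::file_path_sans_ext(basename(path)),
                           seq_along(seqs))
  }
  seqs
}

normalize_rna <- function(seqs) {
  chartr("Tt", "UU", toupper(seqs))
}

#' One-hot encode sequence windows
#'
#' Encodes records into a rank-3 array `N x L x 4` with the fixed channel order
#' A, C, G, U: A = (1,0,0,0), C = (0,1,0,0), G = (0,0,1,0), U = (0,0,0,1).
#'
#' @param records a data frame from [read_labeled_sequences()] /
#'   [generate_dataset()], or a character vector of equal-length sequences.
#' @return An `encoded_batch`: list with `x` (array `N x L x 4`), `y`
#'   (labels or NULL) and `ids`.
#' @export
one_hot_encode <- function(records) {
  if (is.character(records)) {
    records <- data.frame(id = sprintf("seq_%d", seq_along(records)),
                          seq = normalize_rna(records), label = NA_integer_,
                          stringsAsFactors = FALSE)
  }
  seqs <- records$seq
  n <- length(seqs)
  if (n == 0L) stop("no sequences to encode", call. = FALSE)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences have mixed lengths", call. = FALSE)
  chars <- strsplit(seqs, "", fixed = TRUE)
  codes <- match(unlist(chars), BASES)
  if (anyNA(codes)) {
    stop("sequences contain characters outside {A,C,G,U}; validate first",
         call. = FALSE)
  }
  x <- array(0, dim = c(n, L, 4L), dimnames = list(NULL, NULL, BASES))
  x[cbind(rep(seq_len(n), each = L), rep(seq_len(L), times = n), codes)] <- 1
  y <- if (all(is.na(records$label))) NULL else records$label
  structure(list(x = x, y = y, ids = records$id), class = "encoded_batch")
}

#' Decode a one-hot batch back to sequences
#'
#' Inverse of [one_hot_encode()]; used mainly to assert that encoding is a
#' bijection on valid sequences.
#'
#' @param batch an `encoded_batch`.
#' @return Character vector of sequences.
#' @export
decode_one_hot <- function(batch) {
  stopifnot(inherits(batch, "encoded_batch"))
  x <- batch$x
  apply(x, 1L, function(m) paste(BASES[max.col(m)], collapse = ""))
}

#' @export
print.encoded_batch <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<encoded_batch> %d sequences x %d positions x %d channels (%s)\n",
              d[1], d[2], d[3], paste(BASES, collapse = ",")))
  if (!is.null(x$y)) {
    cat(sprintf("  labels: %d positive / %d negative\n",
                sum(x$y == 1L), sum(x$y == 0L)))
  }
  invisible(x)
}

split_indices_stratified <- function(labels, fracs, seed, shuffle = TRUE) {
  parts <- vector("list", length(fracs))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (shuffle) idx <- sample(idx)
      n <- length(idx)
      sizes <- round(fracs * n)
      # keep partitions exhaustive: last fraction absorbs rounding remainder
      sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
      if (any(sizes < 0L)) stop("fractions leave a negative partition",
                                call. = FALSE)
      start <- 1L
      for (k in seq_along(fracs)) {
        take <- if (sizes[k] > 0L) idx[start:(start + sizes[k] - 1L)] else integer()
        parts[[k]] <- c(parts[[k]], take)
        start <- start + sizes[k]
      }
    }
  })
  lapply(parts, sort.int)
}

#' Stratified train/test split
#'
#' Splits records into a training and a test partition, stratified by class:
#' per-class training counts equal `round(train_frac * class_count)`.  The
#' shuffle (on by default) and the partition are fully determined by `seed`.
#'
#' @param records labelled records data frame.
#' @param train_frac training fraction in (0,1); default 0.8.
#' @param seed integer seed controlling the shuffle.
#' @param shuffle shuffle before splitting (default TRUE).
#' @return list with elements `train` and `test` (record data frames).
#' @export
stratified_split <- function(records, train_frac = 0.8, seed = 1L,
                             shuffle = TRUE) {
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must lie strictly between 0 and 1", call. = FALSE)
  }
  check_min_class_counts(records$label)
  idx <- split_indices_stratified(records$label, c(train_frac, 1 - train_frac),
                                  seed, shuffle)
  list(train = records[idx[[1L]], , drop = FALSE],
       test = records[idx[[2L]], , drop = FALSE])
}

#' Stratified train/validation/test split
#'
#' Three-way stratified split with the published 70/10/20 default fractions.
#' Partitions are disjoint, exhaustive, and reproducible under `seed`.
#'
#' @param records labelled records data frame.
#' @param fractions length-3 fractions summing to 1 (default `c(.7,.1,.2)`).
#' @param seed integer seed.
#' @param shuffle shuffle before splitting (default TRUE).
#' @return A `dataset_split`: list with `train`, `validation`, `test`,
#'   `fractions`, `seed`.
#' @export
three_way_split <- function(records, fractions = c(0.70, 0.10, 0.20),
                            seed = 1L, shuffle = TRUE) {
  if (length(fractions) != 3L || any(fractions <= 0)) {
    stop("fractions must be three positive numbers", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  check_min_class_counts(records$label)
  idx <- split_indices_stratified(records$label, fractions, seed, shuffle)
  structure(list(train = records[idx[[1L]], , drop = FALSE],
                 validation = records[idx[[2L]], , drop = FALSE],
                 test = records[idx[[3L]], , drop = FALSE],
                 fractions = fractions, seed = seed),
            class = "dataset_split")
}

check_min_class_counts <- function(labels) {
  tab <- table(labels)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("need at least 2 records per class to split", call. = FALSE)
  }
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d / validation %d / test %d (seed %d)\n",
              nrow(x$train), nrow(x$validation), nrow(x$test), x$seed))
  invisible(x)
}
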