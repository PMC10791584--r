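#' Labeled sequence sets
#'
#' The training substrate shared by the simulator, the classifier and the
#' interpretation tools: a set of fixed-alphabet DNA strings with a binary
#' label matrix. Topic labels are multi-label (a row may carry several 1s);
#' zonation and activity labels are one-of-k. `parent_id` records the region a
#' window was derived from, so cross-validation can keep augmented windows of
#' one region together.
#'
#' @param sequences Character vector of DNA strings (`A/C/G/T/N`).
#' @param labels Binary matrix, one row per sequence, one column per class
#'   (column names are the class names).
#' @param ids Sequence identifiers; defaults to `seq_1 ...`.
#' @param parent_ids Parent-region identifiers; defaults to `ids`.
#' @param label_mode `"multilabel"` (independent classes) or `"onehot"`
#'   (exactly one 1 per row).
#' @return A `seq_set` object.
#' @export
seq_set <- function(sequences, labels, ids = NULL, parent_ids = NULL,
                    label_mode = c("multilabel", "onehot")) {
  label_mode <- match.arg(label_mode)
  sequences <- toupper(as.character(sequences))
  if (is.null(dim(labels))) labels <- matrix(labels, ncol = 1L)
  labels <- as.matrix(labels)
  storage.mode(labels) <- "double"
  stopifnot(nrow(labels) == length(sequences), !is.null(colnames(labels)))
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  if (label_mode == "onehot" && !all(rowSums(labels) == 1)) {
    stop("one-of-k labels must have exactly one 1 per row")
  }
  if (is.null(ids)) ids <- paste0("seq_", seq_along(sequences))
  if (is.null(parent_ids)) parent_ids <- ids
  stopifnot(length(ids) == length(sequences), length(parent_ids) == length(sequences))
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) stop("sequences contain characters outside A/C/G/T/N")
  structure(
    list(
      sequences = sequences,
      labels = labels,
      ids = as.character(ids),
      parent_ids = as.character(parent_ids),
      label_mode = label_mode,
      class_names = colnames(labels)
    ),
    class = "seq_set"
  )
}

#' @export
print.seq_set <- function(x, ...) {
  cat(
    "<seq_set> ", length(x$sequences), " sequences of length ",
    paste(range(nchar(x$sequences)), collapse = "-"),
    " bp; classes (", x$label_mode, "): ",
    paste(x$class_names, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
length.seq_set <- function(x) length(x$sequences)

#' Subset a seq_set by index
#' @param x A `seq_set`.
#' @param i Integer or logical index.
#' @param ... Unused.
#' @export
`[.seq_set` <- function(x, i, ...) {
  seq_set(
    x$sequences[i], x$labels[i, , drop = FALSE],
    ids = x$ids[i], parent_ids = x$parent_ids[i], label_mode = x$label_mode
  )
}

#' @export
as_tibble.seq_set <- function(x, ...) {
  tibble::tibble(
    id = x$ids,
    parent_id = x$parent_ids,
    sequence = x$sequences,
    label = lapply(seq_along(x$ids), function(i) x$labels[i, ])
  )
}

#' One-hot encode DNA sequences
#'
#' Encodes sequences of equal length into an `(n, L, 4)` array with channel
#' order `A, C, G, T`. `N` encodes as an all-zero row; any other character is
#' an error. `decode_one_hot()` inverts the encoding.
#'
#' @param seqs Character vector of equal-length DNA strings (case-insensitive)
#'   or a `seq_set`.
#' @return An `(n, L, 4)` numeric array.
#' @examples
#' x <- one_hot("ACGT")
#' x[1, , ]          # 4 x 4 identity
#' decode_one_hot(x) # "ACGT"
#' @export
one_hot <- function(seqs) {
  if (inherits(seqs, "seq_set")) seqs <- seqs$sequences
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("all sequences must have equal length")
  n <- length(seqs)
  L <- lens[1]
  chars <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE), nrow = n, byrow = TRUE)
  code <- match(chars, c(DNA_BASES, "N"))
  if (anyNA(code)) stop("sequences contain characters outside A/C/G/T/N")
  x <- array(0, dim = c(n, L, 4L), dimnames = list(NULL, NULL, DNA_BASES))
  keep <- code <= 4L
  idx <- cbind(row(chars)[keep], col(chars)[keep], code[keep])
  x[idx] <- 1
  x
}

#' @rdname one_hot
#' @param x An `(n, L, 4)` one-hot array.
#' @export
decode_one_hot <- function(x) {
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == 4L)
  apply(x, 1L, function(m) {
    hit <- max.col(m, ties.method = "first")
    hit[rowSums(m) == 0] <- 5L
    paste(c(DNA_BASES, "N")[hit], collapse = "")
  })
}

#' Reverse complement of DNA strings
#'
#' @param seqs Character vector over `A/C/G/T/N`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seqs) {
  flipped <- chartr("ACGTNacgtn", "TGCANtgcan", seqs)
  vapply(
    strsplit(flipped, ""),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  )
}

#' Slide fixed windows over the sequences of a set
#'
#' Sequence-level analogue of [augment_windows()]: every sequence of length
#' `extend_to` yields `floor((extend_to - window)/stride) + 1` windows of
#' length `window`, each inheriting the parent labels and id. The window whose
#' offset centres it in the parent is flagged so evaluation can use the
#' non-augmented view.
#'
#' @param x A `seq_set` whose sequences all have length `extend_to`.
#' @param window Window width in bp.
#' @param stride Stride in bp.
#' @return A list with `set` (the augmented `seq_set`) and `is_center`
#'   (logical flag per window).
#' @export
augment_seq_set <- function(x, window = 500L, stride = 50L) {
  stopifnot(inherits(x, "seq_set"))
  L <- nchar(x$sequences[1])
  if (window > L) stop("window exceeds sequence length")
  offsets <- seq(0L, L - window, by = stride)
  center_off <- offsets[which.min(abs(offsets - (L - window) / 2))]
  pieces <- lapply(offsets, function(off) substr(x$sequences, off + 1L, off + window))
  n_win <- length(offsets)
  seqs <- unlist(pieces, use.names = FALSE)
  ord <- rep(seq_along(x$sequences), times = n_win)
  set <- seq_set(
    seqs,
    x$labels[ord, , drop = FALSE],
    ids = paste0(rep(x$ids, times = n_win), "_w", rep(seq_len(n_win), each = length(x$sequences))),
    parent_ids = rep(x$parent_ids, times = n_win),
    label_mode = x$label_mode
  )
  list(set = set, is_center = rep(offsets == center_off, each = length(x$sequences)))
}
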