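#' Simulate labeled DNA sequences from a motif grammar
#'
#' Generates background sequences at the grammar's GC composition and embeds
#' motif instances according to the class recipe, recording every insertion as
#' ground truth. Three label schemes are supported:
#'
#' * `zonation`: classes `general` (core motifs only), `pericentral`
#'   (core + TCF7L1-like repressor) and `periportal` (core + TBX3-like
#'   repressor);
#' * `activity`: `active` sequences carry at least two core-motif insertions,
#'   `inactive` sequences carry none (decoy motifs only);
#' * `topic`: the three hepatocyte classes above plus one class per decoy
#'   topic, emitted as a multi-label matrix.
#'
#' Insertion positions are uniform over valid offsets and strands are uniform;
#' overlapping insertions are re-drawn up to 100 times before erroring.
#'
#' @param grammar A [motif_grammar()].
#' @param n_per_class Number of sequences per class (>= 1).
#' @param label_scheme One of `"topic"`, `"zonation"`, `"activity"`.
#' @param seed Integer seed; output is a pure function of
#'   `(grammar, n_per_class, label_scheme, seed)`.
#' @return A list with
#' * `set`: a [seq_set()] (`multilabel` for topics, `onehot` otherwise);
#' * `ground_truth`: tibble of insertions (`seq_id`, `class`, `motif`,
#'   `start`, `end`, `strand`) with 0-based half-open coordinates within the
#'   sequence.
#' @examples
#' g <- make_default_grammar(1)
#' sim <- simulate_labeled_sequences(g, n_per_class = 5, "zonation", seed = 7)
#' sim$set
#' @export
simulate_labeled_sequences <- function(grammar, n_per_class, label_scheme, seed = 1L) {
  stopifnot(inherits(grammar, "motif_grammar"), n_per_class >= 1)
  classes <- grammar_classes(label_scheme)
  withr::with_seed(seed, {
    rows <- list()
    gt <- list()
    k <- 0L
    for (cl in classes) {
      for (i in seq_len(n_per_class)) {
        k <- k + 1L
        id <- sprintf("%s_%03d", cl, i)
        plan <- class_insertion_plan(grammar, label_scheme, cl)
        sim <- embed_motifs(grammar, plan)
        rows[[k]] <- tibble::tibble(id = id, class = cl, sequence = sim$sequence)
        if (nrow(sim$insertions)) {
          gt[[k]] <- dplyr::mutate(sim$insertions, seq_id = id, class = cl, .before = 1)
        }
      }
    }
  })
  df <- dplyr::bind_rows(rows)
  labels <- matrix(0, nrow = nrow(df), ncol = length(classes),
                   dimnames = list(NULL, classes))
  labels[cbind(seq_len(nrow(df)), match(df$class, classes))] <- 1
  set <- seq_set(
    df$sequence, labels, ids = df$id,
    label_mode = if (label_scheme == "topic") "multilabel" else "onehot"
  )
  gt <- if (length(gt)) dplyr::bind_rows(gt) else
    tibble::tibble(seq_id = character(), class = character(), motif = character(),
                   start = integer(), end = integer(), strand = character())
  list(set = set, ground_truth = gt)
}

# Which motifs (and how many copies) go into a sequence of a given class.
class_insertion_plan <- function(grammar, label_scheme, class) {
  m <- grammar$motifs
  core <- m[m$role == "core", ]
  draw <- function(rows) {
    if (nrow(rows) == 0L) return(character())
    unlist(lapply(seq_len(nrow(rows)), function(i) {
      rep(rows$name[i], sample(rows$insert_min[i]:rows$insert_max[i], 1L))
    }), use.names = FALSE)
  }
  core_draw <- function(n_motifs) {
    picked <- core[sample(nrow(core), n_motifs), ]
    draw(picked)
  }
  if (label_scheme == "zonation" ||
      (label_scheme == "topic" && grepl("^topic_hep", class))) {
    zone <- sub("^topic_hep_", "", class)
    plan <- core_draw(sample(2:3, 1L))
    if (zone == "pericentral") {
      plan <- c(plan, draw(m[m$role == "repressor_pc", ]))
    } else if (zone == "periportal") {
      plan <- c(plan, draw(m[m$role == "repressor_pp", ]))
    }
    return(plan)
  }
  if (label_scheme == "activity") {
    if (class == "active") {
      plan <- core_draw(sample(2:3, 1L))
      while (length(plan) < 2L) plan <- core_draw(2L)
      return(plan)
    }
    # inactive: no core motifs at all, a few decoys for realism
    decoys <- m[m$role == "decoy", ]
    return(draw(decoys[sample(nrow(decoys), 2L), ]))
  }
  # non-hepatocyte topic class: its own decoy motifs
  draw(m[m$role == "decoy" & !is.na(m$decoy_class) & m$decoy_class == class, ])
}

# Sample a background sequence and embed the planned motif copies without
# overlaps. Coordinates are 0-based half-open within the sequence.
embed_motifs <- function(grammar, motif_names, max_attempts = 100L) {
  L <- grammar$length
  gc <- grammar$background_gc
  seq_chars <- sample(
    DNA_BASES, L, replace = TRUE,
    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  )
  occupied <- integer(0)
  ins <- list()
  pwms <- stats::setNames(grammar$motifs$pwm, grammar$motifs$name)
  for (nm in motif_names) {
    pwm <- pwms[[nm]]
    w <- ncol(pwm)
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      start <- sample.int(L - w + 1L, 1L) - 1L
      span <- (start + 1L):(start + w)
      if (any(span %in% occupied)) next
      strand <- sample(c("+", "-"), 1L)
      use <- if (strand == "+") pwm else pwm_revcomp(pwm)
      bases <- vapply(seq_len(w), function(j) sample(DNA_BASES, 1L, prob = use[, j]),
                      character(1))
      seq_chars[span] <- bases
      occupied <- c(occupied, span)
      ins[[length(ins) + 1L]] <- tibble::tibble(
        motif = nm, start = start, end = start + w, strand = strand
      )
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place motif ", nm, " without overlap after ",
           max_attempts, " attempts")
    }
  }
  list(
    sequence = paste(seq_chars, collapse = ""),
    insertions = if (length(ins)) dplyr::bind_rows(ins) else
      tibble::tibble(motif = character(), start = integer(),
                     end = integer(), strand = character())
  )
}
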