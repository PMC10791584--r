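#' Per-nucleotide contribution scores by expected gradients
#'
#' Attribution of a model's class score to each nucleotide via integrated
#' gradients averaged over a set of baseline sequences (expected gradients, a
#' DeepSHAP-class estimator). The estimator satisfies local accuracy: the
#' contributions over all `(position, base)` features sum to
#' `f(seq) - mean f(baselines)` up to path-integration error (tested, not
#' assumed). The returned `map` is the full importance matrix multiplied by
#' the one-hot encoding of the sequence, so rows are zero except at the
#' reference nucleotide; the unmasked importance is kept alongside.
#'
#' @param model A `sequence_model`.
#' @param seq A single DNA string of the model's input length.
#' @param class Class name (or index) to explain.
#' @param baseline_set Sequences (character vector or `seq_set`) from which
#'   baselines are drawn.
#' @param n_baseline Number of baselines (default 500; capped at the size of
#'   `baseline_set`).
#' @param n_steps Integration steps per baseline.
#' @param target `"probability"` (attribute the post-activation class score)
#'   or `"logit"` (pre-activation).
#' @param seed Seed for the baseline draw.
#' @return A `contribution_map`: list with `map` (L x 4, one-hot masked),
#'   `importance` (L x 4, unmasked), `class`, `seq_id`, `f_x`, `f_baseline`,
#'   `completeness_error`.
#' @export
contribution_scores <- function(model, seq, class, baseline_set,
                                n_baseline = 500L, n_steps = 20L,
                                target = c("probability", "logit"),
                                seed = 1L) {
  target <- match.arg(target)
  stopifnot(inherits(model, "sequence_model"), length(seq) == 1L)
  baselines <- if (inherits(baseline_set, "seq_set")) baseline_set$sequences else baseline_set
  if (length(baselines) == 0L) stop("baseline set is empty")
  j <- class_index(model, class)
  withr::with_seed(seed, {
    take <- sample(length(baselines), min(n_baseline, length(baselines)))
  })
  baselines <- baselines[take]
  x <- nn_flatten_onehot(one_hot(seq))
  bm <- nn_flatten_onehot(one_hot(baselines))
  nb <- nrow(bm)
  l4 <- ncol(x)
  alphas <- (seq_len(n_steps) - 0.5) / n_steps
  total_grad <- matrix(0, nb, l4) # per-baseline mean path gradient
  xrep <- matrix(rep(x, each = nb), nb, l4)
  diff <- xrep - bm
  for (a in alphas) {
    g <- nn_class_input_grad(model, bm + a * diff, j, target)
    total_grad <- total_grad + g / n_steps
  }
  contrib <- colMeans(diff * total_grad) # length L*4, channel fastest
  imp <- matrix(contrib, ncol = 4L, byrow = TRUE)
  colnames(imp) <- DNA_BASES
  oh <- one_hot(seq)[1, , ]
  f_x <- class_score(model, x, j, target)
  f_b <- mean(class_score(model, bm, j, target))
  structure(
    list(
      map = imp * oh,
      importance = imp,
      sequence = toupper(seq),
      class = model$class_names[j],
      seq_id = names(seq) %||% "seq",
      f_x = f_x,
      f_baseline = f_b,
      completeness_error = sum(contrib) - (f_x - f_b),
      target = target
    ),
    class = "contribution_map"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

class_index <- function(model, class) {
  if (is.numeric(class)) return(as.integer(class))
  j <- match(class, model$class_names)
  if (is.na(j)) stop("unknown class: ", class)
  j
}

class_score <- function(model, xm, j, target, batch_size = 256L) {
  n <- nrow(xm)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fwd <- nn_forward(model$weights, xm[idx, , drop = FALSE],
                      model$config$filter_len, model$activation,
                      rc = model$config$rc_invariant)
    out[idx] <- if (target == "logit") fwd$o[, j] else fwd$p[, j]
  }
  out
}

# gradient of the class score (probability or logit) w.r.t. the flattened input
nn_class_input_grad <- function(model, xm, j, target, batch_size = 256L) {
  n <- nrow(xm)
  out <- matrix(0, n, ncol(xm))
  k <- length(model$class_names)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fwd <- nn_forward(model$weights, xm[idx, , drop = FALSE],
                      model$config$filter_len, model$activation,
                      keep_cache = TRUE, rc = model$config$rc_invariant)
    b <- length(idx)
    d_o <- matrix(0, b, k)
    if (target == "logit" || model$activation == "linear") {
      d_o[, j] <- 1
    } else if (model$activation == "sigmoid") {
      pj <- fwd$p[, j]
      d_o[, j] <- pj * (1 - pj)
    } else { # softmax
      pj <- fwd$p[, j]
      d_o <- -fwd$p * pj
      d_o[, j] <- d_o[, j] + pj
    }
    g <- nn_backward(model$weights, fwd, d_o, want_input_grad = TRUE)
    out[idx, ] <- g$input
  }
  out
}

#' @export
print.contribution_map <- function(x, ...) {
  cat(
    "<contribution_map> class ", x$class, ", ", nrow(x$map), " bp, f(x) = ",
    signif(x$f_x, 4), ", baseline = ", signif(x$f_baseline, 4),
    ", completeness error = ", signif(x$completeness_error, 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' In-silico saturation mutagenesis
#'
#' Scores every possible single-nucleotide variant of a sequence (3L mutants,
#' evaluated in one deterministic batch) and returns the delta class score
#' (mutant minus reference) as an L x 4 matrix; entries at each position's
#' reference base are exactly 0.
#'
#' @param model A `sequence_model`.
#' @param seq A single DNA string of the model's input length.
#' @param class Class name or index.
#' @return A `mutagenesis_matrix`: list with `delta` (L x 4), `class`,
#'   `sequence`, `ref_score`.
#' @export
saturation_mutagenesis <- function(model, seq, class) {
  stopifnot(length(seq) == 1L)
  j <- class_index(model, class)
  seq <- toupper(seq)
  l <- nchar(seq)
  x <- nn_flatten_onehot(one_hot(seq))
  ref_base <- match(strsplit(seq, "")[[1]], DNA_BASES)
  if (anyNA(ref_base)) stop("saturation mutagenesis requires an N-free sequence")
  # rows: reference first, then one row per (position, alternative base)
  muts <- list()
  pos_list <- integer(0)
  base_list <- integer(0)
  for (b in 1:4) {
    pos <- which(ref_base != b)
    pos_list <- c(pos_list, pos)
    base_list <- c(base_list, rep(b, length(pos)))
  }
  xmut <- matrix(rep(x, each = length(pos_list)), length(pos_list), ncol(x))
  # clear the reference base and set the alternative at each mutated position
  rows <- seq_along(pos_list)
  xmut[cbind(rows, (pos_list - 1L) * 4L + ref_base[pos_list])] <- 0
  xmut[cbind(rows, (pos_list - 1L) * 4L + base_list)] <- 1
  scores <- nn_predict_batched(model$weights, rbind(x, xmut),
                               model$config$filter_len, model$activation,
                               rc = model$config$rc_invariant)
  ref_score <- scores[1L, j]
  delta <- matrix(0, l, 4L, dimnames = list(NULL, DNA_BASES))
  delta[cbind(pos_list, base_list)] <- scores[-1L, j] - ref_score
  structure(
    list(delta = delta, class = model$class_names[j], sequence = seq,
         seq_id = names(seq) %||% "seq", ref_score = ref_score),
    class = "mutagenesis_matrix"
  )
}

#' @export
print.mutagenesis_matrix <- function(x, ...) {
  cat(
    "<mutagenesis_matrix> class ", x$class, ", ", nrow(x$delta),
    " bp, reference score ", signif(x$ref_score, 4),
    ", delta range [", signif(min(x$delta), 3), ", ",
    signif(max(x$delta), 3), "]\n", sep = ""
  )
  invisible(x)
}

#' Call motif instances on sequences or contribution maps
#'
#' In `activation` mode the trimmed patterns are converted to log-odds
#' convolutional filters and cross-correlated with the one-hot sequence on
#' both strands; offsets reaching the pattern's activation threshold are kept
#' (thresholds are explicit configuration, there are no hidden defaults), and
#' overlapping calls of the same pattern are resolved to the maximum-scoring
#' offset. In `contribution` mode the inputs are [contribution_scores()] maps
#' and the score at each offset is the sum of contribution entries under the
#' pattern window (`sum_score`), thresholded and resolved the same way.
#'
#' @param x Sequences (`seq_set` / character) in activation mode; a
#'   `contribution_map` or list of them in contribution mode.
#' @param patterns A `pattern_filter` or list of them (see [trim_by_ic()]).
#' @param mode `"activation"` or `"contribution"`.
#' @param thresholds Optional named numeric vector overriding the patterns'
#'   thresholds. Every pattern must end up with a non-missing threshold.
#' @return Tibble of instances: `seq_id`, `start`, `end` (0-based half-open,
#'   within-sequence), `strand`, `pattern`, `sum_score`, `activation_score`.
#' @export
scan_instances <- function(x, patterns, mode = c("activation", "contribution"),
                           thresholds = NULL) {
  mode <- match.arg(mode)
  if (inherits(patterns, "pattern_filter")) patterns <- list(patterns)
  pat_names <- vapply(patterns, function(p) p$name, character(1))
  thr <- vapply(patterns, function(p) p$threshold, numeric(1))
  names(thr) <- pat_names
  if (!is.null(thresholds)) thr[names(thresholds)] <- thresholds
  if (anyNA(thr)) {
    stop("no activation threshold for pattern(s): ",
         paste(pat_names[is.na(thr)], collapse = ", "),
         " (thresholds are explicit configuration)")
  }
  if (mode == "activation") {
    seqs <- if (inherits(x, "seq_set")) {
      stats::setNames(x$sequences, x$ids)
    } else {
      if (is.null(names(x))) names(x) <- paste0("seq_", seq_along(x))
      x
    }
    out <- purrr::map2(patterns, thr, function(p, t) {
      scan_activation(seqs, p, t)
    })
  } else {
    maps <- if (inherits(x, "contribution_map")) list(x) else x
    out <- purrr::map2(patterns, thr, function(p, t) {
      scan_contribution(maps, p, t)
    })
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble::tibble(
      seq_id = character(), start = integer(), end = integer(),
      strand = character(), pattern = character(),
      sum_score = numeric(), activation_score = numeric()
    ))
  }
  dplyr::arrange(res, .data$seq_id, .data$start)
}

scan_activation <- function(seqs, pattern, threshold) {
  w <- pattern$width
  lo_fwd <- as.vector(pwm_log_odds(pattern$pwm))
  lo_rev <- as.vector(pwm_log_odds(pwm_revcomp(pattern$pwm)))
  rows <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    if (nchar(s) < w) stop("pattern ", pattern$name, " longer than sequence ", id)
    xm <- nn_flatten_onehot(one_hot(s))
    ic <- nn_im2col(xm, w)
    sf <- as.vector(ic$xc %*% lo_fwd)
    sr <- as.vector(ic$xc %*% lo_rev)
    strand <- ifelse(sf >= sr, "+", "-")
    score <- pmax(sf, sr)
    hits <- which(score >= threshold)
    if (length(hits) == 0L) return(NULL)
    keep <- resolve_overlaps(hits - 1L, w, score[hits])
    tibble::tibble(
      seq_id = id, start = keep$start, end = keep$start + w,
      strand = strand[keep$start + 1L], pattern = pattern$name,
      sum_score = NA_real_, activation_score = score[keep$start + 1L]
    )
  })
  dplyr::bind_rows(rows)
}

scan_contribution <- function(maps, pattern, threshold) {
  w <- pattern$width
  rows <- lapply(maps, function(m) {
    stopifnot(inherits(m, "contribution_map"))
    per_pos <- rowSums(m$map)
    l <- length(per_pos)
    if (l < w) stop("pattern ", pattern$name, " longer than the map")
    cs <- cumsum(c(0, per_pos))
    score <- cs[(w + 1):(l + 1)] - cs[1:(l - w + 1)]
    hits <- which(score >= threshold)
    if (length(hits) == 0L) return(NULL)
    keep <- resolve_overlaps(hits - 1L, w, score[hits])
    tibble::tibble(
      seq_id = m$seq_id, start = keep$start, end = keep$start + w,
      strand = "+", pattern = pattern$name,
      sum_score = score[keep$start + 1L], activation_score = NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

# greedy best-per-locus resolution of overlapping same-pattern calls
resolve_overlaps <- function(starts, width, scores) {
  ord <- order(-scores, starts)
  kept <- integer(0)
  for (i in ord) {
    if (!any(abs(starts[i] - kept) < width)) kept <- c(kept, starts[i])
  }
  list(start = sort(kept))
}

#' Design gain- or loss-of-function variants of a motif instance
#'
#' `GOF` replaces the locus with the pattern consensus (maximum-probability
#' base per column); `LOF` mutates the `k` highest-information positions of
#' the instance to the column's lowest-probability base. The edit list records
#' every substitution; a locus already equal to the consensus yields zero
#' edits under GOF.
#'
#' @param seq A single DNA string.
#' @param pattern A `pattern_filter`.
#' @param locus Integer pair `c(start, end)`, 0-based half-open, width equal
#'   to the pattern width, within the sequence.
#' @param mode `"GOF"` or `"LOF"`.
#' @param k Number of positions destroyed under LOF.
#' @param strand Strand of the instance (`"+"` or `"-"`).
#' @return List with `sequence` (edited string) and `edits` (tibble `pos`
#'   (0-based), `ref`, `alt`).
#' @export
design_variant <- function(seq, pattern, locus, mode = c("GOF", "LOF"),
                           k = 3L, strand = "+") {
  mode <- match.arg(mode)
  stopifnot(inherits(pattern, "pattern_filter"), length(locus) == 2L)
  w <- pattern$width
  l <- nchar(seq)
  if (locus[1] < 0 || locus[2] > l) stop("locus outside the sequence")
  if (locus[2] - locus[1] != w) {
    stop("locus width (", locus[2] - locus[1], ") must equal the pattern width (", w, ")")
  }
  pwm <- if (strand == "+") pattern$pwm else pwm_revcomp(pattern$pwm)
  chars <- strsplit(toupper(seq), "")[[1]]
  span <- (locus[1] + 1L):locus[2]
  if (mode == "GOF") {
    target <- DNA_BASES[apply(pwm, 2L, which.max)]
  } else {
    ic <- pwm_ic(pwm)
    worst <- DNA_BASES[apply(pwm, 2L, which.min)]
    top <- order(-ic, seq_along(ic))[seq_len(min(k, w))]
    target <- chars[span]
    target[top] <- worst[top]
  }
  changed <- which(chars[span] != target)
  edits <- tibble::tibble(
    pos = locus[1] + changed - 1L,
    ref = chars[span][changed],
    alt = target[changed]
  )
  chars[span] <- target
  list(sequence = paste(chars, collapse = ""), edits = edits)
}
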