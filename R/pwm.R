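#' Position weight matrix utilities
#'
#' A PWM here is a 4 x W numeric matrix with rownames `A, C, G, T` whose
#' columns each sum to 1. Helpers construct consensus-dominated PWMs, compute
#' per-column information content (in bits, against a uniform background),
#' take reverse complements and log-odds transforms.
#'
#' @param consensus A DNA string over `A/C/G/T`.
#' @param p_max Probability mass given to the consensus base in each column;
#'   the remainder is spread uniformly over the other three bases.
#' @return `pwm_from_consensus()` returns a 4 x nchar(consensus) PWM.
#' @examples
#' pwm <- pwm_from_consensus("CAAAGTCA")
#' pwm_consensus(pwm)
#' pwm_ic(pwm)
#' @export
pwm_from_consensus <- function(consensus, p_max = 0.85) {
  stopifnot(is.character(consensus), length(consensus) == 1L, p_max > 0.25, p_max <= 1)
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% DNA_BASES)) {
    stop("consensus must contain only A/C/G/T, got: ", consensus)
  }
  w <- length(bases)
  pwm <- matrix((1 - p_max) / 3, nrow = 4L, ncol = w, dimnames = list(DNA_BASES, NULL))
  pwm[cbind(match(bases, DNA_BASES), seq_len(w))] <- p_max
  pwm
}

DNA_BASES <- c("A", "C", "G", "T")

check_pwm <- function(pwm, tol = 1e-9) {
  stopifnot(is.matrix(pwm), nrow(pwm) == 4L)
  if (is.null(rownames(pwm))) rownames(pwm) <- DNA_BASES
  if (!identical(rownames(pwm), DNA_BASES)) pwm <- pwm[DNA_BASES, , drop = FALSE]
  if (any(pwm < 0) || any(abs(colSums(pwm) - 1) > tol)) {
    stop("PWM columns must be non-negative and sum to 1")
  }
  pwm
}

#' @rdname pwm_from_consensus
#' @param pwm A 4 x W PWM (rows `A,C,G,T`, columns summing to 1).
#' @export
pwm_consensus <- function(pwm) {
  pwm <- check_pwm(pwm)
  paste(DNA_BASES[apply(pwm, 2L, which.max)], collapse = "")
}

#' @rdname pwm_from_consensus
#' @return `pwm_ic()` returns the per-column information content in bits
#'   (2 + sum p log2 p), i.e. 0 for a uniform column and 2 for a point mass.
#' @export
pwm_ic <- function(pwm) {
  pwm <- check_pwm(pwm)
  plogp <- ifelse(pwm > 0, pwm * log2(pwm), 0)
  2 + colSums(plogp)
}

#' @rdname pwm_from_consensus
#' @export
pwm_revcomp <- function(pwm) {
  pwm <- check_pwm(pwm)
  out <- pwm[4:1, rev(seq_len(ncol(pwm))), drop = FALSE]
  rownames(out) <- DNA_BASES
  out
}

#' @rdname pwm_from_consensus
#' @param background Background base probability (uniform, 0.25).
#' @param clip Symmetric clip bound for the log-odds values; `Inf` disables
#'   clipping. Probabilities are floored at 1e-4 before the log.
#' @export
pwm_log_odds <- function(pwm, background = 0.25, clip = Inf) {
  pwm <- check_pwm(pwm)
  lo <- log2(pmax(pwm, 1e-4) / background)
  pmin(pmax(lo, -clip), clip)
}

#' Trim uninformative PWM flanks by information content
#'
#' Leading and trailing columns whose information content falls below
#' `ic_threshold` times the maximum column IC of the PWM are removed;
#' interior low-IC columns are kept. The result is a pattern filter object
#' carrying the trimmed PWM, its per-column IC, the retained bounds within
#' the source PWM and an (optional) activation threshold used by
#' [scan_instances()].
#'
#' @param pwm A 4 x W PWM, or a `pattern_filter` (re-trimming is idempotent).
#' @param ic_threshold Fraction of the maximum column IC below which flank
#'   columns are dropped.
#' @param name Pattern name carried into instance calls.
#' @param threshold Activation-score threshold for instance calling. No
#'   default is imposed at scan time; it must be supplied here or to
#'   [scan_instances()].
#' @return A `pattern_filter` object.
#' @examples
#' pf <- trim_by_ic(pwm_from_consensus("CAAAGTCA"), name = "Hnf4a")
#' pf$width
#' @export
trim_by_ic <- function(pwm, ic_threshold = 0.25, name = "pattern", threshold = NA_real_) {
  if (inherits(pwm, "pattern_filter")) {
    if (name == "pattern") name <- pwm$name
    if (is.na(threshold)) threshold <- pwm$threshold
    pwm <- pwm$pwm
  }
  pwm <- check_pwm(pwm)
  ic <- pwm_ic(pwm)
  if (max(ic) <= 1e-9) {
    stop("all PWM columns are uninformative; nothing above threshold")
  }
  cut <- ic_threshold * max(ic)
  keep <- which(ic >= cut)
  bounds <- c(min(keep), max(keep))
  trimmed <- pwm[, bounds[1]:bounds[2], drop = FALSE]
  if (ncol(trimmed) < 3L) {
    stop("trimmed pattern is narrower than 3 columns")
  }
  structure(
    list(
      name = name,
      pwm = trimmed,
      source_pwm = pwm,
      bounds = bounds,
      ic = pwm_ic(trimmed),
      width = ncol(trimmed),
      threshold = threshold
    ),
    class = "pattern_filter"
  )
}

#' @export
print.pattern_filter <- function(x, ...) {
  cat(
    "<pattern_filter> ", x$name, ": ", pwm_consensus(x$pwm),
    " (width ", x$width, ", kept cols ", x$bounds[1], "-", x$bounds[2],
    ", threshold ", format(x$threshold), ")\n",
    sep = ""
  )
  invisible(x)
}
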