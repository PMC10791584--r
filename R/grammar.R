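#' Construct a motif grammar
#'
#' A motif grammar is the generative model behind the synthetic training data:
#' a set of named PWMs, each with a role and a per-class insertion rule, a
#' background GC fraction and a sequence length. The default grammar
#' ([make_default_grammar()]) encodes the hepatocyte enhancer logic this
#' package is organised around: a core hepatocyte code (HNF4A-, HNF1A-,
#' CEBPA-, FOXA1-, ONECUT1- and NFIB-like motifs) shared by all hepatocyte
#' classes, one periportal-only repressor motif (TBX3-like) and one
#' pericentral-only repressor motif (TCF7L1-like), plus decoy motifs that
#' define non-hepatocyte topic classes.
#'
#' @param motifs A tibble with columns `name`, `pwm` (list of 4 x W PWMs),
#'   `role` (one of `core`, `repressor_pp`, `repressor_pc`, `decoy`),
#'   `decoy_class` (topic class name for decoys, `NA` otherwise) and
#'   `insert_min`/`insert_max` (copy-number range when the motif is inserted).
#' @param background_gc Background GC fraction in `[0, 1]`.
#' @param length Sequence length in bp.
#' @return A `motif_grammar` object.
#' @export
motif_grammar <- function(motifs, background_gc = 0.41, length = 500L) {
  stopifnot(
    is.data.frame(motifs),
    all(c("name", "pwm", "role", "decoy_class", "insert_min", "insert_max") %in% names(motifs)),
    background_gc >= 0, background_gc <= 1, length >= 1
  )
  motifs$pwm <- lapply(motifs$pwm, check_pwm)
  if (any(vapply(motifs$pwm, ncol, 1L) > length)) {
    stop("a motif is longer than the sequence length")
  }
  stopifnot(all(motifs$insert_min >= 0), all(motifs$insert_max >= motifs$insert_min))
  bad_role <- setdiff(motifs$role, c("core", "repressor_pp", "repressor_pc", "decoy"))
  if (length(bad_role)) stop("unknown motif role(s): ", paste(bad_role, collapse = ", "))
  structure(
    list(
      motifs = tibble::as_tibble(motifs),
      background_gc = background_gc,
      length = as.integer(length)
    ),
    class = "motif_grammar"
  )
}

#' @export
print.motif_grammar <- function(x, ...) {
  cat(
    "<motif_grammar> ", nrow(x$motifs), " motifs, ", x$length, " bp, GC ",
    x$background_gc, "\n", sep = ""
  )
  info <- x$motifs
  for (i in seq_len(nrow(info))) {
    cat(
      "  ", format(info$name[i], width = 10), format(info$role[i], width = 13),
      pwm_consensus(info$pwm[[i]]), "\n", sep = " "
    )
  }
  invisible(x)
}

#' @rdname motif_grammar
#' @param seed Integer seed; the grammar (including the small perturbations
#'   that make the PWMs non-degenerate) is a pure function of it.
#' @param length Sequence length in bp (500 by default).
#' @details The TCF7L1-like and HNF4A-like motifs deliberately share a
#'   `CAAAG` core (their consensus cores are `GATCAAAG` and `CAAAGTCA`): the
#'   two motifs overlap in real hepatocyte enhancers, which is exactly what
#'   makes zonation classification a non-trivial sequence problem. The two
#'   repressor PWMs carry moderately informative flanks around those cores
#'   (11 bp total), reflecting that the printed 8-mers are the cores of wider
#'   binding-site models; with naked 8-mers a 500-bp background yields
#'   near-consensus matches by chance and the zonation classes stop being
#'   identifiable even to an oracle scan with the true PWMs.
#' @export
make_default_grammar <- function(seed = 1L, length = 500L) {
  consensi <- c(
    # core hepatocyte code
    Hnf4a   = "CAAAGTCA",
    Hnf1a   = "GTTAATGATTAA",
    Cebpa   = "ATTGCGCAAT",
    Foxa1   = "TGTTTACTTA",
    Onecut1 = "AATCAATCA",
    Nfib    = "TTGGCTAGCCAA",
    # zonated repressors: printed cores AGGTGTGA / GATCAAAG with flanks
    Tbx3    = "TCAGGTGTGAA",
    Tcf7l1  = "CAGATCAAAGG",
    # decoys for non-hepatocyte topic classes
    Spi1    = "AAAGAGGAAGTG",
    Erg     = "ACAGGAAGTG",
    Gata4   = "AGATAAGA",
    Sox9    = "AACAATGG"
  )
  roles <- c(
    rep("core", 6), "repressor_pp", "repressor_pc",
    rep("decoy", 4)
  )
  decoy_class <- c(
    rep(NA_character_, 8),
    "topic_kupffer", "topic_kupffer", "topic_stellate", "topic_stellate"
  )
  withr::with_seed(seed, {
    pwms <- lapply(consensi, function(cons) {
      pwm <- pwm_from_consensus(cons, p_max = 0.92)
      # tiny dirichlet-style jitter on the minor bases so columns are not all identical
      jitter <- matrix(stats::runif(base::length(pwm), 0, 0.008), nrow = 4L)
      pwm <- pwm + jitter
      sweep(pwm, 2L, colSums(pwm), "/")
    })
  })
  motifs <- tibble::tibble(
    name = names(consensi),
    pwm = unname(pwms),
    role = roles,
    decoy_class = decoy_class,
    insert_min = ifelse(roles == "core", 1L, 2L),
    insert_max = ifelse(roles == "core", 3L, 2L)
  )
  motif_grammar(motifs, background_gc = 0.41, length = length)
}

grammar_classes <- function(label_scheme) {
  switch(label_scheme,
    zonation = c("general", "pericentral", "periportal"),
    activity = c("active", "inactive"),
    topic = c(
      "topic_hep_general", "topic_hep_pericentral", "topic_hep_periportal",
      "topic_kupffer", "topic_stellate"
    ),
    stop("unknown label_scheme: ", label_scheme)
  )
}
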