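#' Simulate an MPRA count table with known activities
#'
#' Emulates a barcoded episomal reporter experiment: every enhancer gets a
#' latent plasmid abundance; plasmid replicates draw negative-binomial counts
#' around that abundance scaled to the sequencing depth, and cDNA replicates
#' draw counts around abundance times `2^activity` (renormalised so each
#' sample sums to `depth` in expectation). A block of shuffled-control
#' entries with true activity exactly 0 is appended and flagged; their
#' abundances are drawn from the same distribution as the real enhancers so
#' their plasmid count marginals match.
#'
#' The negative binomial is parameterised by (mean, dispersion) with
#' `variance = mean + dispersion * mean^2`.
#'
#' @param true_activity Named (or unnamed) numeric vector of per-enhancer
#'   log2 activities.
#' @param n_shuffled Number of shuffled controls (> 0; the downstream null
#'   fit requires controls).
#' @param n_plasmid_reps,n_cdna_reps Replicate counts (>= 1).
#' @param depth Expected reads per sample (> 0).
#' @param dispersion NB dispersion (> 0; the Poisson limit as it approaches 0).
#' @param seed Integer seed.
#' @return A list with `table` (an [mpra_table()]) and `ground_truth`
#'   (tibble: `enhancer`, `activity`, `shuffled`, `abundance`).
#' @examples
#' sim <- simulate_mpra_counts(c(e1 = 0, e2 = 2), n_shuffled = 20, seed = 1)
#' dim(sim$table$counts)
#' @export
simulate_mpra_counts <- function(true_activity, n_shuffled,
                                 n_plasmid_reps = 3L, n_cdna_reps = 3L,
                                 depth = 1e6, dispersion = 0.1, seed = 1L) {
  stopifnot(dispersion > 0, depth > 0, n_plasmid_reps >= 1, n_cdna_reps >= 1)
  if (n_shuffled <= 0) {
    stop("n_shuffled must be > 0: the downstream null fit requires shuffled controls")
  }
  n_real <- length(true_activity)
  if (is.null(names(true_activity))) {
    names(true_activity) <- sprintf("enh_%04d", seq_len(n_real))
  }
  ids <- c(names(true_activity), sprintf("shuffle_%04d", seq_len(n_shuffled)))
  activity <- c(unname(true_activity), rep(0, n_shuffled))
  shuffled <- c(rep(FALSE, n_real), rep(TRUE, n_shuffled))
  n <- length(ids)

  withr::with_seed(seed, {
    abundance <- stats::rgamma(n, shape = 4, rate = 4) # mean 1, moderate spread
    mu_plasmid <- depth * abundance / sum(abundance)
    w_cdna <- abundance * 2^activity
    mu_cdna <- depth * w_cdna / sum(w_cdna)
    rnb <- function(mu) {
      if (dispersion < 1e-8) return(stats::rpois(length(mu), mu))
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    counts <- cbind(
      vapply(seq_len(n_plasmid_reps), function(r) rnb(mu_plasmid), numeric(n)),
      vapply(seq_len(n_cdna_reps), function(r) rnb(mu_cdna), numeric(n))
    )
  })
  samples <- tibble::tibble(
    sample = c(
      sprintf("plasmid_%d", seq_len(n_plasmid_reps)),
      sprintf("cdna_%d", seq_len(n_cdna_reps))
    ),
    role = c(rep("plasmid", n_plasmid_reps), rep("cdna", n_cdna_reps)),
    replicate = c(seq_len(n_plasmid_reps), seq_len(n_cdna_reps)),
    fraction = NA_character_
  )
  dimnames(counts) <- list(ids, samples$sample)
  storage.mode(counts) <- "integer"
  list(
    table = mpra_table(counts, samples, shuffled = shuffled),
    ground_truth = tibble::tibble(
      enhancer = ids, activity = activity, shuffled = shuffled,
      abundance = abundance
    )
  )
}

#' MPRA count table container
#'
#' An enhancer-by-sample count matrix with a sample sheet (role
#' `plasmid`/`cdna`, replicate number, optional FACS fraction tag) and a
#' shuffled-control flag per enhancer.
#'
#' @param counts Non-negative integer matrix, rownames = enhancer ids.
#' @param samples Tibble with columns `sample`, `role`, `replicate`,
#'   `fraction` matching the matrix columns.
#' @param shuffled Logical flag per enhancer.
#' @return An `mpra_table` object.
#' @export
mpra_table <- function(counts, samples, shuffled = NULL) {
  counts <- as.matrix(counts)
  stopifnot(
    !is.null(rownames(counts)), all(counts >= 0),
    is.data.frame(samples),
    all(c("sample", "role", "replicate") %in% names(samples)),
    nrow(samples) == ncol(counts)
  )
  if (!all(samples$role %in% c("plasmid", "cdna"))) {
    stop("sample roles must be 'plasmid' or 'cdna'")
  }
  if (!any(samples$role == "plasmid") || !any(samples$role == "cdna")) {
    stop("need at least one plasmid and one cDNA sample")
  }
  if (is.null(samples[["fraction"]])) samples$fraction <- NA_character_
  if (is.null(shuffled)) shuffled <- rep(FALSE, nrow(counts))
  stopifnot(length(shuffled) == nrow(counts))
  structure(
    list(
      counts = counts,
      samples = tibble::as_tibble(samples),
      shuffled = as.logical(shuffled)
    ),
    class = "mpra_table"
  )
}

#' @export
print.mpra_table <- function(x, ...) {
  cat(
    "<mpra_table> ", nrow(x$counts), " enhancers (", sum(x$shuffled),
    " shuffled controls) x ", ncol(x$counts), " samples (",
    sum(x$samples$role == "plasmid"), " plasmid, ",
    sum(x$samples$role == "cdna"), " cDNA)\n",
    sep = ""
  )
  invisible(x)
}
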