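#' Default synthetic enhancer-driven gene regulatory network
#'
#' A small ground-truth network with the mutual-repression motif between the
#' two zonation transcription factors: `Tcf7l1` (pericentral, rises along the
#' zone coordinate) and `Tbx3` (periportal, falls along it) directly repress
#' each other, each activates its own block of zonated target genes, and a
#' non-zonated core TF (`Hnf4a`) activates a block of housekeeping targets.
#'
#' @param n_targets_per_tf Number of activated targets per zonation TF.
#' @param n_core_targets Number of targets of the non-zonated TF.
#' @return Edge-list tibble with columns `tf`, `target`, `sign` (+1/-1).
#' @export
make_default_egrn <- function(n_targets_per_tf = 8L, n_core_targets = 4L) {
  dplyr::bind_rows(
    tibble::tibble(tf = "Tcf7l1", target = "Tbx3", sign = -1),
    tibble::tibble(tf = "Tbx3", target = "Tcf7l1", sign = -1),
    tibble::tibble(
      tf = "Tcf7l1", target = sprintf("PCgene%02d", seq_len(n_targets_per_tf)), sign = 1
    ),
    tibble::tibble(
      tf = "Tbx3", target = sprintf("PPgene%02d", seq_len(n_targets_per_tf)), sign = 1
    ),
    tibble::tibble(
      tf = "Hnf4a", target = sprintf("Coregene%02d", seq_len(n_core_targets)), sign = 1
    )
  )
}

#' Simulate a zonated expression matrix from a ground-truth network
#'
#' Cells sit on a uniform zone-coordinate grid over `[0, 1]` (portal to
#' central), so pseudotime equals the zone rank exactly. The first zonation TF
#' of the mutual-repression pair increases linearly with the zone coordinate
#' and the second decreases; every target gene is a linear combination of its
#' regulators (signs respected, positive weights) plus Gaussian noise. A
#' target with no regulators is generated as noise only, with a warning.
#'
#' @param egrn Edge list (`tf`, `target`, `sign`); must contain two TFs with
#'   mutual-repression edges (A represses B and B represses A).
#' @param n_cells Number of cells.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return List with
#' * `expr`: cell x gene matrix;
#' * `pseudotime`: tibble (`cell_id`, `pseudotime`, `zone`);
#' * `ground_truth`: list with `tf_up` / `tf_down` (which zonation TF rises /
#'   falls with the zone coordinate), `weights` (tibble of true regulator
#'   weights) and `zone` (per-cell coordinate).
#' @export
simulate_zonated_expression <- function(egrn, n_cells, noise_sd = 0.1, seed = 1L) {
  stopifnot(is.data.frame(egrn), all(c("tf", "target", "sign") %in% names(egrn)),
            n_cells >= 1, noise_sd >= 0)
  pair <- find_mutual_repression(egrn)
  tf_up <- pair[1]
  tf_down <- pair[2]
  zone <- if (n_cells == 1L) 0 else seq(0, 1, length.out = n_cells)
  genes <- unique(c(egrn$tf, egrn$target))
  targets <- setdiff(genes, c(tf_up, tf_down))
  withr::with_seed(seed, {
    expr <- matrix(0, nrow = n_cells, ncol = length(genes),
                   dimnames = list(sprintf("cell_%04d", seq_len(n_cells)), genes))
    expr[, tf_up] <- 0.2 + 2 * zone + stats::rnorm(n_cells, 0, noise_sd)
    expr[, tf_down] <- 2.2 - 2 * zone + stats::rnorm(n_cells, 0, noise_sd)
    # non-zonated root TFs (regulators that are nobody's target): constant + noise
    other_tfs <- setdiff(unique(egrn$tf), c(tf_up, tf_down, egrn$target))
    for (tf in other_tfs) {
      expr[, tf] <- 1 + stats::rnorm(n_cells, 0, noise_sd)
    }
    wts <- list()
    # targets in dependency order: regulators are TFs, already filled above
    for (g in setdiff(targets, other_tfs)) {
      ed <- egrn[egrn$target == g & egrn$tf != g, ] # self-edges are not predictors
      if (nrow(ed) == 0L) {
        warning("target ", g, " has no regulators; generated as noise only")
        expr[, g] <- stats::rnorm(n_cells, 0, max(noise_sd, 1e-3))
        next
      }
      w <- stats::runif(nrow(ed), 0.5, 1.5) * ed$sign
      lin <- as.vector(expr[, ed$tf, drop = FALSE] %*% w)
      intercept <- max(0, -min(lin)) + 0.5
      expr[, g] <- intercept + lin + stats::rnorm(n_cells, 0, noise_sd)
      wts[[g]] <- tibble::tibble(target = g, tf = ed$tf, weight = w,
                                 intercept = intercept)
    }
  })
  pt <- tibble::tibble(
    cell_id = rownames(expr),
    pseudotime = rank(zone, ties.method = "first"),
    zone = zone
  )
  list(
    expr = expr,
    pseudotime = pt,
    ground_truth = list(
      tf_up = tf_up, tf_down = tf_down,
      weights = if (length(wts)) dplyr::bind_rows(wts) else NULL,
      zone = zone
    )
  )
}

find_mutual_repression <- function(egrn) {
  rep_edges <- egrn[egrn$sign < 0, ]
  key <- paste(rep_edges$tf, rep_edges$target)
  rev_key <- paste(rep_edges$target, rep_edges$tf)
  hit <- which(key %in% rev_key)
  if (length(hit) == 0L) {
    stop("egrn must contain two zonation TFs with mutual-repression edges")
  }
  first <- rep_edges[hit[1], ]
  # first-listed TF of the pair rises with the zone coordinate
  c(first$tf, first$target)
}
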