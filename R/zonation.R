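#' Equal-frequency pseudotime bins
#'
#' Divides cells into `n_bins` rank-based bins along pseudotime (bin sizes
#' differ by at most one); ties are broken by stable input order so the
#' binning is deterministic.
#'
#' @param ordering Tibble with `cell_id` and `pseudotime` columns, or a named
#'   numeric vector of pseudotime values.
#' @param n_bins Number of bins (default ten, one decile per bin).
#' @return Tibble with `cell_id`, `pseudotime`, `bin`.
#' @export
bin_pseudotime <- function(ordering, n_bins = 10L) {
  if (is.numeric(ordering)) {
    ordering <- tibble::tibble(
      cell_id = names(ordering) %||% paste0("cell_", seq_along(ordering)),
      pseudotime = unname(ordering)
    )
  }
  stopifnot(all(c("cell_id", "pseudotime") %in% names(ordering)))
  if (anyNA(ordering$pseudotime)) stop("pseudotime contains missing values")
  n <- nrow(ordering)
  if (n_bins > n) stop("more bins than cells")
  tibble::tibble(
    cell_id = ordering$cell_id,
    pseudotime = ordering$pseudotime,
    bin = rank_bins(ordering$pseudotime, n_bins)
  )
}

#' Map real cell profiles onto a virtual tissue template
#'
#' For zonated cell types, every virtual cell receives a real profile drawn
#' from the real pseudotime bin matching the virtual cell's radial-distance
#' bin: if the bin holds more real cells than virtual ones, sampling is
#' without repetition; if more virtual than real, each real profile is used
#' `floor(v/r)` or `ceiling(v/r)` times so multiplicities stay balanced.
#' Non-zonated cell types are sampled the same way at the whole-type level,
#' ignoring bins. Attribute matrices transfer through the assignment with
#' [transfer_profiles()].
#'
#' @param template A `virtual_template` from [simulate_lobule()] (columns
#'   `virtual_id`, `cell_type`, `bin`).
#' @param real_cells Tibble with `cell_id`, `cell_type` and `bin` (`NA` bins
#'   mark non-zonated cells; see [bin_pseudotime()]).
#' @param seed Integer seed for the random draws.
#' @return Tibble `virtual_id`, `cell_type`, `bin`, `real_id`.
#' @export
map_cells <- function(template, real_cells, seed = 1L) {
  stopifnot(
    all(c("virtual_id", "cell_type", "bin") %in% names(template)),
    all(c("cell_id", "cell_type") %in% names(real_cells))
  )
  if (is.null(real_cells$bin)) real_cells$bin <- NA_integer_
  missing_types <- setdiff(unique(template$cell_type), unique(real_cells$cell_type))
  if (length(missing_types)) {
    stop("no real cells for template cell type(s): ",
         paste(missing_types, collapse = ", "))
  }
  tpl <- tibble::as_tibble(template)
  tpl$.group <- paste(tpl$cell_type, ifelse(is.na(tpl$bin), "all", tpl$bin))
  out <- withr::with_seed(seed, {
    pieces <- lapply(split(seq_len(nrow(tpl)), tpl$.group), function(rows) {
      type <- tpl$cell_type[rows[1]]
      bin <- tpl$bin[rows[1]]
      pool <- if (is.na(bin)) {
        real_cells$cell_id[real_cells$cell_type == type]
      } else {
        real_cells$cell_id[real_cells$cell_type == type &
                             !is.na(real_cells$bin) & real_cells$bin == bin]
      }
      if (length(pool) == 0L) {
        stop("no real cells for cell type ", type,
             if (!is.na(bin)) paste0(" in bin ", bin))
      }
      v <- length(rows)
      r <- length(pool)
      picks <- if (r >= v) {
        sample(pool, v)
      } else {
        # every profile used floor(v/r) times, remainder once more
        base <- rep(pool, v %/% r)
        extra <- sample(pool, v %% r)
        sample(c(base, extra))
      }
      tibble::tibble(
        virtual_id = tpl$virtual_id[rows],
        cell_type = type, bin = bin, real_id = picks
      )
    })
    dplyr::bind_rows(pieces)
  })
  out[match(tpl$virtual_id, out$virtual_id), ]
}

#' @rdname map_cells
#' @param assignment Output of `map_cells()`.
#' @param values Matrix with real cell ids as rownames (cells x features).
#' @return `transfer_profiles()`: matrix of the assigned values, rows named
#'   and ordered by `virtual_id`.
#' @export
transfer_profiles <- function(assignment, values) {
  stopifnot(all(assignment$real_id %in% rownames(values)))
  out <- values[assignment$real_id, , drop = FALSE]
  rownames(out) <- assignment$virtual_id
  out
}

#' Test features for zonation along pseudotime
#'
#' Fits, per feature, a natural cubic spline regression (`df` basis
#' functions) on the pseudotime rank scale against an intercept-only null and
#' reports the F-test p-value, Benjamini-Hochberg adjusted over all testable
#' features; a feature is flagged significant when the adjusted p is strictly
#' below `alpha` (default 0.01). Rank-based fitting makes the test invariant
#' to monotone relabelling of pseudotime. Zero-variance features are flagged
#' untestable with `p = 1`. The fitted curve on a 100-point pseudotime grid is
#' returned per feature.
#'
#' @param values Feature x cell matrix (finite values; e.g. log-normalised
#'   expression or imputed accessibility).
#' @param ordering Tibble with `cell_id`, `pseudotime` (see
#'   [bin_pseudotime()]); cells must match the matrix columns.
#' @param df Spline degrees of freedom.
#' @param alpha Adjusted-p significance threshold.
#' @return A `zonation_fit` tibble: `feature`, `statistic`, `p`, `padj`,
#'   `significant`, `untestable`, `curve` (list column of 100 fitted values
#'   along the pseudotime grid).
#' @export
fit_zonation <- function(values, ordering, df = 5L, alpha = 0.01) {
  stopifnot(is.matrix(values), all(is.finite(values)))
  if (is.numeric(ordering)) ordering <- bin_pseudotime(ordering)
  n <- ncol(values)
  if (n < 20L) stop("need at least 20 cells")
  stopifnot(n == nrow(ordering))
  if (!is.null(colnames(values)) &&
      !identical(colnames(values), ordering$cell_id)) {
    values <- values[, match(ordering$cell_id, colnames(values)), drop = FALSE]
  }
  x <- rank(ordering$pseudotime, ties.method = "first") / n
  basis <- splines::ns(x, df = df)
  design <- cbind(1, basis)
  qrx <- qr(design)
  y <- t(values) # cells x features
  coefs <- qr.coef(qrx, y)
  fitted <- design %*% coefs
  rss1 <- colSums((y - fitted)^2)
  rss0 <- colSums(sweep(y, 2L, colMeans(y))^2)
  df_res <- n - df - 1L
  fstat <- ((rss0 - rss1) / df) / (rss1 / df_res)
  p <- stats::pf(fstat, df, df_res, lower.tail = FALSE)
  untestable <- rss0 <= .Machine$double.eps * n
  p[untestable] <- 1
  fstat[untestable] <- 0
  grid <- seq(min(x), max(x), length.out = 100L)
  grid_design <- cbind(1, stats::predict(basis, grid))
  curves <- grid_design %*% coefs
  padj <- stats::p.adjust(p, method = "BH")
  out <- tibble::tibble(
    feature = rownames(values) %||% paste0("feature_", seq_len(nrow(values))),
    statistic = unname(fstat),
    p = unname(p),
    padj = unname(padj),
    significant = unname(padj < alpha & !untestable),
    untestable = unname(untestable),
    curve = lapply(seq_len(nrow(values)), function(i) unname(curves[, i]))
  )
  attr(out, "pseudotime_grid") <- grid
  attr(out, "alpha") <- alpha
  class(out) <- c("zonation_fit", class(out))
  out
}

#' @export
glance.zonation_fit <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_significant = sum(x$significant),
    n_untestable = sum(x$untestable),
    alpha = attr(x, "alpha")
  )
}
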