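#' Generate a parametric virtual liver-lobule template
#'
#' Places virtual cells in a hexagonal disc: the central vein sits at the
#' centre, portal structures (portal-vein cells) at the six vertices, and the
#' zonated parenchymal cell types fill the lobule. Every zonated virtual cell
#' carries its radial distance to the central vein, normalised to `[0, 1]`
#' within the lobule, and a distance bin (equal-frequency, per cell type) used
#' by [map_cells()].
#'
#' @param n_virtual Total number of virtual cells (>= number of cell types).
#' @param cell_type_fractions Named fractions summing to 1. Names
#'   `central_vein` and `portal_vein` are treated as landmark (non-zonated)
#'   structures; all other types are zonated parenchymal types.
#' @param n_bins Number of radial distance bins for zonated types.
#' @param seed Integer seed.
#' @return A `virtual_template`: tibble with columns `virtual_id`, `x`, `y`,
#'   `cell_type`, `radial_dist` (NA for landmark types) and `bin` (NA for
#'   landmark types).
#' @examples
#' tpl <- simulate_lobule(500, c(hepatocyte = 0.8, central_vein = 0.1, portal_vein = 0.1))
#' dplyr::count(tpl, cell_type)
#' @export
simulate_lobule <- function(n_virtual,
                            cell_type_fractions = c(
                              hepatocyte = 0.7, lsec = 0.15, hsc = 0.05,
                              central_vein = 0.05, portal_vein = 0.05
                            ),
                            n_bins = 10L, seed = 1L) {
  stopifnot(n_virtual >= 1, !is.null(names(cell_type_fractions)))
  if (abs(sum(cell_type_fractions) - 1) > 1e-6) {
    stop("cell_type_fractions must sum to 1")
  }
  types <- names(cell_type_fractions)
  if (n_virtual < length(types[cell_type_fractions > 0])) {
    stop("n_virtual is smaller than the number of cell types")
  }
  # largest-remainder apportionment of cells to types
  raw <- n_virtual * cell_type_fractions
  n_type <- floor(raw)
  rem <- n_virtual - sum(n_type)
  if (rem > 0) {
    extra <- order(raw - n_type, decreasing = TRUE)[seq_len(rem)]
    n_type[extra] <- n_type[extra] + 1
  }
  landmark <- types %in% c("central_vein", "portal_vein")
  withr::with_seed(seed, {
    out <- lapply(seq_along(types), function(ti) {
      k <- n_type[ti]
      if (k == 0L) return(NULL)
      type <- types[ti]
      if (type == "central_vein") {
        pts <- runif_hex(k, radius = 0.06)
      } else if (type == "portal_vein") {
        # split across the six lobule vertices
        vert <- hex_vertices()
        vi <- sample(rep_len(seq_len(6L), k))
        pts <- runif_hex(k, radius = 0.08)
        pts$x <- pts$x + vert$x[vi]
        pts$y <- pts$y + vert$y[vi]
      } else {
        pts <- runif_hex(k, radius = 1)
      }
      tibble::tibble(x = pts$x, y = pts$y, cell_type = type)
    })
    out <- dplyr::bind_rows(out)
    out <- out[sample.int(nrow(out)), ] # interleave types
  })
  out$virtual_id <- sprintf("vc_%05d", seq_len(nrow(out)))
  r <- sqrt(out$x^2 + out$y^2)
  zonated <- !(out$cell_type %in% c("central_vein", "portal_vein"))
  out$radial_dist <- ifelse(zonated, pmin(r, 1), NA_real_)
  out$bin <- NA_integer_
  for (type in unique(out$cell_type[zonated])) {
    sel <- which(out$cell_type == type)
    out$bin[sel] <- rank_bins(out$radial_dist[sel], min(n_bins, length(sel)))
  }
  out <- dplyr::select(
    out, "virtual_id", "x", "y", "cell_type", "radial_dist", "bin"
  )
  class(out) <- c("virtual_template", class(out))
  out
}

hex_vertices <- function() {
  ang <- pi / 180 * (seq(0, 300, by = 60) + 30)
  list(x = cos(ang), y = sin(ang))
}

# uniform samples in a regular hexagon of given circumradius, centred at 0
runif_hex <- function(n, radius = 1) {
  xs <- numeric(0)
  ys <- numeric(0)
  apothem <- sqrt(3) / 2
  while (length(xs) < n) {
    m <- 2L * (n - length(xs)) + 8L
    x <- stats::runif(m, -1, 1)
    y <- stats::runif(m, -apothem, apothem)
    inside <- abs(y) <= apothem & abs(y) <= sqrt(3) * (1 - abs(x))
    xs <- c(xs, x[inside])
    ys <- c(ys, y[inside])
  }
  list(x = xs[seq_len(n)] * radius, y = ys[seq_len(n)] * radius)
}

# equal-frequency bins of a numeric vector, ties broken by stable order
rank_bins <- function(v, n_bins) {
  n <- length(v)
  stopifnot(n_bins >= 1, n_bins <= n)
  ord <- order(v, seq_len(n))
  sizes <- diff(floor(seq(0, n, length.out = n_bins + 1)))
  bins <- integer(n)
  bins[ord] <- rep(seq_len(n_bins), times = sizes)
  bins
}
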