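#' Genomic region tables
#'
#' Regions are plain tibbles in BED convention (0-based half-open) with
#' columns `chrom`, `start`, `end`, `name`, `score` and, for peaks, `summit`
#' (bp offset of the summit within the region). `genomic_regions()` validates
#' and normalises such a tibble.
#'
#' @param df Data frame with at least `chrom`, `start`, `end`.
#' @return A validated tibble.
#' @export
genomic_regions <- function(df) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (!all(df$start < df$end)) stop("regions must satisfy start < end")
  if (is.null(df[["name"]])) df$name <- sprintf("region_%d", seq_len(nrow(df)))
  if (is.null(df[["score"]])) df$score <- 0
  if (any(df$score < 0)) stop("region scores must be non-negative")
  if (!is.null(df[["summit"]])) {
    ok <- is.na(df$summit) | (df$summit >= 0 & df$summit < df$end - df$start)
    if (!all(ok)) stop("summit offsets must lie within the region")
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' Iterative overlap merging of summit-extended peaks
#'
#' Two-pass consensus-peak procedure. Pass 1, within each pseudobulk peak set:
#' every summit is extended `half_width` bp in each direction; peaks are
#' ranked by score (descending); the most significant peak is kept and every
#' peak overlapping it is removed; the procedure repeats with the next
#' surviving peak. Pass 2: scores are normalised per set (CPM-style,
#' `score / set total * 1e6`, so scores are comparable across pseudobulks) and
#' the same iterative filter runs on the pooled survivors. The output regions
#' all have width `2 * half_width` and are pairwise non-overlapping; the
#' procedure is idempotent. Rank ties are broken by (score desc, chrom,
#' start) for determinism.
#'
#' @param peak_sets A list of per-pseudobulk peak tibbles (each needs `chrom`,
#'   `start`, `end`, `score` and a `summit` offset), or a single tibble.
#' @param half_width Summit extension in bp (250 by default, giving 500-bp
#'   consensus regions).
#' @return Tibble of fixed-width non-overlapping regions with the
#'   (pass-2-normalised) score of the surviving peak.
#' @examples
#' peaks <- tibble::tibble(chrom = "chr1", start = 900, end = 1100,
#'                         summit = 100, score = 5, name = "p1")
#' iterative_peak_merge(list(peaks)) # chr1:750-1250
#' @export
iterative_peak_merge <- function(peak_sets, half_width = 250L) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  peak_sets <- lapply(peak_sets, function(p) {
    p <- genomic_regions(p)
    if (is.null(p[["summit"]]) || anyNA(p$summit)) stop("every peak needs a summit offset")
    p
  })
  extended <- lapply(seq_along(peak_sets), function(si) {
    p <- peak_sets[[si]]
    pos <- p$start + p$summit
    tibble::tibble(
      chrom = p$chrom,
      start = as.integer(pmax(pos - half_width, 0L)),
      end = as.integer(pos + half_width),
      name = p$name,
      score = p$score,
      set = si
    )
  })
  pass1 <- lapply(extended, greedy_keep)
  pooled <- dplyr::bind_rows(lapply(pass1, function(p) {
    p$score <- p$score / sum(p$score) * 1e6
    p
  }))
  out <- greedy_keep(pooled)
  dplyr::select(out, "chrom", "start", "end", "name", "score")
}

# keep the highest-scoring peak, drop everything overlapping it, repeat
greedy_keep <- function(peaks) {
  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  peaks <- peaks[ord, ]
  keep <- logical(nrow(peaks))
  kept_start <- list()
  kept_end <- list()
  for (i in seq_len(nrow(peaks))) {
    chr <- peaks$chrom[i]
    ks <- kept_start[[chr]]
    if (!is.null(ks) &&
        any(peaks$start[i] < kept_end[[chr]] & peaks$end[i] > ks)) {
      next
    }
    keep[i] <- TRUE
    kept_start[[chr]] <- c(ks, peaks$start[i])
    kept_end[[chr]] <- c(kept_end[[chr]], peaks$end[i])
  }
  out <- peaks[keep, ]
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Multi-label training labels from a region-by-topic score matrix
#'
#' Per topic, the `top_n` regions by score are labelled 1; a region appearing
#' in several topics' top lists receives several 1s. Ties at the cutoff are
#' resolved by keeping the first `top_n` regions after a deterministic
#' (score desc, row order) sort, with a warning.
#'
#' @param region_topic_scores Numeric matrix (regions x topics); rownames are
#'   region ids, colnames topic names.
#' @param top_n Number of positive regions per topic (<= number of regions).
#' @return Binary label matrix of the same shape.
#' @export
select_topic_training_set <- function(region_topic_scores, top_n = 3000L) {
  m <- as.matrix(region_topic_scores)
  if (top_n > nrow(m)) stop("top_n exceeds the number of regions")
  labels <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    ord <- order(-m[, j], seq_len(nrow(m)))
    cut_score <- m[ord[top_n], j]
    if (top_n < nrow(m) && m[ord[top_n + 1L], j] == cut_score) {
      warning("ties at the top_n cutoff in topic ", j,
              "; keeping the first ", top_n, " after deterministic sort")
    }
    labels[ord[seq_len(top_n)], j] <- 1
  }
  labels
}

#' Sliding-window augmentation of fixed-width regions
#'
#' Each region is symmetrically extended to `extend_to` bp around its centre
#' and tiled with windows of `window` bp every `stride` bp, yielding
#' `floor((extend_to - window) / stride) + 1` windows per region that all
#' inherit the parent's name (id suffix `_w<k>`) and score. Regions whose
#' extension would run past the contig start are shifted inward (never
#' clipped) so every window has exact width.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`, `name`, ...).
#' @param extend_to Extension target in bp (>= `window`).
#' @param window Window width in bp.
#' @param stride Stride in bp.
#' @return Tibble of windows with columns `chrom`, `start`, `end`, `name`,
#'   `parent`, `offset`.
#' @examples
#' r <- tibble::tibble(chrom = "chrSYN", start = 1000, end = 1500, name = "r1")
#' nrow(augment_windows(r)) # 5 windows
#' @export
augment_windows <- function(regions, extend_to = 700L, window = 500L, stride = 50L) {
  if (window > extend_to) stop("window must not exceed extend_to")
  regions <- genomic_regions(regions)
  center <- (regions$start + regions$end) / 2
  ext_start <- as.integer(round(center - extend_to / 2))
  ext_start <- pmax(ext_start, 0L) # shift inward at the contig start
  offsets <- seq(0L, extend_to - window, by = stride)
  out <- lapply(seq_along(offsets), function(k) {
    tibble::tibble(
      chrom = regions$chrom,
      start = ext_start + offsets[k],
      end = ext_start + offsets[k] + as.integer(window),
      name = paste0(regions$name, "_w", k),
      parent = regions$name,
      offset = offsets[k]
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$parent, .data$offset)
}
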