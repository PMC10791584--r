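#' Assign reporter barcodes to enhancers
#'
#' Collapses raw (barcode, enhancer) read observations into assignments,
#' optionally filtering barcodes against an IUPAC template (e.g. the
#' degenerate barcode design `NNNYRNNNYRNNNYRNNN`), dropping assignments below
#' a read-support floor and flagging barcodes seen with more than one
#' enhancer, which are excluded from downstream counting.
#'
#' @param read_pairs Tibble (or data frame) with columns `barcode` and
#'   `enhancer`, one row per read (or with a `reads` column of precollapsed
#'   counts).
#' @param pattern Optional IUPAC template the barcode must match (same
#'   length as the barcodes).
#' @param min_reads Minimum supporting reads for an assignment.
#' @return Tibble with `barcode`, `enhancer`, `reads`, `unique`; the fraction
#'   of barcodes assigned to a unique enhancer is attached as attribute
#'   `unique_fraction` and reported by `summary()`.
#' @examples
#' obs <- tibble::tibble(barcode = c("AAATGAAACGAAATGAAA", "AAATGAAACGAAATGAAA"),
#'                       enhancer = c("e1", "e1"))
#' assign_barcodes(obs, pattern = "NNNYRNNNYRNNNYRNNN")
#' @export
assign_barcodes <- function(read_pairs, pattern = NULL, min_reads = 1L) {
  stopifnot(is.data.frame(read_pairs),
            all(c("barcode", "enhancer") %in% names(read_pairs)))
  if (nrow(read_pairs) == 0L) stop("no barcode observations")
  df <- tibble::as_tibble(read_pairs)
  if (is.null(df[["reads"]])) df$reads <- 1L
  if (!is.null(pattern)) {
    if (any(nchar(df$barcode) != nchar(pattern))) {
      stop("barcodes must have the same length as the IUPAC pattern")
    }
    ok <- grepl(iupac_to_regex(pattern), df$barcode)
    df <- df[ok, ]
    if (nrow(df) == 0L) stop("no barcodes match the IUPAC pattern")
  }
  out <- df |>
    dplyr::group_by(.data$barcode, .data$enhancer) |>
    dplyr::summarise(reads = sum(.data$reads), .groups = "drop") |>
    dplyr::filter(.data$reads >= min_reads) |>
    dplyr::group_by(.data$barcode) |>
    dplyr::mutate(unique = dplyr::n() == 1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$barcode, .data$enhancer)
  n_bc <- dplyr::n_distinct(out$barcode)
  uf <- if (n_bc == 0L) NA_real_ else
    dplyr::n_distinct(out$barcode[out$unique]) / n_bc
  attr(out, "unique_fraction") <- uf
  out
}

IUPAC_MAP <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

iupac_to_regex <- function(pattern) {
  codes <- strsplit(toupper(pattern), "")[[1]]
  if (!all(codes %in% names(IUPAC_MAP))) {
    stop("invalid IUPAC code in pattern: ", pattern)
  }
  paste0("^", paste(IUPAC_MAP[codes], collapse = ""), "$")
}

#' Assemble a designed reporter oligo
#'
#' Concatenates the 5' adaptor, the enhancer sequence, the barcode and the 3'
#' adaptor into the synthesised oligo; the defaults are the study's 15-bp
#' adaptors, so a 258-bp enhancer plus a 12-bp barcode yields a 300-bp oligo.
#'
#' @param enhancer Enhancer sequence.
#' @param barcode Barcode sequence.
#' @param adaptor5,adaptor3 Flanking adaptors.
#' @return The oligo string.
#' @export
build_oligo <- function(enhancer, barcode,
                        adaptor5 = "CCAGTGCAAGTGCAG",
                        adaptor3 = "GGCCTAACTGGCCGG") {
  paste0(adaptor5, toupper(enhancer), toupper(barcode), adaptor3)
}

#' Normalised log2 fold change per enhancer
#'
#' Size factors are estimated by median-of-ratios across all samples
#' (pseudo-reference = per-enhancer geometric mean over samples; enhancers
#' with any zero count are excluded from factor estimation), then
#' `logFC = mean over cDNA replicates of log2(normalised count + 0.5)` minus
#' the same over plasmid replicates. The 0.5 pseudocount avoids minus
#' infinity on zero counts.
#'
#' @param table An [mpra_table()].
#' @param fraction Optional FACS fraction tag: only cDNA samples with this
#'   `fraction` are used (plasmid samples are reused from the bulk experiment,
#'   matching the study design where fractions have no plasmid of their own).
#' @return Tibble with `enhancer`, `logfc`, `se`, `shuffled`.
#' @export
compute_logfc <- function(table, fraction = NULL) {
  stopifnot(inherits(table, "mpra_table"))
  counts <- table$counts
  if (any(colSums(counts) == 0)) stop("a sample has all-zero counts")
  sf <- median_of_ratios(counts)
  norm <- sweep(counts, 2L, sf, "/")
  cdna_cols <- table$samples$role == "cdna"
  if (!is.null(fraction)) {
    cdna_cols <- cdna_cols & !is.na(table$samples$fraction) &
      table$samples$fraction == fraction
    if (!any(cdna_cols)) stop("no cDNA samples with fraction ", fraction)
  }
  plasmid_cols <- table$samples$role == "plasmid"
  lc <- log2(norm[, cdna_cols, drop = FALSE] + 0.5)
  lp <- log2(norm[, plasmid_cols, drop = FALSE] + 0.5)
  nc <- ncol(lc)
  np <- ncol(lp)
  se <- sqrt(
    apply(lc, 1L, stats::var) / nc + apply(lp, 1L, stats::var) / np
  )
  se[is.na(se)] <- 0 # single-replicate designs carry no spread estimate
  tibble::tibble(
    enhancer = rownames(counts),
    logfc = unname(rowMeans(lc) - rowMeans(lp)),
    se = unname(se),
    shuffled = table$shuffled
  )
}

median_of_ratios <- function(counts) {
  pos <- rowSums(counts == 0) == 0
  if (!any(pos)) stop("no enhancer has all-positive counts; cannot estimate size factors")
  geo <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
  apply(counts[pos, , drop = FALSE], 2L, function(col) {
    stats::median(col / geo)
  })
}

#' Call active enhancers against a shuffled-control Gaussian null
#'
#' A Gaussian is fitted to the shuffled negative-control log fold changes --
#' robustly by default (median location, scaled MAD) or by mean/SD -- and
#' every enhancer gets a one-sided upper-tail p-value from that null.
#' Benjamini-Hochberg adjustment runs over all non-control enhancers and an
#' enhancer is called active if its adjusted p-value is strictly below
#' `alpha` (default 0.1).
#'
#' @param logfc Tibble from [compute_logfc()] (columns `enhancer`, `logfc`,
#'   `shuffled`), or a numeric vector with `shuffled_ids` naming the controls.
#' @param shuffled_ids Control ids when `logfc` is a bare named vector.
#' @param alpha Adjusted-p threshold for the active call.
#' @param robust Use median/MAD (`TRUE`) or mean/SD (`FALSE`) for the null fit.
#' @return An `activity_calls` tibble: `enhancer`, `logfc`, `z`, `p`, `padj`,
#'   `active`, `shuffled` (controls keep `padj = NA`, `active = NA`). The
#'   fitted null is attached as attribute `null_fit`.
#' @export
call_active <- function(logfc, shuffled_ids = NULL, alpha = 0.1, robust = TRUE) {
  if (is.numeric(logfc)) {
    stopifnot(!is.null(names(logfc)), !is.null(shuffled_ids))
    logfc <- tibble::tibble(
      enhancer = names(logfc), logfc = unname(logfc),
      shuffled = names(logfc) %in% shuffled_ids
    )
  }
  stopifnot(all(c("enhancer", "logfc", "shuffled") %in% names(logfc)))
  null_vals <- logfc$logfc[logfc$shuffled]
  if (length(null_vals) < 20L) {
    stop("need at least 20 shuffled controls to estimate the null")
  }
  if (robust) {
    mu <- stats::median(null_vals)
    sdv <- stats::mad(null_vals) # 1.4826 * MAD, normal-consistent
  } else {
    mu <- mean(null_vals)
    sdv <- stats::sd(null_vals)
  }
  if (sdv <= 0) stop("null scale is zero (MAD = 0); cannot compute p-values")
  out <- dplyr::mutate(
    tibble::as_tibble(logfc),
    z = (.data$logfc - mu) / sdv,
    p = stats::pnorm(.data$z, lower.tail = FALSE)
  )
  out$padj <- NA_real_
  out$padj[!out$shuffled] <- stats::p.adjust(out$p[!out$shuffled], method = "BH")
  out$active <- out$padj < alpha
  attr(out, "null_fit") <- list(location = mu, scale = sdv, robust = robust,
                                n_controls = length(null_vals), alpha = alpha)
  class(out) <- c("activity_calls", class(out))
  out
}

#' @export
glance.activity_calls <- function(x, ...) {
  nf <- attr(x, "null_fit")
  tibble::tibble(
    n_enhancers = sum(!x$shuffled),
    n_controls = nf$n_controls,
    n_active = sum(x$active, na.rm = TRUE),
    frac_active = mean(x$active[!x$shuffled]),
    null_location = nf$location,
    null_scale = nf$scale,
    alpha = nf$alpha
  )
}

#' Compare enhancer activity between two FACS fractions
#'
#' Joins two activity-call tables over the same enhancer universe and reports
#' the per-enhancer difference in log fold change (a - b), e.g. the
#' pericentral (CD73-high) minus periportal (ECAD-high) readout.
#'
#' @param calls_a,calls_b `activity_calls` (or `compute_logfc()` output) over
#'   identical enhancer sets.
#' @return Tibble with `enhancer`, `logfc_a`, `logfc_b`, `delta_logfc` and,
#'   when available, both active flags.
#' @export
compare_fractions <- function(calls_a, calls_b) {
  stopifnot(is.data.frame(calls_a), is.data.frame(calls_b))
  if (!setequal(calls_a$enhancer, calls_b$enhancer)) {
    stop("the two call sets cover different enhancer universes")
  }
  a <- dplyr::select(tibble::as_tibble(calls_a), "enhancer", logfc_a = "logfc",
                     dplyr::any_of(c(active_a = "active")))
  b <- dplyr::select(tibble::as_tibble(calls_b), "enhancer", logfc_b = "logfc",
                     dplyr::any_of(c(active_b = "active")))
  dplyr::inner_join(a, b, by = "enhancer") |>
    dplyr::mutate(delta_logfc = .data$logfc_a - .data$logfc_b)
}
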