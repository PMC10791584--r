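#' Fit per-gene regressors on an enhancer-driven GRN
#'
#' For every target gene in the edge list, a regressor predicting its
#' expression from the expression of its listed transcription-factor
#' regulators is fitted (gradient-boosted trees by default, 500 rounds of
#' depth 3 at learning rate 0.05; a linear mode exists and enables exact
#' analytic checks). A gene is never used as its own predictor. In-sample R2
#' is recorded per gene.
#'
#' @param expr Cell x gene expression matrix (genes in columns, named).
#' @param edges Edge list tibble (`tf`, `target`, `sign`).
#' @param engine `"gbm"` (xgboost) or `"linear"` (ordinary least squares).
#' @param seed Integer seed (GBM fitting).
#' @param nrounds,max_depth,eta GBM hyperparameters.
#' @return An `egrn_model`: list with `fits` (per-target regressor +
#'   regulator list), `edges`, `engine`, `r2` tibble.
#' @export
fit_target_models <- function(expr, edges, engine = c("gbm", "linear"),
                              seed = 1L, nrounds = 500L, max_depth = 3L,
                              eta = 0.05) {
  engine <- match.arg(engine)
  stopifnot(is.matrix(expr), !is.null(colnames(expr)),
            all(c("tf", "target", "sign") %in% names(edges)))
  missing_genes <- setdiff(unique(c(edges$tf, edges$target)), colnames(expr))
  if (length(missing_genes)) {
    stop("edge genes absent from the expression matrix: ",
         paste(missing_genes, collapse = ", "))
  }
  targets <- unique(edges$target)
  fits <- list()
  r2 <- numeric(length(targets))
  for (i in seq_along(targets)) {
    g <- targets[i]
    regs <- setdiff(unique(edges$tf[edges$target == g]), g) # no self-edge predictor
    if (length(regs) == 0L) stop("target ", g, " has zero regulators")
    x <- expr[, regs, drop = FALSE]
    y <- expr[, g]
    if (engine == "gbm") {
      fit <- xgboost::xgboost(
        x, y, nrounds = nrounds, max_depth = max_depth,
        learning_rate = eta, objective = "reg:squarederror",
        verbosity = 0, nthreads = 1L, seed = seed
      )
      pred <- stats::predict(fit, x)
    } else {
      fit <- stats::lm.fit(cbind(1, x), y)
      # rank-deficient designs (e.g. a constant regulator in noiseless data)
      # leave NA coefficients; treat the dropped column as zero effect
      fit$coefficients[is.na(fit$coefficients)] <- 0
      pred <- cbind(1, x) %*% fit$coefficients
    }
    sst <- sum((y - mean(y))^2)
    r2[i] <- if (sst == 0) NA_real_ else 1 - sum((y - pred)^2) / sst
    fits[[g]] <- list(fit = fit, regulators = regs)
  }
  structure(
    list(
      fits = fits, edges = tibble::as_tibble(edges), engine = engine,
      seed = seed,
      r2 = tibble::tibble(target = targets, r2 = r2),
      hyperparameters = if (engine == "gbm") {
        list(nrounds = nrounds, max_depth = max_depth, eta = eta)
      } else {
        list()
      }
    ),
    class = "egrn_model"
  )
}

#' @export
print.egrn_model <- function(x, ...) {
  cat(
    "<egrn_model> ", length(x$fits), " target genes, ",
    dplyr::n_distinct(x$edges$tf), " TFs, engine ", x$engine,
    "; median in-sample R2 ", signif(stats::median(x$r2$r2, na.rm = TRUE), 3),
    "\n", sep = ""
  )
  invisible(x)
}

#' @export
glance.egrn_model <- function(x, ...) {
  tibble::tibble(
    n_targets = length(x$fits),
    n_tfs = dplyr::n_distinct(x$edges$tf),
    engine = x$engine,
    median_r2 = stats::median(x$r2$r2, na.rm = TRUE)
  )
}

predict_target <- function(model, g, expr) {
  fit <- model$fits[[g]]
  x <- expr[, fit$regulators, drop = FALSE]
  if (model$engine == "gbm") {
    stats::predict(fit$fit, x)
  } else {
    as.vector(cbind(1, x) %*% fit$fit$coefficients)
  }
}

#' Simulate a transcription-factor knockdown or overexpression
#'
#' The selected TF's expression column is clamped -- to 0 for knockdown, or to
#' the maximum expression observed over `cell_mask` (all cells if absent) for
#' overexpression -- and every target gene is re-predicted from the current
#' matrix over `n_iter` iterations, re-clamping the TF after each pass so
#' downstream (indirect) effects propagate. All iterates are returned along
#' with per-gene fold changes (perturbed / original, pseudocount 0.01).
#'
#' @param model An `egrn_model` from [fit_target_models()].
#' @param expr Cell x gene matrix the perturbation starts from.
#' @param tf TF gene name (must be in the model's edge list).
#' @param mode `"KD"` or `"OE"`.
#' @param n_iter Number of update iterations (>= 1).
#' @param cell_mask Optional logical/integer cell selector for the OE clamp
#'   value (e.g. hepatocytes).
#' @return A `perturbation_result`: list with `iterates` (list of matrices,
#'   `[[1]]` = clamped input), `final` (last iterate), `fold_change` tibble
#'   (`gene`, `fc`, mean perturbed, mean original), `tf`, `mode`,
#'   `convergence` (per-iteration mean absolute update).
#' @export
simulate_perturbation <- function(model, expr, tf, mode = c("KD", "OE"),
                                  n_iter = 5L, cell_mask = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "egrn_model"), n_iter >= 1)
  if (!(tf %in% colnames(expr))) stop("TF ", tf, " absent from the matrix")
  if (!(tf %in% model$edges$tf)) stop("TF ", tf, " is not a regulator in the model")
  clamp <- if (mode == "KD") {
    0
  } else {
    vals <- if (is.null(cell_mask)) expr[, tf] else expr[cell_mask, tf]
    if (length(vals) == 0L) stop("cell_mask selects no cells")
    max(vals)
  }
  cur <- expr
  cur[, tf] <- clamp
  iterates <- list(cur)
  deltas <- numeric(n_iter)
  targets <- names(model$fits)
  for (it in seq_len(n_iter)) {
    nxt <- cur
    for (g in targets) {
      nxt[, g] <- predict_target(model, g, cur)
    }
    nxt[, tf] <- clamp # clamping is exact at every iterate
    deltas[it] <- mean(abs(nxt - cur))
    cur <- nxt
    iterates[[it + 1L]] <- cur
  }
  eps <- 0.01
  fc <- (colMeans(cur) + eps) / (colMeans(expr) + eps)
  structure(
    list(
      iterates = iterates, final = cur,
      fold_change = tibble::tibble(
        gene = colnames(expr), fc = unname(fc),
        mean_perturbed = unname(colMeans(cur)),
        mean_original = unname(colMeans(expr))
      ),
      tf = tf, mode = mode, n_iter = n_iter,
      convergence = deltas
    ),
    class = "perturbation_result"
  )
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(
    "<perturbation_result> ", x$tf, " ", x$mode, ", ", x$n_iter,
    " iterations; mean |update| per iteration: ",
    paste(signif(x$convergence, 3), collapse = ", "), "\n", sep = ""
  )
  invisible(x)
}

#' @export
tidy.perturbation_result <- function(x, ...) x$fold_change

#' Embedding displacement of perturbed expression profiles
#'
#' Places each perturbed cell profile at the distance-weighted mean embedding
#' coordinate of its `k` nearest original cells -- neighbours found in a
#' 50-component principal-component feature space fitted on the original
#' matrix -- and returns the displacement arrows from each cell's original
#' position.
#'
#' @param original_expr,perturbed_expr Cell x gene matrices (same cells/genes).
#' @param embedding Cell x 2 coordinate matrix aligned with the original rows.
#' @param k Number of nearest neighbours (`k = 1` snaps to the nearest
#'   original cell's coordinate).
#' @param n_pcs Feature-space dimensionality cap.
#' @return Tibble with `cell`, `x`, `y`, `dx`, `dy`, `magnitude`.
#' @export
embedding_shift <- function(original_expr, perturbed_expr, embedding, k = 10L,
                            n_pcs = 50L) {
  stopifnot(
    all(dim(original_expr) == dim(perturbed_expr)),
    nrow(embedding) == nrow(original_expr), ncol(embedding) >= 2L
  )
  n <- nrow(original_expr)
  if (k > n) stop("k exceeds the number of cells")
  keep <- apply(original_expr, 2L, stats::sd) > 0
  pca <- stats::prcomp(original_expr[, keep, drop = FALSE], center = TRUE,
                       scale. = FALSE, rank. = min(n_pcs, sum(keep), n - 1L))
  orig_pc <- pca$x
  pert_pc <- scale(perturbed_expr[, keep, drop = FALSE], center = pca$center,
                   scale = FALSE) %*% pca$rotation
  # squared distances perturbed x original via the expansion trick
  d2 <- outer(rowSums(pert_pc^2), rowSums(orig_pc^2), "+") -
    2 * tcrossprod(pert_pc, orig_pc)
  d2[d2 < 0] <- 0
  emb <- as.matrix(embedding[, 1:2])
  placed <- t(apply(cbind(seq_len(n)), 1L, function(i) {
    nn <- order(d2[i, ])[seq_len(k)]
    w <- 1 / (sqrt(d2[i, nn]) + 1e-8)
    colSums(emb[nn, , drop = FALSE] * w) / sum(w)
  }))
  dx <- placed[, 1] - emb[, 1]
  dy <- placed[, 2] - emb[, 2]
  tibble::tibble(
    cell = if (!is.null(rownames(original_expr))) rownames(original_expr) else
      sprintf("cell_%04d", seq_len(n)),
    x = emb[, 1], y = emb[, 2], dx = dx, dy = dy,
    magnitude = sqrt(dx^2 + dy^2)
  )
}
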