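#' Configuration for the sequence classifier
#'
#' Defaults follow the original study where it states them (1,024 filters of
#' width 24; base learning rate 1e-3; transfer learning rate 1e-5); the
#' remaining knobs are desk-scale package defaults. The transfer rate must be
#' smaller than the base rate.
#'
#' @param n_filters Number of convolutional filters.
#' @param filter_len Filter width in bp.
#' @param dense_units Width of the dense layer after global max pooling.
#' @param dropout Dropout rate on the dense layer during training.
#' @param lr_base Adam learning rate for base training (and for the fresh
#'   output head during transfer).
#' @param lr_transfer Adam learning rate for transferred layers during
#'   fine-tuning; must be `< lr_base`.
#' @param max_epochs Epoch budget.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping; best-epoch weights are restored.
#' @param fixed_epochs If set, train exactly this many epochs with no early
#'   stopping (fixed-epoch evaluation for cross-validation).
#' @param batch_size Minibatch size.
#' @param validation_fraction Fraction of the input held out internally for
#'   early stopping (10% of the input data).
#' @param rc_invariant Pool convolution activations over both the sequence
#'   and its reverse complement (elementwise maximum), making predictions
#'   strand-invariant -- motif instances land on either strand. Disable only
#'   for single-orientation diagnostics.
#' @param seed Integer seed controlling initialisation, the validation split,
#'   shuffling and dropout.
#' @return A `model_config` list.
#' @export
model_config <- function(n_filters = 1024L, filter_len = 24L,
                         dense_units = 64L, dropout = 0.4,
                         lr_base = 1e-3, lr_transfer = 1e-5,
                         max_epochs = 30L, early_stop_patience = 6L,
                         fixed_epochs = NULL,
                         batch_size = 64L, validation_fraction = 0.1,
                         rc_invariant = TRUE, seed = 1L) {
  if (!(lr_transfer < lr_base)) stop("lr_transfer must be smaller than lr_base")
  stopifnot(n_filters >= 1, filter_len >= 1, dense_units >= 1,
            dropout >= 0, dropout < 1, max_epochs >= 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(
    list(
      n_filters = as.integer(n_filters), filter_len = as.integer(filter_len),
      dense_units = as.integer(dense_units), dropout = dropout,
      lr_base = lr_base, lr_transfer = lr_transfer,
      max_epochs = as.integer(max_epochs),
      early_stop_patience = as.integer(early_stop_patience),
      fixed_epochs = if (is.null(fixed_epochs)) NULL else as.integer(fixed_epochs),
      batch_size = as.integer(batch_size),
      validation_fraction = validation_fraction,
      rc_invariant = isTRUE(rc_invariant),
      seed = as.integer(seed)
    ),
    class = "model_config"
  )
}

#' Initialise convolutional filters from PWMs
#'
#' Each PWM is log-odds transformed (`log2(p / 0.25)`, clipped to `[-3, 3]`),
#' centred and zero-padded into one filter column; the remaining filters are
#' randomly initialised with the configuration seed. Requires
#' `n_filters >= length(pwms)` and every PWM no longer than `filter_len`.
#'
#' @param pwms List of 4 x W PWMs (possibly empty).
#' @param config A [model_config()].
#' @return List with `wc` (a `(filter_len*4) x n_filters` weight matrix) and
#'   `bc` (zero biases).
#' @export
init_filters_from_pwms <- function(pwms, config) {
  stopifnot(inherits(config, "model_config"))
  if (length(pwms) > config$n_filters) {
    stop("more PWMs than filters; increase n_filters")
  }
  w4 <- 4L * config$filter_len
  wc <- withr::with_seed(config$seed, {
    matrix(stats::rnorm(w4 * config$n_filters, 0, sqrt(2 / w4)),
           w4, config$n_filters)
  })
  for (j in seq_along(pwms)) {
    pwm <- check_pwm(pwms[[j]])
    w <- ncol(pwm)
    if (w > config$filter_len) stop("PWM ", j, " is longer than filter_len")
    lo <- pwm_log_odds(pwm, clip = 3)
    offset <- floor((config$filter_len - w) / 2)
    col <- numeric(w4)
    for (pos in seq_len(w)) {
      col[(offset + pos - 1L) * 4L + 1:4] <- lo[, pos]
    }
    wc[, j] <- col
  }
  list(wc = wc, bc = rep(0, config$n_filters))
}

new_sequence_model <- function(weights, config, class_names, input_length,
                               output_mode, provenance, history, best_epoch,
                               val_loss) {
  structure(
    list(
      weights = weights, config = config, class_names = class_names,
      input_length = as.integer(input_length), output_mode = output_mode,
      activation = switch(output_mode, multilabel = "sigmoid",
                          onehot = "softmax", linear = "linear"),
      provenance = provenance, history = history,
      best_epoch = best_epoch, val_loss = val_loss
    ),
    class = "sequence_model"
  )
}

#' @export
print.sequence_model <- function(x, ...) {
  cat(
    "<sequence_model> ", length(x$class_names), " classes (", x$output_mode,
    "), input ", x$input_length, " bp, ", x$config$n_filters, " filters; ",
    "provenance: ", x$provenance$type,
    if (!is.null(x$provenance$parent_id)) paste0(" of ", x$provenance$parent_id),
    "; best epoch ", x$best_epoch, "\n",
    sep = ""
  )
  invisible(x)
}

prepare_training <- function(data) {
  stopifnot(inherits(data, "seq_set"))
  if (length(unique(nchar(data$sequences))) != 1L) {
    stop("all training sequences must have the same length")
  }
  if (ncol(data$labels) < 2L) stop("need at least 2 classes")
  zero <- colSums(data$labels) == 0
  if (any(zero)) {
    stop("class(es) with zero positive examples: ",
         paste(colnames(data$labels)[zero], collapse = ", "))
  }
  list(
    xm = nn_flatten_onehot(one_hot(data$sequences)),
    y = data$labels,
    input_length = nchar(data$sequences[1])
  )
}

#' Train the base (topic) sequence classifier
#'
#' Multi-label classifier (independent sigmoid outputs with binary
#' cross-entropy) mapping one-hot DNA to regulatory-topic membership.
#' Convolutional filters can be initialised from PWMs; a 10% internal split
#' (drawn with the configuration seed) is used for early stopping and the
#' weights of the best epoch (minimum validation loss, accuracy tiebreak) are
#' kept. The training history is retained on the model.
#'
#' @param data A [seq_set()] with topic labels.
#' @param config A [model_config()].
#' @param pwms Optional list of PWMs for filter initialisation.
#' @param val_idx Optional indices into `data` used as the validation set for
#'   early stopping, replacing the internal random split.
#' @return A `sequence_model` with provenance `base`.
#' @export
train_base <- function(data, config = model_config(), pwms = NULL,
                       val_idx = NULL) {
  prep <- prepare_training(data)
  conv_init <- if (!is.null(pwms)) init_filters_from_pwms(pwms, config)
  activation <- if (data$label_mode == "multilabel") "sigmoid" else "softmax"
  fit <- nn_train(prep$xm, prep$y, config, activation, conv_init = conv_init,
                  val_idx = val_idx)
  new_sequence_model(
    fit$weights, config, data$class_names, prep$input_length,
    output_mode = data$label_mode,
    provenance = list(type = "base", id = model_id(config, data)),
    history = fit$history, best_epoch = fit$best_epoch, val_loss = fit$val_loss
  )
}

model_id <- function(config, data) {
  sprintf("model_%d_%dc_%ds", config$seed, ncol(data$labels), length(data))
}

#' Transfer-learn a new classification head from a trained base model
#'
#' All layers are initialised from the base model except a fresh output head
#' sized to the new classes. During fine-tuning the transferred layers move at
#' `lr_transfer` while the fresh head trains at `lr_base` (a randomly
#' initialised head cannot leave its initialisation at the fine-tuning rate).
#' The provenance chain records the parent model.
#'
#' @param base A trained `sequence_model`.
#' @param data A [seq_set()] with the new labels (e.g. zonation or activity
#'   classes); sequence length must match the base model.
#' @param config A [model_config()]; filter geometry must match the base.
#' @param val_idx Optional explicit validation indices (see [train_base()]).
#' @return A `sequence_model` with provenance `transfer`.
#' @export
train_transfer <- function(base, data, config = base$config, val_idx = NULL) {
  stopifnot(inherits(base, "sequence_model"))
  prep <- prepare_training(data)
  if (prep$input_length != base$input_length) {
    stop("input length mismatch: base expects ", base$input_length, " bp")
  }
  if (config$n_filters != base$config$n_filters ||
      config$filter_len != base$config$filter_len ||
      config$dense_units != base$config$dense_units) {
    stop("filter/dense geometry must match the base model")
  }
  k <- ncol(prep$y)
  init <- withr::with_seed(config$seed, {
    list(
      wc = base$weights$wc, bc = base$weights$bc,
      wh = base$weights$wh, bh = base$weights$bh,
      wo = matrix(stats::rnorm(config$dense_units * k, 0,
                               sqrt(1 / config$dense_units)),
                  config$dense_units, k),
      bo = rep(0, k)
    )
  })
  lr <- c(
    wc = config$lr_transfer, bc = config$lr_transfer,
    wh = config$lr_transfer, bh = config$lr_transfer,
    wo = config$lr_base, bo = config$lr_base
  )
  activation <- if (data$label_mode == "multilabel") "sigmoid" else "softmax"
  fit <- nn_train(prep$xm, prep$y, config, activation,
                  init_weights = init, lr = lr, val_idx = val_idx)
  new_sequence_model(
    fit$weights, config, data$class_names, prep$input_length,
    output_mode = data$label_mode,
    provenance = list(type = "transfer", parent_id = base$provenance$id,
                      id = model_id(config, data)),
    history = fit$history, best_epoch = fit$best_epoch, val_loss = fit$val_loss
  )
}

#' Score sequences with a trained model
#'
#' @param object A `sequence_model`.
#' @param newdata A `seq_set` or character vector of sequences whose length
#'   equals the model's input length.
#' @param ... Unused.
#' @return Numeric score matrix (sequences x classes) in `[0, 1]`; rows sum
#'   to 1 for one-of-k models.
#' @export
predict.sequence_model <- function(object, newdata, ...) {
  seqs <- if (inherits(newdata, "seq_set")) newdata$sequences else newdata
  if (any(nchar(seqs) != object$input_length)) {
    stop("sequence length must equal the model input length (",
         object$input_length, " bp)")
  }
  xm <- nn_flatten_onehot(one_hot(seqs))
  p <- nn_predict_batched(object$weights, xm, object$config$filter_len,
                          object$activation, rc = object$config$rc_invariant)
  colnames(p) <- object$class_names
  rownames(p) <- if (inherits(newdata, "seq_set")) newdata$ids else names(seqs)
  p
}

#' Per-class AUROC and AUPR of a model on a test set
#'
#' One-vs-rest evaluation. A test set where some class has no positives or no
#' negatives makes AUROC undefined and is an explicit error.
#'
#' @param model A `sequence_model` (or a precomputed score matrix via
#'   `scores`).
#' @param test A [seq_set()].
#' @param scores Optional score matrix overriding `predict()`.
#' @return Tibble with `class`, `auroc`, `aupr`, `n_pos`, `n_neg`.
#' @export
evaluate <- function(model, test, scores = NULL) {
  stopifnot(inherits(test, "seq_set"), length(test) > 0)
  if (is.null(scores)) scores <- stats::predict(model, test)
  y <- test$labels
  out <- lapply(seq_len(ncol(y)), function(j) {
    pos <- sum(y[, j] == 1)
    neg <- sum(y[, j] == 0)
    if (pos == 0L || neg == 0L) {
      stop("class ", colnames(y)[j],
           " has a single label value in the test set; AUROC undefined")
    }
    tibble::tibble(
      class = colnames(y)[j],
      auroc = auroc(scores[, j], y[, j]),
      aupr = average_precision(scores[, j], y[, j]),
      n_pos = pos, n_neg = neg
    )
  })
  dplyr::bind_rows(out)
}

#' Grouped cross-validation with a leakage guard
#'
#' The data are split into `n_groups` by parent region, so augmented windows
#' of one region never span training and evaluation. Each rotation uses one
#' group as the test set, the next group as the validation set (early
#' stopping) and the rest for training. When `window` is smaller than the
#' sequence length, training and validation sequences are augmented with
#' sliding windows ([augment_seq_set()]) and the test set is evaluated on the
#' non-augmented centre windows only.
#'
#' @param data A [seq_set()] of full-length sequences.
#' @param config A [model_config()].
#' @param n_groups Number of groups (>= 3).
#' @param window,stride Optional sliding-window augmentation.
#' @param pwms Optional PWM filter initialisation.
#' @return List with `reports` (tibble of per-class metrics with `fold`) and
#'   `assignments` (tibble `parent_id`, `group`).
#' @export
cross_validate <- function(data, config = model_config(), n_groups = 10L,
                           window = NULL, stride = 50L, pwms = NULL) {
  stopifnot(inherits(data, "seq_set"), n_groups >= 3L)
  parents <- unique(data$parent_ids)
  if (n_groups > length(parents)) stop("more groups than parent regions")
  groups <- withr::with_seed(config$seed, {
    g <- rep(seq_len(n_groups), length.out = length(parents))
    stats::setNames(sample(g), parents)
  })
  reports <- list()
  for (fold in seq_len(n_groups)) {
    val_group <- fold %% n_groups + 1L
    grp <- groups[data$parent_ids]
    test_set <- data[grp == fold]
    val_set <- data[grp == val_group]
    train_set <- data[grp != fold & grp != val_group]
    if (!is.null(window)) {
      train_set <- augment_seq_set(train_set, window = window, stride = stride)$set
      aug_val <- augment_seq_set(val_set, window = window, stride = stride)
      val_set <- aug_val$set
      aug_test <- augment_seq_set(test_set, window = window, stride = stride)
      test_set <- aug_test$set[aug_test$is_center]
    }
    fit <- cv_fit(train_set, val_set, config, pwms)
    rep_fold <- evaluate(fit, test_set)
    rep_fold$fold <- fold
    reports[[fold]] <- rep_fold
  }
  list(
    reports = dplyr::bind_rows(reports),
    assignments = tibble::tibble(parent_id = names(groups), group = unname(groups))
  )
}

# fit with an explicit validation set (rather than an internal split)
cv_fit <- function(train_set, val_set, config, pwms) {
  combined <- seq_set(
    c(train_set$sequences, val_set$sequences),
    rbind(train_set$labels, val_set$labels),
    ids = make.unique(c(train_set$ids, val_set$ids)),
    parent_ids = c(train_set$parent_ids, val_set$parent_ids),
    label_mode = train_set$label_mode
  )
  prep <- prepare_training(combined)
  conv_init <- if (!is.null(pwms)) init_filters_from_pwms(pwms, config)
  activation <- if (combined$label_mode == "multilabel") "sigmoid" else "softmax"
  fit <- nn_train_explicit_val(
    prep$xm, prep$y, config, activation,
    val_idx = length(train_set) + seq_len(length(val_set)),
    conv_init = conv_init
  )
  new_sequence_model(
    fit$weights, config, combined$class_names, prep$input_length,
    output_mode = combined$label_mode,
    provenance = list(type = "base", id = model_id(config, combined)),
    history = fit$history, best_epoch = fit$best_epoch, val_loss = fit$val_loss
  )
}

#' Save / load a model bundle
#'
#' A model bundle is a directory with `config.json`, `class_names.txt`,
#' `weights.bin` (a single binary array container: little-endian doubles,
#' shapes in `shapes.json`) and `history.tsv`. Reload is bit-exact.
#'
#' @param model A `sequence_model`.
#' @param path Directory to create.
#' @return `save_model()` the path, invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sequence_model"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    config = unclass(model$config),
    input_length = model$input_length,
    output_mode = model$output_mode,
    provenance = model$provenance,
    best_epoch = model$best_epoch,
    val_loss = model$val_loss
  )
  jsonlite::write_json(meta, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(model$class_names, file.path(path, "class_names.txt"))
  shapes <- lapply(model$weights, function(w) if (is.matrix(w)) dim(w) else length(w))
  jsonlite::write_json(shapes, file.path(path, "shapes.json"))
  con <- file(file.path(path, "weights.bin"), "wb")
  on.exit(close(con))
  for (nm in names(model$weights)) {
    writeBin(as.vector(model$weights[[nm]]), con, size = 8, endian = "little")
  }
  readr::write_tsv(model$history, file.path(path, "history.tsv"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "config.json"),
                              simplifyVector = TRUE)
  class_names <- readLines(file.path(path, "class_names.txt"))
  shapes <- jsonlite::read_json(file.path(path, "shapes.json"),
                                simplifyVector = TRUE)
  con <- file(file.path(path, "weights.bin"), "rb")
  on.exit(close(con))
  weights <- lapply(shapes, function(sh) {
    v <- readBin(con, "double", n = prod(sh), size = 8, endian = "little")
    if (length(sh) == 2L) matrix(v, sh[1], sh[2]) else v
  })
  cfg <- meta$config
  config <- model_config(
    n_filters = cfg$n_filters, filter_len = cfg$filter_len,
    dense_units = cfg$dense_units, dropout = cfg$dropout,
    lr_base = cfg$lr_base, lr_transfer = cfg$lr_transfer,
    max_epochs = cfg$max_epochs, early_stop_patience = cfg$early_stop_patience,
    fixed_epochs = cfg$fixed_epochs, batch_size = cfg$batch_size,
    validation_fraction = cfg$validation_fraction,
    rc_invariant = cfg$rc_invariant, seed = cfg$seed
  )
  history <- readr::read_tsv(file.path(path, "history.tsv"),
                             show_col_types = FALSE)
  new_sequence_model(
    weights, config, class_names, meta$input_length, meta$output_mode,
    provenance = meta$provenance, history = history,
    best_epoch = meta$best_epoch, val_loss = meta$val_loss
  )
}

#' @export
tidy.sequence_model <- function(x, ...) x$history

#' @export
glance.sequence_model <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$class_names),
    output_mode = x$output_mode,
    input_length = x$input_length,
    n_filters = x$config$n_filters,
    best_epoch = x$best_epoch,
    val_loss = x$val_loss,
    provenance = x$provenance$type
  )
}

#' Broom-style tidiers
#'
#' `tidy()` returns the per-epoch training history of a model (or per-feature
#' results of a fit); `glance()` a one-row model summary.
#' @param x Object to tidy.
#' @param ... Unused.
#' @name tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")
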