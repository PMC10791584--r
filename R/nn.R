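# Internal neural-network engine for the sequence classifier.
#
# Architecture: 1-D convolution over one-hot DNA (filters x filter_len),
# ReLU, global max pooling over positions, dense ReLU layer with inverted
# dropout, and a sigmoid (multi-label), softmax (one-of-k) or linear output
# head. Everything is dense matrix algebra on BLAS; all randomness is drawn
# from R's RNG so runs are reproducible from a seed. Gradients with respect
# to the input are available for attribution.
#
# Weight layout: Wc is (filter_len*4) x n_filters with rows ordered
# position-major, channel (A,C,G,T) fastest -- matching the im2col layout.

nn_flatten_onehot <- function(x) {
  # (n, L, 4) array -> (n, L*4) matrix, channel fastest within position
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == 4L)
  n <- dim(x)[1]
  matrix(aperm(x, c(1L, 3L, 2L)), nrow = n)
}

nn_im2col <- function(xm, filter_len) {
  b <- nrow(xm)
  l <- ncol(xm) / 4L
  w4 <- 4L * filter_len
  lout <- l - filter_len + 1L
  if (lout < 1L) stop("sequence shorter than the filter")
  colind <- as.vector(outer(seq_len(w4), (seq_len(lout) - 1L) * 4L, "+"))
  xw <- xm[, colind, drop = FALSE]
  dim(xw) <- c(b, w4, lout)
  xc <- aperm(xw, c(1L, 3L, 2L))
  dim(xc) <- c(b * lout, w4)
  list(xc = xc, b = b, l = l, lout = lout, w4 = w4)
}

nn_init <- function(input_len, n_classes, config, conv_init = NULL) {
  f <- config$n_filters
  w4 <- 4L * config$filter_len
  d <- config$dense_units
  init_mat <- function(nr, nc, scale) {
    matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)
  }
  weights <- withr::with_seed(config$seed, {
    wc <- if (is.null(conv_init)) init_mat(w4, f, sqrt(2 / w4)) else conv_init$wc
    bc <- if (is.null(conv_init)) rep(0, f) else conv_init$bc
    list(
      wc = wc, bc = bc,
      wh = init_mat(f, d, sqrt(2 / f)), bh = rep(0, d),
      wo = init_mat(d, n_classes, sqrt(1 / d)), bo = rep(0, n_classes)
    )
  })
  weights
}

nn_activate <- function(o, activation) {
  switch(activation,
    sigmoid = 1 / (1 + exp(-o)),
    softmax = {
      e <- exp(o - apply(o, 1L, max))
      e / rowSums(e)
    },
    linear = o,
    stop("unknown activation: ", activation)
  )
}

# index permutation turning a flattened one-hot into its reverse complement
# (position l -> L+1-l, channel c -> 5-c); it is an involution
nn_rc_index <- function(l) {
  pos <- rep(l:1, each = 4L)
  ch <- rep(4:1, times = l)
  (pos - 1L) * 4L + ch
}

# convolution + ReLU + global max pooling for one orientation
nn_conv_pool <- function(weights, xm, filter_len) {
  ic <- nn_im2col(xm, filter_len)
  z <- ic$xc %*% weights$wc
  z <- sweep(z, 2L, weights$bc, "+")
  a <- z
  a[a < 0] <- 0
  f <- ncol(z)
  b <- ic$b
  lout <- ic$lout
  dim(a) <- c(b, lout, f)
  am <- aperm(a, c(1L, 3L, 2L))
  dim(am) <- c(b * f, lout)
  amax_vec <- max.col(am, ties.method = "first")
  list(
    m = matrix(am[cbind(seq_len(b * f), amax_vec)], b, f),
    amax = matrix(amax_vec, b, f),
    xc = ic$xc, zpos = z > 0,
    b = b, lout = lout, l = ic$l, w4 = ic$w4, f = f
  )
}

# Forward pass. With rc = TRUE (the default architecture) the convolution and
# max pooling run on both the sequence and its reverse complement, and the
# pooled feature is the elementwise maximum over the two orientations, so a
# motif instance scores identically on either strand.
nn_forward <- function(weights, xm, filter_len, activation,
                       dropout_mask = NULL, keep_cache = FALSE, rc = TRUE) {
  cp1 <- nn_conv_pool(weights, xm, filter_len)
  if (rc) {
    rc_idx <- nn_rc_index(ncol(xm) / 4L)
    cp2 <- nn_conv_pool(weights, xm[, rc_idx, drop = FALSE], filter_len)
    orient <- cp2$m > cp1$m
    m <- cp1$m
    m[orient] <- cp2$m[orient]
  } else {
    cp2 <- NULL
    orient <- NULL
    m <- cp1$m
  }
  hpre <- sweep(m %*% weights$wh, 2L, weights$bh, "+")
  h <- hpre
  h[h < 0] <- 0
  if (!is.null(dropout_mask)) h <- h * dropout_mask
  o <- sweep(h %*% weights$wo, 2L, weights$bo, "+")
  p_out <- nn_activate(o, activation)
  if (!keep_cache) return(list(p = p_out, o = o))
  list(
    p = p_out, o = o,
    cache = list(
      cp1 = cp1, cp2 = cp2, orient = orient, m = m,
      hpos = hpre > 0, h = h, dropout_mask = dropout_mask, rc = rc
    )
  )
}

# scatter the pooled-feature gradient back through one orientation's
# convolution; returns conv-weight grads and (optionally) the input gradient
nn_conv_backward <- function(weights, cp, dm, want_input_grad) {
  b <- cp$b
  lout <- cp$lout
  f <- cp$f
  da <- numeric(b * lout * f)
  bidx <- rep(seq_len(b), f)
  fidx <- rep(seq_len(f) - 1L, each = b)
  idx <- bidx + (as.vector(cp$amax) - 1L) * b + fidx * b * lout
  da[idx] <- as.vector(dm)
  dim(da) <- c(b * lout, f)
  dz <- da * cp$zpos
  out <- list(wc = crossprod(cp$xc, dz), bc = colSums(dz))
  if (want_input_grad) {
    dxc <- dz %*% t(weights$wc)
    dim(dxc) <- c(b, lout, cp$w4)
    dxm <- matrix(0, b, cp$l * 4L)
    for (p in seq_len(lout)) {
      cols <- (p - 1L) * 4L + seq_len(cp$w4)
      dxm[, cols] <- dxm[, cols] + matrix(dxc[, p, ], b, cp$w4)
    }
    out$input <- dxm
  }
  out
}

# dO: gradient of the loss w.r.t. the pre-activation output (b x K)
nn_backward <- function(weights, fwd, d_o, want_input_grad = FALSE) {
  cache <- fwd$cache
  grads <- list()
  grads$wo <- crossprod(cache$h, d_o)
  grads$bo <- colSums(d_o)
  dh <- d_o %*% t(weights$wo)
  if (!is.null(cache$dropout_mask)) dh <- dh * cache$dropout_mask
  dhpre <- dh * cache$hpos
  grads$wh <- crossprod(cache$m, dhpre)
  grads$bh <- colSums(dhpre)
  dm <- dhpre %*% t(weights$wh)
  if (cache$rc) {
    dm1 <- dm
    dm1[cache$orient] <- 0
    dm2 <- dm
    dm2[!cache$orient] <- 0
    g1 <- nn_conv_backward(weights, cache$cp1, dm1, want_input_grad)
    g2 <- nn_conv_backward(weights, cache$cp2, dm2, want_input_grad)
    grads$wc <- g1$wc + g2$wc
    grads$bc <- g1$bc + g2$bc
    if (want_input_grad) {
      rc_idx <- nn_rc_index(cache$cp1$l)
      grads$input <- g1$input + g2$input[, rc_idx, drop = FALSE]
    }
  } else {
    g1 <- nn_conv_backward(weights, cache$cp1, dm, want_input_grad)
    grads$wc <- g1$wc
    grads$bc <- g1$bc
    if (want_input_grad) grads$input <- g1$input
  }
  grads
}

# loss value and output-gradient for one batch
nn_loss <- function(p, o, y, activation) {
  eps <- 1e-12
  b <- nrow(y)
  if (activation == "sigmoid") {
    loss <- -mean(rowSums(y * log(p + eps) + (1 - y) * log(1 - p + eps)))
    d_o <- (p - y) / b
  } else if (activation == "softmax") {
    loss <- -mean(log(rowSums(p * y) + eps))
    d_o <- (p - y) / b
  } else {
    loss <- mean(rowSums((p - y)^2))
    d_o <- 2 * (p - y) / b
  }
  list(loss = loss, d_o = d_o)
}

nn_adam_init <- function(weights) {
  list(
    m = lapply(weights, function(w) w * 0),
    v = lapply(weights, function(w) w * 0),
    t = 0L
  )
}

# lr: named vector of per-parameter learning rates (names of `weights`)
nn_adam_step <- function(weights, grads, state, lr,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    weights[[nm]] <- weights[[nm]] - lr[[nm]] * mhat / (sqrt(vhat) + eps)
  }
  list(weights = weights, state = state)
}

nn_predict_batched <- function(weights, xm, filter_len, activation,
                               batch_size = 256L, rc = TRUE) {
  n <- nrow(xm)
  out <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    p <- nn_forward(weights, xm[idx, , drop = FALSE], filter_len, activation,
                    rc = rc)$p
    if (is.null(out)) out <- matrix(0, n, ncol(p))
    out[idx, ] <- p
  }
  out
}

# Full training loop: internal validation split, Adam, early stopping on
# validation loss (accuracy as tiebreak), best-epoch weight restore.
nn_train <- function(xm, y, config, activation, conv_init = NULL,
                     init_weights = NULL, lr = NULL, val_idx = NULL) {
  n <- nrow(xm)
  k <- ncol(y)
  dimnames(y) <- NULL # keep weight containers free of label dimnames
  weights <- if (is.null(init_weights)) {
    nn_init(ncol(xm) / 4L, k, config, conv_init = conv_init)
  } else {
    init_weights
  }
  if (is.null(lr)) {
    lr <- stats::setNames(rep(config$lr_base, length(weights)), names(weights))
  }
  state <- nn_adam_init(weights)
  dropout <- config$dropout
  bs <- config$batch_size
  fixed <- !is.null(config$fixed_epochs)
  n_epochs <- if (fixed) config$fixed_epochs else config$max_epochs

  withr::with_seed(config$seed + 1L, {
    if (is.null(val_idx)) {
      val_n <- max(1L, round(config$validation_fraction * n))
      val_idx <- sample.int(n, val_n)
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(tr_idx) == 0L) stop("training split is empty")

    best <- list(loss = Inf, acc = -Inf, weights = weights, epoch = 0L)
    history <- vector("list", n_epochs)
    wait <- 0L
    for (epoch in seq_len(n_epochs)) {
      ord <- sample(tr_idx)
      tr_loss <- 0
      n_batches <- 0L
      for (start in seq(1L, length(ord), by = bs)) {
        idx <- ord[start:min(start + bs - 1L, length(ord))]
        mask <- NULL
        if (dropout > 0) {
          mask <- matrix(
            stats::rbinom(length(idx) * config$dense_units, 1L, 1 - dropout),
            length(idx), config$dense_units
          ) / (1 - dropout)
        }
        fwd <- nn_forward(weights, xm[idx, , drop = FALSE], config$filter_len,
                          activation, dropout_mask = mask, keep_cache = TRUE,
                          rc = config$rc_invariant)
        ls <- nn_loss(fwd$p, fwd$o, y[idx, , drop = FALSE], activation)
        grads <- nn_backward(weights, fwd, ls$d_o)
        upd <- nn_adam_step(weights, grads, state, lr)
        weights <- upd$weights
        state <- upd$state
        tr_loss <- tr_loss + ls$loss
        n_batches <- n_batches + 1L
      }
      val_p <- nn_predict_batched(weights, xm[val_idx, , drop = FALSE],
                                  config$filter_len, activation,
                                  rc = config$rc_invariant)
      val_y <- y[val_idx, , drop = FALSE]
      val_loss <- nn_loss(val_p, NULL, val_y, activation)$loss
      val_acc <- nn_accuracy(val_p, val_y, activation)
      val_aupr <- mean(vapply(seq_len(k), function(j) {
        if (all(val_y[, j] == 0) || all(val_y[, j] == 1)) return(NA_real_)
        average_precision(val_p[, j], val_y[, j])
      }, numeric(1)), na.rm = TRUE)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = tr_loss / n_batches,
        val_loss = val_loss, val_accuracy = val_acc, val_aupr = val_aupr
      )
      improved <- val_loss < best$loss - 1e-9 ||
        (abs(val_loss - best$loss) <= 1e-9 && val_acc > best$acc)
      if (improved) {
        best <- list(loss = val_loss, acc = val_acc, weights = weights,
                     epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (!fixed && wait >= config$early_stop_patience) break
      }
    }
  })
  final_weights <- if (fixed) weights else best$weights
  final_epoch <- if (fixed) n_epochs else best$epoch
  list(
    weights = final_weights,
    history = dplyr::bind_rows(history),
    best_epoch = final_epoch,
    val_loss = best$loss
  )
}

nn_accuracy <- function(p, y, activation) {
  if (activation == "sigmoid") {
    mean((p > 0.5) == (y > 0.5))
  } else {
    mean(max.col(p, ties.method = "first") == max.col(y, ties.method = "first"))
  }
}

# training with a caller-provided validation index (used by cross_validate)
nn_train_explicit_val <- function(xm, y, config, activation, val_idx,
                                  conv_init = NULL) {
  nn_train(xm, y, config, activation, conv_init = conv_init, val_idx = val_idx)
}
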