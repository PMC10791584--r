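# Shared fixtures: a desk-scale grammar/model cache so expensive training runs
# once per test session, plus independent oracles used across files.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# small grammar for unit tests: shorter sequences, same motif logic
tiny_grammar <- function() memo("tiny_grammar", make_default_grammar(1, length = 200L))

tiny_config <- function(seed = 3L, ...) {
  args <- list(
    n_filters = 24L, filter_len = 13L, dense_units = 24L, dropout = 0.2,
    max_epochs = 12L, early_stop_patience = 5L, batch_size = 32L, seed = seed
  )
  do.call(model_config, utils::modifyList(args, list(...)))
}

# one zonation model on the tiny grammar, shared by interpretation tests
tiny_zonation <- function() {
  memo("tiny_zonation", {
    g <- tiny_grammar()
    sim <- simulate_labeled_sequences(g, 150L, "zonation", seed = 11L)
    model <- train_base(sim$set, tiny_config(), pwms = g$motifs$pwm)
    list(grammar = g, sim = sim, model = model)
  })
}

# one topic-head base model on the tiny grammar, for transfer tests
tiny_topic_base <- function() {
  memo("tiny_topic_base", {
    g <- tiny_grammar()
    topic <- simulate_labeled_sequences(g, 150L, "topic", seed = 41L)
    train_base(topic$set, tiny_config(max_epochs = 16L, early_stop_patience = 16L),
               pwms = g$motifs$pwm)
  })
}

# a hand-built strictly linear scorer: one full-length positive filter, one
# dense unit, linear head, single orientation -- f(x) = sum(w * x) exactly
linear_surrogate <- function(l = 40L, seed = 5L) {
  withr::with_seed(seed, {
    w <- matrix(stats::runif(4L * l, 0.1, 1), 4L * l, 1L)
  })
  cfg <- model_config(
    n_filters = 1L, filter_len = l, dense_units = 1L, dropout = 0,
    max_epochs = 1L, rc_invariant = FALSE
  )
  weights <- list(
    wc = w, bc = 0,
    wh = matrix(1, 1L, 1L), bh = 0,
    wo = matrix(1, 1L, 1L), bo = 0
  )
  model <- zonereg:::new_sequence_model(
    weights, cfg, class_names = "score", input_length = l,
    output_mode = "linear",
    provenance = list(type = "base", id = "linear_surrogate"),
    history = tibble::tibble(), best_epoch = 1L, val_loss = NA_real_
  )
  list(model = model, w = w)
}

rand_dna <- function(n, l, seed = 1L) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
    }, character(1))
  })
}

# Mann-Whitney pair-counting AUROC (independent of the package implementation)
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  pairs <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(pairs)
}

# direct simulation of the stated iterative filter: repeatedly take the most
# significant remaining region, emit it, delete every region overlapping it
greedy_oracle <- function(df) {
  kept <- df[0, ]
  remaining <- df[order(-df$score, df$chrom, df$start), ]
  while (nrow(remaining) > 0) {
    top <- remaining[1, ]
    kept <- rbind(kept, top)
    overlaps <- remaining$chrom == top$chrom &
      remaining$start < top$end & remaining$end > top$start
    remaining <- remaining[!overlaps, ]
  }
  kept[order(kept$chrom, kept$start), ]
}

merge_oracle_one_set <- function(peaks, half_width) {
  pos <- peaks$start + peaks$summit
  greedy_oracle(data.frame(
    chrom = peaks$chrom,
    start = pmax(pos - half_width, 0),
    end = pos + half_width,
    name = peaks$name,
    score = peaks$score
  ))
}

merge_oracle <- function(peak_sets, half_width = 250) {
  pass1 <- lapply(peak_sets, merge_oracle_one_set, half_width = half_width)
  pooled <- do.call(rbind, lapply(pass1, function(p) {
    p$score <- p$score / sum(p$score) * 1e6
    p
  }))
  greedy_oracle(pooled)
}

expect_tibble_cols <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% names(x)))
}

# Full-scale models for the acceptance checks: default grammar (500 bp,
# 5 topics x 500 sequences), desk-scale network, shared across test blocks.
acc_config <- function(seed = 7L) {
  model_config(
    n_filters = 24L, filter_len = 12L, dense_units = 32L, dropout = 0.2,
    max_epochs = 24L, early_stop_patience = 6L, batch_size = 64L, seed = seed
  )
}

acc_fixture <- function() {
  memo("acc_fixture", {
    g <- make_default_grammar(1)
    cfg <- acc_config()
    topic <- simulate_labeled_sequences(g, 500L, "topic", seed = 101)
    ti <- withr::with_seed(7, sample(length(topic$set)))
    base <- train_base(topic$set[ti[1:2000]], cfg, pwms = g$motifs$pwm)

    zon <- simulate_labeled_sequences(g, 500L, "zonation", seed = 102)
    zi <- withr::with_seed(8, sample(length(zon$set)))
    zon_model <- train_transfer(base, zon$set[zi[1:1200]], cfg)

    act <- simulate_labeled_sequences(g, 500L, "activity", seed = 103)
    ai <- withr::with_seed(9, sample(length(act$set)))
    act_model <- train_transfer(base, act$set[ai[1:800]], cfg)

    list(
      grammar = g, config = cfg,
      topic = topic, ti = ti, base = base,
      zon = zon, zi = zi, zon_model = zon_model,
      act = act, ai = ai, act_model = act_model
    )
  })
}
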