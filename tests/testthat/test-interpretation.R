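test_that("attribution on a linear scorer matches the closed form exactly", {
  lin <- linear_surrogate(l = 30L)
  seqs <- rand_dna(12, 30L, seed = 8)
  x <- seqs[1]
  baselines <- seqs[-1]
  cm <- contribution_scores(lin$model, x, "score", baselines,
                            n_baseline = 11L, n_steps = 4L)
  # closed form: contribution = w * (x - mean(baselines)), summed per feature
  xoh <- zonereg:::nn_flatten_onehot(one_hot(x))
  boh <- zonereg:::nn_flatten_onehot(one_hot(baselines))
  want <- as.vector(lin$w) * (as.vector(xoh) - colMeans(boh))
  expect_equal(as.vector(t(cm$importance)), want, tolerance = 1e-9)
  # exact local accuracy for a linear model
  expect_lt(abs(cm$completeness_error), 1e-9)
  # the one-hot product zeroes all non-reference entries
  oh <- one_hot(x)[1, , ]
  expect_true(all(cm$map[oh == 0] == 0))
})

test_that("a constant model attributes nothing", {
  lin <- linear_surrogate(l = 20L)
  lin$model$weights$wo[] <- 0 # output head zeroed -> f is constant
  seqs <- rand_dna(6, 20L, seed = 9)
  cm <- contribution_scores(lin$model, seqs[1], "score", seqs[-1],
                            n_baseline = 5L, n_steps = 3L)
  expect_equal(max(abs(cm$importance)), 0)
  expect_error(contribution_scores(lin$model, seqs[1], "score", character(0)),
               "baseline set is empty")
})

test_that("attribution satisfies local accuracy on a trained network", {
  tz <- tiny_zonation()
  pc_ids <- tz$sim$set$labels[, "pericentral"] == 1
  seq_pc <- tz$sim$set$sequences[pc_ids][1]
  baselines <- tz$sim$set$sequences[seq(1, 450, by = 10)]
  cm <- contribution_scores(tz$model, seq_pc, "pericentral", baselines,
                            n_baseline = 30L, n_steps = 50L)
  gap <- cm$f_x - cm$f_baseline
  expect_gt(abs(gap), 0.05) # the explained prediction is non-trivial
  expect_lt(abs(cm$completeness_error), 0.05 * abs(gap))
})

test_that("saturation mutagenesis matches the linear closed form and zeroes refs", {
  lin <- linear_surrogate(l = 25L)
  s <- rand_dna(1, 25L, seed = 10)
  mm <- saturation_mutagenesis(lin$model, s, "score")
  w <- matrix(as.vector(lin$w), nrow = 4L) # 4 x L weights
  ref <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  for (i in seq_len(25)) {
    for (b in 1:4) {
      want <- w[b, i] - w[ref[i], i]
      expect_equal(mm$delta[i, b], want, tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  }
  expect_equal(mm$delta[cbind(seq_len(25), ref)], rep(0, 25))
})

test_that("the strongest zonation-destroying mutation falls in the planted repressor", {
  tz <- tiny_zonation()
  lab <- tz$sim$set$labels
  ids <- tz$sim$set$ids
  pick <- c(which(lab[, "pericentral"] == 1)[1:5],
            which(lab[, "periportal"] == 1)[1:5])
  hit <- vapply(pick, function(i) {
    cls <- if (lab[i, "pericentral"] == 1) "pericentral" else "periportal"
    motif <- if (cls == "pericentral") "Tcf7l1" else "Tbx3"
    mm <- saturation_mutagenesis(tz$model, tz$sim$set$sequences[i], cls)
    worst <- which(mm$delta == min(mm$delta), arr.ind = TRUE)[1, "row"]
    gt <- tz$sim$ground_truth
    iv <- gt[gt$seq_id == ids[i] & gt$motif == motif, ]
    any(worst - 1 >= iv$start & worst - 1 < iv$end)
  }, logical(1))
  expect_gte(mean(hit), 0.8)
})

test_that("mutagenesis and attribution agree on where importance lies", {
  # background positions carry near-zero independent noise in both maps, so
  # agreement is measured on the linear scale (signal positions dominate)
  tz <- tiny_zonation()
  lab <- tz$sim$set$labels
  idx <- which(lab[, "periportal"] == 1)[2:5]
  cors <- vapply(idx, function(i) {
    s <- tz$sim$set$sequences[i]
    mm <- saturation_mutagenesis(tz$model, s, "periportal")
    cm <- contribution_scores(tz$model, s, "periportal",
                              tz$sim$set$sequences[seq(5, 400, by = 13)],
                              n_baseline = 20L, n_steps = 20L)
    stats::cor(apply(abs(mm$delta), 1L, max), abs(rowSums(cm$map)))
  }, numeric(1))
  expect_gte(mean(cors), 0.5)
})

test_that("activation scanning finds planted consensus instances on both strands", {
  g <- tiny_grammar()
  pwm <- g$motifs$pwm[[match("Hnf1a", g$motifs$name)]]
  cons <- pwm_consensus(pwm)
  pf <- trim_by_ic(pwm, name = "Hnf1a", threshold = 15)
  bg <- rand_dna(1, 300, seed = 21)
  planted <- bg
  substr(planted, 101, 100 + nchar(cons)) <- cons
  hits <- scan_instances(planted, pf, mode = "activation")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 100L)
  expect_equal(hits$end, 100L + pf$width)
  expect_equal(hits$strand, "+")
  # reverse-complement planting reports the minus strand at the same locus
  planted_rc <- bg
  substr(planted_rc, 101, 100 + nchar(cons)) <- revcomp(cons)
  hits_rc <- scan_instances(planted_rc, pf, mode = "activation")
  expect_equal(hits_rc$start, 100L)
  expect_equal(hits_rc$strand, "-")
  # an infinite threshold yields no instances
  none <- scan_instances(planted, pf, mode = "activation",
                         thresholds = c(Hnf1a = Inf))
  expect_equal(nrow(none), 0L)
  # thresholds are mandatory configuration
  pf_na <- trim_by_ic(pwm, name = "Hnf1a")
  expect_error(scan_instances(planted, pf_na, mode = "activation"),
               "explicit configuration")
  expect_error(scan_instances(substr(planted, 1, 8), pf, "activation"),
               "longer than sequence")
})

test_that("scanning recovers planted instances with few false loci", {
  # operating point: wide patterns (>= 11 bp; shorter degenerate motifs carry
  # too little information for locus-level calling in a 500-bp background)
  # with a 2-mismatch score budget below the maximum attainable log-odds
  g <- make_default_grammar(1)
  sim <- simulate_labeled_sequences(g, 67L, "zonation", seed = 61) # ~200 seqs
  gt <- sim$ground_truth
  wide <- g$motifs$name[vapply(g$motifs$pwm, ncol, 1L) >= 11 &
                          g$motifs$name %in% unique(gt$motif)]
  gtw <- gt[gt$motif %in% wide, ]
  pats <- lapply(wide, function(nm) {
    pwm <- g$motifs$pwm[[match(nm, g$motifs$name)]]
    thr <- sum(apply(pwm_log_odds(pwm), 2, max)) - 12
    trim_by_ic(pwm, name = nm, threshold = thr)
  })
  hits <- scan_instances(sim$set, pats, mode = "activation")
  # recovery: a same-motif call starts within +/- 2 bp of the planted start
  found <- vapply(seq_len(nrow(gtw)), function(i) {
    h <- hits[hits$seq_id == gtw$seq_id[i] & hits$pattern == gtw$motif[i], ]
    any(abs(h$start - gtw$start[i]) <= 2)
  }, logical(1))
  expect_gte(mean(found), 0.9)
  # false loci: calls whose window overlaps no planted instance at all
  false_hit <- vapply(seq_len(nrow(hits)), function(i) {
    iv <- gt[gt$seq_id == hits$seq_id[i], ]
    !any(hits$start[i] < iv$end & hits$end[i] > iv$start)
  }, logical(1))
  expect_lte(mean(false_hit), 0.1)
})

test_that("contribution-mode scanning sums importance under the window", {
  g <- tiny_grammar()
  pwm <- g$motifs$pwm[[1]]
  pf <- trim_by_ic(pwm, name = "m", threshold = 2.5)
  map <- matrix(0, 60, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  seqchars <- strsplit(rand_dna(1, 60, seed = 3), "")[[1]]
  oh <- one_hot(paste(seqchars, collapse = ""))[1, , ]
  map[20:27, ] <- oh[20:27, ] * 0.5 # an 8-bp block of importance
  cmap <- structure(
    list(map = map, importance = map, class = "x", seq_id = "s1",
         sequence = paste(seqchars, collapse = "")),
    class = "contribution_map"
  )
  hits <- scan_instances(cmap, pf, mode = "contribution")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$sum_score, 8 * 0.5, tolerance = 1e-9)
  # the best window covers the important block
  expect_true(hits$start <= 19 && hits$end >= 27)
})

test_that("variant design edits minimally and flips scanner calls", {
  g <- tiny_grammar()
  pwm <- g$motifs$pwm[[match("Nfib", g$motifs$name)]]
  cons <- pwm_consensus(pwm)
  w <- nchar(cons)
  thr <- 0.72 * sum(apply(pwm_log_odds(pwm), 2, max))
  pf <- trim_by_ic(pwm, name = "Nfib", threshold = thr)
  bg <- rand_dna(1, 200, seed = 31)
  planted <- bg
  substr(planted, 51, 50 + w) <- cons
  # GOF on a locus already equal to consensus: zero edits
  gof <- design_variant(planted, pf, c(50, 50 + pf$width), mode = "GOF")
  expect_equal(nrow(gof$edits), 0L)
  expect_equal(gof$sequence, planted)
  # GOF on background creates the site; edit count <= pattern width
  gof2 <- design_variant(bg, pf, c(120, 120 + pf$width), mode = "GOF")
  expect_lte(nrow(gof2$edits), pf$width)
  expect_equal(nrow(scan_instances(gof2$sequence, pf, "activation")), 1L)
  # LOF kills the planted call with exactly k edits
  lof <- design_variant(planted, pf, c(50, 50 + pf$width), mode = "LOF", k = 3)
  expect_equal(nrow(lof$edits), 3L)
  before <- scan_instances(planted, pf, "activation")
  after <- scan_instances(lof$sequence, pf, "activation")
  expect_equal(nrow(before), 1L)
  expect_equal(nrow(after), 0L)
  expect_error(design_variant(planted, pf, c(50, 52), mode = "GOF"),
               "locus width")
})

test_that("destroying the planted periportal repressor de-represses pericentral", {
  tz <- tiny_zonation()
  lab <- tz$sim$set$labels
  gt <- tz$sim$ground_truth
  g <- tz$grammar
  pwm <- g$motifs$pwm[[match("Tbx3", g$motifs$name)]]
  pf <- trim_by_ic(pwm, name = "Tbx3", threshold = NA)
  pp_idx <- which(lab[, "periportal"] == 1)[1:8]
  delta <- vapply(pp_idx, function(i) {
    s <- tz$sim$set$sequences[i]
    iv <- gt[gt$seq_id == tz$sim$set$ids[i] & gt$motif == "Tbx3", ][1, ]
    # locate the trimmed pattern inside the planted full-width instance
    off <- pf$bounds[1] - 1L
    locus <- if (iv$strand == "+") {
      c(iv$start + off, iv$start + off + pf$width)
    } else {
      c(iv$end - off - pf$width, iv$end - off)
    }
    lof <- design_variant(s, pf, locus, mode = "LOF", k = 3,
                          strand = iv$strand)
    p0 <- predict(tz$model, s)[1, "pericentral"]
    p1 <- predict(tz$model, lof$sequence)[1, "pericentral"]
    p1 - p0
  }, numeric(1))
  # losing the periportal repressor site shifts mass toward pericentral
  expect_gt(mean(delta > 0), 0.5)
  expect_gt(mean(delta), 0)
})
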