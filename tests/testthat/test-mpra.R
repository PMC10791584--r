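test_that("barcode assignment applies the IUPAC template and uniqueness rule", {
  obs <- tibble::tibble(
    barcode = c(
      "AAATGAAACGAAATGAAA", # matches NNNYRNNNYRNNNYRNNN (Y at 4,9,14; R at 5,10,15)
      "AAAAAAAACGAAATGAAA", # position 4 = A, fails the Y slot
      "AAATGAAACGAAATGAAA"
    ),
    enhancer = c("e1", "e2", "e1")
  )
  out <- assign_barcodes(obs, pattern = "NNNYRNNNYRNNNYRNNN")
  expect_equal(nrow(out), 1L)
  expect_equal(out$reads, 2L)
  expect_true(out$unique)
  # a barcode seen with two enhancers is flagged non-unique
  multi <- tibble::tibble(
    barcode = c("AAAA", "AAAA", "CCCC"),
    enhancer = c("e1", "e2", "e3")
  )
  out2 <- assign_barcodes(multi)
  expect_equal(sort(out2$unique), c(FALSE, FALSE, TRUE))
  expect_equal(attr(out2, "unique_fraction"), 0.5)
  expect_error(assign_barcodes(obs[0, ]), "no barcode observations")
})

test_that("unique fraction matches enumeration on hand-written observations", {
  obs <- tibble::tibble(
    barcode = c("AA", "AA", "AA", "CC", "CC", "GG", "GG", "TT", "TA", "AT"),
    enhancer = c("e1", "e1", "e2", "e1", "e1", "e2", "e2", "e3", "e1", "e2")
  )
  out <- assign_barcodes(obs)
  # by hand: AA -> {e1, e2} (non-unique); CC -> e1; GG -> e2; TT -> e3;
  # TA -> e1; AT -> e2 => 5 of 6 barcodes unique
  expect_equal(attr(out, "unique_fraction"), 5 / 6)
  expect_equal(sum(!out$unique), 2L)
})

test_that("designed oligos have the expected anatomy", {
  enh <- strrep("A", 258)
  bc <- strrep("C", 12)
  oligo <- build_oligo(enh, bc)
  expect_equal(nchar(oligo), 300L)
  expect_true(startsWith(oligo, "CCAGTGCAAGTGCAG"))
  expect_true(endsWith(oligo, "GGCCTAACTGGCCGG"))
})

test_that("logFC is zero for identical roles and invariant to sample scaling", {
  counts <- matrix(
    rep(c(100L, 400L, 50L, 800L), 4), ncol = 4,
    dimnames = list(paste0("e", 1:4), c("p1", "p2", "c1", "c2"))
  )
  samples <- tibble::tibble(
    sample = colnames(counts),
    role = c("plasmid", "plasmid", "cdna", "cdna"),
    replicate = c(1, 2, 1, 2)
  )
  tab <- mpra_table(counts, samples)
  lfc <- compute_logfc(tab)
  expect_equal(lfc$logfc, rep(0, 4))
  # doubling every count of one cDNA sample is absorbed by its size factor
  counts2 <- counts
  counts2[, "c1"] <- counts2[, "c1"] * 2L
  lfc2 <- compute_logfc(mpra_table(counts2, samples))
  expect_equal(lfc2$logfc, lfc$logfc, tolerance = 1e-12)
})

test_that("logFC matches a hand-computed median-of-ratios result", {
  counts <- matrix(
    c(100, 200, 300, 400,   # p1
      110, 190, 310, 390,   # p2
      400, 220, 330, 440,   # c1
      420, 180, 290, 460),  # c2
    ncol = 4,
    dimnames = list(paste0("e", 1:4), c("p1", "p2", "c1", "c2"))
  )
  samples <- tibble::tibble(
    sample = colnames(counts),
    role = c("plasmid", "plasmid", "cdna", "cdna"),
    replicate = c(1, 2, 1, 2)
  )
  # independent arithmetic: geometric means, per-sample median ratios,
  # normalised counts, then mean log2 difference with the 0.5 pseudocount
  geo <- exp(rowMeans(log(counts)))
  sf <- apply(counts, 2, function(col) median(col / geo))
  norm <- sweep(counts, 2, sf, "/")
  want <- rowMeans(log2(norm[, 3:4] + 0.5)) - rowMeans(log2(norm[, 1:2] + 0.5))
  got <- compute_logfc(mpra_table(counts, samples))
  expect_equal(got$logfc, unname(want), tolerance = 1e-12)
  # all-zero sample is rejected
  bad <- counts
  bad[, 1] <- 0
  expect_error(compute_logfc(mpra_table(bad, samples)), "all-zero")
})

test_that("activity calls follow the Gaussian null with a strict alpha rule", {
  sim <- simulate_mpra_counts(c(rep(0, 300), rep(3, 20)), n_shuffled = 100,
                              seed = 5)
  lfc <- compute_logfc(sim$table)
  calls <- call_active(lfc, alpha = 0.1)
  expect_s3_class(calls, "activity_calls")
  # controls are excluded from BH and carry no call
  expect_true(all(is.na(calls$padj[calls$shuffled])))
  # p in (0, 1]; monotone: larger logFC never gives a larger p
  expect_true(all(calls$p > 0 & calls$p <= 1))
  ord <- order(calls$logfc)
  expect_true(all(diff(calls$p[ord]) <= 1e-12))
  # the call is exactly (padj < alpha), strict: padj == alpha is inactive
  keep <- !calls$shuffled
  expect_equal(calls$active[keep], calls$padj[keep] < 0.1)
  thr <- sort(calls$padj[keep])[5]
  calls_at <- call_active(lfc, alpha = thr)
  expect_false(calls_at$active[which(calls_at$padj == thr)[1]])
  # an enhancer at the shuffled median scores p = 0.5 and stays inactive
  lfc2 <- lfc
  lfc2$logfc[1] <- stats::median(lfc$logfc[lfc$shuffled])
  calls2 <- call_active(lfc2)
  expect_equal(unname(calls2$p[1]), 0.5, tolerance = 1e-12)
  expect_false(calls2$active[1])
  # degenerate nulls are rejected
  flat <- tibble::tibble(enhancer = paste0("s", 1:30), logfc = 0,
                         shuffled = TRUE)
  expect_error(call_active(flat), "MAD = 0")
  expect_error(call_active(lfc[1:10, ]), "at least 20 shuffled")
})

test_that("fraction comparison reports deltas over a shared universe", {
  a <- tibble::tibble(enhancer = c("e1", "e2"), logfc = c(2, 0),
                      shuffled = FALSE)
  b <- tibble::tibble(enhancer = c("e2", "e1"), logfc = c(1, 0.5),
                      shuffled = FALSE)
  cmp <- compare_fractions(a, b)
  expect_equal(cmp$delta_logfc[match(c("e1", "e2"), cmp$enhancer)],
               c(1.5, -1))
  expect_equal(compare_fractions(a, a)$delta_logfc, c(0, 0))
  expect_error(compare_fractions(a, b[1, ]), "different enhancer universes")
})

test_that("zone-fraction readout recovers the planted activity difference", {
  # pericentral-active enhancers: higher activity in the CD73 (pericentral)
  # fraction than the ECAD (periportal) fraction
  act_cd73 <- c(rep(2, 50), rep(0, 150))
  act_ecad <- c(rep(0.3, 50), rep(0, 150))
  cd73 <- simulate_mpra_counts(act_cd73, n_shuffled = 50, seed = 11)
  ecad <- simulate_mpra_counts(act_ecad, n_shuffled = 50, seed = 12)
  cmp <- compare_fractions(compute_logfc(cd73$table), compute_logfc(ecad$table))
  pc <- cmp$enhancer %in% sprintf("enh_%04d", 1:50)
  expect_gt(mean(cmp$delta_logfc[pc]), 0)
  expect_gt(mean(cmp$delta_logfc[pc]) - mean(cmp$delta_logfc[!pc]), 1)
})
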