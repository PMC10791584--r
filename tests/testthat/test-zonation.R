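test_that("pseudotime bins are rank-based, balanced and tie-stable", {
  b <- bin_pseudotime(stats::setNames(runif(100), paste0("c", 1:100)), 10)
  expect_equal(unname(table(b$bin)), rep(10L, 10), ignore_attr = TRUE)
  # monotone pseudotime 1..10 in 5 bins -> {1,2},{3,4},...
  b2 <- bin_pseudotime(stats::setNames(1:10, paste0("c", 1:10)), 5)
  expect_equal(b2$bin, rep(1:5, each = 2))
  # ties broken by stable input order, sizes still balanced
  b3 <- bin_pseudotime(stats::setNames(rep(1, 9), paste0("c", 1:9)), 3)
  expect_equal(b3$bin, rep(1:3, each = 3))
  expect_error(bin_pseudotime(c(a = 1, b = NA), 2), "missing")
  expect_error(bin_pseudotime(c(a = 1), 2), "more bins than cells")
})

make_real_cells <- function(n, type = "hepatocyte", n_bins = 10) {
  tibble::tibble(
    cell_id = sprintf("%s_%03d", type, seq_len(n)),
    cell_type = type,
    bin = rep_len(seq_len(n_bins), n)
  )
}

test_that("mapping matches bins exactly and balances multiplicities", {
  tpl <- simulate_lobule(400, c(hepatocyte = 1.0), seed = 3)
  real <- make_real_cells(800)
  asg <- map_cells(tpl, real, seed = 1)
  # bin audit: every virtual cell's bin equals its real cell's bin
  real_bins <- stats::setNames(real$bin, real$cell_id)
  expect_true(all(asg$bin == real_bins[asg$real_id]))
  # more real than virtual: injective within bin
  expect_false(any(duplicated(asg$real_id)))
  # more virtual than real: floor/ceiling multiplicities, counts conserved
  real_small <- make_real_cells(25)
  asg2 <- map_cells(tpl, real_small, seed = 2)
  for (b in unique(asg2$bin)) {
    m <- table(asg2$real_id[asg2$bin == b])
    v <- sum(asg2$bin == b)
    r <- sum(real_small$bin == b)
    expect_true(all(m %in% c(v %/% r, v %/% r + 1L)))
    expect_equal(sum(m), v) # count conservation
  }
  # 3 virtual vs 2 real in a bin: multiplicities {2, 1}
  tpl3 <- tpl[tpl$bin == 1, ][1:3, ]
  real2 <- make_real_cells(2, n_bins = 1)
  asg3 <- map_cells(tpl3, real2, seed = 3)
  expect_equal(as.integer(sort(table(asg3$real_id))), c(1L, 2L))
  # reproducible under a fixed seed
  expect_identical(map_cells(tpl, real, seed = 1), asg)
  expect_false(identical(map_cells(tpl, real, seed = 9)$real_id, asg$real_id))
})

test_that("non-zonated types ignore bins; missing (type, bin) pools error", {
  tpl <- simulate_lobule(
    300, c(hepatocyte = 0.8, central_vein = 0.1, portal_vein = 0.1), seed = 4
  )
  real <- dplyr::bind_rows(
    make_real_cells(500),
    tibble::tibble(cell_id = sprintf("cv_%02d", 1:20),
                   cell_type = "central_vein", bin = NA_integer_),
    tibble::tibble(cell_id = sprintf("pv_%02d", 1:20),
                   cell_type = "portal_vein", bin = NA_integer_)
  )
  asg <- map_cells(tpl, real, seed = 5)
  expect_equal(nrow(asg), 300L)
  cv <- asg[asg$cell_type == "central_vein", ]
  expect_true(all(grepl("^cv_", cv$real_id)))
  # a zonated bin with no real cells is an error
  real_gap <- make_real_cells(90, n_bins = 9) # bin 10 empty
  expect_error(map_cells(tpl[tpl$cell_type == "hepatocyte", ], real_gap, seed = 1),
               "bin 10")
  expect_error(map_cells(tpl, real[real$cell_type != "portal_vein", ], seed = 1),
               "portal_vein")
})

test_that("profiles transfer through the assignment by real id", {
  tpl <- simulate_lobule(50, c(hepatocyte = 1.0), seed = 6)
  real <- make_real_cells(100)
  asg <- map_cells(tpl, real, seed = 7)
  vals <- matrix(seq_len(200), ncol = 2,
                 dimnames = list(real$cell_id, c("g1", "g2")))
  out <- transfer_profiles(asg, vals)
  expect_equal(rownames(out), asg$virtual_id)
  expect_equal(out[3, ], vals[asg$real_id[3], ])
})

test_that("a zonated feature maps onto the lobule gradient; shuffling kills it", {
  tpl <- simulate_lobule(600, c(hepatocyte = 1.0), seed = 8)
  real <- make_real_cells(1000)
  # feature increases along the real pseudotime bin (the zone axis)
  withr::with_seed(9, {
    feature <- real$bin + stats::rnorm(nrow(real), 0, 0.5)
  })
  vals <- matrix(feature, ncol = 1, dimnames = list(real$cell_id, "zoned"))
  asg <- map_cells(tpl, real, seed = 10)
  mapped <- transfer_profiles(asg, vals)[tpl$virtual_id, ]
  expect_gte(abs(stats::cor(mapped, tpl$radial_dist)), 0.8)
  # destroy the bin structure: the spatial gradient disappears
  real_shuf <- real
  withr::with_seed(11, real_shuf$bin <- sample(real_shuf$bin))
  asg_s <- map_cells(tpl, real_shuf, seed = 10)
  mapped_s <- transfer_profiles(asg_s, vals)[tpl$virtual_id, ]
  expect_lt(abs(stats::cor(mapped_s, tpl$radial_dist)), 0.15)
})

test_that("spline zonation test detects gradients and stays calibrated", {
  n <- 500
  pt <- tibble::tibble(cell_id = paste0("c", 1:n), pseudotime = seq_len(n))
  x <- seq(0, 1, length.out = n)
  withr::with_seed(12, {
    strong <- t(vapply(1:50, function(i) 2 * x + stats::rnorm(n, 0, 1),
                       numeric(n))) # slope = 2 x noise SD
    null <- t(vapply(1:400, function(i) stats::rnorm(n), numeric(n)))
  })
  vals <- rbind(strong, null)
  rownames(vals) <- c(paste0("s", 1:50), paste0("n", 1:400))
  colnames(vals) <- pt$cell_id
  fit <- fit_zonation(vals, pt, df = 5, alpha = 0.01)
  strong_rows <- grepl("^s", fit$feature)
  expect_gte(mean(fit$significant[strong_rows]), 0.99)
  # type-I calibration on the null block: raw p roughly uniform, adjusted
  # significance rare
  null_p <- fit$p[!strong_rows]
  expect_lte(mean(null_p < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 400))
  expect_lte(mean(fit$significant[!strong_rows]), 0.01 + 2 * sqrt(0.01 * 0.99 / 400))
  # fitted curves track the gradient
  curve1 <- fit$curve[[1]]
  expect_gt(curve1[100] - curve1[1], 1)
})

test_that("zonation fitting is invariant to monotone pseudotime relabelling", {
  n <- 100
  pt1 <- tibble::tibble(cell_id = paste0("c", 1:n), pseudotime = seq_len(n))
  pt2 <- tibble::tibble(cell_id = paste0("c", 1:n),
                        pseudotime = exp(seq_len(n) / 20))
  withr::with_seed(13, {
    vals <- matrix(stats::rnorm(5 * n), nrow = 5,
                   dimnames = list(paste0("f", 1:5), pt1$cell_id))
  })
  f1 <- fit_zonation(vals, pt1)
  f2 <- fit_zonation(vals, pt2)
  expect_equal(f1$p, f2$p, tolerance = 1e-10)
})

test_that("degenerate features are flagged untestable", {
  n <- 40
  pt <- tibble::tibble(cell_id = paste0("c", 1:n), pseudotime = seq_len(n))
  vals <- rbind(flat = rep(1, n), ok = stats::rnorm(n))
  colnames(vals) <- pt$cell_id
  fit <- fit_zonation(vals, pt)
  expect_true(fit$untestable[1])
  expect_equal(fit$p[1], 1)
  expect_false(fit$significant[1])
  expect_error(fit_zonation(vals[, 1:10], pt[1:10, ]), "at least 20 cells")
})
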