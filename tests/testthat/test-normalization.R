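test_that("delta-Ct normalization has the defining housekeeping properties", {
  sim <- generate_ct_matrix(panel_truth(seed = 2))
  m <- detection_filter(sim$matrix)$matrix
  hk <- sim$truth$hkg_ids
  norm <- normalize_ct(m, hk)
  # per-sample mean housekeeping delta-Ct is zero by construction
  expect_equal(unname(colMeans(norm$delta_ct[hk, ])), rep(0, ncol(m$ct)),
               tolerance = 1e-9)
  # a single housekeeping assay normalizes itself to zero everywhere
  single <- normalize_ct(m, hk[1])
  expect_equal(unname(single$delta_ct[hk[1], ]), rep(0, ncol(m$ct)),
               tolerance = 1e-12)
  # linear relative quantities are exactly 2^-delta
  expect_equal(norm$rel_quantity, 2^-norm$delta_ct, tolerance = 1e-12)
  expect_true(all(norm$rel_quantity[!is.na(norm$rel_quantity)] > 0))
})

test_that("adding a constant to one sample leaves its delta-Ct unchanged", {
  ct <- matrix(c(20, 24, 28, 21, 25, 29, 19, 23, 27, 20, 24, 28), 3, 4,
               dimnames = list(c("h1", "h2", "t1"), sprintf("s%d", 1:4)))
  m <- make_ct(ct)
  base <- normalize_ct(m, c("h1", "h2"))
  m$ct[, 2] <- m$ct[, 2] + 1
  shifted <- normalize_ct(m, c("h1", "h2"))
  expect_equal(shifted$delta_ct, base$delta_ct, tolerance = 1e-12)
})

test_that("fold changes follow the delta-delta-Ct arithmetic and orientation", {
  # test group 1 cycle lower on average than reference -> fold change 2
  ct <- rbind(h = rep(25, 6), t = c(26, 26, 26, 25, 25, 25))
  m <- make_ct(ct)
  fc <- fold_change(normalize_ct(m, "h"), toy_design(m))
  expect_equal(fc$fc[fc$assay_id == "t"], 2)
  expect_equal(fc$fc[fc$assay_id == "h"], 1)
  # worked delta-delta-Ct: mean ref 5.000, mean test 5.455 -> 2^-0.455
  ct2 <- rbind(h = rep(20, 6), t = 20 + c(5, 5, 5, 5.455, 5.455, 5.455))
  m2 <- make_ct(ct2)
  fc2 <- fold_change(normalize_ct(m2, "h"), toy_design(m2))
  expect_equal(fc2$fc[fc2$assay_id == "t"], 2^-0.455, tolerance = 1e-9)
  expect_equal(fc2$fc[fc2$assay_id == "t"], 0.7295106, tolerance = 1e-6)
})

test_that("swapping the contrast inverts fold changes exactly", {
  sim <- generate_ct_matrix(panel_truth(seed = 6))
  m <- detection_filter(sim$matrix)$matrix
  norm <- normalize_ct(m, sim$truth$hkg_ids)
  conds <- sim$truth$design$conditions
  f1 <- fold_change(norm, group_design(m, conds))
  f2 <- fold_change(norm, group_design(m, rev(conds)))
  expect_equal(f1$fc * f2$fc, rep(1, nrow(f1)), tolerance = 1e-12)
})

test_that("designed fold changes are recovered without bias", {
  truth <- panel_truth(seed = 30)
  target <- names(truth$de_spec)
  est <- matrix(NA_real_, 200, length(target))
  for (r in 1:200) {
    sim <- generate_ct_matrix(truth, seed = 3000 + r)
    norm <- normalize_ct(sim$matrix, truth$hkg_ids)
    fc <- fold_change(norm, group_design(sim$matrix, truth$design$conditions))
    est[r, ] <- fc$log2fc[match(target, fc$assay_id)]
  }
  mean_est <- colMeans(est)
  se <- apply(est, 2, sd) / sqrt(nrow(est))
  z <- abs(mean_est - log2(truth$de_spec)) / se
  # per-assay 2-SE criterion, familywise-adjusted across the 15 assays
  expect_true(all(z < qnorm(1 - 0.025 / length(z))))
})

test_that("pooling averages linear quantities, not Ct values", {
  ct <- rbind(a = c(20, 21, 25), b = c(30, 30, 30))
  m <- make_ct(ct, conditions = c("ctrl", "ctrl", "ko"))
  pooled <- pool_samples(m, c("s01", "s02"), "pool1", condition = "ctrl")
  expect_equal(unname(pooled$ct["a", "pool1"]),
               -log2((2^-20 + 2^-21) / 2), tolerance = 1e-12)
  expect_equal(unname(pooled$ct["a", "pool1"]), 20.41504, tolerance = 1e-5)
  # identical members pool to themselves; order of members is irrelevant
  same <- pool_samples(m, c("s02", "s01"), "pool2", condition = "ctrl")
  expect_equal(same$ct[, "pool2"], pooled$ct[, "pool1"], tolerance = 1e-12)
  expect_equal(unname(pooled$ct["b", "pool1"]), 30, tolerance = 1e-12)
  expect_identical(pooled$meta$pooled[pooled$meta$sample_id == "pool1"], 1L)
  expect_error(pool_samples(m, c("s01", "nope"), "p"), "missing")
  expect_error(pool_samples(m, "s01", "p"), ">= 2")
})

test_that("normalize-then-pool agrees with pool-then-normalize on stable panels", {
  set.seed(77)
  hk <- matrix(25 + rnorm(40, 0, 0.02), 10, 4)
  tg <- matrix(28 + rnorm(8, 0, 0.02), 2, 4)
  ct <- rbind(hk, tg)
  rownames(ct) <- c(sprintf("h%d", 1:10), "t1", "t2")
  m <- make_ct(ct)
  hkids <- sprintf("h%d", 1:10)
  # path A: pool raw samples, then normalize
  a <- normalize_ct(pool_samples(m, c("s01", "s02"), "pool", condition = "ctrl"),
                    hkids)$delta_ct[, "pool"]
  # path B: normalize, then pool linear normalized quantities
  normed <- normalize_ct(m, hkids)
  b <- -log2(rowMeans(2^-normed$delta_ct[, c("s01", "s02")]))
  expect_lt(max(abs(a - b)), 0.05)
})

test_that("precision summaries match hand-computed dispersion", {
  # two assays with designed deviations of 10% and 30%
  lv <- rbind(c(90, 110), c(70, 130))
  pm <- c(100, 100)
  dev_expected <- c(100 * sd(c(90, 110)) / 100, 100 * sd(c(70, 130)) / 100)
  ps <- precision_summary(lv, pm)
  expect_equal(unname(ps$per_assay_deviation), dev_expected)
  expect_equal(ps$median, mean(dev_expected))
  # all replicates equal to the pooled mean: zero dispersion
  ps0 <- precision_summary(rbind(c(5, 5, 5), c(2, 2, 2)), c(5, 2))
  expect_equal(ps0$median, 0)
  expect_equal(ps0$iqr, c(0, 0))
  # five-assay spreadsheet-style check, both deviation definitions
  set.seed(8)
  lv5 <- matrix(rlnorm(20, 0, 0.3), 5, 4)
  pm5 <- rowMeans(lv5) * runif(5, 0.9, 1.1)
  ps5 <- precision_summary(lv5, pm5)
  dev5 <- sapply(1:5, function(i) 100 * sd(lv5[i, ]) / pm5[i])
  expect_equal(unname(ps5$per_assay_deviation), dev5)
  expect_equal(ps5$median, median(dev5))
  expect_equal(ps5$iqr, unname(quantile(dev5, c(.25, .75))))
  psm <- precision_summary(lv5, pm5, method = "mad_pct")
  devm <- sapply(1:5, function(i) 100 * mean(abs(lv5[i, ] - pm5[i])) / pm5[i])
  expect_equal(unname(psm$per_assay_deviation), devm)
  # incomplete assays are excluded from the summary
  lvna <- lv5; lvna[2, 3] <- NA
  psna <- precision_summary(lvna, pm5)
  expect_true(is.na(psna$per_assay_deviation[2]))
  expect_identical(psna$n_assays, 4L)
  expect_error(precision_summary(lv5, c(0, pm5[-1])), "non-zero")
})
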