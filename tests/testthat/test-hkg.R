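test_that("exact Mann-Whitney p-values match full enumeration", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_identical(res$U, 0)
  expect_equal(res$p, 0.1)  # 2 * 1/20 assignments
  # identical multisets are maximally compatible with the null
  expect_equal(mann_whitney_u(c(5, 5, 7), c(5, 5, 7))$p, 1)
  # random data, with and without ties, against the independent oracle
  set.seed(101)
  for (i in 1:25) {
    x <- sample(1:8, 4, replace = TRUE)
    y <- sample(1:8, 5, replace = TRUE)
    got <- mann_whitney_u(x, y, mode = "exact")
    want <- oracle_mwu(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(1, c(2, 3)), "at least 2")
})

test_that("normal approximation tracks the exact test closely at 6 vs 6", {
  set.seed(202)
  dmax <- 0
  for (i in 1:200) {
    x <- rnorm(6); y <- rnorm(6, sample(c(0, 1), 1))
    pe <- mann_whitney_u(x, y, mode = "exact")$p
    pa <- mann_whitney_u(x, y, mode = "approx")$p
    dmax <- max(dmax, abs(pe - pa))
  }
  expect_lt(dmax, 0.02)
  # tie correction keeps the approximation sane under heavy ties
  x <- c(1, 1, 2, 2, 3, 3); y <- c(1, 2, 2, 3, 3, 3)
  expect_gt(mann_whitney_u(x, y, mode = "approx")$p, 0.3)
})

test_that("the mean-Ct reference equals the geometric mean of linear quantities", {
  m <- make_ct(matrix(c(20, 22, 20, 22, 24, 26), 2, 3,
                      dimnames = list(c("h1", "h2"), c("a", "b", "c"))),
               conditions = c("ctrl", "ctrl", "ko"))
  expect_equal(unname(geometric_mean_reference(m, c("h1", "h2"))[1]), 21)
  # single housekeeping assay: the reference is its own profile
  expect_equal(geometric_mean_reference(m, "h1"), m$ct["h1", ])
  # identity 2^-mean(Ct) = geomean(2^-Ct)
  set.seed(3)
  ct <- matrix(runif(40, 18, 32), 8, 5,
               dimnames = list(sprintf("h%d", 1:8), sprintf("s%d", 1:5)))
  ref <- geometric_mean_reference(make_ct(ct, rep(c("ctrl", "ko"), c(3, 2))),
                                  rownames(ct))
  geo <- apply(2^-ct, 2, function(v) exp(mean(log(v))))
  expect_equal(2^-ref, geo, tolerance = 1e-12)
  # undetected housekeeping wells are an error
  m$ct[1, 2] <- NA; m$status[1, 2] <- "undetermined"
  expect_error(geometric_mean_reference(m, c("h1", "h2")), "not detected")
})

test_that("housekeeping screen matches a brute-force oracle on the toy panel", {
  m <- make_toy_hkg_panel()
  des <- toy_design(m)
  sel <- select_hkgs(m, des)
  want <- oracle_hkg(m$ct, ref_cols = 1:3, tst_cols = 4:6)
  expect_same_set(sel$selected, want)
  # the frozen toy panel is designed so exactly the constant assays survive
  expect_same_set(sel$selected, sprintf("const%d", 1:4))
  # diagnostics cover every assay with the four pass flags
  expect_identical(nrow(sel$diagnostics), 10L)
  expect_true(all(sel$diagnostics$pass_iv[sel$diagnostics$assay_id %in% sel$selected]))
  # group-shifted assays fall at the stability criterion
  d <- sel$diagnostics
  expect_true(all(d$mwu_p[grepl("shift", d$assay_id)] <= 0.1))
})

test_that("identical constant profiles are all selected in one round", {
  m <- make_ct(matrix(25, 5, 6))
  sel <- select_hkgs(m, toy_design(m))
  expect_same_set(sel$selected, rownames(m$ct))
  expect_identical(sel$iterations, 1L)
  expect_equal(unname(sel$reference_profile), rep(25, 6))
})

test_that("median Ct at or above the expression threshold fails criterion (i)", {
  ct <- rbind(matrix(25, 4, 6), matrix(31, 1, 6))
  rownames(ct) <- c(sprintf("ok%d", 1:4), "dim1")
  m <- make_ct(ct)
  sel <- select_hkgs(m, toy_design(m))
  expect_false("dim1" %in% sel$selected)
  expect_false(sel$diagnostics$pass_i[sel$diagnostics$assay_id == "dim1"])
})

test_that("selection is invariant to assay and sample reordering", {
  sim <- generate_ct_matrix(panel_truth(seed = 9))
  m <- detection_filter(sim$matrix)$matrix
  des <- group_design(m, sim$truth$design$conditions)
  sel1 <- select_hkgs(m, des)
  set.seed(1)
  pr <- sample(nrow(m$ct)); pc <- sample(ncol(m$ct))
  m2 <- ct_matrix(m$ct[pr, pc], m$meta[pc, ], m$status[pr, pc])
  sel2 <- select_hkgs(m2, des)
  expect_same_set(sel1$selected, sel2$selected)
  expect_identical(sel1$iterations, sel2$iterations)
})

test_that("a constant Ct shift changes no selection decision", {
  # all criteria except the absolute expression level are scale-free, so a
  # shift that keeps medians on the same side of the threshold must leave
  # the selection unchanged
  sim <- generate_ct_matrix(panel_truth(seed = 13))
  m <- detection_filter(sim$matrix)$matrix
  des <- group_design(m, sim$truth$design$conditions)
  sel1 <- select_hkgs(m, des)
  m2 <- m
  m2$ct <- m$ct + 1
  m2$ct[m2$ct > 40] <- 40
  sel2 <- select_hkgs(m2, des, hkg_criteria(median_ct_max = 31))
  expect_same_set(sel1$selected, sel2$selected)
})

test_that("criterion cascade failures name the first emptying criterion", {
  dim_panel <- make_ct(matrix(35, 3, 6))
  expect_error(select_hkgs(dim_panel, toy_design(dim_panel)), "criterion \\(i\\)")
  # strong group shift on every assay empties criterion (ii)
  shifted <- make_ct(matrix(rep(c(22, 26), each = 3), 3, 6, byrow = TRUE))
  expect_error(select_hkgs(shifted, toy_design(shifted)), "criterion \\(ii\\)")
})

test_that("leave-self-out correlation mode is exposed and consistent", {
  sim <- generate_ct_matrix(panel_truth(seed = 21))
  m <- detection_filter(sim$matrix)$matrix
  des <- group_design(m, sim$truth$design$conditions)
  sel_in <- select_hkgs(m, des)
  sel_out <- select_hkgs(m, des, correlation = "leave_self_out")
  # designed stable assays dominate both selections
  expect_gt(mean(sel_out$selected %in% sim$truth$hkg_ids), 0.9)
  expect_gt(length(intersect(sel_in$selected, sel_out$selected)), 30)
})

test_that("overlap percentages support the three denominators", {
  a <- sprintf("m%02d", 1:48)
  b <- sprintf("m%02d", 7:48)  # 42 assays, all within a
  expect_equal(as.numeric(hkg_overlap(a, a)), 100)
  expect_equal(as.numeric(hkg_overlap(a, sprintf("x%d", 1:5))), 0)
  expect_equal(as.numeric(hkg_overlap(a, b)), 100 * 42 / 48)  # union
  expect_equal(as.numeric(hkg_overlap(a, b, "smaller")), 100)
  expect_equal(as.numeric(hkg_overlap(b, a, "reference")), 100)
  expect_error(hkg_overlap(character(), character()), "empty")
})
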