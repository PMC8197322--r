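sim_dct <- function(m = 50, n1 = 3, n2 = 3, seed = 1, effect_sd = 0.3,
                    var_shape = 4) {
  # delta-Ct matrix with heterogeneous per-assay variances (inverse-chisq-ish)
  set.seed(seed)
  sds <- sqrt(var_shape * 0.04 / rchisq(m, var_shape))
  eff <- rnorm(m, 0, effect_sd)
  dct <- cbind(matrix(rnorm(m * n1, 0, sds), m, n1),
               matrix(rnorm(m * n2, eff, sds), m, n2))
  dimnames(dct) <- list(sprintf("a%02d", 1:m),
                        sprintf("s%d", 1:(n1 + n2)))
  dct
}
des_33 <- function(dct) group_design(
  stats::setNames(rep(c("ctrl", "ko"), each = 3), colnames(dct)), c("ctrl", "ko"))

test_that("moderated-t moment estimates match an independent implementation", {
  for (seed in c(1, 2, 3)) {
    dct <- sim_dct(seed = seed)
    fit <- fit_ebayes(dct, des_33(dct))
    want <- oracle_ebayes(dct, 1:3, 4:6)
    expect_equal(fit$params$d0, want$d0, tolerance = 1e-6)
    expect_equal(fit$params$s0_sq, want$s0_sq, tolerance = 1e-6)
    expect_equal(fit$table$t_mod, want$t_mod, tolerance = 1e-6)
    expect_equal(fit$table$p, want$p, tolerance = 1e-6)
  }
})

test_that("moderated-t agrees with the reference Bioconductor implementation", {
  skip_if_not_installed("limma")
  dct <- sim_dct(seed = 11)
  fit <- fit_ebayes(dct, des_33(dct))
  design <- cbind(1, rep(c(0, 1), each = 3))
  lf <- limma::eBayes(limma::lmFit(dct, design))
  expect_equal(fit$params$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(fit$params$s0_sq, lf$s2.prior, tolerance = 1e-6)
  # limma's coefficient is test minus reference; ours is reference minus test
  expect_equal(fit$table$t_mod, -unname(lf$t[, 2]), tolerance = 1e-6)
  expect_equal(fit$table$p, unname(lf$p.value[, 2]), tolerance = 1e-6)
})

test_that("shrinkage limits recover the ordinary t and the pooled z", {
  dct <- sim_dct(seed = 4)
  des <- des_33(dct)
  # d0 = 0: ordinary two-sample pooled t for every assay
  off <- fit_ebayes(dct, des, d0 = 0)
  plain_t <- apply(dct, 1, function(v)
    unname(t.test(v[1:3], v[4:6], var.equal = TRUE)$statistic))
  expect_equal(off$table$t_mod, unname(plain_t), tolerance = 1e-9)
  expect_equal(off$table$df_total, rep(4, nrow(dct)))
  # d0 = Inf: every posterior variance equals the prior variance
  full <- fit_ebayes(dct, des, d0 = Inf)
  expect_equal(full$table$s_tilde_sq, rep(full$params$s0_sq, nrow(dct)))
  # identical residual variances are a fixed point of shrinkage
  flat <- rbind(c(0, 1, -1, 2, 3, 1), c(1, 2, 0, 0, 1, -1)) / 2
  flat <- flat[c(1, 2, 1, 2, 1, 2), ] + 5  # repeated rows: equal sg_sq
  colnames(flat) <- sprintf("s%d", 1:6); rownames(flat) <- sprintf("a%d", 1:6)
  ffit <- fit_ebayes(flat, des_33(flat))
  expect_true(is.infinite(ffit$params$d0))
  expect_equal(ffit$table$s_tilde_sq, rep(ffit$params$s0_sq, 6), tolerance = 1e-9)
})

test_that("Storey q-values reproduce the worked example and the definition", {
  st <- storey_qvalues(c(0.01, 0.2, 0.8, 0.9), lambda = 0.5)
  expect_equal(st$pi0, 1)
  expect_equal(st$q, c(0.04, 0.4, 0.9, 0.9))
  # all p = 1: pi0 caps at 1 and all q = 1
  st1 <- storey_qvalues(rep(1, 5))
  expect_equal(st1$pi0, 1)
  expect_equal(st1$q, rep(1, 5))
  # random vectors against the thresholding-definition oracle
  set.seed(19)
  for (i in 1:20) {
    p <- runif(40)^sample(1:3, 1)
    got <- storey_qvalues(p)
    want <- oracle_storey(p)
    expect_equal(got$pi0, want$pi0, tolerance = 1e-12)
    expect_equal(got$q, want$q, tolerance = 1e-12)
  }
  expect_error(storey_qvalues(numeric()), "empty")
  expect_error(storey_qvalues(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("q-values reduce to Benjamini-Hochberg when pi0 is fixed at 1", {
  set.seed(23)
  for (i in 1:20) {
    p <- runif(60)^2
    q <- storey_qvalues(p, pi0 = 1)$q
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("q-values are monotone in p and ties share a q-value", {
  set.seed(29)
  p <- pmax(round(runif(50), 2), 0.01)  # rounding forces ties
  q <- storey_qvalues(p)$q
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  for (pv in unique(p[duplicated(p)]))
    expect_equal(diff(range(q[p == pv])), 0)
})

test_that("differential expression composes the stack and partitions directions", {
  sim <- generate_ct_matrix(panel_truth(seed = 3))
  m <- detection_filter(sim$matrix)$matrix
  norm <- normalize_ct(m, sim$truth$hkg_ids)
  des <- group_design(m, sim$truth$design$conditions)
  de <- differential_expression(norm, des, fdr_level = 0.10)
  expect_s3_class(de, "diffexpr_table")
  expect_true(all(de$significant == (de$q <= 0.10)))
  expect_true(all(de$direction[de$significant & de$fc > 1] == "increased"))
  truth_up <- names(sim$truth$de_spec)[sim$truth$de_spec > 1]
  truth_dn <- names(sim$truth$de_spec)[sim$truth$de_spec < 1]
  expect_true(all(de$significant[match(truth_up, de$assay_id)]))
  expect_true(all(de$direction[match(truth_up, de$assay_id)] == "increased"))
  expect_true(all(de$direction[match(truth_dn, de$assay_id)] == "decreased"))
  # q is monotone when sorted by p (table is returned p-sorted)
  expect_true(all(diff(de$q) >= -1e-12))
})

test_that("a single-assay table degenerates to q = min(p * pi0, 1)", {
  dct <- matrix(c(5.1, 5.0, 4.9, 5.4, 5.6, 5.5), 1, 6,
                dimnames = list("only", sprintf("s%d", 1:6)))
  dct <- rbind(only = dct[1, ])
  norm <- structure(list(delta_ct = dct, rel_quantity = 2^-dct,
                         reference_profile = rep(0, 6), hkgs = character(),
                         meta = data.frame(sample_id = colnames(dct),
                                           condition = rep(c("ctrl", "ko"), each = 3))),
                    class = "normalized_expression")
  de <- differential_expression(norm, des_33(dct))
  p <- de$p[1]
  pi0 <- min(1, (p > 0.5) / 0.5)
  if (pi0 == 0) pi0 <- 1  # degenerate single-p estimate floors at 1/m
  expect_equal(de$q[1], min(1, max(p * pi0, p / length(p))))
})

test_that("zero residual degrees of freedom and zero variances are refused", {
  dct <- matrix(rnorm(8), 2, 4, dimnames = list(c("a", "b"), sprintf("s%d", 1:4)))
  cond <- stats::setNames(c("ctrl", "ctrl", "ko", "ko"), colnames(dct))
  expect_error(group_design(stats::setNames(c("ctrl", "ko", "ko", "ko"),
                                            colnames(dct)), c("ctrl", "ko")),
               ">= 2")
  flatrow <- rbind(a = c(1, 1, 1, 2, 2, 2), b = c(1, 2, 1, 2, 1, 2))
  colnames(flatrow) <- sprintf("s%d", 1:6)
  expect_error(fit_ebayes(flatrow, des_33(flatrow)), "zero residual variance")
})
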