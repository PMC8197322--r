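# Small in-code fixtures shared across test files.

# Wrap a plain numeric matrix into a ct_matrix with a two-condition design.
make_ct <- function(ct, conditions = NULL) {
  if (is.null(colnames(ct)))
    colnames(ct) <- sprintf("s%02d", seq_len(ncol(ct)))
  if (is.null(rownames(ct)))
    rownames(ct) <- sprintf("miR-t%02d", seq_len(nrow(ct)))
  if (is.null(conditions))
    conditions <- rep(c("ctrl", "ko"), each = ncol(ct) / 2)
  ct_matrix(ct, data.frame(sample_id = colnames(ct), condition = conditions,
                           stringsAsFactors = FALSE))
}

# 10-assay toy panel for the housekeeping screen: 4 constant assays,
# 2 group-shifted assays, 4 high-noise assays; seed frozen so that the
# brute-force oracle yields exactly the 4 constant assays.
make_toy_hkg_panel <- function(seed = 42) {
  set.seed(seed)
  n <- 6
  ct <- rbind(
    matrix(25, 4, n),
    matrix(24 + rep(c(0, 2), each = 3), 2, n, byrow = TRUE),
    matrix(rnorm(4 * n, 25, 3), 4, n))
  ct[ct > 39] <- 39; ct[ct < 10] <- 10  # keep inside the Ct validity range
  rownames(ct) <- c(sprintf("const%d", 1:4), sprintf("shift%d", 1:2),
                    sprintf("noisy%d", 1:4))
  make_ct(ct)
}

toy_design <- function(m) group_design(m, c("ctrl", "ko"))

expect_same_set <- function(a, b) expect_setequal(a, b)
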