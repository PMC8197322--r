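#' Thresholds for housekeeping-miRNA selection
#'
#' Bundles the tunable thresholds of the modified Bianchi reference-gene
#' screen implemented by [select_hkgs()]:
#' \describe{
#'   \item{median_ct_max}{criterion (i): candidates must be expressed at high
#'     level, median Ct strictly below this many cycles (default 30).}
#'   \item{stability_p_min}{criterion (ii): two-sided Mann-Whitney p between
#'     the contrast groups must be strictly greater than this (default 0.1).}
#'   \item{cv_sd_multiplier}{criterion (iii): a candidate's coefficient of
#'     variation (on the linear 2^-Ct scale) must be below
#'     mean(CV) + multiplier * SD(CV) computed over the criterion-(i)
#'     survivors (default 2).}
#'   \item{outlier_fold}{criterion (iii): every sample's linear level must lie
#'     within this fold of the assay's mean level (default 5).}
#'   \item{r_min}{criterion (iv): Pearson correlation with the geometric-mean
#'     reference must be strictly greater than this (default 0.7).}
#' }
#'
#' @param median_ct_max Cycles; strictly positive.
#' @param stability_p_min Probability in (0, 1).
#' @param cv_sd_multiplier Dimensionless, strictly positive.
#' @param outlier_fold Dimensionless, strictly positive.
#' @param r_min Correlation in (0, 1).
#' @return An object of class `hkg_criteria`.
#' @export
hkg_criteria <- function(median_ct_max = 30, stability_p_min = 0.1,
                         cv_sd_multiplier = 2, outlier_fold = 5, r_min = 0.7) {
  stopifnot(median_ct_max > 0, cv_sd_multiplier > 0, outlier_fold > 0,
            stability_p_min > 0, stability_p_min < 1, r_min > 0, r_min < 1)
  structure(list(median_ct_max = median_ct_max,
                 stability_p_min = stability_p_min,
                 cv_sd_multiplier = cv_sd_multiplier,
                 outlier_fold = outlier_fold,
                 r_min = r_min),
            class = "hkg_criteria")
}

#' Mann-Whitney U test (exact permutation or tie-corrected normal)
#'
#' Two-sided Mann-Whitney U test.  In `"exact"` mode the p-value is computed
#' by full enumeration of all \eqn{\binom{n_1+n_2}{n_1}} group assignments of
#' the observed (midranked) data, which handles ties by construction; in
#' `"approx"` mode the normal approximation with tie correction and
#' continuity correction is used.  `"auto"` (default) enumerates exactly when
#' \eqn{n_1+n_2 \le 12} and approximates otherwise.
#'
#' U is the number of (x, y) pairs with x > y, counting ties as 1/2, i.e.
#' \eqn{U = R_1 - n_1(n_1+1)/2} with midranks.  The two-sided p-value is
#' \eqn{\min(1,\; 2\min(P(U \le u), P(U \ge u)))}.
#'
#' @param x,y Numeric vectors, at least 2 values each.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return A list with elements `U` (statistic) and `p` (two-sided p in
#'   (0, 1]), plus the `mode` actually used.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 values per group")
  if (anyNA(x) || anyNA(y)) stop("missing values in input")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (mode == "auto") mode <- if (N <= 12L) "exact" else "approx"
  if (mode == "exact") {
    sets <- utils::combn(N, n1)
    us <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps))
  } else {
    mu <- n1 * n2 / 2
    tie <- table(r)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sig2)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  list(U = u_obs, p = min(1, p), mode = mode)
}

#' Per-sample reference profile from a housekeeping set
#'
#' The reference value of a sample is the arithmetic mean of the Ct values
#' of the housekeeping assays in that sample.  On the linear scale this is
#' exactly the geometric mean of the relative quantities 2^-Ct, i.e.
#' \eqn{2^{-\mathrm{mean}(Ct)} = \mathrm{geomean}(2^{-Ct})}, the identity
#' that motivates averaging on the Ct (log) scale.
#'
#' @param m A [ct_matrix()] object.
#' @param hkgs Character vector of housekeeping assay ids; all must be
#'   present and detected in every sample.
#' @return Named numeric vector, one reference Ct (cycles) per sample.
#' @export
geometric_mean_reference <- function(m, hkgs) {
  validate_ct_matrix(m)
  hkgs <- as.character(hkgs)
  if (!length(hkgs)) stop("housekeeping set is empty")
  missing_ids <- setdiff(hkgs, m$assay_ids)
  if (length(missing_ids))
    stop("housekeeping assay(s) absent from matrix: ",
         paste(missing_ids, collapse = ", "))
  sub <- m$ct[hkgs, , drop = FALSE]
  if (anyNA(sub)) {
    bad <- hkgs[apply(is.na(sub), 1, any)]
    stop("housekeeping assay(s) not detected in every sample: ",
         paste(bad, collapse = ", "))
  }
  colMeans(sub)
}

# Pearson correlation with stability screen semantics for degenerate profiles:
# an exactly constant assay is perfectly stable (r := 1); a varying assay
# cannot track an exactly constant reference (r := 0).
.stability_cor <- function(v, ref) {
  if (stats::sd(v) == 0) return(1)
  if (stats::sd(ref) == 0) return(0)
  stats::cor(v, ref)
}

#' Select housekeeping miRNAs by the modified Bianchi screen
#'
#' Applies four criteria in order to the assays of a detection-filtered Ct
#' matrix:
#' (i) expressed in all samples and at high level (median Ct below
#' `median_ct_max`); (ii) not different between the two contrast groups
#' (Mann-Whitney U, p strictly above `stability_p_min`); (iii) not highly
#' variable -- the coefficient of variation of the linear quantities 2^-Ct
#' must fall below mean(CV) + `cv_sd_multiplier` * SD(CV) taken over the
#' criterion-(i) survivors -- and free of outlying samples (every sample
#' within `outlier_fold` of the assay's mean linear level); (iv) correlated
#' (Pearson r strictly above `r_min`) with the geometric-mean reference of
#' the current housekeeping set, iterating -- recompute the reference from
#' the survivors, drop assays falling below `r_min`, repeat -- until a fixed
#' point.  The set shrinks monotonically, so the iteration terminates in at
#' most as many rounds as there are assays.
#'
#' By default the reference includes the candidate itself (the reference is
#' "the geometric mean of the HKGs" as a running set); `correlation =
#' "leave_self_out"` excludes the candidate from its own reference.
#'
#' @param m A [ct_matrix()] object, normally already passed through
#'   [detection_filter()].  Assays with any undetected sample fail
#'   criterion (i).
#' @param design A [group_design()] covering the samples of `m`.
#' @param crit An [hkg_criteria()] object.
#' @param correlation `"leave_self_in"` (default) or `"leave_self_out"`.
#' @param mwu_mode Passed to [mann_whitney_u()].
#' @return An object of class `hkg_selection`: list with `selected`
#'   (character vector of assay ids), `diagnostics` (one row per assay:
#'   `median_ct`, `mwu_p`, `cv`, `outlier_flag`, `r_with_geomean`,
#'   `pass_i` .. `pass_iv`), `iterations` (criterion-(iv) rounds, >= 1),
#'   `reference_profile` (per-sample mean housekeeping Ct) and `criteria`.
#' @export
select_hkgs <- function(m, design, crit = hkg_criteria(),
                        correlation = c("leave_self_in", "leave_self_out"),
                        mwu_mode = c("auto", "exact", "approx")) {
  correlation <- match.arg(correlation)
  mwu_mode <- match.arg(mwu_mode)
  validate_ct_matrix(m)
  stopifnot(inherits(design, "group_design"), inherits(crit, "hkg_criteria"))
  if (!all(m$sample_ids %in% names(design$condition_of)))
    stop("design does not cover all samples")

  a_ids <- m$assay_ids
  ref_s <- .design_samples(design, "reference", m$sample_ids)
  tst_s <- .design_samples(design, "test", m$sample_ids)
  if (length(ref_s) < 2L || length(tst_s) < 2L)
    stop("need >= 2 samples per contrast group")

  detected_all <- !apply(is.na(m$ct), 1, any)
  median_ct <- apply(m$ct, 1, stats::median, na.rm = TRUE)
  pass_i <- detected_all & median_ct < crit$median_ct_max
  if (!any(pass_i)) stop("criterion (i) (expression level) left no candidates")

  mwu_p <- rep(NA_real_, length(a_ids))
  mwu_p[pass_i] <- vapply(which(pass_i), function(i)
    mann_whitney_u(m$ct[i, ref_s], m$ct[i, tst_s], mode = mwu_mode)$p, 0)
  pass_ii <- pass_i & !is.na(mwu_p) & mwu_p > crit$stability_p_min
  if (!any(pass_ii)) stop("criterion (ii) (group stability) left no candidates")

  lin <- 2^(-m$ct)
  cv <- rep(NA_real_, length(a_ids))
  outlier_flag <- rep(NA, length(a_ids))
  for (i in which(pass_i)) {
    v <- lin[i, ]
    mu <- mean(v)
    cv[i] <- stats::sd(v) / mu
    outlier_flag[i] <- any(v < mu / crit$outlier_fold | v > mu * crit$outlier_fold)
  }
  cv_pool <- cv[pass_i]
  cv_thr <- mean(cv_pool) + crit$cv_sd_multiplier * stats::sd(cv_pool)
  if (is.na(cv_thr)) cv_thr <- Inf  # single candidate: no dispersion screen
  # a candidate at or below the average CV is never "highly variable", which
  # also keeps the degenerate all-equal-CV case (threshold = mean) sane
  cv_ok <- cv < cv_thr | cv <= mean(cv_pool)
  pass_iii <- pass_ii & cv_ok & !outlier_flag
  if (!any(pass_iii)) stop("criterion (iii) (variability/outliers) left no candidates")

  current <- a_ids[pass_iii]
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    ref_profile <- colMeans(m$ct[current, , drop = FALSE])
    r <- vapply(current, function(a) {
      prof <- if (correlation == "leave_self_out" && length(current) > 1L)
        colMeans(m$ct[setdiff(current, a), , drop = FALSE]) else ref_profile
      .stability_cor(-m$ct[a, ], -prof)
    }, 0)
    surviving <- current[r > crit$r_min]
    if (!length(surviving))
      stop("criterion (iv) (reference correlation) left no candidates")
    if (length(surviving) == length(current)) break
    current <- surviving
  }

  final_ref <- colMeans(m$ct[current, , drop = FALSE])
  r_final <- vapply(seq_along(a_ids), function(i) {
    if (anyNA(m$ct[i, ])) return(NA_real_)
    .stability_cor(-m$ct[i, ], -final_ref)
  }, 0)
  pass_iv <- pass_iii & a_ids %in% current

  diagnostics <- data.frame(
    assay_id = a_ids,
    median_ct = median_ct,
    mwu_p = mwu_p,
    cv = cv,
    outlier_flag = outlier_flag,
    r_with_geomean = r_final,
    pass_i = pass_i, pass_ii = pass_ii, pass_iii = pass_iii, pass_iv = pass_iv,
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(selected = current,
                 diagnostics = diagnostics,
                 iterations = iterations,
                 reference_profile = final_ref,
                 cv_threshold = cv_thr,
                 criteria = crit,
                 correlation = correlation),
            class = "hkg_selection")
}

#' @export
print.hkg_selection <- function(x, ...) {
  cat(sprintf("hkg_selection: %d of %d assays selected (%d correlation round%s)\n",
              length(x$selected), nrow(x$diagnostics), x$iterations,
              if (x$iterations == 1) "" else "s"))
  invisible(x)
}

#' Percentage overlap between two housekeeping sets
#'
#' @param a,b Character vectors (sets of assay ids); not both empty.
#' @param denominator `"union"` (default, Jaccard-style), `"smaller"`
#'   (overlap relative to the smaller set) or `"reference"` (relative to
#'   `a`).
#' @return Percentage in \[0, 100\], with the denominator choice attached as
#'   attribute `"denominator"`.
#' @export
hkg_overlap <- function(a, b, denominator = c("union", "smaller", "reference")) {
  denominator <- match.arg(denominator)
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (!length(a) && !length(b)) stop("both sets are empty")
  inter <- length(intersect(a, b))
  den <- switch(denominator,
                union = length(union(a, b)),
                smaller = min(length(a), length(b)),
                reference = length(a))
  if (den == 0) stop("denominator set is empty")
  structure(100 * inter / den, denominator = denominator)
}
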