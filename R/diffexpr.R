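#' Inverse of the trigamma function
#'
#' Newton solve of `trigamma(x) = y` for `x > 0`, used by the moment
#' estimator of the variance-prior degrees of freedom in [fit_ebayes()].
#'
#' @param y Positive numeric vector.
#' @return `x` with `trigamma(x) = y` (elementwise); `Inf` maps to 0 and
#'   values below `trigamma(1e7)` effectively to very large `x`.
#' @keywords internal
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(if (is.infinite(yi)) 0 else Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (iter in 1:60) {
      tri <- trigamma(x)
      dif <- (tri - yi) / psigamma(x, 2L)
      x <- x - dif
      if (x <= 0) x <- .Machine$double.eps
      if (abs(dif) < 1e-10 * x) break
    }
    x
  }, 0)
}

#' Empirical-Bayes moderated two-sample statistics on delta-Ct values
#'
#' For each assay, the effect is the difference of group means of delta-Ct
#' (reference minus test, equal to the log2 fold change test vs reference)
#' and `sg_sq` the pooled two-sample residual variance on `dg = n1 + n2 - 2`
#' degrees of freedom.  A scaled inverse-chi-square prior
#' (`d0`, `s0_sq`) is estimated from the ensemble of log residual variances
#' by the method of moments: with `e = log(sg_sq) - digamma(dg/2) +
#' log(dg/2)`, solve `trigamma(d0/2) = var(e) - trigamma(dg/2)` and
#' `s0_sq = exp(mean(e) + digamma(d0/2) - log(d0/2))`.  When the observed
#' spread of variances is no larger than expected under a common variance,
#' `d0` is infinite and the posterior variance equals `s0_sq` everywhere.
#' Posterior (shrunken) variances are
#' `s_tilde_sq = (d0 * s0_sq + dg * sg_sq) / (d0 + dg)`, the moderated t is
#' `effect / sqrt(s_tilde_sq * (1/n1 + 1/n2))`, and p-values are two-sided
#' from a t distribution on `d0 + dg` degrees of freedom.
#'
#' @param delta_ct Numeric matrix of delta-Ct values (assays x samples)
#'   with sample column names, or a [normalize_ct()] result.
#' @param design A [group_design()].
#' @param d0 Optional fixed prior degrees of freedom, bypassing estimation;
#'   `d0 = 0` gives the ordinary two-sample pooled t-test, `d0 = Inf` full
#'   shrinkage to `s0_sq`.
#' @param s0_sq Optional fixed prior variance (cycles squared), used only
#'   with a fixed `d0 > 0`.
#' @return A list: `table` (data frame with `assay_id`, `effect`, `sg_sq`,
#'   `dg`, `stderr`, `s_tilde_sq`, `t_mod`, `df_total`, `p`) and `params`
#'   (list `d0`, `s0_sq`, `n_ref`, `n_test`).  Assays with missing values in
#'   the contrast samples are dropped with a warning.
#' @export
fit_ebayes <- function(delta_ct, design, d0 = NULL, s0_sq = NULL) {
  if (inherits(delta_ct, "normalized_expression")) delta_ct <- delta_ct$delta_ct
  stopifnot(is.matrix(delta_ct), inherits(design, "group_design"))
  ref_s <- .design_samples(design, "reference", colnames(delta_ct))
  tst_s <- .design_samples(design, "test", colnames(delta_ct))
  n1 <- length(ref_s); n2 <- length(tst_s)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per group")
  dg <- n1 + n2 - 2L
  if (dg < 1L) stop("zero residual degrees of freedom")
  x <- delta_ct[, ref_s, drop = FALSE]
  y <- delta_ct[, tst_s, drop = FALSE]
  complete <- !(apply(is.na(x), 1, any) | apply(is.na(y), 1, any))
  if (!all(complete)) {
    warning(sum(!complete), " assay(s) dropped for missing values in contrast samples")
    x <- x[complete, , drop = FALSE]; y <- y[complete, , drop = FALSE]
  }
  if (nrow(x) < 2L && is.null(d0))
    d0 <- 0  # no ensemble to estimate a prior from; fall back to ordinary t
  effect <- rowMeans(x) - rowMeans(y)
  rss <- rowSums((x - rowMeans(x))^2) + rowSums((y - rowMeans(y))^2)
  sg_sq <- rss / dg
  if (any(sg_sq == 0))
    stop("zero residual variance for assay(s): ",
         paste(utils::head(rownames(x)[sg_sq == 0], 3), collapse = ", "))

  if (is.null(d0)) {
    e <- log(sg_sq) - digamma(dg / 2) + log(dg / 2)
    evar <- stats::var(e) - trigamma(dg / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_sq <- exp(mean(e))
    }
  } else {
    if (d0 > 0 && is.null(s0_sq)) {
      e <- log(sg_sq) - digamma(dg / 2) + log(dg / 2)
      s0_sq <- if (is.infinite(d0)) exp(mean(e))
               else exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
    if (d0 == 0) s0_sq <- NA_real_
  }

  s_tilde_sq <- if (is.infinite(d0)) rep(s0_sq, length(sg_sq))
                else if (d0 == 0) sg_sq
                else (d0 * s0_sq + dg * sg_sq) / (d0 + dg)
  se_unit <- sqrt(1 / n1 + 1 / n2)
  t_mod <- effect / (sqrt(s_tilde_sq) * se_unit)
  df_total <- d0 + dg
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  table <- data.frame(assay_id = rownames(x),
                      effect = effect,
                      sg_sq = sg_sq,
                      dg = dg,
                      stderr = sqrt(s_tilde_sq) * se_unit,
                      s_tilde_sq = s_tilde_sq,
                      t_mod = t_mod,
                      df_total = df_total,
                      p = p,
                      stringsAsFactors = FALSE, row.names = NULL)
  list(table = table,
       params = list(d0 = d0, s0_sq = s0_sq, n_ref = n1, n_test = n2))
}

#' Storey (2002) q-values
#'
#' The point estimator of the null proportion is
#' `pi0 = #\{p_i > lambda\} / (m * (1 - lambda))`, capped at 1.  On the
#' sorted p-values, `q_(i) = min_{j >= i} pi0 * m * p_(j) / j`; tied
#' p-values share a q-value.  With `pi0` fixed at 1 this reduces to the
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param p Vector of p-values, all in (0, 1].
#' @param lambda Tuning parameter in \[0, 1) (default 0.5, the simple 2002
#'   point estimator).
#' @param pi0 Optional fixed null proportion overriding estimation.
#' @return List with `q` (same order as `p`) and `pi0`.
#' @examples
#' storey_qvalues(c(0.01, 0.2, 0.8, 0.9))$q  # 0.04 0.40 0.90 0.90
#' @export
storey_qvalues <- function(p, lambda = 0.5, pi0 = NULL) {
  p <- as.numeric(p)
  if (!length(p)) stop("empty p-value vector")
  if (anyNA(p) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (lambda < 0 || lambda >= 1) stop("'lambda' must be in [0, 1)")
  m <- length(p)
  if (is.null(pi0)) pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  if (pi0 <= 0) pi0 <- 1 / m  # all p below lambda: smallest non-degenerate value
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  list(q = q, pi0 = pi0, lambda = lambda)
}

#' Differential expression of normalized miRNA panels
#'
#' Composes [fit_ebayes()] (moderated t on delta-Ct), [storey_qvalues()]
#' (FDR estimation) and [fold_change()] into a per-assay result table.
#' An assay is significant when its q-value is at or below `fdr_level`;
#' significant assays are partitioned into increased (`fc > 1`) and
#' decreased (`fc < 1`) in the test group.
#'
#' @param norm A [normalize_ct()] result.
#' @param design A [group_design()]; effects are test vs reference.
#' @param fdr_level Significance threshold on the q-value (default 0.10).
#' @param lambda Storey tuning parameter (default 0.5).
#' @param d0 Optional fixed prior degrees of freedom (see [fit_ebayes()]).
#' @return A data frame of class `diffexpr_table` with columns `assay_id`,
#'   `fc`, `log2fc`, `t_mod`, `df_total`, `p`, `q`, `direction`
#'   (`"increased"`/`"decreased"` for significant assays, `"-"` otherwise)
#'   and `significant`; attributes `pi0`, `d0`, `s0_sq`, `fdr_level` and
#'   `contrast`.
#' @export
differential_expression <- function(norm, design, fdr_level = 0.10,
                                    lambda = 0.5, d0 = NULL) {
  stopifnot(inherits(norm, "normalized_expression"))
  if (fdr_level <= 0 || fdr_level >= 1) stop("'fdr_level' must be in (0, 1)")
  fit <- fit_ebayes(norm, design, d0 = d0)
  st <- storey_qvalues(fit$table$p, lambda = lambda)
  fcs <- fold_change(norm, design)
  tab <- fit$table
  tab$q <- st$q
  tab <- merge(tab, fcs[, c("assay_id", "log2fc", "fc")], by = "assay_id",
               sort = FALSE)
  tab$significant <- tab$q <= fdr_level
  tab$direction <- ifelse(!tab$significant, "-",
                          ifelse(tab$fc > 1, "increased", "decreased"))
  out <- tab[order(tab$p),
             c("assay_id", "fc", "log2fc", "t_mod", "df_total", "p", "q",
               "direction", "significant")]
  rownames(out) <- NULL
  structure(out,
            class = c("diffexpr_table", "data.frame"),
            pi0 = st$pi0,
            d0 = fit$params$d0,
            s0_sq = fit$params$s0_sq,
            fdr_level = fdr_level,
            contrast = attr(fcs, "contrast"))
}

#' @export
print.diffexpr_table <- function(x, ...) {
  up <- sum(x$significant & x$direction == "increased")
  dn <- sum(x$significant & x$direction == "decreased")
  cat(sprintf("diffexpr_table: %d assays, %d significant at FDR %.0f%% (%d increased, %d decreased)\n",
              nrow(x), up + dn, 100 * attr(x, "fdr_level"), up, dn))
  cat(sprintf("  %s; pi0 = %.3f, prior df = %s\n", attr(x, "contrast"),
              attr(x, "pi0"), format(attr(x, "d0"), digits = 4)))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
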