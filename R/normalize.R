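#' Delta-Ct normalization against a housekeeping reference
#'
#' For each sample the reference value is the mean housekeeping Ct (the
#' geometric mean of the linear quantities, see
#' [geometric_mean_reference()]); each assay's delta-Ct is its Ct minus the
#' sample's reference value, and the relative quantity is 2^-delta-Ct.
#' Lower delta-Ct means higher abundance.  Housekeeping assays are retained
#' in the output; by construction their per-sample mean delta-Ct is zero.
#'
#' @param m A [ct_matrix()] object.
#' @param hkgs Character vector of housekeeping assay ids (e.g.
#'   `select_hkgs(...)$selected`).
#' @return An object of class `normalized_expression`: list with `delta_ct`
#'   and `rel_quantity` matrices (undetected wells stay `NA`),
#'   `reference_profile`, `hkgs` and the sample `meta`.
#' @export
normalize_ct <- function(m, hkgs) {
  ref <- geometric_mean_reference(m, hkgs)
  delta <- sweep(m$ct, 2, ref)
  structure(list(delta_ct = delta,
                 rel_quantity = 2^(-delta),
                 reference_profile = ref,
                 hkgs = as.character(hkgs),
                 meta = m$meta),
            class = "normalized_expression")
}

#' @export
print.normalized_expression <- function(x, ...) {
  cat(sprintf("normalized_expression: %d assays x %d samples, %d housekeeping assays\n",
              nrow(x$delta_ct), ncol(x$delta_ct), length(x$hkgs)))
  invisible(x)
}

#' Per-assay fold change between two groups
#'
#' log2 fold change is the difference of group mean delta-Ct values,
#' reference minus test, so that `fc > 1` means higher abundance in the test
#' group (a lower delta-Ct is a higher abundance).  `fc = 2^log2fc`.
#'
#' @param norm A [normalize_ct()] result.
#' @param design A [group_design()]; fold changes are test vs reference.
#' @return Data frame with columns `assay_id`, `log2fc`, `fc`, `n_ref`,
#'   `n_test` and `undefined` (flagged when a group has no defined value for
#'   the assay).  Column ordering of the contrast is echoed in the
#'   `"contrast"` attribute.
#' @export
fold_change <- function(norm, design) {
  stopifnot(inherits(norm, "normalized_expression"), inherits(design, "group_design"))
  ids <- colnames(norm$delta_ct)
  ref_s <- .design_samples(design, "reference", ids)
  tst_s <- .design_samples(design, "test", ids)
  if (length(ref_s) < 2L || length(tst_s) < 2L)
    stop("need >= 2 samples per contrast group")
  ref_mean <- rowMeans(norm$delta_ct[, ref_s, drop = FALSE], na.rm = TRUE)
  tst_mean <- rowMeans(norm$delta_ct[, tst_s, drop = FALSE], na.rm = TRUE)
  log2fc <- ref_mean - tst_mean
  undefined <- !is.finite(log2fc)
  out <- data.frame(assay_id = rownames(norm$delta_ct),
                    log2fc = log2fc,
                    fc = 2^log2fc,
                    n_ref = rowSums(!is.na(norm$delta_ct[, ref_s, drop = FALSE])),
                    n_test = rowSums(!is.na(norm$delta_ct[, tst_s, drop = FALSE])),
                    undefined = undefined,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$log2fc[undefined] <- NA_real_
  out$fc[undefined] <- NA_real_
  attr(out, "contrast") <- sprintf("%s vs %s (fc > 1 means higher in %s)",
                                   design$contrast[2], design$contrast[1],
                                   design$contrast[2])
  out
}

#' Emulate pooling of samples on the linear scale
#'
#' Pooling equal cell numbers of several lines mixes their transcripts, so
#' the pooled linear quantity is the arithmetic mean of the member
#' quantities 2^-Ct, and the pooled Ct is -log2 of that mean.  The pooled
#' sample is appended to the matrix.  Wells where any member is not
#' detected are marked undetermined in the pooled sample.
#'
#' @param m A [ct_matrix()] object.
#' @param members Character vector of >= 2 member sample ids.
#' @param name Sample id for the new pooled sample.
#' @param condition Condition label for the pooled sample; defaults to the
#'   members' shared label (required if the members disagree).
#' @return A [ct_matrix()] with one added sample (metadata `pooled = 1`).
#' @export
pool_samples <- function(m, members, name, condition = NULL) {
  validate_ct_matrix(m)
  members <- as.character(members)
  if (length(members) < 2L) stop("need >= 2 member samples to pool")
  absent <- setdiff(members, m$sample_ids)
  if (length(absent)) stop("member sample(s) missing: ", paste(absent, collapse = ", "))
  if (name %in% m$sample_ids) stop("sample id already present: ", name)
  sub <- m$ct[, members, drop = FALSE]
  ok <- rowSums(is.na(sub)) == 0L
  pooled_ct <- rep(NA_real_, nrow(sub))
  pooled_ct[ok] <- -log2(rowMeans(2^(-sub[ok, , drop = FALSE])))
  conds <- unique(m$meta$condition[m$meta$sample_id %in% members])
  if (is.null(condition)) {
    if (length(conds) != 1L)
      stop("members span conditions (", paste(conds, collapse = ", "),
           "); supply 'condition' explicitly")
    condition <- conds
  }
  ct <- cbind(m$ct, pooled_ct)
  colnames(ct)[ncol(ct)] <- name
  status <- cbind(m$status, ifelse(ok, "ok", "undetermined"))
  colnames(status)[ncol(status)] <- name
  meta <- rbind(m$meta,
                data.frame(sample_id = name, condition = condition,
                           cell_line = "pooled", batch = NA_character_,
                           pooled = 1L, stringsAsFactors = FALSE))
  ct_matrix(ct, meta, status)
}

#' Replicate-dispersion summary against pooled means
#'
#' Summarizes, assay by assay, how far replicate expression levels (from
#' individual cell lines or repeat experiments) deviate from the mean of
#' the corresponding pooled-sample expression, as a percentage of that
#' pooled mean.  The default deviation measure is SD(replicates) / pooled
#' mean x 100; `method = "mad_pct"` uses the mean absolute deviation from
#' the pooled mean instead.  The median and interquartile range are taken
#' over assays with complete replicate data (100% amplified); assays with
#' missing replicates get an `NA` deviation and are excluded from the
#' summary.
#'
#' @param levels Numeric matrix of linear expression levels, assays in rows
#'   and replicates (lines/experiments) in columns, or a list of per-assay
#'   replicate vectors.
#' @param pooled_mean Numeric vector, one pooled-group mean level per assay;
#'   must be positive.
#' @param method `"sd_pct"` (default) or `"mad_pct"`.
#' @return An object of class `precision_summary`: list with
#'   `per_assay_deviation` (percent, `NA` where replicates are incomplete),
#'   `median`, `iqr` (lower, upper) and `n_assays` used.
#' @export
precision_summary <- function(levels, pooled_mean, method = c("sd_pct", "mad_pct")) {
  method <- match.arg(method)
  if (is.list(levels) && !is.data.frame(levels)) {
    n <- max(lengths(levels))
    levels <- t(vapply(levels, function(v) c(v, rep(NA_real_, n - length(v))),
                       numeric(n)))
  }
  levels <- as.matrix(levels)
  if (length(pooled_mean) != nrow(levels))
    stop("'pooled_mean' must have one value per assay row")
  if (any(!is.finite(pooled_mean) | pooled_mean == 0))
    stop("pooled means must be finite and non-zero")
  if (any(rowSums(!is.na(levels)) < 2L))
    stop("every assay needs >= 2 replicate levels")
  dev <- vapply(seq_len(nrow(levels)), function(i) {
    v <- levels[i, ]
    if (anyNA(v)) return(NA_real_)
    if (method == "sd_pct") 100 * stats::sd(v) / pooled_mean[i]
    else 100 * mean(abs(v - pooled_mean[i])) / pooled_mean[i]
  }, 0)
  names(dev) <- rownames(levels)
  used <- dev[!is.na(dev)]
  if (!length(used)) stop("no assay has complete replicate data")
  structure(list(per_assay_deviation = dev,
                 median = stats::median(used),
                 iqr = stats::quantile(used, c(0.25, 0.75), names = FALSE),
                 n_assays = length(used),
                 method = method),
            class = "precision_summary")
}

#' @export
print.precision_summary <- function(x, ...) {
  cat(sprintf("precision_summary (%s): median %.1f%% (IQR %.1f-%.1f%%), %d assays\n",
              x$method, x$median, x$iqr[1], x$iqr[2], x$n_assays))
  invisible(x)
}
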