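#' Define a two-group contrast over samples
#'
#' @param condition_of Named character vector mapping sample id to condition
#'   label, or a `ct_matrix` whose metadata supplies the mapping.
#' @param contrast Ordered pair `c(reference, test)` of condition labels.
#'   Fold changes and effects are reported as test vs reference.
#' @return An object of class `group_design` with elements `condition_of`
#'   and `contrast`.
#' @export
group_design <- function(condition_of, contrast) {
  if (inherits(condition_of, "ct_matrix")) {
    condition_of <- stats::setNames(condition_of$meta$condition,
                                    condition_of$meta$sample_id)
  }
  if (is.null(names(condition_of)) || any(!nzchar(names(condition_of))))
    stop("'condition_of' must be a named vector (names are sample ids)")
  contrast <- as.character(contrast)
  if (length(contrast) != 2L || anyDuplicated(contrast))
    stop("'contrast' must be two distinct condition labels c(reference, test)")
  for (cond in contrast) {
    n <- sum(condition_of == cond)
    if (n < 2L)
      stop(sprintf("condition '%s' has %d sample(s); need >= 2", cond, n))
  }
  structure(list(condition_of = condition_of, contrast = contrast),
            class = "group_design")
}

# sample ids of one side of the contrast, restricted to ids present in `ids`
.design_samples <- function(design, side = c("reference", "test"), ids = NULL) {
  side <- match.arg(side)
  cond <- design$contrast[if (side == "reference") 1L else 2L]
  s <- names(design$condition_of)[design$condition_of == cond]
  if (!is.null(ids)) s <- intersect(s, ids)
  s
}

#' @export
print.group_design <- function(x, ...) {
  cat(sprintf("group_design: %s (reference) vs %s (test); %d vs %d samples\n",
              x$contrast[1], x$contrast[2],
              sum(x$condition_of == x$contrast[1]),
              sum(x$condition_of == x$contrast[2])))
  invisible(x)
}
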