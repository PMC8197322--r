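#' Clonogenic plating efficiency
#'
#' PE = colonies counted / cells plated x 100%.
#'
#' @param colonies Non-negative colony count(s).
#' @param cells_plated Positive count(s) of cells seeded.
#' @return Plating efficiency in percent (vectorized).
#' @examples
#' plating_efficiency(95, 500)   # 19
#' plating_efficiency(102, 500)  # 20.4
#' @export
plating_efficiency <- function(colonies, cells_plated) {
  if (any(cells_plated <= 0)) stop("'cells_plated' must be positive")
  if (any(colonies < 0)) stop("'colonies' must be non-negative")
  if (any(colonies > cells_plated)) stop("more colonies than cells plated")
  100 * colonies / cells_plated
}

#' Clonogenic survival fraction
#'
#' SF = PE(treated) / PE(untreated control) x 100%.
#'
#' @param pe_irradiated Plating efficiency (percent) of the treated cells.
#' @param pe_control Plating efficiency (percent) of the unirradiated
#'   control; must be positive.
#' @return Survival fraction in percent (vectorized).
#' @examples
#' survival_fraction(plating_efficiency(88, 750), plating_efficiency(102, 500))
#' @export
survival_fraction <- function(pe_irradiated, pe_control) {
  if (any(pe_control <= 0)) stop("control plating efficiency must be positive")
  if (any(pe_irradiated < 0)) stop("plating efficiency cannot be negative")
  100 * pe_irradiated / pe_control
}

#' Survival fractions from a clonogenic count table
#'
#' Computes per-replicate plating efficiencies at each dose and the
#' survival fraction of every non-zero dose against the zero-dose control.
#' By default SF is computed per replicate and then averaged (replicate i
#' of the treated dose against replicate i of the control), matching
#' per-experiment means; `mode = "pooled"` instead sums colony and plated
#' counts over replicates before forming the ratio.
#'
#' @param records Data frame with columns `sample`, `dose`, `cells_plated`,
#'   `colonies`, `replicate`.
#' @param mode `"per_replicate"` (default) or `"pooled"`.
#' @return Data frame with columns `sample`, `dose`, `sf_mean`, `sf_sd`
#'   (NA in pooled mode), `n_replicates`.
#' @export
survival_fraction_table <- function(records, mode = c("per_replicate", "pooled")) {
  mode <- match.arg(mode)
  need <- c("sample", "dose", "cells_plated", "colonies", "replicate")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  out <- list()
  for (smp in unique(records$sample)) {
    rs <- records[records$sample == smp, ]
    ctrl <- rs[rs$dose == 0, ]
    if (!nrow(ctrl)) stop("no zero-dose control for sample ", smp)
    for (d in setdiff(unique(rs$dose), 0)) {
      trt <- rs[rs$dose == d, ]
      if (mode == "per_replicate") {
        reps <- intersect(trt$replicate, ctrl$replicate)
        if (!length(reps)) stop("no matching replicates for sample ", smp)
        sf <- vapply(reps, function(rp) {
          survival_fraction(
            plating_efficiency(trt$colonies[trt$replicate == rp][1],
                               trt$cells_plated[trt$replicate == rp][1]),
            plating_efficiency(ctrl$colonies[ctrl$replicate == rp][1],
                               ctrl$cells_plated[ctrl$replicate == rp][1]))
        }, 0)
        out[[length(out) + 1L]] <- data.frame(
          sample = smp, dose = d, sf_mean = mean(sf),
          sf_sd = stats::sd(sf), n_replicates = length(sf),
          stringsAsFactors = FALSE)
      } else {
        sf <- survival_fraction(
          plating_efficiency(sum(trt$colonies), sum(trt$cells_plated)),
          plating_efficiency(sum(ctrl$colonies), sum(ctrl$cells_plated)))
        out[[length(out) + 1L]] <- data.frame(
          sample = smp, dose = d, sf_mean = sf, sf_sd = NA_real_,
          n_replicates = nrow(trt), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Vehicle normalization of Annexin/PI quadrant percentages
#'
#' Viable percentages are expressed relative to the vehicle control
#' (treated viable / vehicle viable x 100); vehicle early- and
#' late-apoptotic percentages are subtracted from the treated ones,
#' clamping at zero (clamps are flagged so they remain auditable).
#'
#' @param treated,vehicle Lists or one-row data frames with elements
#'   `viable_pct`, `early_apoptotic_pct`, `late_apoptotic_pct`.
#' @return List with `viable_norm_pct`, `early_norm_pct`, `late_norm_pct`,
#'   `early_clamped`, `late_clamped`.
#' @export
normalize_apoptosis <- function(treated, vehicle) {
  g <- function(x, f) {
    v <- x[[f]]
    if (is.null(v) || is.na(v) || v < 0 || v > 100)
      stop("'", f, "' must be a percentage in [0, 100]")
    as.numeric(v)
  }
  tv <- g(treated, "viable_pct"); te <- g(treated, "early_apoptotic_pct")
  tl <- g(treated, "late_apoptotic_pct")
  vv <- g(vehicle, "viable_pct"); ve <- g(vehicle, "early_apoptotic_pct")
  vl <- g(vehicle, "late_apoptotic_pct")
  if (vv == 0) stop("vehicle viable percentage is zero")
  early <- te - ve
  late <- tl - vl
  list(viable_norm_pct = 100 * tv / vv,
       early_norm_pct = max(early, 0),
       late_norm_pct = max(late, 0),
       early_clamped = early < 0,
       late_clamped = late < 0)
}

# 4PL response: decreasing in dose for hill > 0 (top at dose 0)
.fourpl <- function(x, bottom, top, log_ic50, hill) {
  bottom + (top - bottom) / (1 + exp(hill * (log(x) - log_ic50)))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' \deqn{y = bottom + \frac{top - bottom}{1 + (x / IC50)^{hill}}}
#' with the IC50 parameterized internally as log(IC50) for stability.
#' A decreasing response (viability falling with dose) corresponds to
#' `hill > 0`.  Fitting uses Levenberg-Marquardt least squares
#' (`minpack.lm`) from a data-driven start, falling back to a multi-start
#' grid over IC50 and Hill slope if the first attempt fails or stalls.
#' The reported IC50 is the curve midpoint (relative IC50); the dose at
#' which the fitted curve crosses an absolute response of 50 is reported
#' alongside as `ic50_absolute` (NA when the curve never crosses 50).
#'
#' @param doses Positive dose vector (vehicle/zero doses are dropped from
#'   the fit); at least 5 distinct doses.
#' @param responses Response values (e.g. viable percent), finite, same
#'   length as `doses`.
#' @return An object of class `fourpl_fit`: list with `bottom`, `top`,
#'   `ic50`, `hill`, `ic50_absolute`, `rss`, `converged`, `n`.
#' @examples
#' d <- c(1, 5, 10, 20, 50, 100)
#' y <- 0 + (100 - 0) / (1 + (d / 10)^1)
#' fit_4pl(d, y)$ic50  # 10
#' @export
fit_4pl <- function(doses, responses) {
  keep <- doses > 0
  x <- as.numeric(doses[keep]); y <- as.numeric(responses[keep])
  if (length(x) != length(y)) stop("doses and responses differ in length")
  if (length(unique(x)) < 5L) stop("need >= 5 distinct positive doses")
  if (any(!is.finite(y))) stop("responses must be finite")

  df <- data.frame(x = x, y = y)
  span <- max(y) - min(y)
  if (span == 0) stop("responses are constant; no dose-response to fit")
  # data-driven start: midpoint dose by linear interpolation of sorted means
  half <- min(y) + span / 2
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  below <- which(ys <= half)
  start_ic50 <- if (length(below)) xs[below[1]] else stats::median(xs)

  tryfit <- function(b, t, li, h) {
    tryCatch(
      minpack.lm::nlsLM(y ~ .fourpl(x, bottom, top, log_ic50, hill),
                        data = df,
                        start = list(bottom = as.numeric(b), top = as.numeric(t),
                                     log_ic50 = as.numeric(li), hill = as.numeric(h)),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  starts <- rbind(
    c(min(y), max(y), log(start_ic50), 1),
    as.matrix(expand.grid(bottom = min(y), top = max(y),
                          log_ic50 = log(exp(seq(log(min(x)), log(max(x)),
                                                 length.out = 4))),
                          hill = c(0.5, 1, 2, 4))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryfit(starts[i, 1], starts[i, 2], starts[i, 3], starts[i, 4])
    if (!is.null(f)) {
      rss <- sum(stats::residuals(f)^2)
      if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = f, rss = rss)
      if (i == 1 && rss <= 1e-10 * span^2 * length(y)) break  # near-exact first fit
    }
  }
  if (is.null(best))
    stop("4PL fit failed to converge from all starts")
  cf <- stats::coef(best$fit)
  bottom <- unname(cf["bottom"]); top <- unname(cf["top"])
  ic50 <- exp(unname(cf["log_ic50"])); hill <- unname(cf["hill"])
  if (top < bottom) {  # canonicalize orientation: top is the zero-dose asymptote
    tmp <- top; top <- bottom; bottom <- tmp; hill <- -hill
  }
  ic50_abs <- if ((top - 50) * (50 - bottom) > 0)
    ic50 * ((top - 50) / (50 - bottom))^(1 / hill) else NA_real_
  structure(list(bottom = bottom, top = top, ic50 = ic50, hill = hill,
                 ic50_absolute = ic50_abs, rss = best$rss,
                 converged = TRUE, n = length(y)),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf("4PL fit: bottom %.3g, top %.3g, IC50 %.4g, hill %.3g (RSS %.4g, n = %d)\n",
              x$bottom, x$top, x$ic50, x$hill, x$rss, x$n))
  invisible(x)
}

#' Evaluate a fitted four-parameter logistic curve at a dose
#'
#' At the fitted IC50 the response equals `(top + bottom) / 2` by
#' definition; the dose-to-zero limit is `top` and the large-dose limit is
#' `bottom` (for `hill > 0`).
#'
#' @param fit A [fit_4pl()] result with `converged = TRUE`.
#' @param dose Positive dose(s).
#' @return Interpolated response value(s).
#' @export
interpolate_at <- function(fit, dose) {
  stopifnot(inherits(fit, "fourpl_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  if (any(dose <= 0)) stop("dose must be positive")
  .fourpl(dose, fit$bottom, fit$top, log(fit$ic50), fit$hill)
}

#' Total-protein densitometry normalization
#'
#' Each lane's normalization factor is its total-protein intensity divided
#' by the intensity of the most heavily loaded lane on the membrane; each
#' band intensity is divided by its lane's factor, removing loading
#' differences.  Scaling all lane intensities by a constant leaves the
#' normalized bands unchanged.
#'
#' @param lane_intensities Positive total-protein intensities, one per lane.
#' @param band_intensities Positive band intensities, same length.
#' @return List with `factors` and `normalized` band values.
#' @examples
#' densitometry_normalize(c(1000, 800), c(50, 40))$normalized  # 50 50
#' @export
densitometry_normalize <- function(lane_intensities, band_intensities) {
  if (length(lane_intensities) != length(band_intensities))
    stop("lane and band vectors differ in length")
  if (any(lane_intensities <= 0) || any(band_intensities <= 0))
    stop("intensities must be positive")
  factors <- lane_intensities / max(lane_intensities)
  list(factors = factors, normalized = band_intensities / factors)
}
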