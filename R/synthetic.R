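#' Ground truth for a synthetic Ct panel
#'
#' Describes a synthetic miRNA OpenArray-style panel from which
#' [generate_ct_matrix()] simulates data.  The default panel emulates the
#' structure of a 111-assay knockout-study panel:
#' \itemize{
#'   \item 48 designed housekeeping assays (stable, well expressed,
#'     baseline Ct 19-28),
#'   \item 15 designed differentially expressed assays (5 increased, 10
#'     decreased in the test condition, fold changes of at least 1.5 in
#'     magnitude so that designed effects are unambiguous),
#'   \item 10 stable but weakly expressed assays (median Ct above 30),
#'   \item 9 technically noisy assays (per-assay noise inflated by
#'     `noisy_multiplier`),
#'   \item 29 assays with designed detection dropout in at least one
#'     sample, so a detection filter retains exactly 82 of 111 assays.
#' }
#' Samples follow a two-condition design with `n_lines` cell lines per
#' condition measured in `n_experiments` experiments.  The Ct model is
#' `baseline + batch effect + sample effect + group shift + noise`, with
#' the group shift equal to -log2 of the designed fold change in test
#' samples -- which makes designed fold changes exactly recoverable by the
#' delta-Ct / differential-expression stack, the generator's core
#' parameter-recovery contract.  Detection dropout is deterministic: the
#' designated wells are pushed above `dropout_ct` regardless of the noise
#' draw, so the designed detection count is exact.
#'
#' @param n_assays Total number of assays (default 111).
#' @param n_hkg,n_de_up,n_de_down,n_highct,n_noisy Class sizes; the
#'   remainder of `n_assays` becomes dropout-designed assays.
#' @param de_fc Named or unnamed fold changes (test vs reference) for the
#'   designed DE assays, increased first; length `n_de_up + n_de_down`.
#' @param noise_sd Residual technical noise SD in cycles (default 0.05, a
#'   low-noise regime; see the package vignette).
#' @param batch_sd SD of shared per-experiment (batch) Ct offsets (default
#'   0.15 cycles).
#' @param sample_sd SD of per-sample Ct offsets (default 0.03 cycles).
#' @param noisy_multiplier Noise-SD multiplier for the noisy class
#'   (default 50).
#' @param dropout_ct Detection ceiling in cycles (default 40); wells above
#'   it are reported as not amplified.
#' @param n_lines Cell lines per condition (default 3).
#' @param n_experiments Repeat experiments (default 4).
#' @param conditions Length-2 character vector `c(reference, test)`.
#' @param seed Default seed used by the generator when none is supplied.
#' @return An object of class `panel_truth` listing `assay_ids`, the truth
#'   classes (`hkg_ids`, `de_spec`, `highct_ids`, `noisy_ids`,
#'   `dropout_ids`), `baseline_ct`, per-assay `noise_sd_assay`, the
#'   designed dropout wells, and the design.
#' @export
panel_truth <- function(n_assays = 111, n_hkg = 48, n_de_up = 5, n_de_down = 10,
                        n_highct = 10, n_noisy = 9,
                        de_fc = c(1.6, 1.7, 1.8, 2.0, 2.2,
                                  0.65, 0.62, 0.59, 0.55, 0.52,
                                  0.50, 0.48, 0.45, 0.42, 0.40),
                        noise_sd = 0.05, batch_sd = 0.15, sample_sd = 0.03,
                        noisy_multiplier = 50, dropout_ct = 40,
                        n_lines = 3, n_experiments = 4,
                        conditions = c("parental", "p53KO"), seed = 1L) {
  n_de <- n_de_up + n_de_down
  n_dropout <- n_assays - n_hkg - n_de - n_highct - n_noisy
  if (n_dropout < 0) stop("class sizes exceed n_assays")
  if (length(de_fc) != n_de) stop("'de_fc' must have n_de_up + n_de_down values")
  if (any(de_fc <= 0)) stop("fold changes must be positive")
  if (n_de_up && any(de_fc[seq_len(n_de_up)] <= 1))
    stop("increased assays need fold change > 1")
  if (n_de_down && any(de_fc[n_de_up + seq_len(n_de_down)] >= 1))
    stop("decreased assays need fold change < 1")
  stopifnot(noise_sd > 0, batch_sd >= 0, sample_sd >= 0, dropout_ct <= 40,
            n_lines >= 2, n_experiments >= 1, length(conditions) == 2)

  ids <- sprintf("miR-sim-%03d", seq_len(n_assays))
  cls <- rep(c("hkg", "de", "highct", "noisy", "dropout"),
             c(n_hkg, n_de, n_highct, n_noisy, n_dropout))
  seg <- function(what) ids[cls == what]
  baseline <- numeric(n_assays)
  baseline[cls == "hkg"] <- seq(19, 28, length.out = n_hkg)
  baseline[cls == "de"] <- seq(21, 27, length.out = max(n_de, 1))[seq_len(n_de)]
  baseline[cls == "highct"] <- seq(30.6, 33.8, length.out = max(n_highct, 1))[seq_len(n_highct)]
  baseline[cls == "noisy"] <- seq(23, 27, length.out = max(n_noisy, 1))[seq_len(n_noisy)]
  baseline[cls == "dropout"] <- seq(33, 38, length.out = max(n_dropout, 1))[seq_len(n_dropout)]
  names(baseline) <- ids
  de_spec <- stats::setNames(de_fc, seg("de"))
  noise_sd_assay <- stats::setNames(
    rep(noise_sd, n_assays) * ifelse(cls == "noisy", noisy_multiplier, 1), ids)

  n_samples <- 2 * n_lines * n_experiments
  # designed dropout wells: assay k of the dropout class misses its first
  # 1 + (k mod 3) samples, deterministically
  dropout_wells <- lapply(stats::setNames(seq_len(n_dropout), seg("dropout")),
                          function(k) seq_len(min(1 + (k %% 3), n_samples)))

  structure(list(n_assays = n_assays, assay_ids = ids, class = cls,
                 hkg_ids = seg("hkg"), de_spec = de_spec,
                 highct_ids = seg("highct"), noisy_ids = seg("noisy"),
                 dropout_ids = seg("dropout"), dropout_wells = dropout_wells,
                 baseline_ct = baseline, noise_sd = noise_sd,
                 noise_sd_assay = noise_sd_assay,
                 batch_sd = batch_sd, sample_sd = sample_sd,
                 dropout_ct = dropout_ct,
                 design = list(conditions = conditions, n_lines = n_lines,
                               n_experiments = n_experiments),
                 seed = seed),
            class = "panel_truth")
}

#' @export
print.panel_truth <- function(x, ...) {
  cat(sprintf(paste0("panel_truth: %d assays (%d housekeeping, %d DE, %d high-Ct, ",
                     "%d noisy, %d dropout); %d x %d-sample design\n"),
              x$n_assays, length(x$hkg_ids), length(x$de_spec),
              length(x$highct_ids), length(x$noisy_ids), length(x$dropout_ids),
              2L, x$design$n_lines * x$design$n_experiments))
  invisible(x)
}

# run `expr` under a temporary seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate a Ct matrix from a panel truth
#'
#' Draws `Ct = baseline + batch + sample + group shift + noise`, where the
#' group shift of a designed DE assay is -log2(fold change) in test-group
#' samples; wells with Ct above `dropout_ct` -- including the designed
#' dropout wells, which are forced above it -- are reported as not
#' amplified.  Fully reproducible from the seed.
#'
#' @param truth A [panel_truth()] object.
#' @param seed Integer seed; defaults to `truth$seed`.
#' @return List with `matrix` (a [ct_matrix()]) and `truth` (the input,
#'   echoed with the seed actually used).
#' @export
generate_ct_matrix <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "panel_truth"))
  if (is.null(seed)) seed <- truth$seed
  d <- truth$design
  sample_grid <- expand.grid(line = seq_len(d$n_lines),
                             condition = d$conditions,
                             experiment = seq_len(d$n_experiments),
                             stringsAsFactors = FALSE)
  sample_ids <- sprintf("%s_line%d_exp%d", sample_grid$condition,
                        sample_grid$line, sample_grid$experiment)
  ns <- nrow(sample_grid)
  shift <- stats::setNames(numeric(truth$n_assays), truth$assay_ids)
  shift[names(truth$de_spec)] <- -log2(truth$de_spec)
  is_test <- sample_grid$condition == d$conditions[2]

  ct <- .with_seed(seed, {
    beta <- stats::rnorm(d$n_experiments, 0, truth$batch_sd)[sample_grid$experiment]
    eta <- stats::rnorm(ns, 0, truth$sample_sd)
    eps <- matrix(stats::rnorm(truth$n_assays * ns), truth$n_assays, ns) *
      truth$noise_sd_assay
    outer(truth$baseline_ct, beta + eta, "+") +
      outer(shift, as.numeric(is_test)) + eps
  })
  dimnames(ct) <- list(truth$assay_ids, sample_ids)
  for (a in names(truth$dropout_wells))
    ct[a, truth$dropout_wells[[a]]] <- truth$dropout_ct + 1.5

  status <- matrix("ok", nrow(ct), ncol(ct), dimnames = dimnames(ct))
  status[ct > truth$dropout_ct] <- "undetermined"
  ct[status != "ok"] <- NA_real_
  meta <- data.frame(sample_id = sample_ids,
                     condition = sample_grid$condition,
                     cell_line = sprintf("%s_line%d", sample_grid$condition,
                                         sample_grid$line),
                     batch = sprintf("exp%d", sample_grid$experiment),
                     pooled = 0L, stringsAsFactors = FALSE)
  list(matrix = ct_matrix(ct, meta, status),
       truth = utils::modifyList(truth, list(seed = seed)))
}

#' Ground truth for treatment-response assays
#'
#' @param true_pe Named list per condition of plating-efficiency
#'   probabilities named by dose (defaults match a radioresistance
#'   experiment: control PEs of 0.19 and 0.204 and designed 2-Gy survival
#'   fractions of 38% and 56% for the reference and test conditions).
#' @param true_4pl Named list per drug of 4PL parameter vectors
#'   `c(bottom, top, ic50, hill)` in percent viability and micromolar;
#'   default IC50s 8, 19, 7.8 and 6.7 uM.
#' @param events_per_replicate Flow-cytometry events collected per
#'   replicate (default 2000); `Inf` gives noiseless percentages.
#' @param early_fraction Fraction of apoptotic cells classified as early
#'   apoptotic (default 0.5).
#' @param seed Default seed.
#' @return An object of class `assay_truth`.
#' @export
assay_truth <- function(true_pe = list(parental = c("0" = 0.19, "2" = 0.19 * 0.38),
                                       p53KO = c("0" = 0.204, "2" = 0.204 * 0.56)),
                        true_4pl = list(
                          cisplatin = c(bottom = 5, top = 90, ic50 = 8, hill = 1.5),
                          fluorouracil = c(bottom = 5, top = 90, ic50 = 19, hill = 1.5),
                          hydroxytamoxifen = c(bottom = 5, top = 90, ic50 = 7.8, hill = 1.5),
                          endoxifen = c(bottom = 5, top = 90, ic50 = 6.7, hill = 1.5)),
                        events_per_replicate = 2000, early_fraction = 0.5,
                        seed = 1L) {
  for (pe in true_pe)
    if (any(pe <= 0 | pe >= 1)) stop("plating-efficiency probabilities must be in (0, 1)")
  for (pl in true_4pl) {
    if (!all(c("bottom", "top", "ic50", "hill") %in% names(pl)))
      stop("each 4PL truth needs bottom, top, ic50, hill")
    if (pl["ic50"] <= 0) stop("true IC50 must be positive")
  }
  stopifnot(events_per_replicate > 0, early_fraction >= 0, early_fraction <= 1)
  structure(list(true_pe = true_pe, true_4pl = true_4pl,
                 events_per_replicate = events_per_replicate,
                 early_fraction = early_fraction, seed = seed),
            class = "assay_truth")
}

#' Simulate clonogenic colony counts
#'
#' Colonies are binomially sampled given the designed plating-efficiency
#' probability: `colonies ~ Binomial(cells plated, true PE)`, in triplicate
#' wells per dose and condition.
#'
#' @param truth An [assay_truth()] object.
#' @param plated Named vector of cells plated per dose (default 500 at
#'   0 Gy, 750 at 2 Gy, matching the doses in `truth$true_pe`).
#' @param n_replicates Wells per dose (default 3).
#' @param seed Integer seed; defaults to `truth$seed`.
#' @return Data frame with columns `sample`, `dose`, `cells_plated`,
#'   `colonies`, `replicate`.
#' @export
generate_clonogenic <- function(truth, plated = c("0" = 500, "2" = 750),
                                n_replicates = 3, seed = NULL) {
  stopifnot(inherits(truth, "assay_truth"))
  if (any(plated <= 0)) stop("'plated' counts must be positive")
  if (is.null(seed)) seed <- truth$seed
  .with_seed(seed, {
    out <- list()
    for (cond in names(truth$true_pe)) {
      pes <- truth$true_pe[[cond]]
      for (dose in names(pes)) {
        if (!dose %in% names(plated))
          stop("no plating count for dose ", dose)
        n <- plated[[dose]]
        col <- stats::rbinom(n_replicates, n, pes[[dose]])
        out[[length(out) + 1L]] <- data.frame(
          sample = cond, dose = as.numeric(dose), cells_plated = n,
          colonies = col, replicate = seq_len(n_replicates),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Simulate Annexin/PI dose-response records
#'
#' Viability at each dose follows the designed 4PL curve; the remaining
#' cells are apoptotic, split into early and late by `early_fraction`.
#' Quadrant percentages are multinomially sampled at
#' `events_per_replicate` events (exact percentages when that is `Inf`).
#' A vehicle (dose 0) record at the top asymptote is included.
#'
#' @param truth An [assay_truth()] object.
#' @param doses Positive dose vector in micromolar, at least 5 values
#'   (default the 1-100 uM treatment grid).
#' @param drug Which entry of `truth$true_4pl` to simulate (default the
#'   first).
#' @param n_replicates Replicates per dose (default 3).
#' @param seed Integer seed; defaults to `truth$seed`.
#' @return Data frame with columns `sample`, `dose`, `viable_pct`,
#'   `early_apoptotic_pct`, `late_apoptotic_pct`, `vehicle`, `replicate`.
#' @export
generate_dose_response <- function(truth, doses = c(1, 5, 10, 20, 50, 100),
                                   drug = NULL, n_replicates = 3, seed = NULL) {
  stopifnot(inherits(truth, "assay_truth"))
  if (length(doses) < 5L) stop("need >= 5 doses")
  if (any(doses <= 0)) stop("doses must be positive")
  if (is.null(drug)) drug <- names(truth$true_4pl)[1]
  pl <- truth$true_4pl[[drug]]
  if (is.null(pl)) stop("no 4PL truth for drug ", drug)
  if (is.null(seed)) seed <- truth$seed
  ev <- truth$events_per_replicate
  all_doses <- c(0, sort(doses))
  .with_seed(seed, {
    out <- list()
    for (d in all_doses) {
      v <- if (d == 0) pl[["top"]] else
        .fourpl(d, pl[["bottom"]], pl[["top"]], log(pl[["ic50"]]), pl[["hill"]])
      probs <- c(v / 100,
                 (1 - v / 100) * truth$early_fraction,
                 (1 - v / 100) * (1 - truth$early_fraction))
      for (r in seq_len(n_replicates)) {
        pct <- if (is.infinite(ev)) 100 * probs
               else 100 * as.numeric(stats::rmultinom(1, ev, probs)) / ev
        out[[length(out) + 1L]] <- data.frame(
          sample = drug, dose = d, viable_pct = pct[1],
          early_apoptotic_pct = pct[2], late_apoptotic_pct = pct[3],
          vehicle = d == 0, replicate = r, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}
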