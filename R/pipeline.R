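#' Run the panel analysis pipeline end to end
#'
#' Orchestrates simulate/read -> detection filter -> housekeeping selection
#' -> delta-Ct normalization -> differential expression -> (optional)
#' target/pathway over-representation, writing each stage's table and a
#' run manifest to the output directory.  All randomness flows from the
#' single `seed` entry, so a rerun with the same configuration produces
#' byte-identical result tables.
#'
#' The configuration is a plain named list (or a path to a YAML file with
#' the same keys):
#' \describe{
#'   \item{ct, meta}{paths to a Ct matrix and sample metadata; omit to
#'     simulate a default synthetic panel instead.}
#'   \item{contrast}{length-2 vector `c(reference, test)`; defaults to the
#'     synthetic panel's conditions.}
#'   \item{ct_max, median_ct_max, p_min, r_min, cv_sd_multiplier,
#'     outlier_fold}{detection and housekeeping thresholds (defaults 40,
#'     30, 0.1, 0.7, 2, 5).}
#'   \item{fdr_level, lambda}{differential-expression settings (defaults
#'     0.10, 0.5).}
#'   \item{targets, pathways, correction}{paths to target and pathway
#'     tables plus correction method; enrichment runs only when both paths
#'     are given and some assay is significant.}
#'   \item{seed}{integer seed (default 1).}
#'   \item{outdir}{output directory (required).}
#' }
#'
#' @param config Named list or path to a YAML configuration file.
#' @return The manifest, invisibly: package version, configuration hash,
#'   seed, per-stage row counts and output paths.  Written as
#'   `manifest.json` in `outdir`.  A failing stage stops with an error
#'   naming the stage; outputs of earlier stages are retained.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(ct = NULL, meta = NULL, contrast = NULL, ct_max = 40,
                   median_ct_max = 30, p_min = 0.1, r_min = 0.7,
                   cv_sd_multiplier = 2, outlier_fold = 5,
                   fdr_level = 0.10, lambda = 0.5,
                   targets = NULL, pathways = NULL, correction = "BH",
                   seed = 1L, outdir = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$outdir)) stop("config needs an 'outdir'")
  for (key in c("ct", "meta", "targets", "pathways"))
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("config path for '", key, "' does not exist: ", cfg[[key]])
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  counts <- list()
  outputs <- character()
  emit <- function(tab, file) {
    path <- file.path(cfg$outdir, file)
    write_results(tab, path, "tsv")
    outputs[[file]] <<- path
    invisible(path)
  }

  m <- stage("input", {
    if (is.null(cfg$ct)) {
      sim <- generate_ct_matrix(panel_truth(seed = cfg$seed))
      if (is.null(cfg$contrast))
        cfg$contrast <- sim$truth$design$conditions
      write_ct_matrix(sim$matrix, file.path(cfg$outdir, "ct_matrix.tsv"))
      outputs[["ct_matrix.tsv"]] <- file.path(cfg$outdir, "ct_matrix.tsv")
      sim$matrix
    } else {
      read_ct_matrix(cfg$ct, meta = cfg$meta)
    }
  })
  if (is.null(cfg$contrast))
    stop("config needs a 'contrast' when reading external data")
  counts$input_assays <- nrow(m$ct)
  counts$samples <- ncol(m$ct)

  flt <- stage("detection_filter", detection_filter(m, ct_max = cfg$ct_max))
  emit(flt$report, "detection_report.tsv")
  counts$detected_assays <- nrow(flt$matrix$ct)

  design <- stage("design", group_design(flt$matrix, cfg$contrast))
  hkg <- stage("select_hkgs", select_hkgs(
    flt$matrix, design,
    hkg_criteria(median_ct_max = cfg$median_ct_max,
                 stability_p_min = cfg$p_min,
                 cv_sd_multiplier = cfg$cv_sd_multiplier,
                 outlier_fold = cfg$outlier_fold,
                 r_min = cfg$r_min)))
  stage("select_hkgs", {
    jsonlite::write_json(
      list(selected = hkg$selected,
           iterations = hkg$iterations,
           criteria = unclass(hkg$criteria),
           diagnostics = hkg$diagnostics,
           reference_profile = as.list(hkg$reference_profile)),
      file.path(cfg$outdir, "hkg.json"),
      dataframe = "rows", digits = NA, auto_unbox = TRUE, pretty = TRUE)
    outputs[["hkg.json"]] <- file.path(cfg$outdir, "hkg.json")
  })
  counts$hkgs_selected <- length(hkg$selected)

  norm <- stage("normalize", normalize_ct(flt$matrix, hkg$selected))
  emit(data.frame(assay_id = rownames(norm$delta_ct), norm$delta_ct,
                  check.names = FALSE), "normalized_delta_ct.tsv")

  de <- stage("diffexpr", differential_expression(
    norm, design, fdr_level = cfg$fdr_level, lambda = cfg$lambda))
  emit(as.data.frame(de), "diffexpr.tsv")
  counts$de_significant <- sum(de$significant)

  if (!is.null(cfg$targets) && !is.null(cfg$pathways)) {
    enr <- stage("enrichment", {
      sig <- de$assay_id[de$significant]
      tdb <- read_target_db(cfg$targets)
      known <- intersect(sig, names(tdb$mirna_to_genes))
      if (!length(known)) NULL else {
        pdb <- read_pathway_db(cfg$pathways)
        overrepresentation(targets_of(known, tdb), pdb,
                           correction = cfg$correction)
      }
    })
    if (!is.null(enr)) {
      emit(enr, "enrichment.tsv")
      counts$enriched_pathways <- sum(enr$significant)
    } else counts$enriched_pathways <- 0L
  }

  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg[order(names(cfg))], cfg_file, auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest <- list(
    package = "mirpanel",
    version = as.character(utils::packageVersion("mirpanel")),
    config = cfg[!vapply(cfg, is.null, TRUE)],
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = cfg$seed,
    row_counts = counts,
    outputs = as.list(outputs))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
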