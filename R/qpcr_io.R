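#' Construct a Ct matrix object
#'
#' A `ct_matrix` is the central container of the package: a miRNA-by-sample
#' matrix of qPCR cycle-threshold (Ct) values together with per-sample
#' metadata.  Wells that failed to amplify ("Undetermined" in instrument
#' exports) and wells that are absent altogether are both stored as `NA` in
#' the numeric matrix but kept distinct in a parallel status matrix, because
#' instrument exports conflate the two while downstream rules must treat
#' both as "not detected".
#'
#' @param ct Numeric matrix, assays in rows, samples in columns, with
#'   dimnames.  `NA` marks wells that did not yield a Ct value.  Finite
#'   values must lie in (0, 40] cycles (the PCR run length).
#' @param meta Data frame of per-sample metadata with columns `sample_id`,
#'   `condition`, and optionally `cell_line`, `batch`, `pooled` (0/1).
#'   Rows are matched to `colnames(ct)` by `sample_id`.
#' @param status Optional character matrix, same shape as `ct`, with values
#'   `"ok"`, `"undetermined"` (well present, no amplification) or
#'   `"missing"` (no well).  Defaults to `"ok"` where `ct` is finite and
#'   `"undetermined"` where it is `NA`.
#'
#' @return An object of class `ct_matrix`: a list with elements `ct`,
#'   `status`, `assay_ids`, `sample_ids` and `meta`.
#' @seealso [read_ct_matrix()], [detection_filter()]
#' @export
ct_matrix <- function(ct, meta, status = NULL) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("'ct' must be a numeric matrix")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("'ct' must have assay rownames and sample colnames")
  if (is.null(status)) {
    status <- matrix(ifelse(is.na(ct), "undetermined", "ok"),
                     nrow = nrow(ct), dimnames = dimnames(ct))
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta)) stop("'meta' must have a sample_id column")
  if (!"condition" %in% names(meta)) stop("'meta' must have a condition column")
  for (col in c("cell_line", "batch")) if (!col %in% names(meta)) meta[[col]] <- NA_character_
  if (!"pooled" %in% names(meta)) meta$pooled <- 0L
  meta <- meta[match(colnames(ct), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  obj <- structure(
    list(ct = ct, status = status,
         assay_ids = rownames(ct), sample_ids = colnames(ct), meta = meta),
    class = "ct_matrix")
  validate_ct_matrix(obj)
  obj
}

#' Validate a Ct matrix against its invariants
#'
#' Checks uniqueness of assay and sample identifiers, the Ct value range
#' (finite values in (0, 40] cycles), metadata completeness (every sample has
#' a non-empty condition label), dimension agreement, and consistency between
#' the numeric and status matrices.
#'
#' @param x A [ct_matrix()] object.
#' @return `x`, invisibly; an error is thrown on the first violated invariant.
#' @export
validate_ct_matrix <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  dup <- x$assay_ids[duplicated(x$assay_ids)]
  if (length(dup)) stop("duplicate assay id(s): ", paste(unique(dup), collapse = ", "))
  dup <- x$sample_ids[duplicated(x$sample_ids)]
  if (length(dup)) stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  if (!identical(dim(x$ct), c(length(x$assay_ids), length(x$sample_ids))))
    stop("ct dimensions do not match assay_ids x sample_ids")
  fin <- x$ct[is.finite(x$ct)]
  if (any(fin <= 0 | fin > 40))
    stop("Ct values out of range (0, 40]: ", paste(
      utils::head(signif(fin[fin <= 0 | fin > 40], 4), 3), collapse = ", "))
  if (!identical(dim(x$status), dim(x$ct)))
    stop("status matrix dimensions differ from ct")
  if (!all(x$status %in% c("ok", "undetermined", "missing")))
    stop("status values must be 'ok', 'undetermined' or 'missing'")
  if (any(is.na(x$ct) & x$status == "ok"))
    stop("NA Ct with status 'ok'")
  if (any(!is.na(x$ct) & x$status != "ok"))
    stop("finite Ct with non-'ok' status")
  cond <- x$meta$condition
  if (any(is.na(cond) | !nzchar(cond)))
    stop("every sample needs a non-empty condition label; offending sample(s): ",
         paste(x$sample_ids[is.na(cond) | !nzchar(cond)], collapse = ", "))
  invisible(x)
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d assays x %d samples\n",
              length(x$assay_ids), length(x$sample_ids)))
  nd <- sum(x$status != "ok")
  cat(sprintf("  not amplified / missing wells: %d (%.1f%%)\n",
              nd, 100 * nd / length(x$ct)))
  cat("  conditions: ", paste(unique(x$meta$condition), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

# header heuristic: miRNA assay identifiers, not sample names
.looks_like_assay <- function(ids) {
  mean(grepl("(miR|let-7|hsa-|mmu-)", ids, ignore.case = TRUE))
}

#' Read a Ct matrix from a delimited file
#'
#' Canonical input format: first column assay identifier, header row sample
#' identifiers, one Ct value per cell.  The tokens `"Undetermined"` (case
#' insensitive; well present but never crossed threshold) and `"NA"` or an
#' empty cell (well absent) are mapped to the not-amplified and missing-well
#' markers respectively.  A file whose column headers look like miRNA assay
#' names while its row identifiers do not is rejected as transposed rather
#' than silently flipped, as silent transposition is a classic qPCR pipeline
#' bug.
#'
#' @param path Path to the matrix file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param meta Optional sample metadata: a data frame or a path to a
#'   tab-separated file with columns `sample_id`, `condition`, `cell_line`,
#'   `batch`, `pooled`.  When omitted, all samples are labelled with
#'   condition `"unspecified"`.
#' @return A [ct_matrix()] object.
#' @export
read_ct_matrix <- function(path, dialect = c("tsv", "csv"), meta = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", comment.char = "",
                           quote = "\"", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("matrix file needs an assay id column plus >=1 sample column")
  assays <- raw[[1]]
  samples <- colnames(raw)[-1]
  if (.looks_like_assay(samples) > 0.5 && .looks_like_assay(samples) > .looks_like_assay(assays))
    stop("input appears transposed (assay names in header row); ",
         "expected assays in rows and samples in columns")
  cells <- as.matrix(raw[, -1, drop = FALSE])
  ct <- matrix(NA_real_, nrow = length(assays), ncol = length(samples),
               dimnames = list(assays, samples))
  status <- matrix("ok", nrow = length(assays), ncol = length(samples),
                   dimnames = list(assays, samples))
  for (j in seq_along(samples)) {
    v <- trimws(cells[, j])
    undet <- grepl("^undetermined$", v, ignore.case = TRUE)
    miss <- is.na(v) | v == "" | toupper(v) == "NA"
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!undet & !miss & is.na(num))
    if (length(bad))
      stop(sprintf("cannot parse cell at row %d (assay '%s'), column '%s': '%s'",
                   bad[1], assays[bad[1]], samples[j], v[bad[1]]))
    ct[!undet & !miss, j] <- num[!undet & !miss]
    status[undet, j] <- "undetermined"
    status[miss, j] <- "missing"
  }
  if (is.character(meta) && length(meta) == 1L) meta <- read_sample_meta(meta)
  if (is.null(meta))
    meta <- data.frame(sample_id = samples, condition = "unspecified",
                       stringsAsFactors = FALSE)
  ct_matrix(ct, meta, status)
}

#' Read a sample metadata table
#'
#' Tab-separated, UTF-8, columns `sample_id`, `condition`, `cell_line`,
#' `batch`, `pooled` (0/1).
#'
#' @param path Path to the metadata file.
#' @return Data frame of per-sample records.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "condition")
  if (!all(need %in% names(meta)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  meta
}

#' Write a Ct matrix to a delimited file
#'
#' Inverse of [read_ct_matrix()]: not-amplified wells are written as
#' `Undetermined`, missing wells as `NA`, and numeric Ct values at 15
#' significant digits so that read-write round trips are loss-free.
#'
#' @param x A [ct_matrix()] object.
#' @param path Output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_ct_matrix <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  validate_ct_matrix(x)
  sep <- if (dialect == "tsv") "\t" else ","
  chr <- matrix(sprintf("%.15g", x$ct), nrow = nrow(x$ct))
  chr[x$status == "undetermined"] <- "Undetermined"
  chr[x$status == "missing"] <- "NA"
  out <- cbind(assay_id = x$assay_ids, as.data.frame(chr, stringsAsFactors = FALSE))
  colnames(out) <- c("assay_id", x$sample_ids)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep only assays detected in every sample
#'
#' The study-style detection rule: an assay is retained only when it has a
#' finite Ct at or below `ct_max` cycles in every sample; an assay that
#' failed to amplify (or is missing) in even one sample is dropped.  The
#' rule is idempotent.
#'
#' @param m A [ct_matrix()] object.
#' @param ct_max Detection ceiling in cycles (default 40, the PCR run length).
#' @return A list with elements `matrix` (the filtered [ct_matrix()]) and
#'   `report`, a data frame with one row per input assay: `assay_id`,
#'   `n_detected`, `n_samples`, `detected_all`, `dropped`.
#' @examples
#' truth <- panel_truth(seed = 1)
#' sim <- generate_ct_matrix(truth)
#' flt <- detection_filter(sim$matrix)
#' nrow(flt$matrix$ct)  # assays detected in all samples
#' @export
detection_filter <- function(m, ct_max = 40) {
  validate_ct_matrix(m)
  det <- (m$status == "ok") & !is.na(m$ct) & m$ct <= ct_max
  n_det <- rowSums(det)
  keep <- n_det == ncol(m$ct)
  report <- data.frame(assay_id = m$assay_ids,
                       n_detected = as.integer(n_det),
                       n_samples = ncol(m$ct),
                       detected_all = keep,
                       dropped = !keep,
                       stringsAsFactors = FALSE)
  if (!any(keep))
    stop("detection filter removed every assay (empty panel)")
  out <- m
  out$ct <- m$ct[keep, , drop = FALSE]
  out$status <- m$status[keep, , drop = FALSE]
  out$assay_ids <- m$assay_ids[keep]
  list(matrix = out, report = report)
}

#' Write a result table to TSV or JSON
#'
#' Numeric columns are serialized at full double precision (>= 15
#' significant digits) so that write-read round trips preserve values.
#'
#' @param table A non-empty data frame.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @seealso [read_results()]
#' @export
write_results <- function(table, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  table <- as.data.frame(table)
  if (nrow(table) == 0L) stop("refusing to write an empty result table")
  if (format == "tsv") {
    out <- table
    for (j in seq_along(out))
      if (is.double(out[[j]])) out[[j]] <- sprintf("%.15g", out[[j]])
    ok <- tryCatch({
      utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
      TRUE
    }, error = function(e) e, warning = function(w) w)
    if (!isTRUE(ok)) stop("cannot write to '", path, "': ", conditionMessage(ok))
  } else {
    ok <- tryCatch({
      jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                           na = "null", auto_unbox = FALSE)
      TRUE
    }, error = function(e) e, warning = function(w) w)
    if (!isTRUE(ok)) stop("cannot write to '", path, "': ", conditionMessage(ok))
  }
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path Input path.
#' @param format `"tsv"` (default) or `"json"`.
#' @return A data frame.
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    as.data.frame(jsonlite::fromJSON(path))
  }
}
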