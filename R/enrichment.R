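#' Read a miRNA-to-target-gene table
#'
#' Tab-separated with columns `mirna`, `gene` and optionally `evidence`.
#' Lines starting with `#` are treated as a header carrying the source and
#' version tag (e.g. `# source: ...; version: ...`).  Gene symbols are
#' uppercased and deduplicated per miRNA.
#'
#' @param path Path to the TSV file.
#' @return An object of class `target_db`: list with `mirna_to_genes`
#'   (named list of character vectors), `source` and `version`.
#' @export
read_target_db <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- grep("^#", readLines(path, n = 5L), value = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("mirna", "gene") %in% names(tab)))
    stop("target table needs 'mirna' and 'gene' columns")
  tab$gene <- toupper(tab$gene)
  sets <- lapply(split(tab$gene, tab$mirna), function(g) sort(unique(g)))
  if (any(lengths(sets) == 0L)) stop("empty target set in table")
  version <- sub(".*version:\\s*", "", hdr[grepl("version:", hdr)][1])
  structure(list(mirna_to_genes = sets,
                 source = paste(hdr, collapse = " "),
                 version = if (length(version)) version else NA_character_),
            class = "target_db")
}

#' Read a pathway-to-gene table
#'
#' Tab-separated with columns `pathway` and `gene`; `#` header lines carry
#' provenance.  The gene universe is the union of all genes in the table.
#'
#' @param path Path to the TSV file.
#' @return An object of class `pathway_db`: list with `pathway_to_genes`
#'   (named list of character vectors), `universe` (character vector) and
#'   `source`.
#' @export
read_pathway_db <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- grep("^#", readLines(path, n = 5L), value = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("pathway", "gene") %in% names(tab)))
    stop("pathway table needs 'pathway' and 'gene' columns")
  tab$gene <- toupper(tab$gene)
  sets <- lapply(split(tab$gene, tab$pathway), function(g) sort(unique(g)))
  if (any(lengths(sets) == 0L)) stop("empty pathway in table")
  structure(list(pathway_to_genes = sets,
                 universe = sort(unique(tab$gene)),
                 source = paste(hdr, collapse = " ")),
            class = "pathway_db")
}

#' Validated target genes of a miRNA set
#'
#' @param mirnas Character vector of miRNA ids to query.
#' @param db A [read_target_db()] object (or a compatible list).
#' @param mode `"union"` (default: targets of any queried miRNA) or
#'   `"intersection"` (targets shared by all queried miRNAs found in the
#'   database).
#' @return Character vector of gene symbols; attribute `"provenance"` maps
#'   each gene to the contributing miRNAs, and `"missing"` lists queried
#'   miRNAs absent from the database (reported with a warning; an error is
#'   raised only when none is present).
#' @export
targets_of <- function(mirnas, db, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  mirnas <- unique(as.character(mirnas))
  sets <- db$mirna_to_genes
  present <- intersect(mirnas, names(sets))
  absent <- setdiff(mirnas, names(sets))
  if (!length(present))
    stop("none of the queried miRNAs is in the target database")
  if (length(absent))
    warning("miRNA(s) not in target database: ", paste(absent, collapse = ", "))
  hit <- sets[present]
  genes <- if (mode == "union") sort(unique(unlist(hit)))
           else sort(Reduce(intersect, hit))
  prov <- lapply(stats::setNames(genes, genes), function(g)
    present[vapply(hit, function(s) g %in% s, TRUE)])
  structure(genes, provenance = prov, missing = absent)
}

#' Hypergeometric over-representation analysis
#'
#' For each pathway, tests whether the overlap between the query gene set
#' and the pathway is larger than expected by chance within the database
#' universe: the upper-tail hypergeometric probability
#' \eqn{P(X \ge k)} of drawing at least the observed overlap `k` when
#' `|query \cap universe|` genes are drawn without replacement from a
#' universe containing `pathway_size` pathway members.  Raw p-values are
#' corrected for multiple testing (Benjamini-Hochberg by default) and rows
#' are sorted by corrected p.
#'
#' This is a standard reimplementation of the over-representation flow used
#' with public pathway databases, not a byte-level replica of any specific
#' web service: the exact statistic and correction such services apply is
#' version-dependent.
#'
#' @param query Character vector of gene symbols (uppercased internally).
#' @param db A [read_pathway_db()] object.
#' @param correction `"BH"` (default) or `"bonferroni"`.
#' @param alpha Significance threshold on the corrected p (default 0.05).
#' @return Data frame with columns `pathway`, `uploaded_count` (overlap),
#'   `pathway_size`, `universe_size`, `query_size`, `p_raw`, `p_corrected`,
#'   `significant`.
#' @export
overrepresentation <- function(query, db, correction = c("BH", "bonferroni"),
                               alpha = 0.05) {
  correction <- match.arg(correction)
  query <- unique(toupper(as.character(query)))
  universe <- unique(toupper(db$universe))
  pathways <- lapply(db$pathway_to_genes, function(g) unique(toupper(g)))
  q_eff <- intersect(query, universe)
  if (!length(q_eff))
    stop("no queried gene is in the pathway database universe")
  N <- length(universe)
  k <- length(q_eff)
  rows <- lapply(names(pathways), function(pw) {
    genes <- pathways[[pw]]
    K <- length(genes)
    x <- length(intersect(q_eff, genes))
    p <- stats::phyper(x - 1, K, N - K, k, lower.tail = FALSE)
    data.frame(pathway = pw, uploaded_count = x, pathway_size = K,
               universe_size = N, query_size = k, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- stats::p.adjust(out$p_raw,
                                     method = if (correction == "BH") "BH" else "bonferroni")
  out$significant <- out$p_corrected <= alpha
  out <- out[order(out$p_corrected, out$p_raw, out$pathway), ]
  rownames(out) <- NULL
  out
}
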