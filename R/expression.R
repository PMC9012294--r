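# single-cell expression summaries: normalization, cluster proportions,
# pseudobulk logFC, disturbance score, pathway scoring, cluster annotation

#' Counts-per-10k log normalization
#'
#' For each cell, counts are scaled to 10,000 and natural-log1p transformed:
#' `value = ln(1 + 1e4 * count / cell_total)`. Cells with zero total count are
#' dropped with a warning. The transform is invariant to rescaling a cell's
#' counts by a constant.
#'
#' @param m Sparse or dense cell-by-gene count matrix (cells in rows) with
#'   dimnames.
#' @return A `dgCMatrix` of normalized values, same orientation.
#' @export
normalize_cp10k_log <- function(m) {
  m <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  if (any(m@x < 0)) stop("counts must be nonnegative", call. = FALSE)
  totals <- Matrix::rowSums(m)
  if (all(totals == 0)) stop("all cells have zero total count", call. = FALSE)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " zero-count cell(s) dropped", call. = FALSE)
    m <- m[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  norm <- methods::as(Matrix::Diagonal(x = 1e4 / totals) %*% m, "CsparseMatrix")
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(m)
  norm
}

validate_metadata <- function(meta) {
  req <- c("cell_id", "patient_id", "timepoint", "cluster_id")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(meta$cell_id))
    stop("duplicate cell_id in metadata", call. = FALSE)
  invisible(meta)
}

#' Cluster proportions of one sample
#'
#' @param meta Cell metadata (`cell_id`, `patient_id`, `timepoint`,
#'   `cluster_id`).
#' @param patient_id,timepoint Sample selector.
#' @param clusters Optional cluster universe; defaults to all clusters present
#'   in `meta`.
#' @return Named proportion vector over clusters (sums to 1).
#' @export
cluster_proportions <- function(meta, patient_id, timepoint, clusters = NULL) {
  validate_metadata(meta)
  sel <- meta$patient_id == patient_id & meta$timepoint == timepoint
  if (!any(sel))
    stop("no cells for patient ", patient_id, " at timepoint ", timepoint,
         call. = FALSE)
  clusters <- clusters %||% sort(unique(meta$cluster_id))
  tab <- table(factor(meta$cluster_id[sel], levels = clusters))
  stats::setNames(as.vector(tab) / sum(tab), clusters)
}

#' Per-cluster cell counts of one sample
#'
#' @inheritParams cluster_proportions
#' @return Named integer vector of cell counts over `clusters`.
#' @export
cluster_cell_counts <- function(meta, patient_id, timepoint, clusters = NULL) {
  validate_metadata(meta)
  sel <- meta$patient_id == patient_id & meta$timepoint == timepoint
  clusters <- clusters %||% sort(unique(meta$cluster_id))
  tab <- table(factor(meta$cluster_id[sel], levels = clusters))
  stats::setNames(as.integer(tab), clusters)
}

#' Cluster-proportion log fold change with Haldane-style continuity
#'
#' `log2( ((n_post + 0.5) / (N_post + 0.5 K)) / ((n_pre + 0.5) / (N_pre + 0.5 K)) )`
#' per cluster, where `K` is the number of clusters. A cluster absent at both
#' timepoints gets exactly 0 by the symmetry of the correction.
#'
#' @param pre_counts,post_counts Per-cluster cell counts (equal length `K`).
#' @return Numeric vector of per-cluster log2 fold changes.
#' @export
proportion_logfc <- function(pre_counts, post_counts) {
  if (length(pre_counts) != length(post_counts))
    stop("count vectors must have equal length", call. = FALSE)
  if (any(pre_counts < 0) || any(post_counts < 0))
    stop("counts must be nonnegative", call. = FALSE)
  K <- length(pre_counts)
  n_pre <- sum(pre_counts)
  n_post <- sum(post_counts)
  if (n_pre <= 0 || n_post <= 0)
    stop("total cell counts must be positive", call. = FALSE)
  log2(((post_counts + 0.5) / (n_post + 0.5 * K)) /
         ((pre_counts + 0.5) / (n_pre + 0.5 * K)))
}

#' Pseudobulk mean expression of one stratum
#'
#' Arithmetic mean of normalized values per gene over the cells of one
#' (patient, timepoint, cluster) stratum. Strata with fewer than `min_cells`
#' cells are unstable and are skipped (`NULL` returned) so callers can record
#' them as missing rather than propagate noise.
#'
#' @param norm Normalized cell-by-gene matrix (see [normalize_cp10k_log()]).
#' @param meta Cell metadata.
#' @param patient_id,timepoint,cluster_id Stratum selector.
#' @param min_cells Minimum cells required (default 3).
#' @return Named per-gene mean vector, or `NULL` if the stratum is too small.
#' @export
pseudobulk_mean <- function(norm, meta, patient_id, timepoint, cluster_id,
                            min_cells = 3) {
  validate_metadata(meta)
  cells <- meta$cell_id[meta$patient_id == patient_id &
                          meta$timepoint == timepoint &
                          meta$cluster_id == cluster_id]
  idx <- match(cells, rownames(norm))
  idx <- idx[!is.na(idx)]
  if (length(idx) < min_cells) return(NULL)
  mu <- Matrix::colMeans(norm[idx, , drop = FALSE])
  stats::setNames(as.vector(mu), colnames(norm))
}

#' Per-gene log fold change between paired pseudobulk means
#'
#' `log2((mean_post + pseudocount) / (mean_pre + pseudocount))` over the genes
#' detected (nonzero mean) in the pre or post stratum (`gene_universe =
#' "detected"`, the default) or over all genes (`"all"`).
#'
#' @param mean_pre,mean_post Aligned named per-gene mean vectors.
#' @param pseudocount Stabilizing constant on the normalized scale
#'   (default 0.01).
#' @param patient_id,cluster_id Optional identifiers carried in the result.
#' @param gene_universe `"detected"` or `"all"`.
#' @return Object of class `cluster_logfc`: list with `patient_id`,
#'   `cluster_id`, named `logfc` vector, `genes_used`, `pseudocount`.
#' @export
gene_logfc <- function(mean_pre, mean_post, pseudocount = 0.01,
                       patient_id = NA_character_, cluster_id = NA,
                       gene_universe = c("detected", "all")) {
  gene_universe <- match.arg(gene_universe)
  if (is.null(names(mean_pre)) || is.null(names(mean_post)) ||
      !identical(names(mean_pre), names(mean_post)))
    stop("mean vectors must be aligned on identical gene names", call. = FALSE)
  if (pseudocount <= 0) stop("'pseudocount' must be positive", call. = FALSE)
  used <- if (gene_universe == "detected")
    mean_pre > 0 | mean_post > 0 else rep(TRUE, length(mean_pre))
  genes_used <- names(mean_pre)[used]
  lfc <- log2((mean_post[used] + pseudocount) / (mean_pre[used] + pseudocount))
  structure(list(patient_id = patient_id, cluster_id = cluster_id,
                 logfc = stats::setNames(as.vector(lfc), genes_used),
                 genes_used = genes_used, pseudocount = pseudocount),
            class = "cluster_logfc")
}

#' Disturbance score of a cluster
#'
#' Mean of the absolute per-gene expression log fold changes of one patient's
#' cluster between paired samples: a scalar measure of global transcriptional
#' activation.
#'
#' @param logfc A [gene_logfc()] result.
#' @return One-row data.frame (class `disturbance_record`) with `patient_id`,
#'   `cluster_id`, `score`, `n_genes`.
#' @export
disturbance_score <- function(logfc) {
  stopifnot(inherits(logfc, "cluster_logfc"))
  if (!length(logfc$logfc)) stop("empty logFC vector", call. = FALSE)
  out <- data.frame(patient_id = logfc$patient_id,
                    cluster_id = logfc$cluster_id,
                    score = mean(abs(logfc$logfc)),
                    n_genes = length(logfc$logfc),
                    stringsAsFactors = FALSE)
  class(out) <- c("disturbance_record", "data.frame")
  out
}

#' Gene set
#'
#' @param name Set name.
#' @param genes Character vector of gene identifiers; duplicates removed.
#' @return Object of class `gene_set`.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("gene set '", name, "' is empty", call. = FALSE)
  structure(list(name = as.character(name), genes = genes), class = "gene_set")
}

#' Read gene sets from a GMT-style file
#'
#' One set per line: name, description, then gene identifiers, tab-separated.
#'
#' @param path File path.
#' @return Named list of [gene_set] objects.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no gene sets in ", path, call. = FALSE)
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed gene-set line (need name, description, genes): ",
           substr(l, 1, 40), call. = FALSE)
    gene_set(f[1], f[-(1:2)])
  })
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Write gene sets to a GMT-style file
#'
#' @param sets List of [gene_set] objects.
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, "na", s$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Per-cell pathway mean-expression score
#'
#' For each cell, the arithmetic mean of normalized expression over the set's
#' genes present in the matrix. Genes absent from the matrix are dropped with
#' a warning giving the tally.
#'
#' @param norm Normalized cell-by-gene matrix.
#' @param set A [gene_set].
#' @return Named per-cell score vector.
#' @export
pathway_mean_score <- function(norm, set) {
  stopifnot(inherits(set, "gene_set"))
  present <- intersect(set$genes, colnames(norm))
  if (!length(present))
    stop("no gene of set '", set$name, "' present in the matrix",
         call. = FALSE)
  n_absent <- length(set$genes) - length(present)
  if (n_absent > 0)
    warning(n_absent, " gene(s) of set '", set$name,
            "' absent from the matrix and dropped", call. = FALSE)
  sc <- Matrix::rowMeans(norm[, present, drop = FALSE])
  stats::setNames(as.vector(sc), rownames(norm))
}

#' Marker-based cluster annotation
#'
#' For each cluster and candidate label, computes the mean (over the label's
#' marker genes) of the across-cluster z-score of cluster-mean expression, and
#' assigns each cluster the argmax label. Ties are broken by lexicographic
#' label order. Marker genes with zero variance across clusters are
#' uninformative and excluded; a label whose markers are all degenerate is
#' skipped with a warning.
#'
#' @param norm Normalized cell-by-gene matrix.
#' @param meta Cell metadata.
#' @param panel Named list of [gene_set]s (label -> markers); every set must
#'   have at least one gene in the matrix.
#' @return List with `labels` (named character vector, cluster -> label) and
#'   `scores` (clusters x labels score matrix).
#' @export
annotate_clusters <- function(norm, meta, panel) {
  validate_metadata(meta)
  clusters <- sort(unique(meta$cluster_id))
  if (length(clusters) < 2)
    stop("need at least 2 clusters to annotate", call. = FALSE)
  cmeans <- t(vapply(clusters, function(cl) {
    idx <- match(meta$cell_id[meta$cluster_id == cl], rownames(norm))
    idx <- idx[!is.na(idx)]
    as.vector(Matrix::colMeans(norm[idx, , drop = FALSE]))
  }, numeric(ncol(norm))))
  dimnames(cmeans) <- list(clusters, colnames(norm))
  mu <- colMeans(cmeans)
  sdv <- apply(cmeans, 2, stats::sd)
  z <- sweep(sweep(cmeans, 2, mu), 2, ifelse(sdv > 0, sdv, NA))
  labels_sorted <- sort(names(panel))
  scores <- matrix(NA_real_, length(clusters), length(labels_sorted),
                   dimnames = list(clusters, labels_sorted))
  for (lab in labels_sorted) {
    genes <- intersect(panel[[lab]]$genes, colnames(norm))
    if (!length(genes))
      stop("marker set '", lab, "' has no gene in the matrix", call. = FALSE)
    usable <- genes[!is.na(sdv[genes]) & sdv[genes] > 0]
    if (!length(usable)) {
      warning("marker set '", lab,
              "' has zero variance across clusters; skipped", call. = FALSE)
      next
    }
    scores[, lab] <- rowMeans(z[, usable, drop = FALSE])
  }
  ok <- colSums(is.na(scores)) < nrow(scores)
  assign <- apply(scores[, ok, drop = FALSE], 1,
                  function(v) colnames(scores)[ok][which.max(v)])
  list(labels = stats::setNames(assign, clusters), scores = scores)
}
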