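# on-disk cohort layout: AIRR TSV repertoires, Matrix-Market expression with
# TSV sidecars, TSV metadata/ground truth, GMT gene sets, YAML config

#' Write a clonotype table as AIRR Rearrangement TSV
#'
#' Columns: `v_call`, `j_call`, `junction`, `junction_aa`, `duplicate_count`.
#'
#' @param table A [clonotype_table].
#' @param path Output path.
#' @export
write_clonotypes <- function(table, path) {
  stopifnot(inherits(table, "clonotype_table"))
  out <- table$clones
  names(out)[names(out) == "count"] <- "duplicate_count"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_counts_mtx <- function(m, prefix) {
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), paste0(prefix, ".mtx"))
  writeLines(rownames(m), paste0(prefix, "_cells.tsv"))
  invisible(prefix)
}

read_counts_mtx <- function(prefix, genes) {
  m <- methods::as(Matrix::readMM(paste0(prefix, ".mtx")), "CsparseMatrix")
  cells <- readLines(paste0(prefix, "_cells.tsv"))
  dimnames(m) <- list(cells, genes)
  m
}

#' Read a dense CSV count matrix
#'
#' First column = cell identifiers, remaining columns = genes.
#'
#' @param path CSV path.
#' @return Sparse `dgCMatrix`, cells in rows.
#' @export
read_counts_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

#' Write a simulated cohort to a directory
#'
#' Layout: `repertoire/<patient>_<timepoint>.tsv` (AIRR), `expression/genes.tsv`
#' plus per-sample `<patient>_<timepoint>.mtx` and cell sidecars,
#' `metadata.tsv`, `ground_truth.tsv`, `cluster_labels.tsv`, `gene_sets.gmt`,
#' `marker_panel.gmt`, `config.yaml`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(file.path(dir, "repertoire"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "expression"), recursive = TRUE, showWarnings = FALSE)
  genes <- colnames(cohort$patients[[1]]$expression$pre)
  writeLines(genes, file.path(dir, "expression", "genes.tsv"))
  metas <- list()
  for (p in cohort$patients) {
    for (tp in c("pre", "post")) {
      write_clonotypes(p$repertoire[[tp]],
                       file.path(dir, "repertoire",
                                 sprintf("%s_%s.tsv", p$patient_id, tp)))
      write_counts_mtx(p$expression[[tp]],
                       file.path(dir, "expression",
                                 sprintf("%s_%s", p$patient_id, tp)))
    }
    metas[[p$patient_id]] <- p$expression$meta
  }
  utils::write.table(do.call(rbind, metas), file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- cohort$ground_truth
  utils::write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  labs <- attr(gt, "planted_cluster_labels")
  utils::write.table(data.frame(cluster_id = names(labs), label = unname(labs)),
                     file.path(dir, "cluster_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gene_sets(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_gene_sets(cohort$marker_panel, file.path(dir, "marker_panel.gmt"))
  yaml::write_yaml(unclass(cohort$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Repertoire files are re-parsed through [read_clonotypes()]; a patient
#' missing the pre or post repertoire keeps whatever is present (downstream
#' paired analyses exclude unpaired patients).
#'
#' @param dir Cohort directory.
#' @return A `cohort` object (ground truth and config included when present).
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) stop("cohort directory not found: ", dir, call. = FALSE)
  meta_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(meta_path)) stop("missing metadata.tsv in ", dir, call. = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  validate_metadata(meta)
  genes <- readLines(file.path(dir, "expression", "genes.tsv"))
  pids <- sort(unique(meta$patient_id))
  patients <- lapply(pids, function(pid) {
    rep_tabs <- list()
    for (tp in c("pre", "post")) {
      path <- file.path(dir, "repertoire", sprintf("%s_%s.tsv", pid, tp))
      if (file.exists(path))
        rep_tabs[[tp]] <- read_clonotypes(path, pid, tp)
    }
    expr <- list()
    for (tp in c("pre", "post")) {
      prefix <- file.path(dir, "expression", sprintf("%s_%s", pid, tp))
      if (file.exists(paste0(prefix, ".mtx")))
        expr[[tp]] <- read_counts_mtx(prefix, genes)
    }
    expr$meta <- meta[meta$patient_id == pid, , drop = FALSE]
    list(patient_id = pid, repertoire = rep_tabs, expression = expr)
  })
  gt <- NULL
  gt_path <- file.path(dir, "ground_truth.tsv")
  if (file.exists(gt_path))
    gt <- utils::read.delim(gt_path, stringsAsFactors = FALSE)
  gene_sets <- NULL
  gs_path <- file.path(dir, "gene_sets.gmt")
  if (file.exists(gs_path)) gene_sets <- read_gene_sets(gs_path)
  panel <- NULL
  mp_path <- file.path(dir, "marker_panel.gmt")
  if (file.exists(mp_path)) panel <- read_gene_sets(mp_path)
  config <- NULL
  cfg_path <- file.path(dir, "config.yaml")
  if (file.exists(cfg_path)) {
    raw <- yaml::read_yaml(cfg_path)
    config <- do.call(cohort_config, raw[setdiff(names(raw), character())])
  }
  structure(list(patients = patients, ground_truth = gt,
                 gene_sets = gene_sets, marker_panel = panel, config = config),
            class = "cohort")
}
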