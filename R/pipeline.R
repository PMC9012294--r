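# end-to-end orchestration: repertoire -> expression -> enrichment -> linking

#' Resolve analysis parameters
#'
#' Fills unspecified analysis parameters with their recorded defaults.
#'
#' @param params Named list of overrides.
#' @return Complete named parameter list.
#' @export
default_params <- function(params = list()) {
  defaults <- list(di_variant = "gini_simpson", epsilon = 1e-6, n_top = 200L,
                   pseudocount = 0.01, min_cells = 3L,
                   gene_universe = "detected", gsea_n_perm = 499L,
                   gsea_seed = 1L, weight_p = 1, correlation_method = "auto",
                   pdc_cluster = NULL)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  utils::modifyList(defaults, params)
}

#' Run the full cohort analysis
#'
#' Executes the pipeline on a simulated or loaded cohort: paired repertoire
#' diversity and top-clone expansion, cluster proportions and their logFC,
#' per-cluster pseudobulk gene logFC and disturbance scores, pathway
#' mean-expression summaries, preranked GSEA on the innate-cluster mean logFC
#' ranking, the expansion-vs-activation correlations, and the DI-ordered
#' signature panel. Optional stages without inputs (no gene sets, no marker
#' panel) are marked absent rather than failing; patients missing a paired
#' repertoire are excluded from repertoire outputs but kept in expression
#' outputs.
#'
#' @param config A [cohort_config] (simulate mode; ignored when `input_dir`
#'   is given).
#' @param input_dir Optional cohort directory (files mode, see
#'   [read_cohort()]).
#' @param params Analysis parameter overrides, see [default_params()].
#' @return Object of class `report_bundle`: list of result tables, the
#'   signature matrix, a manifest (resolved config, parameters, seed,
#'   package version) and `absent`, the names of skipped sections.
#' @export
run_cohort_analysis <- function(config = cohort_config(), input_dir = NULL,
                                params = list()) {
  if (is.null(input_dir)) {
    stopifnot(inherits(config, "cohort_config"))
    cohort <- simulate_cohort(config)
    mode <- "simulate"
  } else {
    cohort <- read_cohort(input_dir)
    config <- cohort$config
    mode <- "files"
  }
  params <- default_params(params)
  if (is.null(params$gsea_seed) || identical(params$gsea_seed, 1L))
    if (!is.null(config)) params$gsea_seed <- config$seed
  pdc <- params$pdc_cluster %||%
    (if (!is.null(config)) config$pdc_cluster_index else NULL)
  innate <- if (!is.null(config)) config$innate_cluster_indices else pdc
  absent <- character()

  ## repertoire stage ------------------------------------------------------
  paired <- Filter(function(p)
    !is.null(p$repertoire$pre) && !is.null(p$repertoire$post),
    cohort$patients)
  unpaired <- setdiff(vapply(cohort$patients, `[[`, "", "patient_id"),
                      vapply(paired, `[[`, "", "patient_id"))
  if (!length(paired))
    stop("no patient has a paired pre/post repertoire", call. = FALSE)
  diversity <- do.call(rbind, lapply(paired, function(p)
    di_logfc(p$repertoire$pre, p$repertoire$post,
             variant = params$di_variant, epsilon = params$epsilon)))
  expansion <- do.call(rbind, lapply(paired, function(p) {
    prof <- top_clone_mass(p$repertoire$pre, p$repertoire$post, params$n_top)
    data.frame(patient_id = prof$patient_id, chain = prof$chain,
               n_top = prof$n_top, n_tracked = length(prof$top_clone_keys),
               mass_pre = prof$mass_pre, mass_post = prof$mass_post,
               stringsAsFactors = FALSE)
  }))

  ## expression stage ------------------------------------------------------
  all_meta <- do.call(rbind, lapply(cohort$patients, function(p)
    p$expression$meta))
  clusters <- sort(unique(all_meta$cluster_id))
  prop_rows <- list()
  dist_rows <- list()
  lfc_by_patient <- list()
  for (p in cohort$patients) {
    if (is.null(p$expression$pre) || is.null(p$expression$post)) next
    meta <- p$expression$meta
    norm <- list(pre = normalize_cp10k_log(p$expression$pre),
                 post = normalize_cp10k_log(p$expression$post))
    n_pre <- cluster_cell_counts(meta, p$patient_id, "pre", clusters)
    n_post <- cluster_cell_counts(meta, p$patient_id, "post", clusters)
    plfc <- proportion_logfc(n_pre, n_post)
    prop_rows[[p$patient_id]] <- data.frame(
      patient_id = p$patient_id, cluster_id = clusters,
      n_pre = n_pre, n_post = n_post, prop_logfc = plfc,
      stringsAsFactors = FALSE)
    per_cluster <- list()
    for (cl in clusters) {
      m_pre <- pseudobulk_mean(norm$pre, meta, p$patient_id, "pre", cl,
                               params$min_cells)
      m_post <- pseudobulk_mean(norm$post, meta, p$patient_id, "post", cl,
                                params$min_cells)
      if (is.null(m_pre) || is.null(m_post)) {
        dist_rows[[paste(p$patient_id, cl)]] <- data.frame(
          patient_id = p$patient_id, cluster_id = cl, score = NA_real_,
          n_genes = NA_integer_, stringsAsFactors = FALSE)
        next
      }
      lfc <- gene_logfc(m_pre, m_post, params$pseudocount, p$patient_id, cl,
                        params$gene_universe)
      per_cluster[[as.character(cl)]] <- lfc
      dist_rows[[paste(p$patient_id, cl)]] <- disturbance_score(lfc)
    }
    lfc_by_patient[[p$patient_id]] <- per_cluster
  }
  prop_table <- do.call(rbind, prop_rows)
  dist_table <- do.call(rbind, dist_rows)
  rownames(prop_table) <- rownames(dist_table) <- NULL

  ## pathway scores --------------------------------------------------------
  pathway_table <- NULL
  if (length(cohort$gene_sets)) {
    path_rows <- list()
    for (p in cohort$patients) {
      if (is.null(p$expression$pre) || is.null(p$expression$post)) next
      meta <- p$expression$meta
      for (tp in c("pre", "post")) {
        norm <- normalize_cp10k_log(p$expression[[tp]])
        for (set in cohort$gene_sets) {
          sc <- pathway_mean_score(norm, set)
          cl_of <- meta$cluster_id[match(names(sc), meta$cell_id)]
          agg <- tapply(sc, factor(cl_of, levels = clusters), mean)
          path_rows[[paste(p$patient_id, tp, set$name)]] <- data.frame(
            set = set$name, patient_id = p$patient_id, timepoint = tp,
            cluster_id = c(as.character(clusters), "all"),
            mean_score = c(as.vector(agg), mean(sc)),
            stringsAsFactors = FALSE)
        }
      }
    }
    pathway_table <- do.call(rbind, path_rows)
    rownames(pathway_table) <- NULL
  } else absent <- c(absent, "pathway_scores")

  ## enrichment stage ------------------------------------------------------
  enrichment_table <- NULL
  if (length(cohort$gene_sets) && length(lfc_by_patient)) {
    targets <- innate %||% clusters
    enr_rows <- list()
    for (cl in targets) {
      vecs <- lapply(lfc_by_patient, function(pc) pc[[as.character(cl)]])
      vecs <- Filter(Negate(is.null), vecs)
      if (!length(vecs)) next
      genes <- sort(unique(unlist(lapply(vecs, function(v) v$genes_used))))
      mat <- vapply(vecs, function(v) v$logfc[match(genes, v$genes_used)],
                    numeric(length(genes)))
      mean_lfc <- rowMeans(as.matrix(mat), na.rm = TRUE)
      names(mean_lfc) <- genes
      ranked <- rank_by_logfc(mean_lfc)
      res <- preranked_gsea(ranked, cohort$gene_sets,
                            n_perm = params$gsea_n_perm,
                            seed = params$gsea_seed,
                            weight_p = params$weight_p)
      res <- cbind(cluster_id = cl, res)
      enr_rows[[as.character(cl)]] <- res
    }
    if (length(enr_rows)) {
      enrichment_table <- do.call(rbind, enr_rows)
      rownames(enrichment_table) <- NULL
    } else absent <- c(absent, "enrichment")
  } else absent <- c(absent, "enrichment")

  ## linking stage ---------------------------------------------------------
  correlation_table <- NULL
  if (!is.null(pdc) && nrow(diversity) >= 3) {
    cors <- list()
    sub <- prop_table[prop_table$cluster_id == pdc &
                        prop_table$n_pre > 0 & prop_table$n_post > 0, ]
    if (nrow(sub) >= 3) {
      act <- data.frame(patient_id = sub$patient_id, value = sub$prop_logfc)
      res <- suppressMessages(correlate_expansion_with_activation(
        diversity, act, params$correlation_method))
      cors$pdc_proportion_logfc <- cbind(activation = "pdc_proportion_logfc",
                                         as.data.frame(res))
    }
    dsub <- dist_table[dist_table$cluster_id == pdc & !is.na(dist_table$score), ]
    if (nrow(dsub) >= 3) {
      act <- data.frame(patient_id = dsub$patient_id, value = dsub$score)
      res <- suppressMessages(correlate_expansion_with_activation(
        diversity, act, params$correlation_method))
      cors$pdc_disturbance <- cbind(activation = "pdc_disturbance",
                                    as.data.frame(res))
    }
    if (length(cors)) {
      correlation_table <- do.call(rbind, cors)
      rownames(correlation_table) <- NULL
    }
  }
  if (is.null(correlation_table)) absent <- c(absent, "correlation")

  ## signature stage -------------------------------------------------------
  signature <- NULL
  signature_table <- NULL
  if (length(cohort$marker_panel) && length(lfc_by_patient) &&
      nrow(diversity) >= 3) {
    genes <- sort(unique(unlist(lapply(lfc_by_patient, function(pc)
      unlist(lapply(pc, function(v) v$genes_used))))))
    stat <- vapply(lfc_by_patient, function(pc) {
      m <- vapply(pc, function(v) v$logfc[match(genes, v$genes_used)],
                  numeric(length(genes)))
      rowMeans(as.matrix(m), na.rm = TRUE)
    }, numeric(length(genes)))
    rownames(stat) <- genes
    panel <- gene_set("marker_panel",
                      unlist(lapply(cohort$marker_panel, `[[`, "genes")))
    signature <- signature_panel(stat, diversity, panel)
    signature_table <- data.frame(gene = names(signature$gene_r),
                                  spearman_r = unname(signature$gene_r),
                                  stringsAsFactors = FALSE)
  } else absent <- c(absent, "signature")

  manifest <- list(
    package = "immunotraj",
    version = as.character(utils::packageVersion("immunotraj")),
    mode = mode,
    seed = if (!is.null(config)) config$seed else NA_integer_,
    config = if (!is.null(config)) unclass(config) else NULL,
    params = params,
    n_patients = length(cohort$patients),
    n_paired_repertoires = nrow(diversity),
    unpaired_patients = unpaired,
    absent_sections = absent)

  structure(list(
    tables = list(diversity = as.data.frame(diversity),
                  expansion = expansion,
                  cluster_proportion_logfc = prop_table,
                  disturbance = dist_table,
                  pathway_scores = pathway_table,
                  enrichment = enrichment_table,
                  correlation = correlation_table,
                  signature_gene_r = signature_table),
    signature = signature, manifest = manifest, absent = absent),
    class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  for (nm in names(x$tables)) {
    t <- x$tables[[nm]]
    cat(sprintf("  %-26s %s\n", nm,
                if (is.null(t)) "(absent)" else sprintf("%d rows", nrow(t))))
  }
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Emits one tidy TSV per result table plus `manifest.json`. The manifest
#' records every resolved parameter and carries no timestamps, so
#' simulate-mode bundles are byte-identical across runs with one seed.
#'
#' @param bundle A [run_cohort_analysis()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(bundle$tables)) {
    t <- bundle$tables[[nm]]
    if (is.null(t)) next
    path <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(t, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  if (!is.null(bundle$signature)) {
    path <- file.path(dir, "signature_matrix.tsv")
    sm <- data.frame(gene = rownames(bundle$signature$matrix),
                     bundle$signature$matrix, check.names = FALSE)
    utils::write.table(sm, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(bundle$manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  paths <- c(paths, mpath)
  invisible(paths)
}

#' Hash of a written report bundle
#'
#' MD5 over the sorted per-file MD5 sums of every file in the bundle
#' directory; equal hashes mean byte-identical bundles.
#'
#' @param dir Bundle directory.
#' @return Character scalar.
#' @export
bundle_hash <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  sums <- tools::md5sum(files)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(basename(names(sums)), unname(sums)), tmp)
  unname(tools::md5sum(tmp))
}
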