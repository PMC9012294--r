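#' Synthetic cohort configuration
#'
#' Parameterizes the paired pre/post-treatment cohort generator: a Zipf-law TCR
#' repertoire with multiplicative top-clone expansion in responders, and
#' per-cluster negative-binomial single-cell expression with a planted
#' type-1-interferon-responsive gene (T1IRG) module, a pDC-like cluster whose
#' proportion shifts in responders, and a global per-gene "disturbance" logFC.
#' A single per-patient responder-strength scalar couples the repertoire and
#' expression effects so that clonal expansion and dendritic-cell activation
#' co-vary (switch off with `couple_effects = FALSE`).
#'
#' @param n_patients Number of patients in the cohort.
#' @param responder_fraction Fraction of patients flagged as responders;
#'   `ceiling(responder_fraction * n_patients)` patients carry planted effects.
#' @param n_clones Distinct clonotypes per repertoire.
#' @param zipf_exponent Exponent of the Zipf clone-abundance law
#'   (base probabilities proportional to `i^-zipf_exponent`).
#' @param reads_per_sample Sequencing depth of each repertoire multinomial draw.
#' @param expansion_factor Multiplicative reweighting (gamma >= 1) applied to
#'   the top clones of responders after treatment.
#' @param expansion_top_fraction Fraction of clones (by base abundance rank)
#'   that are reweighted; the paper-scale analogue of "the top clones".
#' @param n_clusters Number of cell clusters (>= 2).
#' @param cells_per_sample Cells per patient per timepoint.
#' @param n_genes Genes in the simulated universe.
#' @param baseline_dirichlet Dirichlet prior over cluster proportions
#'   (length `n_clusters`, positive). Default gives the pDC-like cluster a
#'   small prior mass, mimicking the rarity of pDCs in blood.
#' @param pdc_cluster_index 1-based index of the pDC-like cluster.
#' @param innate_cluster_indices 1-based indices of the designated innate
#'   clusters carrying the planted T1IRG module (default: the pDC cluster and
#'   its neighbour, a T1IRG-monocyte analogue).
#' @param pdc_shift log2 proportional increase of the pDC-like cluster in
#'   responders after treatment.
#' @param t1irg_set_size Size of the planted interferon-responsive module
#'   (default 99 genes, the size of the canonical GO:0034340 response set).
#' @param t1irg_effect log2 upregulation of the planted module in designated
#'   innate clusters of responders.
#' @param disturbance_sd Standard deviation of the random per-gene log2FC
#'   applied to all genes of responders after treatment.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`) shared by all genes.
#' @param couple_effects If `TRUE` (default) one responder-strength scalar per
#'   patient scales the repertoire and expression effects jointly; if `FALSE`
#'   the expression arm receives an independently permuted responder
#'   assignment and independent strengths, so the two arms share no
#'   per-patient structure (the uncoupled null).
#' @param strength_jitter_sd Standard deviation of the narrow jitter of the
#'   per-patient responder strength around 1.
#' @param seed Master seed; identical seeds give byte-identical cohorts.
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @examples
#' cfg <- cohort_config(n_patients = 4, cells_per_sample = 120, n_genes = 60,
#'                      t1irg_set_size = 10, seed = 1)
#' @export
cohort_config <- function(n_patients = 12,
                          responder_fraction = 0.75,
                          n_clones = 2000,
                          zipf_exponent = 1.2,
                          reads_per_sample = 50000,
                          expansion_factor = 5,
                          expansion_top_fraction = 0.01,
                          n_clusters = 8,
                          cells_per_sample = 480,
                          n_genes = 400,
                          baseline_dirichlet = NULL,
                          pdc_cluster_index = n_clusters,
                          innate_cluster_indices = NULL,
                          pdc_shift = 1,
                          t1irg_set_size = 99,
                          t1irg_effect = 1,
                          disturbance_sd = 1.2,
                          nb_dispersion = 0.4,
                          couple_effects = TRUE,
                          strength_jitter_sd = 0.3,
                          seed = 1L) {
  for (nm in c("n_patients", "n_clones", "reads_per_sample", "n_clusters",
               "cells_per_sample", "n_genes", "t1irg_set_size"))
    assert_scalar_number(get(nm), nm)
  counts <- c(n_patients = n_patients, n_clones = n_clones,
              reads_per_sample = reads_per_sample, n_clusters = n_clusters,
              cells_per_sample = cells_per_sample, n_genes = n_genes,
              t1irg_set_size = t1irg_set_size)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all count parameters must be positive integers", call. = FALSE)
  if (n_clusters < 2)
    stop("'n_clusters' must be at least 2", call. = FALSE)
  if (cells_per_sample < n_clusters)
    stop("'cells_per_sample' must be at least 'n_clusters'", call. = FALSE)
  if (responder_fraction < 0 || responder_fraction > 1)
    stop("'responder_fraction' must lie in [0, 1]", call. = FALSE)
  if (expansion_top_fraction < 0 || expansion_top_fraction > 1)
    stop("'expansion_top_fraction' must lie in [0, 1]", call. = FALSE)
  if (expansion_factor < 1)
    stop("'expansion_factor' must be >= 1", call. = FALSE)
  if (zipf_exponent <= 0) stop("'zipf_exponent' must be positive", call. = FALSE)
  if (nb_dispersion <= 0) stop("'nb_dispersion' must be positive", call. = FALSE)
  if (disturbance_sd < 0) stop("'disturbance_sd' must be nonnegative", call. = FALSE)
  if (t1irg_set_size > n_genes)
    stop("'t1irg_set_size' cannot exceed 'n_genes'", call. = FALSE)
  if (is.null(baseline_dirichlet)) {
    baseline_dirichlet <- rep(36, n_clusters)
    baseline_dirichlet[pdc_cluster_index] <- 12
  }
  if (length(baseline_dirichlet) != n_clusters || any(baseline_dirichlet <= 0))
    stop("'baseline_dirichlet' must be ", n_clusters, " positive values",
         call. = FALSE)
  if (pdc_cluster_index < 1 || pdc_cluster_index > n_clusters)
    stop("'pdc_cluster_index' must lie in 1..n_clusters", call. = FALSE)
  if (is.null(innate_cluster_indices)) {
    buddy <- if (pdc_cluster_index > 1) pdc_cluster_index - 1L
             else pdc_cluster_index + 1L
    innate_cluster_indices <- sort(unique(c(pdc_cluster_index, buddy)))
  }
  innate_cluster_indices <- as.integer(innate_cluster_indices)
  if (any(innate_cluster_indices < 1) || any(innate_cluster_indices > n_clusters))
    stop("'innate_cluster_indices' must lie in 1..n_clusters", call. = FALSE)

  cfg <- list(
    n_patients = as.integer(n_patients),
    responder_fraction = responder_fraction,
    n_clones = as.integer(n_clones),
    zipf_exponent = zipf_exponent,
    reads_per_sample = as.integer(reads_per_sample),
    expansion_factor = expansion_factor,
    expansion_top_fraction = expansion_top_fraction,
    n_clusters = as.integer(n_clusters),
    cells_per_sample = as.integer(cells_per_sample),
    n_genes = as.integer(n_genes),
    baseline_dirichlet = as.numeric(baseline_dirichlet),
    pdc_cluster_index = as.integer(pdc_cluster_index),
    innate_cluster_indices = innate_cluster_indices,
    pdc_shift = pdc_shift,
    t1irg_set_size = as.integer(t1irg_set_size),
    t1irg_effect = t1irg_effect,
    disturbance_sd = disturbance_sd,
    nb_dispersion = nb_dispersion,
    couple_effects = isTRUE(couple_effects),
    strength_jitter_sd = strength_jitter_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d patients (%.0f%% responders), seed %d\n",
              x$n_patients, 100 * x$responder_fraction, x$seed))
  cat(sprintf("  repertoire: %d clones, Zipf %.2f, %d reads, gamma=%.2f on top %.1f%%\n",
              x$n_clones, x$zipf_exponent, x$reads_per_sample,
              x$expansion_factor, 100 * x$expansion_top_fraction))
  cat(sprintf("  expression: %d clusters x %d cells x %d genes; pDC cluster %d (shift %.2f)\n",
              x$n_clusters, x$cells_per_sample, x$n_genes,
              x$pdc_cluster_index, x$pdc_shift))
  cat(sprintf("  planted module: %d genes, effect %.2f in clusters {%s}; disturbance sd %.2f\n",
              x$t1irg_set_size, x$t1irg_effect,
              paste(x$innate_cluster_indices, collapse = ","), x$disturbance_sd))
  invisible(x)
}
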