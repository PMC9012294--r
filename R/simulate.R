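# synthetic paired pre/post cohort generator

# Deterministic clonotype identities for one patient: a fixed function of
# (seed, patient_index, clone index). Junctions are 36-nt random sequences;
# the rare duplicate identity is disambiguated by re-encoding the clone index
# into the junction tail (base 4 -> nucleotides).
make_clone_identities <- function(config, patient_index, chain = "TRB") {
  with_seed(substream_seed(config$seed, patient_index, 0L), {
    n <- config$n_clones
    vg <- if (chain == "TRB") "TRBV" else "TRAV"
    jg <- if (chain == "TRB") "TRBJ" else "TRAJ"
    v_call <- sprintf("%s%d-%d", vg, sample(30L, n, replace = TRUE),
                      sample(2L, n, replace = TRUE))
    j_call <- sprintf("%s%d-%d", jg, sample(2L, n, replace = TRUE),
                      sample(7L, n, replace = TRUE))
    nt <- c("A", "C", "G", "T")
    mat <- matrix(sample(nt, 36L * n, replace = TRUE), nrow = n)
    junction <- do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    aam <- matrix(sample(aa, 10L * n, replace = TRUE), nrow = n)
    junction_aa <- paste0("C", do.call(paste0,
                          as.data.frame(aam, stringsAsFactors = FALSE)), "F")
    key <- paste(v_call, j_call, junction, sep = "|")
    dup <- which(duplicated(key))
    for (i in dup) {
      code <- paste(nt[(i %/% 4L^(7:0)) %% 4L + 1L], collapse = "")
      junction[i] <- paste0(substr(junction[i], 1L, 28L), code)
    }
    data.frame(v_call = v_call, j_call = j_call, junction = junction,
               junction_aa = junction_aa, stringsAsFactors = FALSE)
  })
}

#' Simulate a paired pre/post TCR repertoire for one patient
#'
#' Base clone probabilities follow a Zipf law, `p_i` proportional to
#' `i^-zipf_exponent`. The pre-treatment table is a multinomial draw of
#' `reads_per_sample` reads over `p`. The post-treatment table is drawn from
#' `p` for non-responders; for responders the top
#' `ceiling(expansion_top_fraction * n_clones)` clones are reweighted by the
#' expansion factor (raised to the patient's responder `strength`) and the
#' distribution renormalized, concentrating repertoire mass into top clones.
#'
#' @param config A [cohort_config].
#' @param patient_index Patient index in `1..n_patients`.
#' @param responder Logical: does this patient carry the planted expansion?
#' @param strength Responder-strength scalar (default 1); the effective
#'   expansion factor is `expansion_factor^strength`.
#' @return List with elements `pre` and `post`, both [clonotype_table]s
#'   (clones with zero sampled reads are omitted).
#' @export
simulate_repertoire_pair <- function(config, patient_index, responder,
                                     strength = 1) {
  stopifnot(inherits(config, "cohort_config"))
  if (patient_index < 1 || patient_index > config$n_patients)
    stop("'patient_index' must lie in 1..n_patients", call. = FALSE)
  if (config$reads_per_sample <= 0)
    stop("'reads_per_sample' must be positive", call. = FALSE)
  k <- ceiling(config$expansion_top_fraction * config$n_clones)
  if (isTRUE(responder) && k == 0L) {
    warning("expansion_top_fraction = 0: responder treated as non-responder",
            call. = FALSE)
    responder <- FALSE
  }
  p <- seq_len(config$n_clones)^(-config$zipf_exponent)
  p <- p / sum(p)
  w <- p
  gamma_eff <- config$expansion_factor^strength
  if (isTRUE(responder) && gamma_eff > 1) {
    w[seq_len(k)] <- w[seq_len(k)] * gamma_eff
    w <- w / sum(w)
  }
  ids <- make_clone_identities(config, patient_index)
  pre_counts <- with_seed(substream_seed(config$seed, patient_index, 1L),
                          drop(stats::rmultinom(1L, config$reads_per_sample, p)))
  post_counts <- with_seed(substream_seed(config$seed, patient_index, 2L),
                           drop(stats::rmultinom(1L, config$reads_per_sample, w)))
  pid <- sprintf("P%02d", patient_index)
  mk <- function(counts, tp) {
    keep <- counts > 0
    clones <- ids[keep, , drop = FALSE]
    clones$count <- counts[keep]
    clonotype_table(clones, pid, tp)
  }
  list(pre = mk(pre_counts, "pre"), post = mk(post_counts, "post"))
}

# Cohort-level expression structure shared by all patients: gene identifiers,
# baseline per-gene means, per-cluster marker upregulation, the planted
# interferon-responsive module, a size-matched control set, and cluster labels.
# Depends only on the master seed, so standalone calls to
# simulate_expression_pair() see the same universe as simulate_cohort().
make_expression_structure <- function(config) {
  with_seed(substream_seed(config$seed, 0L, 10L), {
    G <- config$n_genes
    K <- config$n_clusters
    genes <- sprintf("G%04d", seq_len(G))
    base <- exp(stats::rnorm(G, mean = log(0.8), sd = 1))
    n_marker <- min(5L, max(1L, G %/% (2L * K)))
    marker_idx <- split(seq_len(n_marker * K), rep(seq_len(K), each = n_marker))
    cluster_means <- matrix(rep(base, each = K), nrow = K,
                            dimnames = list(NULL, genes))
    for (kk in seq_len(K))
      cluster_means[kk, marker_idx[[kk]]] <- cluster_means[kk, marker_idx[[kk]]] * 8
    non_marker <- setdiff(seq_len(G), unlist(marker_idx))
    t1irg_idx <- sort(sample(non_marker, config$t1irg_set_size))
    ctrl_pool <- setdiff(non_marker, t1irg_idx)
    ctrl_idx <- sort(sample(ctrl_pool, min(73L, length(ctrl_pool))))
    labels <- rep(c("T_naive", "T_cytotoxic", "T_memory", "NK", "B_cell",
                    "Monocyte", "T_reg", "T_exhausted"), length.out = K)
    labels[config$pdc_cluster_index] <- "pDC"
    extra_innate <- setdiff(config$innate_cluster_indices,
                            config$pdc_cluster_index)
    labels[extra_innate] <- "T1IRG_monocyte"
    labels <- make.unique(labels, sep = "_")
    list(genes = genes, cluster_means = cluster_means,
         marker_genes = lapply(marker_idx, function(i) genes[i]),
         t1irg_genes = genes[t1irg_idx], control_genes = genes[ctrl_idx],
         cluster_labels = stats::setNames(labels, seq_len(K)))
  })
}

#' Simulate paired pre/post single-cell expression for one patient
#'
#' Cluster proportions are drawn once per patient from the Dirichlet prior;
#' for responders the pDC-like cluster's post-treatment proportion is
#' multiplied by `2^(pdc_shift * strength)` and the proportions renormalized.
#' Counts are negative binomial around cluster-specific gene means. In
#' responder post-treatment samples, planted-module genes in the designated
#' innate clusters have means multiplied by `2^(t1irg_effect * strength)`, and
#' every gene receives a random log2FC with scale
#' `disturbance_sd * strength`.
#'
#' @inheritParams simulate_repertoire_pair
#' @return List with sparse cell-by-gene count matrices `pre` and `post`
#'   (`dgCMatrix`, cells in rows), a `meta` data.frame (`cell_id`,
#'   `patient_id`, `timepoint`, `cluster_id`) covering both timepoints, and
#'   `structure`, the cohort-level gene/cluster structure.
#' @export
simulate_expression_pair <- function(config, patient_index, responder,
                                     strength = 1) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_clusters < 2) stop("need at least 2 clusters", call. = FALSE)
  if (config$cells_per_sample < config$n_clusters)
    stop("'cells_per_sample' must be at least 'n_clusters'", call. = FALSE)
  st <- make_expression_structure(config)
  K <- config$n_clusters
  pid <- sprintf("P%02d", patient_index)

  props <- with_seed(substream_seed(config$seed, patient_index, 3L), {
    g <- stats::rgamma(K, shape = config$baseline_dirichlet, rate = 1)
    base <- g / sum(g)
    post <- base
    if (isTRUE(responder) && config$pdc_shift != 0) {
      post[config$pdc_cluster_index] <-
        post[config$pdc_cluster_index] * 2^(config$pdc_shift * strength)
      post <- post / sum(post)
    }
    list(pre = base, post = post)
  })

  draw <- function(tp, prop, mod, stage) {
    with_seed(substream_seed(config$seed, patient_index, stage), {
      ncell <- config$cells_per_sample
      ccounts <- drop(stats::rmultinom(1L, ncell, prop))
      cl <- rep(seq_len(K), ccounts)
      mu <- (st$cluster_means * mod)[cl, , drop = FALSE]
      counts <- matrix(stats::rnbinom(length(mu), size = 1 / config$nb_dispersion,
                                      mu = as.vector(mu)),
                       nrow = nrow(mu))
      ids <- sprintf("%s_%s_%04d", pid, tp, seq_len(ncell))
      dimnames(counts) <- list(ids, st$genes)
      list(mat = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
           meta = data.frame(cell_id = ids, patient_id = pid, timepoint = tp,
                             cluster_id = cl, stringsAsFactors = FALSE))
    })
  }

  mod_pre <- matrix(1, K, config$n_genes)
  mod_post <- mod_pre
  if (isTRUE(responder)) {
    if (config$disturbance_sd > 0) {
      delta <- with_seed(substream_seed(config$seed, patient_index, 6L),
                         stats::rnorm(config$n_genes, 0,
                                      config$disturbance_sd * strength))
      mod_post <- mod_post * rep(2^delta, each = K)
    }
    if (config$t1irg_effect != 0) {
      t1 <- match(st$t1irg_genes, st$genes)
      mod_post[config$innate_cluster_indices, t1] <-
        mod_post[config$innate_cluster_indices, t1, drop = FALSE] *
        2^(config$t1irg_effect * strength)
    }
  }
  pre <- draw("pre", props$pre, mod_pre, 4L)
  post <- draw("post", props$post, mod_post, 5L)
  list(pre = pre$mat, post = post$mat, meta = rbind(pre$meta, post$meta),
       structure = st)
}

#' Simulate a full paired cohort with ground truth
#'
#' Flags `ceiling(responder_fraction * n_patients)` patients as responders and
#' generates each patient's paired repertoire and expression data. Each
#' responder draws a strength scalar from a narrow jitter around 1; with
#' `couple_effects = TRUE` one scalar jointly scales the clonal expansion,
#' the pDC proportion shift, the planted-module effect and the disturbance
#' scale, making clonal expansion and dendritic-cell activation co-vary across
#' patients. With `couple_effects = FALSE` the expression arm receives an
#' independently permuted responder assignment and independent strengths, so
#' per-patient repertoire and expression effects are unrelated (the exchangeable
#' null used for correlation calibration); marginal effect distributions are
#' unchanged.
#'
#' @param config A [cohort_config].
#' @return List of class `cohort` with elements `patients` (per patient: id,
#'   `repertoire$pre/post`, `expression$pre/post/meta`), `ground_truth` (one
#'   row per patient: responder flag, realized expansion factor, pDC shift and
#'   module effect; planted gene ids and cluster labels as attributes),
#'   `gene_sets` (the planted module and a size-matched control set),
#'   `marker_panel` (cluster label -> marker [gene_set]) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  n_resp <- ceiling(config$responder_fraction * n)
  responder <- seq_len(n) <= n_resp
  draws <- with_seed(substream_seed(config$seed, 0L, 20L), {
    s1 <- pmax(0.2, stats::rnorm(n, 1, config$strength_jitter_sd))
    s2 <- pmax(0.2, stats::rnorm(n, 1, config$strength_jitter_sd))
    resp_expr <- responder
    if (config$couple_effects) s2 <- s1 else resp_expr <- sample(responder)
    list(s_rep = s1, s_expr = s2, resp_expr = resp_expr)
  })
  resp_expr <- draws$resp_expr
  st <- make_expression_structure(config)
  patients <- vector("list", n)
  gt <- data.frame(patient_id = sprintf("P%02d", seq_len(n)),
                   responder = responder,
                   responder_expression = resp_expr,
                   strength_repertoire = draws$s_rep,
                   strength_expression = draws$s_expr,
                   realized_expansion = ifelse(
                     responder, config$expansion_factor^draws$s_rep, 1),
                   realized_pdc_shift = ifelse(
                     resp_expr, config$pdc_shift * draws$s_expr, 0),
                   realized_t1irg_effect = ifelse(
                     resp_expr, config$t1irg_effect * draws$s_expr, 0),
                   stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    rep_pair <- simulate_repertoire_pair(config, i, responder[i],
                                         draws$s_rep[i])
    expr <- simulate_expression_pair(config, i, resp_expr[i],
                                     draws$s_expr[i])
    patients[[i]] <- list(patient_id = sprintf("P%02d", i),
                          repertoire = rep_pair,
                          expression = expr[c("pre", "post", "meta")])
  }
  attr(gt, "t1irg_gene_ids") <- st$t1irg_genes
  attr(gt, "planted_cluster_labels") <- st$cluster_labels
  gene_sets <- list(
    t1irg_response = gene_set("t1irg_response", st$t1irg_genes),
    control_inflammatory = gene_set("control_inflammatory", st$control_genes))
  marker_panel <- stats::setNames(
    lapply(seq_along(st$marker_genes), function(k)
      gene_set(unname(st$cluster_labels[k]), st$marker_genes[[k]])),
    unname(st$cluster_labels))
  structure(list(patients = patients, ground_truth = gt,
                 gene_sets = gene_sets, marker_panel = marker_panel,
                 config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients (%d responders), seed %d\n",
              length(x$patients), sum(x$ground_truth$responder),
              x$config$seed))
  invisible(x)
}
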