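# Independent brute-force recomputations used as oracles. Everything here is
# written in plain loops, deliberately sharing no code path with the package.

oracle_gini <- function(counts) {
  p <- counts / sum(counts)
  acc <- 0
  for (v in p) acc <- acc + v * v
  1 - acc
}

oracle_di_logfc <- function(counts_pre, counts_post, eps = 1e-6) {
  log2((oracle_gini(counts_post) + eps) / (oracle_gini(counts_pre) + eps))
}

# top-N mass by explicit sort on (count desc, key asc)
oracle_top_mass <- function(pre_df, post_df, n_top) {
  key <- function(df) paste(df$v_call, df$j_call, df$junction, sep = "|")
  kpost <- key(post_df)
  ord <- order(-post_df$count, kpost)
  m <- min(n_top, nrow(post_df))
  sel <- ord[seq_len(m)]
  mass_post <- sum(post_df$count[sel]) / sum(post_df$count)
  kpre <- key(pre_df)
  mass_pre <- 0
  for (k in kpost[sel]) {
    i <- which(kpre == k)
    if (length(i)) mass_pre <- mass_pre + pre_df$count[i] / sum(pre_df$count)
  }
  c(mass_pre = mass_pre, mass_post = mass_post)
}

oracle_normalize <- function(counts) {
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (i in seq_len(nrow(counts))) {
    tot <- sum(counts[i, ])
    for (j in seq_len(ncol(counts)))
      out[i, j] <- log(1 + 1e4 * counts[i, j] / tot)
  }
  out
}

oracle_colmeans <- function(mat) {
  out <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) out[j] <- sum(mat[, j]) / nrow(mat)
  names(out) <- colnames(mat)
  out
}

oracle_gene_logfc <- function(m_pre, m_post, c = 0.01) {
  used <- which(m_pre > 0 | m_post > 0)
  out <- numeric(length(used))
  for (i in seq_along(used))
    out[i] <- log2((m_post[used[i]] + c) / (m_pre[used[i]] + c))
  names(out) <- names(m_pre)[used]
  out
}

oracle_disturbance <- function(lfc) {
  acc <- 0
  for (v in lfc) acc <- acc + abs(v)
  acc / length(lfc)
}

# explicit running-sum walk tracking the max deviation
oracle_es <- function(scores, hits, p = 1) {
  N <- length(scores)
  nh <- sum(hits)
  denom <- 0
  for (i in which(hits)) denom <- denom + abs(scores[i])^p
  run <- 0
  best <- 0
  trace <- numeric(N)
  for (i in seq_len(N)) {
    if (hits[i]) {
      run <- run + (if (denom > 0) abs(scores[i])^p / denom else 1 / nh)
    } else {
      run <- run - 1 / (N - nh)
    }
    trace[i] <- run
    if (abs(run) > abs(best)) best <- run
  }
  list(es = best, running = trace)
}

# exact two-sided Spearman permutation p via recursive enumeration, an
# algorithm independent of the insertion-based matrix in the package
oracle_exact_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  r_obs <- cor(rx, ry)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  hits <- 0; total <- 0
  for (pp in perms(seq_len(n))) {
    total <- total + 1
    if (abs(cor(rx, ry[pp])) >= abs(r_obs) - 1e-12) hits <- hits + 1
  }
  hits / total
}

# small random clonotype data.frame (possibly with a distinct key per row)
rand_clone_df <- function(n, max_count = 20) {
  data.frame(
    v_call = sprintf("TRBV%d", sample(5, n, replace = TRUE)),
    j_call = sprintf("TRBJ%d", sample(3, n, replace = TRUE)),
    junction = sprintf("TGT%04dTTT", sample(9999, n)),
    count = sample(max_count, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

rand_clonotype_pair <- function(n, pid = "P01") {
  df <- rand_clone_df(n)
  pre <- df; pre$count <- sample(20, n, replace = TRUE)
  post <- df; post$count <- sample(20, n, replace = TRUE)
  list(pre = clonotype_table(pre, pid, "pre"),
       post = clonotype_table(post, pid, "post"))
}

# small config for fast cohort-level tests
small_config <- function(seed = 1, ...) {
  cohort_config(n_patients = 4, n_clones = 300, reads_per_sample = 5000,
                n_clusters = 5, cells_per_sample = 160, n_genes = 120,
                t1irg_set_size = 20, seed = seed, ...)
}
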