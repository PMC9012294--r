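make_mat <- function(counts, cells = NULL, genes = NULL) {
  m <- as.matrix(counts)
  rownames(m) <- cells %||% sprintf("c%02d", seq_len(nrow(m)))
  colnames(m) <- genes %||% sprintf("g%02d", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cp10k-log normalization follows its closed form and invariances", {
  m <- make_mat(rbind(c(10, 9990), c(0, 50)))
  norm <- normalize_cp10k_log(m)
  expect_equal(norm[1, 1], log(11), tolerance = 1e-12)
  expect_equal(norm[2, 1], 0)
  # scale invariance: doubling a cell's counts leaves its row unchanged
  m2 <- m; m2[1, ] <- m[1, ] * 2
  expect_equal(as.matrix(normalize_cp10k_log(m2))[1, ],
               as.matrix(norm)[1, ], tolerance = 1e-12)
  # zero-count cells dropped with a warning; all-zero input refused
  m3 <- rbind(m, zero = c(0, 0))
  expect_warning(n3 <- normalize_cp10k_log(m3), "zero-count")
  expect_equal(nrow(n3), 2L)
  expect_error(normalize_cp10k_log(make_mat(matrix(0, 2, 2))), "zero")
})

test_that("normalization and pseudobulk match dense brute-force recomputation", {
  set.seed(21)
  for (i in 1:30) {
    nc <- sample(4:20, 1); ng <- sample(3:15, 1)
    m <- make_mat(matrix(rpois(nc * ng, 3) + rbinom(nc * ng, 1, 0.5), nc, ng))
    m[1, ] <- m[1, ] + 1  # guarantee no zero-count cell
    keep <- rowSums(m) > 0
    m <- m[keep, , drop = FALSE]
    norm <- normalize_cp10k_log(m)
    expect_equal(as.matrix(norm), oracle_normalize(m), tolerance = 1e-10)
    meta <- data.frame(cell_id = rownames(m), patient_id = "P01",
                       timepoint = "pre", cluster_id = 1L)
    pb <- pseudobulk_mean(norm, meta, "P01", "pre", 1L, min_cells = 1)
    expect_equal(pb, oracle_colmeans(as.matrix(norm)), tolerance = 1e-10)
  }
})

test_that("cluster proportions count cells within one sample", {
  meta <- data.frame(cell_id = sprintf("c%d", 1:6), patient_id = "P01",
                     timepoint = "pre", cluster_id = c(1, 1, 1, 2, 2, 3))
  p <- cluster_proportions(meta, "P01", "pre")
  expect_equal(unname(p), c(0.5, 1 / 3, 1 / 6))
  expect_equal(sum(p), 1)
  expect_error(cluster_proportions(meta, "P01", "post"), "no cells")
  one <- meta; one$cluster_id <- 2
  expect_equal(unname(cluster_proportions(one, "P01", "pre")), 1)
})

test_that("proportion logFC uses Haldane continuity and is antisymmetric", {
  expect_equal(proportion_logfc(c(10, 90), c(40, 160)),
               c(log2((40.5 / 201) / (10.5 / 101)),
                 log2((160.5 / 201) / (90.5 / 101))), tolerance = 1e-12)
  expect_lt(abs(proportion_logfc(c(10, 90), c(40, 160))[1] - 0.954), 0.001)
  expect_equal(proportion_logfc(c(3, 7, 0), c(3, 7, 0)), rep(0, 3))
  # absent in both samples: continuity gives exactly zero
  expect_equal(proportion_logfc(c(0, 10), c(0, 25))[1],
               log2((0.5 / 26) / (0.5 / 11)) , tolerance = 1e-12)
  set.seed(22)
  a <- rpois(5, 20) + 1; b <- rpois(5, 20) + 1
  expect_equal(proportion_logfc(a, b), -proportion_logfc(b, a),
               tolerance = 1e-12)
  expect_error(proportion_logfc(c(-1, 2), c(1, 2)), "nonnegative")
})

test_that("pseudobulk_mean skips strata below min_cells", {
  m <- make_mat(matrix(5, 4, 3))
  norm <- normalize_cp10k_log(m)
  meta <- data.frame(cell_id = rownames(m), patient_id = "P01",
                     timepoint = "pre", cluster_id = c(1, 1, 1, 2))
  expect_null(pseudobulk_mean(norm, meta, "P01", "pre", 2L))
  pb <- pseudobulk_mean(norm, meta, "P01", "pre", 1L)
  expect_length(pb, 3L)
  expect_named(pb, colnames(m))
})

test_that("gene logFC detects genes and applies the pseudocount", {
  mp <- c(a = 1, b = 0, c = 2)
  mq <- c(a = 2, b = 0, c = 2)
  lfc <- gene_logfc(mp, mq)
  expect_s3_class(lfc, "cluster_logfc")
  expect_equal(lfc$genes_used, c("a", "c"))     # b undetected in both
  expect_equal(unname(lfc$logfc["a"]), log2(2.01 / 1.01), tolerance = 1e-12)
  expect_lt(abs(lfc$logfc[["a"]] - 0.9928), 1e-4)
  expect_equal(unname(lfc$logfc["c"]), 0)
  full <- gene_logfc(mp, mq, gene_universe = "all")
  expect_length(full$logfc, 3L)
  expect_error(gene_logfc(mp, mq[c(2, 1, 3)]), "aligned")
})

test_that("disturbance score is the mean absolute logFC", {
  mp <- c(a = 1, b = 1, c = 1)
  mq <- c(a = 1, b = 1, c = 1)
  expect_equal(disturbance_score(gene_logfc(mp, mq))$score, 0)
  # engineered vector (1, -1, 0): post/pre ratios 2^1, 2^-1, 2^0 (eps-free)
  lfc <- gene_logfc(c(a = 1, b = 1, c = 1) - 0.01,
                    c(a = 2, b = 0.5, c = 1) * 1 - 0.01)
  expect_equal(disturbance_score(lfc)$score, 2 / 3, tolerance = 1e-12)
  set.seed(23)
  for (i in 1:20) {
    mp <- setNames(runif(8, 0.1, 3), letters[1:8])
    mq <- setNames(runif(8, 0.1, 3), letters[1:8])
    lfc <- gene_logfc(mp, mq)
    expect_equal(disturbance_score(lfc)$score, oracle_disturbance(lfc$logfc),
                 tolerance = 1e-12)
    expect_equal(unname(lfc$logfc), oracle_gene_logfc(mp, mq),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("pathway mean score averages present set genes per cell", {
  m <- make_mat(matrix(c(0, 4, 8, 2, 0, 6), 3, 2), genes = c("gA", "gB"))
  norm <- normalize_cp10k_log(m)
  # set covering all genes equals the per-cell mean
  sc <- pathway_mean_score(norm, gene_set("all", c("gA", "gB")))
  expect_equal(unname(sc), unname(rowMeans(as.matrix(norm))), tolerance = 1e-12)
  # absent genes tallied, fully absent set refused
  expect_warning(one <- pathway_mean_score(norm, gene_set("s", c("gA", "gX"))),
                 "1 gene")
  expect_equal(unname(one), unname(as.matrix(norm)[, "gA"]))
  expect_error(pathway_mean_score(norm, gene_set("s", "gZ")), "no gene")
  # a cell with zero counts in all set genes scores zero
  expect_equal(unname(sc[1]), mean(oracle_normalize(m)[1, ]))
})

test_that("marker panels annotate constructed clusters perfectly", {
  # 3 clusters x 3 marker genes, each marker expressed only in its own cluster
  counts <- rbind(c(50, 1, 1, 5), c(50, 1, 1, 5),
                  c(1, 50, 1, 5), c(1, 50, 1, 5),
                  c(1, 1, 50, 5), c(1, 1, 50, 5))
  m <- make_mat(counts, genes = c("mA", "mB", "mC", "house"))
  meta <- data.frame(cell_id = rownames(m), patient_id = "P01",
                     timepoint = "pre", cluster_id = rep(1:3, each = 2))
  norm <- normalize_cp10k_log(m)
  panel <- list(alpha = gene_set("alpha", "mA"),
                beta = gene_set("beta", "mB"),
                gamma = gene_set("gamma", "mC"))
  ann <- annotate_clusters(norm, meta, panel)
  expect_equal(unname(ann$labels), c("alpha", "beta", "gamma"))
  # identical marker sets tie; the lexicographically first label wins
  panel2 <- list(zeta = gene_set("zeta", "mA"), eta = gene_set("eta", "mA"))
  ann2 <- annotate_clusters(norm, meta, panel2)
  expect_equal(unname(ann2$labels[1]), "eta")
  expect_error(annotate_clusters(norm, meta, list(q = gene_set("q", "gX"))),
               "no gene")
})
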