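test_that("read_clonotypes merges duplicate identity keys and filters bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "v_call\tj_call\tjunction\tduplicate_count",
    "TRBV1\tTRBJ1\tTGTGCA\t3",
    "TRBV1\tTRBJ1\tTGTGCA\t2",
    "TRBV2\tTRBJ1\tTGTCCA\t7",
    "TRBV3\tTRBJ2\t\t4",
    "TRBV4\tTRBJ2\tTGTAAA\tNA"), path)
  expect_warning(tab <- read_clonotypes(path, "P01", "pre"), "2 row")
  expect_equal(nrow(tab$clones), 2L)
  merged <- tab$clones$count[tab$clones$v_call == "TRBV1"]
  expect_equal(merged, 5)
  expect_equal(sum(tab$clones$count), 12)
})

test_that("read_clonotypes reports missing required columns by name", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("v_call\tj_call\tjunction", "TRBV1\tTRBJ1\tTGT"), path)
  expect_error(read_clonotypes(path, "P01", "pre"), "duplicate_count")
})

test_that("a well-formed file round-trips with totals preserved", {
  df <- rand_clone_df(3)
  tab0 <- clonotype_table(df, "P02", "post")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clonotypes(tab0, path)
  tab <- read_clonotypes(path, "P02", "post")
  expect_equal(nrow(tab$clones), 3L)
  expect_equal(sum(tab$clones$count), sum(df$count))
})

test_that("clone_proportions normalizes counts and rejects empty repertoires", {
  df <- rand_clone_df(3)
  df$count <- c(5, 3, 2)
  p <- clone_proportions(clonotype_table(df, "P01", "pre"))
  expect_equal(unname(sort(p, decreasing = TRUE)), c(0.5, 0.3, 0.2))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  df$count <- c(0, 0, 0)
  expect_error(clone_proportions(clonotype_table(df, "P01", "pre")), "zero")
})

test_that("simpson_di matches closed forms on uniform and monoclonal inputs", {
  expect_equal(simpson_di(rep(0.25, 4)), 0.75)
  expect_equal(simpson_di(1), 0)
  expect_equal(simpson_di(c(0.5, 0.3, 0.2)), 0.62)
  expect_equal(simpson_di(rep(0.25, 4), "inverse_simpson"), 4)
  expect_equal(simpson_di(c(0.5, 0.5), "simpson_concentration"), 0.5)
  expect_error(simpson_di(numeric(0)), "empty")
  expect_error(simpson_di(c(0.5, 0.2)), "sum to 1")
})

test_that("simpson_di is permutation-invariant and maximal at uniformity", {
  set.seed(11)
  for (i in 1:25) {
    K <- sample(2:5, 1)
    p <- as.vector(rmultinom(1, 50, rgamma(K, 1)))
    p <- p[p > 0] / sum(p[p > 0])
    expect_equal(simpson_di(p), simpson_di(sample(p)))
    expect_lte(simpson_di(p), simpson_di(rep(1 / length(p), length(p))) + 1e-12)
  }
})

test_that("gini-Simpson agrees with vegan and merging clones never raises it", {
  skip_if_not_installed("vegan")
  set.seed(12)
  for (i in 1:50) {
    counts <- sample(30, sample(2:12, 1), replace = TRUE)
    expect_equal(simpson_di(counts / sum(counts)),
                 unname(vegan::diversity(counts, index = "simpson")),
                 tolerance = 1e-12)
    # merge two random clones
    j <- sample(length(counts), 2)
    merged <- c(counts[-j], sum(counts[j]))
    expect_lte(simpson_di(merged / sum(merged)),
               simpson_di(counts / sum(counts)) + 1e-12)
  }
})

test_that("di_logfc follows the log2-ratio definition with epsilon guard", {
  # pre: 5 equal clones, gini DI 0.8; post: counts (3,1), gini DI 0.375
  pre_df <- rand_clone_df(5); pre_df$count <- rep(2, 5)
  post_df <- rand_clone_df(2); post_df$count <- c(3, 1)
  pre <- clonotype_table(pre_df, "P01", "pre")
  post <- clonotype_table(post_df, "P01", "post")
  rec <- di_logfc(pre, post)
  expect_s3_class(rec, "diversity_record")
  expect_equal(rec$di_pre, 0.8)
  expect_equal(rec$di_post, 0.375)
  expect_equal(rec$di_logfc, log2((0.375 + 1e-6) / (0.8 + 1e-6)),
               tolerance = 1e-12)
  expect_true(rec$expansion)
  expect_equal(rec$variant, "gini_simpson")

  # identical repertoires: exactly zero
  rec0 <- di_logfc(pre, clonotype_table(pre_df, "P01", "post"))
  expect_equal(rec0$di_logfc, 0)

  # monoclonal post (DI 0) against DI 0.5 pre: epsilon keeps it finite
  half <- rand_clone_df(2); half$count <- c(1, 1)
  mono <- rand_clone_df(1); mono$count <- 9
  rec_m <- di_logfc(clonotype_table(half, "P01", "pre"),
                    clonotype_table(mono, "P01", "post"))
  expect_equal(rec_m$di_logfc, log2(1e-6 / 0.500001), tolerance = 1e-4)
  expect_lt(abs(rec_m$di_logfc - (-18.93)), 0.01)

  # mismatched patients refuse to pair
  other <- clonotype_table(post_df, "P99", "post")
  expect_error(di_logfc(pre, other), "patient")
})

test_that("di_logfc is antisymmetric under pre/post swap", {
  set.seed(13)
  for (i in 1:20) {
    pair <- rand_clonotype_pair(sample(3:10, 1))
    a <- di_logfc(pair$pre, pair$post, epsilon = 0)$di_logfc
    swapped <- di_logfc(
      clonotype_table(pair$post$clones, "P01", "pre"),
      clonotype_table(pair$pre$clones, "P01", "post"), epsilon = 0)$di_logfc
    expect_equal(a, -swapped, tolerance = 1e-12)
  }
})

test_that("top_clone_mass ranks by post abundance and sums paired proportions", {
  post_df <- data.frame(v_call = "TRBV1", j_call = "TRBJ1",
                        junction = c("TGTA", "TGTB", "TGTC"),
                        count = c(5, 3, 2), stringsAsFactors = FALSE)
  pre_df <- post_df; pre_df$count <- c(1, 1, 8)
  pre <- clonotype_table(pre_df, "P01", "pre")
  post <- clonotype_table(post_df, "P01", "post")
  prof <- top_clone_mass(pre, post, 2)
  expect_equal(prof$mass_post, 0.8)
  expect_equal(prof$mass_pre, 0.2)
  expect_equal(nrow(prof$clones), 2L)

  # n_top beyond the repertoire covers everything
  all_prof <- top_clone_mass(pre, post, 100)
  expect_equal(all_prof$mass_post, 1)
  # identical tables give equal masses
  same <- top_clone_mass(clonotype_table(post_df, "P01", "pre"),
                         clonotype_table(post_df, "P01", "post"), 2)
  expect_equal(same$mass_pre, same$mass_post)
  expect_error(top_clone_mass(pre, post, 0), "n_top")
})

test_that("top_clone_mass is monotone in n_top and deterministic under ties", {
  set.seed(14)
  pair <- rand_clonotype_pair(15)
  masses <- vapply(1:15, function(k)
    top_clone_mass(pair$pre, pair$post, k)$mass_post, numeric(1))
  expect_true(all(diff(masses) >= -1e-12))
  expect_equal(masses[15], 1)
  # tie-break: all-equal counts rank lexicographically by identity key
  df <- rand_clone_df(6); df$count <- rep(4, 6)
  tab_pre <- clonotype_table(df, "P01", "pre")
  tab_post <- clonotype_table(df, "P01", "post")
  keys <- top_clone_mass(tab_pre, tab_post, 3)$top_clone_keys
  expect_equal(keys, sort(paste(df$v_call, df$j_call, df$junction,
                                sep = "|"))[1:3])
})

test_that("repertoire statistics match brute-force recomputation", {
  set.seed(15)
  for (i in 1:100) {
    pair <- rand_clonotype_pair(sample(3:12, 1))
    cp <- pair$pre$clones$count
    cq <- pair$post$clones$count
    expect_equal(simpson_di(clone_proportions(pair$pre)), oracle_gini(cp),
                 tolerance = 1e-12)
    expect_equal(di_logfc(pair$pre, pair$post)$di_logfc,
                 oracle_di_logfc(cp, cq), tolerance = 1e-12)
    k <- sample(12, 1)
    prof <- top_clone_mass(pair$pre, pair$post, k)
    om <- oracle_top_mass(pair$pre$clones, pair$post$clones, k)
    expect_equal(prof$mass_pre, unname(om["mass_pre"]), tolerance = 1e-12)
    expect_equal(prof$mass_post, unname(om["mass_post"]), tolerance = 1e-12)
  }
})
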