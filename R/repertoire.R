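#' Clonotype table
#'
#' A TCR repertoire for one patient and timepoint: unique clonotypes (identity
#' key = V gene, J gene, junction nucleotide sequence) with abundance counts,
#' as extracted from an AIRR Rearrangement table.
#'
#' @param clones data.frame with columns `v_call`, `j_call`, `junction`,
#'   optional `junction_aa`, and `count` (nonnegative integers).
#' @param patient_id Patient identifier.
#' @param timepoint `"pre"` or `"post"`.
#' @param chain `"TRB"` (default) or `"TRA"`.
#' @return An object of class `clonotype_table`.
#' @export
clonotype_table <- function(clones, patient_id, timepoint, chain = "TRB") {
  timepoint <- match.arg(timepoint, c("pre", "post"))
  chain <- match.arg(chain, c("TRB", "TRA"))
  req <- c("v_call", "j_call", "junction", "count")
  miss <- setdiff(req, names(clones))
  if (length(miss))
    stop("clonotype table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(is.na(clones$count)) || any(clones$count < 0))
    stop("clone counts must be nonnegative", call. = FALSE)
  if (any(is.na(clones$junction)) || any(!nzchar(clones$junction)))
    stop("junction sequences must be nonempty", call. = FALSE)
  key <- clone_key(clones)
  if (anyDuplicated(key))
    stop("duplicate clonotype identity keys (v_call, j_call, junction)",
         call. = FALSE)
  if (!"junction_aa" %in% names(clones)) clones$junction_aa <- NA_character_
  clones <- clones[, c("v_call", "j_call", "junction", "junction_aa", "count")]
  rownames(clones) <- NULL
  structure(list(patient_id = as.character(patient_id), timepoint = timepoint,
                 chain = chain, clones = clones),
            class = "clonotype_table")
}

clone_key <- function(clones) {
  paste(clones$v_call, clones$j_call, clones$junction, sep = "|")
}

#' @export
print.clonotype_table <- function(x, ...) {
  cat(sprintf("<clonotype_table> %s %s %s: %d clones, %d reads\n",
              x$patient_id, x$timepoint, x$chain, nrow(x$clones),
              sum(x$clones$count)))
  invisible(x)
}

#' Read an AIRR Rearrangement TSV into a clonotype table
#'
#' Requires columns `v_call`, `j_call`, `junction`, `duplicate_count`. Rows
#' with a missing junction or count are dropped (with a warning giving the
#' tally); rows sharing an identity key are merged by summing their counts.
#'
#' @param path Path to a tab-separated AIRR Rearrangement file.
#' @inheritParams clonotype_table
#' @return A [clonotype_table].
#' @export
read_clonotypes <- function(path, patient_id, timepoint, chain = "TRB") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  req <- c("v_call", "j_call", "junction", "duplicate_count")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("AIRR file lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  count <- suppressWarnings(as.numeric(raw$duplicate_count))
  bad <- is.na(count) | is.na(raw$junction) | !nzchar(trimws(raw$junction))
  if (any(bad))
    warning(sum(bad), " row(s) with missing junction or count dropped from ",
            basename(path), call. = FALSE)
  raw <- raw[!bad, , drop = FALSE]
  count <- count[!bad]
  if (!nrow(raw))
    stop("no usable clonotype rows in ", path, call. = FALSE)
  key <- paste(raw$v_call, raw$j_call, raw$junction, sep = "|")
  agg <- rowsum(count, group = key)
  first <- !duplicated(key)
  clones <- data.frame(v_call = raw$v_call[first], j_call = raw$j_call[first],
                       junction = raw$junction[first],
                       count = agg[match(key[first], rownames(agg)), 1],
                       stringsAsFactors = FALSE)
  if ("junction_aa" %in% names(raw)) clones$junction_aa <- raw$junction_aa[first]
  clonotype_table(clones, patient_id, timepoint, chain)
}

#' Clone proportions of a repertoire
#'
#' @param table A [clonotype_table] with positive total count.
#' @return Numeric vector of clone proportions (sums to 1), named by identity
#'   key.
#' @export
clone_proportions <- function(table) {
  stopifnot(inherits(table, "clonotype_table"))
  total <- sum(table$clones$count)
  if (total <= 0) stop("total clone count is zero", call. = FALSE)
  p <- table$clones$count / total
  names(p) <- clone_key(table$clones)
  p
}

#' Simpson diversity index
#'
#' From the clone-proportion concentration `lambda = sum(p^2)` returns one of
#' three variants: `gini_simpson` (`1 - lambda`, the default; high values mean
#' an even repertoire, low values clonal expansion), `inverse_simpson`
#' (`1 / lambda`) or `simpson_concentration` (`lambda` itself).
#'
#' @param p Proportion vector summing to 1.
#' @param variant Index variant; see above.
#' @return A single number.
#' @examples
#' simpson_di(rep(0.25, 4))                      # 0.75
#' simpson_di(rep(0.25, 4), "inverse_simpson")   # 4
#' @export
simpson_di <- function(p, variant = c("gini_simpson", "inverse_simpson",
                                      "simpson_concentration")) {
  variant <- match.arg(variant)
  if (!length(p)) stop("empty proportion vector", call. = FALSE)
  if (any(p < 0)) stop("proportions must be nonnegative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8)
    stop("proportions must sum to 1", call. = FALSE)
  lambda <- sum(p^2)
  switch(variant,
         gini_simpson = 1 - lambda,
         inverse_simpson = 1 / lambda,
         simpson_concentration = lambda)
}

#' Diversity log fold change between paired repertoires
#'
#' Computes the Simpson diversity of the pre- and post-treatment repertoires
#' and their log2 ratio `log2((DI_post + epsilon) / (DI_pre + epsilon))`.
#' Negative values indicate post-treatment clonal expansion (for the
#' diversity-oriented variants).
#'
#' @param pre,post [clonotype_table]s for the same patient and chain.
#' @param variant Simpson variant, see [simpson_di()].
#' @param epsilon Guard added to both indices before the ratio, protecting
#'   monoclonal repertoires (gini-Simpson DI of 0). Default `1e-6`.
#' @return One-row data.frame (class `diversity_record`) with columns
#'   `patient_id`, `chain`, `di_pre`, `di_post`, `di_logfc`, `variant`,
#'   `expansion` (logical, `di_logfc < 0`).
#' @export
di_logfc <- function(pre, post, variant = "gini_simpson", epsilon = 1e-6) {
  stopifnot(inherits(pre, "clonotype_table"), inherits(post, "clonotype_table"))
  if (pre$patient_id != post$patient_id || pre$chain != post$chain)
    stop("pre and post tables must share patient_id and chain", call. = FALSE)
  if (epsilon < 0) stop("'epsilon' must be nonnegative", call. = FALSE)
  d_pre <- simpson_di(clone_proportions(pre), variant)
  d_post <- simpson_di(clone_proportions(post), variant)
  lf <- log2((d_post + epsilon) / (d_pre + epsilon))
  out <- data.frame(patient_id = pre$patient_id, chain = pre$chain,
                    di_pre = d_pre, di_post = d_post, di_logfc = lf,
                    variant = variant, expansion = lf < 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("diversity_record", "data.frame")
  out
}

#' Top-clone expansion profile
#'
#' Ranks post-treatment clones by abundance (ties broken by identity key) and
#' reports the summed repertoire proportion of the top `n_top` clones after
#' treatment (`mass_post`) and of the same clonotypes before treatment
#' (`mass_pre`; clones absent pre-treatment contribute 0).
#'
#' @param pre,post [clonotype_table]s for the same patient and chain.
#' @param n_top Number of top post-treatment clones to track (default 200).
#' @return An object of class `expansion_profile`: list with `patient_id`,
#'   `chain`, `n_top`, `top_clone_keys`, `mass_pre`, `mass_post` and a
#'   per-clone data.frame `clones` (`key`, `prop_pre`, `prop_post`).
#' @export
top_clone_mass <- function(pre, post, n_top = 200) {
  stopifnot(inherits(pre, "clonotype_table"), inherits(post, "clonotype_table"))
  if (pre$patient_id != post$patient_id || pre$chain != post$chain)
    stop("pre and post tables must share patient_id and chain", call. = FALSE)
  if (!is.numeric(n_top) || length(n_top) != 1L || n_top < 1)
    stop("'n_top' must be a positive integer", call. = FALSE)
  p_post <- clone_proportions(post)
  p_pre <- clone_proportions(pre)
  key_post <- names(p_post)
  ord <- order(-post$clones$count, key_post)
  m <- min(floor(n_top), length(ord))
  top <- ord[seq_len(m)]
  keys <- key_post[top]
  prop_pre <- unname(p_pre[match(keys, names(p_pre))])
  prop_pre[is.na(prop_pre)] <- 0
  structure(list(patient_id = post$patient_id, chain = post$chain,
                 n_top = as.integer(n_top), top_clone_keys = keys,
                 mass_pre = sum(prop_pre), mass_post = sum(p_post[top]),
                 clones = data.frame(key = keys, prop_pre = prop_pre,
                                     prop_post = unname(p_post[top]),
                                     stringsAsFactors = FALSE)),
            class = "expansion_profile")
}

#' @export
print.expansion_profile <- function(x, ...) {
  cat(sprintf(
    "<expansion_profile> %s %s: top %d clones hold %.1f%% post vs %.1f%% pre\n",
    x$patient_id, x$chain, length(x$top_clone_keys),
    100 * x$mass_post, 100 * x$mass_pre))
  invisible(x)
}
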