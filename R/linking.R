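# linking repertoire expansion to innate activation: Spearman correlation
# with exact small-n permutation inference, and the DI-ordered signature panel

# All n! permutations of 1..n as an integer matrix (insertion construction).
# n = 9 gives 362,880 rows, the largest size used by the exact method.
# Cached per n: repeated exact calls (replicated cohorts) reuse the matrix.
.perm_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  out <- all_permutations_impl(n)
  if (n <= 9) .perm_cache[[key]] <- out
  out
}

all_permutations_impl <- function(n) {
  out <- matrix(1L, 1L, 1L)
  if (n == 1L) return(out)
  for (k in 2L:n) {
    m <- nrow(out)
    blocks <- vector("list", k)
    for (pos in seq_len(k)) {
      left <- out[, seq_len(pos - 1L), drop = FALSE]
      right <- if (pos <= k - 1L) out[, pos:(k - 1L), drop = FALSE]
               else matrix(integer(), m, 0L)
      blocks[[pos]] <- cbind(left, matrix(k, m, 1L), right)
    }
    out <- do.call(rbind, blocks)
  }
  out
}

#' Spearman correlation with exact permutation inference
#'
#' Computes the Spearman coefficient as the Pearson correlation of (average,
#' for ties) ranks. The two-sided p-value is obtained either by exact
#' enumeration of all `n!` rank permutations (counting `|r| >= |r_obs|`), the
#' default whenever `n <= 9`, or by the t approximation with `n - 2` degrees
#' of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, neither constant.
#' @param method `"auto"` (exact for `n <= 9`), `"exact"` or `"approx"`.
#' @return One-row data.frame (class `correlation_result`) with `r`,
#'   `p_value`, `n`, `method`.
#' @examples
#' spearman_cor(1:5, c(5, 4, 3, 2, 1))  # r = -1, exact p = 1/60
#' @export
spearman_cor <- function(x, y, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("constant input vector", call. = FALSE)
  r <- stats::cor(rx, ry)
  if (method == "auto") method <- if (n <= 9) "exact" else "approx"
  if (method == "exact") {
    if (n > 9)
      stop("exact enumeration supported only for n <= 9", call. = FALSE)
    P <- all_permutations(n)
    cx <- rx - mean(rx)
    cy <- ry - mean(ry)
    denom <- sqrt(sum(cx^2) * sum(cy^2))
    rv <- as.vector(matrix(ry[P], nrow(P), n) %*% cx) / denom
    p <- mean(abs(rv) >= abs(r) - 1e-12)
    used <- "exact_permutation"
  } else {
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- max(2 * stats::pt(-abs(tt), df = n - 2), .Machine$double.xmin)
    used <- "t_approximation"
  }
  out <- data.frame(r = r, p_value = p, n = n, method = used,
                    stringsAsFactors = FALSE)
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Correlate clonal expansion with innate activation across patients
#'
#' Spearman correlation of per-patient diversity log fold change against a
#' per-patient activation scalar (e.g. pDC proportion logFC or pDC
#' disturbance score) on the patients present, with finite values, in both
#' inputs. Patients missing either value are excluded and reported via a
#' message. Exact permutation inference is used for `n <= 9` (method
#' `"auto"`).
#'
#' @param diversity data.frame with `patient_id` and `di_logfc` (e.g. rbound
#'   [di_logfc()] records).
#' @param activation data.frame with `patient_id` and `value`.
#' @param method Passed to [spearman_cor()].
#' @return A `correlation_result` with the matched patient ids attached as
#'   attribute `"patients"`.
#' @export
correlate_expansion_with_activation <- function(diversity, activation,
                                                method = "auto") {
  if (!all(c("patient_id", "di_logfc") %in% names(diversity)))
    stop("'diversity' needs columns patient_id, di_logfc", call. = FALSE)
  if (!all(c("patient_id", "value") %in% names(activation)))
    stop("'activation' needs columns patient_id, value", call. = FALSE)
  merged <- merge(diversity[, c("patient_id", "di_logfc")],
                  activation[, c("patient_id", "value")], by = "patient_id")
  ok <- is.finite(merged$di_logfc) & is.finite(merged$value)
  excluded <- setdiff(unique(c(diversity$patient_id, activation$patient_id)),
                      merged$patient_id[ok])
  if (length(excluded))
    message("excluded ", length(excluded), " patient(s) without both values: ",
            paste(excluded, collapse = ", "))
  merged <- merged[ok, , drop = FALSE]
  if (nrow(merged) < 3)
    stop("fewer than 3 matched patients", call. = FALSE)
  res <- spearman_cor(merged$di_logfc, merged$value, method = method)
  attr(res, "patients") <- merged$patient_id
  res
}

#' DI-ordered gene-panel signature matrix
#'
#' Restricts a genes-by-patients statistic matrix (by default a per-patient
#' cross-cluster mean gene logFC) to a marker panel, orders patient columns by
#' increasing diversity logFC, and computes each gene's Spearman correlation
#' against the diversity logFC. Negative correlations mark genes tracking
#' clonal expansion.
#'
#' @param stat_matrix Numeric matrix, genes in rows, patients in columns.
#' @param diversity data.frame with `patient_id`, `di_logfc`.
#' @param panel A [gene_set] of panel genes; at least one must be present.
#' @return Object of class `signature_matrix`: list with `matrix` (panel genes
#'   x DI-ordered patients), `patient_order`, `di_logfc` (sorted), `gene_r`.
#' @export
signature_panel <- function(stat_matrix, diversity, panel) {
  stopifnot(inherits(panel, "gene_set"))
  genes <- intersect(panel$genes, rownames(stat_matrix))
  if (!length(genes))
    stop("no panel gene present in the statistic matrix", call. = FALSE)
  patients <- intersect(colnames(stat_matrix), diversity$patient_id)
  if (length(patients) < 3)
    stop("fewer than 3 patients shared between matrix and diversity records",
         call. = FALSE)
  dlf <- diversity$di_logfc[match(patients, diversity$patient_id)]
  ord <- order(dlf)
  patients <- patients[ord]
  dlf <- dlf[ord]
  sub <- stat_matrix[genes, patients, drop = FALSE]
  gene_r <- apply(sub, 1, function(v) {
    if (anyNA(v) || stats::var(v) == 0) return(NA_real_)
    stats::cor(rank(v), rank(dlf))
  })
  structure(list(matrix = sub, patient_order = patients, di_logfc = dlf,
                 gene_r = gene_r),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix> %d genes x %d patients (DI-ordered); %d/%d genes with r < 0\n",
              nrow(x$matrix), ncol(x$matrix),
              sum(x$gene_r < 0, na.rm = TRUE), length(x$gene_r)))
  invisible(x)
}
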