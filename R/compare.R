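# Cross-method comparison of abundance profiles and pairwise
# between-subject metacluster correlations.

#' Collapse several genus rows into one family row
#'
#' Used to merge genera whose assignment differs between methods (e.g.
#' the Enterobacteriaceae genera) before comparing matrices.  Member
#' genera absent from the matrix are treated as zero rows.
#'
#' @param mat feature x subject matrix.
#' @param family_name name of the new family row.
#' @param member_genera genera to collapse.
#' @return matrix with member rows replaced by their element-wise sum.
#' @export
merge_family <- function(mat, family_name, member_genera) {
  if (family_name %in% setdiff(rownames(mat), member_genera))
    stopf("row '%s' already exists and is not a member genus", family_name)
  present <- intersect(member_genera, rownames(mat))
  fam_row <- if (length(present))
    colSums(mat[present, , drop = FALSE])
  else stats::setNames(numeric(ncol(mat)), colnames(mat))
  keep <- !(rownames(mat) %in% c(member_genera, family_name))
  out <- rbind(unclass(mat)[keep, , drop = FALSE], matrix(
    fam_row, nrow = 1, dimnames = list(family_name, colnames(mat))))
  method <- attr(mat, "method")
  if (!is.null(method)) out <- abundance_matrix(out, method)
  out
}

correlation_result <- function(rho, r, n, pair = NA_character_) {
  structure(list(pair = pair, spearman_rho = rho, pearson_r = r,
                 r_squared = r^2, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation (%s): Spearman rho = %.3f, Pearson r = %.3f (r^2 = %.3f), n = %d\n",
              x$pair, x$spearman_rho, x$pearson_r, x$r_squared, x$n))
  invisible(x)
}

#' Correlate two abundance matrices across methods
#'
#' Aligns the matrices on their shared subjects and the union of their
#' feature rows (features missing from one method enter as zeros),
#' flattens the aligned taxon x subject cells into paired vectors and
#' returns Spearman (average ranks for ties) and Pearson coefficients.
#'
#' @param a,b feature x subject matrices (e.g. proteomics spectral
#'   counts and 16S read counts).
#' @return \code{correlation_result}.
#' @export
cross_method_correlation <- function(a, b) {
  subjects <- intersect(colnames(a), colnames(b))
  if (!length(subjects)) stopf("matrices share no subjects")
  feats <- sort(union(rownames(a), rownames(b)))
  pad <- function(m) {
    out <- matrix(0, nrow = length(feats), ncol = length(subjects),
                  dimnames = list(feats, subjects))
    common <- intersect(rownames(m), feats)
    out[common, ] <- m[common, subjects, drop = FALSE]
    out
  }
  x <- as.vector(pad(a))
  y <- as.vector(pad(b))
  if (length(x) < 3) stopf("fewer than 3 paired cells")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("correlation undefined: one matrix is constant")
  correlation_result(
    rho = stats::cor(x, y, method = "spearman"),
    r = stats::cor(x, y, method = "pearson"),
    n = length(x),
    pair = paste(attr(a, "method") %||% "a",
                 attr(b, "method") %||% "b", sep = " vs "))
}

#' Pairwise metacluster correlation between two subjects
#'
#' Pearson correlation of metacluster spectral counts over the union
#' support — metaclusters detected in at least one of the two subjects.
#'
#' @param counts metacluster x subject count matrix.
#' @param subject_a,subject_b subject ids (columns of \code{counts}).
#' @param log1p correlate \code{log1p}-transformed counts instead of raw
#'   counts.
#' @return \code{correlation_result} (Spearman included for reference).
#' @export
pairwise_metacluster_correlation <- function(counts, subject_a, subject_b,
                                             log1p = FALSE) {
  for (s in c(subject_a, subject_b))
    if (!s %in% colnames(counts)) stopf("unknown subject: %s", s)
  x <- counts[, subject_a]
  y <- counts[, subject_b]
  support <- x > 0 | y > 0
  if (sum(support) < 3)
    stopf("fewer than 3 metaclusters detected in subjects %s/%s",
          subject_a, subject_b)
  x <- x[support]; y <- y[support]
  if (log1p) { x <- log1p(x); y <- log1p(y) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("correlation undefined: constant counts in the union support")
  correlation_result(
    rho = stats::cor(x, y, method = "spearman"),
    r = stats::cor(x, y, method = "pearson"),
    n = sum(support),
    pair = paste(subject_a, subject_b, sep = " vs "))
}

#' Order a matrix for heat-map display
#'
#' Keeps the \code{top_k} features by total count, sums the remainder
#' into an \code{"unknown/others"} row, and bins values into tertiles
#' (low/medium/high) computed over the positive cells.
#'
#' @param mat feature x subject matrix.
#' @param top_k number of features to keep (>= 1).
#' @return list: \code{matrix} (top_k + others row), \code{bins}
#'   (character matrix: "zero"/"low"/"medium"/"high") and \code{breaks}
#'   (the two tertile cut points).
#' @export
heatmap_matrix <- function(mat, top_k = 12L) {
  if (top_k < 1) stopf("top_k must be >= 1")
  ord <- order(rowSums(mat), decreasing = TRUE)
  keep <- ord[seq_len(min(top_k, nrow(mat)))]
  rest <- setdiff(seq_len(nrow(mat)), keep)
  others <- if (length(rest))
    colSums(mat[rest, , drop = FALSE]) else numeric(ncol(mat))
  out <- rbind(mat[keep, , drop = FALSE],
               matrix(others, nrow = 1,
                      dimnames = list("unknown/others", colnames(mat))))
  pos <- out[out > 0]
  breaks <- if (length(pos)) unname(stats::quantile(pos, c(1, 2) / 3))
  else c(NA_real_, NA_real_)
  bins <- matrix("zero", nrow(out), ncol(out), dimnames = dimnames(out))
  if (length(pos)) {
    bins[out > 0] <- "low"
    bins[out > breaks[1]] <- "medium"
    bins[out > breaks[2]] <- "high"
  }
  list(matrix = out, bins = bins, breaks = breaks)
}
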