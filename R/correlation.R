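# Pearson correlation screening between taste and odor variables, plus
# hierarchical clustering support for heatmap layouts.

#' Pairwise Pearson correlations with significance flags
#'
#' All pairwise correlations between the columns of `A` and `B` over matched
#' observations, with two-sided p-values from the t-distribution with n - 2
#' degrees of freedom and the conventional star flags (`significant` at
#' p < 0.05, `highly_significant` at p < 0.01). Sample (n - 1) variance is
#' used inside r. Zero-variance columns are excluded and reported rather
#' than yielding NaN.
#'
#' @param A,B numeric matrices or data.frames with the same number of rows
#'   (observations). `B` defaults to `A`.
#' @param p_adjust `"none"` (default, mirroring the raw-p star convention of
#'   the source analyses) or `"BH"` for Benjamini-Hochberg adjustment of the
#'   flags (raw p-values stay in `p`, adjusted ones in `p_adj`).
#' @return object of class `correlation_result`: a long data.frame `var1`,
#'   `var2`, `r`, `p`, `n`, `flag`, with excluded column names in
#'   `attr(, "excluded")`.
#' @export
pearson_matrix <- function(A, B = A, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B))
    stop("pearson_matrix: A and B need matched observations", call. = FALSE)
  n <- nrow(A)
  if (n < 3)
    stop("pearson_matrix: need at least 3 observations", call. = FALSE)
  if (is.null(colnames(A))) colnames(A) <- paste0("A", seq_len(ncol(A)))
  if (is.null(colnames(B))) colnames(B) <- paste0("B", seq_len(ncol(B)))
  const_a <- apply(A, 2, stats::sd) == 0
  const_b <- apply(B, 2, stats::sd) == 0
  excluded <- c(colnames(A)[const_a], colnames(B)[const_b])
  A <- A[, !const_a, drop = FALSE]; B <- B[, !const_b, drop = FALSE]
  r <- stats::cor(A, B)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-15] <- 0
  out <- data.frame(var1 = rep(colnames(A), times = ncol(B)),
                    var2 = rep(colnames(B), each = ncol(A)),
                    r = as.vector(r), p = as.vector(p), n = n,
                    stringsAsFactors = FALSE)
  p_flag <- out$p
  if (p_adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    p_flag <- out$p_adj
  }
  out$flag <- ifelse(p_flag < 0.01, "highly_significant",
                     ifelse(p_flag < 0.05, "significant", "ns"))
  attr(out, "excluded") <- excluded
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Z-score the rows of a matrix
#'
#' Each row is centered and scaled to SD 1 under the population (divide by
#' n) convention, the standard preprocessing for clustered heatmaps.
#'
#' @param M numeric matrix.
#' @return matrix of the same shape, each row mean 0 and population SD 1.
#' @export
zscore_rows <- function(M) {
  M <- as.matrix(M)
  ctr <- M - rowMeans(M)
  s <- sqrt(rowMeans(ctr^2))
  bad <- which(s == 0)
  if (length(bad) > 0)
    stop("zscore_rows: constant row(s): ",
         paste(if (is.null(rownames(M))) bad else rownames(M)[bad],
               collapse = ", "), call. = FALSE)
  ctr / s
}

#' Agglomerative hierarchical clustering
#'
#' Deterministic clustering of the rows of `M`; the leaf order is the
#' standard recursive left-to-right dendrogram traversal.
#'
#' @param M numeric matrix (rows are clustered).
#' @param metric `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @param linkage `"average"`, `"ward"` (Ward.D2) or `"complete"`.
#' @return object of class `cluster_layout`: `order`, `labels`, `merge`,
#'   `height`, `metric`, `linkage`, and the underlying `hclust` object.
#' @export
hierarchical_cluster <- function(M, metric = c("euclidean", "correlation"),
                                 linkage = c("average", "ward", "complete")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  M <- as.matrix(M)
  if (nrow(M) < 2)
    stop("hierarchical_cluster: need at least 2 rows", call. = FALSE)
  if (anyNA(M) || any(!is.finite(M)))
    stop("hierarchical_cluster: matrix contains NaN/NA", call. = FALSE)
  d <- switch(metric,
              euclidean = stats::dist(M),
              correlation = stats::as.dist(1 - stats::cor(t(M))))
  hc <- stats::hclust(d, method = switch(linkage, average = "average",
                                         ward = "ward.D2",
                                         complete = "complete"))
  structure(list(order = hc$order, labels = hc$labels, merge = hc$merge,
                 height = hc$height, metric = metric, linkage = linkage,
                 hclust = hc), class = "cluster_layout")
}

#' Export a cluster layout as newick-like bracket text
#'
#' @param layout a `cluster_layout`.
#' @return single newick string with merge heights as branch annotations.
#' @export
as_newick <- function(layout) {
  stopifnot(inherits(layout, "cluster_layout"))
  lab <- if (is.null(layout$labels))
    as.character(seq_len(nrow(layout$merge) + 1)) else layout$labels
  build <- function(i) {
    node <- layout$merge[i, ]
    part <- vapply(node, function(j)
      if (j < 0) lab[-j] else build(j), character(1))
    sprintf("(%s,%s):%g", part[1], part[2], layout$height[i])
  }
  paste0(build(nrow(layout$merge)), ";")
}
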