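#' Identity-by-state dissimilarity between samples
#'
#' For dosage vectors of two samples, IBS is the mean over sites of
#' `(2 - |d_i - d_j|) / 2`; the dissimilarity is `1 - IBS`, i.e. the mean
#' absolute dosage difference halved. Values lie in `[0, 1]` with a zero
#' diagonal.
#'
#' @param matrix Dosage matrix (samples x sites), e.g. [genotype_matrix()].
#' @return Symmetric numeric matrix of pairwise dissimilarities.
#' @export
ibs_dissimilarity <- function(matrix) {
  if (nrow(matrix) < 2) abort("need at least two samples")
  if (ncol(matrix) == 0) abort("zero sites")
  d <- as.matrix(dist(matrix, method = "manhattan")) / (2 * ncol(matrix))
  dimnames(d) <- list(rownames(matrix), rownames(matrix))
  d
}

#' Principal components of a genotype matrix
#'
#' Columns are standardized by their estimated allele frequency: dosage `g`
#' becomes `(g - 2p) / sqrt(2p(1-p))` with `p = colMeans(g)/2` (Patterson
#' scaling). Monomorphic columns are dropped. Coordinates come from the SVD
#' of the standardized matrix; variance fractions are squared singular values
#' over their total.
#'
#' @param matrix Dosage matrix (samples x sites).
#' @return Object of class `pca_embed`: list with `coords` (tibble `sample`,
#'   `PC1`, `PC2`, ...) and `var_frac` (numeric vector).
#' @export
pca_embed <- function(matrix) {
  if (nrow(matrix) < 2 || ncol(matrix) < 2) abort("need >= 2 samples and >= 2 sites")
  p <- colMeans(matrix) / 2
  poly <- p > 0 & p < 1 & apply(matrix, 2, function(x) any(x != x[1]))
  if (!any(poly)) abort("all columns are monomorphic")
  m <- matrix[, poly, drop = FALSE]
  p <- p[poly]
  x <- sweep(sweep(m, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
  s <- svd(x)
  k <- sum(s$d > 1e-9)
  coords <- s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k, k)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(
    list(
      coords = tibble(sample = rownames(matrix), as_tibble(coords)),
      var_frac = s$d[seq_len(k)]^2 / sum(s$d^2)
    ),
    class = "pca_embed"
  )
}

#' @export
tidy.pca_embed <- function(x, ...) x$coords

#' @export
autoplot.pca_embed <- function(object, colour_by = NULL, ...) {
  df <- object$coords
  if (!is.null(colour_by)) df$group <- colour_by
  pct <- round(100 * object$var_frac[1:2], 2)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  p <- if (is.null(colour_by)) p + ggplot2::geom_point(size = 2) else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  p + ggplot2::labs(x = paste0("PC1 (", pct[1], "%)"),
                    y = paste0("PC2 (", pct[2], "%)"))
}

#' Average-linkage dendrogram from a dissimilarity matrix
#'
#' Agglomerative clustering (UPGMA) of the pairwise dissimilarities; the
#' result carries both the `hclust` object and an `ape` phylogeny whose
#' branch lengths derive from merge heights, exportable as Newick.
#'
#' @param dissimilarity Symmetric matrix, e.g. [ibs_dissimilarity()].
#' @return Object of class `sample_dendrogram`: list with `hclust` and
#'   `phylo` components.
#' @export
hclust_dendrogram <- function(dissimilarity) {
  if (!isSymmetric(unname(dissimilarity), tol = 1e-12)) {
    abort("dissimilarity matrix must be symmetric")
  }
  hc <- hclust(as.dist(dissimilarity), method = "average")
  structure(list(hclust = hc, phylo = ape::as.phylo(hc)),
            class = "sample_dendrogram")
}

#' Export a dendrogram as Newick
#'
#' @param tree A `sample_dendrogram` (or `phylo`).
#' @param path Optional output path; when NULL the Newick string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  phy <- if (inherits(tree, "sample_dendrogram")) tree$phylo else tree
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
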