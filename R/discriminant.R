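#' Random-forest ranking of group-discriminant SNPs
#'
#' Fits a focal-vs-rest random forest on the dosage matrix and ranks sites by
#' permutation importance (mean decrease in accuracy). The proximity matrix
#' is OOB-restricted: the fraction of out-of-bag trees in which two samples
#' share a terminal node.
#'
#' @param matrix Dosage matrix (samples x sites) from [genotype_matrix()].
#' @param labels Factor/character of class labels per sample, or a panel
#'   tibble together with `focal` to derive focal-vs-rest labels.
#' @param focal When `labels` is a panel: the focal group name.
#' @param n_trees Number of trees (default 500).
#' @param mtry Variables tried per split (default `floor(sqrt(p))`).
#' @param seed Integer seed; the fit is deterministic for a fixed seed.
#' @return Object of class `rf_discriminant`: list with `importance` tibble
#'   (`site`, `mda`, `rank`), `proximity` matrix, `oob_error`, `params`.
#' @export
fit_random_forest <- function(matrix, labels, focal = NULL, n_trees = 500,
                              mtry = NULL, seed = 1L) {
  if (is.data.frame(labels)) {
    if (is.null(focal)) abort("supply `focal` when `labels` is a panel")
    labels <- ifelse(labels$group[match(rownames(matrix), labels$sample)] == focal,
                     focal, "rest")
  }
  y <- factor(labels)
  if (nlevels(y) < 2) abort("labels contain a single class")
  if (any(table(y) < 2)) abort("each class needs at least two samples")
  if (anyNA(matrix)) abort("dosage matrix contains missing values")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(matrix))))
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(
    x = matrix, y = y, ntree = n_trees, mtry = mtry,
    importance = TRUE, proximity = TRUE, oob.prox = TRUE
  )
  mda <- fit$importance[, "MeanDecreaseAccuracy"]
  imp <- tibble(site = colnames(matrix), mda = as.numeric(mda)) %>%
    arrange(dplyr::desc(.data$mda)) %>%
    mutate(rank = row_number())
  prox <- fit$proximity
  dimnames(prox) <- list(rownames(matrix), rownames(matrix))
  structure(
    list(importance = imp, proximity = prox,
         oob_error = as.numeric(fit$err.rate[n_trees, "OOB"]),
         labels = y,
         params = list(n_trees = n_trees, mtry = mtry, seed = seed)),
    class = "rf_discriminant"
  )
}

#' @export
tidy.rf_discriminant <- function(x, ...) x$importance

#' @export
glance.rf_discriminant <- function(x, ...) {
  tibble(n_trees = x$params$n_trees, mtry = x$params$mtry,
         oob_error = x$oob_error, n_sites = nrow(x$importance))
}

#' Classical MDS of a random-forest proximity matrix
#'
#' Torgerson scaling of the dissimilarity `1 - proximity`; the first two
#' principal coordinates are returned (zero-padded when the solution is rank
#' deficient), centred at the origin.
#'
#' @param proximity Symmetric proximity matrix (unit diagonal), or an
#'   `rf_discriminant`.
#' @return Object of class `rf_mds`: list with `coords` tibble (`sample`,
#'   `dim1`, `dim2`), `eig`, and `stress` (residual misfit of embedding
#'   distances to the dissimilarities).
#' @export
mds_embed <- function(proximity) {
  if (inherits(proximity, "rf_discriminant")) proximity <- proximity$proximity
  d <- 1 - proximity
  off <- d[upper.tri(d)]
  if (all(abs(off - off[1]) < 1e-12)) {
    abort("degenerate proximity: all sample pairs equally similar")
  }
  fit <- cmdscale(as.dist(d), k = 2, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < 2) pts <- cbind(pts, matrix(0, nrow(pts), 2 - ncol(pts)))
  emb <- as.matrix(dist(pts))
  stress <- sqrt(sum((emb - d)^2) / sum(d^2))
  structure(
    list(coords = tibble(sample = rownames(proximity),
                         dim1 = pts[, 1], dim2 = pts[, 2]),
         eig = fit$eig, stress = stress),
    class = "rf_mds"
  )
}

#' @export
tidy.rf_mds <- function(x, ...) x$coords

#' @export
autoplot.rf_mds <- function(object, labels = NULL, ...) {
  df <- object$coords
  if (!is.null(labels)) df$label <- as.character(labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2))
  p <- if (is.null(labels)) p + ggplot2::geom_point(size = 2) else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 2)
  p + ggplot2::labs(x = "MDS dimension 1", y = "MDS dimension 2")
}

#' Davies-Bouldin index of a labelled embedding
#'
#' `DB = mean_i max_{j != i} (s_i + s_j) / d(c_i, c_j)` with `s` the mean
#' Euclidean distance of cluster members to their centroid and `c` the
#' centroids. Lower is better-separated; two singleton clusters give 0.
#'
#' @param coords Numeric matrix / tibble of coordinates (n x d).
#' @param labels Cluster labels (>= 2 clusters, each nonempty).
#' @return The DB index (scalar).
#' @export
davies_bouldin_index <- function(coords, labels) {
  if (is.data.frame(coords)) {
    coords <- as.matrix(coords[vapply(coords, is.numeric, TRUE)])
  }
  labels <- as.character(labels)
  cl <- unique(labels)
  if (length(cl) < 2) abort("need at least two clusters")
  cent <- t(vapply(cl, function(g)
    colMeans(coords[labels == g, , drop = FALSE]), numeric(ncol(coords))))
  s <- vapply(seq_along(cl), function(j) {
    pts <- coords[labels == cl[j], , drop = FALSE]
    mean(sqrt(rowSums((pts - matrix(cent[j, ], nrow(pts),
                                    ncol(coords), byrow = TRUE))^2)))
  }, 1)
  m <- as.matrix(dist(cent))
  if (any(m[upper.tri(m)] == 0)) abort("coincident cluster centroids")
  k <- length(cl)
  r <- outer(s, s, "+") / m
  diag(r) <- -Inf
  mean(apply(r, 1, max))
}

#' Monte-Carlo permutation test of cluster separation
#'
#' Permutes the labels over the fixed embedding, preserving class sizes, and
#' reports the plus-one corrected fraction of permutations whose
#' Davies-Bouldin index is at least as good (<=) as observed:
#' `p = (1 + #[DB_perm <= DB_obs]) / (n_perm + 1)`.
#'
#' @param coords Embedding coordinates (n x d).
#' @param labels Observed labels.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return Object of class `separation_test`: list with `db_index`,
#'   `n_perm`, `p_value`.
#' @export
db_permutation_test <- function(coords, labels, n_perm = 999, seed = 1L) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  if (is.data.frame(coords)) {
    coords <- as.matrix(coords[vapply(coords, is.numeric, TRUE)])
  }
  obs <- davies_bouldin_index(coords, labels)
  set.seed(as.integer(seed))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(labels)
    db <- tryCatch(davies_bouldin_index(coords, perm),
                   error = function(e) Inf)
    if (db <= obs) hits <- hits + 1L
  }
  structure(
    list(db_index = obs, n_perm = n_perm,
         p_value = (1 + hits) / (n_perm + 1)),
    class = "separation_test"
  )
}

#' @export
tidy.separation_test <- function(x, ...) {
  tibble(db_index = x$db_index, n_perm = x$n_perm, p_value = x$p_value)
}

#' @export
print.separation_test <- function(x, ...) {
  cat("Davies-Bouldin permutation test: DB =", signif(x$db_index, 4),
      ", p =", signif(x$p_value, 4), "(", x$n_perm, "permutations )\n")
  invisible(x)
}

#' Select candidate markers by the gene-context / genotype-pattern rule
#'
#' Walks the importance-ranked site list and keeps sites that (a) are not
#' intergenic per the supplied annotation, (b) carry the alternate allele in
#' a strict majority of focal-group samples, and (c) have every focal sample
#' heterozygous or homozygous-alternate while every non-focal sample is
#' heterozygous or homozygous-reference. Stops after `k` sites are kept.
#'
#' @param ranked Importance tibble (`site`, `mda`, `rank`) or an
#'   `rf_discriminant`.
#' @param annotation Tibble `site`, `context` (e.g. "intronic", "upstream",
#'   "downstream", "intergenic"); sites missing from the annotation are
#'   treated as intergenic.
#' @param matrix Dosage matrix.
#' @param panel Sample panel.
#' @param focal Focal group name.
#' @param k Number of markers to keep (default 22).
#' @return Tibble of kept markers (`site`, `rank`, `mda`, `context`,
#'   `focal_pattern`, `other_pattern`), rank order preserved. If fewer than
#'   `k` qualify, all found are returned with attribute `incomplete = TRUE`
#'   and a warning.
#' @export
select_candidate_markers <- function(ranked, annotation, matrix, panel, focal,
                                     k = 22) {
  if (inherits(ranked, "rf_discriminant")) ranked <- ranked$importance
  focal_samples <- group_samples(panel, focal)
  fm <- matrix[rownames(matrix) %in% focal_samples, , drop = FALSE]
  om <- matrix[!rownames(matrix) %in% focal_samples, , drop = FALSE]
  ctx <- annotation$context[match(ranked$site, annotation$site)]
  ctx[is.na(ctx)] <- "intergenic"
  kept <- integer(0)
  for (i in seq_len(nrow(ranked))) {
    if (length(kept) >= k) break
    site <- ranked$site[i]
    if (ctx[i] == "intergenic") next
    f <- fm[, site]
    o <- om[, site]
    if (sum(f >= 1) * 2 <= length(f)) next          # majority rule, strict
    if (!all(f %in% c(1, 2))) next                  # focal het or hom-alt
    if (!all(o %in% c(0, 1))) next                  # others het or hom-ref
    kept <- c(kept, i)
  }
  out <- ranked[kept, ]
  out$context <- ctx[kept]
  out$focal_pattern <- vapply(out$site, function(s)
    paste(fm[, s], collapse = "/"), "")
  out$other_pattern <- vapply(out$site, function(s)
    paste(om[, s], collapse = "/"), "")
  if (nrow(out) < k) {
    warn(paste0("only ", nrow(out), " of the requested ", k,
                " markers satisfy the selection rule"))
    attr(out, "incomplete") <- TRUE
  }
  out
}

#' Nearest genes to each marker
#'
#' For each marker, the `k` nearest genes by interval distance (0 when the
#' marker falls inside the gene), subsequently filtered to signed distances
#' within `max_dist`. Distance is negative when the gene lies 5'-ward of the
#' marker on the + axis (gene end before the marker) and positive when
#' 3'-ward; ties are broken by the lower gene start.
#'
#' @param markers Tibble with `chrom`, `pos`.
#' @param genes Gene tibble (`chrom`, `start`, `stop`, `name`).
#' @param k Neighbours per marker before distance filtering (default 10).
#' @param max_dist Maximum |signed distance| kept (default 40000).
#' @return Tibble `chrom`, `pos`, `gene`, `signed_dist`, `neighbor_rank`.
#' @export
nearest_genes <- function(markers, genes, k = 10, max_dist = 40000) {
  out <- lapply(seq_len(nrow(markers)), function(i) {
    chr <- markers$chrom[i]; pos <- markers$pos[i]
    g <- genes[genes$chrom == chr, ]
    if (nrow(g) == 0) {
      abort(paste0("marker chromosome '", chr, "' absent from annotation"))
    }
    d <- ifelse(g$start <= pos & g$stop >= pos, 0,
                ifelse(g$stop < pos, g$stop - pos, g$start - pos))
    ord <- order(abs(d), g$start)
    take <- head(ord, k)
    keep <- take[abs(d[take]) <= max_dist]
    if (length(keep) == 0) return(NULL)
    tibble(chrom = chr, pos = pos, gene = g$name[keep],
           signed_dist = d[keep], neighbor_rank = seq_along(keep))
  })
  bind_rows(out)
}
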