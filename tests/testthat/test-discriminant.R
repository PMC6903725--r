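test_that("random-forest fits expose importance, proximity and OOB error", {
  fx <- marker_fixture(seed = 121, n_markers = 10, fst = 0)
  m <- genotype_matrix(fx$table, fx$panel)
  rf <- fit_random_forest(m, fx$panel, focal = "NAA", seed = 1)
  expect_equal(rf$proximity, t(rf$proximity))
  expect_equal(unname(diag(rf$proximity)), rep(1, nrow(m)))
  expect_true(all(rf$proximity >= 0 & rf$proximity <= 1))
  expect_true(all(is.finite(rf$importance$mda)))
  expect_equal(sort(rf$importance$rank), seq_len(ncol(m)))
  expect_gte(rf$oob_error, 0)
  # determinism for a fixed seed
  rf2 <- fit_random_forest(m, fx$panel, focal = "NAA", seed = 1)
  expect_equal(rf$importance, rf2$importance)
  # planted markers dominate the ranking (single-seed recovery smoke test)
  planted <- paste0(fx$truth$chrom, ":", fx$truth$pos)
  expect_gte(sum(planted %in% rf$importance$site[1:20]), 8)

  expect_error(fit_random_forest(m, rep("x", nrow(m))), "single class")
  expect_error(fit_random_forest(m, c("a", rep("b", nrow(m) - 1))),
               "at least two samples")
})

test_that("marker recovery is stable under feature-column shuffling", {
  # exact MDA values shift when columns are permuted (the tree-growing RNG
  # stream is tied to column indices), but the recovered marker set is stable
  fx <- marker_fixture(seed = 131, n_markers = 10, fst = 0)
  m <- genotype_matrix(fx$table, fx$panel)
  planted <- paste0(fx$truth$chrom, ":", fx$truth$pos)
  set.seed(9)
  shuffled <- m[, sample(ncol(m))]
  attr(shuffled, "allele_meta") <- NULL
  for (mm in list(m, shuffled)) {
    rf <- fit_random_forest(mm, fx$panel, focal = "NAA", n_trees = 1500, seed = 4)
    expect_gte(sum(planted %in% rf$importance$site[1:20]), 8)
  }
})

test_that("near-duplicate samples co-terminate in most trees", {
  set.seed(8)
  base <- matrix(sample(0:2, 2 * 300, replace = TRUE), nrow = 2)
  m <- rbind(A1 = base[1, ], A2 = base[1, ],   # identical pair, class a
             A3 = pmin(2, base[1, ] + sample(0:1, 300, TRUE, c(.9, .1))),
             B1 = base[2, ], B2 = base[2, ],
             B3 = pmin(2, base[2, ] + sample(0:1, 300, TRUE, c(.9, .1))))
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  rf <- fit_random_forest(m, rep(c("a", "b"), each = 3), seed = 2)
  expect_gt(rf$proximity["A1", "A2"], 0.9)
  expect_gt(rf$proximity["B1", "B2"], 0.9)
})

test_that("under label-independent features the top importance is not extreme", {
  # null fixture: labels carry no information, so the observed maximum MDA
  # should fall within the spread of label-permuted maxima
  fx <- marker_fixture(seed = 300, n_markers = 0, fst = 0)
  m <- genotype_matrix(fx$table, fx$panel)
  m <- m[, seq_len(500)]
  obs <- max(fit_random_forest(m, fx$panel, focal = "NAA", seed = 1)$importance$mda)
  set.seed(41)
  perm_max <- vapply(1:10, function(i) {
    labs <- sample(ifelse(fx$panel$group == "NAA", "f", "r"))
    max(fit_random_forest(m, labs, seed = i)$importance$mda)
  }, 1)
  expect_lte(obs, max(perm_max))
})

test_that("MDS embeds proximity structure with cluster geometry preserved", {
  prox <- diag(8)
  prox[1:4, 1:4] <- 0.9; prox[5:8, 5:8] <- 0.9
  prox[1:4, 5:8] <- 0.05; prox[5:8, 1:4] <- 0.05
  # break eigenvalue degeneracy so the 2-D embedding is unique up to isometry
  set.seed(6)
  jit <- matrix(runif(64, 0, 0.02), 8)
  prox <- prox + (jit + t(jit)) / 2
  diag(prox) <- 1
  dimnames(prox) <- list(paste0("S", 1:8), paste0("S", 1:8))
  emb <- mds_embed(prox)
  co <- as.matrix(emb$coords[, c("dim1", "dim2")])
  within <- c(dist(co[1:4, ]), dist(co[5:8, ]))
  between <- as.matrix(dist(co))[1:4, 5:8]
  expect_gt(min(between), 5 * max(within))
  expect_equal(colMeans(co), c(dim1 = 0, dim2 = 0), tolerance = 1e-9)

  # sample-order invariance up to rotation/reflection: distances agree
  ord <- c(3, 1, 8, 5, 2, 7, 4, 6)
  emb2 <- mds_embed(prox[ord, ord])
  d1 <- as.matrix(dist(co))
  d2 <- as.matrix(dist(as.matrix(emb2$coords[, c("dim1", "dim2")])))
  expect_equal(unname(d2), unname(d1[ord, ord]), tolerance = 1e-9)

  expect_error(mds_embed(matrix(1, 4, 4)), "degenerate")
})

test_that("the Davies-Bouldin index matches hand computation and geometry", {
  # two singleton clusters: zero scatter
  co <- rbind(c(0, 0), c(3, 4))
  expect_equal(davies_bouldin_index(co, c("a", "b")), 0)

  # hand-built 4-point layout: cluster a = (0,0),(2,0); b = (10,0),(14,0)
  # s_a = 1, s_b = 2, centroid distance 11 -> DB = (1+2)/11
  co4 <- rbind(c(0, 0), c(2, 0), c(10, 0), c(14, 0))
  expect_equal(davies_bouldin_index(co4, c("a", "a", "b", "b")), 3 / 11)

  # moving clusters apart strictly decreases DB
  co_far <- co4; co_far[3:4, 1] <- co_far[3:4, 1] + 50
  expect_lt(davies_bouldin_index(co_far, c("a", "a", "b", "b")), 3 / 11)

  expect_error(davies_bouldin_index(rbind(c(0, 0), c(0, 0)), c("a", "b")),
               "coincident")
  expect_error(davies_bouldin_index(co4, rep("a", 4)), "two clusters")
})

test_that("the DB permutation test is exact on separated clusters and bounded", {
  set.seed(1)
  co <- rbind(matrix(rnorm(20, 0, 0.1), 10), matrix(rnorm(20, 50, 0.1), 10))
  labels <- rep(c("a", "b"), each = 10)
  res <- db_permutation_test(co, labels, n_perm = 999, seed = 11)
  expect_equal(res$p_value, 1 / 1000)
  expect_lte(res$p_value, 1)
  # deterministic under a fixed seed
  res2 <- db_permutation_test(co, labels, n_perm = 999, seed = 11)
  expect_equal(res$p_value, res2$p_value)
})

test_that("null permutation p-values are uniform", {
  set.seed(202)
  pvals <- vapply(1:200, function(i) {
    co <- matrix(rnorm(24), 12, 2)
    labels <- rep(c("a", "b"), each = 6)
    db_permutation_test(co, labels, n_perm = 99, seed = 1000 + i)$p_value
  }, 1)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("candidate-marker selection enforces all three rules in rank order", {
  sites <- paste0("1:", 1:6 * 100)
  m <- rbind(
    F1 = c(1, 1, 1, 0, 1, 1),
    F2 = c(1, 2, 1, 1, 0, 1),
    F3 = c(2, 1, 1, 1, 1, 1),
    F4 = c(2, 2, 2, 2, 2, 1),
    O1 = c(0, 0, 0, 0, 0, 0),
    O2 = c(0, 2, 1, 0, 0, 0),
    O3 = c(0, 0, 0, 0, 0, 1))
  colnames(m) <- sites
  panel <- make_toy_panel(rownames(m), c(rep("F", 4), rep("O", 3)))
  ranked <- tibble::tibble(site = sites, mda = seq(0.6, 0.1, by = -0.1),
                           rank = 1:6)
  ann <- tibble::tibble(site = sites,
                        context = c("intronic", "intronic", "intergenic",
                                    "intronic", "intronic", "intronic"))
  sel <- select_candidate_markers(ranked, ann, m, panel, "F", k = 2)
  # site 1 kept; site 2 rejected (O2 hom-alt); site 3 intergenic;
  # site 4 rejected (F1 hom-ref); site 6 kept (O3 het allowed)
  expect_equal(sel$site, c("1:100", "1:600"))
  expect_equal(sel$rank, c(1L, 6L))  # rank order preserved, subset of input

  # fewer than k qualifying: flagged and warned
  expect_warning(
    out <- select_candidate_markers(ranked, ann, m, panel, "F", k = 5),
    "only 2")
  expect_true(isTRUE(attr(out, "incomplete")))
})

test_that("nearest-gene lookup matches a quadratic oracle with signed distances", {
  genes <- tibble::tibble(
    chrom = "1",
    start = c(100, 3000, 10000, 50000, 100000),
    stop = c(1000, 4000, 20000, 60000, 100500),
    gene_id = paste0("g", 1:5), name = paste0("G", 1:5))

  # marker inside a gene: distance zero, listed first
  nb <- nearest_genes(tibble::tibble(chrom = "1", pos = 15000), genes, k = 4)
  expect_equal(nb$gene[1], "G3")
  expect_equal(nb$signed_dist[1], 0)
  # signs: gene before the marker is negative, after is positive
  expect_equal(nb$signed_dist[nb$gene == "G2"], 4000 - 15000)
  expect_equal(nb$signed_dist[nb$gene == "G4"], 50000 - 15000)
  expect_false("G5" %in% nb$gene)  # 5th nearest, beyond k = 4

  # a gene exactly 40,001 bp away is excluded, 40,000 kept
  g2 <- tibble::tibble(chrom = "1", start = c(50001, 100000),
                       stop = c(50002, 100100),
                       gene_id = c("near", "far"), name = c("NEAR", "FAR"))
  # pos 10000: NEAR is 40,001 bp away -> excluded (and FAR further still)
  nb2 <- nearest_genes(tibble::tibble(chrom = "1", pos = 10000), g2, k = 10)
  expect_equal(nrow(nb2), 0)
  # pos 10001: NEAR is exactly 40,000 bp away -> kept
  nb3 <- nearest_genes(tibble::tibble(chrom = "1", pos = 10001), g2, k = 10)
  expect_equal(nb3$gene, "NEAR")
  expect_equal(nb3$signed_dist, 40000)

  expect_error(nearest_genes(tibble::tibble(chrom = "9", pos = 5), genes),
               "absent")

  # oracle comparison over 50 random markers
  set.seed(15)
  rg <- tibble::tibble(chrom = "1", start = sort(sample.int(2e5, 40)))
  rg$stop <- rg$start + sample.int(2000, 40, replace = TRUE)
  rg$gene_id <- paste0("g", 1:40); rg$name <- paste0("G", 1:40)
  markers <- tibble::tibble(chrom = "1", pos = sample.int(2.2e5, 50))
  got <- nearest_genes(markers, rg, k = 10, max_dist = 40000)
  for (i in seq_len(nrow(markers))) {
    pos <- markers$pos[i]
    d <- ifelse(rg$start <= pos & rg$stop >= pos, 0,
                ifelse(rg$stop < pos, rg$stop - pos, rg$start - pos))
    ord <- order(abs(d), rg$start)[1:10]
    keep <- ord[abs(d[ord]) <= 40000]
    expect_equal(got$gene[got$pos == pos], rg$name[keep])
  }
})
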