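test_that("two-locus Rp genotypes classify by their joint pattern", {
  expect_equal(classify_rp_genotype("A/A", "A/A"), "wildtype")
  expect_equal(classify_rp_genotype("A/C", "A/C"), "het_both")
  expect_equal(classify_rp_genotype("C/C", "C/C"), "hom_both")
  expect_equal(classify_rp_genotype("A/C", "C/C"), "mixed_het_hom")
  expect_equal(classify_rp_genotype("C/C", "A/C"), "mixed_het_hom")
  expect_equal(classify_rp_genotype("A/C", "A/A"), "variant_single_locus")
  expect_equal(classify_rp_genotype("A/A", "C/C"), "variant_single_locus")
  # unordered pairs: C/A is the same genotype as A/C
  expect_equal(classify_rp_genotype("C/A", "A/C"), "het_both")
  expect_error(classify_rp_genotype("A/G", "A/A"), "invalid")
})

test_that("Rp tabulation over the shipped genotyping records matches the counts", {
  rec <- rp_genotyping_records()
  out <- tabulate_rp(rec)
  tab <- out$table
  getn <- function(ph, cl) {
    n <- tab$n[tab$phenotype == ph & tab$class == cl]
    if (length(n) == 0) 0L else n
  }
  expect_equal(getn("tailed_wildtype", "wildtype"), 42L)
  expect_equal(getn("tailed_araucana", "wildtype"), 18L)
  expect_equal(getn("partial", "het_both"), 19L)
  expect_equal(getn("rumpless", "het_both"), 26L)
  expect_equal(getn("rumpless", "hom_both"), 32L)
  expect_equal(getn("partial", "mixed_het_hom"), 2L)
  expect_equal(getn("rumpless", "mixed_het_hom"), 3L)
  # no bird carries a variant at exactly one locus
  expect_equal(sum(tab$n[tab$class == "variant_single_locus"]), 0L)
  # conservation: cells sum to input birds
  expect_equal(sum(tab$n), nrow(rec))
  expect_equal(out$n_birds, 142L)
  expect_equal(nrow(out$violations), 0)
})

test_that("Rp tabulation validates input and handles empty and violating records", {
  expect_error(tabulate_rp(tibble::tibble(phenotype = "odd", sv1 = "A/A",
                                          sv2 = "A/A")), "unknown phenotype")
  empty <- tabulate_rp(tibble::tibble(phenotype = character(),
                                      sv1 = character(), sv2 = character()))
  expect_equal(nrow(empty$table), 0)
  v <- tabulate_rp(tibble::tibble(
    phenotype = c("tailed_wildtype", "rumpless"),
    sv1 = c("A/C", "A/C"), sv2 = c("A/C", "A/A")))
  expect_equal(nrow(v$violations), 2)
})

test_that("deletion sizes follow the stop - start convention", {
  expect_equal(deletion_size(1019583, 1027972), 8389)
  expect_equal(deletion_size(347555, 348072), 517)
  expect_equal(deletion_size(5, 5), 0)
  expect_error(deletion_size(10, 9), ">=")
})

test_that("the shipped chromosome-15 deletion table is internally consistent", {
  del <- araucana_deletions()
  recs <- dplyr::distinct(del, start, stop, size)
  expect_equal(nrow(recs), 21)
  expect_equal(recs$size, recs$stop - recs$start)
  expect_equal(max(recs$size), 8389)
  expect_equal(min(recs$size), 88)
  expect_setequal(unique(del$sample), sprintf("NAA%02d", 1:6))
  # 0/0 pairs with absent, variants with pass/unfiltered
  expect_true(all((del$genotype == "0/0") == (del$status == "absent")))
})

test_that("tufted-specific filtering recovers the known deletion set", {
  del <- araucana_deletions()
  panel <- araucana_panel()
  spec <- tufted_specific_deletions(del, panel)
  expect_equal(dplyr::n_distinct(spec$start), 7)

  cand <- candidate_tuft_deletion(del, panel)
  expect_equal(unique(cand$start), 1019583)
  expect_equal(unique(cand$stop), 1027972)
  expect_equal(unique(cand$gene), "TXNRD2")

  # planting a clean-faced carrier into a kept record removes it
  broken <- del
  i <- broken$start == 3225855 & broken$sample == "NAA03"
  broken$genotype[i] <- "0/1"; broken$status[i] <- "pass"
  spec2 <- tufted_specific_deletions(broken, panel)
  expect_equal(dplyr::n_distinct(spec2$start), 6)
  expect_false(3225855 %in% spec2$start)

  # a record absent everywhere is never kept
  ghost <- del[del$start == 347555, ]
  ghost$start <- 999; ghost$stop <- 1999; ghost$size <- 1000
  ghost$genotype <- "0/0"; ghost$status <- "absent"
  expect_false(999 %in% tufted_specific_deletions(rbind(del, ghost), panel)$start)

  # hom-alt in one tufted bird disqualifies the all-het candidate rule
  hom <- del
  j <- hom$start == 1019583 & hom$sample == "NAA01"
  hom$genotype[j] <- "1/1"
  expect_equal(nrow(candidate_tuft_deletion(hom, panel)), 0)

  expect_error(tufted_specific_deletions(del, dplyr::mutate(panel, tufted = "clean")),
               "no tufted")
})

test_that("CNV log2 ratios follow the normalized-rate model", {
  d <- tibble::tibble(
    sample = rep(c("T", "R"), each = 4),
    chrom = "1",
    start = rep(c(1, 4001, 8001, 12001), 2),
    stop = rep(c(4000, 8000, 12000, 16000), 2),
    count = c(100, 200, 50, 100, 100, 100, 50, 200))
  cw <- cnv_log2(d, "T", "R")
  # totals equal: window 1 ratio 1 -> log2 0; window 2 ratio 2 -> log2 1
  expect_equal(cw$log2_ratio[1], 0)
  expect_equal(cw$log2_ratio[2], 1)
  expect_equal(cw$log2_ratio[4], -1)
  # antisymmetry under test/ref swap
  sw <- cnv_log2(d, "R", "T")
  expect_equal(sw$log2_ratio, -cw$log2_ratio)
  expect_equal(sw$p_value, cw$p_value)

  # zero counts are flagged undefined
  d0 <- d; d0$count[3] <- 0
  cw0 <- cnv_log2(d0, "T", "R")
  expect_false(cw0$defined[3])
  expect_true(is.na(cw0$log2_ratio[3]))
})

test_that("significant segments honour the four-window minimum and match the run oracle", {
  mk <- function(p, l2) tibble::tibble(
    sample = NA, chrom = "1",
    start = seq(1, by = 4000, length.out = length(p)),
    stop = seq(4000, by = 4000, length.out = length(p)),
    test_count = 100, ref_count = 100,
    log2_ratio = l2, p_value = p, defined = !is.na(l2))
  # 3 qualifying windows: nothing
  w3 <- mk(c(1, 1e-5, 1e-5, 1e-5, 1), c(0, 2, 2, 2, 0))
  expect_equal(nrow(cnv_significant_segments(w3)), 0)
  # 4 qualifying: one segment
  w4 <- mk(c(1, 1e-5, 1e-5, 1e-5, 1e-5, 1), c(0, 2, 2, 2, 2, 0))
  seg <- cnv_significant_segments(w4)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_windows, 4L)
  expect_equal(seg$direction, "gain")
  # sign flip inside a run splits it
  w5 <- mk(rep(1e-5, 8), c(2, 2, 2, 2, -2, -2, -2, -2))
  expect_equal(nrow(cnv_significant_segments(w5)), 2)

  # brute-force run-scan oracle on random labelings
  set.seed(77)
  for (i in 1:1000) {
    n <- sample(5:30, 1)
    qual <- runif(n) < 0.5
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    l2 <- ifelse(qual, sgn * 2, 0)
    p <- ifelse(qual, 1e-5, 1)
    w <- mk(p, l2)
    got <- cnv_significant_segments(w)
    # oracle: literal scan for runs of >= 4 same-sign qualifying windows
    runs <- 0L; len <- 0L; cur <- 0
    for (j in seq_len(n)) {
      if (qual[j] && (len == 0L || sgn[j] == cur)) {
        len <- len + 1L; cur <- sgn[j]
      } else {
        if (len >= 4L) runs <- runs + 1L
        len <- if (qual[j]) 1L else 0L
        cur <- if (qual[j]) sgn[j] else 0
      }
    }
    if (len >= 4L) runs <- runs + 1L
    expect_equal(nrow(got), runs)
  }
})

test_that("region medians summarize overlapping defined windows", {
  w <- tibble::tibble(
    chrom = "1", start = c(1, 4001, 8001), stop = c(4000, 8000, 12000),
    test_count = 1, ref_count = 1,
    log2_ratio = c(2.0, 2.3, 2.5), p_value = 0, defined = TRUE)
  expect_equal(region_median_log2(w, "1:1-12000"), 2.3)
  expect_equal(region_median_log2(w, "1:5000-6000"), 2.3) # single window
  expect_error(region_median_log2(w, "1:50000-60000"), "no defined windows")
  expect_error(region_median_log2(w, "2:1-10"), "no defined windows")
})

test_that("a planted eight-fold duplication yields in-dup medians near log2(8)", {
  # 200 kb duplication on a chromosome-1-scale grid: the duplicated windows
  # are ~0.1% of the genome, so total-count normalization stays unbiased and
  # the median over 50 in-dup windows is tight
  meds <- vapply(1:20, function(s) {
    d <- simulate_depth_windows(c("T", "R"), "1", chrom_len = 2e8,
                                window = 4000, base_depth = 100,
                                dup = list(start = 1e6 + 1, stop = 1.2e6,
                                           fold = 8, carriers = "T"), seed = s)
    region_median_log2(cnv_log2(d, "T", "R"), "1:1000001-1200000")
  }, 1)
  expect_true(all(abs(meds - 3) < 0.1))
})

test_that("null depth fixtures rarely produce significant segments", {
  n_seg <- vapply(1:50, function(s) {
    d <- simulate_depth_windows(c("T", "R"), "1", chrom_len = 4e5,
                                window = 4000, base_depth = 100,
                                dup = NULL, seed = 500 + s)
    nrow(cnv_significant_segments(cnv_log2(d, "T", "R")))
  }, 1L)
  expect_gte(sum(n_seg == 0), 48)  # >= 95% of seeds
})

test_that("pairwise region-median matrices have the expected shape", {
  d <- dplyr::bind_rows(lapply(c("N1", "N2", "W1", "W2"), function(s)
    simulate_depth_windows(s, "1", 2e6, window = 4000, base_depth = 100,
                           dup = if (startsWith(s, "N"))
                             list(start = 1e6 + 1, stop = 1e6 + 6e4,
                                  fold = 8, carriers = s)
                           else NULL,
                           seed = match(s, c("N1", "N2", "W1", "W2")))))
  m <- cnv_region_median_matrix(d, tests = c("N1", "N2"),
                                refs = c("W1", "W2"),
                                region = "1:1000001-1060000")
  expect_equal(dim(m), c(2, 3))
  expect_equal(names(m), c("sample", "W1", "W2"))
  expect_true(all(as.matrix(m[, -1]) > 2.5))
})
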