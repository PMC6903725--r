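#' Classify a two-locus rumplessness genotype
#'
#' Rumplessness (Rp) in Araucana chickens tracks two linked SNPs upstream of
#' the IRX1/IRX2 cluster (SV1 at chr2:86,770,373 and SV2 at chr2:86,870,271;
#' A reference, C alternate). Genotypes are unordered allele pairs over
#' {A, C}; the joint class over the two loci is:
#' wildtype (A/A, A/A), het_both (A/C, A/C), hom_both (C/C, C/C),
#' mixed_het_hom (A/C with C/C in either order), and variant_single_locus
#' (variant at exactly one locus with wildtype at the other -- a pattern
#' never observed in genotyped birds and therefore flagged).
#'
#' @param sv1,sv2 Character vectors of genotypes like "A/C" (order within the
#'   pair is ignored).
#' @return Character vector of classes.
#' @export
classify_rp_genotype <- function(sv1, sv2) {
  norm <- function(g) {
    parts <- strsplit(g, "/", fixed = TRUE)
    bad <- vapply(parts, function(p)
      length(p) != 2 || !all(p %in% c("A", "C")), TRUE)
    if (any(bad)) {
      abort(paste0("invalid Rp genotype: ", g[bad][1],
                   " (alleles must be A or C)"))
    }
    vapply(parts, function(p) paste(sort(p), collapse = "/"), "")
  }
  g1 <- norm(sv1); g2 <- norm(sv2)
  dplyr::case_when(
    g1 == "A/A" & g2 == "A/A" ~ "wildtype",
    g1 == "A/C" & g2 == "A/C" ~ "het_both",
    g1 == "C/C" & g2 == "C/C" ~ "hom_both",
    (g1 == "A/C" & g2 == "C/C") | (g1 == "C/C" & g2 == "A/C") ~ "mixed_het_hom",
    TRUE ~ "variant_single_locus"
  )
}

#' Tabulate rumplessness genotypes against phenotypes
#'
#' Builds the (phenotype x genotype class) contingency table of bird records
#' and a violation list: birds with a variant at exactly one locus, and
#' tailed birds carrying any non-wildtype class.
#'
#' @param records Tibble with `phenotype` (one of `tailed_araucana`,
#'   `tailed_wildtype`, `partial`, `rumpless`), `sv1`, `sv2`.
#' @return Object of class `rp_table`: list with `table` (tibble `phenotype`,
#'   `class`, `n`), `violations` (offending rows with a `reason` column), and
#'   `n_birds`.
#' @export
tabulate_rp <- function(records) {
  allowed <- c("tailed_araucana", "tailed_wildtype", "partial", "rumpless")
  bad <- setdiff(unique(records$phenotype), allowed)
  if (length(bad)) abort(paste0("unknown phenotype label(s): ",
                                paste(bad, collapse = ", ")))
  if (nrow(records) == 0) {
    return(structure(list(
      table = tibble(phenotype = character(), class = character(), n = integer()),
      violations = tibble(), n_birds = 0L), class = "rp_table"))
  }
  rec <- mutate(records, class = classify_rp_genotype(.data$sv1, .data$sv2))
  tab <- count(rec, .data$phenotype, .data$class, name = "n")
  tailed <- rec$phenotype %in% c("tailed_araucana", "tailed_wildtype")
  v1 <- mutate(rec[rec$class == "variant_single_locus", ],
               reason = "variant at exactly one locus")
  v2 <- mutate(rec[tailed & rec$class != "wildtype", ],
               reason = "tailed bird with variant genotype")
  structure(list(table = tab, violations = bind_rows(v1, v2),
                 n_birds = nrow(rec)),
            class = "rp_table")
}

#' @export
tidy.rp_table <- function(x, ...) x$table

#' @export
print.rp_table <- function(x, ...) {
  cat("Rp genotype x phenotype table (", x$n_birds, "birds )\n")
  print(x$table, n = Inf)
  if (nrow(x$violations)) cat(nrow(x$violations), "violating record(s)\n")
  invisible(x)
}

#' Deletion size from breakpoints
#'
#' Size is `stop - start` (the breakpoint convention of structural-variant
#' callers, verified against every printed record shipped with the package).
#'
#' @param start,stop 1-based breakpoint coordinates, `stop >= start`.
#' @return Numeric vector of sizes in bp.
#' @export
deletion_size <- function(start, stop) {
  if (any(stop < start)) abort("stop must be >= start")
  stop - start
}

#' Deletions specific to tufted carriers
#'
#' Keeps deletion records present (genotype 0/1 or 1/1, whether the call
#' passed filtering or appears only in the unfiltered set) in at least one
#' tufted bird and absent (0/0) in every clean-faced bird.
#'
#' @param records Long deletion tibble: one row per record x sample with
#'   `chrom`, `start`, `stop`, `sample`, `status` (`pass`, `unfiltered`,
#'   `absent`) and `genotype` (`0/0`, `0/1`, `1/1`).
#' @param panel Sample panel with a `tufted` column (`tufted` / `clean`).
#' @param strict_filter If TRUE only pass-filter calls count as present.
#' @return Subset of `records` (all sample rows of the kept deletions).
#' @export
tufted_specific_deletions <- function(records, panel, strict_filter = FALSE) {
  tufted <- panel$sample[panel$tufted == "tufted"]
  clean <- panel$sample[panel$tufted == "clean"]
  if (length(tufted) == 0) abort("panel has no tufted birds")
  present <- records$genotype %in% c("0/1", "1/1") &
    (if (strict_filter) records$status == "pass" else
       records$status %in% c("pass", "unfiltered"))
  keep <- records %>%
    mutate(present = present) %>%
    group_by(.data$chrom, .data$start, .data$stop) %>%
    summarise(
      any_tufted = any(.data$present & .data$sample %in% tufted),
      none_clean = all(!(.data$present & .data$sample %in% clean)),
      .groups = "drop") %>%
    filter(.data$any_tufted, .data$none_clean)
  semi_join(records, keep, by = c("chrom", "start", "stop"))
}

#' All-tufted heterozygous candidate deletion
#'
#' Keeps records heterozygous (0/1) in every tufted bird and absent (0/0) in
#' every other bird covered by the record -- the signature of a dominant
#' hemizygous trait deletion.
#'
#' @inheritParams tufted_specific_deletions
#' @return Subset of `records`.
#' @export
candidate_tuft_deletion <- function(records, panel) {
  tufted <- panel$sample[panel$tufted == "tufted"]
  keep <- records %>%
    group_by(.data$chrom, .data$start, .data$stop) %>%
    summarise(
      all_tufted_het = all(.data$genotype[.data$sample %in% tufted] == "0/1") &&
        sum(.data$sample %in% tufted) == length(tufted),
      others_absent = all(.data$genotype[!.data$sample %in% tufted] == "0/0"),
      .groups = "drop") %>%
    filter(.data$all_tufted_het, .data$others_absent)
  semi_join(records, keep, by = c("chrom", "start", "stop"))
}

#' Depth-window log2 copy-number ratios
#'
#' For one test / reference sample pair on a shared window grid, computes
#' `log2((x_t / N_t) / (x_r / N_r))` per window with `N` the sample's total
#' best-hit count, and a two-sided p-value from the normal approximation to
#' the log ratio of two Poisson counts (variance `1/x_t + 1/x_r` on the
#' natural-log scale). Windows with a zero count in either sample have an
#' undefined ratio and are flagged (`defined = FALSE`).
#'
#' @param depth Long depth tibble (`sample`, `chrom`, `start`, `stop`,
#'   `count`), e.g. from [simulate_depth_windows()].
#' @param test,ref Sample ids to compare.
#' @return Tibble `chrom`, `start`, `stop`, `test_count`, `ref_count`,
#'   `log2_ratio`, `p_value`, `defined`, with attributes `test` and `ref`.
#' @export
cnv_log2 <- function(depth, test, ref) {
  t_w <- filter(depth, .data$sample == test)
  r_w <- filter(depth, .data$sample == ref)
  if (nrow(t_w) == 0 || nrow(r_w) == 0) abort("test or ref sample absent")
  joined <- inner_join(
    select(t_w, "chrom", "start", "stop", test_count = "count"),
    select(r_w, "chrom", "start", "stop", ref_count = "count"),
    by = c("chrom", "start", "stop"))
  if (nrow(joined) != nrow(t_w)) abort("test and ref window grids differ")
  n_t <- sum(joined$test_count)
  n_r <- sum(joined$ref_count)
  if (n_t <= 0 || n_r <= 0) abort("total counts must be positive")
  defined <- joined$test_count > 0 & joined$ref_count > 0
  lr <- rep(NA_real_, nrow(joined))
  pv <- rep(NA_real_, nrow(joined))
  lr[defined] <- log2((joined$test_count[defined] / n_t) /
                        (joined$ref_count[defined] / n_r))
  se_ln <- sqrt(1 / joined$test_count[defined] + 1 / joined$ref_count[defined])
  # ln ratio of normalized rates, centred at 0 under equal copy number
  z <- (log(joined$test_count[defined] / joined$ref_count[defined]) -
          log(n_t / n_r)) / se_ln
  pv[defined] <- 2 * pnorm(-abs(z))
  out <- mutate(joined, log2_ratio = lr, p_value = pv, defined = defined)
  attr(out, "test") <- test
  attr(out, "ref") <- ref
  out
}

#' Significant copy-number segments
#'
#' Maximal runs of at least `min_windows` grid-consecutive windows, each
#' meeting `p <= p_max` and `|log2| >= log2_min` with a consistent sign of
#' the log2 ratio within the run.
#'
#' @param windows Output of [cnv_log2()].
#' @param p_max P-value ceiling (default 0.001).
#' @param log2_min Minimum |log2 ratio| (default 0.6).
#' @param min_windows Minimum run length (default 4).
#' @return Tibble `chrom`, `start`, `stop`, `n_windows`, `mean_log2`,
#'   `direction` (`gain` / `loss`).
#' @export
cnv_significant_segments <- function(windows, p_max = 0.001, log2_min = 0.6,
                                     min_windows = 4) {
  w <- arrange(windows, .data$chrom, .data$start)
  qual <- !is.na(w$log2_ratio) & !is.na(w$p_value) & w$p_value <= p_max &
    abs(w$log2_ratio) >= log2_min
  empty <- tibble(chrom = character(), start = numeric(), stop = numeric(),
                  n_windows = integer(), mean_log2 = numeric(),
                  direction = character())
  if (!any(qual)) return(empty)
  sgn <- sign(w$log2_ratio)
  sgn[!qual] <- 0
  adjacent <- c(FALSE, w$chrom[-1] == w$chrom[-nrow(w)] &
                  w$start[-1] == w$stop[-nrow(w)] + 1)
  run_id <- cumsum(!(qual & adjacent & sgn == dplyr::lag(sgn, default = 0)))
  w$run <- run_id
  w$qual <- qual
  segs <- w %>%
    filter(.data$qual) %>%
    group_by(.data$run) %>%
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              stop = max(.data$stop), n_windows = n(),
              mean_log2 = mean(.data$log2_ratio),
              direction = ifelse(first(sign(.data$log2_ratio)) > 0, "gain", "loss"),
              .groups = "drop") %>%
    filter(.data$n_windows >= min_windows) %>%
    select(-"run") %>%
    arrange(.data$chrom, .data$start)
  segs
}

#' Median log2 ratio over a region
#'
#' Median of the defined window log2 ratios overlapping the 1-based closed
#' region (any overlap counts).
#'
#' @param windows Output of [cnv_log2()].
#' @param region Region list or `"chrom:start-stop"` string.
#' @return Scalar median.
#' @export
region_median_log2 <- function(windows, region) {
  region <- parse_region(region)
  hit <- windows$chrom == region$chrom &
    windows$start <= region$stop & windows$stop >= region$start &
    windows$defined
  if (!any(hit)) abort("no defined windows overlap the region")
  median(windows$log2_ratio[hit])
}

#' Region-median matrix across sample pairs
#'
#' Computes [region_median_log2()] for every test x reference sample pair --
#' the shape of a published pairwise CNV comparison table.
#'
#' @param depth Long depth tibble.
#' @param tests,refs Sample id vectors.
#' @param region Region of interest.
#' @return Tibble with one row per test sample and one column per reference.
#' @export
cnv_region_median_matrix <- function(depth, tests, refs, region) {
  rows <- lapply(tests, function(ts) {
    med <- vapply(refs, function(rf)
      region_median_log2(cnv_log2(depth, ts, rf), region), 1)
    as_tibble(c(list(sample = ts), setNames(as.list(med), refs)))
  })
  bind_rows(rows)
}
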