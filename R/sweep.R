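#' Creeping-window parameters
#'
#' A creeping window grows SNP-by-SNP from a start SNP, subject to three
#' constraints: total span at most `max_span` bp, inter-SNP gaps strictly
#' below `max_gap` bp, and at least `min_snps` SNPs for the window to be
#' emitted. `start_step` controls how many SNPs the start advances between
#' windows (1 = a window attempted at every SNP).
#'
#' @param max_span Maximum window span in bp (default 40000).
#' @param max_gap Exclusive upper bound on the gap between adjacent SNPs
#'   (default 10000: a 10 kb gap breaks the window).
#' @param min_snps Minimum SNP count per emitted window (default 50).
#' @param start_step SNP stride between window starts (default 1).
#' @param count_mode `"allele_depth"` (pool AD read counts; default) or
#'   `"genotype"` (two observations per sample per site from GT).
#' @return Object of class `window_params`.
#' @export
window_params <- function(max_span = 40000, max_gap = 10000, min_snps = 50,
                          start_step = 1,
                          count_mode = c("allele_depth", "genotype")) {
  if (max_span <= 0 || max_gap <= 0) abort("max_span and max_gap must be positive")
  if (min_snps < 1 || start_step < 1) abort("min_snps and start_step must be >= 1")
  structure(
    list(max_span = max_span, max_gap = max_gap, min_snps = min_snps,
         start_step = as.integer(start_step),
         count_mode = match.arg(count_mode)),
    class = "window_params"
  )
}

#' Build creeping windows over sorted SNP positions
#'
#' From each eligible start SNP, the window extends rightwards while the next
#' SNP is within `max_gap` (exclusive) of the current SNP and within
#' `max_span` (inclusive) of the window start. Windows never span
#' chromosomes.
#'
#' @param positions Tibble with `chrom` and `pos` (one row per SNP), sorted
#'   ascending within chromosome.
#' @param params A [window_params()].
#' @return Tibble `chrom`, `start`, `stop` (positions of first/last SNP),
#'   `n_snps`, `start_idx`, `end_idx` (row indices into the per-chromosome
#'   position vector).
#' @export
build_creeping_windows <- function(positions, params = window_params()) {
  stopifnot(inherits(params, "window_params"))
  out <- positions %>%
    group_by(.data$chrom) %>%
    dplyr::group_modify(function(df, key) {
      pos <- df$pos
      if (is.unsorted(pos, strictly = FALSE)) abort("positions must be sorted")
      n <- length(pos)
      # windows cannot cross a gap >= max_gap: split into segments
      seg <- cumsum(c(0L, diff(pos) >= params$max_gap))
      last_of_seg <- tapply(seq_len(n), seg, max)
      seg_last <- as.integer(last_of_seg[as.character(seg)])
      starts <- seq(1L, n, by = params$start_step)
      span_end <- findInterval(pos[starts] + params$max_span, pos)
      end <- pmin(span_end, seg_last[starts])
      n_snps <- end - starts + 1L
      keep <- n_snps >= params$min_snps
      tibble(start = pos[starts[keep]], stop = pos[end[keep]],
             n_snps = n_snps[keep],
             start_idx = starts[keep], end_idx = end[keep])
    }) %>%
    ungroup()
  out
}

#' Pooled per-site allele counts for a group
#'
#' Pools allele observations across a group's samples at every site. In
#' allele-depth mode the AD read counts are summed per allele; in genotype
#' mode each sample contributes two observations per site from its GT. The
#' larger pooled count is the major-allele count `n_maj`, the smaller the
#' minor `n_min` (a tie yields equal counts).
#'
#' @param table Variant table.
#' @param panel Sample panel.
#' @param group Group name.
#' @param count_mode `"allele_depth"` or `"genotype"`.
#' @return Tibble `chrom`, `pos`, `n_maj`, `n_min`, sorted by position.
#' @export
site_allele_counts <- function(table, panel, group,
                               count_mode = c("allele_depth", "genotype")) {
  count_mode <- match.arg(count_mode)
  samples <- group_samples(panel, group)
  sub <- filter(table, .data$sample %in% samples)
  if (count_mode == "allele_depth") {
    if (anyNA(sub$ad_ref) || anyNA(sub$ad_alt)) {
      abort("AD is missing for some genotypes; use count_mode = \"genotype\"")
    }
    counts <- sub %>%
      group_by(.data$chrom, .data$pos) %>%
      summarise(n_ref = sum(.data$ad_ref), n_alt = sum(.data$ad_alt),
                .groups = "drop")
  } else {
    counts <- sub %>%
      group_by(.data$chrom, .data$pos) %>%
      summarise(n_alt = sum(gt_to_dosage(.data$gt), na.rm = TRUE),
                n_ref = sum(2L - gt_to_dosage(.data$gt), na.rm = TRUE),
                .groups = "drop")
  }
  counts %>%
    mutate(n_maj = pmax(.data$n_ref, .data$n_alt),
           n_min = pmin(.data$n_ref, .data$n_alt)) %>%
    select("chrom", "pos", "n_maj", "n_min") %>%
    arrange(.data$chrom, .data$pos)
}

#' Sum pooled allele counts over windows
#'
#' @param windows Window tibble from [build_creeping_windows()] (with
#'   `start_idx` / `end_idx`).
#' @param counts Per-site counts from [site_allele_counts()], in the same
#'   per-chromosome order used to build the windows.
#' @return `windows` with `sum_maj` and `sum_min` columns added.
#' @export
window_allele_sums <- function(windows, counts) {
  counts <- arrange(counts, .data$chrom, .data$pos)
  out <- windows %>%
    group_by(.data$chrom) %>%
    dplyr::group_modify(function(df, key) {
      cc <- counts[counts$chrom == key$chrom, ]
      cmaj <- cumsum(c(0, cc$n_maj))
      cmin <- cumsum(c(0, cc$n_min))
      mutate(df,
             sum_maj = cmaj[.data$end_idx + 1L] - cmaj[.data$start_idx],
             sum_min = cmin[.data$end_idx + 1L] - cmin[.data$start_idx])
    }) %>%
    ungroup()
  out
}

#' Pooled heterozygosity
#'
#' `Hp = 2 * S_maj * S_min / (S_maj + S_min)^2` where `S_maj`, `S_min` are
#' the window sums of pooled major/minor allele observations. Bounded in
#' `[0, 0.5]`, attaining 0.5 only when the sums are equal and 0 when the
#' minor sum vanishes (approach to fixation).
#'
#' @param sum_maj,sum_min Nonnegative numeric vectors.
#' @return Numeric vector of Hp values.
#' @export
pooled_heterozygosity <- function(sum_maj, sum_min) {
  tot <- sum_maj + sum_min
  if (any(tot <= 0)) abort("sum_maj + sum_min must be positive")
  2 * sum_maj * sum_min / tot^2
}

#' Standardize Hp values genome-wide
#'
#' `ZHp = (Hp - mean(Hp)) / sd(Hp)` with the sample standard deviation,
#' computed across all supplied windows (one genome-wide mean and sd).
#'
#' @param hp Numeric vector of window Hp values (length >= 2).
#' @return Numeric vector with mean 0 and sample sd 1.
#' @export
zhp_standardize <- function(hp) {
  if (length(hp) < 2) abort("need at least two windows to standardize")
  s <- sd(hp)
  if (s == 0) abort("all windows have identical Hp; sd is zero")
  (hp - mean(hp)) / s
}

#' Classify standardized windows
#'
#' Strong selection at `zhp <= strong` (default -6), suggestive at
#' `strong < zhp <= suggestive` (default -4); both boundaries inclusive.
#'
#' @param zhp Numeric vector of standardized scores.
#' @param suggestive,strong Class thresholds.
#' @return Factor with levels `none`, `suggestive`, `strong`.
#' @export
classify_windows <- function(zhp, suggestive = -4, strong = -6) {
  cls <- rep("none", length(zhp))
  cls[zhp <= suggestive] <- "suggestive"
  cls[zhp <= strong] <- "strong"
  factor(cls, levels = c("none", "suggestive", "strong"))
}

#' Creeping-window ZHp selective-sweep scan
#'
#' Runs the full scan for one group: pooled per-site allele counts, creeping
#' windows, window Hp, genome-wide (or per-chromosome) ZHp standardization
#' and selection classification.
#'
#' @param table Variant table.
#' @param panel Sample panel.
#' @param group Group to scan.
#' @param params A [window_params()].
#' @param standardize `"genome"` (one mean/sd across all windows; default) or
#'   `"chromosome"` (standardize within each chromosome).
#' @param suggestive,strong Classification thresholds (default -4, -6).
#' @return Object of class `sweep_scan`: list with `windows` tibble (`chrom`,
#'   `start`, `stop`, `n_snps`, `sum_maj`, `sum_min`, `hp`, `zhp`,
#'   `selection`), `group`, `params`, `hp_mean`, `hp_sd`.
#' @export
sweep_scan <- function(table, panel, group, params = window_params(),
                       standardize = c("genome", "chromosome"),
                       suggestive = -4, strong = -6) {
  standardize <- match.arg(standardize)
  counts <- site_allele_counts(table, panel, group, params$count_mode)
  windows <- build_creeping_windows(counts[, c("chrom", "pos")], params)
  if (nrow(windows) == 0) abort("no windows satisfy the parameters")
  windows <- window_allele_sums(windows, counts)
  windows$hp <- pooled_heterozygosity(windows$sum_maj, windows$sum_min)
  if (standardize == "genome") {
    windows$zhp <- zhp_standardize(windows$hp)
  } else {
    windows <- windows %>%
      group_by(.data$chrom) %>%
      mutate(zhp = zhp_standardize(.data$hp)) %>%
      ungroup()
  }
  windows$selection <- classify_windows(windows$zhp, suggestive, strong)
  structure(
    list(windows = select(windows, -"start_idx", -"end_idx"),
         group = group, params = params,
         hp_mean = mean(windows$hp), hp_sd = sd(windows$hp),
         thresholds = c(suggestive = suggestive, strong = strong)),
    class = "sweep_scan"
  )
}

#' @export
tidy.sweep_scan <- function(x, ...) x$windows

#' @export
glance.sweep_scan <- function(x, ...) {
  tibble(
    group = x$group,
    n_windows = nrow(x$windows),
    hp_mean = x$hp_mean, hp_sd = x$hp_sd,
    min_zhp = min(x$windows$zhp),
    n_suggestive = sum(x$windows$selection == "suggestive"),
    n_strong = sum(x$windows$selection == "strong")
  )
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat("ZHp sweep scan for group", x$group, "\n")
  print(glance(x))
  invisible(x)
}

#' Manhattan-style plot of a sweep scan
#'
#' Plots window ZHp along concatenated chromosomes with the suggestive and
#' strong thresholds as horizontal lines.
#'
#' @param object A `sweep_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sweep_scan <- function(object, ...) {
  w <- object$windows %>%
    group_by(.data$chrom) %>%
    mutate(mid = (.data$start + .data$stop) / 2) %>%
    ungroup()
  offs <- w %>%
    group_by(.data$chrom) %>%
    summarise(len = max(.data$stop), .groups = "drop") %>%
    mutate(offset = dplyr::lag(cumsum(.data$len), default = 0))
  w <- left_join(w, offs, by = "chrom") %>%
    mutate(x = .data$mid + .data$offset)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$x, y = .data$zhp,
                                  colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = object$thresholds[["suggestive"]],
                        colour = "red") +
    ggplot2::geom_hline(yintercept = object$thresholds[["strong"]],
                        colour = "blue") +
    ggplot2::labs(x = "genome position", y = "ZHp")
}

#' Merge strong windows into sweep regions
#'
#' Windows of the requested class whose intervals overlap or abut are
#' unioned into regions; each region reports its window count, mean and
#' sample-SD of member ZHp (SD absent for single-window regions) and the
#' names of overlapping genes.
#'
#' @param scan A `sweep_scan` (or a window tibble with `chrom`, `start`,
#'   `stop`, `zhp`, `selection`).
#' @param genes Optional gene tibble (`chrom`, `start`, `stop`, `name`).
#' @param class Window class to merge (default `"strong"`).
#' @return Tibble `chrom`, `start`, `stop`, `n_windows`, `mean_zhp`,
#'   `sd_zhp`, `genes` (comma-joined names, `""` if none or no annotation).
#' @export
merge_sweep_regions <- function(scan, genes = NULL, class = "strong") {
  w <- if (inherits(scan, "sweep_scan")) scan$windows else scan
  w <- filter(w, .data$selection == class)
  if (nrow(w) == 0) {
    return(tibble(chrom = character(), start = numeric(), stop = numeric(),
                  n_windows = integer(), mean_zhp = numeric(),
                  sd_zhp = numeric(), genes = character()))
  }
  w <- arrange(w, .data$chrom, .data$start, .data$stop)
  regions <- w %>%
    group_by(.data$chrom) %>%
    mutate(new_region = cumsum(
      c(1L, as.integer(.data$start[-1] > cummax(.data$stop)[-n()] + 1)))) %>%
    group_by(.data$chrom, .data$new_region) %>%
    summarise(start = min(.data$start), stop = max(.data$stop),
              n_windows = n(),
              mean_zhp = mean(.data$zhp),
              sd_zhp = if (n() > 1) sd(.data$zhp) else NA_real_,
              .groups = "drop") %>%
    select(-"new_region")
  regions$genes <- vapply(seq_len(nrow(regions)), function(i) {
    if (is.null(genes)) return("")
    hit <- genes$chrom == regions$chrom[i] &
      genes$start <= regions$stop[i] & genes$stop >= regions$start[i]
    paste(genes$name[hit], collapse = ",")
  }, "")
  regions
}

#' Descriptive summary of ZHp scores
#'
#' Reports the count, extrema, mode (after rounding to 2 decimals, with its
#' multiplicity), median, mean and sample SD of the window scores.
#'
#' @param scan A `sweep_scan` or numeric vector of ZHp values.
#' @return One-row tibble `n_windows`, `min`, `max`, `mode`, `n_mode`,
#'   `median`, `mean`, `sd` (`sd` is NA for a single score).
#' @export
zhp_summary <- function(scan) {
  z <- if (inherits(scan, "sweep_scan")) scan$windows$zhp else scan
  if (length(z) == 0) abort("no scores")
  rz <- round(z, 2)
  tab <- table(rz)
  top <- max(tab)
  mode_val <- min(as.numeric(names(tab)[tab == top]))
  tibble(
    n_windows = length(z),
    min = min(z), max = max(z),
    mode = mode_val, n_mode = as.integer(top),
    median = median(z), mean = mean(z),
    sd = if (length(z) > 1) sd(z) else NA_real_
  )
}

#' Half-set robustness check of strong sweep regions
#'
#' Draws a phenotype-balanced subset of the scanned group (stratified by
#' `trait`, largest-remainder rounding of stratum targets), reruns the scan
#' on the subset, and reports for every full-set strong region the subset's
#' window count, mean and SD of ZHp over the same interval and whether the
#' region still passes the suggestive threshold (subset mean ZHp at or below
#' `suggestive`).
#'
#' @param table Variant table.
#' @param panel Sample panel.
#' @param group Group to scan.
#' @param params A [window_params()].
#' @param subset_size Subset size (default half the group, rounded).
#' @param trait Panel column used for phenotype balance (default "tufted";
#'   NULL for unstratified sampling).
#' @param seed Integer seed for the within-stratum draw.
#' @param suggestive Pass threshold (default -4).
#' @return Object of class `half_set_check`: list with `regions` (per-region
#'   tibble incl. `sub_n_windows`, `sub_mean_zhp`, `sub_sd_zhp`, `pass`),
#'   `subset` (sample ids), `all_pass`.
#' @export
half_set_check <- function(table, panel, group, params = window_params(),
                           subset_size = NULL, trait = "tufted", seed = 1L,
                           suggestive = -4) {
  samples <- group_samples(panel, group)
  if (is.null(subset_size)) subset_size <- round(length(samples) / 2)
  if (subset_size < 2) abort("subset size must be at least 2")
  if (subset_size > length(samples)) {
    abort(paste0("subset size exceeds group size (", length(samples), ")"))
  }
  gp <- panel[panel$sample %in% samples, ]
  if (!is.null(trait) && subset_size < length(samples)) {
    if (!trait %in% names(panel)) abort(paste0("no trait column '", trait, "'"))
    strata <- split(gp$sample, gp[[trait]])
    target <- subset_size * lengths(strata) / length(samples)
    take <- floor(target)
    rem <- subset_size - sum(take)
    if (rem > 0) {
      ord <- order(target - take, decreasing = TRUE)
      take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
    }
    if (any(take > lengths(strata))) {
      abort(paste0("cannot balance trait '", trait, "'; achievable per-stratum ",
                   "maxima: ", paste(names(strata), lengths(strata),
                                     sep = "=", collapse = ", ")))
    }
    set.seed(as.integer(seed))
    subset <- unlist(Map(function(s, k) if (k > 0) sort(sample(s, k)) else character(0),
                         strata, take), use.names = FALSE)
  } else {
    set.seed(as.integer(seed))
    subset <- sort(sample(samples, subset_size))
  }

  full <- sweep_scan(table, panel, group, params)
  regions <- merge_sweep_regions(full)
  sub_panel <- panel[panel$sample %in% subset | panel$group != group, ]
  sub_table <- filter(table, .data$sample %in% sub_panel$sample)
  sub <- sweep_scan(sub_table, sub_panel, group, params)

  res <- regions
  stats <- lapply(seq_len(nrow(regions)), function(i) {
    hit <- sub$windows$chrom == regions$chrom[i] &
      sub$windows$start <= regions$stop[i] &
      sub$windows$stop >= regions$start[i]
    z <- sub$windows$zhp[hit]
    tibble(sub_n_windows = sum(hit),
           sub_mean_zhp = if (length(z)) mean(z) else NA_real_,
           sub_sd_zhp = if (length(z) > 1) sd(z) else NA_real_)
  })
  res <- dplyr::bind_cols(res, bind_rows(stats))
  res$pass <- !is.na(res$sub_mean_zhp) & res$sub_mean_zhp <= suggestive
  structure(
    list(regions = res, subset = subset,
         all_pass = nrow(res) == 0 || all(res$pass),
         full_scan = full, subset_scan = sub),
    class = "half_set_check"
  )
}

#' @export
tidy.half_set_check <- function(x, ...) x$regions

#' Export windows or regions as BED
#'
#' Converts 1-based closed intervals to BED's 0-based half-open convention.
#'
#' @param x Tibble with `chrom`, `start`, `stop` (1-based closed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  readr::write_tsv(
    tibble(chrom = x$chrom, start = as.integer(x$start - 1),
           stop = as.integer(x$stop)),
    path, col_names = FALSE)
  invisible(path)
}
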