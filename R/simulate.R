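#' Declare a synthetic genome layout
#'
#' @param chromosomes Named numeric vector: chromosome name -> length (bp).
#' @param snp_density SNPs per bp (default 1 per 200 bp).
#' @param base_depth Mean sequencing depth per sample per site.
#' @param fst Between-group divergence parameter in `[0, 1)`; under the
#'   Balding-Nichols construction each group's allele frequency is Beta
#'   distributed around the ancestral frequency with variance
#'   `fst * p * (1 - p)`.
#' @return An object of class `genome_spec`.
#' @examples
#' genome_spec(c(`1` = 2e6, `2` = 2e6))
#' @export
genome_spec <- function(chromosomes = c(`1` = 2e6, `2` = 2e6),
                        snp_density = 1 / 200,
                        base_depth = 10,
                        fst = 0.1) {
  if (length(chromosomes) == 0 || is.null(names(chromosomes))) {
    abort("`chromosomes` must be a named vector of lengths")
  }
  if (any(chromosomes <= 0)) abort("chromosome lengths must be positive")
  if (snp_density <= 0) abort("snp_density must be positive")
  if (fst < 0 || fst >= 1) abort("fst must lie in [0, 1)")
  structure(
    list(chromosomes = chromosomes, snp_density = snp_density,
         base_depth = base_depth, fst = fst),
    class = "genome_spec"
  )
}

#' Simulate a multi-sample diploid genotype table
#'
#' Draws biallelic SNPs along each chromosome. Ancestral allele frequencies
#' are Uniform(0.05, 0.95); each group's frequency is Balding-Nichols
#' (Beta with mean `p` and variance `fst * p * (1-p)`); diploid dosages are
#' Binomial(2, group frequency). Per-sample read depth is Poisson(base_depth)
#' floored at 1, allele depths are Binomial(DP, dosage/2), and site QUAL / MQ
#' are Uniform(41, 100) so that all sites survive the default filters.
#'
#' @param panel Sample panel tibble (see [simulate_panel()]).
#' @param genome A [genome_spec()].
#' @param seed Integer seed; output is deterministic for a fixed seed.
#' @param missing_rate Fraction of genotypes set missing (default 0; the
#'   default matches a pipeline demanding 0% missing data, the knob exists to
#'   exercise the missingness filter).
#' @param low_quality_rate Fraction of sites drawn with QUAL/MQ below the
#'   default filter thresholds (Uniform(1, 40)), to exercise quality filters.
#' @return A variant table: long tibble with one row per site x sample and
#'   columns `chrom`, `pos`, `ref`, `alt`, `qual`, `mq`, `sample`, `gt`,
#'   `dp`, `ad_ref`, `ad_alt`.
#' @export
simulate_genotypes <- function(panel, genome, seed = 1L,
                               missing_rate = 0, low_quality_rate = 0) {
  stopifnot(inherits(genome, "genome_spec"))
  if (nrow(panel) == 0) abort("panel is empty")
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  fst <- genome$fst

  site_list <- lapply(names(genome$chromosomes), function(chr) {
    len <- genome$chromosomes[[chr]]
    n <- max(1L, round(len * genome$snp_density))
    tibble(
      chrom = chr,
      pos = sort(sample.int(len, n)),
      p = runif(n, 0.05, 0.95)
    )
  })
  sites <- bind_rows(site_list)
  ns <- nrow(sites)
  ref <- sample(bases, ns, replace = TRUE)
  alt_shift <- sample.int(3, ns, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1L + alt_shift) %% 4L + 1L]
  qual <- round(runif(ns, 41, 100), 2)
  mq <- round(runif(ns, 41, 100), 2)
  if (low_quality_rate > 0) {
    lowq <- runif(ns) < low_quality_rate
    qual[lowq] <- round(runif(sum(lowq), 1, 40), 2)
    lowm <- runif(ns) < low_quality_rate
    mq[lowm] <- round(runif(sum(lowm), 1, 40), 2)
  }
  sites <- mutate(sites, ref = ref, alt = alt, qual = qual, mq = mq)

  groups <- unique(panel$group)
  gfreq <- matrix(NA_real_, ns, length(groups), dimnames = list(NULL, groups))
  for (g in groups) {
    if (fst == 0) {
      gfreq[, g] <- sites$p
    } else {
      shape_scale <- (1 - fst) / fst
      gfreq[, g] <- rbeta(ns, sites$p * shape_scale, (1 - sites$p) * shape_scale)
    }
  }

  per_sample <- lapply(seq_len(nrow(panel)), function(i) {
    q <- gfreq[, panel$group[i]]
    dosage <- rbinom(ns, 2L, q)
    dp <- pmax(1L, rpois(ns, genome$base_depth))
    ad_alt <- rbinom(ns, dp, dosage / 2)
    gt <- dosage_to_gt(dosage)
    if (missing_rate > 0) {
      miss <- runif(ns) < missing_rate
      gt[miss] <- NA_character_
    }
    tibble(
      chrom = sites$chrom, pos = sites$pos,
      sample = panel$sample[i],
      gt = gt, dp = dp, ad_ref = dp - ad_alt, ad_alt = ad_alt
    )
  })
  calls <- bind_rows(per_sample)
  out <- inner_join(sites[, c("chrom", "pos", "ref", "alt", "qual", "mq")],
                    calls, by = c("chrom", "pos"))
  arrange(out, factor(.data$chrom, levels = names(genome$chromosomes)),
          .data$pos, match(.data$sample, panel$sample))
}

# Deterministically rewrite allele depths after a genotype edit.
redraw_ad <- function(dp, dosage) {
  ad_alt <- as.integer(round(dp * dosage / 2))
  list(ad_ref = dp - ad_alt, ad_alt = ad_alt)
}

#' Plant a selective sweep into a variant table
#'
#' Within `region`, for the named group, genotypes are rewritten so the
#' group's major allele reaches at least the requested frequency; sites where
#' the major allele already meets it are left unchanged. Other groups are
#' untouched. Allele depths are recomputed from the new dosages with depth
#' preserved, so allele-depth pooling sees the fixation too.
#'
#' @param table Variant table (long tibble, see [simulate_genotypes()]).
#' @param region Region list or `"chrom:start-stop"` string (1-based closed).
#' @param group Group whose haplotypes sweep.
#' @param panel Sample panel mapping samples to groups.
#' @param fixation Target major-allele frequency in `[0, 1]`.
#' @return The modified variant table.
#' @export
plant_sweep <- function(table, region, group, panel, fixation = 1) {
  if (fixation < 0 || fixation > 1) abort("fixation must lie in [0, 1]")
  region <- parse_region(region)
  samples <- group_samples(panel, group)
  in_region <- table$chrom == region$chrom &
    table$pos >= region$start & table$pos <= region$stop
  if (!any(in_region)) {
    warn("region overlaps no sites; table returned unchanged")
    return(table)
  }
  target <- table[in_region & table$sample %in% samples, ]
  if (nrow(target) == 0) return(table)

  edited <- target %>%
    group_by(.data$chrom, .data$pos) %>%
    mutate(new_dosage = fix_major(gt_to_dosage(.data$gt), fixation)) %>%
    ungroup()
  changed <- edited$new_dosage != gt_to_dosage(edited$gt)
  ad <- redraw_ad(edited$dp[changed], edited$new_dosage[changed])
  edited$gt[changed] <- dosage_to_gt(edited$new_dosage[changed])
  edited$ad_ref[changed] <- ad$ad_ref
  edited$ad_alt[changed] <- ad$ad_alt
  edited$new_dosage <- NULL
  # group_by/mutate preserves row order, so `edited` aligns with `target`
  table[which(in_region & table$sample %in% samples), ] <- edited
  table
}

# Raise the within-group major allele of one site to >= `fixation` frequency.
# Returns the new dosage vector (alt-allele dosage). Deterministic: samples
# already carrying more of the major allele are converted first.
fix_major <- function(dosage, fixation) {
  if (anyNA(dosage)) abort("cannot plant a sweep over missing genotypes")
  n2 <- 2L * length(dosage)
  alt_count <- sum(dosage)
  major_is_alt <- alt_count * 2L > n2 # strict majority; tie -> ref is major
  maj <- if (major_is_alt) dosage else 2L - dosage
  need <- ceiling(fixation * n2)
  if (sum(maj) >= need) return(dosage)
  ord <- order(-maj, seq_along(maj))
  maj_new <- maj
  for (i in ord) {
    if (sum(maj_new) >= need) break
    maj_new[i] <- min(2L, maj_new[i] + (need - sum(maj_new)))
  }
  if (major_is_alt) maj_new else 2L - maj_new
}

#' Plant breed-discriminant marker sites
#'
#' Rewrites `n` randomly chosen sites so that every focal-group sample is
#' heterozygous or homozygous alternate (alternating 0/1 and 1/1) and every
#' other sample is homozygous reference -- the genotype pattern used for
#' candidate-marker selection. Allele depths are recomputed accordingly.
#'
#' @inheritParams plant_sweep
#' @param n Number of marker sites to plant.
#' @param focal_group The group that carries the alternate allele.
#' @param seed Integer seed for site choice.
#' @return List with elements `table` (modified variant table) and `truth`
#'   (tibble of planted `chrom`, `pos`, `pattern`).
#' @export
plant_discriminant_markers <- function(table, n, focal_group, panel, seed = 1L) {
  sites <- distinct(table, .data$chrom, .data$pos)
  if (n > nrow(sites)) abort("n exceeds the number of available sites")
  if (n == 0) {
    return(list(table = table, truth = tibble(chrom = character(), pos = integer(),
                                              pattern = character())))
  }
  set.seed(as.integer(seed))
  chosen <- sites[sort(sample.int(nrow(sites), n)), ]
  focal <- group_samples(panel, focal_group)

  key <- paste(table$chrom, table$pos)
  sel <- key %in% paste(chosen$chrom, chosen$pos)
  sub <- table[sel, ]
  is_focal <- sub$sample %in% focal
  # alternate het / hom-alt across focal samples, stable in sample order
  focal_rank <- ave(seq_len(nrow(sub)), paste(sub$chrom, sub$pos),
                    FUN = function(i) cumsum(is_focal[i]))
  new_dosage <- ifelse(is_focal, ifelse(focal_rank %% 2 == 1, 1L, 2L), 0L)
  ad <- redraw_ad(sub$dp, new_dosage)
  table[sel, c("gt", "ad_ref", "ad_alt")] <-
    tibble(gt = dosage_to_gt(new_dosage), ad_ref = ad$ad_ref, ad_alt = ad$ad_alt)
  list(table = table,
       truth = mutate(chosen, pattern = "focal_het_or_alt"))
}

#' Simulate per-sample read-depth windows with an optional duplication
#'
#' Counts per non-overlapping window are Poisson(base_depth); inside a
#' planted duplication interval the counts of carrier samples are multiplied
#' by the fold change.
#'
#' @param samples Character vector of sample ids.
#' @param chrom Chromosome name.
#' @param chrom_len Chromosome length (bp).
#' @param window Window size in bp (default 4000); the last window is
#'   truncated at the chromosome end.
#' @param base_depth Mean best-hit read count per window per sample.
#' @param dup Optional list `(start, stop, fold, carriers)` describing a
#'   duplication; `fold` must be positive.
#' @param seed Integer seed.
#' @return Long tibble `sample`, `chrom`, `start`, `stop`, `count`.
#' @export
simulate_depth_windows <- function(samples, chrom, chrom_len, window = 4000,
                                   base_depth = 100, dup = NULL, seed = 1L) {
  if (window <= 0) abort("window size must be positive")
  if (!is.null(dup) && dup$fold <= 0) abort("duplication fold must be positive")
  set.seed(as.integer(seed))
  starts <- seq(1, chrom_len, by = window)
  stops <- pmin(starts + window - 1, chrom_len)
  nw <- length(starts)
  out <- lapply(samples, function(s) {
    count <- rpois(nw, base_depth)
    if (!is.null(dup) && s %in% dup$carriers) {
      in_dup <- starts <= dup$stop & stops >= dup$start
      count[in_dup] <- count[in_dup] * dup$fold
    }
    tibble(sample = s, chrom = chrom, start = starts, stop = stops, count = count)
  })
  bind_rows(out)
}

#' Build the default synthetic study fixture
#'
#' Convenience wrapper producing the package's standard desk-scale fixture:
#' the 15-sample, 4-group panel of [default_panel_spec()], a 2 x 2 Mb genome
#' at 1 SNP / 200 bp (~20k sites) with group divergence `fst`, one planted
#' full-fixation sweep in the focal group, and optionally planted
#' discriminant markers.
#'
#' @param seed Integer seed driving all randomness.
#' @param fst Divergence parameter (default 0.1).
#' @param sweep_region Region to sweep (default `"1:1000000-1100000"`,
#'   a 100 kb interval) or NULL to skip planting.
#' @param focal_group Group carrying the sweep/markers (default "NAA").
#' @param n_markers Number of planted discriminant marker sites (default 0).
#' @return List with `table`, `panel`, `genome`, `truth` (list with
#'   `sweep_regions` and `discriminant_sites` tibbles).
#' @export
default_fixture <- function(seed = 1L, fst = 0.1,
                            sweep_region = "1:1000000-1100000",
                            focal_group = "NAA", n_markers = 0) {
  panel <- simulate_panel(default_panel_spec())
  genome <- genome_spec(fst = fst)
  table <- simulate_genotypes(panel, genome, seed = seed)
  truth <- list(
    sweep_regions = tibble(chrom = character(), start = numeric(),
                           stop = numeric(), group = character()),
    discriminant_sites = tibble(chrom = character(), pos = integer(),
                                pattern = character())
  )
  if (!is.null(sweep_region)) {
    r <- parse_region(sweep_region)
    table <- plant_sweep(table, r, focal_group, panel, fixation = 1)
    truth$sweep_regions <- tibble(chrom = r$chrom, start = r$start,
                                  stop = r$stop, group = focal_group)
  }
  if (n_markers > 0) {
    planted <- plant_discriminant_markers(table, n_markers, focal_group, panel,
                                          seed = seed + 1L)
    table <- planted$table
    truth$discriminant_sites <- planted$truth
  }
  list(table = table, panel = panel, genome = genome, truth = truth)
}
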