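#' Site filter criteria
#'
#' The default criteria reproduce a stringent post-calling SNP filter:
#' biallelic SNPs on autosomes only, site QUAL strictly above 40, RMS mapping
#' quality (INFO MQ) strictly above 40, every sample's depth at least 3, and
#' zero missing genotypes. Strict vs non-strict boundaries are deliberate:
#' `QUAL > 40`, `MQ > 40`, `DP >= 3`.
#'
#' @param snps_only Keep only sites whose REF and every ALT are single bases.
#' @param biallelic_only Keep only sites with exactly one ALT allele.
#' @param autosomes Character vector of admissible chromosome names. Defaults
#'   to chicken autosomes 1-28, 30, 32, 33 and LGE64.
#' @param min_dp Minimum per-sample depth (inclusive).
#' @param min_mq_exclusive Sites must have MQ strictly greater than this.
#' @param min_qual_exclusive Sites must have QUAL strictly greater than this.
#' @param max_missing_fraction Maximum tolerated fraction of missing
#'   genotypes per site (default 0).
#' @return An object of class `filter_criteria`.
#' @export
filter_criteria <- function(snps_only = TRUE,
                            biallelic_only = TRUE,
                            autosomes = c(as.character(c(1:28, 30, 32, 33)), "LGE64"),
                            min_dp = 3,
                            min_mq_exclusive = 40,
                            min_qual_exclusive = 40,
                            max_missing_fraction = 0) {
  if (length(autosomes) == 0) abort("autosome set must be nonempty")
  if (min_dp < 0 || min_mq_exclusive < 0 || min_qual_exclusive < 0 ||
      max_missing_fraction < 0) {
    abort("thresholds must be nonnegative")
  }
  structure(
    list(snps_only = snps_only, biallelic_only = biallelic_only,
         autosomes = autosomes, min_dp = min_dp,
         min_mq_exclusive = min_mq_exclusive,
         min_qual_exclusive = min_qual_exclusive,
         max_missing_fraction = max_missing_fraction),
    class = "filter_criteria"
  )
}

#' Apply site filters to a variant table
#'
#' A site is kept only if it satisfies every rule. The rejection tally
#' attributes each rejected site to its first failing rule in the fixed
#' order autosome, snp, biallelic, qual, mq, dp, missing (the kept set is
#' order-independent; only the attribution needs an order).
#'
#' @param table Variant table (long tibble).
#' @param criteria A [filter_criteria()].
#' @return List with `sites` (kept rows of `table`), `tally` (tibble `rule`,
#'   `n_rejected`), `n_input` and `n_kept` (site counts).
#' @export
apply_site_filters <- function(table, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  site <- table %>%
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt, .data$qual, .data$mq) %>%
    summarise(
      min_dp_ok = all(!is.na(.data$dp) & .data$dp >= criteria$min_dp),
      missing_frac = mean(is.na(.data$gt)),
      .groups = "drop"
    )
  alt_lens <- strsplit(site$alt, ",", fixed = TRUE)
  ok <- list(
    autosome = site$chrom %in% criteria$autosomes,
    snp = !criteria$snps_only |
      (nchar(site$ref) == 1 &
         vapply(alt_lens, function(a) all(nchar(a) == 1), TRUE)),
    biallelic = !criteria$biallelic_only |
      vapply(alt_lens, length, 1L) == 1L,
    qual = !is.na(site$qual) & site$qual > criteria$min_qual_exclusive,
    mq = !is.na(site$mq) & site$mq > criteria$min_mq_exclusive,
    dp = site$min_dp_ok,
    missing = site$missing_frac <= criteria$max_missing_fraction
  )
  keep <- Reduce(`&`, ok)
  # first failing rule per rejected site
  fail_idx <- apply(!do.call(cbind, ok), 1, function(x) {
    w <- which(x)
    if (length(w)) w[1] else NA_integer_
  })
  tally <- tibble(rule = names(ok),
                  n_rejected = vapply(seq_along(ok), function(i)
                    sum(fail_idx == i, na.rm = TRUE), 1L))
  kept_sites <- site[keep, c("chrom", "pos")]
  out <- semi_join(table, kept_sites, by = c("chrom", "pos"))
  list(sites = out, tally = tally,
       n_input = nrow(site), n_kept = sum(keep))
}

#' Drop sites monomorphic-reference within a group
#'
#' Retains sites where at least one sample of `group` carries an alternate
#' allele; used before per-group consequence annotation.
#'
#' @param table Variant table.
#' @param panel Sample panel.
#' @param group Group name.
#' @return Filtered variant table.
#' @export
remove_group_monomorphic <- function(table, panel, group) {
  samples <- group_samples(panel, group)
  keep <- table %>%
    filter(.data$sample %in% samples) %>%
    group_by(.data$chrom, .data$pos) %>%
    summarise(has_alt = any(gt_to_dosage(.data$gt) > 0, na.rm = TRUE),
              .groups = "drop") %>%
    filter(.data$has_alt)
  semi_join(table, keep, by = c("chrom", "pos"))
}

#' Build a dosage genotype matrix
#'
#' @param table Variant table with zero missing genotypes (post-filter).
#' @param panel Sample panel; rows of the matrix follow its sample order.
#' @return Numeric matrix samples x sites of alt-allele dosage in {0,1,2};
#'   column names are `chrom:pos`, with per-site ref/alt carried in the
#'   `allele_meta` attribute.
#' @export
genotype_matrix <- function(table, panel) {
  miss <- is.na(table$gt)
  if (any(miss)) {
    i <- which(miss)[1]
    abort(paste0("missing genotype at ", table$chrom[i], ":", table$pos[i],
                 " sample ", table$sample[i]))
  }
  extra <- setdiff(unique(table$sample), panel$sample)
  if (length(extra)) abort(paste0("samples not in panel: ",
                                  paste(extra, collapse = ", ")))
  sites <- distinct(table, .data$chrom, .data$pos, .data$ref, .data$alt) %>%
    arrange(.data$chrom, .data$pos)
  if (nrow(sites) == 0) {
    m <- matrix(numeric(0), nrow = nrow(panel), ncol = 0,
                dimnames = list(panel$sample, NULL))
    attr(m, "allele_meta") <- sites
    return(m)
  }
  key <- paste0(sites$chrom, ":", sites$pos)
  m <- matrix(NA_real_, nrow = nrow(panel), ncol = nrow(sites),
              dimnames = list(panel$sample, key))
  ri <- match(table$sample, panel$sample)
  ci <- match(paste0(table$chrom, ":", table$pos), key)
  m[cbind(ri, ci)] <- gt_to_dosage(table$gt)
  if (anyNA(m)) abort("genotype matrix has holes: table does not cover all panel samples at all sites")
  attr(m, "allele_meta") <- sites
  m
}

#' Greedy LD pruning of a genotype matrix (optional)
#'
#' A light composite-LD pruner: within sliding windows of `window_bp`, sites
#' are dropped greedily whenever their squared Pearson correlation of dosages
#' with an already-kept site exceeds `r2_threshold`. Provided as an optional
#' pre-analysis thinning step; no default pipeline applies it.
#'
#' @param matrix Dosage matrix from [genotype_matrix()].
#' @param r2_threshold Squared-correlation threshold (default 0.2).
#' @param window_bp Window span in bp (default 5e5).
#' @return Pruned matrix (same class / attributes).
#' @export
ld_prune <- function(matrix, r2_threshold = 0.2, window_bp = 5e5) {
  meta <- attr(matrix, "allele_meta")
  if (ncol(matrix) < 2) return(matrix)
  keep <- logical(ncol(matrix))
  kept_idx <- integer(0)
  for (j in seq_len(ncol(matrix))) {
    cand <- kept_idx[meta$chrom[kept_idx] == meta$chrom[j] &
                       meta$pos[j] - meta$pos[kept_idx] <= window_bp]
    ok <- TRUE
    for (i in cand) {
      v1 <- matrix[, i]; v2 <- matrix[, j]
      if (sd(v1) == 0 || sd(v2) == 0) next
      if (stats::cor(v1, v2)^2 > r2_threshold) { ok <- FALSE; break }
    }
    keep[j] <- ok
    if (ok) kept_idx <- c(kept_idx, j)
  }
  out <- matrix[, keep, drop = FALSE]
  attr(out, "allele_meta") <- meta[keep, ]
  out
}
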