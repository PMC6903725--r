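# Shared fixture builders and independent oracles for the test suite.

# Build a long variant table from a genotype string matrix (samples x sites).
# Depth is constant; allele depths follow the dosage deterministically.
make_toy_table <- function(gt, chrom = "1", pos = NULL, samples = NULL,
                           qual = 60, mq = 60, dp = 10) {
  n_samp <- nrow(gt); n_site <- ncol(gt)
  if (is.null(pos)) pos <- seq(100, by = 100, length.out = n_site)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(n_samp))
  qual <- rep_len(qual, n_site); mq <- rep_len(mq, n_site)
  dp <- rep_len(dp, n_site)
  j <- rep(seq_len(n_site), each = n_samp)   # site-major, sample-minor
  i <- rep(seq_len(n_samp), times = n_site)
  g <- gt[cbind(i, j)]
  dos <- dplyr::case_match(g, "0/0" ~ 0L, "0/1" ~ 1L, "1/1" ~ 2L)
  ad_alt <- as.integer(round(dp[j] * dos / 2))
  tibble::tibble(
    chrom = chrom, pos = pos[j], ref = "A", alt = "C",
    qual = qual[j], mq = mq[j], sample = samples[i],
    gt = g, dp = dp[j],
    ad_ref = dp[j] - ad_alt, ad_alt = ad_alt)
}

make_toy_panel <- function(samples, groups) {
  tibble::tibble(sample = samples, group = groups)
}

# Independent brute-force creeping-window builder: literal loop over starts,
# extending one SNP at a time under the gap and span rules.
brute_force_windows <- function(pos, max_span, max_gap, min_snps, start_step = 1) {
  n <- length(pos)
  out <- list()
  for (i in seq(1, n, by = start_step)) {
    j <- i
    while (j < n &&
           pos[j + 1] - pos[j] < max_gap &&
           pos[j + 1] - pos[i] <= max_span) {
      j <- j + 1
    }
    if (j - i + 1 >= min_snps) {
      out[[length(out) + 1L]] <- c(start = pos[i], stop = pos[j],
                                   n_snps = j - i + 1)
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = numeric(0), stop = numeric(0), n_snps = numeric(0)))
  }
  as.data.frame(do.call(rbind, out))
}

# Independent interval-union oracle: connected components of the overlap/abut
# graph, quadratic in the number of intervals.
brute_force_merge <- function(start, stop) {
  n <- length(start)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- start[j] <= stop[i] + 1 && start[i] <= stop[j] + 1
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nb <- which(adj[frontier[1], ] & is.na(comp))
      comp[nb] <- cur
      frontier <- c(frontier[-1], nb)
    }
  }
  data.frame(
    start = tapply(start, comp, min),
    stop = tapply(stop, comp, max),
    n = as.integer(table(comp))
  )
}

# A compact 5k-site fixture for discriminant tests: one 1 Mb chromosome at
# 1 SNP / 200 bp, 15 samples, with n_markers planted pattern sites.
marker_fixture <- function(seed, n_markers = 10, fst = 0.1) {
  panel <- simulate_panel(default_panel_spec())
  genome <- genome_spec(chromosomes = c(`1` = 1e6), fst = fst)
  tab <- simulate_genotypes(panel, genome, seed = seed)
  planted <- plant_discriminant_markers(tab, n_markers, "NAA", panel,
                                        seed = seed + 1L)
  list(table = planted$table, panel = panel, truth = planted$truth)
}

# Independent per-site rule oracle: literal evaluation of each filter rule
# on one site's rows of the long table.
oracle_keep <- function(site_rows, crit) {
  alts <- strsplit(site_rows$alt[1], ",")[[1]]
  all(
    site_rows$chrom[1] %in% crit$autosomes,
    nchar(site_rows$ref[1]) == 1 && all(nchar(alts) == 1),
    length(alts) == 1,
    !is.na(site_rows$qual[1]) && site_rows$qual[1] > crit$min_qual_exclusive,
    !is.na(site_rows$mq[1]) && site_rows$mq[1] > crit$min_mq_exclusive,
    all(!is.na(site_rows$dp) & site_rows$dp >= crit$min_dp),
    mean(is.na(site_rows$gt)) <= crit$max_missing_fraction
  )
}

# 20-site toy panel covering every rule violation plus boundary cases.
toy_filter_table <- function() {
  gt <- matrix("0/1", nrow = 3, ncol = 20)
  tab <- make_toy_table(gt, chrom = "1", pos = seq(1000, by = 1000, length.out = 20))
  edit <- function(tab, pos, col, value, sample = NULL) {
    i <- tab$pos == pos & (if (is.null(sample)) TRUE else tab$sample == sample)
    tab[i, col] <- value
    tab
  }
  tab <- edit(tab, 2000, "qual", 40)       # boundary: QUAL = 40 -> reject
  tab <- edit(tab, 3000, "qual", 40.01)    # just above -> keep
  tab <- edit(tab, 4000, "mq", 40)         # boundary: MQ = 40 -> reject
  tab <- edit(tab, 5000, "mq", 12)         # well below -> reject
  tab <- edit(tab, 6000, "dp", 2, "S01")   # one sample below DP 3 -> reject
  tab <- edit(tab, 7000, "dp", 3)          # boundary: DP = 3 everywhere -> keep
  tab <- edit(tab, 8000, "gt", NA, "S02")  # missing genotype -> reject
  tab <- edit(tab, 9000, "alt", "C,G")     # multiallelic -> reject
  tab <- edit(tab, 10000, "alt", "CT")     # indel-like alt -> reject
  tab <- edit(tab, 11000, "ref", "AT")     # indel-like ref -> reject
  tab$chrom[tab$pos == 12000] <- "Z"       # sex chromosome -> reject
  tab$chrom[tab$pos == 13000] <- "LGE64"   # named autosome -> keep
  tab <- edit(tab, 14000, "qual", NA)      # missing QUAL -> reject
  tab
}
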