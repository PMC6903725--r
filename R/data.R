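#' Chromosome 15 deletion records of the Araucana study population
#'
#' The 21 break-end structural variants called on chicken chromosome 15 in
#' six North American Araucana, with per-sample call status and genotype.
#' The published table's sample header is garbled (one sample listed twice,
#' one never); the shipped copy assigns the six columns to NAA01-NAA06 in
#' order, consistent with the published per-bird phenotypes.
#'
#' @param path Optional alternative TSV (same wide layout: one row per
#'   record, two columns `<sample>_status` / `<sample>_gt` per sample).
#' @return Long tibble: `chrom`, `start`, `stop`, `size`, `gene`,
#'   `description`, `position_class`, `sample`, `status`, `genotype`.
#' @export
araucana_deletions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "chr15_deletions.tsv", package = "sweepkit")
  }
  read_deletion_table(path)
}

#' Read a wide deletion table TSV into long form
#'
#' @param path TSV with `start`, `stop`, `size`, `gene`, `description`,
#'   `position` and paired `<sample>_status` / `<sample>_gt` columns.
#' @param chrom Chromosome name to attach (default "15").
#' @return Long tibble as in [araucana_deletions()].
#' @export
read_deletion_table <- function(path, chrom = "15") {
  wide <- readr::read_tsv(path, col_types = readr::cols(
    start = readr::col_double(), stop = readr::col_double(),
    size = readr::col_double(), .default = readr::col_character()))
  status_cols <- grep("_status$", names(wide), value = TRUE)
  samples <- sub("_status$", "", status_cols)
  long <- lapply(samples, function(s) {
    tibble(chrom = chrom,
           start = wide$start, stop = wide$stop, size = wide$size,
           gene = wide$gene, description = wide$description,
           position_class = wide$position,
           sample = s,
           status = wide[[paste0(s, "_status")]],
           genotype = wide[[paste0(s, "_gt")]])
  })
  out <- bind_rows(long) %>% arrange(.data$start, .data$sample)
  bad <- (out$genotype == "0/0") != (out$status == "absent")
  if (any(bad)) abort("inconsistent deletion record: 0/0 must pair with status 'absent'")
  out
}

#' Two-locus rumplessness genotyping records
#'
#' Per-bird genotyping outcomes for the two rumplessness SNPs (SV1, SV2)
#' across tailed, partially tailed and rumpless birds, expanded to one row
#' per bird from the shipped count table.
#'
#' @param path Optional alternative TSV (`phenotype`, `sv1`, `sv2`, `n`).
#' @return Tibble `phenotype`, `sv1`, `sv2` (one row per bird).
#' @export
rp_genotyping_records <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rp_genotyping.tsv", package = "sweepkit")
  }
  counts <- readr::read_tsv(path, col_types = "ccci")
  counts[rep(seq_len(nrow(counts)), counts$n), c("phenotype", "sv1", "sv2")]
}

#' The study's 15-sample panel
#'
#' Sample-to-breed assignments and recorded phenotypes for the six North
#' American Araucana plus the three Korean Araucana, three Korean Domestic
#' and three White Leghorn comparison birds.
#'
#' @return Panel tibble (`sample`, `group`, `tufted`, `tail_status`, `sex`).
#' @export
araucana_panel <- function() {
  read_panel(system.file("extdata", "naa_panel.tsv", package = "sweepkit"))
}
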