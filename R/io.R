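#' Write a variant table as VCFv4.2
#'
#' Emits a plain-text VCF with QUAL, `INFO MQ=<float>` and per-sample
#' `GT:DP:AD`. Output is byte-identical for identical input tables.
#'
#' @param table Variant table (long tibble).
#' @param path Output file path.
#' @param sample_order Optional explicit sample column order; defaults to
#'   order of first appearance.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path, sample_order = NULL) {
  if (is.null(sample_order)) sample_order <- unique(table$sample)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepkit",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_order), collapse = "\t")
  )
  gt <- ifelse(is.na(table$gt), "./.", table$gt)
  call_str <- paste0(gt, ":", table$dp, ":", table$ad_ref, ",", table$ad_alt)
  wide <- table %>%
    mutate(call = call_str) %>%
    select("chrom", "pos", "ref", "alt", "qual", "mq", "sample", "call") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "call")
  fmt_num <- function(x) ifelse(is.na(x), ".", formatC(x, format = "f", digits = 2))
  body <- paste(
    wide$chrom, wide$pos, ".", wide$ref, wide$alt,
    fmt_num(wide$qual),
    ".", paste0("MQ=", fmt_num(wide$mq)),
    "GT:DP:AD",
    do.call(paste, c(unname(as.list(wide[, sample_order])), sep = "\t")),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a multi-sample VCF into a variant table
#'
#' Parsed with `vcfR`; multiallelic records are preserved as-is (comma-joined
#' ALT) unless `split_multiallelic` drops them to one row per record still --
#' splitting is intentionally not performed, downstream filters reject
#' multiallelic sites. Missing FORMAT fields become NA, never fabricated.
#'
#' @param path VCF file (plain or bgzipped).
#' @return Long variant table tibble (`chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `mq`, `sample`, `gt`, `dp`, `ad_ref`, `ad_alt`), samples in VCF column
#'   order.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "MQ")))
  n_na <- function() matrix(NA_character_, nrow(vcf@fix), length(samples))
  gt <- tryCatch(vcfR::extract.gt(vcf, "GT"), error = function(e) n_na())
  dp <- tryCatch(suppressWarnings(vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)),
                 error = function(e) n_na())
  ad <- tryCatch(vcfR::extract.gt(vcf, "AD"), error = function(e) n_na())
  n_site <- nrow(fix)
  site <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    mq = mq
  )
  long <- tidyr::expand_grid(i = seq_len(n_site), sample = samples)
  ad_vec <- if (is.null(ad)) rep(NA_character_, n_site * length(samples)) else
    as.vector(t(ad))
  ad_parts <- strsplit(ifelse(is.na(ad_vec), ",", ad_vec), ",", fixed = TRUE)
  ad_ref <- suppressWarnings(as.integer(vapply(
    ad_parts, function(x) if (length(x) >= 1) x[1] else NA_character_, "")))
  ad_alt <- suppressWarnings(as.integer(vapply(
    ad_parts, function(x) if (length(x) >= 2) x[2] else NA_character_, "")))
  gt_vec <- as.vector(t(gt))
  gt_vec[gt_vec %in% c("./.", ".|.", ".")] <- NA_character_
  out <- tibble(
    site[long$i, ],
    sample = long$sample,
    gt = gt_vec,
    dp = as.integer(as.vector(t(dp))),
    ad_ref = ad_ref,
    ad_alt = ad_alt
  )
  out
}

#' Write gene records as GFF3
#'
#' @param genes Tibble with `chrom`, `start`, `stop`, `gene_id`, `name`
#'   (1-based closed coordinates, as in GFF3).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  header <- "##gff-version 3"
  if (nrow(genes) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  body <- paste(genes$chrom, "sweepkit", "gene", genes$start, genes$stop,
                ".", "+", ".",
                paste0("ID=", genes$gene_id, ";Name=", genes$name),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read gene records from a GFF3 file
#'
#' Keeps rows of type "gene" and extracts ID / Name attributes.
#'
#' @param path GFF3 path.
#' @return Tibble `chrom`, `start`, `stop`, `gene_id`, `name`.
#' @export
read_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = numeric(), stop = numeric(),
                  gene_id = character(), name = character()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(f, length, 1L) != 9L)
  if (length(bad)) abort(paste0("malformed GFF3 record at data line ", bad[1]))
  m <- do.call(rbind, f)
  keep <- m[, 3] == "gene"
  m <- m[keep, , drop = FALSE]
  attr_field <- function(attrs, key) {
    v <- stringr::str_match(attrs, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
    v
  }
  tibble(
    chrom = m[, 1],
    start = as.numeric(m[, 4]),
    stop = as.numeric(m[, 5]),
    gene_id = attr_field(m[, 9], "ID"),
    name = attr_field(m[, 9], "Name")
  )
}

#' Write a complete fixture set
#'
#' Writes the VCF, GFF3 gene records, sample panel TSV and ground-truth JSON
#' for a simulated dataset; files round-trip losslessly through the package
#' readers.
#'
#' @param table Variant table.
#' @param panel Sample panel.
#' @param genes Gene tibble (may be empty).
#' @param truth List of truth tables (tibbles); written as JSON.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixtures <- function(table, panel, genes, truth, outdir) {
  if (!all(unique(table$sample) %in% panel$sample)) {
    abort("sample ids in table and panel disagree")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(outdir, "variants.vcf"),
    genes = file.path(outdir, "genes.gff3"),
    panel = file.path(outdir, "panel.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  write_vcf(table, paths[["vcf"]], sample_order = panel$sample)
  write_gff3(genes, paths[["genes"]])
  write_panel(panel, paths[["panel"]])
  jsonlite::write_json(truth, paths[["truth"]], digits = NA, pretty = TRUE)
  invisible(paths)
}

#' @rdname write_fixtures
#' @param path Truth JSON path.
#' @export
read_truth <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(out, as_tibble)
}
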