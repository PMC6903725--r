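#' Declare a sample panel design
#'
#' A panel spec describes the group composition (e.g. breeds) and per-sample
#' phenotype assignments of a resequencing panel. [simulate_panel()] expands
#' it into a one-row-per-sample tibble.
#'
#' @param groups Named integer vector: group name -> number of samples.
#' @param phenotypes Optional named list of trait -> character vector with one
#'   value per sample (in group order). Traits omitted here are not added.
#' @param seed Integer seed stored with the spec (used by downstream
#'   simulation helpers).
#' @return An object of class `panel_spec`.
#' @examples
#' panel_spec(c(NAA = 6, KA = 3, KD = 3, WL = 3))
#' @export
panel_spec <- function(groups, phenotypes = list(), seed = 1L) {
  if (length(groups) == 0 || is.null(names(groups)) || any(names(groups) == "")) {
    abort("`groups` must be a named vector of group sizes")
  }
  if (anyDuplicated(names(groups))) abort("duplicate group names")
  if (any(groups < 1)) abort("every group needs at least one sample")
  n <- sum(groups)
  for (trait in names(phenotypes)) {
    if (length(phenotypes[[trait]]) != n) {
      abort(paste0("phenotype '", trait, "' must have one value per sample (", n, ")"))
    }
  }
  structure(
    list(groups = groups, phenotypes = phenotypes, seed = as.integer(seed)),
    class = "panel_spec"
  )
}

#' Expand a panel spec into a sample panel table
#'
#' @param spec A [panel_spec()].
#' @return Tibble with columns `sample`, `group`, and one column per declared
#'   trait. Sample ids are `<group><index>` with zero-padded index; the result
#'   is deterministic for a fixed spec.
#' @examples
#' simulate_panel(panel_spec(c(NAA = 6, WL = 3)))
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  groups <- spec$groups
  group <- rep(names(groups), groups)
  idx <- unlist(lapply(groups, seq_len), use.names = FALSE)
  panel <- tibble(
    sample = sprintf("%s%02d", group, idx),
    group = group
  )
  for (trait in names(spec$phenotypes)) {
    panel[[trait]] <- spec$phenotypes[[trait]]
  }
  panel
}

#' Default four-breed chicken panel
#'
#' A 15-sample, 4-group panel mirroring the study design this package
#' emulates: six North American Araucana (NAA; four ear-tufted, two
#' clean-faced; five rumpless, one tailed), three Korean Araucana (KA), three
#' Korean Domestic (KD) and three White Leghorn (WL), all clean-faced and
#' tailed.
#'
#' @return A `panel_spec`.
#' @export
default_panel_spec <- function() {
  panel_spec(
    groups = c(NAA = 6, KA = 3, KD = 3, WL = 3),
    phenotypes = list(
      tufted = c("tufted", "tufted", "clean", "tufted", "clean", "tufted",
                 rep("clean", 9)),
      tail_status = c("rumpless", "rumpless", "rumpless", "rumpless", "tailed",
                      "rumpless", rep("tailed", 9)),
      sex = c("M", "M", "U", "F", "M", "M", rep("U", 9))
    )
  )
}

#' Read / write a sample panel TSV
#'
#' @param path File path. The TSV carries `sample`, `group` and any trait
#'   columns.
#' @return `read_panel()` returns a tibble.
#' @export
read_panel <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' @param panel Panel tibble.
#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  readr::write_tsv(panel, path)
  invisible(path)
}

group_samples <- function(panel, group) {
  if (!group %in% panel$group) abort(paste0("group '", group, "' not in panel"))
  s <- panel$sample[panel$group == group]
  if (length(s) == 0) abort(paste0("group '", group, "' has zero samples"))
  s
}
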