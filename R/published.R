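#' Published census tables
#'
#' The printed per-class census (probe counts, regulator counts and the
#' two rounded percentage columns) and the regulator-family cross-tab
#' (35 families of induced gene-expression regulators), shipped as
#' plain-text fixtures. Used as worked-example inputs: the class counts
#' sum to the reported 3,437 regulated probes, the up-regulated classes
#' to 2,050, and the regulator columns to 192; the percentage columns are
#' reproduced by `percent()` from their stored numerators and
#' denominators.
#'
#' @return `published_class_census()`: data.frame with `class_label`,
#'   `n_probes`, `n_regulators`, `pct_up`, `pct_reg` (NA where the
#'   printed table leaves the cell blank). `published_regulator_families()`:
#'   data.frame with `family`, `regulated_process`, `induced_genes`,
#'   `n_classes`.
#' @export
published_class_census <- function() {
  utils::read.delim(
    system.file("extdata", "published_class_census.tsv", package = "nodclass",
                mustWork = TRUE),
    sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname published_class_census
#' @export
published_regulator_families <- function() {
  utils::read.delim(
    system.file("extdata", "published_regulator_families.tsv",
                package = "nodclass", mustWork = TRUE),
    sep = "\t", stringsAsFactors = FALSE)
}
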