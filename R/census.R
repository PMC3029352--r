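#' Integer percentage, half away from zero
#'
#' percent(n, d) = 100 n / d rounded to the nearest integer with exact
#' halves rounded away from zero (so 2.5 -> 3, -2.5 -> -3). This is the
#' rounding convention that reproduces every printed percentage cell of
#' the published class table (e.g. 2.60 -> 3, 16.29 -> 16).
#'
#' @param n Numerator(s).
#' @param d Denominator(s).
#' @return Integer percentage(s); NA where d is 0.
#' @export
percent <- function(n, d) {
  x <- 100 * n / d
  out <- sign(x) * floor(abs(x) + 0.5)
  out[d == 0] <- NA_real_
  out
}

#' Per-condition up/down counts
#'
#' @param calls A `RegulationCallTable`.
#' @return data.frame: `condition`, `n_up`, `n_down`.
#' @export
per_condition_counts <- function(calls) {
  data.frame(condition = calls$conditions,
             n_up = as.integer(colSums(calls$call == "up")),
             n_down = as.integer(colSums(calls$call == "down")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of a condition's induced genes induced nowhere else
#'
#' For each condition: numerator = probes up in exactly that condition,
#' denominator = probes up in that condition; NA when no probe is up.
#'
#' @param calls A `RegulationCallTable`.
#' @return data.frame: `condition`, `n_up`, `n_unique`, `fraction`.
#' @export
unique_up_fraction <- function(calls) {
  up <- calls$call == "up"
  n_up_total <- rowSums(up)
  data.frame(
    condition = calls$conditions,
    n_up = as.integer(colSums(up)),
    n_unique = as.integer(colSums(up & n_up_total == 1L)),
    fraction = ifelse(colSums(up) > 0,
                      colSums(up & n_up_total == 1L) / colSums(up), NA_real_),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Pairwise condition overlap of regulated genes
#'
#' Condition x condition counts of shared differentially regulated genes,
#' separately for up and down calls. Symmetric; the diagonal equals the
#' per-condition counts.
#'
#' @param calls A `RegulationCallTable`.
#' @return List of two symmetric integer matrices, `up` and `down`.
#' @export
pairwise_overlap <- function(calls) {
  cross <- function(m) {
    x <- crossprod(m * 1L)
    storage.mode(x) <- "integer"
    x
  }
  list(up = cross(calls$call == "up"), down = cross(calls$call == "down"))
}

#' Class census with regulator cross-tabs
#'
#' The summary tables of the analysis: per-class probe and regulator
#' counts; percentage columns relating each up-regulated class to the
#' total up-regulated differential probes and to the total up-regulated
#' regulators; a regulator-family cross-tab (per family: induced genes
#' and number of distinct classes they fall in); NCR peptide-gene tallies
#' per class; and an opposite-regulation report (families containing both
#' induced and repressed members). Annotation rows whose probe ids do not
#' appear in the assignment are dropped from the family/NCR tallies with
#' a warning.
#'
#' A probe counts as an up-regulated regulator when it is annotated as a
#' regulator and assigned to any class other than `repressed` / `not_DE`.
#'
#' @param assignment A `NoduleClassAssignment`.
#' @param annotations Annotation data.frame (`probe_id`, `family`,
#'   `is_regulator`, `is_NCR`).
#' @param config An `analysis_config` (reserved; rounding is fixed).
#' @return An object of class `"CensusReport"`: `classes` (data.frame with
#'   `class_label`, `n_probes`, `n_regulators`, `pct_up`, `pct_reg`),
#'   `families`, `ncr`, `opposite_families`, `totals`.
#' @export
class_census <- function(assignment, annotations = NULL,
                         config = analysis_config()) {
  labs <- setdiff(class_labels(), "not_DE")
  up_labs <- setdiff(labs, "repressed")
  counts <- class_counts(assignment)
  total_de <- sum(counts)
  total_up <- sum(counts[up_labs])

  lab_of <- stats::setNames(assignment$class_label, assignment$probe_id)

  n_reg <- stats::setNames(rep(0L, length(labs)), labs)
  families <- ncr <- opposite <- NULL
  total_up_reg <- 0L
  if (!is.null(annotations)) {
    known <- annotations$probe_id %in% assignment$probe_id
    if (any(!known)) {
      warning(sum(!known), " annotation row(s) without assignment; ",
              "excluded from family/NCR tallies")
      annotations <- annotations[known, , drop = FALSE]
    }
    ann_lab <- lab_of[annotations$probe_id]
    reg <- annotations$is_regulator & ann_lab %in% labs
    tab <- table(factor(ann_lab[reg], levels = labs))
    n_reg <- stats::setNames(as.integer(tab), labs)
    total_up_reg <- sum(n_reg[up_labs])

    up_reg <- annotations$is_regulator & ann_lab %in% up_labs
    if (any(up_reg)) {
      fam <- annotations$family[up_reg]
      fam_lab <- ann_lab[up_reg]
      families <- data.frame(
        family = sort(unique(fam)),
        induced_genes = as.integer(table(fam)[sort(unique(fam))]),
        n_classes = vapply(sort(unique(fam)), function(f)
          length(unique(fam_lab[fam == f])), 0L),
        row.names = NULL, stringsAsFactors = FALSE
      )
    }
    is_ncr <- annotations$is_NCR & ann_lab %in% labs
    ncr_tab <- table(factor(ann_lab[is_ncr], levels = labs))
    ncr <- data.frame(class_label = labs,
                      n_NCR = as.integer(ncr_tab),
                      row.names = NULL, stringsAsFactors = FALSE)

    fam_all <- annotations$family
    up_fam <- unique(fam_all[ann_lab %in% up_labs])
    down_fam <- unique(fam_all[ann_lab == "repressed"])
    both <- sort(intersect(up_fam, down_fam))
    if (length(both))
      opposite <- data.frame(family = both, stringsAsFactors = FALSE)
  }

  classes <- data.frame(
    class_label = labs,
    n_probes = as.integer(counts[labs]),
    n_regulators = as.integer(n_reg[labs]),
    pct_up = ifelse(labs %in% up_labs, percent(counts[labs], total_up), NA_real_),
    pct_reg = ifelse(labs %in% up_labs, percent(n_reg[labs], total_up_reg), NA_real_),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(classes = classes, families = families, ncr = ncr,
         opposite_families = opposite,
         totals = list(de_probes = total_de, up_probes = total_up,
                       up_regulators = total_up_reg)),
    class = "CensusReport"
  )
}

#' @export
print.CensusReport <- function(x, ...) {
  cat(sprintf("CensusReport: %d DE probes (%d up-regulated, %d up regulators)\n",
              x$totals$de_probes, x$totals$up_probes, x$totals$up_regulators))
  print(x$classes, row.names = FALSE)
  invisible(x)
}
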