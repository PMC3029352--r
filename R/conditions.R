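#' Condition panels
#'
#' Fixed registries of experimental conditions. The nodule panel holds the
#' seven nodule samples hybridised against nitrogen-starved control roots:
#' wild-type nodules at 4, 10 and 14 days post-inoculation (`WT4`, `WT10`,
#' `WT14`), ammonium-nitrate-treated 16-dpi nodules (`NN`), and nodules
#' induced by the `exoA` (infection-defective), `bacA` (bacteroid
#' differentiation-defective) and `fixJ` (fixation-defective) rhizobial
#' mutants. The root panel holds the eight qRT-PCR conditions: Nod-factor
#' treatment (`NF`), wild-type inoculation at 1 and 3 dpi (`WT1`, `WT3`),
#' and the `nfp`, `hcl1`, `lin`, `exoA` and `efd1` symbiotic mutants.
#' `CTRL` labels the uninoculated control-root sample in Ct tables.
#'
#' Condition names are matched case-sensitively; unknown names are rejected
#' at read/validation time.
#'
#' @param panel `"nodule"` or `"root"`.
#' @param with_ctrl Include the `CTRL` label (used by Ct tables, where the
#'   control is an explicit sample rather than the ratio denominator).
#' @return Character vector of condition names in canonical order.
#' @export
panel_conditions <- function(panel = c("nodule", "root"), with_ctrl = FALSE) {
  panel <- match.arg(panel)
  conds <- switch(panel,
    nodule = c("WT4", "WT10", "WT14", "NN", "exoA", "bacA", "fixJ"),
    root   = c("NF", "WT1", "WT3", "nfp", "hcl1", "lin", "exoA", "efd1")
  )
  if (with_ctrl) conds <- c(conds, "CTRL")
  conds
}

#' @rdname panel_conditions
#' @export
nodule_conditions <- function() panel_conditions("nodule")

#' @rdname panel_conditions
#' @export
root_conditions <- function() panel_conditions("root")
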