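#' Nodule expression-class templates
#'
#' One canonical level template per expression class, over the seven nodule
#' conditions in fixed order (WT4, WT10, WT14, NN, exoA, bacA, fixJ).
#' Levels: `"max"` (maximal induction), `"weak"` (weak induction),
#' `"down"` (repressed), `"none"` (no differential expression). These
#' templates are the single source of truth shared by the synthetic-data
#' generator (which plants them) and by the classifier tests (which must
#' recover them), so the two cannot drift apart.
#'
#' The sixteen classes: `repressed` (down-regulated in nodules);
#' `zone1_2` (strongest in immature 4-dpi nodules, absent from exoA);
#' `bacA` / `fixJ` (maximal in the respective mutant nodules);
#' `diff1` / `diff2` (not induced at 4 dpi, induced in 10-dpi and older
#' nodules, with / without bacA); `fix_plus` (nitrogen-fixing nodules,
#' switched off by nitrate); `all_star` / `all` (most samples, NN not
#' considered, without / with exoA); `NN` (maximal after nitrate);
#' `exo1` / `exo2` (maximal / exclusive in exoA nodules); `N4` (maximal at
#' 4 dpi but also in exoA); `fix_plus_NN` (mature nodules, nitrate-
#' insensitive); `wt_nodules` (wild-type-induced nodules only);
#' `unclear` (mixed pattern).
#'
#' @return A named list: per class, a named character vector of levels over
#'   the seven nodule conditions.
#' @export
nodule_class_templates <- function() {
  conds <- nodule_conditions()
  tpl <- function(...) {
    v <- c(...)
    stopifnot(length(v) == 7L)
    stats::setNames(v, conds)
  }
  list(
    #              WT4     WT10    WT14    NN      exoA    bacA    fixJ
    repressed   = tpl("down", "down", "down", "down", "down", "down", "down"),
    zone1_2     = tpl("max",  "weak", "weak", "none", "none", "weak", "weak"),
    bacA        = tpl("none", "none", "none", "none", "none", "max",  "none"),
    fixJ        = tpl("none", "none", "none", "none", "none", "none", "max"),
    diff1       = tpl("none", "weak", "weak", "none", "none", "weak", "max"),
    diff2       = tpl("none", "weak", "weak", "none", "none", "none", "max"),
    fix_plus    = tpl("none", "max",  "max",  "down", "none", "none", "none"),
    all_star    = tpl("weak", "weak", "max",  "none", "none", "weak", "weak"),
    all         = tpl("weak", "weak", "max",  "none", "weak", "weak", "weak"),
    NN          = tpl("none", "weak", "weak", "max",  "none", "none", "none"),
    exo1        = tpl("weak", "weak", "none", "none", "max",  "none", "none"),
    exo2        = tpl("none", "none", "none", "none", "max",  "none", "none"),
    N4          = tpl("max",  "weak", "none", "none", "weak", "none", "none"),
    fix_plus_NN = tpl("none", "max",  "weak", "weak", "none", "none", "none"),
    wt_nodules  = tpl("weak", "max",  "weak", "none", "none", "none", "none"),
    unclear     = tpl("max",  "none", "none", "none", "down", "weak", "none")
  )
}

#' All class labels, including the non-differential sink
#'
#' @return Character vector of the sixteen class labels plus `"not_DE"`.
#' @export
class_labels <- function() c(names(nodule_class_templates()), "not_DE")
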