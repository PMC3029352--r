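#' Derive induction levels from one probe's calls and ratios
#'
#' Translates a probe's per-condition calls into the four-level alphabet
#' used for class assignment. Among the conditions called "up", let R_max
#' be the largest mean linear ratio; a condition is `"max-up"` (maximal
#' induction) when its ratio reaches `weak_fraction * R_max`, otherwise
#' `"weak-up"` (weak induction). Down calls map to `"down"`, the rest to
#' `"none"`. The argmax condition (largest up ratio, ties broken by the
#' fixed condition order WT4, WT10, WT14, NN, exoA, bacA, fixJ) is
#' attached as an attribute.
#'
#' @param calls Named character vector over the seven nodule conditions,
#'   values in `up`/`none`/`down`.
#' @param ratios Named numeric vector of mean linear ratios, same names.
#' @param config An `analysis_config`.
#' @return Named character vector of levels with attribute `argmax`
#'   (condition name, or NA if no up call).
#' @export
call_levels <- function(calls, ratios, config = analysis_config()) {
  conds <- nodule_conditions()
  calls <- calls[conds]; ratios <- ratios[conds]
  levels <- rep("none", length(conds)); names(levels) <- conds
  levels[calls == "down"] <- "down"
  up <- which(calls == "up")
  argmax <- NA_character_
  if (length(up)) {
    r_max <- max(ratios[up])
    argmax <- conds[up[which.max(ratios[up])]]  # which.max: first of ties
    levels[up] <- ifelse(ratios[up] >= config$weak_fraction * r_max,
                         "max-up", "weak-up")
  }
  structure(levels, argmax = argmax)
}

#' Assign one probe to an expression class
#'
#' Applies the fixed precedence rules over a probe's level vector; the
#' first matching rule wins, making the sixteen classes exhaustive and
#' mutually exclusive over all call vectors:
#' \enumerate{
#'   \item no up call and at least one down: `repressed`
#'   \item up and down calls mixed, with a down outside NN: `unclear`
#'   \item up exclusively in exoA: `exo2`
#'   \item argmax exoA with other up calls: `exo1`
#'   \item argmax WT4, exoA not up: `zone1_2`
#'   \item argmax WT4, exoA up: `N4`
#'   \item up in WT4 and in at least `most_samples_k` of \{WT10, WT14,
#'     bacA, fixJ\}, argmax neither WT4 nor exoA: `all` if exoA is up,
#'     else `all_star`
#'   \item argmax NN: `NN`
#'   \item WT4 not up, up in WT10 or WT14, fixJ up: `diff1` if bacA is up,
#'     else `diff2`
#'   \item argmax bacA: `bacA`
#'   \item argmax fixJ: `fixJ`
#'   \item up confined to \{WT10, WT14\}, NN not up: `fix_plus`
#'     (a down call confined to NN is compatible: nitrate switches these
#'     genes off)
#'   \item up in (WT10 or WT14) and in NN, no mutant up: `fix_plus_NN`
#'   \item up confined to \{WT4, WT10, WT14, NN\}: `wt_nodules`
#'   \item otherwise: `unclear`
#' }
#' A probe with no call at all returns `not_DE`.
#'
#' @param levels Level vector from `call_levels()` (attribute `argmax`
#'   used for the argmax rules).
#' @param config An `analysis_config`.
#' @return A single class label.
#' @export
classify_probe <- function(levels, config = analysis_config()) {
  conds <- nodule_conditions()
  levels_v <- as.character(levels[conds]); names(levels_v) <- conds
  up <- conds[levels_v %in% c("weak-up", "max-up")]
  down <- conds[levels_v == "down"]
  argmax <- attr(levels, "argmax")
  if (length(up) == 0 && length(down) == 0) return("not_DE")
  if (length(up) == 0) return("repressed")                              # 1
  if (length(down) > 0 && length(setdiff(down, "NN")) > 0) return("unclear") # 2
  if (identical(up, "exoA")) return("exo2")                             # 3
  if (identical(argmax, "exoA")) return("exo1")                         # 4
  if (identical(argmax, "WT4")) {
    if (!"exoA" %in% up) return("zone1_2")                              # 5
    return("N4")                                                        # 6
  }
  core <- c("WT10", "WT14", "bacA", "fixJ")
  if ("WT4" %in% up && sum(core %in% up) >= config$most_samples_k &&
      !argmax %in% c("WT4", "exoA")) {                                  # 7
    return(if ("exoA" %in% up) "all" else "all_star")
  }
  if (identical(argmax, "NN")) return("NN")                             # 8
  if (!"WT4" %in% up && any(c("WT10", "WT14") %in% up) && "fixJ" %in% up)
    return(if ("bacA" %in% up) "diff1" else "diff2")                    # 9
  if (identical(argmax, "bacA")) return("bacA")                         # 10
  if (identical(argmax, "fixJ")) return("fixJ")                         # 11
  if (all(up %in% c("WT10", "WT14")) && !"NN" %in% up) return("fix_plus") # 12
  if (any(c("WT10", "WT14") %in% up) && "NN" %in% up &&
      !any(c("exoA", "bacA", "fixJ") %in% up)) return("fix_plus_NN")    # 13
  if (all(up %in% c("WT4", "WT10", "WT14", "NN"))) return("wt_nodules") # 14
  "unclear"                                                             # 15
}

#' Classify every probe of a call table
#'
#' Derives levels with `call_levels()` and applies `classify_probe()` to
#' every probe. Probes without any non-"none" call are labelled `not_DE`;
#' the sixteen class labels partition the differentially regulated probes.
#'
#' @param calls A `RegulationCallTable` over the nodule panel.
#' @param config An `analysis_config`.
#' @return data.frame of class `"NoduleClassAssignment"` with columns
#'   `probe_id`, `class_label`, `argmax`, and `levels` (compact 7-character
#'   encoding, one of `M`/`w`/`d`/`.` per condition in panel order).
#' @export
classify_dataset <- function(calls, config = analysis_config()) {
  probes <- rownames(calls$call)
  code <- c("max-up" = "M", "weak-up" = "w", "down" = "d", "none" = ".")
  out <- lapply(probes, function(p) {
    lv <- call_levels(calls$call[p, ], calls$ratio[p, ], config)
    list(label = classify_probe(lv, config),
         argmax = attr(lv, "argmax"),
         enc = paste(code[as.character(lv)], collapse = ""))
  })
  res <- data.frame(
    probe_id = probes,
    class_label = vapply(out, `[[`, "", "label"),
    argmax = vapply(out, function(o) as.character(o$argmax), ""),
    levels = vapply(out, `[[`, "", "enc"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(res) <- c("NoduleClassAssignment", "data.frame")
  res
}

#' Per-class probe counts
#'
#' @param assignment A `NoduleClassAssignment`.
#' @param include_not_de Count the `not_DE` sink too.
#' @return Named integer vector over all class labels (zeros kept).
#' @export
class_counts <- function(assignment, include_not_de = FALSE) {
  labs <- class_labels()
  if (!include_not_de) labs <- setdiff(labs, "not_DE")
  tab <- table(factor(assignment$class_label, levels = labs))
  stats::setNames(as.integer(tab), labs)
}

#' Read / write a class assignment table
#'
#' @param assignment A `NoduleClassAssignment`.
#' @param path File path.
#' @return data.frame / `path` invisibly.
#' @export
write_assignment <- function(assignment, path) {
  df <- assignment[order(assignment$probe_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assignment
#' @export
read_assignment <- function(path) {
  res <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  class(res) <- c("NoduleClassAssignment", "data.frame")
  res
}
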