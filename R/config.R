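#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline. Defaults follow the
#' study design: a probe is differentially regulated when its mean linear
#' ratio versus control roots reaches 1.5-fold (either direction) at a
#' Benjamini-Hochberg adjusted p-value of at most 0.05; both bounds are
#' inclusive. Co-expression neighbours are reported at Pearson r >= 0.8.
#'
#' @param ratio_threshold Linear fold-ratio call threshold (> 1). Default 1.5.
#' @param alpha Adjusted-p call threshold in (0, 1). Default 0.05.
#' @param coexpr_threshold Pearson correlation threshold for co-expression
#'   queries, in \[-1, 1\]. Default 0.8.
#' @param weak_fraction Fraction of the per-probe maximum linear ratio below
#'   which an up call counts as "weak induction" rather than "maximal
#'   induction" when levels are derived for class assignment. Default 0.5.
#' @param most_samples_k How many of \{WT10, WT14, bacA, fixJ\} (besides the
#'   required WT4) must be induced for the "expressed in most samples"
#'   classes. Default 3.
#' @param high_factor qRT-PCR "++" rule: the gene's maximum fold must reach
#'   `high_factor` times the largest other significant wild-type-situation
#'   fold. Default 2.
#' @param weak_vs_wt qRT-PCR "+-" rule: a mutant-condition induction is
#'   "weaker than wild type" when its fold is below `weak_vs_wt` times the
#'   weakest significant wild-type induction. Default 0.5.
#' @param pooled_bh Adjust p-values pooled across all conditions instead of
#'   within each condition (each condition is one contrast). Default FALSE.
#' @param rng_seed Optional integer seed recorded with the configuration.
#' @return An object of class `"analysis_config"` (a validated list).
#' @export
analysis_config <- function(ratio_threshold = 1.5,
                            alpha = 0.05,
                            coexpr_threshold = 0.8,
                            weak_fraction = 0.5,
                            most_samples_k = 3,
                            high_factor = 2,
                            weak_vs_wt = 0.5,
                            pooled_bh = FALSE,
                            rng_seed = NULL) {
  cfg <- list(
    ratio_threshold = ratio_threshold, alpha = alpha,
    coexpr_threshold = coexpr_threshold, weak_fraction = weak_fraction,
    most_samples_k = most_samples_k, high_factor = high_factor,
    weak_vs_wt = weak_vs_wt, pooled_bh = isTRUE(pooled_bh),
    rng_seed = rng_seed
  )
  if (!is.numeric(ratio_threshold) || ratio_threshold <= 1)
    stop("ratio_threshold must be > 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.numeric(coexpr_threshold) || coexpr_threshold < -1 || coexpr_threshold > 1)
    stop("coexpr_threshold must lie in [-1, 1]")
  if (!is.numeric(weak_fraction) || weak_fraction <= 0 || weak_fraction > 1)
    stop("weak_fraction must lie in (0, 1]")
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Unknown keys are rejected so typos in a config file fail loudly.
#'
#' @param path Path to a YAML file whose keys are `analysis_config()`
#'   argument names.
#' @return An `analysis_config` object.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  for (k in setdiff(names(x), "rng_seed"))
    cat(sprintf("  %-16s %s\n", k, format(x[[k]])))
  invisible(x)
}
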