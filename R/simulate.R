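#' Simulation configuration
#'
#' Study conditions for the synthetic generator. The nodule design mirrors
#' the source experiment: seven nodule conditions hybridised against a
#' common control with four replicates each; Gaussian replicate noise on
#' the log2 scale (log-normal on the linear scale). Planted effects:
#' "maximal induction" at `max_log2_effect` (default 3.0, i.e. 8-fold),
#' "weak induction" at `weak_log2_effect` (default 0.8, linear ratio about
#' 1.74: above the 1.5 call threshold but below half the maximal ratio, so
#' the weak/maximal distinction is exercised), repression at
#' `-max_log2_effect`. Non-differential probes are planted at 0 so the
#' per-sample median stays anchored at 0 (as on a genome-scale array where
#' most genes do not respond).
#'
#' @param n_probes_per_class Named integer vector: probes to plant per
#'   class label (see `class_labels()`); may include `not_DE`. Default: 50
#'   per class plus 1600 non-differential probes (about one third of
#'   probes differential, mirroring a genome-scale array at desk scale).
#' @param noise_sd Replicate standard deviation on the log2 scale.
#'   Default 0.15.
#' @param n_replicates Replicates per condition. Default 4.
#' @param max_log2_effect Planted maximal-induction level (log2). Default 3.
#' @param weak_log2_effect Planted weak-induction level (log2). Default 0.8.
#' @param ct_noise_sd Ct-scale noise for qRT-PCR tables. Default 0.10.
#' @param n_qpcr_replicates Biological repetitions per qRT-PCR sample.
#'   Default 3.
#' @param seed Optional integer seed; identical seeds give identical
#'   output.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_probes_per_class = NULL,
                       noise_sd = 0.15,
                       n_replicates = 4,
                       max_log2_effect = 3.0,
                       weak_log2_effect = 0.8,
                       ct_noise_sd = 0.10,
                       n_qpcr_replicates = 3,
                       seed = NULL) {
  if (is.null(n_probes_per_class)) {
    n_probes_per_class <- stats::setNames(
      rep(50L, length(class_labels())), class_labels())
    n_probes_per_class["not_DE"] <- 1600L
  }
  unknown <- setdiff(names(n_probes_per_class), class_labels())
  if (length(unknown))
    stop("unknown class label(s) in n_probes_per_class: ",
         paste(unknown, collapse = ", "))
  if (any(n_probes_per_class < 0)) stop("probe counts must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (weak_log2_effect >= max_log2_effect)
    stop("weak_log2_effect must be below max_log2_effect")
  structure(
    list(n_probes_per_class = n_probes_per_class, noise_sd = noise_sd,
         n_replicates = as.integer(n_replicates),
         max_log2_effect = max_log2_effect,
         weak_log2_effect = weak_log2_effect,
         ct_noise_sd = ct_noise_sd,
         n_qpcr_replicates = as.integer(n_qpcr_replicates),
         seed = seed),
    class = "sim_config"
  )
}

# per-condition true mean log2 ratios for one class template
template_effects <- function(template, config) {
  eff <- c(max = config$max_log2_effect, weak = config$weak_log2_effect,
           down = -config$max_log2_effect, none = 0)
  stats::setNames(eff[template], names(template))
}

#' Generate a nodule expression dataset with planted classes
#'
#' Plants `n_probes_per_class[label]` probes per expression class at the
#' canonical level template of that class (`nodule_class_templates()`),
#' translated to true mean log2 ratios, and adds Gaussian replicate noise.
#' Probe annotations (gene family, regulator and NCR flags) are drawn at
#' random so census reports can be exercised.
#'
#' @param config A `sim_config`.
#' @return List with elements `dataset` (an `ExpressionDataset`) and
#'   `truth` (data.frame: `probe_id`, `class_label`, plus the true mean
#'   log2 ratio per condition as `true_<condition>` columns).
#' @export
generate_nodule_dataset <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  templates <- nodule_class_templates()
  conds <- nodule_conditions()
  counts <- config$n_probes_per_class
  counts <- counts[counts > 0]
  labels <- rep(names(counts), counts)
  n <- length(labels)
  probe_ids <- sprintf("MTS%05d", seq_len(n))

  means <- matrix(0, nrow = n, ncol = length(conds),
                  dimnames = list(probe_ids, conds))
  for (lab in setdiff(names(counts), "not_DE")) {
    rows <- labels == lab
    means[rows, ] <- matrix(template_effects(templates[[lab]], config),
                            nrow = sum(rows), ncol = length(conds), byrow = TRUE)
  }

  nrep <- config$n_replicates
  condition <- rep(conds, each = nrep)
  replicate <- rep(seq_len(nrep), times = length(conds))
  values <- means[, condition, drop = FALSE] +
    stats::rnorm(n * length(condition), sd = config$noise_sd)
  colnames(values) <- paste0(condition, ":", replicate)

  families <- c("Myb", "bHLH", "ERF_AP2", "WRKY", "NAM", "HB", "C2H2",
                "bZIP", "GRAS", "NCR_CCP", "leghemoglobin", "transporter")
  is_reg <- stats::runif(n) < 0.06
  fam <- sample(families, n, replace = TRUE,
                prob = c(rep(0.05, 9), 0.2, 0.05, 0.3))
  is_ncr <- fam == "NCR_CCP"
  annotations <- data.frame(probe_id = probe_ids, family = fam,
                            is_regulator = is_reg, is_NCR = is_ncr,
                            stringsAsFactors = FALSE)

  truth <- data.frame(probe_id = probe_ids, class_label = labels,
                      stringsAsFactors = FALSE)
  truth[paste0("true_", conds)] <- as.data.frame(means)

  list(dataset = expression_dataset(values, condition, replicate,
                                    panel = "nodule",
                                    annotations = annotations),
       truth = truth)
}

#' Generate a qRT-PCR Ct table with planted root patterns
#'
#' Builds Ct values for genes planted to follow the root activation (A1-A4)
#' and repression (R1-R4) archetypes across the eight root conditions plus
#' control, with a constant-expression reference gene (the internal
#' standard; baseline Ct 20) and three biological repetitions per sample.
#' Target genes start from Ct 25 in control roots; a planted fold change f
#' in a condition lowers the target Ct by log2(f). Gaussian noise with
#' `ct_noise_sd` is added to every Ct value (reference included).
#'
#' @param pattern_counts Named integer vector over
#'   \{A1, A2, A3, A4, R1, R2, R3, R4, none\}: genes to plant per pattern.
#' @param config A `sim_config`.
#' @return List with `ct` (a `CtTable`) and `truth` (data.frame:
#'   `gene_id`, `pattern`).
#' @export
generate_root_qpcr <- function(pattern_counts, config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  folds <- root_pattern_fold_templates()
  unknown <- setdiff(names(pattern_counts), c(names(folds), "none"))
  if (length(unknown))
    stop("unknown pattern name(s): ", paste(unknown, collapse = ", "))
  if (any(pattern_counts < 0)) stop("pattern counts must be >= 0")
  pattern_counts <- pattern_counts[pattern_counts > 0]
  labels <- rep(names(pattern_counts), pattern_counts)
  n <- length(labels)
  conds <- c(root_conditions(), "CTRL")
  nrep <- config$n_qpcr_replicates
  condition <- rep(conds, each = nrep)
  replicate <- rep(seq_len(nrep), times = length(conds))

  gene_ids <- if (n) sprintf("GENE%03d", seq_len(n)) else character(0)
  ref_id <- "UBQ_REF"
  ct <- matrix(NA_real_, nrow = n + 1, ncol = length(condition),
               dimnames = list(c(gene_ids, ref_id),
                               paste0(condition, ":", replicate)))
  for (i in seq_len(n)) {
    f <- c(if (labels[i] == "none")
             stats::setNames(rep(1, length(root_conditions())), root_conditions())
           else folds[[labels[i]]],
           CTRL = 1)
    ct[i, ] <- 25 - log2(f[condition])
  }
  ct[n + 1, ] <- 20
  ct <- ct + stats::rnorm(length(ct), sd = config$ct_noise_sd)

  truth <- data.frame(gene_id = gene_ids, pattern = labels,
                      stringsAsFactors = FALSE)
  list(ct = ct_table(ct, condition, replicate, ref_gene = ref_id),
       truth = truth)
}
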