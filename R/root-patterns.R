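#' qRT-PCR Ct table
#'
#' Genes x samples matrix of raw Ct values over the root panel plus the
#' `CTRL` control-root condition, with one designated reference gene (the
#' internal standard, e.g. ubiquitin) used for delta-delta-Ct relative
#' quantification.
#'
#' @param ct Numeric matrix of Ct values, gene ids as rownames.
#' @param condition Character vector per column (root panel + `CTRL`).
#' @param replicate Integer vector per column.
#' @param ref_gene Row name of the reference gene.
#' @return An object of class `"CtTable"`.
#' @export
ct_table <- function(ct, condition, replicate, ref_gene) {
  stopifnot(is.matrix(ct), is.numeric(ct))
  if (is.null(rownames(ct))) stop("ct matrix must carry gene ids as rownames")
  if (!ref_gene %in% rownames(ct))
    stop("reference gene absent from the table: ", ref_gene)
  registry <- panel_conditions("root", with_ctrl = TRUE)
  unknown <- setdiff(unique(condition), registry)
  if (length(unknown))
    stop("condition not in the root panel: ", paste(unknown, collapse = ", "))
  if (!"CTRL" %in% condition)
    stop("Ct table needs CTRL control-root samples")
  structure(
    list(ct = ct, condition = as.character(condition),
         replicate = as.integer(replicate), ref_gene = ref_gene),
    class = "CtTable"
  )
}

#' @export
print.CtTable <- function(x, ...) {
  cat(sprintf("CtTable: %d target genes + reference '%s', %d samples\n",
              nrow(x$ct) - 1L, x$ref_gene, ncol(x$ct)))
  invisible(x)
}

#' Delta-delta-Ct relative expression
#'
#' Fold change of a target gene in a sample versus control, normalized to
#' the reference gene, assuming 100% amplification efficiency:
#' fold = 2^-ddCt with
#' ddCt = (Ct_target - Ct_reference) - (Ct_target_control -
#' Ct_reference_control). Strictly decreasing in `ct_target`, strictly
#' increasing in `ct_reference`; a constant added to both Cts of one
#' sample cancels.
#'
#' @param ct_target,ct_reference Ct values in the sample of interest.
#' @param ct_target_control,ct_reference_control Ct values in the control.
#' @return Linear fold change (vectorized).
#' @export
relative_expression <- function(ct_target, ct_reference,
                                ct_target_control, ct_reference_control) {
  ddct <- (ct_target - ct_reference) - (ct_target_control - ct_reference_control)
  2^(-ddct)
}

#' Root activation/repression pattern templates
#'
#' The eight archetypes over (NF, WT 1 dpi, WT 3 dpi, nfp, hcl-1, lin,
#' exoA, efd-1), as allowed symbol sets. `+`, `-` and `0` mean induction,
#' repression and no differential expression versus control roots; `++`
#' the highest level of expression; `+-` an induction weaker than in the
#' wild-type situations. Composite printed slots (`+/++`, `+/+-`) are
#' encoded as allowed sets.
#'
#' A1/A2: Nod-factor-inducible, NFP-dependent (A2 additionally requires
#' infection-thread initiation: no response in hcl-1 or exoA). A3/A4:
#' later, infection-dependent activation (A3 weakly detectable in lin and
#' exoA, A4 absent there). R1-R4: repression archetypes differing in NF
#' and mutant dependence.
#'
#' @return Named list of templates; each a list of allowed symbol vectors
#'   per condition.
#' @export
root_pattern_templates <- function() {
  conds <- root_conditions()
  tpl <- function(...) {
    v <- list(...)
    stopifnot(length(v) == 8L)
    stats::setNames(v, conds)
  }
  list(
    #        NF     WT1    WT3           nfp    hcl1   lin     exoA    efd1
    A1 = tpl("+",   "+",   c("+", "++"), "0",   "+",   "+",    "+",    "+"),
    A2 = tpl("+",   "+",   "++",         "0",   "0",   "+",    "0",    "+"),
    A3 = tpl("0",   "+",   "++",         "0",   "0",   "+-",   "+-",   "+"),
    A4 = tpl("0",   "+",   "++",         "0",   "0",   "0",    "0",    c("+", "+-")),
    R1 = tpl("-",   "-",   "-",          "0",   "-",   "-",    "-",    "-"),
    R2 = tpl("0",   "-",   "-",          "0",   "0",   "0",    "0",    "-"),
    R3 = tpl("-",   "-",   "-",          "-",   "-",   "0",    "0",    "-"),
    R4 = tpl("-",   "-",   "-",          "-",   "-",   "-",    "-",    "-")
  )
}

#' Canonical fold-change realisations of the root patterns
#'
#' One concrete linear fold per condition realising each pattern under the
#' default calling thresholds (induction 4-fold; maximal induction 16-fold
#' at WT 3 dpi; weakened induction 1.7-fold, i.e. above the 1.5 call
#' threshold but below half the weakest wild-type induction; repression
#' 3-fold down). Shared between the generator and the pattern tests.
#'
#' @return Named list of named numeric fold vectors over the root panel.
#' @export
root_pattern_fold_templates <- function() {
  conds <- root_conditions()
  tpl <- function(...) stats::setNames(c(...), conds)
  list(
    #        NF   WT1  WT3  nfp  hcl1 lin  exoA efd1
    A1 = tpl(4,   4,   4,   1,   4,   4,   4,   4),
    A2 = tpl(4,   4,   16,  1,   1,   4,   1,   4),
    A3 = tpl(1,   4,   16,  1,   1,   1.7, 1.7, 4),
    A4 = tpl(1,   4,   16,  1,   1,   1,   1,   4),
    R1 = tpl(1/3, 1/3, 1/3, 1,   1/3, 1/3, 1/3, 1/3),
    R2 = tpl(1,   1/3, 1/3, 1,   1,   1,   1,   1/3),
    R3 = tpl(1/3, 1/3, 1/3, 1/3, 1/3, 1,   1,   1/3),
    R4 = tpl(1/3, 1/3, 1/3, 1/3, 1/3, 1/3, 1/3, 1/3)
  )
}

#' Call per-condition symbols for one gene
#'
#' Translates per-condition folds and adjusted p-values into the
#' five-symbol alphabet \{++, +, +-, 0, -\}:
#' \itemize{
#'   \item `0`: not significant, or fold inside (1/ratio_threshold,
#'     ratio_threshold);
#'   \item `-`: significant with fold <= 1/ratio_threshold;
#'   \item among significant inductions, the condition(s) attaining the
#'     gene's maximum fold get `++` when that maximum reaches
#'     `high_factor` times the largest other significant
#'     wild-type-situation fold (NF, WT1, WT3);
#'   \item a mutant condition (nfp, hcl-1, lin, exoA, efd-1) whose fold is
#'     below `weak_vs_wt` times the weakest significant wild-type
#'     induction (min over WT1/WT3, overridable via `wt_reference`) gets
#'     `+-`;
#'   \item every other significant induction gets `+`.
#' }
#'
#' @param folds Named numeric vector over the eight root conditions.
#' @param p_adj Named numeric vector of adjusted p-values, same names.
#' @param config An `analysis_config`.
#' @param wt_reference Optional explicit wild-type reference fold for the
#'   `+-` rule; default: min significant induction among WT1/WT3. An
#'   error is raised if a `+-` evaluation is needed and no reference
#'   exists.
#' @return Named character vector of symbols (a root symbol vector).
#' @export
call_symbols <- function(folds, p_adj, config = analysis_config(),
                         wt_reference = NULL) {
  conds <- root_conditions()
  folds <- folds[conds]; p_adj <- p_adj[conds]
  rt <- config$ratio_threshold
  sig <- !is.na(p_adj) & p_adj <= config$alpha
  sym <- rep("0", length(conds)); names(sym) <- conds
  sym[sig & folds <= 1 / rt] <- "-"
  up <- sig & folds >= rt
  if (any(up)) {
    f_max <- max(folds[up])
    wt_sit <- c("NF", "WT1", "WT3")
    for (cc in conds[up]) sym[cc] <- "+"
    # ++ : attains the maximum, clearly above the other WT situations
    at_max <- conds[up][folds[conds[up]] >= f_max - 1e-12]
    for (cc in at_max) {
      others <- setdiff(wt_sit, cc)
      others <- others[up[others]]
      if (length(others) && f_max >= config$high_factor * max(folds[others]))
        sym[cc] <- "++"
    }
    # +- : mutant induction weaker than wild type
    mutants <- c("nfp", "hcl1", "lin", "exoA", "efd1")
    up_mut <- intersect(conds[up], mutants)
    up_mut <- setdiff(up_mut, names(sym)[sym == "++"])
    if (length(up_mut)) {
      if (is.null(wt_reference)) {
        wt_up <- intersect(c("WT1", "WT3"), conds[up])
        if (!length(wt_up))
          stop("no significant wild-type induction to evaluate '+-' against")
        wt_reference <- min(folds[wt_up])
      }
      weak <- up_mut[folds[up_mut] < config$weak_vs_wt * wt_reference]
      sym[weak] <- "+-"
    }
  }
  sym
}

#' Match a symbol vector to a root pattern
#'
#' Returns the template whose allowed sets contain every symbol; when
#' several match, the most specific template (fewest allowed symbols in
#' total) wins; no match returns `"unclassified"`.
#'
#' @param symbols Named character vector over the eight root conditions.
#' @return Pattern id (`A1`..`A4`, `R1`..`R4`) or `"unclassified"`.
#' @export
match_pattern <- function(symbols) {
  conds <- root_conditions()
  symbols <- symbols[conds]
  templates <- root_pattern_templates()
  matches <- names(templates)[vapply(templates, function(tpl) {
    all(vapply(conds, function(cc) symbols[[cc]] %in% tpl[[cc]], TRUE))
  }, TRUE)]
  if (!length(matches)) return("unclassified")
  if (length(matches) > 1L) {
    width <- vapply(templates[matches],
                    function(tpl) sum(lengths(tpl)), 0)
    matches <- matches[order(width, match(matches, names(templates)))]
  }
  matches[[1L]]
}

#' Classify every gene of a Ct table
#'
#' Full root pipeline: per-replicate delta-delta-Ct against the mean
#' control delta-Ct, fold change from the mean ddCt, significance from a
#' one-sample t-test of the replicate ddCt values against 0 with
#' Benjamini-Hochberg adjustment across genes within each condition (the
#' same calling machinery as the array pipeline), then `call_symbols()`
#' and `match_pattern()`.
#'
#' @param ct A `CtTable`.
#' @param config An `analysis_config`.
#' @return data.frame: `gene_id`, one symbol column per root condition,
#'   `pattern`; attribute `folds` holds the genes x conditions fold
#'   matrix.
#' @export
classify_gene_panel <- function(ct, config = analysis_config()) {
  conds <- root_conditions()
  genes <- setdiff(rownames(ct$ct), ct$ref_gene)
  dct <- sweep(ct$ct[genes, , drop = FALSE], 2, ct$ct[ct$ref_gene, ], "-")
  ctrl_base <- rowMeans(dct[, ct$condition == "CTRL", drop = FALSE], na.rm = TRUE)

  folds <- p_raw <- matrix(NA_real_, nrow = length(genes), ncol = length(conds),
                           dimnames = list(genes, conds))
  for (cc in conds) {
    dd <- dct[, ct$condition == cc, drop = FALSE] - ctrl_base
    n <- rowSums(!is.na(dd))
    m <- rowMeans(dd, na.rm = TRUE)
    s2 <- rowSums((dd - m)^2, na.rm = TRUE) / (n - 1)
    se <- sqrt(s2 / n)
    p <- 2 * stats::pt(abs(m / se), df = n - 1, lower.tail = FALSE)
    degenerate <- n >= 2 & s2 == 0
    p[degenerate] <- ifelse(m[degenerate] != 0, 0, 1)
    p[n < 2] <- NA_real_
    folds[, cc] <- 2^(-m)
    p_raw[, cc] <- p
  }
  p_adj <- apply(p_raw, 2, bh_adjust)
  p_adj <- matrix(p_adj, nrow = length(genes), dimnames = dimnames(p_raw))

  sym <- t(vapply(genes, function(g)
    call_symbols(folds[g, ], p_adj[g, ], config), character(length(conds))))
  colnames(sym) <- conds
  out <- data.frame(gene_id = genes, sym,
                    pattern = apply(sym, 1, match_pattern),
                    row.names = NULL, stringsAsFactors = FALSE,
                    check.names = FALSE)
  attr(out, "folds") <- folds
  out
}

#' Read / write a Ct table
#'
#' Tab-delimited: columns `gene`, `role` (`REF` for the reference gene,
#' `target` otherwise), then `condition:replicate` Ct columns.
#'
#' @param ct A `CtTable`.
#' @param path File path.
#' @return `read_ct_table()` returns a `CtTable`; `write_ct_table()`
#'   returns `path` invisibly.
#' @export
write_ct_table <- function(ct, path) {
  conds <- panel_conditions("root", with_ctrl = TRUE)
  ord_sample <- order(match(ct$condition, conds), ct$replicate)
  genes <- rownames(ct$ct)
  ord_gene <- order(genes != ct$ref_gene, genes)  # reference first
  vals <- ct$ct[ord_gene, ord_sample, drop = FALSE]
  headers <- paste0(ct$condition[ord_sample], ":", ct$replicate[ord_sample])
  role <- ifelse(rownames(vals) == ct$ref_gene, "REF", "target")
  lines <- c(
    paste(c("gene", "role", headers), collapse = "\t"),
    vapply(seq_len(nrow(vals)), function(i) {
      paste(c(rownames(vals)[i], role[i], num_field(vals[i, ])),
            collapse = "\t")
    }, "")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  ref <- df$gene[df$role == "REF"]
  if (length(ref) != 1L) stop("Ct table needs exactly one REF row")
  lab <- parse_sample_labels(setdiff(names(df), c("gene", "role")))
  vals <- as.matrix(df[, setdiff(names(df), c("gene", "role")), drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- df$gene
  ct_table(vals, lab$condition, lab$replicate, ref_gene = ref)
}
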