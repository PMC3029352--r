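#' Median-centre each sample column
#'
#' Per-sample normalization for log2-ratio data: each sample column is
#' shifted so its median is zero, leaving within-sample ordering untouched.
#' Idempotent.
#'
#' @param dataset An `ExpressionDataset` of log2 ratios.
#' @return The normalized `ExpressionDataset`.
#' @export
normalize_dataset <- function(dataset) {
  meds <- apply(dataset$values, 2, stats::median, na.rm = TRUE)
  if (any(is.na(meds)))
    stop("cannot normalize: sample column(s) entirely NA")
  dataset$values <- sweep(dataset$values, 2, meds, "-")
  dataset
}

#' One-sample t-test of replicate log2 ratios against zero
#'
#' For each probe, the replicates of one condition are tested two-sided
#' against a null mean of 0 (the common-reference two-colour design puts
#' the control in the denominator of every ratio, so "no change" is log2
#' ratio 0). Degenerate cases are deterministic: zero replicate variance
#' with a nonzero mean yields the limit p of 0 and a flag; zero variance
#' and zero mean yields p = 1; fewer than two non-NA replicates marks the
#' probe untestable (p = NA, downstream call forced to "none").
#'
#' @param dataset An `ExpressionDataset`.
#' @param condition One condition name present in the dataset.
#' @return data.frame with `probe_id`, `mean_log2`, `p_raw`, and flags
#'   `degenerate` (zero variance) and `untestable`.
#' @export
test_condition <- function(dataset, condition) {
  cols <- dataset$condition == condition
  if (!any(cols)) stop("condition not present: ", condition)
  x <- dataset$values[, cols, drop = FALSE]
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  ss <- rowSums((x - m)^2, na.rm = TRUE)
  s2 <- ifelse(n > 1, ss / (n - 1), NA_real_)
  se <- sqrt(s2 / n)
  tt <- m / se
  p <- 2 * stats::pt(abs(tt), df = n - 1, lower.tail = FALSE)
  degenerate <- n >= 2 & s2 == 0
  p[degenerate] <- ifelse(m[degenerate] != 0, 0, 1)
  untestable <- n < 2
  p[untestable] <- NA_real_
  m[n == 0] <- NA_real_
  data.frame(probe_id = rownames(dataset$values), mean_log2 = m, p_raw = p,
             degenerate = degenerate, untestable = untestable,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, validating wrapper around `stats::p.adjust(method = "BH")`:
#' p-values are sorted ascending, multiplied by m/i, monotonicity is
#' enforced from the largest down, values are capped at 1 and returned in
#' the original order. NAs are ignored (kept NA, not counted in m).
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call per-condition regulation against control roots
#'
#' Runs `test_condition()` for every condition, adjusts p-values with
#' Benjamini-Hochberg (within each condition by default: each condition is
#' one contrast against the common control), and calls each probe
#' `"up"` (mean linear ratio >= `ratio_threshold` and adjusted p <=
#' `alpha`), `"down"` (ratio <= 1/`ratio_threshold`, same alpha) or
#' `"none"`. Both thresholds are inclusive. Untestable probes are "none".
#'
#' @param dataset A normalized `ExpressionDataset`.
#' @param config An `analysis_config`.
#' @return An object of class `"RegulationCallTable"`: list of probes x
#'   conditions matrices `call`, `ratio` (linear, 2^mean log2), `p_raw`,
#'   `p_adj`, plus logical flag matrices `degenerate` and `untestable`.
#' @export
call_regulation <- function(dataset, config = analysis_config()) {
  conds <- intersect(panel_conditions(dataset$panel), unique(dataset$condition))
  probes <- rownames(dataset$values)
  shape <- function(init) matrix(init, nrow = length(probes), ncol = length(conds),
                                 dimnames = list(probes, conds))
  ratio <- p_raw <- p_adj <- shape(NA_real_)
  call <- shape("none")
  degenerate <- untestable <- shape(FALSE)
  for (cc in conds) {
    res <- test_condition(dataset, cc)
    ratio[, cc] <- 2^res$mean_log2
    p_raw[, cc] <- res$p_raw
    degenerate[, cc] <- res$degenerate
    untestable[, cc] <- res$untestable
  }
  if (config$pooled_bh) {
    p_adj[] <- bh_adjust(as.vector(p_raw))
  } else {
    for (cc in conds) p_adj[, cc] <- bh_adjust(p_raw[, cc])
  }
  sig <- !is.na(p_adj) & p_adj <= config$alpha
  call[sig & ratio >= config$ratio_threshold] <- "up"
  call[sig & ratio <= 1 / config$ratio_threshold] <- "down"
  call[untestable] <- "none"
  structure(
    list(call = call, ratio = ratio, p_raw = p_raw, p_adj = p_adj,
         degenerate = degenerate, untestable = untestable,
         conditions = conds, panel = dataset$panel),
    class = "RegulationCallTable"
  )
}

#' @export
print.RegulationCallTable <- function(x, ...) {
  cat(sprintf("RegulationCallTable: %d probes x %d conditions\n",
              nrow(x$call), length(x$conditions)))
  up <- colSums(x$call == "up"); dn <- colSums(x$call == "down")
  for (cc in x$conditions)
    cat(sprintf("  %-5s up %5d  down %5d\n", cc, up[cc], dn[cc]))
  invisible(x)
}

#' Probes with at least one non-"none" call
#'
#' @param calls A `RegulationCallTable`.
#' @return Character vector of differentially regulated probe ids.
#' @export
de_probes <- function(calls) {
  rownames(calls$call)[rowSums(calls$call != "none") > 0]
}

#' Read / write a regulation call table
#'
#' Tab-delimited, one row per probe: `probe`, then per condition (fixed
#' panel order) columns `<cond>.call`, `<cond>.ratio`, `<cond>.p_adj`,
#' `<cond>.p_raw`. Rows are sorted by probe id ascending; repeated writes
#' of the same table are byte-identical.
#'
#' @param calls A `RegulationCallTable`.
#' @param path File path.
#' @param panel Panel name for the reader.
#' @return `read_calls()` returns a `RegulationCallTable`; `write_calls()`
#'   returns `path` invisibly.
#' @export
write_calls <- function(calls, path) {
  conds <- calls$conditions
  probes <- rownames(calls$call)
  if (is.null(probes)) probes <- character(0)
  ord <- order(probes)
  header <- c("probe", unlist(lapply(conds, function(cc)
    paste0(cc, ".", c("call", "ratio", "p_adj", "p_raw")))))
  rows <- vapply(ord, function(i) {
    cells <- unlist(lapply(conds, function(cc) c(
      calls$call[i, cc],
      num_field(calls$ratio[i, cc]),
      num_field(calls$p_adj[i, cc]),
      num_field(calls$p_raw[i, cc])
    )))
    paste(c(rownames(calls$call)[i], cells), collapse = "\t")
  }, "")
  writeLines(c(paste(header, collapse = "\t"), rows), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path, panel = "nodule") {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  probes <- as.character(df$probe)
  fields <- strsplit(setdiff(names(df), "probe"), ".", fixed = TRUE)
  conds <- unique(vapply(fields, `[[`, "", 1L))
  grab <- function(what, mode = "double") {
    m <- sapply(conds, function(cc) df[[paste0(cc, ".", what)]])
    m <- matrix(m, nrow = length(probes), dimnames = list(probes, conds))
    if (mode == "double") storage.mode(m) <- "double"
    m
  }
  structure(
    list(call = grab("call", "character"), ratio = grab("ratio"),
         p_raw = grab("p_raw"), p_adj = grab("p_adj"),
         degenerate = NULL, untestable = NULL,
         conditions = conds, panel = panel),
    class = "RegulationCallTable"
  )
}
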