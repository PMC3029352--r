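#' Replicated expression dataset
#'
#' Container for a probes x samples matrix of log2(sample/control) ratios
#' (arrays) with condition and replicate labels drawn from a fixed panel.
#' Every condition must carry at least two replicates; probe identifiers are
#' opaque strings and must be unique. Missing cells are allowed (NA) but a
#' probe row may not be entirely missing.
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns.
#' @param condition Character vector, one condition name per column.
#' @param replicate Integer vector, one replicate index per column.
#' @param panel `"nodule"` or `"root"`.
#' @param annotations Optional data.frame with columns `probe_id`, `family`,
#'   `is_regulator`, `is_NCR`.
#' @return An object of class `"ExpressionDataset"`.
#' @export
expression_dataset <- function(values, condition, replicate,
                               panel = "nodule", annotations = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) stop("values must carry probe ids as rownames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (length(condition) != ncol(values) || length(replicate) != ncol(values))
    stop("condition/replicate labels must match the number of sample columns")
  registry <- panel_conditions(panel, with_ctrl = TRUE)
  unknown <- setdiff(unique(condition), registry)
  if (length(unknown))
    stop("condition not in the ", panel, " panel: ", paste(unknown, collapse = ", "))
  nrep <- table(condition)
  if (any(nrep < 2))
    stop("every condition needs >= 2 replicates; offending: ",
         paste(names(nrep)[nrep < 2], collapse = ", "))
  all_na <- rowSums(!is.na(values)) == 0
  if (any(all_na))
    stop("probe rows entirely missing: ",
         paste(rownames(values)[all_na], collapse = ", "))
  if (!is.null(annotations)) {
    stopifnot(is.data.frame(annotations), "probe_id" %in% names(annotations))
    annotations <- annotations[match(rownames(values), annotations$probe_id), , drop = FALSE]
  }
  structure(
    list(values = values, condition = as.character(condition),
         replicate = as.integer(replicate), panel = panel,
         annotations = annotations),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset (%s panel): %d probes x %d samples\n",
              x$panel, nrow(x$values), ncol(x$values)))
  tab <- table(x$condition)
  cat("  conditions:",
      paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

#' Per-condition mean profiles
#'
#' Arithmetic mean of replicate log2 ratios for each probe and condition
#' (NAs dropped per cell). Columns follow the canonical panel order.
#'
#' @param dataset An `ExpressionDataset`.
#' @return Numeric matrix, probes x conditions.
#' @export
condition_means <- function(dataset) {
  conds <- intersect(panel_conditions(dataset$panel, with_ctrl = TRUE),
                     unique(dataset$condition))
  out <- sapply(conds, function(cc) {
    rowMeans(dataset$values[, dataset$condition == cc, drop = FALSE], na.rm = TRUE)
  })
  matrix(out, nrow = nrow(dataset$values),
         dimnames = list(rownames(dataset$values), conds))
}

# split "cond:rep" header cells; returns list(condition, replicate)
parse_sample_labels <- function(labels) {
  parts <- strsplit(labels, ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad))
    stop("sample headers must read 'condition:replicate'; offending: ",
         paste(labels[bad], collapse = ", "))
  list(condition = vapply(parts, `[[`, "", 1L),
       replicate = as.integer(vapply(parts, `[[`, "", 2L)))
}

#' Read / write an expression table
#'
#' Tab-delimited UTF-8: first column `probe`, remaining headers
#' `condition:replicate`. Missing cells are written and read as `NA`.
#' Writing is deterministic (probes sorted ascending, samples in panel
#' order then replicate order) and numerically lossless, so a
#' write-then-read round trip reproduces the dataset exactly.
#'
#' @param path File path.
#' @param panel Panel name used to validate condition labels.
#' @param dataset An `ExpressionDataset`.
#' @return `read_expression_table()` returns an `ExpressionDataset`;
#'   `write_expression_table()` returns `path` invisibly.
#' @export
read_expression_table <- function(path, panel = "nodule") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression table needs a probe column plus samples")
  probes <- as.character(df[[1]])
  if (anyDuplicated(probes))
    stop("duplicate probe ids in ", path)
  lab <- parse_sample_labels(names(df)[-1])
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- probes
  colnames(values) <- names(df)[-1]
  expression_dataset(values, lab$condition, lab$replicate, panel = panel)
}

#' @rdname read_expression_table
#' @export
write_expression_table <- function(dataset, path) {
  ord_probe <- order(rownames(dataset$values))
  conds <- panel_conditions(dataset$panel, with_ctrl = TRUE)
  ord_sample <- order(match(dataset$condition, conds), dataset$replicate)
  vals <- dataset$values[ord_probe, ord_sample, drop = FALSE]
  headers <- paste0(dataset$condition[ord_sample], ":",
                    dataset$replicate[ord_sample])
  lines <- c(
    paste(c("probe", headers), collapse = "\t"),
    vapply(seq_len(nrow(vals)), function(i) {
      paste(c(rownames(vals)[i], num_field(vals[i, ])), collapse = "\t")
    }, "")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# lossless, locale-independent numeric rendering ("%.17g", NA -> "NA")
num_field <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Read / write a probe annotation table
#'
#' Tab-delimited with columns `probe_id`, `family`, `is_regulator`,
#' `is_NCR` (flags as 0/1).
#'
#' @param path File path.
#' @param annotations Annotation data.frame.
#' @return A data.frame / `path` invisibly.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("probe_id", "family", "is_regulator", "is_NCR")
  if (!all(needed %in% names(df)))
    stop("annotation table must have columns: ", paste(needed, collapse = ", "))
  df$is_regulator <- as.logical(as.integer(df$is_regulator))
  df$is_NCR <- as.logical(as.integer(df$is_NCR))
  df
}

#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  df <- annotations[order(annotations$probe_id), , drop = FALSE]
  df$is_regulator <- as.integer(df$is_regulator)
  df$is_NCR <- as.integer(df$is_NCR)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
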