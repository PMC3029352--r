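#' Cross-platform qualitative concordance
#'
#' Scores how often two call tables agree qualitatively on the probes
#' mapped between them. For every mapped probe pair the call signs
#' (up / none / down) are compared over the shared condition set; a probe
#' is concordant when the signs agree in at least `min_agree` shared
#' conditions (default: all but one). Probes without a mapping are not
#' compared (excluded from the denominator). Symmetric in its two
#' arguments.
#'
#' @param calls_a,calls_b `RegulationCallTable`s.
#' @param id_map Optional data.frame with columns `a`, `b` mapping probe
#'   ids of `calls_a` to probe ids of `calls_b`; default maps shared ids
#'   to themselves.
#' @param min_agree Minimum agreeing conditions; default
#'   `length(shared conditions) - 1`.
#' @return An object of class `"ConcordanceReport"`: `n_compared`,
#'   `n_concordant`, `fraction` (percent), `shared_conditions`,
#'   `verdicts` (per-probe data.frame), `discordant` (per-condition
#'   detail for the discordant probes).
#' @export
concordance <- function(calls_a, calls_b, id_map = NULL, min_agree = NULL) {
  shared <- intersect(calls_a$conditions, calls_b$conditions)
  if (!length(shared)) stop("no shared conditions to compare")
  if (is.null(min_agree)) min_agree <- length(shared) - 1L
  if (is.null(id_map)) {
    ids <- intersect(rownames(calls_a$call), rownames(calls_b$call))
    id_map <- data.frame(a = ids, b = ids, stringsAsFactors = FALSE)
  }
  id_map <- id_map[id_map$a %in% rownames(calls_a$call) &
                   id_map$b %in% rownames(calls_b$call), , drop = FALSE]
  n <- nrow(id_map)
  agree <- integer(n)
  for (i in seq_len(n)) {
    agree[i] <- sum(calls_a$call[id_map$a[i], shared] ==
                    calls_b$call[id_map$b[i], shared])
  }
  concordant <- agree >= min_agree
  verdicts <- data.frame(probe_a = id_map$a, probe_b = id_map$b,
                         n_agree = agree, concordant = concordant,
                         stringsAsFactors = FALSE)
  disc <- verdicts[!verdicts$concordant, , drop = FALSE]
  detail <- if (nrow(disc)) {
    do.call(rbind, lapply(seq_len(nrow(disc)), function(i) {
      data.frame(probe_a = disc$probe_a[i], condition = shared,
                 call_a = calls_a$call[disc$probe_a[i], shared],
                 call_b = calls_b$call[disc$probe_b[i], shared],
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  } else NULL
  structure(
    list(n_compared = n, n_concordant = sum(concordant),
         fraction = if (n) 100 * sum(concordant) / n else NA_real_,
         min_agree = min_agree, shared_conditions = shared,
         verdicts = verdicts, discordant = detail),
    class = "ConcordanceReport"
  )
}

#' @export
print.ConcordanceReport <- function(x, ...) {
  cat(sprintf(
    "Concordance over %d shared conditions (>= %d must agree):\n",
    length(x$shared_conditions), x$min_agree))
  cat(sprintf("  %d / %d probes qualitatively similar (%.1f%%)\n",
              x$n_concordant, x$n_compared, x$fraction))
  invisible(x)
}

#' Flag probes differentially expressed in exactly one condition
#'
#' Single-condition calls are the least corroborated: cross-platform
#' discordance concentrates in them, so they are flagged for downstream
#' caution.
#'
#' @param calls A `RegulationCallTable`.
#' @return Named logical vector per probe.
#' @export
single_condition_flag <- function(calls) {
  rowSums(calls$call != "none") == 1L
}
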