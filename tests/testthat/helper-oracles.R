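# Independent oracles, deliberately written as direct transcriptions of the
# definitions and kept free of the package's own code paths.

# explicit step-up FDR adjustment: sort ascending, p_(i) * m / i, enforce
# monotonicity from the largest down, cap at 1, restore input order
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m >= 2) for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# naive O(n^3) unweighted average linkage: clusters kept as leaf-index sets,
# cross-cluster distance recomputed from the original matrix at every step,
# ties broken by the smallest sorted pair of leaf indices
upgma_oracle <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  steps <- list()
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
      better <- dd < best_d - 1e-12 ||
        (abs(dd - best_d) <= 1e-12 && (is.null(best_key) ||
           key[1] < best_key[1] ||
           (key[1] == best_key[1] && key[2] < best_key[2])))
      if (better) { best <- c(i, j); best_d <- dd; best_key <- key }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    steps[[length(steps) + 1]] <- list(members = merged, height = best_d)
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  steps
}

# member sets per merge step of an hclust object, for comparison with the
# oracle
hclust_steps <- function(tree) {
  sets <- vector("list", nrow(tree$merge))
  expand <- function(id) if (id < 0) -id else sets[[id]]
  for (s in seq_len(nrow(tree$merge))) {
    sets[[s]] <- sort(c(expand(tree$merge[s, 1]), expand(tree$merge[s, 2])))
  }
  lapply(seq_along(sets), function(s)
    list(members = sets[[s]], height = tree$height[s]))
}

# second, independent nodule rule engine: flat transcription of the
# precedence table operating directly on an up/none/down call vector, with
# the argmax supplied (tie convention: first up condition in panel order
# when all up ratios are equal)
rule_engine_oracle <- function(calls, argmax, k = 3) {
  up <- names(calls)[calls == "up"]
  dn <- names(calls)[calls == "down"]
  in_up <- function(x) x %in% up
  if (length(up) == 0 && length(dn) == 0) return("not_DE")
  if (length(up) == 0) return("repressed")
  if (length(dn) > 0 && any(dn != "NN")) return("unclear")
  if (length(up) == 1 && up == "exoA") return("exo2")
  if (argmax == "exoA") return("exo1")
  if (argmax == "WT4" && !in_up("exoA")) return("zone1_2")
  if (argmax == "WT4" && in_up("exoA")) return("N4")
  n_core <- sum(c("WT10", "WT14", "bacA", "fixJ") %in% up)
  if (in_up("WT4") && n_core >= k && argmax != "WT4" && argmax != "exoA") {
    if (in_up("exoA")) return("all") else return("all_star")
  }
  if (argmax == "NN") return("NN")
  if (!in_up("WT4") && (in_up("WT10") || in_up("WT14")) && in_up("fixJ")) {
    if (in_up("bacA")) return("diff1") else return("diff2")
  }
  if (argmax == "bacA") return("bacA")
  if (argmax == "fixJ") return("fixJ")
  if (all(up %in% c("WT10", "WT14")) && !in_up("NN")) return("fix_plus")
  if ((in_up("WT10") || in_up("WT14")) && in_up("NN") &&
      !in_up("exoA") && !in_up("bacA") && !in_up("fixJ")) return("fix_plus_NN")
  if (all(up %in% c("WT4", "WT10", "WT14", "NN"))) return("wt_nodules")
  "unclear"
}

# all 3^7 call vectors over the nodule panel
all_call_vectors <- function() {
  conds <- nodule_conditions()
  grid <- expand.grid(rep(list(c("up", "none", "down")), 7),
                      stringsAsFactors = FALSE)
  names(grid) <- conds
  grid
}

# levels for a call vector under the fixed ratio convention (every up call
# at the same ratio, so all up calls are maximal and the argmax is the
# first up condition in panel order)
levels_from_calls <- function(calls) {
  ratios <- ifelse(calls == "up", 2, ifelse(calls == "down", 0.5, 1))
  names(ratios) <- names(calls)
  call_levels(calls, ratios)
}

# tiny dataset builder used across IO and pipeline tests
make_dataset <- function(n_probes = 3, n_rep = 2, panel = "nodule",
                         seed = 42) {
  set.seed(seed)
  conds <- panel_conditions(panel)
  condition <- rep(conds, each = n_rep)
  values <- matrix(rnorm(n_probes * length(condition)),
                   nrow = n_probes,
                   dimnames = list(sprintf("P%03d", seq_len(n_probes)),
                                   paste0(condition, ":",
                                          rep(seq_len(n_rep), length(conds)))))
  expression_dataset(values, condition,
                     rep(seq_len(n_rep), times = length(conds)),
                     panel = panel)
}
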