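test_that("delta-delta-Ct relative expression follows the closed form", {
  expect_equal(relative_expression(20, 20, 20, 20), 1)
  expect_equal(relative_expression(19, 20, 20, 20), 2)   # ddCt = -1
  expect_equal(relative_expression(22, 20, 25, 20), 8)
  # adding a constant to both Cts of one sample cancels
  expect_equal(relative_expression(21 + 3, 20 + 3, 25, 20),
               relative_expression(21, 20, 25, 20))
  # strictly decreasing in target Ct, increasing in reference Ct
  ct <- seq(18, 30, by = 0.5)
  expect_true(all(diff(relative_expression(ct, 20, 25, 20)) < 0))
  expect_true(all(diff(relative_expression(22, ct, 25, 20)) > 0))
})

test_that("symbol calling reproduces the worked activation example", {
  conds <- root_conditions()
  folds <- stats::setNames(c(3, 3, 8, 1, 1, 3, 1, 3), conds)
  p_adj <- stats::setNames(ifelse(conds %in% c("nfp", "hcl1", "exoA"), 0.8, 0.001),
                           conds)
  sym <- call_symbols(folds, p_adj)
  expect_equal(unname(sym), c("+", "+", "++", "0", "0", "+", "0", "+"))
  expect_equal(match_pattern(sym), "A2")
})

test_that("symbol calling covers repression, weak induction, and silence", {
  conds <- root_conditions()
  # nothing significant -> all 0
  sym <- call_symbols(stats::setNames(rep(5, 8), conds),
                      stats::setNames(rep(0.9, 8), conds))
  expect_true(all(sym == "0"))
  # significant repression at fold 0.4 -> "-"
  folds <- stats::setNames(rep(1, 8), conds); folds["WT3"] <- 0.4
  p <- stats::setNames(rep(0.001, 8), conds)
  expect_equal(unname(call_symbols(folds, p)["WT3"]), "-")
  # near-1 folds stay 0 even when significant
  folds["WT3"] <- 1.2
  expect_equal(unname(call_symbols(folds, p)["WT3"]), "0")
  # mutant induction weaker than half the weakest WT induction -> "+-"
  folds <- stats::setNames(c(1, 4, 16, 1, 1, 1.7, 1.7, 4), conds)
  sym <- call_symbols(folds, p)
  expect_equal(unname(sym), c("0", "+", "++", "0", "0", "+-", "+-", "+"))
  expect_equal(match_pattern(sym), "A3")
  # evaluating "+-" without any significant WT induction is an error
  folds <- stats::setNames(c(1, 1, 1, 1, 1, 2, 1, 1), conds)
  p_mut <- stats::setNames(c(0.9, 0.9, 0.9, 0.9, 0.9, 0.01, 0.9, 0.9), conds)
  expect_error(call_symbols(folds, p_mut), "wild-type")
})

test_that("the eight printed symbol rows each match their own pattern", {
  rows <- list(
    A1 = c("+", "+", "+", "0", "+", "+", "+", "+"),
    A2 = c("+", "+", "++", "0", "0", "+", "0", "+"),
    A3 = c("0", "+", "++", "0", "0", "+-", "+-", "+"),
    A4 = c("0", "+", "++", "0", "0", "0", "0", "+"),
    R1 = c("-", "-", "-", "0", "-", "-", "-", "-"),
    R2 = c("0", "-", "-", "0", "0", "0", "0", "-"),
    R3 = c("-", "-", "-", "-", "-", "0", "0", "-"),
    R4 = c("-", "-", "-", "-", "-", "-", "-", "-")
  )
  for (id in names(rows)) {
    sym <- stats::setNames(rows[[id]], root_conditions())
    expect_equal(match_pattern(sym), id, label = paste("row", id))
  }
  # composite slots: the ++ variant of the A1 row is still A1
  symA1 <- stats::setNames(rows$A1, root_conditions()); symA1["WT3"] <- "++"
  expect_equal(match_pattern(symA1), "A1")
  expect_equal(match_pattern(stats::setNames(rep("0", 8), root_conditions())),
               "unclassified")
})

test_that("planted template vectors never match two patterns", {
  templates <- root_pattern_templates()
  for (id in names(templates)) {
    tpl <- templates[[id]]
    grid <- expand.grid(tpl, stringsAsFactors = FALSE)
    names(grid) <- root_conditions()
    for (i in seq_len(nrow(grid))) {
      sym <- stats::setNames(unlist(grid[i, ], use.names = FALSE),
                             root_conditions())
      hits <- names(templates)[vapply(names(templates), function(k) {
        all(vapply(root_conditions(),
                   function(cc) sym[[cc]] %in% templates[[k]][[cc]], TRUE))
      }, TRUE)]
      expect_equal(match_pattern(sym), id)
      expect_length(hits, 1L)
    }
  }
})

test_that("noise-free planted genes recover their patterns end to end", {
  pc <- stats::setNames(rep(5L, 8), c(paste0("A", 1:4), paste0("R", 1:4)))
  sim <- generate_root_qpcr(pc, sim_config(ct_noise_sd = 0, seed = 61))
  res <- classify_gene_panel(sim$ct)
  expect_identical(res$pattern[match(sim$truth$gene_id, res$gene_id)],
                   sim$truth$pattern)

  # the infection-repressed archetype: repression only on live inoculation,
  # absent in NF treatment and in the infection mutants
  folds <- root_pattern_fold_templates()$R2
  genes <- res$gene_id[sim$truth$pattern == "R2"]
  f <- attr(res, "folds")[genes[1], ]
  expect_equal(unname(f[c("NF", "lin", "exoA")]), c(1, 1, 1), tolerance = 1e-9)
  expect_lt(f[["WT1"]], 1 / 1.5)
})

test_that("a missing reference gene is rejected", {
  pc <- c(A1 = 2L)
  sim <- generate_root_qpcr(pc, sim_config(seed = 62))
  expect_error(ct_table(sim$ct$ct, sim$ct$condition, sim$ct$replicate,
                        ref_gene = "NOPE"), "reference gene")
})
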