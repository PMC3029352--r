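test_that("median centering shifts columns, is idempotent, keeps order", {
  ds <- make_dataset(n_probes = 11, n_rep = 2, seed = 3)
  shifted <- ds
  shifted$values[, 1] <- shifted$values[, 1] - stats::median(shifted$values[, 1]) + 0.3
  norm <- normalize_dataset(shifted)
  expect_equal(unname(apply(norm$values, 2, stats::median)),
               rep(0, ncol(norm$values)))
  expect_equal(norm$values[, 1], shifted$values[, 1] - 0.3)
  expect_equal(order(norm$values[, 1]), order(shifted$values[, 1]))

  # idempotence over random matrices
  for (seed in 1:5) {
    d <- make_dataset(n_probes = 9, n_rep = 3, seed = seed)
    once <- normalize_dataset(d)
    expect_equal(normalize_dataset(once)$values, once$values)
  }
})

test_that("one-sample t handles the anchor and degenerate cases", {
  conds <- nodule_conditions()
  vals <- rbind(
    anchor    = c(0.84, 0.80, 0.88, 0.84),  # mean 0.84 -> ratio 2^0.84 ~ 1.79
    flat      = c(1.0, 1.0, 1.0, 1.0),      # zero variance, nonzero mean
    symmetric = c(-0.5, 0.5, -0.25, 0.25)   # mean 0 -> t = 0 -> p = 1
  )
  values <- cbind(vals, matrix(0.01 * seq_len(3 * 8), nrow = 3))
  colnames(values) <- paste0(rep(c("WT4", "WT10", "WT14"), each = 4), ":", 1:4)
  ds <- expression_dataset(values, rep(c("WT4", "WT10", "WT14"), each = 4),
                           rep(1:4, 3))
  res <- test_condition(ds, "WT4")

  expect_equal(res$mean_log2[1], 0.84)
  expect_equal(round(2^res$mean_log2[1], 2), 1.79)
  # closed-form t on the four replicates, 3 df
  x <- vals["anchor", ]
  t_exp <- mean(x) / (sd(x) / 2)
  expect_equal(res$p_raw[1], 2 * pt(abs(t_exp), df = 3, lower.tail = FALSE))

  expect_true(res$degenerate[2])
  expect_equal(res$p_raw[2], 0)
  expect_equal(res$mean_log2[2], 1.0)

  expect_equal(res$p_raw[3], 1)
})

test_that("probes with fewer than two usable replicates are untestable", {
  ds <- make_dataset(n_probes = 4, n_rep = 3, seed = 11)
  ds$values[1, ds$condition == "WT4"][2:3] <- NA
  res <- test_condition(ds, "WT4")
  expect_true(res$untestable[1])
  expect_true(is.na(res$p_raw[1]))
  calls <- call_regulation(normalize_dataset(ds))
  expect_equal(unname(calls$call[1, "WT4"]), "none")
})

test_that("BH adjustment matches hand values and the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(123)
  for (i in 1:1000) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("regulation calls respect inclusive thresholds", {
  # construct replicate sets whose mean log2 is exactly log2(1.5)
  target <- log2(1.5)
  vals <- rbind(
    boundary = target + c(-0.1, 0.1, -0.05, 0.05),
    strong   = c(0.9, 0.8, 1.0, 0.84),
    null     = c(0.01, -0.02, 0.02, -0.01)
  )
  values <- do.call(cbind, rep(list(vals), 7))
  conds <- nodule_conditions()
  colnames(values) <- paste0(rep(conds, each = 4), ":", 1:4)
  ds <- expression_dataset(values, rep(conds, each = 4), rep(1:4, 7))
  calls <- call_regulation(ds)
  expect_equal(unname(calls$ratio["boundary", "WT4"]), 1.5)
  expect_equal(unname(calls$call["boundary", "WT4"]), "up")
  expect_equal(unname(calls$call["strong", "WT4"]), "up")
  expect_equal(unname(calls$call["null", "WT4"]), "none")

  # adjusted p exactly at alpha is still called
  cfg <- analysis_config()
  cfg$alpha <- unname(calls$p_adj["boundary", "WT4"])
  calls2 <- call_regulation(ds, cfg)
  expect_equal(unname(calls2$call["boundary", "WT4"]), "up")
})

test_that("raising one probe's replicates never flips its call up -> down", {
  set.seed(21)
  for (rep_i in 1:5) {
    ds <- make_dataset(n_probes = 15, n_rep = 4, seed = rep_i)
    p <- sample(rownames(ds$values), 1)
    # plant a clear induction so the starting call is "up"
    ds$values[p, ds$condition == "WT4"] <- c(1.9, 2.0, 2.1, 2.0)
    calls1 <- call_regulation(ds)
    expect_equal(unname(calls1$call[p, "WT4"]), "up")
    ds2 <- ds
    ds2$values[p, ds2$condition == "WT4"] <-
      ds2$values[p, ds2$condition == "WT4"] + runif(1, 0, 2)
    calls2 <- call_regulation(ds2)
    expect_true(calls2$call[p, "WT4"] != "down")
  }
})

test_that("degenerate thresholds reduce up calls to a mean-ratio count", {
  ds <- make_dataset(n_probes = 40, n_rep = 4, seed = 31)
  cfg <- analysis_config()
  cfg$alpha <- 1
  cfg$ratio_threshold <- 1
  calls <- call_regulation(ds, cfg)  # unnormalized: keep means as drawn
  expect_equal(sum(calls$call[, "WT10"] == "up"),
               sum(rowMeans(ds$values[, ds$condition == "WT10"]) > 0))
})
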