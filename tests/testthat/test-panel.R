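test_that("stepwise selection keeps informative peaks and discards redundant ones", {
  m <- simulate_panel_matrix(n_cases = 100, n_controls = 100, seed = 3)
  panel <- fit_panel(m)
  info_mz <- m$peaks$mz_ref[m$peaks$informative]
  expect_gte(sum(panel$peak_mzs %in% info_mz), 4)
  expect_lte(sum(!panel$peak_mzs %in% info_mz), 1)
  # determinism: identical input, identical panel
  panel2 <- fit_panel(m)
  expect_identical(panel, panel2)
})

test_that("no retained coefficient has Wald P above the removal threshold", {
  for (seed in c(3, 14, 27)) {
    m <- simulate_panel_matrix(n_cases = 60, n_controls = 60, seed = seed)
    panel <- fit_panel(m)
    if (length(panel$p_wald)) expect_true(all(panel$p_wald <= 0.10))
  }
})

test_that("an unreachable entry threshold yields an intercept-only panel", {
  m <- simulate_panel_matrix(n_cases = 30, n_controls = 30, seed = 6)
  expect_warning(panel <- fit_panel(m, p_enter = 1e-12, p_remove = 1e-11),
                 "intercept-only")
  expect_length(panel$peak_mzs, 0)
  p <- predict(panel, m, type = "response")
  expect_equal(unique(round(p, 12)), round(0.5, 12))
})

test_that("panel thresholds are validated", {
  m <- simulate_panel_matrix(n_cases = 20, n_controls = 20, seed = 1)
  expect_error(fit_panel(m, p_enter = 0.2, p_remove = 0.1), "p_enter")
  expect_error(fit_panel(m, candidates = 7777.7), "not found")
})

test_that("the training panel weakly dominates each selected single-peak scorer", {
  m <- simulate_panel_matrix(n_cases = 80, n_controls = 80, seed = 10)
  panel <- fit_panel(m)
  prob <- predict(panel, m, type = "response")
  panel_auc <- roc_auc(prob, m$labels)$auc
  for (mz in panel$peak_mzs) {
    col <- m$intensities[, sprintf("%.1f", mz)]
    single <- roc_auc(col, m$labels)$auc
    single <- max(single, 1 - single)  # oriented scorer
    expect_gte(panel_auc, single - 1e-9)
  }
})

test_that("the odds-ratio table reproduces published coefficient arithmetic", {
  # published panel coefficients: beta -> OR must match to 3 decimals
  panel <- peptide_panel(
    peak_mzs = c(1895.3, 2020.9, 2080.7, 2656.8, 3238.5),
    beta = c(0.104, 0.180, -0.118, -0.525, 0.481),
    intercept = -1.237)
  tab <- odds_ratios(panel)
  # the exact exp(beta) identity at 3-decimal rounding for every row
  expect_equal(tab$OR, round(exp(c(0.104, 0.180, -0.118, -0.525, 0.481,
                                   -1.237)), 3))
  # the four rows whose printed ORs are arithmetically consistent
  expect_equal(tab$OR[c(1, 2, 4, 6)], c(1.110, 1.197, 0.592, 0.290))
  expect_equal(unname(panel$or_), exp(unname(panel$beta)))
})

test_that("fitted panels satisfy the OR/CI identities", {
  m <- simulate_panel_matrix(n_cases = 60, n_controls = 60, seed = 21)
  panel <- fit_panel(m)
  expect_equal(unname(panel$or_), unname(exp(panel$beta)))
  # geometric mean of the CI equals the OR
  gm <- sqrt(panel$or_ci[, "low"] * panel$or_ci[, "high"])
  expect_equal(unname(gm), unname(panel$or_), tolerance = 1e-9)
})

test_that("predictions follow the logistic form and its sign structure", {
  panel <- peptide_panel(peak_mzs = c(1000.5, 2000.5),
                         beta = c(1, -2), intercept = 0.4)
  X0 <- matrix(0, 3, 2)
  expect_equal(predict(panel, X0, type = "response"),
               rep(1 / (1 + exp(-0.4)), 3))
  one <- peptide_panel(1500.1, beta = 1, intercept = 0)
  expect_equal(predict(one, matrix(0, 1, 1), type = "response"), 0.5)
  # raising an up-peak's intensity never decreases the probability
  xs <- seq(0, 5, by = 0.5)
  p_up <- predict(panel, cbind(xs, 0), type = "response")
  expect_true(all(diff(p_up) >= 0))
  p_down <- predict(panel, cbind(0, xs), type = "response")
  expect_true(all(diff(p_down) <= 0))
})

test_that("evaluate reproduces the published confusion-matrix arithmetic", {
  # discovery: TP=96 FP=5 FN=4 TN=95
  d <- diag_performance(tp = 96, fp = 5, fn = 4, tn = 95)
  expect_equal(d$accuracy, 0.955)
  expect_equal(d$sensitivity, 0.960)
  expect_equal(d$specificity, 0.950)
  # validation: TP=87 FP=11 FN=4 TN=80
  v <- diag_performance(tp = 87, fp = 11, fn = 4, tn = 80)
  expect_equal(round(v$accuracy, 3), 0.918)
  expect_equal(round(v$sensitivity, 3), 0.956)
  expect_equal(round(v$specificity, 3), 0.879)

  perfect <- evaluate(rep(c("case", "control"), 5),
                      rep(c("case", "control"), 5))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sens_ci, c(1, 1))
  expect_error(evaluate("case", c("case", "control")), "lengths differ")
})

test_that("evaluate builds the confusion matrix from labels with case positive", {
  truth <- c("case", "case", "case", "control", "control")
  pred <- c("case", "control", "case", "case", "control")
  e <- evaluate(pred, truth)
  expect_equal(c(e$tp, e$fp, e$fn, e$tn), c(2, 1, 1, 1))
  expect_equal(e$accuracy, 3 / 5)
})

test_that("external validation is self-consistent and degrades to chance under permutation", {
  m <- simulate_panel_matrix(n_cases = 80, n_controls = 80, seed = 31)
  panel <- fit_panel(m)
  self <- external_validate(panel, m)
  prob <- predict(panel, m, type = "response")
  direct <- evaluate(ifelse(prob >= 0.5, "case", "control"), m$labels,
                     scores = prob)
  expect_equal(self$accuracy, direct$accuracy)
  expect_equal(self$auc, direct$auc)

  # the frozen panel keeps discriminating on exchangeable draws
  # (resubstitution accuracy is optimistic at this size; the 5-point
  # cohort-scale accuracy agreement is asserted in the acceptance suite)
  m_val <- simulate_panel_matrix(n_cases = 80, n_controls = 80, seed = 32)
  val <- external_validate(panel, m_val)
  expect_gt(val$auc, 0.75)
  expect_gt(val$accuracy, 0.65)

  # permuted labels: AUC within binomial noise of 0.5
  set.seed(7)
  m_perm <- m_val
  m_perm$labels <- sample(m_perm$labels)
  perm <- external_validate(panel, m_perm)
  expect_lt(abs(perm$auc - 0.5), 0.15)
})

test_that("unmatched panel peaks fall back to zero intensity with a warning", {
  m <- simulate_panel_matrix(n_cases = 30, n_controls = 30, seed = 41)
  panel <- fit_panel(m)
  m_missing <- m
  drop <- sprintf("%.1f", panel$peak_mzs[1])
  keep <- setdiff(colnames(m$intensities), drop)
  m_missing$intensities <- m_missing$intensities[, keep, drop = FALSE]
  m_missing$peaks <- m_missing$peaks[sprintf("%.1f", m_missing$peaks$mz_ref)
                                     %in% keep, , drop = FALSE]
  expect_warning(val <- external_validate(panel, m_missing), "zero")
  expect_s3_class(val, "diag_perf")
})

test_that("panels round-trip through the JSON model file", {
  m <- simulate_panel_matrix(n_cases = 40, n_controls = 40, seed = 51)
  panel <- fit_panel(m)
  f <- withr::local_tempfile(fileext = ".json")
  write_panel(panel, f)
  panel2 <- read_panel(f)
  expect_equal(panel2$peak_mzs, panel$peak_mzs)
  expect_equal(panel2$beta, panel$beta, tolerance = 1e-12)
  expect_equal(panel2$intercept, panel$intercept, tolerance = 1e-12)
  expect_equal(predict(panel2, m, type = "response"),
               predict(panel, m, type = "response"), tolerance = 1e-12)
})
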