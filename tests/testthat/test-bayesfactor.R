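test_that("JZS t-test matches an independent adaptive-quadrature oracle", {
  # oracle: direct integration over g with pracma, coded independently
  oracle <- function(t, n, r) {
    nu <- n - 1
    f <- function(g) {
      (1 + n * g)^(-0.5) * (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
        sqrt(r^2 / 2) / gamma(0.5) * g^(-1.5) * exp(-r^2 / (2 * g))
    }
    log(pracma::quadinf(f, 0, Inf, tol = 1e-12)$Q) +
      ((nu + 1) / 2) * log(1 + t^2 / nu)
  }
  for (t in c(0, 0.8, 3, 6)) {
    for (r in c(0.5, 0.707, 1)) {
      expect_equal(jzs_ttest_logbf(t = t, n = 40, r = r), oracle(t, 40, r),
                   tolerance = 1e-5)
    }
  }
})

test_that("JZS BF has the right shape: null at t = 0, monotone, symmetric", {
  expect_lt(jzs_ttest_logbf(t = 0, n = 40, r = 0.707), 0)
  ts <- c(0, 0.5, 1, 2, 4, 8)
  vals <- vapply(ts, function(t) jzs_ttest_logbf(t = t, n = 25), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_equal(jzs_ttest_logbf(t = -3, n = 25), jzs_ttest_logbf(t = 3, n = 25))
  # prior collapsing onto the null: BF -> 1 from below
  small_r <- jzs_ttest_logbf(t = 2, n = 25, r = 1e-4)
  expect_lt(abs(small_r), 1e-3)
  expect_error(jzs_ttest_logbf(rep(1.5, 10)), "zero-variance")
  expect_error(jzs_ttest_logbf(c(1)), "at least 2")
})

test_that("log BFs convert to the printed natural-scale values", {
  expect_equal(round(bf_from_log(-1.72), 2), 0.18)
  expect_equal(exp(log_from_bf(0.18)), 0.18, tolerance = 1e-12)
  x <- c(-5.3, 0, 2.7, 24.08)
  expect_equal(log_from_bf(bf_from_log(x)), x, tolerance = 1e-12)
})

test_that("the empty model is the null and returns log BF 0 exactly", {
  tab <- make_amplitude_table(6, 2, seed = 3)
  out <- linear_model_logbf(tab, model_spec(character(0)),
                            n_iterations = 10)
  expect_identical(out$log_bf10, 0)
  expect_identical(out$pe_pct, 0)
})

test_that("linear-model BF is deterministic given a seed", {
  tab <- make_amplitude_table(8, 3, size_effect = 0.5, seed = 4)
  a <- linear_model_logbf(tab, model_spec("size"), n_iterations = 2000,
                          seed = 11)
  b <- linear_model_logbf(tab, model_spec("size"), n_iterations = 2000,
                          seed = 11)
  expect_identical(a, b)
  c <- linear_model_logbf(tab, model_spec("size"), n_iterations = 2000,
                          seed = 12)
  expect_false(identical(a$log_bf10, c$log_bf10))
})

test_that("the linear-model BF agrees with the paired JZS t-test", {
  # the Monte-Carlo marginal must match deterministic quadrature within
  # Monte-Carlo error; the exact BF matches the paired t-test BF up to the
  # small hierarchical-shrinkage residual of the unit-scale nuisance prior
  for (s in 1:4) {
    tab <- make_paired_table(40, 0.4, seed = 200 + s)
    lm_bf <- linear_model_logbf(tab, model_spec("emotion"),
                                prior_spec(0.707), n_iterations = 10000,
                                seed = s)
    exact <- lm_paired_logbf_exact(tab, r_f = 0.707, r_r = 1)
    expect_lt(abs(lm_bf$log_bf10 - exact), 4 * lm_bf$pe_pct / 100)
    d <- tab$amplitude_uV[tab$emotion == "negative"] -
      tab$amplitude_uV[tab$emotion == "neutral"]
    jz <- jzs_ttest_logbf(d, r = 0.707)
    expect_lt(abs(exact - jz), 0.05 + 0.05 * abs(jz))
  }
})

test_that("a strong pure size effect yields positive evidence in most seeds", {
  wins <- 0
  for (s in 1:10) {
    tab <- make_amplitude_table(20, 20, size_effect = 1, subject_sd = 1,
                                sigma = 1, seed = 300 + s)
    bf <- linear_model_logbf(tab, model_spec("size"), prior_spec(0.707),
                             n_iterations = 3000, seed = s)
    wins <- wins + (bf$log_bf10 > 0)
  }
  expect_gte(wins, 9)
})

test_that("Monte-Carlo error shrinks roughly as sqrt(iterations)", {
  tab <- make_amplitude_table(12, 5, size_effect = 0.5, seed = 5)
  pe1 <- pe2 <- numeric(6)
  for (s in 1:6) {
    pe1[s] <- linear_model_logbf(tab, model_spec("size"), n_iterations = 2000,
                                 seed = 50 + s)$pe_pct
    pe2[s] <- linear_model_logbf(tab, model_spec("size"), n_iterations = 8000,
                                 seed = 50 + s)$pe_pct
  }
  expect_equal(mean(pe1) / mean(pe2), 2, tolerance = 0.5)
})

test_that("model comparison returns 6 ranked rows per scale", {
  tab <- make_amplitude_table(10, 4, size_effect = 0.8, emotion_effect = 0.4,
                              seed = 6)
  cmp <- compare_candidate_models(tab, r_fixed = c(0.5, 0.707, 1),
                                  n_iterations = 2000, seed = 2)
  expect_equal(nrow(cmp), 18)
  expect_true(all(table(cmp$r) == 6))
  for (rr in unique(cmp$r)) {
    block <- cmp[cmp$r == rr, ]
    expect_equal(block$rank, 1:6)
    expect_true(all(diff(block$log_bf10) <= 0))
    expect_equal(block$log_bf_best_vs_second[1],
                 block$log_bf10[1] - block$log_bf10[2])
  }
  # evidence ratios on the natural scale
  expect_equal(exp(514.57 - 490.49), 2.87e10, tolerance = 0.01)
  g <- glance(cmp)
  expect_equal(nrow(g), 3)
  expect_equal(g$bf_best_vs_second, exp(g$log_bf_best_vs_second))
})

test_that("model ranking is invariant to the input model-list order", {
  tab <- make_amplitude_table(8, 3, size_effect = 0.8, seed = 7)
  mods <- candidate_models()
  a <- compare_candidate_models(tab, r_fixed = 0.707, n_iterations = 2000,
                                seed = 3, models = mods)
  b <- compare_candidate_models(tab, r_fixed = 0.707, n_iterations = 2000,
                                seed = 3, models = rev(mods))
  expect_equal(a$model, b$model)
  expect_equal(a$log_bf10, b$log_bf10, tolerance = 1e-12)
})

test_that("interactive model names expand to their constituent terms", {
  mods <- candidate_models()
  expect_equal(mods[["size x emotion"]]$terms,
               c("size", "emotion", "size:emotion"))
  expect_length(mods[["size x contrast x emotion"]]$terms, 7)
  expect_error(model_spec("font"), "unknown design term")
})

test_that("top-down omission reports 7 terms with the ratio identity", {
  tab <- make_amplitude_table(10, 4, size_effect = 1, seed = 8)
  om <- topdown_term_omission(tab, r_fixed = 0.707, n_iterations = 2000,
                              seed = 5)
  expect_equal(nrow(om), 7)
  expect_setequal(
    om$omitted_term,
    c("size", "contrast", "emotion", "size:contrast", "size:emotion",
      "contrast:emotion", "size:contrast:emotion")
  )
  # omitting the active factor must hurt; it should be the worst omission
  expect_equal(om$omitted_term[which.min(om$log_bf_omission)], "size")
  expect_lt(om$log_bf_omission[om$omitted_term == "size"], 0)
  # natural-scale reading of an omission log BF
  expect_equal(round(exp(4.41), 2), 82.27)
})

test_that("omission favours dropping emotion when it carries no effect", {
  vals <- vapply(1:8, function(s) {
    tab <- make_amplitude_table(12, 5, size_effect = 0.8, emotion_effect = 0,
                                seed = 400 + s)
    om <- topdown_term_omission(tab, r_fixed = 0.707, n_iterations = 2000,
                                seed = s)
    om$log_bf_omission[om$omitted_term == "emotion"]
  }, numeric(1))
  expect_gt(median(vals), 0)
})

test_that("post-hoc contrasts give 4 cells x 3 scales with paired BFs", {
  tab <- make_amplitude_table(15, 6, emotion_effect = 0.8, seed = 9)
  ph <- posthoc_emotion_contrasts(tab)
  expect_equal(nrow(ph), 12)
  expect_true(all(table(ph$r) == 4))
  # oracle: recompute one cell by hand
  cell <- tab[tab$size == "large" & tab$contrast == "high", ]
  means <- tapply(cell$amplitude_uV, list(cell$subject_id, cell$emotion), mean)
  d <- means[, "negative"] - means[, "neutral"]
  expect_equal(
    ph$log_bf10[ph$size == "large" & ph$contrast == "high" & ph$r == 0.5],
    jzs_ttest_logbf(d, r = 0.5)
  )
  # identical emotion values per subject -> zero-variance error
  tab0 <- tab
  tab0$amplitude_uV <- rep(tapply(tab0$amplitude_uV, tab0$subject_id, mean)[
    as.character(tab0$subject_id)])
  expect_error(posthoc_emotion_contrasts(tab0), "zero-variance")
})

test_that("an effect confined to one cell drives that cell's contrast", {
  hits <- 0
  for (s in 1:8) {
    set.seed(500 + s)
    tab <- make_amplitude_table(15, 6, seed = 500 + s)
    sel <- tab$size == "small" & tab$contrast == "high" &
      tab$emotion == "negative"
    tab$amplitude_uV[sel] <- tab$amplitude_uV[sel] + 1
    ph <- posthoc_emotion_contrasts(tab, r = 0.707)
    top <- ph[which.max(ph$log_bf10), ]
    hits <- hits + (top$size == "small" && top$contrast == "high")
  }
  expect_gte(hits, 7)
})
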