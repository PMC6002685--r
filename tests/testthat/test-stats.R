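# Composites, OLS fits, residualization, and the correlation t.

test_that("zscore centers and scales with the sample SD", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(zscore(rep(2, 5), task = "flanker"), "flanker")
  expect_error(zscore(3), "at least 2")
  withr::with_seed(1, x <- rnorm(20, 10, 3))
  z <- zscore(x)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
})

test_that("composites reproduce the loading table on unit z vectors", {
  z0 <- tibble::tibble(subject_id = "a", vocabulary = 0, flanker = 0,
                       working_memory = 0, card_sort = 0, pattern = 0)
  base <- composite_scores(z0)
  expect_equal(base$control, 0)
  expect_equal(base$working_memory, 0)

  zf <- z0; zf$flanker <- 1
  expect_equal(composite_scores(zf)$control, 0.922)
  expect_equal(composite_scores(zf)$working_memory, 0)
  zw <- z0; zw$working_memory <- 1
  expect_equal(composite_scores(zw)$working_memory, 0.999)
  expect_equal(composite_scores(zw)$control, 0)
  zc <- z0; zc$card_sort <- 1
  expect_equal(composite_scores(zc)$control, 0.509)
  expect_equal(composite_scores(zc)$working_memory, -0.119)
})

test_that("the salient-loadings variant drops only sub-0.3 cross-loadings", {
  l <- nih_loadings("salient")
  expect_equal(l$working_memory[l$task == "working_memory"], 0.999)
  expect_equal(sum(l$working_memory != 0), 1L)
  expect_equal(sum(l$control != 0), 3L)
})

test_that("composite construction is linear in the z scores", {
  withr::with_seed(5, {
    mk <- function() tibble::tibble(
      subject_id = sprintf("s%d", 1:4), vocabulary = rnorm(4),
      flanker = rnorm(4), working_memory = rnorm(4), card_sort = rnorm(4),
      pattern = rnorm(4))
    z1 <- mk(); z2 <- mk()
    mix <- z1
    for (tk in nih_loadings()$task) mix[[tk]] <- 2 * z1[[tk]] - 3 * z2[[tk]]
    c1 <- composite_scores(z1); c2 <- composite_scores(z2)
    cm <- composite_scores(mix)
    expect_equal(cm$control, 2 * c1$control - 3 * c2$control)
    expect_equal(cm$working_memory,
                 2 * c1$working_memory - 3 * c2$working_memory)
  })
})

test_that("missing task scores are reported by subject or column", {
  z <- tibble::tibble(subject_id = c("a", "b"), vocabulary = c(0, NA),
                      flanker = 0, working_memory = 0, card_sort = 0,
                      pattern = 0)
  expect_error(composite_scores(z), "b")
  expect_error(composite_scores(z[-2]), "vocabulary")
})

test_that("fit_linear_model handles exact and degenerate designs", {
  d <- data.frame(y = c(2, 4, 6), x = c(1, 2, 3))
  td <- tidy(fit_linear_model(d, y ~ x))
  expect_equal(td$estimate[td$term == "x"], 2)
  expect_equal(td$std.error[td$term == "x"], 0)
  f0 <- fit_linear_model(data.frame(y = c(1, 5, 9, 2)), y ~ 1)
  expect_equal(tidy(f0)$estimate, mean(c(1, 5, 9, 2)))
  d2 <- data.frame(y = rnorm(10), x = 1:10)
  d2$x2 <- 2 * d2$x
  expect_error(fit_linear_model(d2, y ~ x + x2), "x2")
})

test_that("OLS matches an independent pseudoinverse oracle", {
  withr::with_seed(42, {
    X <- cbind(1, matrix(rnorm(40), 20, 2))
    y <- rnorm(20)
    sv <- svd(X)
    beta_oracle <- sv$v %*% ((t(sv$u) %*% y) / sv$d)
    d <- data.frame(y = y, x1 = X[, 2], x2 = X[, 3])
    fit <- fit_linear_model(d, y ~ x1 + x2)
    expect_equal(unname(tidy(fit)$estimate), as.numeric(beta_oracle),
                 tolerance = 1e-8)
    # t = beta / SE for every term, classical and robust
    d$g <- rep(1:5, each = 4)
    fit2 <- fit_linear_model(d, y ~ x1 + x2, cluster = "g")
    for (rob in c(FALSE, TRUE)) {
      td <- tidy(fit2, robust = rob)
      expect_equal(td$statistic, td$estimate / td$std.error)
    }
    # residuals orthogonal to the design
    r <- residuals(fit)
    expect_lt(max(abs(t(X) %*% r)), 1e-6)
  })
})

test_that("correlation_t implements the closed form", {
  expect_equal(correlation_t(0, 10)$t, 0)
  expect_equal(correlation_t(0.5, 11)$t, 1.5 / sqrt(0.75))
  expect_equal(round(correlation_t(0.5, 11)$t, 4), 1.7321)
  expect_error(correlation_t(1, 10), "< 1")
  expect_error(correlation_t(0.2, 2), ">= 3")
})

test_that("noise-free null cohorts give exactly zero slopes", {
  cfg <- reduced_config(seed = 21, mu_suppression = 1, b_control = 0,
                        b_wm = 0, b_interaction = 0, b_group = 0,
                        residual_sd = 0, trial_sd = 0)
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$truth$subjects$magnitude_db == 1))
  m <- simulate_trial_measurements(coh)
  fit <- cognitive_model(m, coh$metadata)
  td <- tidy(fit)
  slopes <- td$estimate[td$term != "(Intercept)"]
  expect_equal(unname(slopes), rep(0, 3), tolerance = 1e-10)
  expect_equal(td$estimate[td$term == "(Intercept)"], -1)
})

test_that("residualization preserves an unmediated group effect", {
  cfg <- reduced_config(seed = 22)   # group orthogonal to composites
  coh <- simulate_cohort(cfg)
  m <- simulate_trial_measurements(coh)
  fit_c <- cognitive_model(m, coh$metadata)
  fit_r <- residualized_group_model(fit_c, coh$metadata)
  td <- tidy(fit_r)
  expect_lt(td$estimate[td$term == "is_bilingualTRUE"], 0)
})

test_that("a fully mediated group effect vanishes after residualization", {
  # group shifts the task scores (hence composites) but has no direct
  # effect; a noise-free cohort then leaves ~nothing for group to explain
  # beyond what the interaction term cannot absorb
  cfg <- reduced_config(seed = 23, b_group = 0, b_interaction = 0,
                        residual_sd = 0, trial_sd = 0.01,
                        group_task_shift = 1)
  coh <- simulate_cohort(cfg)
  m <- simulate_trial_measurements(coh)
  fit_c <- cognitive_model(m, coh$metadata)
  fit_r <- residualized_group_model(fit_c, coh$metadata)
  td <- tidy(fit_r)
  expect_lt(abs(td$estimate[td$term == "is_bilingualTRUE"]), 0.05)
})

test_that("residuals of a saturated fit regress to zero coefficients", {
  d <- tibble::tibble(subject_id = c("a", "a", "b", "b"),
                      delta_db = c(1, 1, 2, 2),
                      control = c(0, 0, 1, 1),
                      working_memory = c(0, 1, 0, 1))
  fit <- fit_linear_model(d, delta_db ~ control, cluster = "subject_id")
  md <- tibble::tibble(subject_id = c("a", "b"),
                       group = c("mono", "early_bi"))
  fit_r <- residualized_group_model(fit, md)
  expect_equal(unname(tidy(fit_r)$estimate), c(0, 0), tolerance = 1e-12)
})
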