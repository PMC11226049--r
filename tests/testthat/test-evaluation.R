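test_that("train/test splits are subject-level, sized and reproducible", {
  coh <- simulate_cohort(cohort_params(n_subjects = 100, seed = 1))
  sp <- split_train_test(coh, 0.75, seed = 5)
  expect_equal(n_subjects(sp$train), 75)
  expect_equal(n_subjects(sp$test), 25)
  expect_length(intersect(sp$train$survival$subject_id,
                          sp$test$survival$subject_id), 0)
  sp2 <- split_train_test(coh, 0.75, seed = 5)
  expect_identical(sp$train$survival, sp2$train$survival)
  # rounding rule: round(n * fraction) subjects train
  coh7 <- subset_cohort(coh, 1:7)
  sp7 <- split_train_test(coh7, 0.5, seed = 1)
  expect_equal(n_subjects(sp7$train), round(7 * 0.5))
  expect_equal(n_subjects(sp7$test), 7 - round(7 * 0.5))
  expect_error(split_train_test(subset_cohort(coh, 1), 0.5), "at least 2")
})

test_that("concordance AUC follows the pairwise formula", {
  expect_equal(auc_concordance(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(auc_concordance(c(3, 1, 2), c(1, 2, 3), c(1, 1, 1)), 2 / 3)
  # strict inequality: fully tied scores score 0 under the printed form
  expect_equal(auc_concordance(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1)), 0)
  expect_equal(auc_concordance(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1),
                               ties = "half"), 0.5)
  # censored subjects never serve as the earlier member of a pair
  expect_equal(auc_concordance(c(2, 1), c(1, 2), c(0, 1)), NA_real_)
  expect_warning(auc_concordance(c(1, 2), c(1, 1), c(1, 1)), "no usable")
})

test_that("AUC is invariant to strictly monotone transforms of the score", {
  f <- rand_surv(40, 55)
  risk <- rnorm(40)
  a <- auc_concordance(risk, f$times, f$events)
  expect_equal(auc_concordance(exp(risk), f$times, f$events), a)
  expect_equal(auc_concordance(risk^3, f$times, f$events), a)
})

test_that("IPCW Brier scores match hand evaluations", {
  # no censoring, perfect predictions -> 0
  t <- c(5, 1); e <- c(1, 1)
  expect_equal(brier_ipcw_prob(as.numeric(t > 3), t, e, 3), 0)
  # hand: ((0-0.3)^2... ) per the two-term decomposition with G == 1
  expect_equal(brier_ipcw_prob(c(0.8, 0.3), t, e, 3), (0.09 + 0.04) / 2)
  # RMST form, hand evaluation
  expect_equal(brier_ipcw_rmst(c(2, 2), c(1, 5), c(1, 1), 3),
               ((1 - 2)^2 + (3 - 2)^2) / 2)
  # perfect RMST-type predictions
  expect_equal(brier_ipcw_rmst(pmin(t, 3), t, e, 3), 0)
})

test_that("with no censoring the IPCW score reduces to the plain Brier score", {
  for (seed in 1:15) {
    f <- rand_surv(sample(10:50, 1), seed, p_event = 1)
    p <- runif(length(f$times))
    t0 <- quantile(f$times, 0.6)
    plain <- mean((p - as.numeric(f$times > t0))^2)
    expect_equal(brier_ipcw_prob(p, f$times, f$events, t0), plain,
                 tolerance = 1e-12)
  }
})

test_that("the IPCW score equals its term-by-term transcription on censored data", {
  f <- rand_surv(60, 7)
  p <- runif(60)
  t0 <- 1.5
  G <- censoring_km(f$times, f$events)
  num <- 0
  for (i in seq_len(60)) {
    Ti <- f$times[i]; di <- f$events[i]
    if (Ti <= t0 && di == 1)
      num <- num + (0 - p[i])^2 / eval_step_survival(G, Ti, left = TRUE)
    else if (Ti > t0)
      num <- num + (1 - p[i])^2 / eval_step_survival(G, t0)
  }
  expect_equal(brier_ipcw_prob(p, f$times, f$events, t0), num / 60,
               tolerance = 1e-12)
})

test_that("IPCW scores are non-negative and scale quadratically in the error", {
  f <- rand_surv(50, 31)
  mu <- pmin(f$times, 2) + rnorm(50, 0, 0.3)
  s1 <- brier_ipcw_rmst(mu, f$times, f$events, 2)
  expect_gte(s1, 0)
  # inflating every error by k multiplies the score by k^2
  k <- 1.7
  err <- mu - ifelse(f$times <= 2, f$times, 2)
  mu2 <- ifelse(f$times <= 2, f$times, 2) + k * err
  expect_equal(brier_ipcw_rmst(mu2, f$times, f$events, 2), k^2 * s1,
               tolerance = 1e-10)
})

test_that("evaluation over landmarks yields one row per model and landmark", {
  coh <- simulate_cohort(cohort_params(n_subjects = 500, seed = 61))
  sp <- split_train_test(coh, 0.75, seed = 2)
  g <- landmark_grid(0, 1, 0.5, tau = 2)
  st <- add_pseudo_values(stack_landmarks(sp$train, g, truncate = FALSE),
                          kind = "mean")
  covs <- c("age", "meld_na", "albumin")
  dyn <- fit_gee_supermodel(st, covs)
  statics <- lapply(c(sm1 = "sm1", sm2 = "sm2", sm3 = "sm3"),
                    fit_static_model, family = "pm", cohort = sp$train,
                    grid = g, covariates = covs)
  models <- c(list(dynamic = dyn), statics)
  mt <- evaluate_models(models, sp$test, g)
  expect_equal(nrow(mt), 4 * 3)
  expect_true(all(mt$auc >= 0 & mt$auc <= 1, na.rm = TRUE))
  expect_true(all(mt$brier >= 0, na.rm = TRUE))
  # identical predictions -> identical metric rows
  mt2 <- evaluate_models(list(a = dyn, b = dyn), sp$test, g)
  a <- mt2[mt2$model == "a", -1]; b <- mt2[mt2$model == "b", -1]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("a strongly prognostic covariate yields informative AUC everywhere", {
  p <- cohort_params(n_subjects = 1500, log_hazard = c(meld_na = 0.25),
                     baseline_hazard = 0.15, censoring_hazard = 0.3,
                     admin_end = 8, seed = 71)
  coh <- simulate_cohort(p)
  sp <- split_train_test(coh, 0.75, seed = 3)
  g <- landmark_grid(0, 1, 0.5, tau = 2)
  st <- add_pseudo_values(stack_landmarks(sp$train, g, truncate = FALSE),
                          kind = "mean")
  dyn <- fit_gee_supermodel(st, "meld_na")
  mt <- evaluate_models(list(dynamic = dyn), sp$test, g)
  # 3 * binomial-pair standard error above chance at every landmark
  se_pairs <- sqrt(0.25 / (mt$n_events * (mt$n_risk - mt$n_events)))
  expect_true(all(mt$auc > 0.5 + 3 * se_pairs))
})
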