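make_stacked <- function(n = 120, seed = 1, grid = landmark_grid(0, 1, 0.5, 2),
                         kind = "mean") {
  coh <- simulate_cohort(cohort_params(n_subjects = n, seed = seed))
  add_pseudo_values(stack_landmarks(coh, grid, truncate = FALSE),
                    kind = kind)
}

test_that("GEE supermodel interpolates exactly linear pseudo-outcomes", {
  st <- make_stacked(grid = landmark_grid(0, 0, 0.5, 2))
  st$pseudo <- 0.5 + 2 * st$meld_na
  fit <- fit_gee_supermodel(st, "meld_na", degree = 0)
  expect_equal(unname(coef(fit)), c(0.5, 2), tolerance = 1e-10)
  pred <- predict_conditional(fit, st, 0)
  expect_equal(pred, pmin(pmax(st$pseudo, 0), fit$tau), tolerance = 1e-10)
})

test_that("a zero-variance covariate triggers a rank error naming it", {
  st <- make_stacked()
  st$flat <- 1.5
  expect_error(fit_gee_supermodel(st, c("meld_na", "flat")), "flat")
})

test_that("GEE point estimates equal ordinary least squares on unclustered data", {
  st <- make_stacked(grid = landmark_grid(0, 0, 0.5, 2))  # one row/subject
  covs <- c("age", "meld_na", "albumin")
  fit <- fit_gee_supermodel(st, covs, degree = 0)
  X <- cbind(1, as.matrix(as.data.frame(st)[covs]))
  ols <- solve(crossprod(X), crossprod(X, st$pseudo))  # normal equations
  expect_equal(unname(coef(fit)), as.numeric(ols), tolerance = 1e-10)
})

test_that("single-landmark Cox supermodel matches the brute-force partial likelihood", {
  # covariate not monotone in event order, so the partial-likelihood
  # maximum is finite
  coh <- toy_cohort(times = c(1, 2, 3), events = c(1, 1, 0),
                    meld = c(2, 1, 1.5))
  g <- landmark_grid(0, 0, 0.5, tau = 5)
  st <- stack_landmarks(coh, g)
  fit <- fit_cox_supermodel(st, "meld_na", degree = 0)
  x <- st$meld_na
  oracle <- uniroot(breslow_score, c(-5, 5), entry = st$entry,
                    exit = st$exit, event = st$exit_event, x = x,
                    tol = 1e-12)$root
  # the root maximizes the hand-written likelihood
  expect_gt(breslow_loglik(oracle, st$entry, st$exit, st$exit_event,
                           matrix(x)),
            breslow_loglik(oracle + 0.01, st$entry, st$exit,
                           st$exit_event, matrix(x)))
  expect_equal(unname(coef(fit)), oracle, tolerance = 1e-8)
})

test_that("stacked Cox restricted to one landmark equals a left-truncated coxph", {
  coh <- simulate_cohort(cohort_params(n_subjects = 300, seed = 17))
  g <- landmark_grid(1, 1, 0.5, tau = 3)
  st <- stack_landmarks(coh, g)
  fit <- fit_cox_supermodel(st, c("meld_na", "albumin"), degree = 0)
  ref <- survival::coxph(
    survival::Surv(entry, exit, exit_event) ~ meld_na + albumin,
    data = as.data.frame(st), ties = "breslow",
    control = survival::coxph.control(eps = 1e-11, iter.max = 50))
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-10)
})

test_that("Cox supermodel recovers a known log hazard ratio", {
  # balanced two-group exponential survival, log-HR 0.7
  set.seed(23)
  n <- 2000
  x <- rep(0:1, n / 2)
  times <- rexp(n, 0.3 * exp(0.7 * x))
  sv <- data.frame(subject_id = 1:n, age = 55, sex = 0, etoh = x,
                   biliary = 0, chol = 0, time = times, event = 1)
  lg <- data.frame(subject_id = 1:n, time = 0, meld_na = 18, albumin = 3.2,
                   decomp = 0, hcc = 0)
  coh <- as_cohort(sv, lg)
  st <- stack_landmarks(coh, landmark_grid(0, 0, 0.5, tau = 3))
  fit <- fit_cox_supermodel(st, "etoh", degree = 0)
  se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(coef(fit) - 0.7), 3 * se)
})

test_that("PM-GEE recovers the true conditional RMST difference", {
  # binary covariate, constant hazards -> the true effect is the oracle
  # RMST difference, constant across landmarks
  p1 <- cohort_params(n_subjects = 2000, log_hazard = c(etoh = 0.6),
                      p_etoh = 0.5, baseline_hazard = 0.25,
                      censoring_hazard = 0.3, admin_end = 8, seed = 19)
  coh <- simulate_cohort(p1)
  tau <- 3
  truth <- true_conditional_rmst(p1, data.frame(time = 0, etoh = 1), 0, tau) -
    true_conditional_rmst(p1, data.frame(time = 0, etoh = 0), 0, tau)
  st <- add_pseudo_values(
    stack_landmarks(coh, landmark_grid(0, 1, 0.5, tau), truncate = FALSE),
    kind = "mean")
  fit <- fit_gee_supermodel(st, "etoh", degree = 0)
  se <- sqrt(diag(vcov(fit)))["etoh"]
  expect_lt(abs(coef(fit)["etoh"] - truth), 3 * se)
})

test_that("dynamic coefficients evaluate the quadratic basis correctly", {
  m <- supermodel_from_coefficients(
    c(`(Intercept)` = 2.833, decomp = -0.151, decomp_t = 0.640,
      decomp_t2 = -0.671, age = -0.009, age_t = 0.025, age_t2 = -0.021),
    family = "pm")
  expect_equal(dynamic_coefficient(m, "decomp", 5)$estimate, -0.182,
               tolerance = 1e-12)
  expect_equal(dynamic_coefficient(m, "decomp", 0)$estimate, -0.151)
  expect_equal(dynamic_coefficient(m, "age", 2.5)$estimate, -0.00175,
               tolerance = 1e-12)
  expect_error(dynamic_coefficient(m, "sex", 1), "not among")
})

test_that("dynamic coefficient CIs use the delta-method sandwich variance", {
  st <- make_stacked(n = 200, seed = 3)
  fit <- fit_gee_supermodel(st, c("meld_na", "etoh"))
  d <- dynamic_coefficient(fit, "meld_na", 0.5)
  b <- as.numeric(time_basis(0.5))
  idx <- c("meld_na", "meld_na_t", "meld_na_t2")
  expect_equal(d$se, sqrt(b %*% vcov(fit)[idx, idx] %*% b)[1])
  expect_equal(d$upper - d$lower, 2 * qnorm(0.975) * d$se)
  expect_true(d$lower <= d$estimate && d$estimate <= d$upper)
})

test_that("degree-1 fits give dynamic coefficients affine in l", {
  st <- make_stacked(n = 200, seed = 5)
  fit <- fit_gee_supermodel(st, "meld_na", degree = 1)
  ls <- c(0, 1, 2, 3)
  est <- dynamic_coefficient(fit, "meld_na", ls)$estimate
  expect_equal(diff(est, differences = 2), rep(0, 2), tolerance = 1e-12)
})

test_that("truly time-constant effects rarely show significant interactions", {
  hits <- 0
  reps <- 60
  for (s in seq_len(reps)) {
    p <- cohort_params(n_subjects = 400, log_hazard = c(etoh = 0.5),
                       p_etoh = 0.5, baseline_hazard = 0.3,
                       censoring_hazard = 0.25, admin_end = 8, seed = 1000 + s)
    st <- add_pseudo_values(
      stack_landmarks(simulate_cohort(p), landmark_grid(0, 1, 0.5, 2),
                      truncate = FALSE), kind = "mean")
    fit <- fit_gee_supermodel(st, "etoh", degree = 2)
    idx <- c("etoh_t", "etoh_t2")
    b <- coef(fit)[idx]
    W <- as.numeric(b %*% solve(vcov(fit)[idx, idx]) %*% b)
    if (W <= qchisq(0.95, 2)) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("predictions follow the family contracts", {
  # PM: intercept-only model predicts the intercept, in years
  m <- supermodel_from_coefficients(
    c(`(Intercept)` = 2.833, decomp = 0, decomp_t = 0, decomp_t2 = 0),
    family = "pm", tau = 3)
  nd <- data.frame(decomp = c(0, 2))
  expect_equal(predict_conditional(m, nd, 1), c(2.833, 2.833))
  # PP: out-of-range linear predictors are clipped and reported
  mp <- supermodel_from_coefficients(
    c(`(Intercept)` = 1.2, decomp = 0, decomp_t = 0, decomp_t2 = 0),
    family = "pp", tau = 3)
  expect_message(pr <- predict_conditional(mp, nd, 0), "clipped")
  expect_equal(pr, c(1, 1))
  # Cox: zero linear predictor gives the baseline conditional survival
  coh <- simulate_cohort(cohort_params(n_subjects = 200, seed = 29))
  st <- stack_landmarks(coh, landmark_grid(0, 1, 0.5, 3))
  cm <- fit_cox_supermodel(st, "meld_na", degree = 0)
  nd0 <- data.frame(meld_na = 0)
  H <- stepfun(cm$basehaz$time, c(0, cm$basehaz$hazard))
  expect_equal(predict_conditional(cm, nd0, 1), exp(-(H(4) - H(1))))
})

test_that("static comparators have the documented fit counts and nestings", {
  coh <- simulate_cohort(cohort_params(n_subjects = 250, seed = 37))
  g <- landmark_grid(0, 5, 0.5, tau = 3)
  covs <- c("age", "meld_na")
  sm1 <- fit_static_model("sm1", "pm", coh, g, covs)
  sm2 <- fit_static_model("sm2", "pm", coh, g, covs)
  sm3 <- fit_static_model("sm3", "pm", coh, g, covs)
  expect_length(sm1$fits, 11)
  expect_length(sm2$fits, 1)
  expect_length(sm3$fits, 11)

  # at l = 0 SM2 and SM3 are the same fit, so predictions coincide
  p2 <- predict_at_landmark(sm2, coh, 0)
  p3 <- predict_at_landmark(sm3, coh, 0)
  expect_equal(p2, p3, tolerance = 1e-12)

  # SM3 at l = 0 equals the dynamic supermodel restricted to the l = 0
  # dataset with a constant basis
  st0 <- add_pseudo_values(
    stack_landmarks(coh, landmark_grid(0, 0, 0.5, 3), truncate = FALSE),
    kind = "mean")
  dyn0 <- fit_gee_supermodel(st0, covs, degree = 0)
  expect_equal(unname(coef(dyn0)), unname(sm3$fits[["0"]]$coefficients),
               tolerance = 1e-10)
})

test_that("static Cox comparators fit and predict probabilities", {
  coh <- simulate_cohort(cohort_params(n_subjects = 250, seed = 43))
  g <- landmark_grid(0, 2, 1, tau = 3)
  sm2 <- fit_static_model("sm2", "cox", coh, g, c("meld_na", "age"))
  pr <- predict_at_landmark(sm2, coh, 2)
  expect_true(all(pr$prediction >= 0 & pr$prediction <= 1))
})
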