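test_that("km_estimate reproduces hand product-limit calculations", {
  s <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(s$surv, c(2 / 3, 1 / 3, 0))
  s2 <- km_estimate(c(1, 2), c(1, 0))
  expect_equal(eval_step_survival(s2, c(0.5, 1, 2, 5)), c(1, 0.5, 0.5, 0.5))
  s3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(s3$surv == 1))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("rmst_from_km integrates the KM curve with the leading segment", {
  s <- km_estimate(c(1, 3), c(1, 1))
  expect_equal(rmst_from_km(s, 2), 1.5)       # 1*1 + 0.5*1
  s_flat <- km_estimate(c(5, 6), c(0, 0))
  expect_equal(rmst_from_km(s_flat, 3), 3)    # no events: area = tau
  expect_equal(rmst_from_km(s, 0.5), 0.5)     # tau before the first jump
  # flat-tail convention: curve carried forward beyond the last time
  expect_equal(rmst_from_km(km_estimate(c(1, 2), c(1, 0)), 4),
               1 + 0.5 * 3)
})

test_that("pseudo-values reduce to closed forms without censoring", {
  expect_equal(pseudo_means(c(1, 2, 4), c(1, 1, 1), 3), c(1, 2, 3))
  expect_equal(pseudo_probabilities(c(1, 2, 4), c(1, 1, 1), 3), c(0, 0, 1))
  for (seed in 1:20) {
    f <- rand_surv(sample(5:40, 1), seed, p_event = 1)
    tau <- runif(1, 0.5, 3)
    expect_equal(pseudo_means(f$times, f$events, tau),
                 pmin(f$times, tau))
    expect_equal(pseudo_probabilities(f$times, f$events, tau),
                 as.numeric(f$times > tau))
  }
})

test_that("the jackknife mean identity holds on censored data", {
  for (seed in 1:30) {
    f <- rand_surv(sample(5:50, 1), seed)
    tau <- runif(1, 0.1, 0.95) * max(f$times)  # inside the observed range
    km <- km_estimate(f$times, f$events)
    expect_equal(mean(pseudo_means(f$times, f$events, tau)),
                 rmst_from_km(km, tau), tolerance = 1e-12)
    expect_equal(mean(pseudo_probabilities(f$times, f$events, tau)),
                 eval_step_survival(km, tau), tolerance = 1e-12)
  }
})

test_that("the fast engine equals the naive leave-one-out recomputation", {
  set.seed(77)
  for (k in 1:40) {
    n <- sample(2:50, 1)
    t <- round(rexp(n, 0.5), sample(c(1, 7), 1)) + 1e-3  # ties when rounded
    e <- rbinom(n, 1, sample(c(0.3, 0.7, 1), 1))
    tau <- runif(1, 0.2, 4)  # may exceed the observed range on purpose
    suppressWarnings({
      expect_equal(pseudo_means(t, e, tau, "fast"),
                   pseudo_means(t, e, tau, "naive"), tolerance = 1e-10)
      expect_equal(pseudo_probabilities(t, e, tau, "fast"),
                   pseudo_probabilities(t, e, tau, "naive"),
                   tolerance = 1e-10)
    })
  }
})

test_that("a censored fixture matches the naive jackknife exactly", {
  t <- c(0.5, 1.1, 1.1, 2.0, 2.7, 3.5)
  e <- c(1, 0, 1, 1, 0, 1)
  expect_equal(pseudo_means(t, e, 3, "fast"),
               pseudo_means(t, e, 3, "naive"), tolerance = 1e-12)
  expect_equal(pseudo_probabilities(t, e, 3, "fast"),
               pseudo_probabilities(t, e, 3, "naive"), tolerance = 1e-12)
})

test_that("restricted mean is monotone non-decreasing in tau", {
  f <- rand_surv(40, 123)
  km <- km_estimate(f$times, f$events)
  mus <- vapply(seq(0.2, 5, 0.2), function(tau) rmst_from_km(km, tau),
                numeric(1))
  expect_true(all(diff(mus) >= 0))
})

test_that("censoring_km is km_estimate with the indicator flipped", {
  f <- rand_surv(30, 9)
  a <- censoring_km(f$times, f$events)
  b <- km_estimate(f$times, 1 - f$events)
  expect_equal(a$surv, b$surv)
  # no censoring: G identically 1
  g <- censoring_km(c(1, 2, 3), c(1, 1, 1))
  expect_true(all(g$surv == 1))
  # all censored at distinct times: empirical survival of those times
  g2 <- censoring_km(c(1, 2), c(0, 0))
  expect_equal(g2$surv, c(0.5, 0))
})

test_that("leave-one-out needs at least two subjects", {
  expect_error(pseudo_means(1, 1, 2), "at least 2")
})

test_that("a restriction beyond the observed range warns and is convention-bound", {
  # with tau past the largest observed time the KM tail is extrapolated
  # flat; fast and naive still agree, but the mean identity is not owed
  t <- c(0.5, 1.0, 2.0); e <- c(1, 0, 1)
  expect_warning(pm <- pseudo_means(t, e, 5), "flat-tail")
  expect_equal(pm, suppressWarnings(pseudo_means(t, e, 5, "naive")),
               tolerance = 1e-12)
})

test_that("add_pseudo_values works per landmark and averages correctly", {
  coh <- simulate_cohort(cohort_params(n_subjects = 150, seed = 13))
  g <- landmark_grid(0, 1, 0.5, tau = 2)
  st <- add_pseudo_values(stack_landmarks(coh, g, truncate = FALSE),
                          kind = "mean")
  expect_false(anyNA(st$pseudo))
  for (l in g$times) {
    idx <- st$landmark == l
    km <- km_estimate(st$residual_time[idx], st$residual_event[idx])
    expect_equal(mean(st$pseudo[idx]), rmst_from_km(km, 2),
                 tolerance = 1e-10)
  }
})
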