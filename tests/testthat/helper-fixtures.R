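# Build a minimal cohort from observed times/events, one baseline visit per
# subject at t = 0 (plus optional later visits), constant labs unless given.
toy_cohort <- function(times, events,
                       meld = rep(18, length(times)),
                       albumin = rep(3.2, length(times)),
                       age = rep(55, length(times)),
                       extra_visits = NULL) {
  n <- length(times)
  sv <- data.frame(subject_id = seq_len(n), age = age, sex = 0, etoh = 0,
                   biliary = 0, chol = 0, time = times, event = events)
  lg <- data.frame(subject_id = seq_len(n), time = 0, meld_na = meld,
                   albumin = albumin, decomp = 0, hcc = 0)
  if (!is.null(extra_visits)) lg <- rbind(lg, extra_visits)
  lg <- lg[order(lg$subject_id, lg$time), ]
  as_cohort(sv, lg)
}

# Random right-censored fixture on the residual scale.
rand_surv <- function(n, seed, rate = 0.5, p_event = 0.6) {
  set.seed(seed)
  list(times = rexp(n, rate) + 1e-3, events = rbinom(n, 1, p_event))
}

# Breslow log partial likelihood with delayed entry, written from scratch
# as the independent oracle for the Cox supermodel.
breslow_loglik <- function(beta, entry, exit, event, x) {
  lp <- as.numeric(x %*% beta)
  ll <- 0
  for (t in sort(unique(exit[event == 1]))) {
    d <- which(exit == t & event == 1)
    risk <- which(entry < t & exit >= t)
    ll <- ll + sum(lp[d]) - length(d) * log(sum(exp(lp[risk])))
  }
  ll
}

# Analytic score of the single-covariate Breslow partial likelihood; its
# root is the brute-force maximum-likelihood estimate.
breslow_score <- function(beta, entry, exit, event, x) {
  sc <- 0
  for (t in sort(unique(exit[event == 1]))) {
    d <- which(exit == t & event == 1)
    risk <- which(entry < t & exit >= t)
    w <- exp(beta * x[risk])
    sc <- sc + sum(x[d]) - length(d) * sum(x[risk] * w) / sum(w)
  }
  sc
}
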