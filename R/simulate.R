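# Covariates that may enter the true death hazard, in canonical order.
COVARIATE_NAMES <- c("age", "sex", "etoh", "biliary", "chol",
                     "meld_na", "albumin", "decomp", "hcc")

#' Simulate a longitudinal cirrhosis cohort with known ground truth
#'
#' Draws a cohort under the data-generating process described in
#' [cohort_params()]: per-subject baseline covariates, noisy linear lab
#' trajectories observed at jittered regular visits (first visit at t = 0),
#' a Poisson stream of decompensating events, a one-way HCC onset, and a
#' death time drawn from the proportional-hazards model in the current
#' (LOCF) covariate values with a piecewise-constant hazard between visits.
#' Observed time is the minimum of death, exponential loss to follow-up and
#' the administrative end of study; measurements after the observed time are
#' discarded.
#'
#' Randomness is split per subject from the master seed, so increasing
#' `n_subjects` extends the cohort without reshuffling earlier subjects.
#'
#' @param params a [cohort_params()] object.
#' @return An `lm_cohort` (see [as_cohort()]) with an attribute
#'   `"params"` carrying the generating parameters.
#' @examples
#' coh <- simulate_cohort(cohort_params(n_subjects = 100, seed = 7))
#' coh
#' @export
simulate_cohort <- function(params) {
  if (!inherits(params, "cohort_params"))
    stop("`params` must be created by cohort_params()", call. = FALSE)
  n <- params$n_subjects
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)

  sv <- vector("list", n)
  lg <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(subject_seeds[i])
    s <- simulate_subject(i, params)
    sv[[i]] <- s$survival
    lg[[i]] <- s$longitudinal
  }
  coh <- structure(list(survival = do.call(rbind, sv),
                        longitudinal = do.call(rbind, lg)),
                   class = "lm_cohort")
  rownames(coh$survival) <- rownames(coh$longitudinal) <- NULL
  attr(coh, "params") <- params
  coh
}

# One subject's full history. RNG state is assumed seeded by the caller;
# the draw order below is part of the reproducibility contract.
simulate_subject <- function(id, params) {
  p <- params
  age <- stats::rnorm(1, p$age_mean, p$age_sd)
  sex <- stats::rbinom(1, 1, p$p_female)
  etoh <- stats::rbinom(1, 1, p$p_etoh)
  biliary <- stats::rbinom(1, 1, p$p_biliary)
  chol <- stats::rbinom(1, 1, p$p_chol)

  meld_a <- stats::rnorm(1, p$meld$intercept_mean, p$meld$intercept_sd)
  meld_b <- stats::rnorm(1, p$meld$slope_mean, p$meld$slope_sd)
  alb_a <- stats::rnorm(1, p$albumin$intercept_mean, p$albumin$intercept_sd)
  alb_b <- stats::rnorm(1, p$albumin$slope_mean, p$albumin$slope_sd)

  # Visit schedule: jittered regular gaps, first visit pinned at t = 0,
  # covering follow-up out to the administrative end (capped when infinite;
  # the last covariate value is carried forward beyond the final visit).
  horizon <- min(p$admin_end, 15)
  n_vis <- max(1L, ceiling(horizon / p$visit_interval) + 1L)
  gaps <- p$visit_interval +
    stats::runif(n_vis, -p$visit_jitter, p$visit_jitter)
  gaps <- pmax(gaps, p$visit_interval / 10)
  tv <- c(0, cumsum(gaps))

  meld <- meld_a + meld_b * tv + stats::rnorm(length(tv), 0, p$meld$noise_sd)
  albumin <- alb_a + alb_b * tv +
    stats::rnorm(length(tv), 0, p$albumin$noise_sd)
  albumin <- pmax(albumin, 0.5)
  decomp <- cumsum(c(stats::rpois(1, p$decomp_init),
                     stats::rpois(length(tv) - 1L,
                                  p$decomp_rate * diff(tv))))
  hcc0 <- stats::rbinom(1, 1, p$p_hcc0)
  hcc_onset <- if (p$hcc_rate > 0) stats::rexp(1, p$hcc_rate) else Inf
  hcc <- pmax(hcc0, as.integer(tv >= hcc_onset))

  X <- cbind(age = rep(age, length(tv)), sex = sex, etoh = etoh,
             biliary = biliary, chol = chol, meld_na = meld,
             albumin = albumin, decomp = decomp, hcc = hcc)
  haz <- hazard_at(X, p)

  # Piecewise-constant hazard inversion; last piece extends to infinity.
  u <- stats::rexp(1)
  death <- invert_cumhaz(u, tv, haz)
  cens_rand <- if (p$censoring_hazard > 0)
    stats::rexp(1, p$censoring_hazard) else Inf
  cens <- min(cens_rand, p$admin_end)
  obs <- min(death, cens)
  event <- as.integer(death <= cens)
  if (!is.finite(obs))
    stop("subject ", id, ": infinite observed time; set a finite ",
         "admin_end, censoring_hazard or baseline_hazard", call. = FALSE)

  keep <- tv <= obs
  keep[1] <- TRUE
  list(
    survival = data.frame(subject_id = id, age = age, sex = sex,
                          etoh = etoh, biliary = biliary, chol = chol,
                          time = obs, event = event),
    longitudinal = data.frame(subject_id = id, time = tv[keep],
                              meld_na = meld[keep], albumin = albumin[keep],
                              decomp = decomp[keep], hcc = hcc[keep])
  )
}

# Death hazard rows of a covariate matrix under the generating model.
hazard_at <- function(X, params) {
  b <- params$log_hazard
  lp <- if (length(b))
    as.numeric(X[, names(b), drop = FALSE] %*% b -
                 sum(b * params$reference[names(b)]))
  else rep(0, nrow(X))
  params$baseline_hazard * exp(lp)
}

# Solve H(t) = u for piecewise-constant hazard `haz` on intervals starting
# at `starts` (last interval unbounded). Returns Inf when H never reaches u.
invert_cumhaz <- function(u, starts, haz) {
  k <- length(starts)
  dur <- diff(starts)
  H <- c(0, cumsum(haz[-k] * dur))
  j <- findInterval(u, H)
  if (j < k) {
    starts[j] + (u - H[j]) / haz[j]
  } else if (haz[k] > 0) {
    starts[k] + (u - H[k]) / haz[k]
  } else {
    Inf
  }
}

#' True conditional survival under the generating model
#'
#' Evaluates \eqn{P(T > horizon \mid T > \ell)} for a subject whose covariate
#' path is known, by integrating the generator's piecewise-constant hazard
#' exactly (the hazard is constant between covariate-change times, held
#' forward by LOCF beyond the last one). This is the oracle against which
#' fitted models are checked in parameter-recovery tests.
#'
#' @param params a [cohort_params()] object (supplies the hazard model).
#' @param path data frame with a `time` column and covariate columns; values
#'   are carried forward between rows. Covariates named in
#'   `params$log_hazard` but absent from `path` sit at their reference value.
#' @param l landmark time, years.
#' @param horizon prediction time on the same axis, years; must be >= `l`.
#' @return A probability.
#' @examples
#' p <- cohort_params(log_hazard = c(age = 0), baseline_hazard = 0.3)
#' path <- data.frame(time = 0, age = 57)
#' true_conditional_survival(p, path, 1, 4)  # exp(-0.3 * 3)
#' @export
true_conditional_survival <- function(params, path, l, horizon) {
  if (horizon < l) stop("`horizon` must be >= `l`", call. = FALSE)
  if (horizon == l) return(1)
  pieces <- hazard_pieces(params, path, l, horizon)
  exp(-sum(pieces$hazard * pieces$duration))
}

#' True conditional restricted mean survival time under the generating model
#'
#' Integrates [true_conditional_survival()] over the prediction window:
#' \eqn{\int_0^\tau P(T > \ell + u \mid T > \ell)\,du}, in years. The
#' integral is exact because survival is piecewise exponential.
#'
#' @inheritParams true_conditional_survival
#' @param tau prediction horizon, years since the landmark; `tau = 0` gives 0.
#' @return Conditional RMST in years, in `[0, tau]`.
#' @export
true_conditional_rmst <- function(params, path, l, tau) {
  if (tau < 0) stop("`tau` must be >= 0", call. = FALSE)
  if (tau == 0) return(0)
  pieces <- hazard_pieces(params, path, l, l + tau)
  s0 <- 1
  total <- 0
  for (j in seq_along(pieces$hazard)) {
    h <- pieces$hazard[j]; d <- pieces$duration[j]
    total <- total + if (h > 0) s0 * (1 - exp(-h * d)) / h else s0 * d
    s0 <- s0 * exp(-h * d)
  }
  total
}

# Constant-hazard pieces of the true model on [l, horizon] for a covariate
# path (LOCF). Returns parallel vectors hazard, duration.
hazard_pieces <- function(params, path, l, horizon) {
  path <- as.data.frame(path)
  if (!"time" %in% names(path)) stop("`path` needs a `time` column", call. = FALSE)
  path <- path[order(path$time), , drop = FALSE]
  covs <- names(params$log_hazard)
  X <- matrix(rep(params$reference[COVARIATE_NAMES], each = nrow(path)),
              nrow = nrow(path), dimnames = list(NULL, COVARIATE_NAMES))
  for (nm in intersect(names(path), COVARIATE_NAMES)) X[, nm] <- path[[nm]]
  haz <- hazard_at(X, params)
  brk <- sort(unique(c(l, horizon, path$time[path$time > l & path$time < horizon])))
  starts <- brk[-length(brk)]
  idx <- findInterval(starts, path$time)
  idx[idx == 0L] <- 1L  # before the first measurement: use it (first visit is baseline)
  list(hazard = haz[idx], duration = diff(brk))
}
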