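#' Parameters for the synthetic cirrhosis cohort generator
#'
#' Bundles and validates every knob of the data-generating process used by
#' [simulate_cohort()]. The generator emulates a longitudinal EHR cohort of
#' patients with liver cirrhosis: fixed baseline covariates (age, sex, three
#' etiology indicators), two continuous time-varying labs (MELD-Na and serum
#' albumin) following per-subject linear trajectories with measurement noise,
#' a cumulative count of decompensating events, and a one-way indicator of
#' hepatocellular carcinoma (HCC) onset. Death follows a proportional-hazards
#' model in the *current* (last-observed) covariate values, with a
#' piecewise-constant hazard between visits, so the generator itself supplies
#' the ground truth for parameter-recovery checks (see
#' [true_conditional_survival()]).
#'
#' The hazard for subject \eqn{i} at time \eqn{t} is
#' \deqn{\lambda_i(t) = \lambda_0 \exp\{\beta^T (X_i(t) - x_{ref})\}}
#' where \eqn{X_i(t)} holds the last observed covariate values and
#' \eqn{x_{ref}} is a fixed reference profile, so `baseline_hazard` is the
#' death hazard (per year) of a reference patient. Censoring is the minimum of
#' an independent exponential draw (`censoring_hazard`) and the administrative
#' end of study.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param age_mean,age_sd baseline age distribution, years.
#' @param p_female,p_etoh,p_biliary,p_chol Bernoulli probabilities of female
#'   sex and of the alcohol-related, biliary and cholestatic etiology
#'   indicators.
#' @param meld,albumin lists describing the linear-trajectory model of each
#'   lab: `intercept_mean`, `intercept_sd`, `slope_mean`, `slope_sd`
#'   (per year), `noise_sd` (measurement noise at each visit).
#' @param visit_interval,visit_jitter mean spacing of visits in years and the
#'   s.d. of uniform jitter around each scheduled visit; the first visit is
#'   always at t = 0 so every subject has baseline values.
#' @param decomp_rate intensity of decompensating events, events/year.
#' @param decomp_init mean number of decompensating events already on
#'   record at entry (Poisson); cirrhosis cohorts are typically assembled
#'   after diagnosis, not at first decompensation.
#' @param hcc_rate hazard of HCC onset, per year.
#' @param p_hcc0 probability of prevalent HCC at entry.
#' @param log_hazard named numeric vector of true log hazard ratios for death,
#'   one per covariate entering the hazard. Names must be a subset of
#'   `c("age","sex","etoh","biliary","chol","meld_na","albumin","decomp","hcc")`.
#' @param reference named numeric vector, the reference covariate profile
#'   \eqn{x_{ref}}; defaults to a typical patient. Covariates named in
#'   `log_hazard` but absent here default to 0.
#' @param baseline_hazard death hazard of the reference patient, per year.
#' @param censoring_hazard exponential loss-to-follow-up hazard, per year
#'   (0 disables random censoring).
#' @param admin_end administrative end of study, years (`Inf` disables).
#' @param seed master seed; per-subject streams are split from it so that
#'   enlarging `n_subjects` leaves earlier subjects unchanged.
#'
#' @return An object of class `cohort_params` (a validated list).
#' @examples
#' p <- cohort_params(n_subjects = 50, seed = 1)
#' coh <- simulate_cohort(p)
#' @seealso [simulate_cohort()], [true_conditional_survival()]
#' @export
cohort_params <- function(n_subjects = 1000,
                          age_mean = 57, age_sd = 10,
                          p_female = 0.42, p_etoh = 0.35,
                          p_biliary = 0.05, p_chol = 0.07,
                          meld = list(intercept_mean = 18, intercept_sd = 6,
                                      slope_mean = 0.8, slope_sd = 1.5,
                                      noise_sd = 2),
                          albumin = list(intercept_mean = 3.2, intercept_sd = 0.5,
                                         slope_mean = -0.05, slope_sd = 0.15,
                                         noise_sd = 0.25),
                          visit_interval = 0.25, visit_jitter = 0.04,
                          decomp_rate = 0.4, decomp_init = 0.5,
                          hcc_rate = 0.04, p_hcc0 = 0.05,
                          log_hazard = c(age = 0.03, etoh = 0.15,
                                         biliary = 0.10, chol = 0.20,
                                         meld_na = 0.08, albumin = -0.60,
                                         decomp = 0.20, hcc = 0.50),
                          reference = c(age = 57, sex = 0, etoh = 0,
                                        biliary = 0, chol = 0, meld_na = 18,
                                        albumin = 3.2, decomp = 0, hcc = 0),
                          baseline_hazard = 0.065,
                          censoring_hazard = 0.50,
                          admin_end = 11,
                          seed = 1L) {
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop(sprintf("`%s` must be a probability in [0, 1]", nm), call. = FALSE)
  }
  chk_rate <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
      stop(sprintf("`%s` must be a non-negative rate", nm), call. = FALSE)
  }
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L ||
      is.na(n_subjects) || n_subjects < 1 || n_subjects != floor(n_subjects))
    stop("`n_subjects` must be a positive integer", call. = FALSE)
  for (nm in c("p_female", "p_etoh", "p_biliary", "p_chol", "p_hcc0"))
    chk_prob(get(nm), nm)
  for (nm in c("decomp_rate", "decomp_init", "hcc_rate", "baseline_hazard",
               "censoring_hazard"))
    chk_rate(get(nm), nm)
  if (!is.numeric(age_sd) || age_sd < 0) stop("`age_sd` must be >= 0", call. = FALSE)
  if (!is.numeric(visit_interval) || visit_interval <= 0)
    stop("`visit_interval` must be > 0", call. = FALSE)
  if (!is.numeric(visit_jitter) || visit_jitter < 0)
    stop("`visit_jitter` must be >= 0", call. = FALSE)
  if (!is.numeric(admin_end) || length(admin_end) != 1L || admin_end <= 0)
    stop("`admin_end` must be > 0 (possibly Inf)", call. = FALSE)
  if (is.infinite(admin_end) && censoring_hazard == 0 &&
      is.null(names(log_hazard)))
    stop("`log_hazard` must be a named vector", call. = FALSE)
  allowed <- c("age", "sex", "etoh", "biliary", "chol",
               "meld_na", "albumin", "decomp", "hcc")
  if (length(log_hazard) && (is.null(names(log_hazard)) ||
                             !all(names(log_hazard) %in% allowed)))
    stop("`log_hazard` names must be among: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  ref <- setNames(rep(0, length(allowed)), allowed)
  ref[names(reference)] <- reference
  for (traj in list(meld = meld, albumin = albumin)) {
    need <- c("intercept_mean", "intercept_sd", "slope_mean", "slope_sd",
              "noise_sd")
    if (!all(need %in% names(traj)))
      stop("trajectory models need fields: ", paste(need, collapse = ", "),
           call. = FALSE)
    if (any(unlist(traj[c("intercept_sd", "slope_sd", "noise_sd")]) < 0))
      stop("trajectory sds must be >= 0", call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    age_mean = age_mean, age_sd = age_sd,
    p_female = p_female, p_etoh = p_etoh,
    p_biliary = p_biliary, p_chol = p_chol,
    meld = meld, albumin = albumin,
    visit_interval = visit_interval, visit_jitter = visit_jitter,
    decomp_rate = decomp_rate, decomp_init = decomp_init,
    hcc_rate = hcc_rate, p_hcc0 = p_hcc0,
    log_hazard = log_hazard, reference = ref,
    baseline_hazard = baseline_hazard,
    censoring_hazard = censoring_hazard,
    admin_end = admin_end, seed = as.integer(seed)
  ), class = "cohort_params")
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("Synthetic cohort parameters\n")
  cat("  n_subjects:      ", x$n_subjects, "\n")
  cat("  baseline hazard: ", x$baseline_hazard, "/yr at reference profile\n")
  cat("  censoring:       ", x$censoring_hazard, "/yr, admin end ",
      x$admin_end, " yr\n", sep = "")
  cat("  log hazard ratios:\n")
  print(x$log_hazard)
  invisible(x)
}
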