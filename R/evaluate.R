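#' Subject-level train/test split
#'
#' Partitions the cohort's subjects reproducibly: `round(n * fraction)`
#' subjects are sampled (without replacement) into the training set, the
#' rest form the test set; no subject appears in both.
#'
#' @param cohort an `lm_cohort`.
#' @param fraction training fraction in (0, 1); default 0.75 (the usual
#'   75/25 split).
#' @param seed integer seed for the draw.
#' @return List with `train` and `test`, both `lm_cohort`s.
#' @export
split_train_test <- function(cohort, fraction = 0.75, seed = 1L) {
  n <- n_subjects(cohort)
  if (n < 2L) stop("need at least 2 subjects to split", call. = FALSE)
  if (fraction <= 0 || fraction >= 1)
    stop("`fraction` must be in (0, 1)", call. = FALSE)
  ids <- cohort$survival$subject_id
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  train_ids <- sort(sample(ids, round(n * fraction)))
  list(train = subset_cohort(cohort, train_ids),
       test = subset_cohort(cohort, setdiff(ids, train_ids)))
}

#' Concordance-based AUC for survival risk scores
#'
#' Harrell-type concordance over all usable pairs:
#' \deqn{AUC = \frac{\sum_{i,j} 1\{T_j < T_i\} 1\{\eta_j > \eta_i\}
#' \delta_j}{\sum_{i,j} 1\{T_j < T_i\} \delta_j}}
#' where \eqn{\eta} is a *risk* score (higher = worse). Callers holding
#' survival-type predictions (RMST, survival probability) should pass their
#' negative. Under the default `ties = "strict"` tied times or tied scores
#' contribute 0 to the numerator, the literal reading of the formula; with
#' `ties = "half"` tied scores earn half credit, the usual concordance
#' convention.
#'
#' @param risk risk scores (higher = higher risk).
#' @param times observation times.
#' @param events 0/1 event indicators.
#' @param ties `"strict"` (default) or `"half"`.
#' @return AUC in `[0, 1]`, or `NA` with a warning when no usable pairs
#'   exist.
#' @examples
#' auc_concordance(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1))  # 1
#' @export
auc_concordance <- function(risk, times, events,
                            ties = c("strict", "half")) {
  ties <- match.arg(ties)
  stopifnot(length(risk) == length(times), length(times) == length(events))
  usable <- outer(times, times, "<") & matrix(events == 1, length(times),
                                              length(times))
  # usable[j, i]: T_j < T_i and delta_j = 1
  denom <- sum(usable)
  if (denom == 0) {
    warning("no usable pairs; AUC undefined", call. = FALSE)
    return(NA_real_)
  }
  conc <- outer(risk, risk, ">")   # conc[j, i]: eta_j > eta_i
  num <- sum(usable & conc)
  if (ties == "half")
    num <- num + 0.5 * sum(usable & outer(risk, risk, "=="))
  num / denom
}

#' IPCW Brier score for survival-probability predictions
#'
#' Inverse-probability-of-censoring weighted mean squared error at horizon
#' `t`:
#' \deqn{BS(t) = \frac{1}{N}\sum_i \frac{(0-\hat p_i)^2 1\{T_i \le t,
#' \delta_i = 1\}}{\hat G(T_i^-)} + \frac{(1-\hat p_i)^2 1\{T_i > t\}}
#' {\hat G(t)}}
#' with \eqn{\hat G} the KM estimator of the censoring distribution on the
#' same risk set. Subjects censored before `t` carry weight zero. Without
#' censoring this reduces exactly to the plain Brier score
#' \eqn{N^{-1}\sum_i(\hat p_i - 1\{T_i > t\})^2}.
#'
#' @param predictions predicted survival probabilities \eqn{\hat p_i} in
#'   `[0, 1]`.
#' @param times residual observation times (since the landmark).
#' @param events 0/1 event indicators.
#' @param t evaluation horizon on the residual scale (usually \eqn{\tau}).
#' @param cens optional `step_survival` for the censoring distribution;
#'   computed from `times`/`events` via [censoring_km()] when omitted.
#' @return The weighted score (>= 0).
#' @export
brier_ipcw_prob <- function(predictions, times, events, t, cens = NULL) {
  ipcw_score(predictions, times, events, t, cens,
             obs_sq = function(p, Ti) (0 - p)^2,
             surv_sq = function(p, t) (1 - p)^2)
}

#' IPCW prediction error for RMST-type predictions
#'
#' The RMST analogue of [brier_ipcw_prob()]: squared error of the predicted
#' conditional RMST \eqn{\hat\mu_i} against the observed restricted time,
#' \deqn{BS(t) = \frac{1}{N}\sum_i \frac{(T_i-\hat\mu_i)^2 1\{T_i \le t,
#' \delta_i = 1\}}{\hat G(T_i^-)} + \frac{(t-\hat\mu_i)^2 1\{T_i > t\}}
#' {\hat G(t)}.}
#' Units are years squared; unlike the probability version it has no upper
#' bound of 1.
#'
#' @param predictions predicted conditional RMST \eqn{\hat\mu_i}, years.
#' @inheritParams brier_ipcw_prob
#' @return The weighted score (>= 0), years^2.
#' @export
brier_ipcw_rmst <- function(predictions, times, events, t, cens = NULL) {
  ipcw_score(predictions, times, events, t, cens,
             obs_sq = function(mu, Ti) (Ti - mu)^2,
             surv_sq = function(mu, t) (t - mu)^2)
}

ipcw_score <- function(predictions, times, events, t, cens,
                       obs_sq, surv_sq) {
  stopifnot(length(predictions) == length(times),
            length(times) == length(events))
  if (is.null(cens)) cens <- censoring_km(times, events)
  N <- length(times)
  died <- times <= t & events == 1
  alive <- times > t
  G_T <- eval_step_survival(cens, times, left = TRUE)
  G_t <- eval_step_survival(cens, t)
  if (any(died & G_T <= 0) || (any(alive) && G_t <= 0))
    stop("censoring survival estimate is 0 at a needed point; ",
         "use a smaller evaluation time t", call. = FALSE)
  contrib <- numeric(N)
  contrib[died] <- obs_sq(predictions[died], times[died]) / G_T[died]
  contrib[alive] <- surv_sq(predictions[alive], t) / G_t
  sum(contrib) / N
}

#' Evaluate fitted models over the landmark grid on a held-out cohort
#'
#' For every landmark \eqn{\ell} of the grid: rebuilds the test risk set,
#' asks each model for its conditional prediction at horizon \eqn{\tau},
#' and computes discrimination (concordance AUC, with survival-type
#' predictions negated into risk scores) and the family-appropriate
#' calibration score (IPCW Brier for probability predictions, IPCW
#' prediction error for RMST predictions) on the untruncated residual
#' outcomes of that risk set. Metrics are never pooled across landmarks.
#'
#' @param models named list of fitted models (`landmark_supermodel` and/or
#'   `static_landmark_model`); names label the output rows.
#' @param cohort test `lm_cohort`, disjoint from the training data.
#' @param grid a [landmark_grid()].
#' @param ties tie handling for [auc_concordance()].
#' @return Data frame (one row per model x landmark) with columns `model`,
#'   `family`, `landmark`, `auc`, `brier`, `n_risk`, `n_events`.
#' @export
evaluate_models <- function(models, cohort, grid,
                            ties = c("strict", "half")) {
  ties <- match.arg(ties)
  stopifnot(inherits(grid, "landmark_grid"))
  if (is.null(names(models)) || any(names(models) == ""))
    stop("`models` must be a fully named list", call. = FALSE)
  rows <- list()
  for (l in grid$times) {
    ref <- build_landmark_dataset(cohort, l, grid$tau, truncate = FALSE)
    cens <- if (nrow(ref) >= 2) censoring_km(ref$residual_time,
                                             ref$residual_event) else NULL
    in_window <- sum(ref$residual_time <= grid$tau & ref$residual_event == 1)
    for (nm in names(models)) {
      m <- models[[nm]]
      fam <- m$family
      if (nrow(ref) < 2 || in_window == 0) {
        warning("landmark ", l, ": too few usable test subjects; metrics NA",
                call. = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          model = nm, family = fam, landmark = l, auc = NA_real_,
          brier = NA_real_, n_risk = nrow(ref), n_events = in_window)
        next
      }
      pr <- predict_at_landmark(m, cohort, l)
      stopifnot(identical(pr$subject_id, ref$subject_id))
      brier <- if (fam == "pm")
        brier_ipcw_rmst(pr$prediction, ref$residual_time,
                        ref$residual_event, grid$tau, cens)
      else
        brier_ipcw_prob(pr$prediction, ref$residual_time,
                        ref$residual_event, grid$tau, cens)
      rows[[length(rows) + 1L]] <- data.frame(
        model = nm, family = fam, landmark = l,
        auc = auc_concordance(-pr$prediction, ref$residual_time,
                              ref$residual_event, ties = ties),
        brier = brier, n_risk = nrow(ref), n_events = in_window)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
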