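#' Kaplan-Meier estimate as a step function
#'
#' Thin wrapper around [survival::survfit()] returning the product-limit
#' estimator in a plain step-function form used throughout the package.
#' Tied times are grouped; deaths precede censorings at the same time, so a
#' subject censored at an event time is counted at risk for that event.
#'
#' @param times positive observation times (years).
#' @param events 0/1 event indicators, same length.
#' @return An object of class `step_survival`: list with `time` (distinct
#'   observed times), `n_risk`, `n_event`, `n_censor`, `surv`
#'   (right-continuous, `surv[k] = S(time[k])`).
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))$surv  # 2/3, 1/3, 0
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty input", call. = FALSE)
  if (length(times) != length(events))
    stop("`times` and `events` must have the same length", call. = FALSE)
  if (any(times <= 0)) stop("times must be > 0", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 surv = fit$surv),
            class = "step_survival")
}

#' @export
print.step_survival <- function(x, ...) {
  cat("Step survival function with", length(x$time), "distinct times\n")
  print(data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
                   surv = x$surv))
  invisible(x)
}

#' Kaplan-Meier estimate of the censoring distribution
#'
#' The same product-limit machinery applied with censoring as the event
#' (indicator `1 - events`), giving the \eqn{\hat G} used by the IPCW
#' calibration metrics.
#'
#' @inheritParams km_estimate
#' @return A `step_survival` for the censoring times.
#' @export
censoring_km <- function(times, events) km_estimate(times, 1 - events)

#' Evaluate a step survival function
#'
#' @param s a `step_survival`.
#' @param t evaluation times; `left = TRUE` returns the left limit
#'   \eqn{S(t^-)}.
#' @param left take the left limit (default `FALSE`).
#' @return Numeric vector of survival values (1 before the first jump; the
#'   last value is carried forward beyond the final time).
#' @export
eval_step_survival <- function(s, t, left = FALSE) {
  idx <- if (left) findInterval(t, s$time, left.open = TRUE)
  else findInterval(t, s$time)
  c(1, s$surv)[idx + 1L]
}

#' Restricted mean survival time from a step survival function
#'
#' Area under the survival curve on \eqn{[0, \tau]}, including the leading
#' segment of height 1 before the first observed time. If the curve has not
#' reached zero by the last observed time it is carried forward flat to
#' \eqn{\tau} (the standard KM tail convention).
#'
#' @param s a `step_survival`.
#' @param tau restriction time, years (> 0).
#' @return RMST in years, in `[0, tau]`.
#' @examples
#' s <- km_estimate(c(1, 3), c(1, 1))
#' rmst_from_km(s, 2)  # 1*1 + 0.5*1 = 1.5
#' @export
rmst_from_km <- function(s, tau) {
  if (tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  brk <- c(0, pmin(s$time, tau), tau)
  ht <- c(1, s$surv)
  sum(diff(brk) * ht)
}

#' Jackknife pseudo-means (restricted mean survival time)
#'
#' Replaces each censored-or-observed residual outcome with a pseudo-value
#' \eqn{Z_i = n\hat\mu(\tau) - (n-1)\hat\mu^{-i}(\tau)}, where
#' \eqn{\hat\mu(\tau)} is the RMST of the Kaplan-Meier curve of all `n`
#' subjects and \eqn{\hat\mu^{-i}(\tau)} leaves subject \eqn{i} out. The
#' pseudo-mean is subject \eqn{i}'s contribution to the restricted mean and
#' can be used as a regression outcome with standard (GEE) machinery.
#'
#' Two algorithms are provided: `"fast"` (default) updates the leave-one-out
#' KM curve in closed form from the full-sample risk/event counts, costing
#' O(n log n) overall; `"naive"` recomputes the KM curve `n` times and is the
#' correct-by-construction reference the fast path is validated against.
#' Without censoring the pseudo-means reduce exactly to
#' \eqn{\min(T_i, \tau)}.
#'
#' @param times residual observation times (> 0), measured since the
#'   landmark.
#' @param events 0/1 event indicators.
#' @param tau restriction time, years.
#' @param method `"fast"` or `"naive"`.
#' @return Numeric vector of pseudo-values in input order. Whenever
#'   \eqn{\tau} does not exceed the largest observed time, the mean of the
#'   pseudo-values equals \eqn{\hat\mu(\tau)} exactly; beyond it the
#'   restricted mean is not identifiable, the flat-tail convention takes
#'   over and a warning is issued.
#' @examples
#' pseudo_means(c(1, 2, 4), c(1, 1, 1), tau = 3)  # 1, 2, 3
#' @export
pseudo_means <- function(times, events, tau, method = c("fast", "naive")) {
  method <- match.arg(method)
  check_pseudo_input(times, events, tau)
  if (method == "naive") {
    pseudo_jackknife_naive(times, events,
                           function(s) rmst_from_km(s, tau))
  } else {
    pseudo_fast(times, events, tau, kind = "mean")
  }
}

#' Jackknife pseudo-probabilities of surviving the horizon
#'
#' As [pseudo_means()] with the KM survival probability at \eqn{\tau},
#' \eqn{\hat S(\tau)}, in place of the restricted mean. Without censoring the
#' pseudo-probabilities reduce exactly to the indicator
#' \eqn{1\{T_i > \tau\}}.
#'
#' @inheritParams pseudo_means
#' @return Numeric vector of pseudo-values in input order; its mean equals
#'   \eqn{\hat S(\tau)} exactly whenever \eqn{\tau} does not exceed the
#'   largest observed time (see [pseudo_means()] for the boundary case).
#' @export
pseudo_probabilities <- function(times, events, tau,
                                 method = c("fast", "naive")) {
  method <- match.arg(method)
  check_pseudo_input(times, events, tau)
  if (method == "naive") {
    pseudo_jackknife_naive(times, events,
                           function(s) eval_step_survival(s, tau))
  } else {
    pseudo_fast(times, events, tau, kind = "prob")
  }
}

check_pseudo_input <- function(times, events, tau = NULL) {
  if (length(times) < 2L)
    stop("leave-one-out pseudo-values need at least 2 subjects",
         call. = FALSE)
  if (length(times) != length(events))
    stop("`times` and `events` must have the same length", call. = FALSE)
  if (any(times <= 0)) stop("times must be > 0", call. = FALSE)
  if (!all(events %in% c(0, 1)))
    stop("events must be 0/1", call. = FALSE)
  if (!is.null(tau) && tau > max(times))
    warning("restriction time tau = ", format(tau), " exceeds the largest ",
            "observed time (", format(max(times)), "); pseudo-values rely ",
            "on the flat-tail extrapolation of the KM curve there and ",
            "their mean need not equal the full-sample estimate",
            call. = FALSE)
}

# O(n^2) reference jackknife: recompute the statistic without each subject.
pseudo_jackknife_naive <- function(times, events, statistic) {
  n <- length(times)
  full <- statistic(km_estimate(times, events))
  loo <- vapply(seq_len(n), function(i) {
    statistic(km_estimate(times[-i], events[-i]))
  }, numeric(1))
  n * full - (n - 1) * loo
}

# Fast leave-one-out KM. Removing subject i changes only the factors at
# distinct times t_j <= T_i: the at-risk count drops by one, and when i is
# an event at T_i the event count there drops too. Writing
#   r_j = (1 - d_j/(n_j - 1)) / (1 - d_j/n_j)
# the leave-one-out curve is S^{-i}(t) = S(t) * R(min(t, T_i)) * f_i(t),
# with R the cumulative product of r_j and f_i the single corrected factor
# n_J/(n_J - 1) at t_J = T_i for events. Integrals of S and S*R are
# precomputed at the step boundaries, so each subject costs O(1).
pseudo_fast <- function(times, events, tau, kind = c("mean", "prob")) {
  kind <- match.arg(kind)
  n <- length(times)
  km <- km_estimate(times, events)
  tj <- km$time; nj <- km$n_risk; dj <- km$n_event; Sj <- km$surv

  # per-time removal ratio; times where everyone at risk dies are never
  # consumed through the cumulative product (no one remains at risk), so
  # their ratio is neutralized to keep the cumprod finite
  r <- ifelse(dj == 0, 1,
              ifelse(nj - dj > 0 & nj > 1,
                     (1 - dj / (nj - 1)) / (1 - dj / nj), 1))
  Rcum <- cumprod(r)

  J <- match(times, tj)          # index of each subject's own time
  is_event <- events == 1
  Rbefore <- c(1, Rcum)[J]       # R(T_i^-)
  Rat <- Rcum[J]                 # R(T_i)
  f <- ifelse(nj[J] > 1, nj[J] / (nj[J] - 1), 0)
  f[is_event & dj[J] == nj[J]] <- 0   # curve is identically 0 past T_i
  cmult <- ifelse(is_event, Rbefore * f, Rat)
  # sole subject at risk at its own (final) event time: removing it deletes
  # that KM factor entirely, so the leave-one-out curve stays flat at
  # S(T_i^-) R(T_i^-) where the full curve has dropped to 0 -- the S-based
  # tail decomposition does not apply there
  sole <- is_event & nj[J] == 1L
  v_sole <- c(1, Sj)[J] * Rbefore

  if (kind == "prob") {
    p_full <- eval_step_survival(km, tau)
    k_tau <- findInterval(tau, tj)
    R_tau <- c(1, Rcum)[k_tau + 1L]
    loo <- ifelse(times > tau, p_full * R_tau, p_full * cmult)
    loo[sole & times <= tau] <- v_sole[sole & times <= tau]
    return(n * p_full - (n - 1) * loo)
  }

  mu_full <- rmst_from_km(km, tau)
  # cumulative integrals of S and S*R at the step boundaries 0, t_1, ...
  brk <- c(0, tj)
  ht_S <- c(1, Sj)                # S on [brk_k, brk_{k+1})
  ht_SR <- c(1, Sj * Rcum)        # S*R on the same segments
  seg <- diff(c(brk, max(brk[length(brk)], tau)))
  A <- c(0, cumsum(ht_S * seg))   # A[k] = int_0^{brk_k} S
  B <- c(0, cumsum(ht_SR * seg))  # same for S*R
  int_to <- function(x, cumint, ht) {
    k <- findInterval(x, brk)
    cumint[k] + (x - brk[k]) * ht[k]
  }
  x <- pmin(times, tau)
  B_x <- int_to(x, B, ht_SR)
  A_x <- int_to(x, A, ht_S)
  A_tau <- int_to(tau, A, ht_S)
  loo <- B_x + cmult * (A_tau - A_x)
  loo[sole] <- B_x[sole] + v_sole[sole] * pmax(0, tau - x[sole])
  n * mu_full - (n - 1) * loo
}

#' Attach pseudo-value outcomes to a stacked landmark dataset
#'
#' Computes jackknife pseudo-values within each landmark dataset on the
#' residual (time since landmark) scale — the conditional KM curve with
#' survival to the landmark as the condition — and appends them as a
#' `pseudo` column. Residual times must be untruncated for the KM step to
#' see real censoring, so the stack should be built with `truncate = FALSE`
#' or directly from [stack_landmarks()]'s untruncated `exit` columns; the
#' restriction to the window happens inside the RMST/probability at `tau`.
#'
#' @param stacked a `stacked_landmarks` data frame built with
#'   `truncate = FALSE` (residual times beyond `tau` intact).
#' @param tau restriction time, years since the landmark; defaults to the
#'   grid's `tau`.
#' @param kind `"mean"` for pseudo-RMST (years) or `"prob"` for
#'   pseudo-survival probabilities.
#' @param method passed to the pseudo-value engine.
#' @return `stacked` with a `pseudo` column and attribute `pseudo_kind`.
#' @export
add_pseudo_values <- function(stacked, tau = NULL,
                              kind = c("mean", "prob"),
                              method = c("fast", "naive")) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  grid <- attr(stacked, "grid")
  if (is.null(tau)) {
    if (is.null(grid)) stop("supply `tau` or a stack carrying its grid",
                            call. = FALSE)
    tau <- grid$tau
  }
  fun <- if (kind == "mean") pseudo_means else pseudo_probabilities
  stacked$pseudo <- NA_real_
  for (l in unique(stacked$landmark)) {
    idx <- stacked$landmark == l
    stacked$pseudo[idx] <- fun(stacked$residual_time[idx],
                               stacked$residual_event[idx],
                               tau = tau, method = method)
  }
  attr(stacked, "pseudo_kind") <- kind
  attr(stacked, "pseudo_tau") <- tau
  stacked
}
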