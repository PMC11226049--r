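#' Define a grid of landmark times
#'
#' The landmarking approach re-evaluates risk at a set of landmark times
#' \eqn{\ell_j}: at each one, prediction is restricted to subjects still
#' event-free, using covariate values known by \eqn{\ell_j}, over a fixed
#' horizon \eqn{\tau}. The canonical analysis uses 11 landmarks spaced 0.5
#' years apart over \eqn{[0, 5]} with \eqn{\tau = 3} years.
#'
#' @param start,end first and last landmark, years (`end >= start`).
#' @param step spacing, years (> 0); the endpoint is included when it lies on
#'   the grid to within 1e-9.
#' @param tau prediction horizon in years since each landmark (> 0).
#' @param scale time scale \eqn{s} of the interaction basis
#'   \eqn{(1, \ell/s, (\ell/s)^2)}; default 5 years.
#' @return An object of class `landmark_grid` with fields `times`, `tau`,
#'   `scale`.
#' @examples
#' landmark_grid(0, 5, 0.5, tau = 3)  # the 11-landmark grid
#' @export
landmark_grid <- function(start, end, step, tau, scale = 5) {
  if (!is.numeric(step) || step <= 0) stop("`step` must be > 0", call. = FALSE)
  if (end < start) stop("`end` must be >= `start`", call. = FALSE)
  if (!is.numeric(tau) || tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  if (!is.numeric(scale) || scale <= 0) stop("`scale` must be > 0", call. = FALSE)
  k <- floor((end - start) / step + 1e-9)
  times <- start + step * (0:k)
  structure(list(times = times, tau = tau, scale = scale),
            class = "landmark_grid")
}

#' @export
print.landmark_grid <- function(x, ...) {
  cat("Landmark grid: ", length(x$times), " landmarks in [",
      x$times[1], ", ", x$times[length(x$times)], "] yr, tau = ", x$tau,
      " yr, basis scale = ", x$scale, "\n", sep = "")
  invisible(x)
}

#' Covariate values at a landmark by last observation carried forward
#'
#' For every subject with at least one measurement at or before `l`
#' (measurements at exactly `l` count), returns the baseline covariates
#' joined with the most recent time-varying values.
#'
#' @param cohort an `lm_cohort`.
#' @param l landmark time, years.
#' @return Data frame with one row per subject having usable covariates.
#' @keywords internal
covariates_at <- function(cohort, l) {
  lg <- cohort$longitudinal
  lg <- lg[lg$time <= l + 1e-12, , drop = FALSE]
  if (nrow(lg)) {
    lg <- lg[order(lg$subject_id, lg$time), , drop = FALSE]
    last <- !duplicated(lg$subject_id, fromLast = TRUE)
    lg <- lg[last, c("subject_id", "meld_na", "albumin", "decomp", "hcc")]
  } else {
    lg <- lg[, c("subject_id", "meld_na", "albumin", "decomp", "hcc")]
  }
  merge(cohort$survival[, c("subject_id", "age", "sex", "etoh", "biliary",
                            "chol", "time", "event")],
        lg, by = "subject_id")
}

#' Build the landmark dataset at a single landmark time
#'
#' Restricts the cohort to subjects still at risk at `l` (observed time
#' strictly greater than `l`), evaluates covariates at `l` by LOCF, and
#' forms the residual outcome on the time-since-landmark scale. With
#' `truncate = TRUE` the residual time is administratively censored at the
#' horizon: `residual_time = min(T - l, tau)` and events beyond the window
#' are recoded as censored. Entry/exit columns on the study time axis are
#' carried for the Cox supermodel (entry `l`, exit `min(T, l + tau)`).
#'
#' Subjects at risk at `l` but with no measurement at or before `l` are
#' excluded; the count is recorded in the `"n_excluded"` attribute and
#' reported via `message()`.
#'
#' @param cohort an `lm_cohort`.
#' @param l landmark time, years (>= 0).
#' @param tau prediction horizon, years since `l`.
#' @param truncate apply the administrative truncation at `tau`
#'   (default `TRUE`).
#' @return A data frame of class `landmark_data` with attributes `landmark`,
#'   `tau`, `n_excluded`. Columns: `subject_id`, `landmark`, the nine
#'   covariates, `residual_time`, `residual_event`, `entry`, `exit`,
#'   `exit_event`.
#' @examples
#' coh <- simulate_cohort(cohort_params(n_subjects = 200, seed = 1))
#' ld <- build_landmark_dataset(coh, l = 1, tau = 3)
#' head(ld)
#' @export
build_landmark_dataset <- function(cohort, l, tau, truncate = TRUE) {
  if (l < 0) stop("`l` must be >= 0", call. = FALSE)
  if (tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  at_risk <- cohort$survival$subject_id[cohort$survival$time > l]
  cv <- covariates_at(cohort, l)
  n_excl <- sum(!(at_risk %in% cv$subject_id))
  if (n_excl > 0)
    message("landmark ", l, ": excluded ", n_excl,
            " at-risk subject(s) with no measurement at or before the landmark")
  cv <- cv[cv$subject_id %in% at_risk, , drop = FALSE]
  cv <- cv[order(cv$subject_id), , drop = FALSE]

  res_t <- cv$time - l
  res_e <- cv$event
  if (truncate) {
    over <- res_t > tau
    res_e[over] <- 0L
    res_t[over] <- tau
  }
  out <- data.frame(subject_id = cv$subject_id,
                    landmark = rep(l, nrow(cv)),
                    cv[COVARIATE_NAMES],
                    residual_time = res_t, residual_event = res_e,
                    entry = rep(l, nrow(cv)),
                    exit = pmin(cv$time, l + tau),
                    exit_event = as.integer(cv$event == 1 &
                                              cv$time <= l + tau))
  rownames(out) <- NULL
  structure(out, landmark = l, tau = tau, n_excluded = n_excl,
            class = c("landmark_data", "data.frame"))
}

#' Stack the landmark datasets over a grid into a super-dataset
#'
#' Concatenates [build_landmark_dataset()] over every landmark of the grid.
#' Each row carries its landmark in the `landmark` column; the clustering key
#' for robust variance estimation is `subject_id`, since a subject appears in
#' every landmark dataset for which it is still at risk. Rows are ordered by
#' landmark, then subject id.
#'
#' @param cohort an `lm_cohort`.
#' @param grid a [landmark_grid()].
#' @param truncate passed to [build_landmark_dataset()].
#' @return A data frame of class `stacked_landmarks` with attributes `grid`
#'   and `per_landmark_n` (named vector of risk-set sizes).
#' @export
stack_landmarks <- function(cohort, grid, truncate = TRUE) {
  stopifnot(inherits(grid, "landmark_grid"))
  parts <- lapply(grid$times, function(l) {
    d <- build_landmark_dataset(cohort, l, grid$tau, truncate = truncate)
    if (nrow(d) == 0L)
      warning("empty risk set at landmark ", l, call. = FALSE)
    d
  })
  out <- do.call(rbind, lapply(parts, as.data.frame))
  if (is.null(out)) out <- as.data.frame(parts[[1]])
  rownames(out) <- NULL
  structure(out, grid = grid,
            per_landmark_n = stats::setNames(vapply(parts, nrow, 1L),
                                             grid$times),
            class = c("stacked_landmarks", "data.frame"))
}

#' Landmark-time interaction basis
#'
#' The quadratic basis \eqn{(1, \ell/s, (\ell/s)^2)} through which covariate
#' effects vary smoothly across landmarks; `degree` truncates it for linear
#' (\eqn{(1, \ell/s)}) or constant (\eqn{(1)}) time interactions.
#'
#' @param l landmark time(s), years.
#' @param scale time scale \eqn{s} (> 0), default 5 years.
#' @param degree polynomial degree, 0, 1 or 2 (default 2).
#' @return A matrix with `length(l)` rows and `degree + 1` columns.
#' @examples
#' time_basis(c(0, 2.5, 5))
#' @export
time_basis <- function(l, scale = 5, degree = 2) {
  if (scale <= 0) stop("`scale` must be > 0", call. = FALSE)
  if (!degree %in% 0:2) stop("`degree` must be 0, 1 or 2", call. = FALSE)
  u <- l / scale
  b <- cbind(1, u, u^2)[, seq_len(degree + 1L), drop = FALSE]
  colnames(b) <- c("1", "t", "t2")[seq_len(degree + 1L)]
  b
}

#' Expand the stacked data into the supermodel design matrix
#'
#' Builds the regression design: a global intercept (no time interaction)
#' followed, for each covariate, by its products with the landmark-time
#' basis. With the quadratic basis and `p` covariates the design has
#' `1 + 3p` columns named `X`, `X_t`, `X_t2` for each covariate `X`, in
#' the order the covariates are given. Setting
#' `intercept_interaction = TRUE` additionally interacts the intercept with
#' the non-constant basis terms.
#'
#' @param data a `stacked_landmarks` or `landmark_data` data frame (any data
#'   frame with a `landmark` column and the named covariates).
#' @param covariates character vector of covariate column names.
#' @param degree,scale basis degree and time scale, see [time_basis()].
#' @param intercept include the leading intercept column (default `TRUE`;
#'   the Cox partial likelihood needs `FALSE`).
#' @param intercept_interaction interact the intercept with the time basis
#'   (default `FALSE`, matching the usual supermodel layout).
#' @return Numeric design matrix with one row per row of `data`.
#' @export
expand_design <- function(data, covariates, degree = 2, scale = 5,
                          intercept = TRUE, intercept_interaction = FALSE) {
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov))
    stop("covariate(s) not present: ", paste(missing_cov, collapse = ", "),
         "; available: ", paste(names(data), collapse = ", "),
         call. = FALSE)
  if (!"landmark" %in% names(data))
    stop("`data` must carry a `landmark` column", call. = FALSE)
  B <- time_basis(data$landmark, scale = scale, degree = degree)
  suffix <- c("", "_t", "_t2")[seq_len(ncol(B))]
  cols <- list()
  if (intercept) {
    cols[["(Intercept)"]] <- rep(1, nrow(data))
    if (intercept_interaction && ncol(B) > 1L)
      for (k in 2:ncol(B))
        cols[[paste0("(Intercept)", suffix[k])]] <- B[, k]
  }
  for (cv in covariates)
    for (k in seq_len(ncol(B)))
      cols[[paste0(cv, suffix[k])]] <- data[[cv]] * B[, k]
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  X
}
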