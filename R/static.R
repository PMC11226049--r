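#' Fit the static comparator models
#'
#' Three static baselines against which the dynamic supermodels are judged,
#' none carrying landmark-time interactions:
#' \describe{
#'   \item{SM1}{per-landmark refits of the conditional outcome (pseudo-values
#'     of the landmark risk set, or a left-window Cox fit) on covariate
#'     values frozen at t = 0; predictions also use the t = 0 values. The
#'     crudest comparator: conditional on survival to \eqn{\ell} but blind to
#'     covariate updates.}
#'   \item{SM2}{a single fit at \eqn{\ell = 0}; predictions at later
#'     landmarks plug the updated covariates \eqn{X(\ell)} into that baseline
#'     model.}
#'   \item{SM3}{per-landmark refits on the updated covariates
#'     \eqn{X(\ell)}; still static, since each fit sees only one time point,
#'     not the covariate history.}
#' }
#'
#' For the PM/PP families each fit is a pseudo-value regression (identity
#' link) on the landmark's risk set; for the Cox family each fit is a
#' proportional-hazards model of the residual time within the
#' \eqn{[0, \tau]} window.
#'
#' @param variant `"sm1"`, `"sm2"` or `"sm3"`.
#' @param family `"pm"`, `"pp"` or `"cox"`.
#' @param cohort training `lm_cohort`.
#' @param grid a [landmark_grid()].
#' @param covariates covariate names.
#' @return An object of class `static_landmark_model` holding one fit (SM2)
#'   or one per landmark (SM1, SM3) in `fits`, keyed by landmark time.
#' @export
fit_static_model <- function(variant = c("sm1", "sm2", "sm3"),
                             family = c("pm", "pp", "cox"),
                             cohort, grid, covariates) {
  variant <- match.arg(variant)
  family <- match.arg(family)
  stopifnot(inherits(grid, "landmark_grid"))
  fit_times <- if (variant == "sm2") grid$times[1] else grid$times
  if (variant == "sm2" && fit_times != 0)
    warning("SM2 baseline fit uses the first grid landmark (",
            fit_times, "), not t = 0", call. = FALSE)
  x0 <- covariates_at(cohort, 0)
  fits <- lapply(fit_times, function(l) {
    ld <- build_landmark_dataset(cohort, l, grid$tau,
                                 truncate = (family == "cox"))
    if (variant == "sm1") {
      # regress the conditional outcome at l on time-zero covariate values
      keep <- match(ld$subject_id, x0$subject_id)
      ld[COVARIATE_NAMES] <- x0[keep, COVARIATE_NAMES]
    }
    static_fit_one(ld, family, covariates, grid$tau)
  })
  names(fits) <- as.character(fit_times)
  structure(list(variant = variant, family = family, fits = fits,
                 fit_times = fit_times, grid = grid,
                 covariates = covariates, tau = grid$tau),
            class = "static_landmark_model")
}

# One static fit on a single landmark dataset (no time interactions).
static_fit_one <- function(ld, family, covariates, tau) {
  if (family %in% c("pm", "pp")) {
    kind <- if (family == "pm") "mean" else "prob"
    fun <- if (family == "pm") pseudo_means else pseudo_probabilities
    y <- fun(ld$residual_time, ld$residual_event, tau = tau)
    X <- cbind(`(Intercept)` = 1,
               as.matrix(ld[, covariates, drop = FALSE]))
    check_full_rank(X)
    df <- as.data.frame(X)
    names(df) <- make.names(colnames(X))
    df$.y <- y
    fit <- stats::lm(.y ~ . - 1, data = df)
    list(coefficients = stats::setNames(stats::coef(fit), colnames(X)),
         vcov = {
           V <- sandwich::vcovCL(fit, cluster = ld$subject_id)
           dimnames(V) <- list(colnames(X), colnames(X)); V
         })
  } else {
    if (sum(ld$residual_event) == 0L)
      stop("no events in the prediction window at landmark ",
           ld$landmark[1], call. = FALSE)
    df <- ld[covariates]
    names(df) <- make.names(covariates)
    df$.time <- ld$residual_time
    df$.event <- ld$residual_event
    fml <- stats::as.formula(paste(
      "survival::Surv(.time, .event) ~",
      paste(make.names(covariates), collapse = " + ")))
    fit <- survival::coxph(fml, data = df, ties = "breslow")
    bh <- survival::basehaz(fit, centered = FALSE)
    list(coefficients = stats::setNames(stats::coef(fit), covariates),
         vcov = fit$var,
         basehaz = data.frame(time = bh$time, hazard = bh$hazard))
  }
}

#' @export
print.static_landmark_model <- function(x, ...) {
  cat("Static comparator ", toupper(x$variant), " (", toupper(x$family),
      "): ", length(x$fits), " fit(s), tau = ", x$tau, " yr\n", sep = "")
  invisible(x)
}

#' @export
predict_at_landmark.static_landmark_model <- function(model, cohort, l) {
  ld <- build_landmark_dataset(cohort, l, model$tau, truncate = TRUE)
  Xsrc <- ld
  if (model$variant == "sm1") {
    x0 <- covariates_at(cohort, 0)
    keep <- match(ld$subject_id, x0$subject_id)
    Xsrc[COVARIATE_NAMES] <- x0[keep, COVARIATE_NAMES]
  }
  fit <- if (model$variant == "sm2") model$fits[[1]]
  else {
    k <- which.min(abs(model$fit_times - l))
    if (abs(model$fit_times[k] - l) > 1e-9)
      warning("no static fit at landmark ", l, "; using nearest (",
              model$fit_times[k], ")", call. = FALSE)
    model$fits[[k]]
  }
  X <- as.matrix(Xsrc[, model$covariates, drop = FALSE])
  if (model$family %in% c("pm", "pp")) {
    lp <- as.numeric(cbind(1, X) %*% fit$coefficients)
    hi <- if (model$family == "pm") model$tau else 1
    pred <- pmin(pmax(lp, 0), hi)
  } else {
    lp <- as.numeric(X %*% fit$coefficients)
    H <- cumhaz_interval(fit$basehaz, 0, model$tau)
    pred <- exp(-H * exp(lp))
  }
  data.frame(subject_id = ld$subject_id, prediction = pred)
}
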