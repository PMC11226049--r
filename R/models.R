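#' Fit a GEE landmark supermodel on pseudo-value outcomes
#'
#' Models the conditional pseudo-outcome at each landmark as
#' \deqn{g[\mu_i(\ell, \tau \mid X_i(\ell))] = \alpha + X_i(\ell)^T \beta(\ell)}
#' with \eqn{\beta_p(\ell) = \beta_{p0} + \beta_{p1}(\ell/s) +
#' \beta_{p2}(\ell/s)^2}, fitted on the stacked landmark data by
#' generalized estimating equations with an independence working correlation
#' and identity link. Under that choice the point estimates coincide exactly
#' with least squares on the expanded design; the variance is the robust
#' sandwich clustered by subject, which accounts for the same subject
#' recurring across landmarks.
#'
#' @param stacked a `stacked_landmarks` data frame with a `pseudo` column
#'   (see [add_pseudo_values()]); the pseudo kind tags the fitted family.
#' @param covariates covariate names entering the model.
#' @param degree,scale landmark-time interaction basis (see [time_basis()]);
#'   defaults quadratic on \eqn{\ell/5}.
#' @param link only `"identity"` is implemented (the link ultimately used in
#'   this workflow).
#' @return An object of class `landmark_supermodel` with fields
#'   `family` (`"pm"` or `"pp"`), `coefficients`, `vcov` (clustered
#'   sandwich), `covariates`, `degree`, `scale`, `tau`, `grid`.
#' @examples
#' coh <- simulate_cohort(cohort_params(n_subjects = 300, seed = 2))
#' g <- landmark_grid(0, 2, 1, tau = 2)
#' st <- add_pseudo_values(stack_landmarks(coh, g, truncate = FALSE))
#' fit <- fit_gee_supermodel(st, c("age", "meld_na"))
#' coef(fit)
#' @export
fit_gee_supermodel <- function(stacked, covariates, degree = 2, scale = 5,
                               link = "identity") {
  if (!identical(link, "identity"))
    stop("only the identity link is implemented", call. = FALSE)
  if (is.null(stacked$pseudo))
    stop("`stacked` must carry a `pseudo` column; see add_pseudo_values()",
         call. = FALSE)
  X <- expand_design(stacked, covariates, degree = degree, scale = scale)
  check_full_rank(X)
  df <- as.data.frame(X)
  names(df) <- make.names(colnames(X))
  df$.y <- stacked$pseudo
  fit <- stats::lm(.y ~ . - 1, data = df)
  beta <- stats::setNames(stats::coef(fit), colnames(X))
  V <- sandwich::vcovCL(fit, cluster = stacked$subject_id)
  dimnames(V) <- list(colnames(X), colnames(X))
  kind <- attr(stacked, "pseudo_kind")
  structure(list(family = if (identical(kind, "prob")) "pp" else "pm",
                 coefficients = beta, vcov = V, covariates = covariates,
                 degree = degree, scale = scale,
                 tau = attr(stacked, "pseudo_tau") %||%
                   attr(stacked, "grid")$tau,
                 grid = attr(stacked, "grid"), link = link),
            class = "landmark_supermodel")
}

check_full_rank <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the Cox landmark supermodel on the stacked data
#'
#' Maximizes the stacked partial likelihood
#' \eqn{P(T > \ell + \tau \mid T > \ell, X(\ell)) =
#' \exp\{-\Lambda_0(\tau \mid \ell)\exp(\alpha' X(\ell))\}} with delayed
#' entry at each landmark and administrative censoring at \eqn{\ell + \tau},
#' Breslow tie handling, and a single Breslow baseline cumulative hazard on
#' the study time axis. Covariate effects carry the same landmark-time
#' interaction basis as the GEE supermodel; the variance is the robust
#' sandwich clustered by subject.
#'
#' @param stacked a `stacked_landmarks` data frame (the `entry`, `exit`,
#'   `exit_event` columns supply the study-time risk intervals).
#' @inheritParams fit_gee_supermodel
#' @return A `landmark_supermodel` with `family = "cox"` and an additional
#'   `basehaz` field (data frame `time`, `hazard` of the Breslow cumulative
#'   baseline hazard at covariates 0).
#' @export
fit_cox_supermodel <- function(stacked, covariates, degree = 2, scale = 5) {
  if (sum(stacked$exit_event) == 0L)
    stop("no events inside any prediction window", call. = FALSE)
  X <- expand_design(stacked, covariates, degree = degree, scale = scale,
                     intercept = FALSE)
  check_full_rank(X)
  df <- as.data.frame(X)
  names(df) <- make.names(colnames(X))
  df$.entry <- stacked$entry
  df$.exit <- stacked$exit
  df$.event <- stacked$exit_event
  df$.id <- stacked$subject_id
  # guard against zero-length risk intervals from ties T == l (excluded
  # upstream by the strict at-risk rule, but keep coxph strictness honest)
  fml <- stats::as.formula(paste(
    "survival::Surv(.entry, .exit, .event) ~",
    paste(make.names(colnames(X)), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "breslow",
                         cluster = .id, robust = TRUE,
                         control = survival::coxph.control(eps = 1e-11,
                                                           iter.max = 50))
  beta <- stats::setNames(stats::coef(fit), colnames(X))
  V <- fit$var
  dimnames(V) <- list(colnames(X), colnames(X))
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(family = "cox", coefficients = beta, vcov = V,
                 covariates = covariates, degree = degree, scale = scale,
                 tau = attr(stacked, "grid")$tau,
                 grid = attr(stacked, "grid"),
                 basehaz = data.frame(time = bh$time, hazard = bh$hazard),
                 coxph = fit),
            class = "landmark_supermodel")
}

#' @export
print.landmark_supermodel <- function(x, ...) {
  cat("Landmark supermodel (", toupper(x$family), "), basis degree ",
      x$degree, " on l/", x$scale, ", tau = ", x$tau, " yr\n", sep = "")
  print(coef_table(x))
  invisible(x)
}

#' @export
coef.landmark_supermodel <- function(object, ...) object$coefficients

#' @export
vcov.landmark_supermodel <- function(object, ...) object$vcov

#' Coefficient table of a fitted supermodel
#'
#' @param model a `landmark_supermodel`.
#' @return Data frame with term, estimate, robust SE, z and p-value,
#'   mirroring the usual dynamic-model coefficient layout.
#' @export
coef_table <- function(model) {
  est <- model$coefficients
  se <- sqrt(diag(model$vcov))
  z <- est / se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             z = unname(z), p_value = unname(2 * stats::pnorm(-abs(z))))
}

#' Build a supermodel object from externally supplied coefficients
#'
#' Constructs a minimal `landmark_supermodel` from a table of per-covariate
#' basis coefficients — for instance published estimates — so that
#' [dynamic_coefficient()] and [predict_conditional()] (PM/PP families) can
#' be applied without refitting. The covariance defaults to zero (no
#' uncertainty information).
#'
#' @param coefficients named numeric vector over the expanded design, using
#'   the [expand_design()] naming scheme (`X`, `X_t`, `X_t2`, and
#'   `(Intercept)` for PM/PP).
#' @param family `"pm"`, `"pp"` or `"cox"`.
#' @param covariates covariate names; inferred from the coefficient names
#'   when omitted.
#' @param degree,scale,tau basis degree, time scale and horizon.
#' @param vcov optional covariance matrix matching `coefficients`.
#' @return A `landmark_supermodel`.
#' @examples
#' m <- supermodel_from_coefficients(
#'   c(decomp = -0.151, decomp_t = 0.640, decomp_t2 = -0.671),
#'   family = "pm")
#' dynamic_coefficient(m, "decomp", l = 5)
#' @export
supermodel_from_coefficients <- function(coefficients, family = c("pm", "pp", "cox"),
                                         covariates = NULL, degree = 2,
                                         scale = 5, tau = 3, vcov = NULL) {
  family <- match.arg(family)
  if (is.null(names(coefficients)))
    stop("`coefficients` must be named", call. = FALSE)
  if (is.null(covariates)) {
    base <- setdiff(names(coefficients), "(Intercept)")
    covariates <- unique(sub("(_t2|_t)$", "", base))
  }
  if (is.null(vcov)) {
    k <- length(coefficients)
    vcov <- matrix(0, k, k, dimnames = list(names(coefficients),
                                            names(coefficients)))
  }
  structure(list(family = family, coefficients = coefficients, vcov = vcov,
                 covariates = covariates, degree = degree, scale = scale,
                 tau = tau, grid = NULL, link = "identity"),
            class = "landmark_supermodel")
}

#' Dynamic coefficient of a covariate at a landmark time
#'
#' Evaluates \eqn{\beta_p(\ell) = \beta_{p0} + \beta_{p1}(\ell/s) +
#' \beta_{p2}(\ell/s)^2} with a delta-method standard error
#' \eqn{\sqrt{b^T \Sigma_p b}} from the clustered sandwich covariance, where
#' \eqn{b} is the time basis at \eqn{\ell}. The units follow the family:
#' years of conditional RMST (PM), survival probability (PP) or log hazard
#' ratio (Cox).
#'
#' @param model a `landmark_supermodel`.
#' @param covariate one fitted covariate name.
#' @param l landmark time(s), years.
#' @param level confidence level (default 0.95).
#' @return Data frame with columns `covariate`, `landmark`, `estimate`,
#'   `se`, `lower`, `upper`.
#' @export
dynamic_coefficient <- function(model, covariate, l, level = 0.95) {
  if (!covariate %in% model$covariates)
    stop("`", covariate, "` is not among the fitted covariates: ",
         paste(model$covariates, collapse = ", "), call. = FALSE)
  terms <- paste0(covariate, c("", "_t", "_t2"))[seq_len(model$degree + 1L)]
  b <- model$coefficients[terms]
  B <- time_basis(l, scale = model$scale, degree = model$degree)
  est <- as.numeric(B %*% b)
  Vp <- model$vcov[terms, terms, drop = FALSE]
  se <- sqrt(rowSums((B %*% Vp) * B))
  zc <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(covariate = covariate, landmark = l, estimate = est, se = se,
             lower = est - zc * se, upper = est + zc * se)
}
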