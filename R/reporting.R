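#' Plot dynamic coefficient curves with confidence bands
#'
#' One panel per covariate: the dynamic coefficient \eqn{\beta_p(\ell)}
#' (solid) with its pointwise 95% confidence band (dashed) over the landmark
#' range. With the quadratic basis each curve is a parabola; a constant
#' basis gives horizontal lines.
#'
#' @param model a fitted `landmark_supermodel`.
#' @param covariates covariates to plot; default all fitted ones.
#' @param l_range landmark range, default the fitted grid (or `c(0, 5)`).
#' @param file optional path; when given, the figure is written there as a
#'   PDF and the device closed.
#' @param n_points curve resolution.
#' @return Invisibly, the data frame of plotted values (covariate, landmark,
#'   estimate, lower, upper) — every figure is recomputable from it.
#' @export
plot_dynamic_coefficients <- function(model, covariates = model$covariates,
                                      l_range = NULL, file = NULL,
                                      n_points = 101) {
  bad <- setdiff(covariates, model$covariates)
  if (length(bad))
    stop("unknown covariate(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(l_range))
    l_range <- if (!is.null(model$grid)) range(model$grid$times) else c(0, 5)
  ls <- seq(l_range[1], l_range[2], length.out = n_points)
  curves <- do.call(rbind, lapply(covariates, function(cv)
    dynamic_coefficient(model, cv, ls)))
  if (!is.null(file)) {
    grDevices::pdf(file, width = 9, height = 6)
    on.exit(grDevices::dev.off())
  }
  nc <- ceiling(sqrt(length(covariates)))
  nr <- ceiling(length(covariates) / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  ylab <- switch(model$family,
                 pm = "difference in conditional RMST (yr)",
                 pp = "difference in survival probability",
                 cox = "log hazard ratio")
  for (cv in covariates) {
    d <- curves[curves$covariate == cv, ]
    graphics::plot(d$landmark, d$estimate, type = "l", lwd = 2,
                   ylim = range(d$lower, d$upper),
                   xlab = "landmark time (yr)", ylab = ylab, main = cv)
    graphics::lines(d$landmark, d$lower, lty = 2)
    graphics::lines(d$landmark, d$upper, lty = 2)
    graphics::abline(h = 0, col = "grey70")
  }
  invisible(curves)
}

#' Plot individual dynamic vs static prediction trajectories
#'
#' For each requested subject, the conditional prediction over the horizon
#' is traced across the landmarks at which the subject is still at risk:
#' dynamic supermodel solid, static comparator dashed. Trajectories stop at
#' the last landmark with the subject at risk; subjects never at risk are
#' skipped with a warning.
#'
#' @param dynamic a fitted `landmark_supermodel`.
#' @param static a fitted `static_landmark_model` (typically SM2).
#' @param cohort the `lm_cohort` the subjects live in.
#' @param subject_ids subjects to plot.
#' @param grid a [landmark_grid()].
#' @param file optional PDF path.
#' @return Invisibly, the data frame of plotted values (subject_id, model,
#'   landmark, prediction).
#' @export
plot_individual_trajectories <- function(dynamic, static, cohort,
                                         subject_ids, grid, file = NULL) {
  vals <- list()
  for (l in grid$times) {
    at_risk <- cohort$survival$subject_id[cohort$survival$time > l]
    want <- intersect(subject_ids, at_risk)
    if (!length(want)) next
    sub <- subset_cohort(cohort, want)
    for (tag in c("dynamic", "static")) {
      m <- if (tag == "dynamic") dynamic else static
      pr <- predict_at_landmark(m, sub, l)
      pr <- pr[pr$subject_id %in% want, ]
      if (nrow(pr))
        vals[[length(vals) + 1L]] <- data.frame(
          subject_id = pr$subject_id, model = tag, landmark = l,
          prediction = pr$prediction)
    }
  }
  traj <- do.call(rbind, vals)
  plotted <- intersect(subject_ids, unique(traj$subject_id))
  skipped <- setdiff(subject_ids, plotted)
  if (length(skipped))
    warning("subject(s) never at risk, skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  if (!length(plotted)) stop("no subject at risk at any landmark",
                             call. = FALSE)
  if (!is.null(file)) {
    grDevices::pdf(file, width = 8, height = 4 * length(plotted))
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(length(plotted), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  ylab <- if (dynamic$family == "pm") "conditional 3-yr RMST (yr)"
  else "conditional survival probability"
  for (sid in plotted) {
    d <- traj[traj$subject_id == sid & traj$model == "dynamic", ]
    s <- traj[traj$subject_id == sid & traj$model == "static", ]
    graphics::plot(d$landmark, d$prediction, type = "b", lwd = 2,
                   ylim = range(traj$prediction[traj$subject_id == sid]),
                   xlim = range(grid$times),
                   xlab = "landmark time (yr)", ylab = ylab,
                   main = paste("subject", sid))
    graphics::lines(s$landmark, s$prediction, lty = 2, type = "b")
  }
  invisible(traj)
}

#' Configuration for the end-to-end pipeline
#'
#' @param params a [cohort_params()] describing the cohort to simulate, or
#'   `NULL` when `survival_file`/`longitudinal_file` point to existing
#'   tables.
#' @param survival_file,longitudinal_file optional input tables (see
#'   [read_cohort()]); ignored when `params` is given.
#' @param grid_start,grid_end,grid_step,tau,scale landmark grid definition.
#' @param families model families to fit, subset of
#'   `c("pm", "pp", "cox")`.
#' @param static_variants static comparators to fit, subset of
#'   `c("sm1", "sm2", "sm3")`.
#' @param covariates model covariates.
#' @param split_fraction,split_seed train/test split definition.
#' @param out_dir output directory.
#' @param figures emit figure PDFs (default `TRUE`).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(params = cohort_params(),
                            survival_file = NULL, longitudinal_file = NULL,
                            grid_start = 0, grid_end = 5, grid_step = 0.5,
                            tau = 3, scale = 5,
                            families = c("pm", "pp", "cox"),
                            static_variants = c("sm1", "sm2", "sm3"),
                            covariates = c("age", "etoh", "biliary", "chol",
                                           "meld_na", "albumin", "decomp",
                                           "hcc"),
                            split_fraction = 0.75, split_seed = 1L,
                            out_dir = "landstack-run", figures = TRUE) {
  families <- match.arg(families, several.ok = TRUE)
  static_variants <- match.arg(static_variants, several.ok = TRUE)
  if (is.null(params) &&
      (is.null(survival_file) || is.null(longitudinal_file)))
    stop("either `params` or both input files must be given", call. = FALSE)
  if (!is.null(survival_file) && !file.exists(survival_file))
    stop("`survival_file` does not exist: ", survival_file, call. = FALSE)
  if (!is.null(longitudinal_file) && !file.exists(longitudinal_file))
    stop("`longitudinal_file` does not exist: ", longitudinal_file,
         call. = FALSE)
  grid <- landmark_grid(grid_start, grid_end, grid_step, tau, scale)
  structure(list(params = params, survival_file = survival_file,
                 longitudinal_file = longitudinal_file, grid = grid,
                 families = families, static_variants = static_variants,
                 covariates = covariates, split_fraction = split_fraction,
                 split_seed = as.integer(split_seed), out_dir = out_dir,
                 figures = figures),
            class = "pipeline_config")
}

#' Run the full dynamic-prediction pipeline
#'
#' Simulate (or ingest) the cohort, split subjects into train/test, stack
#' the landmark datasets, attach pseudo-values, fit the dynamic supermodels
#' and the requested static comparators for each family, evaluate every
#' model on the held-out test set, and write all tables (CSV), a JSON run
#' manifest with seeds and per-stage row counts, and the coefficient/metric
#' figures. Reruns with the same configuration produce byte-identical
#' tables.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the fitted models, the metric table and
#'   the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- config$grid

  cohort <- if (!is.null(config$params)) simulate_cohort(config$params)
  else read_cohort(config$survival_file, config$longitudinal_file)
  write_cohort(cohort, config$out_dir)

  sp <- split_train_test(cohort, config$split_fraction, config$split_seed)
  stacked <- stack_landmarks(sp$train, grid, truncate = FALSE)
  utils::write.csv(as.data.frame(stacked),
                   file.path(config$out_dir, "stacked_train.csv"),
                   row.names = FALSE)

  models <- list()
  coef_rows <- list()
  for (fam in config$families) {
    dyn <- if (fam == "cox") {
      fit_cox_supermodel(stack_landmarks(sp$train, grid, truncate = TRUE),
                         config$covariates, scale = grid$scale)
    } else {
      st <- add_pseudo_values(stacked, tau = grid$tau,
                              kind = if (fam == "pm") "mean" else "prob")
      fit_gee_supermodel(st, config$covariates, scale = grid$scale)
    }
    models[[paste0("dynamic_", fam)]] <- dyn
    ct <- coef_table(dyn)
    ct$model <- paste0("dynamic_", fam)
    coef_rows[[length(coef_rows) + 1L]] <- ct
    for (v in config$static_variants)
      models[[paste0(v, "_", fam)]] <-
        fit_static_model(v, fam, sp$train, grid, config$covariates)
  }
  coefs <- do.call(rbind, coef_rows)
  utils::write.csv(coefs, file.path(config$out_dir, "coefficients.csv"),
                   row.names = FALSE)

  metrics <- evaluate_models(models, sp$test, grid)
  utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)

  if (config$figures) {
    for (fam in config$families)
      plot_dynamic_coefficients(
        models[[paste0("dynamic_", fam)]],
        file = file.path(config$out_dir,
                         paste0("dynamic_coefficients_", fam, ".pdf")))
  }

  manifest <- list(
    seed = if (!is.null(config$params)) config$params$seed else NA,
    split_seed = config$split_seed,
    n_subjects = n_subjects(cohort),
    n_train = n_subjects(sp$train), n_test = n_subjects(sp$test),
    n_events = sum(cohort$survival$event),
    grid = list(times = grid$times, tau = grid$tau, scale = grid$scale),
    families = config$families, static_variants = config$static_variants,
    covariates = config$covariates,
    stacked_rows = nrow(stacked),
    per_landmark_n = as.list(attr(stacked, "per_landmark_n")),
    metric_rows = nrow(metrics))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(models = models, metrics = metrics, manifest = manifest))
}
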