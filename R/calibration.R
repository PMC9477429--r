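# Per-subject parameter estimation from longitudinal biomarker series.
# The cascade is triangular (Abeta -> taup, tauo -> N -> C), so parameters
# are first estimated sequentially equation-by-equation — each stage fits
# only its own rates/capacity/initial condition with upstream estimates held
# fixed — and the sequential estimate then warm-starts a joint bounded
# Levenberg-Marquardt refinement over all parameters and initial conditions.

#' Longitudinal biomarker record for one subject
#'
#' @param subject_id Opaque subject label.
#' @param series Named list over biomarkers (`Abeta`, `taup`, `tauo`, `N`,
#'   `C`), each a data frame with columns `age` (years, strictly increasing)
#'   and `value` (finite).
#' @return A `longitudinal_record` object.
#' @export
longitudinal_record <- function(subject_id, series) {
  stopifnot(is.list(series), all(names(series) %in% .state_names))
  for (nm in names(series)) {
    s <- series[[nm]]
    stopifnot(is.data.frame(s), all(c("age", "value") %in% names(s)))
    if (any(!is.finite(s$age)) || any(!is.finite(s$value)))
      stop("non-finite data in series '", nm, "'")
    if (is.unsorted(s$age, strictly = TRUE))
      stop("ages in series '", nm, "' must be strictly increasing")
    series[[nm]] <- s[c("age", "value")]
  }
  structure(list(subject_id = subject_id, series = series),
            class = "longitudinal_record")
}

#' @export
print.longitudinal_record <- function(x, ...) {
  cat("Longitudinal record for subject", x$subject_id, "\n")
  for (nm in names(x$series))
    cat(sprintf("  %-6s %d visits, ages %.1f-%.1f\n", nm,
                nrow(x$series[[nm]]), min(x$series[[nm]]$age),
                max(x$series[[nm]]$age)))
  invisible(x)
}

#' Read/write longitudinal records as tidy delimited text
#'
#' Columns: `subject_id`, `biomarker`, `age`, `value`; the biomarker
#' vocabulary is exactly `Abeta`, `taup`, `tauo`, `N`, `C`.
#'
#' @param path File path (tab-separated).
#' @return `read_records()` returns a named list of `longitudinal_record`s.
#' @export
read_records <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "biomarker", "age", "value") %in% names(df)))
  bad <- setdiff(unique(df$biomarker), .state_names)
  if (length(bad)) stop("unknown biomarker name(s): ", paste(bad, collapse = ", "))
  recs <- lapply(split(df, df$subject_id), function(d) {
    series <- lapply(split(d, d$biomarker), function(s) {
      out <- data.frame(age = s$age, value = s$value)[order(s$age), ]
      rownames(out) <- NULL
      out
    })
    series <- series[intersect(.state_names, names(series))]
    longitudinal_record(d$subject_id[1], series)
  })
  recs[unique(df$subject_id)]
}

#' @param records Named list of `longitudinal_record` objects (or one record).
#' @rdname read_records
#' @export
write_records <- function(records, path) {
  if (inherits(records, "longitudinal_record")) records <- list(records)
  rows <- do.call(rbind, lapply(records, function(r)
    do.call(rbind, lapply(names(r$series), function(bm)
      data.frame(subject_id = r$subject_id, biomarker = bm,
                 age = r$series[[bm]]$age, value = r$series[[bm]]$value)))))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean relative error between model and observations
#'
#' Default form (`mad`) is the mean absolute relative deviation
#' `mean(|model - obs| / |obs|)`; `rmsre` is the root mean squared relative
#' error `sqrt(mean((model - obs)^2 / obs^2))`. Both are fractions; multiply
#' by 100 to report percent.
#'
#' @param model_values,observed Equal-length numeric vectors; observations
#'   must be nonzero.
#' @param form `"mad"` or `"rmsre"`.
#' @return Nonnegative scalar.
#' @export
relative_error <- function(model_values, observed, form = c("mad", "rmsre")) {
  form <- match.arg(form)
  stopifnot(length(model_values) == length(observed), length(observed) >= 1)
  if (any(observed == 0)) stop("relative error undefined for zero observations")
  r <- (model_values - observed) / observed
  if (form == "mad") mean(abs(r)) else sqrt(mean(r^2))
}

#' Default calibration bounds
#'
#' Box bounds for the bounded least-squares fits: each rate in
#' `[0, 10 x its reference group mean]`, each capacity in
#' `[max observed value, 10 x max observed]`, and each initial condition in
#' `[0, the capacity's upper bound]` (tauo has no capacity; its initial
#' condition is bounded by 10 x its largest observation).
#'
#' @param record A [longitudinal_record].
#' @param group Reference group (`"AD"`, `"LMCI"` or `"CN"`) supplying the
#'   rate-bound scale.
#' @return List with `lower` and `upper` named vectors over the 16
#'   subject-level quantities.
#' @export
calibration_bounds <- function(record, group = "AD") {
  gm <- cohort_group_defaults()[[group]]$mean
  mx <- function(bm) max(record$series[[bm]]$value)
  rate_nms <- c("lambda_Abeta", "lambda_tau", "lambda_tauo", "lambda_N_tauo",
                "lambda_N_taup", "lambda_CN", "lambda_Ctau")
  upper <- c(setNames(10 * gm[rate_nms], rate_nms),
             K_Abeta = 10 * mx("Abeta"), K_taup = 10 * mx("taup"),
             K_N = 10 * mx("N"), K_C = 10 * mx("C"),
             A0 = 10 * mx("Abeta"), taup0 = 10 * mx("taup"),
             tauo0 = 10 * mx("tauo"), N0 = 10 * mx("N"), C0 = 10 * mx("C"))
  lower <- setNames(rep(0, length(upper)), names(upper))
  lower[c("K_Abeta", "K_taup", "K_N", "K_C")] <-
    c(mx("Abeta"), mx("taup"), mx("N"), mx("C"))
  nm <- c(.param_names, .ic_names)
  list(lower = lower[nm], upper = upper[nm])
}

.require_points <- function(record, bm, n = 3L) {
  s <- record$series[[bm]]
  if (is.null(s) || nrow(s) < n) {
    cond <- structure(
      class = c("adcascade_exclusion", "error", "condition"),
      list(message = sprintf(
        "subject %s excluded: biomarker '%s' has %d longitudinal datapoints (at least %d required)",
        record$subject_id, bm, if (is.null(s)) 0L else nrow(s), n),
        call = NULL))
    stop(cond)
  }
  s
}

# Model values of one biomarker at given ages for an arbitrary (possibly
# partial) parameter assignment; unspecified parameters are inert (rates 0,
# capacities 1, initial conditions 0). Returns large residual surrogate on
# integration failure so bounded LM can back off.
.stage_values <- function(assign, bm, ages, T0, step) {
  full <- setNames(rep(0, 16), c(.param_names, .ic_names))
  full[c("K_Abeta", "K_taup", "K_N", "K_C")] <- 1
  full[names(assign)] <- unlist(assign)
  times <- time_grid(T0, max(ages), step)
  res <- cascade_integrate_cpp(unname(full[.param_names]),
                               unname(full[.ic_names]), times,
                               numeric(length(times)), 1e-6)
  if (res$status != 0L) return(NULL)
  approx(times, res$states[, match(bm, .state_names)], xout = ages, rule = 2)$y
}

.lm_fit <- function(resid_fn, starts, lower, upper) {
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-13, ptol = 1e-13)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("stage optimization failed for all starts")
  best
}

.is_degenerate <- function(values) {
  diff(range(values)) <= 1e-8 * max(abs(values), 1)
}

#' Fit the amyloid equation parameters
#'
#' Least-squares fit of (`lambda_Abeta`, `K_Abeta`, `A0`) to the observed
#' amyloid series using the closed-form logistic solution. Constant series
#' are degenerate (zero-growth flat optimum) and flagged.
#'
#' @param record A [longitudinal_record] with at least 3 amyloid points.
#' @param bounds Bounds from [calibration_bounds()].
#' @return List with `par` (named estimates), `sse`, and `degenerate` flag.
#' @export
fit_abeta <- function(record, bounds = calibration_bounds(record)) {
  s <- .require_points(record, "Abeta")
  lo <- bounds$lower[c("lambda_Abeta", "K_Abeta", "A0")]
  up <- bounds$upper[c("lambda_Abeta", "K_Abeta", "A0")]
  if (.is_degenerate(s$value)) {
    par <- c(lambda_Abeta = 0, K_Abeta = max(s$value), A0 = mean(s$value))
    return(list(par = par, sse = sum((par[["A0"]] - s$value)^2), degenerate = TRUE))
  }
  T0 <- 50
  resid_fn <- function(p) {
    A0 <- min(p[[3]], p[[2]])  # keep A0 <= K during the search
    C1 <- p[[2]] / max(A0, 1e-12) - 1
    p[[2]] / (C1 * exp(-p[[1]] * (s$age - T0)) + 1) - s$value
  }
  starts <- lapply(c(0.05, 0.15, 0.4), function(l)
    c(lambda_Abeta = l, K_Abeta = 2 * max(s$value), A0 = 0.5 * min(s$value)))
  fit <- .lm_fit(resid_fn, starts, lo, up)
  par <- setNames(fit$par, c("lambda_Abeta", "K_Abeta", "A0"))
  par[["A0"]] <- min(par[["A0"]], par[["K_Abeta"]])
  list(par = par, sse = fit$deviance, degenerate = FALSE)
}

# stage definitions: free parameters and the biomarker each stage fits
.stage_defs <- list(
  taup = c("lambda_tau", "K_taup", "taup0"),
  tauo = c("lambda_tauo", "tauo0"),
  N = c("lambda_N_tauo", "lambda_N_taup", "K_N", "N0"),
  C = c("lambda_CN", "K_C", "C0")
)

#' Fit one downstream stage of the cascade
#'
#' Minimizes the stage's least-squares objective over only that stage's
#' parameters and initial condition, integrating the cascade with all
#' upstream (already fitted) parameters held fixed. Stage targets: `taup`
#' fits (`lambda_tau`, `K_taup`, `taup0`); `tauo` fits (`lambda_tauo`,
#' `tauo0`); `N` fits (`lambda_N_tauo`, `lambda_N_taup`, `K_N`, `N0`); `C`
#' fits (`lambda_CN`, `K_C`, `C0`). Saturated or constant series are flagged
#' as degenerate rather than yielding arbitrary interior estimates.
#'
#' @param stage One of `"taup"`, `"tauo"`, `"N"`, `"C"`.
#' @param record A [longitudinal_record].
#' @param fixed Named list/vector of upstream parameter estimates.
#' @param bounds Bounds from [calibration_bounds()].
#' @param group Reference group for start values.
#' @param step Integration step in years.
#' @return List with `par`, `sse`, `degenerate`.
#' @export
fit_stage <- function(stage, record, fixed,
                      bounds = calibration_bounds(record), group = "AD",
                      step = 0.01) {
  stage <- match.arg(stage, names(.stage_defs))
  free <- .stage_defs[[stage]]
  s <- .require_points(record, stage)
  lo <- bounds$lower[free]; up <- bounds$upper[free]
  gm <- cohort_group_defaults()[[group]]$mean
  if (.is_degenerate(s$value)) {
    par <- setNames(rep(0, length(free)), free)
    caps <- intersect(free, c("K_taup", "K_N", "K_C"))
    # a flat series sitting at its plateau pins the capacity, nothing else
    if (length(caps)) par[caps] <- pmax(max(s$value), lo[caps])
    ic <- switch(stage, taup = "taup0", tauo = "tauo0", N = "N0", C = "C0")
    par[[ic]] <- mean(s$value)
    vals <- rep(mean(s$value), nrow(s))
    return(list(par = par, sse = sum((vals - s$value)^2), degenerate = TRUE))
  }
  T0 <- 50
  resid_fn <- function(p) {
    vals <- .stage_values(c(as.list(fixed), setNames(as.list(p), free)),
                          stage, s$age, T0, step)
    if (is.null(vals)) return(rep(1e6, nrow(s)))
    vals - s$value
  }
  starts <- switch(stage,
    taup = lapply(c(0.02, 0.1, 0.4), function(l)
      c(l, 2 * max(s$value), 0.5 * min(s$value))),
    tauo = {
      cf <- stats::coef(stats::lm(value ~ I(age - T0), data = s))
      list(c(max(cf[[2]], 1e-4), max(cf[[1]], 1e-4)),
           c(gm[["lambda_tauo"]], 0.5 * min(s$value)))
    },
    N = list(
      c(gm[["lambda_N_tauo"]], gm[["lambda_N_taup"]], 1.2 * max(s$value),
        0.5 * min(s$value)),
      c(5 * gm[["lambda_N_tauo"]], 0.2 * gm[["lambda_N_taup"]],
        1.05 * max(s$value), 0.9 * min(s$value))),
    C = lapply(c(0.3, 1, 3), function(f)
      c(f * gm[["lambda_CN"]], 2 * max(s$value), 0.5 * min(s$value))))
  starts <- lapply(starts, setNames, free)
  fit <- .lm_fit(resid_fn, starts, lo, up)
  list(par = setNames(fit$par, free), sse = fit$deviance, degenerate = FALSE)
}

# Box bounds cannot couple an initial condition to its (simultaneously
# fitted) capacity, so the constraint IC <= K is enforced inside the model
# evaluation: the optimizer and the reported result see the same model.
.clip_ics <- function(par16) {
  par16[["A0"]] <- min(par16[["A0"]], par16[["K_Abeta"]])
  par16[["taup0"]] <- min(par16[["taup0"]], par16[["K_taup"]])
  par16[["N0"]] <- min(par16[["N0"]], par16[["K_N"]])
  par16[["C0"]] <- min(par16[["C0"]], par16[["K_C"]])
  par16
}

# Model values at every observation age for the full parameter set.
.model_at_obs <- function(par16, record, step) {
  par16 <- .clip_ics(par16)
  tmax <- max(vapply(record$series, function(s) max(s$age), numeric(1)))
  times <- time_grid(50, tmax, step)
  res <- cascade_integrate_cpp(unname(par16[.param_names]),
                               unname(par16[.ic_names]), times,
                               numeric(length(times)), 1e-6)
  if (res$status != 0L) return(NULL)
  lapply(setNames(names(record$series), names(record$series)), function(bm)
    approx(times, res$states[, match(bm, .state_names)],
           xout = record$series[[bm]]$age, rule = 2)$y)
}

.joint_residuals <- function(par16, record, step, weights) {
  mv <- .model_at_obs(par16, record, step)
  if (is.null(mv)) return(rep(1e6, sum(vapply(record$series, nrow, 1L))))
  unlist(lapply(names(record$series), function(bm)
    weights[[bm]] * (mv[[bm]] - record$series[[bm]]$value)), use.names = FALSE)
}

#' Jointly refine all cascade parameters
#'
#' Locally minimizes the pooled sum of squared deviations between the
#' simulated cascade and every observed biomarker/timepoint, over all eleven
#' rates/capacities and five initial conditions, warm-started at the
#' sequential estimate. If the optimizer fails the sequential estimate is
#' returned with a warning flag, never silently.
#'
#' @param record A [longitudinal_record].
#' @param init A [subject_parameters] warm start (from the sequential stages).
#' @param bounds Bounds from [calibration_bounds()].
#' @param step Integration step in years.
#' @param weights Optional named per-biomarker residual weights (default 1;
#'   the pooled objective is unweighted as the biomarker scales already
#'   reflect the measurement units).
#' @param relative_error_form Passed to [relative_error()].
#' @return A `calibration_result`: `params`, `stagewise_sse`,
#'   `joint_objective`, `objective_init`, `relative_errors`, `flags`.
#' @export
fit_joint <- function(record, init, bounds = calibration_bounds(record),
                      step = 0.01, weights = NULL,
                      relative_error_form = c("mad", "rmsre")) {
  nm <- c(.param_names, .ic_names)
  if (is.null(weights))
    weights <- setNames(as.list(rep(1, 5)), .state_names)
  p0 <- unlist(init[nm])
  p0 <- pmin(pmax(p0, bounds$lower[nm]), bounds$upper[nm])
  obj0 <- sum(.joint_residuals(p0, record, step, weights)^2)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, lower = bounds$lower[nm],
                       upper = bounds$upper[nm],
                       fn = .joint_residuals, record = record, step = step,
                       weights = weights,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 300, ftol = 1e-13, ptol = 1e-13)),
    error = function(e) NULL)
  failed <- is.null(fit) || !is.finite(fit$deviance) || fit$deviance > obj0 + 1e-8
  par <- if (failed) p0 else setNames(fit$par, nm)
  obj <- if (failed) obj0 else fit$deviance
  if (failed && !is.null(fit))
    warning("joint refinement did not improve the sequential estimate; keeping it")
  if (is.null(fit))
    warning("joint refinement failed; returning the sequential estimate")
  .calibration_result(par, record, step, obj, obj0,
                      flags = c(joint_failed = failed),
                      relative_error_form = match.arg(relative_error_form))
}

.calibration_result <- function(par16, record, step, obj, obj0, flags,
                                stagewise_sse = NULL,
                                relative_error_form = "mad") {
  par16 <- .clip_ics(par16)
  params <- do.call(subject_parameters,
                    c(as.list(par16[c(.param_names, .ic_names)]), list(T0 = 50)))
  mv <- .model_at_obs(par16, record, step)
  rel <- vapply(names(record$series), function(bm)
    relative_error(mv[[bm]], record$series[[bm]]$value,
                   form = relative_error_form), numeric(1))
  structure(list(subject_id = record$subject_id, params = params,
                 stagewise_sse = stagewise_sse, joint_objective = obj,
                 objective_init = obj0, relative_errors = rel,
                 flags = flags),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration for subject", x$subject_id, "\n")
  cat(sprintf("  joint objective: %.6g (sequential start: %.6g)\n",
              x$joint_objective, x$objective_init))
  cat("  relative errors (%):",
      paste(sprintf("%s %.2f", names(x$relative_errors),
                    100 * x$relative_errors), collapse = ", "), "\n")
  if (any(x$flags)) cat("  flags:", paste(names(x$flags)[x$flags], collapse = ", "), "\n")
  invisible(x)
}

# Initial guess for lambda_Ctau ahead of the joint refinement: the
# sequential stages never estimate it (the C stage holds it at zero), so a
# coarse 1-D grid search plus a 2-parameter (lambda_CN, lambda_Ctau) refit
# supplies a non-degenerate warm start.
.init_lambda_Ctau <- function(record, est, bounds, step) {
  s <- record$series$C
  up <- bounds$upper[["lambda_Ctau"]]
  sse <- function(lct) {
    vals <- .stage_values(c(as.list(est), list(lambda_Ctau = lct)), "C",
                          s$age, 50, step)
    if (is.null(vals)) Inf else sum((vals - s$value)^2)
  }
  cand <- c(0, up * 10^seq(-4, 0, by = 0.5))
  best <- cand[which.min(vapply(cand, sse, numeric(1)))]
  free <- c("lambda_CN", "lambda_Ctau")
  resid_fn <- function(p) {
    vals <- .stage_values(c(as.list(est[setdiff(names(est), free)]),
                            setNames(as.list(p), free)), "C", s$age, 50, step)
    if (is.null(vals)) return(rep(1e6, nrow(s)))
    vals - s$value
  }
  fit <- .lm_fit(resid_fn, list(c(est[["lambda_CN"]], best)),
                 bounds$lower[free], bounds$upper[free])
  setNames(fit$par, free)
}

#' Calibrate one subject (sequential stages, then joint refinement)
#'
#' Runs the full per-subject estimation: amyloid fit from the closed form,
#' then the `taup`, `tauo`, `N`, `C` stages in cascade order with upstream
#' estimates fixed, then (optionally) the joint refinement of all 16
#' quantities warm-started at the sequential estimate. Subjects with fewer
#' than 3 datapoints in any biomarker are excluded with an explicit reason
#' (condition class `adcascade_exclusion`).
#'
#' @param record A [longitudinal_record] covering all five biomarkers.
#' @param group Reference group for bounds/start scales.
#' @param joint If `FALSE`, stop after the sequential stages.
#' @param bounds Optional bounds (default [calibration_bounds()]).
#' @param step Integration step in years.
#' @param weights,relative_error_form Passed to [fit_joint()].
#' @return A `calibration_result`.
#' @export
calibrate_subject <- function(record, group = "AD", joint = TRUE,
                              bounds = NULL, step = 0.01, weights = NULL,
                              relative_error_form = c("mad", "rmsre")) {
  relative_error_form <- match.arg(relative_error_form)
  for (bm in .state_names) .require_points(record, bm)
  if (is.null(bounds)) bounds <- calibration_bounds(record, group)
  ab <- fit_abeta(record, bounds)
  est <- ab$par
  sse <- c(Abeta = ab$sse)
  degen <- c(Abeta = ab$degenerate)
  for (stage in c("taup", "tauo", "N", "C")) {
    st <- fit_stage(stage, record, est, bounds, group, step)
    est <- c(est, st$par)
    sse[[stage]] <- st$sse
    degen[[stage]] <- st$degenerate
  }
  est <- c(est, lambda_Ctau = 0)
  lct <- .init_lambda_Ctau(record, est, bounds, step)
  est[names(lct)] <- lct
  nm <- c(.param_names, .ic_names)
  est <- .clip_ics(pmin(pmax(est[nm], bounds$lower[nm]), bounds$upper[nm]))
  init <- do.call(subject_parameters,
                  c(as.list(est), list(T0 = 50)))
  if (joint) {
    out <- fit_joint(record, init, bounds, step, weights, relative_error_form)
  } else {
    obj0 <- sum(.joint_residuals(est, record, step,
                                 setNames(as.list(rep(1, 5)), .state_names))^2)
    out <- .calibration_result(est, record, step, obj0, obj0,
                               flags = c(joint_failed = FALSE),
                               relative_error_form = relative_error_form)
  }
  out$stagewise_sse <- sse
  out$flags <- c(out$flags, degenerate_stages = any(degen))
  out$degenerate_stages <- names(degen)[degen]
  out
}

#' Calibrate a cohort of subjects
#'
#' Applies [calibrate_subject()] to each record, collecting exclusions
#' (too few datapoints) separately with their reasons.
#'
#' @param records Named list of [longitudinal_record]s.
#' @param groups Single group label or named vector mapping subject ids to
#'   groups.
#' @param ... Passed to [calibrate_subject()].
#' @return List with `results` (named list of `calibration_result`s) and
#'   `exclusions` (named character vector of reasons).
#' @export
calibrate_cohort <- function(records, groups = "AD", ...) {
  results <- list(); exclusions <- character(0)
  for (id in names(records)) {
    g <- if (length(groups) == 1L) groups else groups[[id]]
    res <- tryCatch(calibrate_subject(records[[id]], group = g, ...),
                    adcascade_exclusion = function(e) conditionMessage(e))
    if (is.character(res)) exclusions[[id]] <- res else results[[id]] <- res
  }
  list(results = results, exclusions = exclusions)
}

#' Tabulate calibration results
#'
#' One row per subject with the 16 fitted quantities, per-biomarker relative
#' errors (percent) and the joint objective, mirroring a cohort parameter
#' table.
#'
#' @param results Named list of `calibration_result`s (as returned in
#'   `calibrate_cohort()$results`).
#' @param groups Optional group labels per subject.
#' @return A data frame.
#' @export
calibration_table <- function(results, groups = NULL) {
  rows <- lapply(names(results), function(id) {
    r <- results[[id]]
    v <- unlist(r$params[c(.param_names, .ic_names)])
    cbind(data.frame(subject_id = id,
                     group = if (is.null(groups)) NA_character_
                             else unname(groups[[id]])),
          as.data.frame(as.list(v)),
          setNames(as.data.frame(as.list(100 * r$relative_errors)),
                   paste0("rel_err_", names(r$relative_errors))),
          data.frame(joint_objective = r$joint_objective))
  })
  do.call(rbind, rows)
}

#' Cohort summary (mean and standard deviation per group)
#'
#' @param tab Output of [calibration_table()].
#' @return Data frame with one row per group x parameter: mean, sd, n.
#' @export
calibration_summary <- function(tab) {
  num <- setdiff(names(tab), c("subject_id", "group"))
  do.call(rbind, lapply(split(tab, tab$group), function(d)
    data.frame(group = d$group[1], parameter = num,
               mean = vapply(d[num], mean, numeric(1)),
               sd = vapply(d[num], stats::sd, numeric(1)),
               n = nrow(d), row.names = NULL)))
}
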