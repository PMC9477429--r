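# Five-state biomarker cascade model and its fixed-grid RK4 integration.
# Time unit is YEARS throughout the model core; weekly clinical-trial rates
# are converted at the dose-calibration boundary (rate/year = 52 * rate/week).

#' Subject-level cascade model parameters
#'
#' Bundles the eleven rate/capacity parameters of the biomarker cascade, the
#' five initial conditions, and the reference age at which the initial
#' conditions apply. The cascade states are amyloid-beta (`Abeta`),
#' phosphorylated tau (`taup`), non-amyloid (age-related) tauopathy (`tauo`),
#' neurodegeneration (`N`) and cognitive impairment (`C`).
#'
#' @param lambda_Abeta Amyloid logistic growth rate (1/year).
#' @param K_Abeta Amyloid carrying capacity (biomarker units).
#' @param lambda_tau Amyloid-driven p-tau production rate (1/year).
#' @param K_taup P-tau carrying capacity.
#' @param lambda_tauo Linear growth rate of non-amyloid tauopathy (units/year).
#' @param lambda_N_tauo,lambda_N_taup Rates at which tauo/p-tau drive
#'   neurodegeneration (1/year per tau unit).
#' @param K_N Neurodegeneration carrying capacity.
#' @param lambda_CN,lambda_Ctau Rates at which neurodegeneration/p-tau drive
#'   cognitive decline (1/year per unit).
#' @param K_C Cognitive-score carrying capacity.
#' @param A0,taup0,tauo0,N0,C0 Initial state values at the reference age.
#' @param T0 Reference age in years (default 50, just below the youngest
#'   baseline age seen in typical cohorts).
#' @return An object of class `subject_parameters`.
#' @export
subject_parameters <- function(lambda_Abeta, K_Abeta, lambda_tau, K_taup,
                               lambda_tauo, lambda_N_tauo, lambda_N_taup,
                               K_N, lambda_CN, lambda_Ctau, K_C,
                               A0, taup0, tauo0, N0, C0, T0 = 50) {
  p <- list(lambda_Abeta = lambda_Abeta, K_Abeta = K_Abeta,
            lambda_tau = lambda_tau, K_taup = K_taup,
            lambda_tauo = lambda_tauo, lambda_N_tauo = lambda_N_tauo,
            lambda_N_taup = lambda_N_taup, K_N = K_N,
            lambda_CN = lambda_CN, lambda_Ctau = lambda_Ctau, K_C = K_C,
            A0 = A0, taup0 = taup0, tauo0 = tauo0, N0 = N0, C0 = C0,
            T0 = T0)
  p <- lapply(p, as.numeric)
  validate_subject_parameters(p)
  structure(p, class = "subject_parameters")
}

validate_subject_parameters <- function(p) {
  num <- unlist(p)
  if (any(!is.finite(num)))
    stop("subject parameters must be finite numbers", call. = FALSE)
  rates <- c("lambda_Abeta", "lambda_tau", "lambda_tauo", "lambda_N_tauo",
             "lambda_N_taup", "lambda_CN", "lambda_Ctau")
  caps <- c("K_Abeta", "K_taup", "K_N", "K_C")
  if (any(num[rates] < 0)) stop("rate parameters must be >= 0", call. = FALSE)
  if (any(num[caps] <= 0)) stop("carrying capacities must be > 0", call. = FALSE)
  if (any(num[.ic_names] < 0)) stop("initial conditions must be >= 0", call. = FALSE)
  if (num["A0"] > num["K_Abeta"]) stop("A0 must not exceed K_Abeta", call. = FALSE)
  if (num["taup0"] > num["K_taup"]) stop("taup0 must not exceed K_taup", call. = FALSE)
  if (num["N0"] > num["K_N"]) stop("N0 must not exceed K_N", call. = FALSE)
  if (num["C0"] > num["K_C"]) stop("C0 must not exceed K_C", call. = FALSE)
  if (num["T0"] < 0) stop("T0 must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.subject_parameters <- function(x, ...) {
  cat("Cascade model parameters (reference age T0 =", x$T0, "years)\n")
  v <- unlist(x[c(.param_names, .ic_names)])
  print(signif(v, 4))
  invisible(x)
}

# parameter vector in the order used by the compiled integrator
.par_vec <- function(params) unlist(params[.param_names], use.names = FALSE)
.ic_vec <- function(params) unlist(params[.ic_names], use.names = FALSE)

#' Cascade model right-hand side
#'
#' Time derivative of the five-state cascade at one state point, optionally
#' under an anti-amyloid clearance rate `u` (1/year) that removes amyloid
#' proportionally to its level.
#'
#' @param state Named numeric vector with components `Abeta`, `taup`,
#'   `tauo`, `N`, `C`, all nonnegative.
#' @param params A [subject_parameters] object.
#' @param u Clearance rate (1/year), nonnegative scalar.
#' @return Named numeric vector of time derivatives (units/year).
#' @export
cascade_rhs <- function(state, params, u = 0) {
  state <- state[.state_names]
  if (any(is.na(state))) stop("state must have components Abeta, taup, tauo, N, C")
  if (any(state < 0)) stop("state components must be >= 0")
  if (length(u) != 1L || !is.finite(u) || u < 0) stop("u must be a nonnegative scalar")
  A <- state[["Abeta"]]; taup <- state[["taup"]]; tauo <- state[["tauo"]]
  N <- state[["N"]]; C <- state[["C"]]
  c(Abeta = params$lambda_Abeta * A * (1 - A / params$K_Abeta) - u * A,
    taup = params$lambda_tau * A * (1 - taup / params$K_taup),
    tauo = params$lambda_tauo,
    N = (params$lambda_N_tauo * tauo + params$lambda_N_taup * taup) *
      (1 - N / params$K_N),
    C = (params$lambda_CN * N + params$lambda_Ctau * taup) *
      (1 - C / params$K_C))
}

#' Closed-form untreated amyloid trajectory
#'
#' Logistic-growth solution of the untreated amyloid equation:
#' `K / (C1 * exp(-lambda * (t - T0)) + 1)` with `C1 = K/A0 - 1`.
#' `A0 = 0` is the trivial fixed point (identically zero).
#'
#' @param t Ages in years (vector allowed), all `>= T0`.
#' @param params A [subject_parameters] object with `lambda_Abeta > 0`
#'   requirements relaxed to `>= 0`.
#' @return Amyloid values at `t`, in `(0, K_Abeta]` for `A0 > 0`.
#' @export
analytic_abeta <- function(t, params) {
  if (any(t < params$T0 - 1e-9)) stop("t must be >= T0")
  A0 <- params$A0; K <- params$K_Abeta
  if (A0 == 0) return(rep(0, length(t)))
  if (A0 > K) stop("A0 must not exceed K_Abeta")
  C1 <- K / A0 - 1
  K / (C1 * exp(-params$lambda_Abeta * (t - params$T0)) + 1)
}

# Uniform time grid anchored at both endpoints; the step is adjusted to the
# nearest value that divides the interval evenly.
time_grid <- function(t_start, t_end, step) {
  stopifnot(t_end > t_start, step > 0)
  n <- max(1L, as.integer(round((t_end - t_start) / step)))
  if (abs(n * step - (t_end - t_start)) > 1e-8 * max(1, abs(t_end - t_start)))
    n <- max(1L, as.integer(ceiling((t_end - t_start) / step - 1e-9)))
  seq(t_start, t_end, length.out = n + 1L)
}

.integrate_grid <- function(params, y0, times, u) {
  res <- cascade_integrate_cpp(.par_vec(params), y0, times, u, 1e-12)
  if (res$status == 1L)
    stop(sprintf("state component %s went negative beyond round-off at age %.4f",
                 .state_names[res$component], res$bad_time), call. = FALSE)
  if (res$status == 2L)
    stop(sprintf("integration failure (non-finite %s) at age %.4f",
                 .state_names[res$component], res$bad_time), call. = FALSE)
  colnames(res$states) <- .state_names
  res$states
}

#' Simulate the biomarker cascade
#'
#' Integrates the cascade with classical fixed-step 4th-order Runge-Kutta on
#' a uniform age grid. If `t_start > T0`, the subject is first integrated
#' untreated from the reference age `T0` to `t_start` (pre-treatment
#' burn-in), so the state at `t_start` is model-consistent.
#'
#' @param params A [subject_parameters] object.
#' @param t_start,t_end Simulation window in years of age;
#'   `t_start >= T0`, `t_end > t_start`.
#' @param control Clearance rate over `[t_start, t_end]`: `NULL` (untreated),
#'   a single nonnegative number, a function of age, or a numeric vector of
#'   values at the grid points (interpolated linearly between them).
#' @param step Grid spacing in years (default 0.01).
#' @return A `biomarker_trajectory` data frame with columns `age`, `Abeta`,
#'   `taup`, `tauo`, `N`, `C`, starting exactly at `t_start`.
#' @export
simulate_cascade <- function(params, t_start = params$T0, t_end,
                             control = NULL, step = 0.01) {
  stopifnot(t_end > t_start)
  if (t_start < params$T0) stop("t_start must be >= T0")
  y0 <- .ic_vec(params)
  if (t_start > params$T0 + 1e-9) {
    burn <- time_grid(params$T0, t_start, step)
    y0 <- .integrate_grid(params, y0, burn, numeric(length(burn)))[length(burn), ]
  }
  times <- time_grid(t_start, t_end, step)
  u <- control_on_grid(control, times)
  states <- .integrate_grid(params, y0, times, u)
  traj <- data.frame(age = times, states)
  class(traj) <- c("biomarker_trajectory", "data.frame")
  traj
}

# Resolve a control specification to grid-point values.
control_on_grid <- function(control, times) {
  u <- if (is.null(control)) numeric(length(times))
  else if (is.function(control)) vapply(times, control, numeric(1))
  else if (length(control) == 1L) rep(as.numeric(control), length(times))
  else as.numeric(control)
  if (length(u) != length(times))
    stop("control vector must match the time grid length")
  if (any(!is.finite(u)) || any(u < 0))
    stop("control values must be finite and >= 0")
  u
}

# Linear interpolation of trajectory states at arbitrary ages.
interp_trajectory <- function(traj, ages) {
  out <- vapply(.state_names, function(nm)
    approx(traj$age, traj[[nm]], xout = ages, rule = 2)$y,
    numeric(length(ages)))
  if (length(ages) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, .state_names))
  out
}

#' Write a trajectory as tidy delimited text
#'
#' @param traj A `biomarker_trajectory` (from [simulate_cascade()]).
#' @param subject_id Subject label recorded in the first column.
#' @param path Output file path (tab-separated).
#' @export
write_trajectory <- function(traj, subject_id, path) {
  out <- data.frame(subject_id = subject_id, traj)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize subject parameters as a flat key-value block
#'
#' One `name value` pair per line, using the field names of
#' [subject_parameters()].
#'
#' @param params A [subject_parameters] object.
#' @param path File to write.
#' @export
write_subject_parameters <- function(params, path) {
  v <- unlist(params[c(.param_names, .ic_names, "T0")])
  writeLines(sprintf("%s %.17g", names(v), v), path)
  invisible(path)
}

#' @rdname write_subject_parameters
#' @export
read_subject_parameters <- function(path) {
  kv <- read.table(path, header = FALSE, col.names = c("key", "value"),
                   stringsAsFactors = FALSE)
  vals <- setNames(as.list(kv$value), kv$key)
  do.call(subject_parameters, vals)
}
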