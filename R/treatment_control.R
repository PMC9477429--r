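# Personalized optimal anti-amyloid-beta therapy via Pontryagin's maximum
# principle. The objective penalizes terminal amyloid and cognition, the
# running cognitive burden, and a side-effect term eps(Abeta, t) * u^2 whose
# weight is proportional to the current amyloid burden and decays with time
# on treatment. The optimality system (state equations forward, adjoint
# equations backward, pointwise control characterization) is solved by a
# relaxed forward-backward sweep on one shared fixed RK4 grid.

#' Optimal-control configuration
#'
#' @param u_max Maximum clearance rate (1/year), `>= 0`.
#' @param T1,T2 Treatment start and end ages in years, `T2 > T1`.
#' @param alpha1,alpha2 Terminal weights on amyloid and cognition (default 1).
#' @param eps0 Side-effect scale (default 5).
#' @param gamma Side-effect decay rate per year of treatment (default 2).
#' @param step Grid spacing in years (default 0.01).
#' @param relax Sweep relaxation weight in `(0, 1]` for the convex
#'   combination of old and new controls (default 0.5).
#' @param tol Convergence tolerance on the relative sup-norm change of
#'   states, adjoints and control (default 1e-4).
#' @param max_iter Iteration cap (default 500).
#' @param adjoint_form `"derived"` (full `-dH/dC`, the default) or
#'   `"printed"` (drops the `lambda_Ctau * taup / K_C` feedback term in the
#'   cognition adjoint, reproducing a commonly quoted reduced form).
#' @return An `oc_config` object.
#' @export
oc_config <- function(u_max, T1, T2, alpha1 = 1, alpha2 = 1, eps0 = 5,
                      gamma = 2, step = 0.01, relax = 0.5, tol = 1e-4,
                      max_iter = 500, adjoint_form = c("derived", "printed")) {
  adjoint_form <- match.arg(adjoint_form)
  stopifnot(u_max >= 0, T2 > T1, step > 0, relax > 0, relax <= 1, tol > 0,
            max_iter >= 1, eps0 >= 0, gamma >= 0)
  structure(list(u_max = u_max, T1 = T1, T2 = T2, alpha1 = alpha1,
                 alpha2 = alpha2, eps0 = eps0, gamma = gamma, step = step,
                 relax = relax, tol = tol, max_iter = as.integer(max_iter),
                 adjoint_form = adjoint_form),
            class = "oc_config")
}

#' Side-effect weight
#'
#' `eps = eps0 * Abeta * exp(-gamma * t_since_start)`: anti-amyloid
#' side-effect risk (ARIA-like) scales with current amyloid burden and
#' decays over time on treatment.
#'
#' @param Abeta Amyloid level, `>= 0`.
#' @param t_since_start Years since treatment start.
#' @param eps0,gamma Scale and decay rate.
#' @return Nonnegative weight.
#' @export
side_effect_weight <- function(Abeta, t_since_start, eps0 = 5, gamma = 2) {
  if (any(Abeta < 0)) stop("Abeta must be >= 0")
  eps0 * Abeta * exp(-gamma * t_since_start)
}

#' Treatment objective functional
#'
#' `alpha1 * Abeta(T2) + alpha2 * C(T2) + int C dt + int eps * u^2 dt`,
#' integrals by the composite trapezoid rule on the grid.
#'
#' @param states A `biomarker_trajectory` on the treatment grid
#'   (first age = `T1`, last age = `T2`).
#' @param u Control values on the same grid.
#' @param cfg An [oc_config].
#' @return Scalar objective value.
#' @export
oc_objective <- function(states, u, cfg) {
  t <- states$age
  if (length(u) != length(t)) stop("control and state grids must match")
  if (abs(t[1] - cfg$T1) > 1e-8 || abs(t[length(t)] - cfg$T2) > 1e-8)
    stop("state grid must span [T1, T2]")
  trapz <- function(y) sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
  eps <- side_effect_weight(states$Abeta, t - cfg$T1, cfg$eps0, cfg$gamma)
  cfg$alpha1 * states$Abeta[length(t)] + cfg$alpha2 * states$C[length(t)] +
    trapz(states$C) + trapz(eps * u^2)
}

#' Adjoint (costate) right-hand side
#'
#' Time derivatives `dL/dt = -dH/dx` of the five adjoint variables for the
#' Hamiltonian of the treatment problem, with terminal (transversality)
#' conditions `L1(T2) = alpha1`, `L5(T2) = alpha2`, others zero.
#'
#' @param state Named state vector (`Abeta`, `taup`, `tauo`, `N`, `C`).
#' @param adj Numeric adjoint vector `(L1..L5)`.
#' @param u Clearance rate (1/year).
#' @param t_since_start Years since treatment start (side-effect clock).
#' @param params A [subject_parameters].
#' @param cfg An [oc_config] (uses `eps0`, `gamma`, `adjoint_form`).
#' @return Numeric vector `dL/dt` of length 5.
#' @export
adjoint_rhs <- function(state, adj, u, t_since_start, params, cfg) {
  state <- state[.state_names]
  A <- state[["Abeta"]]; taup <- state[["taup"]]; tauo <- state[["tauo"]]
  N <- state[["N"]]; C <- state[["C"]]
  L <- as.numeric(adj)
  p <- params
  dL1 <- -cfg$eps0 * exp(-cfg$gamma * t_since_start) * u^2 +
    L[1] * (2 * p$lambda_Abeta * A / p$K_Abeta - p$lambda_Abeta + u) -
    L[2] * p$lambda_tau * (1 - taup / p$K_taup)
  dL2 <- L[2] * p$lambda_tau * A / p$K_taup -
    L[4] * p$lambda_N_taup * (1 - N / p$K_N) -
    L[5] * p$lambda_Ctau * (1 - C / p$K_C)
  dL3 <- -L[4] * p$lambda_N_tauo * (1 - N / p$K_N)
  dL4 <- L[4] * (p$lambda_N_tauo * tauo + p$lambda_N_taup * taup) / p$K_N -
    L[5] * p$lambda_CN * (1 - C / p$K_C)
  dL5 <- -1 + L[5] * p$lambda_CN * N / p$K_C
  if (cfg$adjoint_form == "derived")
    dL5 <- dL5 + L[5] * p$lambda_Ctau * taup / p$K_C
  c(dL1, dL2, dL3, dL4, dL5)
}

#' Pointwise optimal-control update
#'
#' The interior stationarity condition `dH/du = 2*eps*u - Abeta*L1 = 0`
#' gives `u = L1 * Abeta / (2 * eps)`, clamped to the admissible box
#' `[0, u_max]`. The degenerate case `eps = 0` returns the appropriate
#' box endpoint (bang control).
#'
#' @param Abeta Amyloid level(s).
#' @param L1 Amyloid adjoint value(s).
#' @param eps Side-effect weight(s), `>= 0`.
#' @param u_max Upper control bound.
#' @return Control value(s) in `[0, u_max]`.
#' @export
control_update <- function(Abeta, L1, eps, u_max) {
  raw <- ifelse(eps > 0, L1 * Abeta / (2 * eps),
                ifelse(L1 * Abeta > 0, u_max, 0))
  pmin(u_max, pmax(0, raw))
}

#' Solve the personalized optimal-treatment problem
#'
#' Forward-backward sweep: starting from the zero control, iterate
#' (i) forward state integration on `[T1, T2]` (preceded by an untreated
#' burn-in from the reference age `T0`, so the state at `T1` is
#' model-consistent), (ii) backward adjoint integration with the
#' transversality conditions, (iii) the pointwise control characterization,
#' and (iv) a relaxed convex-combination control update, until the maximum
#' relative sup-norm change over states, adjoints and control is below
#' `tol`. If the objective increases for 5 consecutive iterations the
#' relaxation weight is halved (logged via `message()`).
#'
#' @param params A [subject_parameters].
#' @param cfg An [oc_config] with `T1 >= params$T0`.
#' @return A `control_solution`: `times`, `u`, `states`
#'   (`biomarker_trajectory`), `adjoints` (data frame `L1..L5`),
#'   `objective`, `iterations`, `converged`, `history` (objective per
#'   sweep iteration).
#' @export
forward_backward_sweep <- function(params, cfg) {
  if (cfg$T1 < params$T0) stop("treatment start T1 must be >= T0")
  y0 <- .ic_vec(params)
  if (cfg$T1 > params$T0 + 1e-9) {
    burn <- time_grid(params$T0, cfg$T1, cfg$step)
    y0 <- .integrate_grid(params, y0, burn, numeric(length(burn)))[length(burn), ]
  }
  times <- time_grid(cfg$T1, cfg$T2, cfg$step)
  n <- length(times)
  pv <- .par_vec(params)
  derived <- cfg$adjoint_form == "derived"
  u <- numeric(n)
  states <- .integrate_grid(params, y0, times, u)
  adjoints <- matrix(0, n, 5)
  relax <- cfg$relax
  history <- numeric(0)
  bad_run <- 0L
  converged <- FALSE
  iter <- 0L
  relchange <- function(new, old)
    max(abs(new - old)) / (max(abs(old)) + 1e-12)
  for (iter in seq_len(cfg$max_iter)) {
    old_states <- states; old_adj <- adjoints; old_u <- u
    states <- .integrate_grid(params, y0, times, u)
    adjoints <- adjoint_integrate_cpp(pv, states, times, u, cfg$eps0,
                                      cfg$gamma, cfg$alpha1, cfg$alpha2,
                                      cfg$T1, derived)
    eps <- side_effect_weight(states[, "Abeta"], times - cfg$T1,
                              cfg$eps0, cfg$gamma)
    u_new <- control_update(states[, "Abeta"], adjoints[, 1], eps, cfg$u_max)
    u <- relax * u_new + (1 - relax) * old_u
    obj <- oc_objective(data.frame(age = times, states), u, cfg)
    history <- c(history, obj)
    if (length(history) >= 2 && obj > history[length(history) - 1]) {
      bad_run <- bad_run + 1L
      if (bad_run >= 5L) {
        relax <- relax / 2
        bad_run <- 0L
        message(sprintf("objective increased 5 consecutive sweeps; relaxation halved to %.3g", relax))
      }
    } else bad_run <- 0L
    err <- max(relchange(states, old_states), relchange(adjoints, old_adj),
               relchange(u, old_u))
    if (err <= cfg$tol) { converged <- TRUE; break }
  }
  states <- .integrate_grid(params, y0, times, u)
  adjoints <- adjoint_integrate_cpp(pv, states, times, u, cfg$eps0,
                                    cfg$gamma, cfg$alpha1, cfg$alpha2,
                                    cfg$T1, derived)
  traj <- data.frame(age = times, states)
  class(traj) <- c("biomarker_trajectory", "data.frame")
  structure(list(times = times, u = u, states = traj,
                 adjoints = setNames(as.data.frame(adjoints),
                                     paste0("L", 1:5)),
                 objective = oc_objective(traj, u, cfg),
                 iterations = iter, converged = converged,
                 history = history, config = cfg),
            class = "control_solution")
}

#' @export
print.control_solution <- function(x, ...) {
  cat(sprintf("Optimal-control solution on [%.4g, %.4g] (%d grid points)\n",
              x$times[1], x$times[length(x$times)], length(x$times)))
  cat(sprintf("  objective %.6g after %d sweeps (%s)\n", x$objective,
              x$iterations, if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  control range [%.3g, %.3g] /year (u_max %.3g)\n",
              min(x$u), max(x$u), x$config$u_max))
  invisible(x)
}

#' Write a control solution as tidy delimited text
#'
#' Columns: age, u, the five states and the five adjoints, plus a
#' `# objective/iterations/converged` comment header.
#'
#' @param sol A `control_solution`.
#' @param path Output file (tab-separated).
#' @export
write_control_solution <- function(sol, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# objective=%.10g iterations=%d converged=%s",
                     sol$objective, sol$iterations, sol$converged), con)
  out <- cbind(data.frame(age = sol$times, u = sol$u),
               sol$states[.state_names], sol$adjoints)
  suppressWarnings(write.table(out, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Objective of an arbitrary fixed control
#'
#' Convenience wrapper: burn-in to `T1`, integrate with the given control,
#' and evaluate the objective. Used for comparing the optimized control
#' against references such as no treatment or constant maximal dosing.
#'
#' @param params A [subject_parameters].
#' @param cfg An [oc_config].
#' @param control As in [simulate_cascade()].
#' @return Scalar objective value.
#' @export
oc_objective_for_control <- function(params, cfg, control = NULL) {
  traj <- simulate_cascade(params, t_start = cfg$T1, t_end = cfg$T2,
                           control = control, step = cfg$step)
  u <- control_on_grid(control, traj$age)
  oc_objective(traj, u, cfg)
}
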