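# Synthetic longitudinal cohort generator. Emulates the sampling design of a
# multicenter natural-history study: CSF-like biomarkers (Abeta, taup, tauo)
# every 2 years up to 10 years, volumetric neurodegeneration yearly, and
# cognition every 6 months, with baseline ages >= 54 and known ground-truth
# parameters for every subject.

#' Reference group-level parameter profiles
#'
#' Published group-level means and standard deviations of the cascade
#' parameters and initial conditions (at reference age 50) for clinically
#' diagnosed Alzheimer's disease (AD, n = 10), late mild cognitive
#' impairment (LMCI, n = 32) and cognitively normal (CN, n = 7) groups.
#' These are the sampling defaults of the synthetic cohort generator.
#'
#' @return Named list with one element per group, each containing `n`,
#'   `mean` and `sd` vectors over the 16 subject-level quantities.
#' @export
cohort_group_defaults <- function() {
  nm <- c(.ic_names, .param_names)
  mk <- function(n, mean, sd) list(n = n, mean = setNames(mean, nm),
                                   sd = setNames(sd, nm))
  list(
    AD = mk(10,
      c(36.03, 12.38, 66.70, 0.26, 3.68,
        0.1835, 259.44, 0.15, 123.35, 1.15, 3.75e-4, 6.90e-3, 1.00, 1.67, 3.83, 169.48),
      c(26.52, 14.47, 58.57, 0.08, 8.30,
        0.0311, 13.21, 0.16, 81.63, 1.70, 1.22e-4, 1.49e-3, 0.01, 2.40, 8.00, 63.35)),
    LMCI = mk(32,
      c(41.57, 4.21, 28.66, 0.48, 6.03,
        0.1612, 264.99, 0.08, 131.66, 1.74, 4.24e-4, 7.37e-3, 1.02, 1.26, 1.93, 129.40),
      c(24.23, 7.68, 33.13, 0.26, 6.56,
        0.0503, 74.69, 0.12, 75.89, 2.08, 1.03e-4, 1.07e-3, 0.05, 1.99, 3.91, 84.31)),
    CN = mk(7,
      c(44.92, 3.69, 24.25, 0.42, 2.58,
        0.1682, 276.21, 0.12, 126.53, 0.87, 4.41e-4, 7.24e-3, 1.03, 3.16, 2.48, 59.89),
      c(24.54, 6.15, 26.98, 0.10, 2.60,
        0.0552, 88.29, 0.17, 91.31, 0.66, 0.89e-4, 1.73e-3, 0.07, 3.06, 3.94, 80.03))
  )
}

#' Default per-biomarker visit schedules
#'
#' Visit offsets in years from the baseline visit: CSF-like biomarkers every
#' 2 years over 10 years (6 visits), neurodegeneration yearly (11 visits),
#' cognition every 6 months (21 visits).
#' @return Named list of numeric offset vectors.
#' @export
default_schedule <- function() {
  list(Abeta = seq(0, 10, by = 2), taup = seq(0, 10, by = 2),
       tauo = seq(0, 10, by = 2), N = seq(0, 10, by = 1),
       C = seq(0, 10, by = 0.5))
}

#' Specification of a synthetic cohort
#'
#' @param n_subjects Named integer vector of subjects per group; names must
#'   exist in `groups`. Defaults to the published group sizes.
#' @param groups Group parameter profiles, as [cohort_group_defaults()].
#' @param schedule Named list of per-biomarker visit offsets (years from
#'   baseline); every biomarker needs at least 3 visits.
#' @param age_range Baseline age range (years), sampled uniformly.
#' @param cv Per-biomarker coefficient of variation of multiplicative
#'   Gaussian observation noise.
#' @param seed Integer seed making cohort generation reproducible.
#' @param step Integration step (years) used when simulating trajectories.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects = c(AD = 10, LMCI = 32, CN = 7),
                        groups = cohort_group_defaults(),
                        schedule = default_schedule(),
                        age_range = c(54, 85),
                        cv = c(Abeta = 0.05, taup = 0.05, tauo = 0.05,
                               N = 0.01, C = 0.10),
                        seed = 1L, step = 0.01) {
  stopifnot(all(names(n_subjects) %in% names(groups)), all(n_subjects >= 1))
  if (any(vapply(schedule, length, 1L) < 3L))
    stop("every biomarker schedule must yield at least 3 visits")
  stopifnot(all(cv[.state_names] >= 0), length(age_range) == 2,
            age_range[1] >= 50, diff(age_range) >= 0)
  structure(list(n_subjects = n_subjects, groups = groups,
                 schedule = schedule, age_range = age_range,
                 cv = cv, seed = as.integer(seed), step = step),
            class = "cohort_spec")
}

# Truncated-normal draw on [lo, hi] by inverse-CDF sampling.
rtruncnorm <- function(n, mean, sd, lo = 1e-6, hi = Inf) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  q <- stats::qnorm(plo + runif(n) * (phi - plo), mean, sd)
  pmin(pmax(q, lo), hi)  # guards against qnorm round-off at the tails
}

#' Sample ground-truth subject parameters for one group
#'
#' Each parameter is drawn independently from a normal with the group's
#' mean and standard deviation, truncated below at 1e-6 to keep the cascade
#' well-posed; initial conditions are additionally truncated above at the
#' subject's sampled carrying capacity. Uses the current RNG state — seed
#' via [synthesize_cohort()] or `set.seed()` for reproducibility.
#'
#' @param spec A [cohort_spec].
#' @param group Group label present in `spec$groups`.
#' @param n Number of subjects (defaults to the group's entry in
#'   `spec$n_subjects`).
#' @return List of [subject_parameters].
#' @export
sample_parameters <- function(spec, group, n = spec$n_subjects[[group]]) {
  g <- spec$groups[[group]]
  if (is.null(g)) stop("unknown group '", group, "'")
  draw <- function(nm, hi = Inf) rtruncnorm(1, g$mean[[nm]], g$sd[[nm]], hi = hi)
  lapply(seq_len(n), function(i) {
    p <- setNames(lapply(.param_names, draw), .param_names)
    ics <- list(A0 = draw("A0", hi = p$K_Abeta),
                taup0 = draw("taup0", hi = p$K_taup),
                tauo0 = draw("tauo0"),
                N0 = draw("N0", hi = p$K_N),
                C0 = draw("C0", hi = p$K_C))
    do.call(subject_parameters, c(p, ics, list(T0 = 50)))
  })
}

#' Generate longitudinal records for known subjects
#'
#' Simulates each subject untreated from the reference age, samples the
#' trajectory at each biomarker's visit ages (baseline age + schedule
#' offsets), and applies multiplicative Gaussian noise
#' `value * (1 + cv * z)`. Baseline ages are drawn uniformly from
#' `spec$age_range` and rounded to 0.01 years. Uses the current RNG state.
#'
#' @param subjects List of [subject_parameters].
#' @param spec A [cohort_spec].
#' @param ids Subject labels (default `S1`, `S2`, ...).
#' @return List of `longitudinal_record` objects with a `baseline_age`
#'   attribute on each record.
#' @export
generate_records <- function(subjects, spec, ids = paste0("S", seq_along(subjects))) {
  stopifnot(length(ids) == length(subjects))
  horizon <- max(unlist(spec$schedule))
  Map(function(params, id) {
    baseline <- round(runif(1, spec$age_range[1], spec$age_range[2]), 2)
    traj <- simulate_cascade(params, t_start = params$T0,
                             t_end = baseline + horizon, step = spec$step)
    series <- lapply(.state_names, function(bm) {
      ages <- baseline + spec$schedule[[bm]]
      vals <- interp_trajectory(traj, ages)[, bm]
      noisy <- vals * (1 + spec$cv[[bm]] * rnorm(length(vals)))
      data.frame(age = ages, value = pmax(noisy, 1e-8))
    })
    rec <- longitudinal_record(id, setNames(series, .state_names))
    attr(rec, "baseline_age") <- baseline
    rec
  }, subjects, ids)
}

#' Generate a complete synthetic cohort
#'
#' Seeds the RNG from `spec$seed`, samples ground-truth parameters for every
#' group, and generates noisy longitudinal records. The same spec always
#' yields the identical cohort.
#'
#' @param spec A [cohort_spec].
#' @return List with elements `parameters` (named list of
#'   [subject_parameters]), `records` (named list of longitudinal records),
#'   `groups` (named character vector of group labels), and `truth` (tidy
#'   data frame of the ground-truth parameter values).
#' @export
synthesize_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  parameters <- list(); groups <- character(0)
  for (g in names(spec$n_subjects)) {
    ps <- sample_parameters(spec, g)
    names(ps) <- sprintf("%s%d", g, seq_along(ps))
    parameters <- c(parameters, ps)
    groups <- c(groups, setNames(rep(g, length(ps)), names(ps)))
  }
  records <- generate_records(parameters, spec, ids = names(parameters))
  names(records) <- names(parameters)
  truth <- do.call(rbind, lapply(names(parameters), function(id) {
    v <- unlist(parameters[[id]][c(.param_names, .ic_names)])
    data.frame(subject_id = id, group = groups[[id]],
               parameter = names(v), value = unname(v))
  }))
  list(parameters = parameters, records = records, groups = groups,
       truth = truth)
}
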