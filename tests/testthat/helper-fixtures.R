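# Fixtures are built in code at test time; no stored data.

# Subject at the published AD-group mean parameters.
ad_mean_parameters <- function() {
  gm <- cohort_group_defaults()$AD$mean
  do.call(subject_parameters,
          c(as.list(gm[c(adcascade:::.param_names, adcascade:::.ic_names)]),
            list(T0 = 50)))
}

# Identifiable-regime subject for generate-and-refit oracles: every state
# traverses most of its dynamic range within the observation window and the
# neurodegeneration/cognition drivers (linear tauo vs sigmoid taup vs
# sigmoid N) have distinguishable shapes, so all 16 quantities carry
# information. Cognition does NOT saturate before the trial ages, so
# treatment-effect orderings are informative too.
oracle_subject <- function() {
  subject_parameters(lambda_Abeta = 0.15, K_Abeta = 250, lambda_tau = 0.10,
                     K_taup = 100, lambda_tauo = 1.2, lambda_N_tauo = 1e-3,
                     lambda_N_taup = 4e-3, K_N = 1, lambda_CN = 1.2,
                     lambda_Ctau = 0.05, K_C = 60, A0 = 40, taup0 = 15,
                     tauo0 = 25, N0 = 0.3, C0 = 8, T0 = 50)
}

# Long dense design observed from the reference age (an algorithm-validation
# design, richer than a clinical follow-up schedule).
oracle_schedule <- function(horizon = 30) {
  list(Abeta = seq(0, horizon, 2), taup = seq(0, horizon, 2),
       tauo = seq(0, horizon, 2), N = seq(0, horizon, 1),
       C = seq(0, horizon, 0.5))
}

# Noise-free record sampled exactly from the model trajectory.
noiseless_record <- function(params, baseline = 50,
                             schedule = oracle_schedule(), id = "fx",
                             step = 0.01) {
  horizon <- max(unlist(schedule))
  traj <- simulate_cascade(params, t_start = params$T0,
                           t_end = baseline + horizon, step = step)
  series <- lapply(setNames(names(schedule), names(schedule)), function(bm) {
    ages <- baseline + schedule[[bm]]
    data.frame(age = ages,
               value = adcascade:::interp_trajectory(traj, ages)[, bm])
  })
  longitudinal_record(id, series)
}

# Per-biomarker scale weights for the joint refinement (series differ by
# orders of magnitude).
scale_weights <- function(record)
  lapply(record$series, function(s) 1 / max(s$value))

param_names16 <- function() c(adcascade:::.param_names, adcascade:::.ic_names)

rel_param_errors <- function(fitted_params, true_params) {
  nms <- param_names16()
  truth <- unlist(true_params[nms])
  abs(unlist(fitted_params[nms]) - truth) / truth
}
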