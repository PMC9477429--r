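test_that("relative error formulas evaluate correctly", {
  expect_equal(relative_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(relative_error(2, 1), 1)
  expect_equal(relative_error(c(1.1, 0.9), c(1, 1)), 0.1)
  expect_equal(relative_error(c(1.1, 0.9), c(1, 1), form = "rmsre"), 0.1)
  expect_equal(relative_error(c(2, 1), c(1, 1), form = "rmsre"),
               sqrt(mean(c(1, 0)^2)))
  expect_error(relative_error(1, 0), "zero")
})

test_that("amyloid parameters are recovered from noise-free logistic data", {
  lam <- 0.18; K <- 260; A0 <- 36; T0 <- 50
  ages <- seq(54, 64, by = 2)
  vals <- K / ((K / A0 - 1) * exp(-lam * (ages - T0)) + 1)
  flat <- data.frame(age = ages, value = rep(1, length(ages)))
  rec <- longitudinal_record("s", list(
    Abeta = data.frame(age = ages, value = vals),
    taup = flat, tauo = flat, N = flat, C = flat))
  fit <- fit_abeta(rec)
  expect_false(fit$degenerate)
  expect_lt(abs(fit$par[["lambda_Abeta"]] - lam) / lam, 0.01)
  expect_lt(abs(fit$par[["K_Abeta"]] - K) / K, 0.01)
  expect_lt(abs(fit$par[["A0"]] - A0) / A0, 0.01)
})

test_that("constant amyloid data gives the zero-growth flat optimum, flagged", {
  ages <- seq(54, 64, by = 2)
  flat <- data.frame(age = ages, value = rep(120, length(ages)))
  rec <- longitudinal_record("s", list(Abeta = flat, taup = flat, tauo = flat,
                                       N = flat, C = flat))
  fit <- fit_abeta(rec)
  expect_true(fit$degenerate)
  expect_equal(fit$par[["lambda_Abeta"]], 0)
  expect_equal(fit$par[["A0"]], 120)
})

test_that("subjects with fewer than 3 datapoints are excluded with a reason", {
  ages <- seq(54, 64, by = 2)
  flat <- data.frame(age = ages, value = rep(1, length(ages)))
  rec <- longitudinal_record("s2", list(
    Abeta = data.frame(age = c(54, 56), value = c(40, 45)),
    taup = flat, tauo = flat, N = flat, C = flat))
  err <- tryCatch(fit_abeta(rec), adcascade_exclusion = function(e) e)
  expect_s3_class(err, "adcascade_exclusion")
  expect_match(conditionMessage(err), "at least 3")
  out <- calibrate_cohort(list(s2 = rec))
  expect_length(out$results, 0)
  expect_match(out$exclusions[["s2"]], "excluded")
})

test_that("linear tauo data identifies its rate and reference-age intercept", {
  ages <- seq(54, 64, by = 2)
  vals <- 30 + 1.5 * (ages - 54)           # slope 1.5, value 30 at age 54
  flat <- data.frame(age = ages, value = rep(1, length(ages)))
  rec <- longitudinal_record("s", list(
    Abeta = flat, taup = flat, N = flat, C = flat,
    tauo = data.frame(age = ages, value = vals)))
  fit <- fit_stage("tauo", rec, fixed = c(lambda_Abeta = 0.1, K_Abeta = 100,
                                          A0 = 10))
  expect_lt(abs(fit$par[["lambda_tauo"]] - 1.5), 1e-6)
  expect_lt(abs(fit$par[["tauo0"]] - (30 - 1.5 * 4)), 1e-6)  # back to T0 = 50
})

test_that("neurodegeneration stage recovers its parameters with upstream truth fixed", {
  p <- oracle_subject()
  rec <- noiseless_record(p)
  fixed <- unlist(p[c("lambda_Abeta", "K_Abeta", "A0", "lambda_tau",
                      "K_taup", "taup0", "lambda_tauo", "tauo0")])
  fit <- fit_stage("N", rec, fixed = fixed)
  truth <- unlist(p[c("lambda_N_tauo", "lambda_N_taup", "K_N", "N0")])
  expect_false(fit$degenerate)
  expect_lt(max(abs(fit$par[names(truth)] - truth) / truth), 0.02)
})

test_that("saturated series are flagged unidentifiable with the plateau as capacity", {
  ages <- seq(54, 64, by = 1)
  flat <- data.frame(age = ages, value = rep(1, length(ages)))
  rec <- longitudinal_record("s", list(
    Abeta = flat, taup = flat, tauo = flat, C = flat,
    N = data.frame(age = ages, value = rep(0.97, length(ages)))))
  fit <- fit_stage("N", rec, fixed = c(lambda_Abeta = 0.1, K_Abeta = 100,
                                       A0 = 10, lambda_tau = 0.1,
                                       K_taup = 100, taup0 = 1,
                                       lambda_tauo = 1, tauo0 = 1))
  expect_true(fit$degenerate)
  expect_equal(fit$par[["lambda_N_tauo"]], 0)
  expect_equal(fit$par[["K_N"]], 0.97)
  expect_equal(fit$par[["N0"]], 0.97)
})

test_that("sequential-then-joint calibration recovers all parameters on an identifiable record", {
  p <- oracle_subject()
  rec <- noiseless_record(p)
  res <- calibrate_subject(rec, group = "AD", weights = scale_weights(rec))
  expect_lte(res$joint_objective, res$objective_init + 1e-8)
  expect_lt(max(rel_param_errors(res$params, p)), 0.02)
  expect_false(res$flags[["joint_failed"]])
})

test_that("joint refinement is a fixed point at an optimal start", {
  p <- oracle_subject()
  rec <- noiseless_record(p, schedule = oracle_schedule(14))
  res <- fit_joint(rec, p)
  expect_lte(res$joint_objective, res$objective_init + 1e-10)
  expect_lt(max(rel_param_errors(res$params, p)), 1e-4)
})

test_that("datapoint order in the input file does not affect the fit", {
  p <- oracle_subject()
  rec <- noiseless_record(p, schedule = oracle_schedule(14))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_records(rec, f)
  tidy <- read.delim(f)
  set.seed(9)
  shuffled <- tidy[sample(nrow(tidy)), ]
  g <- withr::local_tempfile(fileext = ".tsv")
  write.table(shuffled, g, sep = "\t", quote = FALSE, row.names = FALSE)
  rec2 <- read_records(g)[[1]]
  expect_equal(rec2$series, rec$series)
  expect_equal(fit_abeta(rec2), fit_abeta(rec))
})

test_that("reported relative errors equal the formula applied to the training data", {
  p <- oracle_subject()
  rec <- noiseless_record(p, schedule = oracle_schedule(14))
  res <- calibrate_subject(rec, group = "AD")
  traj <- simulate_cascade(res$params, 50, max(rec$series$C$age), step = 0.01)
  for (bm in names(rec$series)) {
    mv <- adcascade:::interp_trajectory(traj, rec$series[[bm]]$age)[, bm]
    expect_equal(res$relative_errors[[bm]],
                 relative_error(mv, rec$series[[bm]]$value))
  }
})

test_that("tidy record files round-trip", {
  p <- oracle_subject()
  rec <- noiseless_record(p, schedule = oracle_schedule(10), id = "A1")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_records(list(A1 = rec), f)
  back <- read_records(f)
  expect_named(back, "A1")
  expect_equal(back$A1$series, rec$series)
  expect_error(read_records({
    ff <- withr::local_tempfile(fileext = ".tsv")
    writeLines("subject_id\tbiomarker\tage\tvalue\nS\tbogus\t60\t1", ff)
    ff
  }), "unknown biomarker")
})
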