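# In-silico clinical trial runner: untreated vs optimally treated cascade
# simulation for every subject in a cohort, reporting cognitive percentage
# change at the end of treatment. Durations are given in weeks or years and
# converted at this boundary (78 weeks = 1.5 years, 76 weeks = 76/52 years);
# the model core works in years throughout.

#' Define a trial arm
#'
#' @param drug A [drug_definition], registry name (see [builtin_drugs()]),
#'   or `"custom:<fraction>:<weeks>"`.
#' @param start_age Treatment start age in years (60 and 70 are the
#'   conventional arms).
#' @param duration Treatment duration: `"78w"`, `"10y"`, a number of years,
#'   or `"<n>w"`/`"<n>y"` strings.
#' @param step Grid spacing in years.
#' @param ... Further arguments for [oc_config()] (`eps0`, `gamma`,
#'   `alpha1`, `alpha2`, `relax`, `tol`, `max_iter`, `adjoint_form`).
#' @return A `trial_arm` with the resolved [oc_config()] (u_max in 1/year).
#' @export
trial_arm <- function(drug, start_age = 60, duration = "78w", step = 0.01,
                      ...) {
  drug <- resolve_drug(drug)
  dur <- parse_duration(duration)
  cfg <- oc_config(u_max = drug$u_max_per_year, T1 = start_age,
                   T2 = start_age + dur, step = step, ...)
  structure(list(drug = drug, start_age = start_age,
                 duration_years = dur, duration_label = format_duration(duration),
                 oc_config = cfg),
            class = "trial_arm")
}

# duration in years from "78w", "10y", or a bare number of years
parse_duration <- function(duration) {
  if (is.numeric(duration)) return(as.numeric(duration))
  stopifnot(is.character(duration), length(duration) == 1L)
  num <- as.numeric(sub("[wy]$", "", duration))
  if (grepl("w$", duration)) num / 52
  else if (grepl("y$", duration)) num
  else as.numeric(duration)
}

format_duration <- function(duration) {
  if (is.numeric(duration)) paste0(duration, "y") else duration
}

#' Cognitive percentage change under treatment
#'
#' `(C_treated - C_untreated) / C_untreated * 100`: negative values mean
#' less cognitive decline under treatment. Reported trial tables use the
#' magnitude (`-change`) so positive entries mean benefit.
#'
#' @param C_treated,C_untreated Cognition values at the same age;
#'   `C_untreated > 0` (zero denominators are classified as no-response).
#' @return Percent change (same length as inputs).
#' @export
cognitive_percent_change <- function(C_treated, C_untreated) {
  ifelse(C_untreated == 0, NA_real_,
         (C_treated - C_untreated) / C_untreated * 100)
}

.NR_TOL <- 1e-7

#' Run one trial arm over a cohort
#'
#' For each subject: simulate untreated from the reference age through the
#' end of treatment, solve the personalized optimal control on
#' `[T1, T2]`, and evaluate the cognitive percentage change at `T2`
#' (plus the maximum effect over the treatment course). Subjects with
#' `|change| < 1e-7` are "no response" (NR) and contribute zero change to
#' the median; subjects whose sweep fails to converge are flagged and
#' excluded from the median but counted.
#'
#' @param cohort Named list of [subject_parameters].
#' @param arm A [trial_arm].
#' @return A `trial_report` with `per_subject` data frame (`subject_id`,
#'   `percent_change` (raw, negative = less decline), `reported`
#'   (`-percent_change`), `max_effect`, `nr`, `objective`, `converged`),
#'   `median_reported`, `n_nr`, `n_nonconverged`, and the arm.
#' @export
run_trial_arm <- function(cohort, arm) {
  stopifnot(length(cohort) >= 1)
  cfg <- arm$oc_config
  ids <- names(cohort)
  if (is.null(ids)) ids <- paste0("S", seq_along(cohort))
  rows <- Map(function(params, id) {
    untreated <- simulate_cascade(params, t_start = cfg$T1, t_end = cfg$T2,
                                  step = cfg$step)
    sol <- forward_backward_sweep(params, cfg)
    n <- length(sol$times)
    change <- cognitive_percent_change(sol$states$C[n], untreated$C[n])
    course <- cognitive_percent_change(sol$states$C, untreated$C)
    nr <- is.na(change) || abs(change) < .NR_TOL
    data.frame(subject_id = id,
               percent_change = if (is.na(change)) NA_real_ else change,
               reported = if (nr) 0 else -change,
               max_effect = if (all(is.na(course))) NA_real_
                            else max(-course, na.rm = TRUE),
               nr = nr, objective = sol$objective,
               converged = sol$converged)
  }, cohort, ids)
  per_subject <- do.call(rbind, rows)
  ok <- per_subject$converged
  structure(list(per_subject = per_subject,
                 median_reported = median(per_subject$reported[ok]),
                 n_nr = sum(per_subject$nr),
                 n_nonconverged = sum(!ok),
                 arm = arm),
            class = "trial_report")
}

#' @export
print.trial_report <- function(x, ...) {
  a <- x$arm
  cat(sprintf("Trial arm: %s, start age %g, duration %s\n", a$drug$name,
              a$start_age, a$duration_label))
  cat(sprintf("  n = %d subjects, %d NR, %d non-converged\n",
              nrow(x$per_subject), x$n_nr, x$n_nonconverged))
  cat(sprintf("  median cognitive change (%% less decline): %.4g\n",
              x$median_reported))
  invisible(x)
}

#' Write trial reports as a delimited table
#'
#' `layout = "tidy"`: one row per subject x arm with all per-subject fields.
#' `layout = "wide"`: subjects as rows and one column per arm
#' (start-age x drug cells), `NR` rendered literally, and a `Median` row
#' appended — the conventional trial-table shape.
#'
#' @param reports A `trial_report` or list of them.
#' @param path Output file (tab-separated).
#' @param layout `"tidy"` or `"wide"`.
#' @export
write_trial_report <- function(reports, path, layout = c("tidy", "wide")) {
  layout <- match.arg(layout)
  if (inherits(reports, "trial_report")) reports <- list(reports)
  arm_label <- function(a) sprintf("age%g_%s_%s", a$start_age, a$drug$name,
                                   a$duration_label)
  if (layout == "tidy") {
    out <- do.call(rbind, lapply(reports, function(r)
      cbind(data.frame(drug = r$arm$drug$name, start_age = r$arm$start_age,
                       duration = r$arm$duration_label), r$per_subject)))
    if (is.null(out)) out <- data.frame(drug = character(0))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (!length(reports) || !nrow(reports[[1]]$per_subject)) {
      writeLines("Subject", path)
      warning("empty cohort: header-only report written")
      return(invisible(path))
    }
    subj <- reports[[1]]$per_subject$subject_id
    cols <- lapply(reports, function(r) {
      stopifnot(identical(r$per_subject$subject_id, subj))
      cell <- ifelse(r$per_subject$nr, "NR",
                     formatC(r$per_subject$reported, format = "g", digits = 4))
      c(cell, formatC(r$median_reported, format = "g", digits = 4))
    })
    out <- data.frame(Subject = c(subj, "Median"),
                      setNames(cols, vapply(reports, function(r)
                        arm_label(r$arm), character(1))),
                      check.names = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a tidy trial report
#'
#' @param path File written by [write_trial_report()] with `layout = "tidy"`.
#' @return Data frame of per-subject results.
#' @export
read_trial_report <- function(path) read.delim(path, stringsAsFactors = FALSE)
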