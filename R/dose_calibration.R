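# Conversion between published trial amyloid-reduction outcomes and maximum
# clearance rates. Under a constant maximal clearance the amyloid equation
# reduces to pure exponential decay, dA/dt = -u_max * A, so a fraction f of
# baseline remaining after d weeks implies u_max = -ln(f)/d per week.

#' Maximum clearance rate from an observed amyloid reduction
#'
#' @param fraction_remaining Fraction of baseline amyloid burden remaining at
#'   the end of the trial, in `(0, 1]`.
#' @param duration_weeks Trial duration in weeks, `> 0`.
#' @return Clearance rate in 1/week.
#' @export
clearance_rate_from_reduction <- function(fraction_remaining, duration_weeks) {
  if (any(fraction_remaining <= 0) || any(fraction_remaining > 1))
    stop("fraction_remaining must be in (0, 1]")
  if (any(duration_weeks <= 0)) stop("duration_weeks must be > 0")
  -log(fraction_remaining) / duration_weeks
}

#' Percent amyloid reduction implied by a clearance rate
#'
#' Inverse of [clearance_rate_from_reduction()]: `100 * (1 - exp(-rate * d))`.
#'
#' @param rate_per_week Clearance rate in 1/week, `>= 0`.
#' @param duration_weeks Duration in weeks.
#' @return Percent reduction from baseline.
#' @export
reduction_from_rate <- function(rate_per_week, duration_weeks) {
  if (any(rate_per_week < 0)) stop("rate_per_week must be >= 0")
  100 * (1 - exp(-rate_per_week * duration_weeks))
}

#' Define an anti-amyloid drug by its trial outcome
#'
#' The maximum clearance rate is derived from the source observation at
#' construction time rather than stored as a rounded constant, so downstream
#' numbers stay self-consistent.
#'
#' @param name Drug label.
#' @param fraction_remaining Fraction of baseline amyloid remaining at the
#'   end of the source trial.
#' @param duration_weeks Source trial duration in weeks.
#' @return A `drug_definition` with fields `name`, `source_fraction_remaining`,
#'   `source_duration_weeks`, `u_max_per_week` and `u_max_per_year`
#'   (`52 * u_max_per_week`, the unit used by the model core).
#' @export
drug_definition <- function(name, fraction_remaining, duration_weeks) {
  rate <- clearance_rate_from_reduction(fraction_remaining, duration_weeks)
  structure(list(name = name,
                 source_fraction_remaining = fraction_remaining,
                 source_duration_weeks = duration_weeks,
                 u_max_per_week = rate,
                 u_max_per_year = 52 * rate),
            class = "drug_definition")
}

#' @export
print.drug_definition <- function(x, ...) {
  cat(sprintf("%s: u_max = %.3g/week (%.3g/year), from %.4g%% reduction over %g weeks\n",
              x$name, x$u_max_per_week, x$u_max_per_year,
              100 * (1 - x$source_fraction_remaining), x$source_duration_weeks))
  invisible(x)
}

#' Built-in anti-amyloid drug registry
#'
#' Three agents with clearance rates derived from published amyloid-PET
#' outcomes: aducanumab low dose (16.5% reduction at week 78), aducanumab
#' high dose (27.2% at week 78), and donanemab (SUVr reduced by 84.13 from a
#' baseline of 107.6 over 76 weeks, i.e. fraction remaining 23.47/107.6).
#'
#' @return Named list of [drug_definition] objects.
#' @export
builtin_drugs <- function() {
  list(
    `aducanumab-low` = drug_definition("aducanumab-low", 0.835, 78),
    `aducanumab-high` = drug_definition("aducanumab-high", 0.728, 78),
    donanemab = drug_definition("donanemab", (107.6 - 84.13) / 107.6, 76)
  )
}

# Resolve a drug given a name from the registry, a drug_definition, or a
# "custom:<fraction_remaining>:<weeks>" string.
resolve_drug <- function(drug) {
  if (inherits(drug, "drug_definition")) return(drug)
  stopifnot(is.character(drug), length(drug) == 1L)
  if (startsWith(drug, "custom:")) {
    parts <- strsplit(drug, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3L) stop("custom drug must be 'custom:<fraction>:<weeks>'")
    return(drug_definition("custom", as.numeric(parts[2]), as.numeric(parts[3])))
  }
  reg <- builtin_drugs()
  if (!drug %in% names(reg))
    stop("unknown drug '", drug, "'; use one of ",
         paste(names(reg), collapse = ", "), " or custom:<fraction>:<weeks>")
  reg[[drug]]
}
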