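#' Experimental condition preset
#'
#' An apical/basal bath pair applied at t = 0, plus optional later
#' solution-replacement events (e.g. the reversibility protocol, where the
#' apical osmotic gradient is removed at 120 min by adding sucrose without
#' changing NaCl).
#'
#' @param name Condition label.
#' @param apical,basal [solution()] objects applied at t = 0.
#' @param switch_events List of `list(time = minutes, baths = bath_pair)`
#'   replacement events after t = 0 (default none).
#' @return An object of class `condition_preset`.
#' @export
condition_preset <- function(name, apical, basal, switch_events = list()) {
  bp <- bath_pair(apical, basal)
  for (ev in switch_events)
    stopifnot(is.numeric(ev$time), ev$time > 0,
              inherits(ev$baths, "bath_pair"))
  structure(list(name = name, baths = bp, switch_events = switch_events),
            class = "condition_preset")
}

#' Bath schedule of a condition preset
#'
#' @param preset A [condition_preset()].
#' @return Schedule list usable with [baths_at()] and
#'   [compute_permeability_series()].
#' @export
condition_schedule <- function(preset) {
  stopifnot(inherits(preset, "condition_preset"))
  c(list(list(time = 0, baths = preset$baths)),
    lapply(preset$switch_events,
           function(ev) list(time = ev$time, baths = ev$baths)))
}

#' Osmotic classification of a bath pair
#'
#' Classifies by the nominal osmolarity difference apical minus basal:
#' below -`tolerance` mOsm/L the condition is relative apical hyposmotic
#' (the stimulus that drives the selectivity change), above +`tolerance`
#' relative apical hyperosmotic, otherwise isosmotic. The tolerance absorbs
#' the ~10 mOsm/L residual of balancing 140 osmotic units of NaCl with
#' 130 mM sucrose.
#'
#' @param baths A [bath_pair()] or [condition_preset()].
#' @param tolerance mOsm/L band treated as isosmotic (default 20).
#' @return `"apical_hypo"`, `"iso"` or `"apical_hyper"`.
#' @export
osmotic_class <- function(baths, tolerance = 20) {
  if (inherits(baths, "condition_preset")) baths <- baths$baths
  stopifnot(inherits(baths, "bath_pair"))
  d <- nominal_osmolarity(baths$apical) - nominal_osmolarity(baths$basal)
  if (d < -tolerance) "apical_hypo"
  else if (d > tolerance) "apical_hyper"
  else "iso"
}

#' The shipped condition presets
#'
#' The eight osmotic-challenge conditions of the permeability time-course
#' matrix (apical or basal NaCl halved to 70 mM or raised to 210 mM, with or
#' without 130 mM sucrose balancing the osmolarity) plus the reversibility
#' protocol (apical hyposmotic for 120 min, then sucrose added apically with
#' NaCl unchanged, removing the osmotic gradient without perturbing the NaCl
#' gradient or the liquid-junction potentials).
#'
#' @param counter_osmolyte `"sucrose"` (default) or `"mannitol"`; the two
#'   are osmotically interchangeable in these presets.
#' @return Named list of [condition_preset()]s.
#' @export
condition_presets <- function(counter_osmolyte = c("sucrose", "mannitol")) {
  counter_osmolyte <- match.arg(counter_osmolyte)
  bal <- function(NaCl) {
    if (counter_osmolyte == "sucrose") solution_a(NaCl, sucrose = 130)
    else solution_a(NaCl, mannitol = 130)
  }
  a140 <- solution_a(140)
  presets <- list(
    apical_isosmotic  = condition_preset("apical_isosmotic", bal(70), a140),
    apical_hyposmotic = condition_preset("apical_hyposmotic",
                                         solution_a(70), a140),
    basal_isosmotic   = condition_preset("basal_isosmotic", a140, bal(70)),
    basal_hyposmotic  = condition_preset("basal_hyposmotic",
                                         a140, solution_a(70)),
    basal_hyperosmotic = condition_preset("basal_hyperosmotic",
                                          a140, solution_a(210)),
    basal_hyperosmotic_balanced = condition_preset(
      "basal_hyperosmotic_balanced", bal(140), solution_a(210)),
    apical_hyperosmotic = condition_preset("apical_hyperosmotic",
                                           solution_a(210), a140),
    apical_hyperosmotic_balanced = condition_preset(
      "apical_hyperosmotic_balanced", solution_a(210), bal(140))
  )
  presets$reversibility <- condition_preset(
    "reversibility", solution_a(70), a140,
    switch_events = list(list(time = 120,
                              baths = bath_pair(bal(70), a140))))
  presets
}

# nearest record within tolerance; NA index if none
.nearest_time <- function(times, target, tolerance) {
  d <- abs(times - target)
  i <- which.min(d)
  if (length(i) && d[i] <= tolerance) i else NA_integer_
}

#' Change in permeabilities over the 5-120 min window
#'
#' Summarises a permeability time course as value(5 min) minus
#' value(120 min) for P_Na and P_Cl (that subtraction order, so a decline in
#' P_Na over the window gives a positive delta). Records are matched to the
#' 5 and 120 min anchors by nearest time within `tolerance`.
#'
#' @param series Permeability series (data frame with `time`, `p_na`,
#'   `p_cl`), e.g. from [compute_permeability_series()].
#' @param tolerance Anchor-matching tolerance in minutes (default 2.5).
#' @return List with `delta_p_na`, `delta_p_cl` (cm/s), and the matched
#'   anchor times `t_early`, `t_late`.
#' @export
delta_115min <- function(series, tolerance = 2.5) {
  stopifnot(all(c("time", "p_na", "p_cl") %in% names(series)))
  i5 <- .nearest_time(series$time, 5, tolerance)
  i120 <- .nearest_time(series$time, 120, tolerance)
  if (is.na(i5) || is.na(i120))
    stop("series lacks a record within +/-", tolerance,
         " min of the ", if (is.na(i5)) "5" else "120", " min anchor")
  list(delta_p_na = series$p_na[i5] - series$p_na[i120],
       delta_p_cl = series$p_cl[i5] - series$p_cl[i120],
       t_early = series$time[i5], t_late = series$time[i120])
}

#' Selectivity before, at, and shortly after a bath switch
#'
#' Extracts beta = P_Na/P_Cl at 5 min, at the switch time, and 5 min after
#' the switch (nearest records within `tolerance`), the three-point summary
#' used to demonstrate prompt recovery of cation selectivity when the
#' osmotic gradient is removed.
#'
#' @param series Permeability series with columns `time`, `beta`.
#' @param switch_time Bath-replacement time in minutes (default 120).
#' @param tolerance Anchor-matching tolerance in minutes (default 2.5).
#' @return List with `beta_pre` (5 min), `beta_at_switch`, `beta_post5min`.
#' @export
recovery_metrics <- function(series, switch_time = 120, tolerance = 2.5) {
  stopifnot(all(c("time", "beta") %in% names(series)))
  anchors <- c(pre = 5, at = switch_time, post = switch_time + 5)
  idx <- vapply(anchors, function(a) .nearest_time(series$time, a, tolerance),
                integer(1))
  if (anyNA(idx))
    stop("series does not cover anchor time(s): ",
         paste(anchors[is.na(idx)], collapse = ", "), " min")
  list(beta_pre = series$beta[idx[["pre"]]],
       beta_at_switch = series$beta[idx[["at"]]],
       beta_post5min = series$beta[idx[["post"]]])
}
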