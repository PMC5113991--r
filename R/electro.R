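#' Nernst equilibrium potentials for the bath pair
#'
#' Bounds of the physically attainable dilution potential in the two-ion
#' constant-field model: as P_Na/P_Cl -> Inf the potential tends to the Na+
#' Nernst potential (RT/F) ln(C_Na,b / C_Na,a), and as P_Na/P_Cl -> 0 to the
#' Cl- Nernst potential (RT/F) ln(C_Cl,a / C_Cl,b). Apical-minus-basal sign
#' convention.
#'
#' @param baths A [bath_pair()].
#' @param ctx A [physical_context()].
#' @return Named numeric `c(cl = , na = )` in mV (the open interval of
#'   attainable dilution potentials, not ordered).
#' @export
nernst_limits <- function(baths, ctx = physical_context()) {
  ions <- bath_ions(baths)
  if (any(ions <= 0))
    stop("Na+ and Cl- concentrations must be positive on both sides")
  vt_mv <- 1000 * thermal_voltage(ctx)
  c(cl = vt_mv * log(ions[["cl_a"]] / ions[["cl_b"]]),
    na = vt_mv * log(ions[["na_b"]] / ions[["na_a"]]))
}

#' Forward GHK dilution potential
#'
#' Two-ion (Na+, Cl-) constant-field dilution potential across the epithelium
#' for a selectivity ratio beta = P_Na/P_Cl:
#'
#'   V = (RT/F) ln\[(beta C_Na,b + C_Cl,a) / (beta C_Na,a + C_Cl,b)\]
#'
#' with `a` = apical, `b` = basal. V is apical-minus-basal, so with apical
#' NaCl diluted and beta > 1 (cation-selective barrier) the result is
#' positive: the dilute side goes positive.
#'
#' @param beta P_Na/P_Cl ratio (> 0). Vectorised.
#' @param baths A [bath_pair()].
#' @param ctx A [physical_context()].
#' @return Dilution potential in mV.
#' @examples
#' baths <- bath_pair(solution("a", NaCl = 70), solution("b", NaCl = 140))
#' ghk_forward_potential(1, baths)      # 0 mV
#' ghk_forward_potential(9.32, baths)   # ~12.7 mV, dilute apical positive
#' @export
ghk_forward_potential <- function(beta, baths, ctx = physical_context()) {
  if (any(!is.finite(beta)) || any(beta <= 0))
    stop("`beta` must be finite and > 0")
  ions <- bath_ions(baths)
  if (any(ions <= 0))
    stop("Na+ and Cl- concentrations must be positive on both sides")
  vt_mv <- 1000 * thermal_voltage(ctx)
  vt_mv * log((beta * ions[["na_b"]] + ions[["cl_a"]]) /
              (beta * ions[["na_a"]] + ions[["cl_b"]]))
}

#' Invert a dilution potential to the selectivity ratio P_Na/P_Cl
#'
#' Closed-form inversion of [ghk_forward_potential()]: with
#' x = exp(VF/RT),
#'
#'   beta = (x C_Cl,b - C_Cl,a) / (C_Na,b - x C_Na,a).
#'
#' The potential must lie strictly inside the open interval bounded by the
#' two Nernst potentials ([nernst_limits()]); at or beyond a limit beta is
#' not identifiable (it would be 0 or infinite).
#'
#' @param dilution_potential Blank-corrected transepithelial potential in mV,
#'   apical minus basal. Vectorised.
#' @param baths A [bath_pair()]; apical and basal NaCl must differ.
#' @param ctx A [physical_context()].
#' @return beta = P_Na/P_Cl (> 0), same length as `dilution_potential`.
#' @examples
#' baths <- bath_pair(solution("a", NaCl = 70), solution("b", NaCl = 140))
#' v <- ghk_forward_potential(3.24, baths)
#' ghk_invert_beta(v, baths)  # 3.24
#' @export
ghk_invert_beta <- function(dilution_potential, baths,
                            ctx = physical_context()) {
  ions <- bath_ions(baths)
  if (any(ions <= 0))
    stop("Na+ and Cl- concentrations must be positive on both sides")
  if (isTRUE(all.equal(ions[["na_a"]], ions[["na_b"]])) &&
      isTRUE(all.equal(ions[["cl_a"]], ions[["cl_b"]])))
    stop("no NaCl gradient between apical and basal baths: ",
         "P_Na/P_Cl is unidentifiable from the dilution potential")
  lim <- nernst_limits(baths, ctx)
  lo <- min(lim); hi <- max(lim)
  out_of_range <- !is.na(dilution_potential) &
    (dilution_potential <= lo | dilution_potential >= hi)
  if (any(out_of_range))
    stop(sprintf(paste0(
      "dilution potential outside the attainable open interval ",
      "(%.4f, %.4f) mV set by the Cl- (%.4f mV) and Na+ (%.4f mV) ",
      "Nernst limits: %s"),
      lo, hi, lim[["cl"]], lim[["na"]],
      paste(format(dilution_potential[out_of_range]), collapse = ", ")))
  x <- exp(dilution_potential / (1000 * thermal_voltage(ctx)))
  (x * ions[["cl_b"]] - ions[["cl_a"]]) / (ions[["na_b"]] - x * ions[["na_a"]])
}

# log mean; continuous limit a -> b
.logmean <- function(a, b) {
  ifelse(abs(a - b) < 1e-12 * pmax(a, b), (a + b) / 2,
         (a - b) / log(a / b))
}

# mean ion concentration entering the KK conductance term, mol/cm^3
.kk_cbar <- function(ions, variant = c("logmean", "arithmetic", "basal")) {
  variant <- match.arg(variant)
  f <- switch(variant,
              logmean    = function(a, b) .logmean(a, b),
              arithmetic = function(a, b) (a + b) / 2,
              basal      = function(a, b) b)
  # 1 mM = 1e-6 mol/cm^3
  c(na = f(ions[["na_a"]], ions[["na_b"]]) * 1e-6,
    cl = f(ions[["cl_a"]], ions[["cl_b"]]) * 1e-6)
}

#' Split TER into absolute Na+ and Cl- permeabilities (Kimizuka-Koketsu)
#'
#' Decomposes the transepithelial conductance G = 1/TER under the
#' constant-field zero-current relation
#'
#'   G = (F^2 / RT) (P_Na Cbar_Na + P_Cl Cbar_Cl)
#'
#' where Cbar is a mean of the apical and basal concentration of that ion in
#' mol/cm^3. With P_Cl = P_Na / beta this gives
#' P_Na = (G RT / F^2) / (Cbar_Na + Cbar_Cl / beta).
#'
#' Under a standing gradient the appropriate mean is not unique; the default
#' is the logarithmic mean (consistent with the constant-field zero-current
#' conductance), with arithmetic-mean and basal-only variants selectable.
#' The choice moves P by at most a few percent for a two-fold gradient.
#'
#' @param ter Blank-corrected transepithelial resistance in ohm cm^2 (> 0).
#' @param beta P_Na/P_Cl ratio (> 0).
#' @param baths A [bath_pair()].
#' @param ctx A [physical_context()].
#' @param variant Concentration-mean variant: `"logmean"` (default),
#'   `"arithmetic"` or `"basal"`.
#' @return A list of class `permeability_result` with `p_na`, `p_cl` (cm/s)
#'   and `beta`.
#' @examples
#' baths <- bath_pair(solution_a(70), solution_a(140))
#' kk_split_permeabilities(60, 9, baths)
#' @export
kk_split_permeabilities <- function(ter, beta, baths,
                                    ctx = physical_context(),
                                    variant = c("logmean", "arithmetic",
                                                "basal")) {
  if (!is.finite(ter) || ter <= 0)
    stop("`ter` must be finite and > 0 (ohm cm^2)")
  if (!is.finite(beta) || beta <= 0)
    stop("`beta` must be finite and > 0")
  variant <- match.arg(variant)
  cbar <- .kk_cbar(bath_ions(baths), variant)
  g <- 1 / ter  # S cm^-2
  rt_f2 <- ctx$gas_constant * ctx$temperature / ctx$faraday^2
  p_na <- g * rt_f2 / (cbar[["na"]] + cbar[["cl"]] / beta)
  structure(list(p_na = p_na, p_cl = p_na / beta, beta = beta),
            class = "permeability_result")
}

#' Conductance implied by (P_Na, beta): the KK forward relation
#'
#' Inverse companion of [kk_split_permeabilities()]; used by the simulator
#' and for round-trip checks against reported permeability values.
#'
#' @inheritParams kk_split_permeabilities
#' @param p_na Na+ permeability in cm/s.
#' @return Conductance G in S cm^-2 (TER = 1/G).
#' @export
kk_conductance <- function(p_na, beta, baths, ctx = physical_context(),
                           variant = c("logmean", "arithmetic", "basal")) {
  if (any(p_na <= 0) || any(beta <= 0))
    stop("`p_na` and `beta` must be > 0")
  variant <- match.arg(variant)
  cbar <- .kk_cbar(bath_ions(baths), variant)
  f2_rt <- ctx$faraday^2 / (ctx$gas_constant * ctx$temperature)
  f2_rt * (p_na * cbar[["na"]] + (p_na / beta) * cbar[["cl"]])
}

#' Build a measurement series
#'
#' @param time Minutes since solution replacement (>= 0).
#' @param resistance Area-normalised resistance readings in ohm cm^2. Raw
#'   ohm readings can be converted with `ohm * area_cm2` beforehand (12-mm
#'   Transwell growth area: 1.12 cm^2).
#' @param potential Transepithelial potential in mV, apical minus basal.
#' @return A data frame of class `measurement_series`.
#' @export
measurement_series <- function(time, resistance, potential) {
  stopifnot(length(time) == length(resistance),
            length(time) == length(potential))
  if (any(time < 0)) stop("`time` must be >= 0 (minutes)")
  structure(data.frame(time = time, resistance = resistance,
                       potential = potential),
            class = c("measurement_series", "data.frame"))
}

#' Blank-filter correction
#'
#' Subtracts the resistance and potential of a cell-free (blank) filter from
#' the epithelium-bearing sample at each time point, pairing records whose
#' times agree within `tolerance`. The blank carries the filter's series
#' resistance and the electrodes' junction-potential offset, so the
#' difference is the epithelium's TER and dilution potential.
#'
#' Records whose corrected TER is not positive are flagged (`flagged = TRUE`)
#' with a warning and must be excluded from downstream permeability math;
#' they are retained in the returned table so nothing is dropped silently.
#'
#' @param sample,blank [measurement_series()] (or data frames with columns
#'   `time`, `resistance`, `potential`).
#' @param tolerance Maximum |time difference| in minutes for pairing
#'   (default 0.5).
#' @return A data frame of class `corrected_series` with columns `time`,
#'   `ter`, `dilution_potential`, `flagged`.
#' @export
blank_correct <- function(sample, blank, tolerance = 0.5) {
  for (s in list(sample, blank))
    stopifnot(all(c("time", "resistance", "potential") %in% names(s)))
  idx <- vapply(sample$time, function(t) {
    d <- abs(blank$time - t)
    i <- which.min(d)
    if (d[i] <= tolerance) i else NA_integer_
  }, integer(1))
  if (anyNA(idx))
    stop("sample time points with no blank reading within +/-", tolerance,
         " min: ", paste(sample$time[is.na(idx)], collapse = ", "))
  ter <- sample$resistance - blank$resistance[idx]
  dp <- sample$potential - blank$potential[idx]
  flagged <- ter <= 0
  if (any(flagged))
    warning(sum(flagged), " record(s) with non-positive corrected TER ",
            "flagged (t = ", paste(sample$time[flagged], collapse = ", "),
            " min); excluded from permeability calculations")
  structure(data.frame(time = sample$time, ter = ter,
                       dilution_potential = dp, flagged = flagged),
            class = c("corrected_series", "data.frame"))
}

#' Bath schedule lookup
#'
#' @param schedule List of `list(time = minutes, baths = bath_pair)` entries;
#'   the pair in force at time t is the entry with the largest `time <= t`.
#' @param time Query time (minutes).
#' @return The active [bath_pair()].
#' @export
baths_at <- function(schedule, time) {
  starts <- vapply(schedule, `[[`, numeric(1), "time")
  ok <- which(starts <= time + 1e-9)
  if (!length(ok))
    stop("bath schedule does not cover time ", time, " min")
  schedule[[ok[which.max(starts[ok])]]]$baths
}

#' TER + dilution potential series to permeability series
#'
#' The full conversion pipeline applied per time point: look up the bath
#' pair in force, invert the dilution potential to beta = P_Na/P_Cl
#' ([ghk_invert_beta()]), then split the TER into absolute P_Na and P_Cl
#' ([kk_split_permeabilities()]). Flagged records propagate as `NA` rows
#' (never dropped).
#'
#' @param corrected A `corrected_series` from [blank_correct()], or a data
#'   frame with columns `time`, `ter`, `dilution_potential` (and optionally
#'   `flagged`).
#' @param schedule Bath schedule as in [baths_at()]; a bare [bath_pair()] is
#'   promoted to a schedule starting at t = 0.
#' @param ctx A [physical_context()].
#' @param variant KK concentration-mean variant, see
#'   [kk_split_permeabilities()].
#' @return Data frame with columns `time`, `ter`, `dilution_potential`,
#'   `beta`, `p_na`, `p_cl`, `flagged`.
#' @export
compute_permeability_series <- function(corrected, schedule,
                                        ctx = physical_context(),
                                        variant = "logmean") {
  stopifnot(all(c("time", "ter", "dilution_potential") %in% names(corrected)))
  if (inherits(schedule, "bath_pair"))
    schedule <- list(list(time = 0, baths = schedule))
  flagged <- if ("flagged" %in% names(corrected)) corrected$flagged
             else rep(FALSE, nrow(corrected))
  n <- nrow(corrected)
  beta <- p_na <- p_cl <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (flagged[i]) next
    baths <- baths_at(schedule, corrected$time[i])
    beta[i] <- ghk_invert_beta(corrected$dilution_potential[i], baths, ctx)
    kk <- kk_split_permeabilities(corrected$ter[i], beta[i], baths, ctx,
                                  variant)
    p_na[i] <- kk$p_na
    p_cl[i] <- kk$p_cl
  }
  data.frame(time = corrected$time, ter = corrected$ter,
             dilution_potential = corrected$dilution_potential,
             beta = beta, p_na = p_na, p_cl = p_cl, flagged = flagged)
}
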