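#' Bath solution composition
#'
#' A named bath solution given as millimolar concentrations of its solutes.
#' The solute set covers the buffer used for the dilution-potential
#' measurements (a HEPES-buffered saline) plus the sucrose/mannitol
#' counter-osmolytes used to balance osmolarity when NaCl is diluted.
#'
#' @param name Label for the solution.
#' @param NaCl,KCl,MgCl2,CaCl2,glucose,HEPES_NaOH,sucrose,mannitol
#'   Concentrations in mM; all must be >= 0.
#' @return An object of class `solution`.
#' @examples
#' solution_a()
#' solution("apical 70", NaCl = 70, KCl = 5, MgCl2 = 1, CaCl2 = 1,
#'          glucose = 5, HEPES_NaOH = 10)
#' @export
solution <- function(name, NaCl = 0, KCl = 0, MgCl2 = 0, CaCl2 = 0,
                     glucose = 0, HEPES_NaOH = 0, sucrose = 0, mannitol = 0) {
  conc <- c(NaCl = NaCl, KCl = KCl, MgCl2 = MgCl2, CaCl2 = CaCl2,
            glucose = glucose, HEPES_NaOH = HEPES_NaOH,
            sucrose = sucrose, mannitol = mannitol)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("all solute concentrations must be finite and >= 0 (mM)")
  structure(c(list(name = as.character(name)), as.list(conc)),
            class = "solution")
}

#' The standard bath ("solution A")
#'
#' 140 mM NaCl, 5 mM KCl, 1 mM MgCl2, 1 mM CaCl2, 5 mM glucose,
#' 10 mM HEPES-NaOH (pH 7.4).
#'
#' @param NaCl NaCl concentration in mM, so the 70/140/210 mM replacement
#'   variants can be built directly.
#' @param sucrose,mannitol Counter-osmolyte in mM (130 mM in the balanced
#'   replacement solutions).
#' @param name Optional label; autogenerated if missing.
#' @return A [solution()].
#' @export
solution_a <- function(NaCl = 140, sucrose = 0, mannitol = 0, name = NULL) {
  if (is.null(name)) {
    name <- sprintf("%g NaCl", NaCl)
    if (sucrose > 0) name <- paste0(name, sprintf(" + %g sucrose", sucrose))
    if (mannitol > 0) name <- paste0(name, sprintf(" + %g mannitol", mannitol))
  }
  solution(name, NaCl = NaCl, KCl = 5, MgCl2 = 1, CaCl2 = 1,
           glucose = 5, HEPES_NaOH = 10, sucrose = sucrose,
           mannitol = mannitol)
}

# ideal dissociation counts (no osmotic coefficients)
.dissociation <- c(NaCl = 2, KCl = 2, MgCl2 = 3, CaCl2 = 3,
                   glucose = 1, HEPES_NaOH = 2, sucrose = 1, mannitol = 1)

#' Nominal osmolarity of a solution
#'
#' Ideal-dissociation osmolarity: the sum over solutes of concentration times
#' the number of particles each formula unit dissociates into (NaCl, KCl,
#' HEPES-NaOH -> 2; MgCl2, CaCl2 -> 3; glucose, sucrose, mannitol -> 1).
#' Used only to classify conditions as iso-/hypo-/hyperosmotic; no osmotic
#' coefficients are applied.
#'
#' @param sol A [solution()].
#' @return Nominal osmolarity in mOsm/L.
#' @examples
#' nominal_osmolarity(solution_a())  # 321
#' @export
nominal_osmolarity <- function(sol) {
  stopifnot(inherits(sol, "solution"))
  sum(vapply(names(.dissociation),
             function(s) .dissociation[[s]] * sol[[s]], numeric(1)))
}

#' Free ion concentrations relevant to the two-ion model
#'
#' Na+ counts NaCl + HEPES-NaOH; Cl- counts NaCl + KCl + 2 MgCl2 + 2 CaCl2.
#' Full dissociation is assumed and molar concentrations are used directly
#' (no activity corrections).
#'
#' @param sol A [solution()].
#' @return Named numeric `c(na = , cl = )` in mM.
#' @export
ion_concentrations <- function(sol) {
  stopifnot(inherits(sol, "solution"))
  c(na = sol$NaCl + sol$HEPES_NaOH,
    cl = sol$NaCl + sol$KCl + 2 * sol$MgCl2 + 2 * sol$CaCl2)
}

#' Apical/basal bath pair
#'
#' @param apical,basal [solution()] objects bathing the apical and basal
#'   compartment.
#' @return An object of class `bath_pair`.
#' @export
bath_pair <- function(apical, basal) {
  stopifnot(inherits(apical, "solution"), inherits(basal, "solution"))
  structure(list(apical = apical, basal = basal), class = "bath_pair")
}

#' Ion concentrations of a bath pair
#'
#' @param baths A [bath_pair()].
#' @return Named numeric `c(na_a, na_b, cl_a, cl_b)` in mM (`_a` apical,
#'   `_b` basal).
#' @export
bath_ions <- function(baths) {
  stopifnot(inherits(baths, "bath_pair"))
  a <- ion_concentrations(baths$apical)
  b <- ion_concentrations(baths$basal)
  c(na_a = unname(a["na"]), na_b = unname(b["na"]),
    cl_a = unname(a["cl"]), cl_b = unname(b["cl"]))
}

#' @export
print.solution <- function(x, ...) {
  nz <- Filter(function(s) x[[s]] > 0, names(.dissociation))
  cat(sprintf("solution '%s': %s (%g mOsm/L)\n", x$name,
              paste(sprintf("%g mM %s", unlist(x[nz]), nz), collapse = ", "),
              nominal_osmolarity(x)))
  invisible(x)
}

#' @export
print.bath_pair <- function(x, ...) {
  cat("apical: "); print(x$apical)
  cat("basal:  "); print(x$basal)
  invisible(x)
}
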