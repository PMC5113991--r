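#' Physical context for electrodiffusion calculations
#'
#' Bundles the gas constant, Faraday constant and absolute temperature used
#' throughout the Goldman-Hodgkin-Katz (GHK) and Kimizuka-Koketsu (KK)
#' computations. The thermal voltage RT/F is always recomputed from the
#' stored constants, never cached independently.
#'
#' @param temperature Absolute temperature in kelvin. Default 310.15 K
#'   (37 degrees C, the incubation temperature of the measurements).
#' @param gas_constant Molar gas constant R in J mol^-1 K^-1.
#' @param faraday Faraday constant F in C mol^-1.
#'
#' @return An object of class `physical_context` with fields `temperature`,
#'   `gas_constant`, `faraday`.
#' @examples
#' ctx <- physical_context()
#' thermal_voltage(ctx)  # ~0.02672 V at 37 C
#' @export
physical_context <- function(temperature = 310.15,
                             gas_constant = 8.314462618,
                             faraday = 96485.33212) {
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0)
    stop("`temperature` must be a single positive number (kelvin)")
  structure(
    list(temperature = temperature,
         gas_constant = gas_constant,
         faraday = faraday),
    class = "physical_context"
  )
}

#' Thermal voltage RT/F
#'
#' @param ctx A [physical_context()].
#' @return RT/F in volts.
#' @export
thermal_voltage <- function(ctx = physical_context()) {
  stopifnot(inherits(ctx, "physical_context"))
  ctx$gas_constant * ctx$temperature / ctx$faraday
}

#' @export
print.physical_context <- function(x, ...) {
  cat(sprintf("physical context: T = %.2f K, RT/F = %.5f V\n",
              x$temperature, thermal_voltage(x)))
  invisible(x)
}
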