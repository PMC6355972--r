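# Hydrogel mechanics (initial modulus, relaxation half-time) and
# PEG-400 osmotic calculators.

#' Initial elastic modulus from a stress-strain curve
#'
#' Least-squares slope of stress against strain restricted to the
#' 5--10% strain window, in kPa per unit strain. Samples outside the
#' window never influence the fit.
#'
#' @param x a [TraceRecord-class] (its ramp phase is used) or a numeric
#'   vector of strain fractions.
#' @param stress_kPa stress values when `x` is a strain vector.
#' @param window strain window, default `c(0.05, 0.10)`.
#' @return Modulus in kPa, with attributes `n` (points used) and `se`
#'   (slope standard error).
#' @export
initialModulus <- function(x, stress_kPa = NULL, window = c(0.05, 0.10)) {
  if (is(x, "TraceRecord")) {
    td <- traceData(x)
    td <- td[td$phase == "ramp", ]
    strain <- td$strain; stress <- td$stress_kPa
  } else {
    strain <- as.numeric(x); stress <- as.numeric(stress_kPa)
  }
  inWin <- strain >= window[1] & strain <= window[2]
  if (sum(inWin) < 2L)
    stop(sprintf(
      "need >= 2 samples with strain in [%g, %g]; trace covers [%g, %g] with %d inside",
      window[1], window[2],
      if (length(strain)) min(strain) else NA,
      if (length(strain)) max(strain) else NA, sum(inWin)))
  fit <- stats::lm(stress[inWin] ~ strain[inWin])
  slope <- unname(coef(fit)[2])
  se <- tryCatch(suppressWarnings(summary(fit)$coefficients[2, 2]),
                 error = function(e) NA_real_)
  structure(slope, n = sum(inWin), se = se)
}

#' Stress-relaxation half-time
#'
#' Time for the hold-phase stress to fall to half of the initial hold
#' stress \eqn{\sigma_0} (the stress at the first sample of the hold,
#' i.e. the stress reached at the hold strain). The crossing is located
#' by linear interpolation between samples, so the estimate does not
#' depend on the sampling grid. When the record never crosses
#' \eqn{\sigma_0/2}, the half-time is reported as none (`NA`) together
#' with the final stress fraction.
#'
#' @param trace a [TraceRecord-class] with a hold phase.
#' @return list: `tau_half_s` (seconds, `NA` when stress never halves),
#'   `crossed`, `sigma0_kPa`, `final_fraction`.
#' @export
tauHalf <- function(trace) {
  stopifnot(is(trace, "TraceRecord"))
  td <- traceData(trace)
  hold <- td[td$phase == "hold", ]
  if (nrow(hold) < 2L) stop("trace has no hold phase")
  sigma0 <- hold$stress_kPa[1]
  if (sigma0 <= 0) stop("non-positive initial hold stress")
  t0 <- hold$time_s[1]
  target <- sigma0 / 2
  below <- which(hold$stress_kPa <= target)
  if (length(below) == 0L)
    return(list(tau_half_s = NA_real_, crossed = FALSE,
                sigma0_kPa = sigma0,
                final_fraction = hold$stress_kPa[nrow(hold)] / sigma0))
  i <- below[1]
  if (i == 1L) {
    th <- 0
  } else {
    s1 <- hold$stress_kPa[i - 1]; s2 <- hold$stress_kPa[i]
    t1 <- hold$time_s[i - 1]; t2 <- hold$time_s[i]
    th <- t1 + (s1 - target) / (s1 - s2) * (t2 - t1) - t0
  }
  list(tau_half_s = th, crossed = TRUE, sigma0_kPa = sigma0,
       final_fraction = hold$stress_kPa[nrow(hold)] / sigma0)
}

#' Osmotic pressure applied by PEG 400
#'
#' Empirical quartic for the osmotic pressure (atm) of polyethylene
#' glycol 400 as a function of its wt/vol concentration `c` (percent)
#' in medium:
#' \deqn{y = 0.00002 c^4 - 0.0007 c^3 + 0.0311 c^2 + 0.5596 c,}
#' converted to kPa at 101.325 kPa/atm. Coefficients are kept verbatim
#' at their published precision; no refit. Osmolarity treats PEG 400 as
#' a single 400 g/mol osmolyte: `10 c` g/L / 0.4 kg/mol = `25 c`
#' mOsm/L. Concentrations 1.5, 3 and 6 give 92, 197 and 441 kPa
#' (nearest integer) and 37.5, 75 and 150 mOsm/L.
#'
#' @param concentrationPct PEG-400 concentration(s), percent wt/vol,
#'   non-negative.
#' @return data.frame: `concentration_pct`, `pressure_atm`,
#'   `pressure_kPa`, `osmolarity_mOsm_L`.
#' @examples
#' pegPressure(c(0, 1.5, 3, 6))
#' @export
pegPressure <- function(concentrationPct) {
  c_ <- as.numeric(concentrationPct)
  if (any(c_ < 0)) stop("concentration must be non-negative")
  y <- 0.00002 * c_^4 - 0.0007 * c_^3 + 0.0311 * c_^2 + 0.5596 * c_
  data.frame(concentration_pct = c_, pressure_atm = y,
             pressure_kPa = y * 101.325,
             osmolarity_mOsm_L = pegOsmolarity(c_))
}

#' Osmolarity contributed by PEG 400
#'
#' `25 c` mOsm/L for a concentration of `c` percent wt/vol
#' (10 c g/L over 0.400 kg/mol).
#'
#' @inheritParams pegPressure
#' @return Osmolarity in mOsm/L.
#' @export
pegOsmolarity <- function(concentrationPct) {
  c_ <- as.numeric(concentrationPct)
  if (any(c_ < 0)) stop("concentration must be non-negative")
  25 * c_
}

#' Osmolarity scale factor of hypoosmotic dilution
#'
#' Diluting medium with a water volume fraction `w` scales its
#' osmolarity by `1 - w` (the protocol used 20% deionized water, factor
#' 0.8).
#'
#' @param waterFraction volume fraction of added water, in `[0, 1)`.
#' @return Scale factor `1 - waterFraction`.
#' @export
hypoosmoticFactor <- function(waterFraction) {
  w <- as.numeric(waterFraction)
  if (any(w < 0 | w >= 1)) stop("waterFraction must be in [0, 1)")
  1 - w
}
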