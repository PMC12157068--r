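#' Mean photosynthesis limitation of the whole plant layer
#'
#' Depth-averaged light limitation factor of a floating duckweed mat. Light
#' entering at the surface with intensity `I_S` decays exponentially with
#' optical depth (Beer-Lambert, attenuation `eps_hat` per unit areal density),
#' and photosynthesis responds to local intensity through a Monod factor
#' \eqn{I/(k+I)}. Averaging the Monod factor over the layer gives the closed
#' form
#' \deqn{\bar f_{phot}(I_S, D) = \frac{\ln(k + I_S) - \ln(k + I_S e^{-\hat\varepsilon D})}{\hat\varepsilon D},}
#' a value in \eqn{[0, 1)} that decreases with density (self-shading) and
#' increases with surface intensity.
#'
#' For \eqn{\hat\varepsilon D < 10^{-8}} the expression is a numerically
#' unstable 0/0 and the analytic zero-depth limit \eqn{I_S/(k + I_S)} is
#' returned instead; the two branches agree to well below 1e-8 at the switch.
#'
#' @param I_S Surface light intensity (PPFD), umol m^-2 s^-1. Vectorized.
#' @param D Areal dry-weight density, gDW m^-2. Vectorized.
#' @param params A [growth_params()] object.
#' @return Dimensionless limitation factor(s) in `[0, 1)`.
#' @export
#' @examples
#' p <- reference_growth_params()
#' mean_photosynthesis_limitation(166.2, 170, p)
mean_photosynthesis_limitation <- function(I_S, D, params) {
  stopifnot(inherits(params, "growth_params"), is.numeric(I_S), is.numeric(D))
  if (any(I_S < 0)) stop("I_S must be >= 0", call. = FALSE)
  if (any(D < 0)) stop("D must be >= 0", call. = FALSE)
  k <- params$k
  x <- params$eps_hat * D
  n <- max(length(I_S), length(D))
  I_S <- rep_len(I_S, n)
  x <- rep_len(x, n)
  out <- numeric(n)
  small <- x < 1e-8
  out[small] <- I_S[small] / (k + I_S[small])
  xl <- x[!small]
  il <- I_S[!small]
  # log(k+I_S) - log(k+I_S e^-x) rewritten via log1p/expm1: no cancellation
  out[!small] <- log1p(il * (-expm1(-xl)) / (k + il * exp(-xl))) / xl
  out
}

#' Monod limitation at a given optical depth in the plant layer
#'
#' Local (not depth-averaged) light limitation at optical depth `exponent`
#' \eqn{= \hat\varepsilon D s}, \eqn{s \in [0,1]}, inside the mat: the light
#' intensity there is \eqn{I = I_S e^{-exponent}} and the factor returned is
#' \eqn{I/(k + I)}. Diagnostic companion of
#' [mean_photosynthesis_limitation()].
#'
#' @param I_S Surface light intensity, umol m^-2 s^-1.
#' @param exponent Dimensionless optical depth \eqn{\hat\varepsilon D s},
#'   >= 0. Vectorized.
#' @param params A [growth_params()] object.
#' @return Dimensionless limitation factor(s), non-increasing in `exponent`.
#' @export
depth_resolved_limitation <- function(I_S, exponent, params) {
  stopifnot(inherits(params, "growth_params"), is.numeric(I_S), is.numeric(exponent))
  if (any(I_S < 0)) stop("I_S must be >= 0", call. = FALSE)
  if (any(exponent < 0)) stop("optical depth must be >= 0", call. = FALSE)
  I <- I_S * exp(-exponent)
  I / (params$k + I)
}

#' Instantaneous growth rate of areal density
#'
#' Right-hand side of the density ODE, for either model. For the canopy model
#' \deqn{dD/dt = D (E\, r_{phot,i}\, \bar f_{phot}(I_S, D) - r_{resp});}
#' for the logistic comparator see [vandyck_params()].
#'
#' @param D Areal density, gDW m^-2 (vectorized).
#' @param I_S Surface light intensity, umol m^-2 s^-1 (vectorized).
#' @param params A [growth_params()] or [vandyck_params()] object.
#' @return dD/dt in gDW m^-2 d^-1.
#' @export
growth_rate <- function(D, I_S, params) UseMethod("growth_rate", params)

#' @export
growth_rate.growth_params <- function(D, I_S, params) {
  f <- mean_photosynthesis_limitation(I_S, D, params)
  D * (params$E * params$r_phot_i * f - params$r_resp)
}

#' @export
growth_rate.vandyck_params <- function(D, I_S, params) {
  if (any(D < 0)) stop("D must be >= 0", call. = FALSE)
  if (any(I_S < 0)) stop("I_S must be >= 0", call. = FALSE)
  monod <- I_S / (params$K_I + I_S)
  D * (params$r_phot_i * (1 - D / params$h_D) * params$E * monod - params$r_resp)
}

#' @rdname growth_rate
#' @export
vandyck_growth_rate <- function(D, I_S, params) {
  stopifnot(inherits(params, "vandyck_params"))
  growth_rate.vandyck_params(D, I_S, params)
}

#' Simulate a density trajectory
#'
#' Integrates the density ODE from `D_0` at constant surface intensity with an
#' embedded Dormand-Prince 5(4) scheme (adaptive error control, `rtol` 1e-8 /
#' `atol` 1e-10 by default) and reports the solution on a regular grid with
#' spacing `step` (default 0.05 d, the conventional reporting grid).
#' Photoperiod enters only through the constant factor `E`; no day/night
#' switching is simulated.
#'
#' @param D_0 Initial areal density, gDW m^-2, >= 0.
#' @param I_S Surface light intensity, umol m^-2 s^-1, held constant.
#' @param params A [growth_params()] or [vandyck_params()] object.
#' @param t_end Simulation horizon, d, > 0.
#' @param step Reporting grid spacing, d (default 0.05).
#' @param rtol,atol Relative/absolute local error tolerances.
#' @return A `lemna_trajectory`: a data frame with columns `time_d` and
#'   `density_gdw_m2`, with the run configuration in attributes.
#' @export
#' @examples
#' tr <- simulate_growth(10, 123.9, reference_growth_params(), t_end = 7)
#' tail(tr, 1)
simulate_growth <- function(D_0, I_S, params, t_end, step = 0.05,
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(length(D_0) == 1L, length(I_S) == 1L, length(t_end) == 1L)
  if (D_0 < 0) stop("D_0 must be >= 0", call. = FALSE)
  if (I_S < 0) stop("I_S must be >= 0", call. = FALSE)
  if (t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  times <- seq(0, t_end, by = step)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  dens <- .cpp_simulate(D_0, I_S, param_vector(params), model_code(params),
                        times, rtol, atol)
  structure(
    data.frame(time_d = times, density_gdw_m2 = dens),
    I_S = I_S, params = params, method = "dormand-prince-5(4)",
    step = step, rtol = rtol, atol = atol,
    class = c("lemna_trajectory", "data.frame")
  )
}

#' @export
print.lemna_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf(
    "<lemna_trajectory> %d points over %g d at I_S = %g umol m-2 s-1\n",
    n, x$time_d[n], attr(x, "I_S")
  ))
  cat(sprintf("  D: %.4g -> %.4g gDW m-2 (%s)\n",
              x$density_gdw_m2[1L], x$density_gdw_m2[n], attr(x, "method")))
  invisible(x)
}

#' Write / read a trajectory as CSV
#'
#' CSV dialect: header `time_d,density_gdw_m2`.
#' @param trajectory A `lemna_trajectory` (or compatible data frame).
#' @param path File path.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(trajectory[, c("time_d", "density_gdw_m2")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Limit density (carrying capacity) at a given light intensity
#'
#' The limit density \eqn{D_L} is the saturation value of the growth curve:
#' the density at which photoperiod-scaled photosynthesis exactly balances
#' respiration. It is found as the unique positive root of the per-capita
#' rate, by bracketed root-finding to a residual below 1e-9 (a long-horizon
#' simulation gives the same value and is used as a cross-check in the test
#' suite). Below the compensation intensity (see
#' [compensation_intensity()]) no positive root exists and 0 is returned.
#'
#' @param I_S Surface light intensity, umol m^-2 s^-1. Vectorized.
#' @param params A [growth_params()] or [vandyck_params()] object. For
#'   `r_resp = 0` the density grows without bound and an error of class
#'   `lemnagrow_no_finite_limit` is signalled.
#' @return Limit density(ies), gDW m^-2.
#' @export
#' @examples
#' limit_density(c(42.7, 166.2), reference_growth_params())
limit_density <- function(I_S, params) {
  stopifnot(is.numeric(I_S))
  if (any(I_S < 0)) stop("I_S must be >= 0", call. = FALSE)
  if (params$r_resp <= 0) {
    stop(structure(
      class = c("lemnagrow_no_finite_limit", "error", "condition"),
      list(message = "r_resp = 0: density is unbounded, no finite limit density",
           call = sys.call())
    ))
  }
  vapply(I_S, function(i) limit_density_scalar(i, params), numeric(1))
}

limit_density_scalar <- function(I_S, params) {
  if (inherits(params, "vandyck_params")) {
    # closed form from the logistic structure
    monod <- I_S / (params$K_I + I_S)
    gross <- params$r_phot_i * params$E * monod
    if (gross <= params$r_resp) return(0)
    return(params$h_D * (1 - params$r_resp / gross))
  }
  percap <- function(D) {
    params$E * params$r_phot_i * mean_photosynthesis_limitation(I_S, D, params) -
      params$r_resp
  }
  if (percap(0) <= 0) return(0)
  upper <- 10
  while (percap(upper) > 0) {
    upper <- upper * 2
    if (upper > 1e9) stop("no finite limit density found below 1e9", call. = FALSE)
  }
  stats::uniroot(percap, c(0, upper), tol = 1e-12)$root
}

#' Compensation light intensity
#'
#' The surface intensity below which even a vanishingly thin mat cannot
#' compensate respiration, i.e. where
#' \eqn{E\, r_{phot,i}\, I_S/(k + I_S) = r_{resp}}:
#' \eqn{I_c = r_{resp} k / (E\, r_{phot,i} - r_{resp})}. Below `I_c` the limit
#' density is 0.
#'
#' @param params A [growth_params()] object.
#' @return Intensity in umol m^-2 s^-1 (`Inf` if gross photosynthesis can
#'   never exceed respiration).
#' @export
compensation_intensity <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  net_max <- params$E * params$r_phot_i - params$r_resp
  if (net_max <= 0) return(Inf)
  params$r_resp * params$k / net_max
}

#' Dry-weight content of a biomass sample
#'
#' Fraction of fresh weight that is dry matter, \eqn{\%DW = DW/FW}. Duckweed
#' in recirculating culture holds a long-term dry-weight content of about 6%.
#'
#' @param dry_weight Dry weight, g; must satisfy 0 < DW <= FW.
#' @param fresh_weight Fresh weight, g; must be > 0.
#' @return Fraction in (0, 1].
#' @export
#' @examples
#' dry_weight_content(1.2, 20) # 0.06
dry_weight_content <- function(dry_weight, fresh_weight) {
  if (any(fresh_weight <= 0)) stop("fresh weight must be > 0", call. = FALSE)
  if (any(dry_weight <= 0) || any(dry_weight > fresh_weight)) {
    stop("dry weight must satisfy 0 < DW <= FW", call. = FALSE)
  }
  dry_weight / fresh_weight
}

#' Leaf area index estimated from areal density
#'
#' LAI = D / LMA, with leaf mass per area LMA defaulting to 11.5 g m^-2, a
#' literature value for Lemna minor. LMA likely varies with environment; treat
#' the result as a rough conversion, which is why density rather than LAI is
#' modelled throughout.
#'
#' @param D Areal density, gDW m^-2, >= 0.
#' @param LMA Leaf mass per area, g m^-2, > 0.
#' @return Dimensionless leaf area index.
#' @export
lai_estimate <- function(D, LMA = 11.5) {
  if (any(D < 0)) stop("D must be >= 0", call. = FALSE)
  if (any(LMA <= 0)) stop("LMA must be > 0", call. = FALSE)
  D / LMA
}
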