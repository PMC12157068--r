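#' Average daily yield of one harvest cycle
#'
#' In a semi-continuous process, biomass is let grow from the residual density
#' `d_start` for one harvest interval `delta_t_h` and the increment is then
#' removed, so the average daily yield of the cycle is
#' \eqn{(D(\Delta t_H; D_{start}) - D_{start}) / \Delta t_H}.
#' `delta_t_h = 0` denotes continuous harvesting, whose yield is the
#' instantaneous net growth rate at `d_start`.
#'
#' @param d_start Residual density left after harvest, gDW m^-2, > 0.
#' @param delta_t_h Harvest interval, d, >= 0.
#' @param i_s Surface light intensity, umol m^-2 s^-1.
#' @param params A parameter object.
#' @param rtol,atol Integrator tolerances.
#' @return Average daily harvestable yield, gDW m^-2 d^-1.
#' @export
cycle_average_yield <- function(d_start, delta_t_h, i_s, params,
                                rtol = 1e-8, atol = 1e-10) {
  if (any(d_start <= 0)) stop("d_start must be > 0", call. = FALSE)
  if (delta_t_h < 0) stop("delta_t_h must be >= 0", call. = FALSE)
  if (delta_t_h == 0) {
    return(growth_rate(d_start, i_s, params))
  }
  term <- .cpp_terminal(d_start, rep_len(i_s, length(d_start)),
                        rep_len(delta_t_h, length(d_start)),
                        param_vector(params), model_code(params), rtol, atol)
  (term - d_start) / delta_t_h
}

# Shared optimizer: coarse grid over (0, D_L), unimodality screen, then local
# refinement of every interior candidate. Returns list(d_opt, yield, d_l).
optimize_cycle <- function(delta_t_h, i_s, params, rtol = 1e-8, atol = 1e-10,
                           n_grid = 61L) {
  d_l <- limit_density(i_s, params)
  if (d_l <= 0) {
    return(list(d_opt = 0, yield = 0, d_l = 0))
  }
  eps <- min(1e-6, d_l * 1e-6)
  grid <- seq(eps, d_l - eps, length.out = n_grid)
  y <- cycle_average_yield(grid, delta_t_h, i_s, params, rtol, atol)
  f <- function(d) cycle_average_yield(d, delta_t_h, i_s, params, rtol, atol)
  # candidate brackets around every local maximum of the coarse profile
  is_locmax <- which(diff(sign(diff(y))) < 0) + 1L
  if (!length(is_locmax)) is_locmax <- which.max(y)
  best <- list(objective = -Inf, maximum = grid[which.max(y)])
  for (i in is_locmax) {
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(n_grid, i + 1L)]
    opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-7)
    if (opt$objective > best$objective) best <- opt
  }
  d_opt <- best$maximum
  yield <- best$objective
  if (yield <= 0) return(list(d_opt = 0, yield = 0, d_l = d_l))
  list(d_opt = d_opt, yield = yield, d_l = d_l)
}

#' Optimal residual density after harvest
#'
#' The residual density \eqn{D_{opt} \in (0, D_L)} that maximizes the average
#' daily yield of a harvest cycle, found by bounded scalar maximization
#' (absolute tolerance about 1e-6 gDW m^-2) after a coarse-grid unimodality
#' screen. Below the compensation intensity no net growth is possible and 0 is
#' returned. Longer harvest intervals reduce `D_opt`; higher intensities raise
#' it towards saturation.
#'
#' @inheritParams cycle_average_yield
#' @return Optimal residual density, gDW m^-2.
#' @export
#' @examples
#' optimal_residual_density(0, 166.2, reference_growth_params())
optimal_residual_density <- function(delta_t_h, i_s, params,
                                     rtol = 1e-8, atol = 1e-10) {
  optimize_cycle(delta_t_h, i_s, params, rtol, atol)$d_opt
}

#' Maximum average daily yield
#'
#' The average daily yield of a density-optimized harvest process:
#' [cycle_average_yield()] evaluated at the optimal residual density. It is
#' non-increasing in the harvest interval (continuous harvesting keeps the
#' culture at its optimum density at all times) and saturates with intensity.
#'
#' @inheritParams cycle_average_yield
#' @return Maximum average daily yield, gDW m^-2 d^-1.
#' @export
max_daily_yield <- function(delta_t_h, i_s, params, rtol = 1e-8, atol = 1e-10) {
  optimize_cycle(delta_t_h, i_s, params, rtol, atol)$yield
}

lue_dose_factor <- function(i_s, params, convention) {
  if (convention == "daily-dose") {
    # umol m-2 s-1 -> mmol m-2 d-1 of photons delivered during the lit fraction
    i_s * params$E * 86400 / 1000
  } else {
    i_s
  }
}

#' Light use efficiency of a density-optimized process
#'
#' Harvested dry mass per photon quantity delivered,
#' \eqn{LUE = \dot m_{max}(\Delta t_H, I_S) / dose(I_S)} in gDW mmol^-1 under
#' the default convention, which converts the surface intensity to a daily
#' photon dose \eqn{I_S \cdot E \cdot 86400/1000} mmol m^-2 d^-1 (photons are
#' counted only during the illuminated fraction `E` of the day).
#' `convention = "raw"` divides by `I_S` directly, reproducing the bare ratio;
#' the two differ by a constant factor, so the location of the LUE maximum
#' over `I_S` is convention-invariant. The convention used is recorded in the
#' `"convention"` attribute of the result.
#'
#' @inheritParams cycle_average_yield
#' @param i_s Surface light intensity, umol m^-2 s^-1, > 0.
#' @param convention `"daily-dose"` (default) or `"raw"`.
#' @return LUE (gDW mmol^-1 for `"daily-dose"`), with attribute `convention`.
#' @export
light_use_efficiency <- function(delta_t_h, i_s, params,
                                 convention = c("daily-dose", "raw"),
                                 rtol = 1e-8, atol = 1e-10) {
  convention <- match.arg(convention)
  if (any(i_s <= 0)) stop("LUE undefined at I_S = 0", call. = FALSE)
  m <- vapply(i_s, function(i) max_daily_yield(delta_t_h, i, params, rtol, atol),
              numeric(1))
  structure(m / lue_dose_factor(i_s, params, convention),
            convention = convention)
}

#' Light intensity of maximum light use efficiency
#'
#' Locates \eqn{I_{LUEmax}}, the surface intensity maximizing the light use
#' efficiency for a given harvest interval, by a coarse log-spaced grid over
#' `(0, i_max]` followed by bounded scalar refinement of every interior
#' candidate. If the parameters admit no positive net growth anywhere (LUE
#' identically zero), an error of class `lemnagrow_no_lue_maximum` is
#' signalled.
#'
#' @inheritParams light_use_efficiency
#' @param i_max Upper end of the searched intensity range,
#'   umol m^-2 s^-1 (default 500, the conventional simulated range).
#' @return The LUE-maximizing intensity, umol m^-2 s^-1.
#' @export
#' @examples
#' lue_optimal_intensity(0, reference_growth_params())
lue_optimal_intensity <- function(delta_t_h, params,
                                  convention = c("daily-dose", "raw"),
                                  i_max = 500, rtol = 1e-8, atol = 1e-10) {
  convention <- match.arg(convention)
  lue <- function(i) {
    as.numeric(light_use_efficiency(delta_t_h, i, params, convention,
                                    rtol, atol))
  }
  grid <- exp(seq(log(0.1), log(i_max), length.out = 80L))
  vals <- vapply(grid, lue, numeric(1))
  if (all(vals <= 0)) {
    stop(structure(
      class = c("lemnagrow_no_lue_maximum", "error", "condition"),
      list(message = "LUE is zero everywhere: no positive maximum exists",
           call = sys.call())
    ))
  }
  cand <- which(diff(sign(diff(vals))) < 0) + 1L
  if (!length(cand)) cand <- which.max(vals)
  best <- list(objective = -Inf, maximum = grid[which.max(vals)])
  for (i in cand) {
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(lue, c(lo, hi), maximum = TRUE, tol = 1e-5)
    if (opt$objective > best$objective) best <- opt
  }
  best$maximum
}

#' Sweep the harvest-process optimum over light and interval grids
#'
#' Evaluates the density-optimized process over a grid of surface intensities
#' and a set of harvest intervals, one row per combination: the optimal
#' residual density, the maximum average daily yield, and the light use
#' efficiency. Failures in individual cells are recorded in the `status`
#' column and the sweep continues.
#'
#' @param params A parameter object.
#' @param i_s_grid Intensities to sweep, umol m^-2 s^-1 (non-empty).
#' @param delta_t_h_set Harvest intervals, d (non-empty).
#' @inheritParams light_use_efficiency
#' @return A data frame with columns `i_s_umol_m2_s`, `delta_t_h_d`,
#'   `d_opt_gdw_m2`, `m_dot_max_gdw_m2_d`, `lue_gdw_mmol`, `d_l_gdw_m2`,
#'   `status`; attribute `convention`.
#' @export
harvest_sweep <- function(params, i_s_grid, delta_t_h_set,
                          convention = c("daily-dose", "raw"),
                          rtol = 1e-8, atol = 1e-10) {
  convention <- match.arg(convention)
  if (!length(i_s_grid) || !length(delta_t_h_set)) {
    stop("grids must be non-empty", call. = FALSE)
  }
  cells <- expand.grid(i_s_umol_m2_s = i_s_grid, delta_t_h_d = delta_t_h_set,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(idx) {
    i_s <- cells$i_s_umol_m2_s[idx]
    dth <- cells$delta_t_h_d[idx]
    tryCatch({
      oc <- optimize_cycle(dth, i_s, params, rtol, atol)
      lue <- if (i_s > 0) oc$yield / lue_dose_factor(i_s, params, convention)
             else NA_real_
      data.frame(d_opt_gdw_m2 = oc$d_opt, m_dot_max_gdw_m2_d = oc$yield,
                 lue_gdw_mmol = lue, d_l_gdw_m2 = oc$d_l, status = "ok",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(d_opt_gdw_m2 = NA_real_, m_dot_max_gdw_m2_d = NA_real_,
                 lue_gdw_mmol = NA_real_, d_l_gdw_m2 = NA_real_,
                 status = conditionMessage(e), stringsAsFactors = FALSE)
    })
  })
  out <- cbind(cells, do.call(rbind, res))
  attr(out, "convention") <- convention
  out
}

#' Write a harvest sweep as CSV plus a metadata JSON
#'
#' The CSV carries the columns
#' `i_s_umol_m2_s,delta_t_h_d,d_opt_gdw_m2,m_dot_max_gdw_m2_d,lue_gdw_mmol`;
#' the side-car `<path>.meta.json` records parameters, convention and grids.
#'
#' @param sweep Output of [harvest_sweep()].
#' @param params The parameter object used.
#' @param path CSV output path.
#' @export
write_sweep <- function(sweep, params, path) {
  utils::write.csv(
    sweep[, c("i_s_umol_m2_s", "delta_t_h_d", "d_opt_gdw_m2",
              "m_dot_max_gdw_m2_d", "lue_gdw_mmol")],
    path, row.names = FALSE, quote = FALSE
  )
  jsonlite::write_json(
    list(params = unclass(params), model = class(params)[1L],
         convention = attr(sweep, "convention"),
         i_s_grid = unique(sweep$i_s_umol_m2_s),
         delta_t_h_set = unique(sweep$delta_t_h_d)),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
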