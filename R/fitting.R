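#' Assemble growth-trial records
#'
#' One record per ring-subarea growth trial: the initial density, the density
#' observed at the end of the trial, the (kriged) mean surface light intensity
#' of the subarea, and the trial duration. These records are the unit of
#' least-squares fitting.
#'
#' @param trial_id Character identifiers (unique per trial).
#' @param i_s_umol_m2_s Per-subarea mean surface intensity, umol m^-2 s^-1.
#' @param d0_gdw_m2 Initial areal density, gDW m^-2, > 0.
#' @param d7_gdw_m2 Observed end-of-trial density, gDW m^-2, > 0.
#' @param duration_d Trial duration, d (default 7).
#' @return A data frame of class `trial_records`.
#' @export
trial_records <- function(trial_id, i_s_umol_m2_s, d0_gdw_m2, d7_gdw_m2,
                          duration_d = 7) {
  df <- data.frame(
    trial_id = as.character(trial_id),
    i_s_umol_m2_s = as.numeric(i_s_umol_m2_s),
    d0_gdw_m2 = as.numeric(d0_gdw_m2),
    d7_gdw_m2 = as.numeric(d7_gdw_m2),
    duration_d = as.numeric(duration_d),
    stringsAsFactors = FALSE
  )
  validate_trials(df)
  class(df) <- c("trial_records", "data.frame")
  df
}

validate_trials <- function(df) {
  need <- c("trial_id", "i_s_umol_m2_s", "d0_gdw_m2", "d7_gdw_m2", "duration_d")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$d0_gdw_m2 <= 0) || any(df$d7_gdw_m2 <= 0)) {
    stop("densities must be > 0", call. = FALSE)
  }
  if (any(df$i_s_umol_m2_s < 0)) stop("I_S must be >= 0", call. = FALSE)
  if (any(df$duration_d <= 0)) stop("duration must be > 0", call. = FALSE)
  invisible(df)
}

#' Read / write trial and long-term CSV tables
#'
#' Trial CSV dialect: `trial_id,i_s_umol_m2_s,d0_gdw_m2,d7_gdw_m2,duration_d`.
#' Long-term CSV dialect: `series_id,i_s_umol_m2_s,time_d,density_gdw_m2`,
#' one row per biweekly observation, times starting at 0.
#'
#' @param path File path.
#' @return `read_trials()` a `trial_records` data frame; `read_longterm()` a
#'   `longterm_series` data frame.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trials(df)
  class(df) <- c("trial_records", "data.frame")
  df
}

#' @rdname read_trials
#' @param trials A `trial_records` data frame.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(
    trials[, c("trial_id", "i_s_umol_m2_s", "d0_gdw_m2", "d7_gdw_m2", "duration_d")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname read_trials
#' @export
read_longterm <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_longterm(df)
  class(df) <- c("longterm_series", "data.frame")
  df
}

#' @rdname read_trials
#' @param series A `longterm_series` data frame.
#' @export
write_longterm <- function(series, path) {
  validate_longterm(series)
  utils::write.csv(
    series[, c("series_id", "i_s_umol_m2_s", "time_d", "density_gdw_m2")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

validate_longterm <- function(df) {
  need <- c("series_id", "i_s_umol_m2_s", "time_d", "density_gdw_m2")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("long-term table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$density_gdw_m2 <= 0)) stop("densities must be > 0", call. = FALSE)
  for (id in unique(df$series_id)) {
    tt <- df$time_d[df$series_id == id]
    if (tt[1L] != 0 || any(diff(tt) <= 0)) {
      stop("series ", id, ": times must be strictly increasing from 0",
           call. = FALSE)
    }
  }
  invisible(df)
}

#' Predict end-of-trial densities
#'
#' Terminal density of each trial's trajectory: the initial density integrated
#' forward over the trial duration at the trial's surface intensity.
#'
#' @param trials A `trial_records` data frame.
#' @param params A [growth_params()] or [vandyck_params()] object.
#' @param rtol,atol Integrator tolerances.
#' @return Numeric vector of predicted densities, gDW m^-2, one per trial.
#' @export
predict_final_density <- function(trials, params, rtol = 1e-8, atol = 1e-10) {
  validate_trials(trials)
  tryCatch(
    .cpp_terminal(trials$d0_gdw_m2, trials$i_s_umol_m2_s, trials$duration_d,
                  param_vector(params), model_code(params), rtol, atol),
    error = function(e) {
      stop("prediction failed (first trial id: ", trials$trial_id[1L], "): ",
           conditionMessage(e), call. = FALSE)
    }
  )
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with the total sum of squares taken about
#' the observed mean. May be negative for models worse than the mean.
#'
#' @param observed,predicted Numeric vectors of equal nonzero length.
#' @return A single number <= 1.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) == 0L) {
    stop("observed and predicted must have equal nonzero length", call. = FALSE)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("R^2 undefined: zero variance in observations", call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

fit_param_names <- function(model) {
  if (model == "canopy") c("r_phot_i", "r_resp", "eps_hat", "k")
  else c("r_phot_i", "r_resp", "h_D", "K_I")
}

fit_default_init <- function(model) {
  if (model == "canopy") c(r_phot_i = 0.5, r_resp = 0.05, eps_hat = 0.1, k = 20)
  else c(r_phot_i = 0.2, r_resp = 0.02, h_D = 70, K_I = 30)
}

make_params <- function(theta, model, E) {
  if (model == "canopy") growth_params(theta[1L], theta[2L], theta[3L], theta[4L], E)
  else vandyck_params(theta[1L], theta[2L], theta[3L], theta[4L], E)
}

#' Fit a growth model to end-of-trial densities
#'
#' Estimates the four free kinetic parameters by minimizing the residual sum
#' of squares of observed vs predicted end-of-trial densities. The photoperiod
#' `E` is fixed, not estimated. Optimization runs in log-parameter space
#' (which enforces positivity) with a Nelder-Mead search from the initial
#' estimates followed by a quasi-Newton (BFGS) polish; estimates are reported
#' on the natural scale.
#'
#' Standard errors use the Gauss-Newton Hessian approximation
#' \eqn{\hat\sigma^2 (J^T J)^{-1}} with \eqn{\hat\sigma^2 = RSS/(n-p)} and `J`
#' the numerical Jacobian of the predictions at the optimum; p-values are
#' two-sided t with `n - p` degrees of freedom. `hessian = "full"` instead
#' uses a finite-difference Hessian of the RSS surface
#' (\eqn{2\hat\sigma^2 H^{-1}}). A singular information matrix yields `NA`
#' standard errors, flagged, never fabricated values.
#'
#' @param trials A `trial_records` data frame with at least as many trials as
#'   free parameters (4).
#' @param model `"canopy"` (Beer-Lambert x Monod) or `"vandyck"` (logistic
#'   comparator).
#' @param init Named or positional initial estimates on the natural scale.
#'   Defaults: canopy `(0.5, 0.05, 0.1, 20)`, comparator `(0.2, 0.02, 70, 30)`.
#' @param E Fixed photoperiod fraction (default 14/24).
#' @param hessian `"gauss-newton"` (default) or `"full"`.
#' @param rtol,atol Integrator tolerances used inside the objective.
#' @return A `lemna_fit` object: list with `model`, `estimate`, `se`,
#'   `p_value`, `rss`, `r_squared`, `sigma2`, `df`, `convergence`,
#'   `iterations`, `trace` (accepted objective values, non-increasing),
#'   `init`, `n`, `fitted_params` (a parameter object ready for simulation).
#' @export
#' @examples
#' set.seed(1)
#' tr <- generate_trials(noise = noise_spec(0, 0, 0, seed = 1))
#' fit <- fit_growth_model(tr, "canopy")
#' fit$estimate
fit_growth_model <- function(trials, model = c("canopy", "vandyck"),
                             init = NULL, E = 14 / 24,
                             hessian = c("gauss-newton", "full"),
                             rtol = 1e-8, atol = 1e-10) {
  model <- match.arg(model)
  hessian <- match.arg(hessian)
  validate_trials(trials)
  pnames <- fit_param_names(model)
  p <- length(pnames)
  n <- nrow(trials)
  if (n < p) stop("need at least ", p, " trials to fit ", p, " parameters",
                  call. = FALSE)
  if (is.null(init)) init <- fit_default_init(model)
  init <- stats::setNames(as.numeric(init), pnames)
  if (any(init <= 0)) stop("initial estimates must be > 0", call. = FALSE)

  mcode <- if (model == "canopy") 0L else 1L
  obs <- trials$d7_gdw_m2
  pred_at <- function(theta) {
    .cpp_terminal(trials$d0_gdw_m2, trials$i_s_umol_m2_s, trials$duration_d,
                  c(theta, E), mcode, rtol, atol)
  }

  trace_env <- new.env(parent = emptyenv())
  trace_env$best <- Inf
  trace_env$trace <- numeric(0)
  objective <- function(ltheta) {
    theta <- exp(ltheta)
    if (any(!is.finite(theta))) return(1e30)
    rss <- tryCatch(sum((obs - pred_at(theta))^2),
                    error = function(e) 1e30)
    if (!is.finite(rss)) rss <- 1e30
    if (rss < trace_env$best) {
      trace_env$best <- rss
      trace_env$trace <- c(trace_env$trace, rss)
    }
    rss
  }

  o1 <- stats::optim(log(init), objective, method = "Nelder-Mead",
                     control = list(maxit = 3000, reltol = 1e-13))
  o2 <- tryCatch(
    stats::optim(o1$par, objective, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14)),
    error = function(e) o1
  )
  best <- if (o2$value <= o1$value) o2 else o1
  # final Nelder-Mead pass guards against BFGS stalling on FD-gradient noise
  o3 <- stats::optim(best$par, objective, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-13))
  if (o3$value < best$value) best <- o3

  theta <- stats::setNames(exp(best$par), pnames)
  rss <- best$value
  converged <- is.finite(rss) && rss < 1e29
  pred <- pred_at(theta)
  r2 <- r_squared(obs, pred)
  sigma2 <- rss / (n - p)

  se <- rep(NA_real_, p)
  if (converged) {
    cov <- tryCatch({
      if (hessian == "gauss-newton") {
        J <- matrix(0, n, p)
        for (j in seq_len(p)) {
          hstep <- max(abs(theta[j]), 1e-8) * 1e-6
          up <- theta; up[j] <- up[j] + hstep
          dn <- theta; dn[j] <- dn[j] - hstep
          J[, j] <- (pred_at(up) - pred_at(dn)) / (2 * hstep)
        }
        sigma2 * solve(crossprod(J))
      } else {
        rss_nat <- function(th) sum((obs - pred_at(th))^2)
        H <- stats::optimHess(theta, rss_nat)
        2 * sigma2 * solve(H)
      }
    }, error = function(e) NULL)
    if (!is.null(cov)) {
      dg <- diag(cov)
      se <- ifelse(dg > 0, sqrt(dg), NA_real_)
    } else {
      warning("singular information matrix: standard errors undefined",
              call. = FALSE)
    }
  }
  se <- stats::setNames(se, pnames)
  tval <- theta / se
  pval <- stats::setNames(2 * stats::pt(-abs(tval), df = n - p), pnames)

  structure(
    list(
      model = model,
      estimate = theta,
      se = se,
      p_value = pval,
      rss = rss,
      r_squared = r2,
      sigma2 = sigma2,
      df = n - p,
      convergence = converged && best$convergence == 0,
      iterations = length(trace_env$trace),
      trace = trace_env$trace,
      init = init,
      n = n,
      E = E,
      fitted_params = make_params(theta, model, E)
    ),
    class = "lemna_fit"
  )
}

#' @export
print.lemna_fit <- function(x, ...) {
  cat(sprintf("<lemna_fit: %s model, n = %d trials>\n", x$model, x$n))
  tab <- data.frame(
    estimate = signif(x$estimate, 6),
    std_error = signif(x$se, 4),
    p_value = signif(x$p_value, 3)
  )
  print(tab)
  cat(sprintf("E (fixed) = %.4f   RSS = %.6g   R^2 = %.4f   converged: %s\n",
              x$E, x$rss, x$r_squared, x$convergence))
  invisible(x)
}

#' Export a fit as JSON
#'
#' @param fit A `lemna_fit` object.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(
      model = fit$model,
      estimate = as.list(fit$estimate),
      std_error = as.list(fit$se),
      p_value = as.list(fit$p_value),
      E_fixed = fit$E,
      rss = fit$rss,
      r_squared = fit$r_squared,
      n = fit$n,
      converged = fit$convergence,
      initial_estimates = as.list(fit$init)
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Score a fitted model against long-term observations
#'
#' Fixed-parameter validation: for each series, the model is simulated from
#' the first observed density (no refitting, parameters copied as-is) and the
#' observed densities are scored against the model densities at the
#' observation times via [r_squared()].
#'
#' @param series A `longterm_series` data frame (columns `series_id`,
#'   `i_s_umol_m2_s`, `time_d`, `density_gdw_m2`).
#' @param params A fitted parameter object.
#' @param rtol,atol Integrator tolerances.
#' @return A data frame with one row per series: `series_id`,
#'   `i_s_umol_m2_s`, `n_obs`, `r_squared`.
#' @export
validate_long_term <- function(series, params, rtol = 1e-8, atol = 1e-10) {
  validate_longterm(series)
  ids <- unique(series$series_id)
  out <- lapply(ids, function(id) {
    s <- series[series$series_id == id, ]
    pred <- .cpp_simulate(s$density_gdw_m2[1L], s$i_s_umol_m2_s[1L],
                          param_vector(params), model_code(params),
                          s$time_d, rtol, atol)
    data.frame(
      series_id = id,
      i_s_umol_m2_s = s$i_s_umol_m2_s[1L],
      n_obs = nrow(s),
      r_squared = r_squared(s$density_gdw_m2, pred),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
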