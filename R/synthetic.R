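#' Factorial design of a growth-trial experiment
#'
#' The default reproduces the reference experiment's layout: 6 initial
#' densities x 4 surface intensities x 5 replicates, 7-day trials, 120 trials
#' in total.
#'
#' @param initial_densities Initial areal densities, gDW m^-2.
#' @param light_intensities Surface intensities, umol m^-2 s^-1.
#' @param replicates Replicates per cell (>= 1).
#' @param duration_d Trial duration, d.
#' @return A list of class `trial_design`.
#' @export
trial_design <- function(initial_densities = c(10, 42, 74, 106, 138, 170),
                         light_intensities = c(42.7, 88.2, 123.9, 166.2),
                         replicates = 5L, duration_d = 7) {
  stopifnot(all(initial_densities > 0), all(light_intensities > 0),
            replicates >= 1L, duration_d > 0)
  structure(
    list(initial_densities = initial_densities,
         light_intensities = light_intensities,
         replicates = as.integer(replicates), duration_d = duration_d),
    class = "trial_design"
  )
}

#' Noise specification for the synthetic generators
#'
#' All noise is mean-one multiplicative lognormal, so the noise-free
#' expectation coincides with the deterministic model. The default CVs are
#' placeholders: the true replicate-level variability of the reference
#' experiment is unpublished. The initial-density jitter mimics the post hoc
#' dry-weight-content correction of the stocking weights.
#'
#' @param d7_cv CV of the multiplicative observation noise on final densities.
#' @param i_s_cv CV of the per-subarea intensity jitter.
#' @param d0_cv CV of the initial-density jitter.
#' @param seed Integer RNG seed; every generator is a pure function of its
#'   inputs and this seed.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(d7_cv = 0.05, i_s_cv = 0.05, d0_cv = 0.02, seed = 1L) {
  stopifnot(d7_cv >= 0, i_s_cv >= 0, d0_cv >= 0)
  structure(list(d7_cv = d7_cv, i_s_cv = i_s_cv, d0_cv = d0_cv,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# mean-one multiplicative lognormal factors; cv = 0 gives exactly 1 without
# consuming RNG state
ln_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate synthetic growth trials
#'
#' Simulates the factorial growth experiment from known ground-truth
#' parameters: per cell and replicate, the initial density and the subarea
#' intensity are jittered, the model is integrated over the trial duration,
#' and mean-one multiplicative observation noise is applied to the final
#' density. With all CVs zero the final densities equal the exact model
#' trajectories. Deterministic given the seed.
#'
#' @param params Ground-truth parameter object (default the published
#'   reference fit).
#' @param design A [trial_design()].
#' @param noise A [noise_spec()].
#' @return A `trial_records` data frame (default design: 120 rows) with a
#'   `manifest` attribute recording design, noise, seed and truth parameters.
#' @export
#' @examples
#' tr <- generate_trials(noise = noise_spec(seed = 42))
#' nrow(tr)
generate_trials <- function(params = reference_growth_params(),
                            design = trial_design(),
                            noise = noise_spec()) {
  stopifnot(inherits(design, "trial_design"), inherits(noise, "noise_spec"))
  set.seed(noise$seed)
  cells <- expand.grid(rep = seq_len(design$replicates),
                       i_s = design$light_intensities,
                       d0 = design$initial_densities,
                       KEEP.OUT.ATTRS = FALSE)
  n <- nrow(cells)
  d0 <- cells$d0 * ln_factor(n, noise$d0_cv)
  i_s <- cells$i_s * ln_factor(n, noise$i_s_cv)
  d7_true <- .cpp_terminal(d0, i_s, rep(design$duration_d, n),
                           param_vector(params), model_code(params),
                           1e-8, 1e-10)
  d7 <- d7_true * ln_factor(n, noise$d7_cv)
  trials <- trial_records(
    trial_id = sprintf("D%03d_I%05.1f_r%d", cells$d0, cells$i_s, cells$rep),
    i_s_umol_m2_s = i_s,
    d0_gdw_m2 = d0,
    d7_gdw_m2 = d7,
    duration_d = design$duration_d
  )
  attr(trials, "manifest") <- list(
    generator = "generate_trials",
    design = unclass(design),
    noise = unclass(noise),
    note = "noise CVs are placeholders; true replicate variability unpublished",
    truth = c(unclass(params), model = class(params)[1L])
  )
  trials
}

#' Generate synthetic long-term density series
#'
#' Biweekly observations of the model trajectory over an eight-week horizon at
#' the long-term validation intensities, starting near 17 gDW m^-2. The
#' initial density of each series is jittered (`d0_cv`) and every observation
#' carries mean-one multiplicative noise (`d7_cv`); intensities are taken as
#' known. Deterministic given the seed.
#'
#' @param params Ground-truth parameter object.
#' @param intensities Series intensities, umol m^-2 s^-1.
#' @param d0 Nominal initial density, gDW m^-2.
#' @param horizon_d Total duration, d; must be a multiple of `cadence_d`.
#' @param cadence_d Observation interval, d.
#' @param noise A [noise_spec()] (`d7_cv` is reused as the observation CV).
#' @return A `longterm_series` data frame (default: 4 series x 5 time points)
#'   with a `manifest` attribute.
#' @export
generate_longterm <- function(params = reference_growth_params(),
                              intensities = c(58.4, 109.2, 136.0, 168.1),
                              d0 = 17, horizon_d = 56, cadence_d = 14,
                              noise = noise_spec()) {
  if (horizon_d %% cadence_d != 0) {
    stop("horizon must be a multiple of the cadence", call. = FALSE)
  }
  set.seed(noise$seed)
  times <- seq(0, horizon_d, by = cadence_d)
  series <- lapply(intensities, function(i_s) {
    d0j <- d0 * ln_factor(1L, noise$d0_cv)
    traj <- .cpp_simulate(d0j, i_s, param_vector(params), model_code(params),
                          times, 1e-8, 1e-10)
    obs <- traj * ln_factor(length(times), noise$d7_cv)
    data.frame(series_id = sprintf("I%05.1f", i_s),
               i_s_umol_m2_s = i_s, time_d = times, density_gdw_m2 = obs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, series)
  validate_longterm(out)
  class(out) <- c("longterm_series", "data.frame")
  attr(out, "manifest") <- list(
    generator = "generate_longterm",
    intensities = intensities, d0 = d0, horizon_d = horizon_d,
    cadence_d = cadence_d, noise = unclass(noise),
    truth = c(unclass(params), model = class(params)[1L])
  )
  out
}

#' Generate a synthetic basin light survey
#'
#' Samples a smooth anisotropic PPFD field (a sum of Gaussian lamp kernels,
#' emulating a row of LED modules above a production basin — the field shape
#' itself is an invention, no published basin geometry exists) at `n_points`
#' jittered grid locations with additive measurement noise. The ground-truth
#' field function is kept in the `truth` attribute for oracle comparisons.
#'
#' @param n_points Number of survey points (>= 3; default 65).
#' @param lamps Data frame `x, y, peak, sx, sy` of Gaussian lamp kernels;
#'   default five lamps in a row over a 1000 x 600 mm basin.
#' @param field_fn Optional override: `function(x, y)` giving the true field
#'   directly (e.g. a constant for degenerate tests).
#' @param noise_sd Additive measurement noise SD, umol m^-2 s^-1.
#' @param bbox Survey extent `c(xmin, xmax, ymin, ymax)`, mm.
#' @param seed Integer RNG seed.
#' @return A [par_measurements()] data frame with attributes `truth`
#'   (the field function) and `manifest`.
#' @export
generate_light_survey <- function(n_points = 65L, lamps = NULL,
                                  field_fn = NULL, noise_sd = 2,
                                  bbox = c(0, 1000, 0, 600), seed = 1L) {
  if (n_points < 3L) stop("n_points must be >= 3", call. = FALSE)
  set.seed(seed)
  if (is.null(lamps)) {
    lamps <- data.frame(x = seq(bbox[1L] + 100, bbox[2L] - 100, length.out = 5),
                        y = mean(bbox[3:4]), peak = 70,
                        sx = 280, sy = 320)
  }
  if (is.null(field_fn)) {
    field_fn <- function(x, y) {
      out <- 0
      for (l in seq_len(nrow(lamps))) {
        out <- out + lamps$peak[l] *
          exp(-((x - lamps$x[l])^2 / (2 * lamps$sx[l]^2) +
                  (y - lamps$y[l])^2 / (2 * lamps$sy[l]^2)))
      }
      out
    }
  }
  # near-square jittered grid covering the basin
  nx <- ceiling(sqrt(n_points * diff(bbox[1:2]) / diff(bbox[3:4])))
  ny <- ceiling(n_points / nx)
  gx <- seq(bbox[1L], bbox[2L], length.out = nx + 2L)[-c(1L, nx + 2L)]
  gy <- seq(bbox[3L], bbox[4L], length.out = ny + 2L)[-c(1L, ny + 2L)]
  pts <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)[seq_len(n_points), ]
  jx <- diff(bbox[1:2]) / (nx + 1) * 0.2
  jy <- diff(bbox[3:4]) / (ny + 1) * 0.2
  pts$x <- pts$x + stats::runif(n_points, -jx, jx)
  pts$y <- pts$y + stats::runif(n_points, -jy, jy)
  z <- field_fn(pts$x, pts$y)
  if (noise_sd > 0) z <- z + stats::rnorm(n_points, 0, noise_sd)
  z <- pmax(z, 0)
  out <- par_measurements(pts$x, pts$y, z)
  attr(out, "truth") <- field_fn
  attr(out, "manifest") <- list(
    generator = "generate_light_survey", n_points = n_points,
    lamps = if (is.null(lamps)) NULL else unclass(lamps),
    noise_sd = noise_sd, bbox = bbox, seed = seed
  )
  out
}

#' Write a generator manifest as JSON
#'
#' @param x An object produced by one of the generators.
#' @param path Output path.
#' @export
write_manifest <- function(x, path) {
  m <- attr(x, "manifest")
  if (is.null(m)) stop("object carries no manifest", call. = FALSE)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
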