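#' Assemble / read / write PAR survey measurements
#'
#' Point measurements of photosynthetic photon flux density over a production
#' basin, in basin-plane millimetre coordinates. CSV dialect:
#' `x_mm,y_mm,intensity_umol_m2_s`.
#'
#' @param x_mm,y_mm Coordinates, mm (finite).
#' @param intensity_umol_m2_s PPFD, umol m^-2 s^-1, >= 0.
#' @return A data frame of class `par_measurements`.
#' @export
par_measurements <- function(x_mm, y_mm, intensity_umol_m2_s) {
  df <- data.frame(x_mm = as.numeric(x_mm), y_mm = as.numeric(y_mm),
                   intensity_umol_m2_s = as.numeric(intensity_umol_m2_s))
  if (!all(is.finite(df$x_mm)) || !all(is.finite(df$y_mm))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (any(df$intensity_umol_m2_s < 0)) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  class(df) <- c("par_measurements", "data.frame")
  df
}

#' @rdname par_measurements
#' @param path File path.
#' @export
read_light_survey <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_mm", "y_mm", "intensity_umol_m2_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("survey CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  par_measurements(df$x_mm, df$y_mm, df$intensity_umol_m2_s)
}

#' @rdname par_measurements
#' @param measurements A `par_measurements` data frame.
#' @export
write_light_survey <- function(measurements, path) {
  utils::write.csv(
    measurements[, c("x_mm", "y_mm", "intensity_umol_m2_s")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Empirical (directional) semivariogram
#'
#' Bins half the squared differences of all measurement pairs by lag distance
#' and, optionally, by direction sector:
#' \eqn{\hat\gamma(h) = \frac{1}{2|N(h)|}\sum_{(i,j) \in N(h)} (z_i - z_j)^2.}
#' Default sectors at 0, 45, 90 and 135 degrees (tolerance 22.5) support the
#' anisotropic fit; `directions = NULL` gives an omnidirectional variogram.
#' Empty bins are kept with `n_pairs = 0` and `gamma = NA`, never interpolated.
#'
#' @param measurements A [par_measurements()] data frame (>= 2 points).
#' @param n_bins Number of lag bins (default 12).
#' @param max_lag Largest lag considered; default half the maximum pairwise
#'   distance.
#' @param directions Sector centre angles in degrees from the x axis, or
#'   `NULL` for omnidirectional.
#' @param angle_tol Half-width of each sector, degrees.
#' @return Data frame of class `empirical_variogram` with columns
#'   `direction_deg` (`NA` when omnidirectional), `lag` (bin centre), `gamma`,
#'   `n_pairs`.
#' @export
empirical_variogram <- function(measurements, n_bins = 12, max_lag = NULL,
                                directions = c(0, 45, 90, 135),
                                angle_tol = 22.5) {
  n <- nrow(measurements)
  if (n < 2L) stop("need at least 2 measurements", call. = FALSE)
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  ij <- utils::combn(n, 2L)
  dx <- measurements$x_mm[ij[2L, ]] - measurements$x_mm[ij[1L, ]]
  dy <- measurements$y_mm[ij[2L, ]] - measurements$y_mm[ij[1L, ]]
  h <- sqrt(dx^2 + dy^2)
  g <- 0.5 * (measurements$intensity_umol_m2_s[ij[2L, ]] -
                measurements$intensity_umol_m2_s[ij[1L, ]])^2
  if (is.null(max_lag)) max_lag <- max(h) / 2
  keep <- h > 0 & h <= max_lag
  h <- h[keep]; g <- g[keep]; dx <- dx[keep]; dy <- dy[keep]
  ang <- (atan2(dy, dx) * 180 / pi) %% 180
  breaks <- seq(0, max_lag, length.out = n_bins + 1L)
  centres <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  bin <- pmin(pmax(findInterval(h, breaks, rightmost.closed = TRUE), 1L), n_bins)

  one_direction <- function(dir) {
    if (is.na(dir)) {
      sel <- rep(TRUE, length(h))
    } else {
      d <- abs(((ang - dir + 90) %% 180) - 90) # angular distance on [0, 90]
      sel <- d <= angle_tol
    }
    gam <- np <- numeric(n_bins)
    for (b in seq_len(n_bins)) {
      m <- sel & bin == b
      np[b] <- sum(m)
      gam[b] <- if (np[b] > 0) mean(g[m]) else NA_real_
    }
    data.frame(direction_deg = dir, lag = centres, gamma = gam, n_pairs = np)
  }
  dirs <- if (is.null(directions)) NA_real_ else directions
  out <- do.call(rbind, lapply(dirs, one_direction))
  structure(out, max_lag = max_lag,
            class = c("empirical_variogram", "data.frame"))
}

spherical_gamma <- function(u) {
  # unit-range spherical structure; u = normalized lag
  ifelse(u >= 1, 1, 1.5 * u - 0.5 * u^3)
}

# Directional effective range of an anisotropy ellipse (major range a1 along
# angle alpha, minor range a2 perpendicular), evaluated at direction phi (deg).
ellipse_range <- function(phi_deg, a1, a2, alpha_deg) {
  phi <- (phi_deg - alpha_deg) * pi / 180
  (a1 * a2) / sqrt((a2 * cos(phi))^2 + (a1 * sin(phi))^2)
}

#' Fit an anisotropic spherical variogram model
#'
#' Weighted least squares (weights = pair counts) over nugget, partial sill,
#' major/minor ranges and anisotropy angle, against a directional empirical
#' variogram. The model is
#' \eqn{\gamma(h) = nugget + psill\,(1.5\,h/a - 0.5\,(h/a)^3)} for `h < a`
#' and `nugget + psill` beyond, with the range `a` varying over directions on
#' an ellipse. An omnidirectional empirical variogram (or
#' `anisotropy = FALSE`) yields an isotropic fit.
#'
#' @param empirical An [empirical_variogram()] result with >= 3 non-empty
#'   bins.
#' @param anisotropy Search over anisotropy angle and range ratio?
#' @return A list of class `variogram_model`: `nugget`, `psill`,
#'   `range_major`, `range_minor`, `angle_deg`, `family = "spherical"`,
#'   `wls` (attained objective), `degenerate` (TRUE when the fitted sill
#'   collapsed to ~0).
#' @export
fit_spherical_variogram <- function(empirical, anisotropy = TRUE) {
  ev <- empirical[empirical$n_pairs > 0, ]
  if (nrow(ev) < 3L) stop("need at least 3 non-empty bins", call. = FALSE)
  if (all(is.na(ev$direction_deg))) anisotropy <- FALSE
  max_lag <- max(ev$lag)
  g_scale <- max(ev$gamma, 1e-12)
  a_cap <- 2.5 * max_lag # ranges beyond the sampled extent are unidentifiable

  # theta = (sqrt nugget, sqrt psill, logit range_major/cap, logit ratio, angle)
  wls_of <- function(theta) {
    nug <- theta[1L]^2
    ps <- theta[2L]^2
    a1 <- a_cap * stats::plogis(theta[3L])
    ratio <- if (anisotropy) stats::plogis(theta[4L]) else 1
    alpha <- if (anisotropy) theta[5L] else 0
    a_dir <- ifelse(is.na(ev$direction_deg), sqrt(a1 * (a1 * ratio)),
                    ellipse_range(ev$direction_deg, a1, a1 * ratio, alpha))
    mod <- nug + ps * spherical_gamma(ev$lag / a_dir)
    sum(ev$n_pairs * (ev$gamma - mod)^2)
  }
  init_ps <- sqrt(max(mean(ev$gamma[ev$lag > max_lag / 2], na.rm = TRUE),
                      g_scale * 0.1))
  angle_starts <- if (anisotropy) c(0, 45, 90, 135) else 0
  range_starts <- c(0.3, 0.7) * max_lag
  best <- NULL
  for (alpha0 in angle_starts) {
    for (a0 in range_starts) {
      th0 <- c(sqrt(g_scale) * 0.05, init_ps,
               stats::qlogis(a0 / a_cap), 0, alpha0)
      o <- stats::optim(th0, wls_of, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
      if (is.null(best) || o$value < best$value) best <- o
    }
  }
  th <- best$par
  ratio <- if (anisotropy) stats::plogis(th[4L]) else 1
  a1 <- a_cap * stats::plogis(th[3L])
  model <- structure(
    list(
      nugget = th[1L]^2,
      psill = th[2L]^2,
      range_major = a1,
      range_minor = a1 * ratio,
      angle_deg = if (anisotropy) th[5L] %% 180 else 0,
      family = "spherical",
      wls = best$value,
      degenerate = th[2L]^2 < 1e-10 * g_scale
    ),
    class = "variogram_model"
  )
  if (model$degenerate) {
    warning("degenerate variogram fit: partial sill is ~0", call. = FALSE)
  }
  model
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf(
    "<variogram_model: %s> nugget %.4g, psill %.4g, ranges %.4g/%.4g mm, angle %.1f deg\n",
    x$family, x$nugget, x$psill, x$range_major, x$range_minor, x$angle_deg
  ))
  invisible(x)
}

#' Semivariance of a fitted model at lag vectors
#'
#' Applies the anisotropy transform (rotation by the model angle, axis scaling
#' by the two ranges) and evaluates the spherical structure. Exactly zero at
#' zero lag; tends to the nugget as the lag approaches zero from above.
#'
#' @param model A `variogram_model`.
#' @param dx,dy Lag vector components, mm (vectorized).
#' @return Semivariance values.
#' @export
semivariance <- function(model, dx, dy) {
  al <- model$angle_deg * pi / 180
  du <- cos(al) * dx + sin(al) * dy
  dv <- -sin(al) * dx + cos(al) * dy
  u <- sqrt((du / model$range_major)^2 + (dv / model$range_minor)^2)
  out <- model$nugget + model$psill * spherical_gamma(u)
  out[dx == 0 & dy == 0] <- 0
  out
}

#' Ordinary kriging onto a regular grid
#'
#' Solves the ordinary-kriging system (unbiasedness enforced through a
#' Lagrange multiplier, weights summing to one at every node) for each node of
#' a regular grid, 100 x 100 by default, spanning the measurements' bounding
#' box. With a zero nugget the predictor interpolates the data exactly.
#'
#' @param measurements A [par_measurements()] data frame (>= 2 points,
#'   no duplicated locations).
#' @param model A `variogram_model`.
#' @param grid_dim Integer vector `c(nx, ny)` (default `c(100, 100)`).
#' @param bbox Optional `c(xmin, xmax, ymin, ymax)`; default the bounding box
#'   of the measurements.
#' @param compute_variance Also return the kriging variance grid?
#' @return A list of class `kriged_field`: `x`, `y` (node coordinate
#'   vectors), `values` (matrix `[nx, ny]`, `values[i, j]` at
#'   `(x[i], y[j])`), optional `variance`, plus the model and geometry.
#' @export
krige <- function(measurements, model, grid_dim = c(100L, 100L), bbox = NULL,
                  compute_variance = FALSE) {
  n <- nrow(measurements)
  if (n < 2L) stop("need at least 2 measurements", call. = FALSE)
  xs <- measurements$x_mm
  ys <- measurements$y_mm
  z <- measurements$intensity_umol_m2_s
  dup <- duplicated(cbind(xs, ys))
  if (any(dup)) {
    stop(sprintf("duplicate measurement location(s): (%s)",
                 paste(sprintf("%g,%g", xs[dup], ys[dup]), collapse = "), (")),
         call. = FALSE)
  }
  if (is.null(bbox)) bbox <- c(range(xs), range(ys))
  gx <- seq(bbox[1L], bbox[2L], length.out = grid_dim[1L])
  gy <- seq(bbox[3L], bbox[4L], length.out = grid_dim[2L])

  A <- matrix(1, n + 1L, n + 1L)
  A[seq_len(n), seq_len(n)] <- semivariance(model, outer(xs, xs, "-"),
                                            outer(ys, ys, "-"))
  A[n + 1L, n + 1L] <- 0
  nodes <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  B <- rbind(
    semivariance(model,
                 outer(xs, nodes$x, "-"),
                 outer(ys, nodes$y, "-")),
    1
  )
  W <- tryCatch(solve(A, B), error = function(e) {
    stop("singular kriging system: ", conditionMessage(e), call. = FALSE)
  })
  pred <- drop(crossprod(W[seq_len(n), , drop = FALSE], z))
  out <- list(
    x = gx, y = gy,
    values = matrix(pred, nrow = grid_dim[1L], ncol = grid_dim[2L]),
    model = model, bbox = bbox
  )
  if (compute_variance) {
    out$variance <- matrix(colSums(W * B), grid_dim[1L], grid_dim[2L])
  }
  structure(out, class = "kriged_field")
}

#' @export
print.kriged_field <- function(x, ...) {
  cat(sprintf(
    "<kriged_field> %d x %d nodes on [%.4g, %.4g] x [%.4g, %.4g] mm; values %.4g-%.4g\n",
    length(x$x), length(x$y), x$bbox[1L], x$bbox[2L], x$bbox[3L], x$bbox[4L],
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Write a kriged field as a CSV grid plus geometry JSON
#'
#' @param field A `kriged_field`.
#' @param path CSV output path (matrix of values, x along rows); the geometry
#'   goes to `<path>.geometry.json`.
#' @export
write_field <- function(field, path) {
  utils::write.table(field$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(nx = length(field$x), ny = length(field$y), bbox = field$bbox,
         x = field$x, y = field$y),
    paste0(path, ".geometry.json"), digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' Mean and SD of the field inside a circular subarea
#'
#' Selects all grid nodes within `diameter/2` of the centre (the footprint of
#' one cultivation ring; default diameter 237.6 mm) and returns their
#' arithmetic mean and sample standard deviation.
#'
#' @param field A `kriged_field`.
#' @param center_x_mm,center_y_mm Ring centre, mm.
#' @param diameter_mm Ring inner diameter, mm (default 237.6).
#' @return A list `mean`, `sd` (sample, `NA` for a single node), `n_nodes`.
#' @export
ring_average <- function(field, center_x_mm, center_y_mm, diameter_mm = 237.6) {
  if (diameter_mm <= 0) stop("diameter must be > 0", call. = FALSE)
  nodes <- expand.grid(x = field$x, y = field$y, KEEP.OUT.ATTRS = FALSE)
  inside <- (nodes$x - center_x_mm)^2 + (nodes$y - center_y_mm)^2 <=
    (diameter_mm / 2)^2
  if (!any(inside)) {
    stop("no grid nodes inside the circle: too small for the grid resolution",
         call. = FALSE)
  }
  v <- as.vector(field$values)[inside]
  list(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
       n_nodes = length(v))
}

#' Ring-average table for a set of subareas
#'
#' @param field A `kriged_field`.
#' @param rings Data frame with columns `ring_id`, `center_x_mm`,
#'   `center_y_mm`, and optionally `diameter_mm` (default 237.6).
#' @return Data frame `ring_id,center_x_mm,center_y_mm,mean,sd` (the ring
#'   table CSV dialect).
#' @export
ring_table <- function(field, rings) {
  need <- c("ring_id", "center_x_mm", "center_y_mm")
  miss <- setdiff(need, names(rings))
  if (length(miss)) {
    stop("rings table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dia <- if ("diameter_mm" %in% names(rings)) rings$diameter_mm else
    rep(237.6, nrow(rings))
  res <- lapply(seq_len(nrow(rings)), function(i) {
    ra <- ring_average(field, rings$center_x_mm[i], rings$center_y_mm[i], dia[i])
    data.frame(ring_id = rings$ring_id[i],
               center_x_mm = rings$center_x_mm[i],
               center_y_mm = rings$center_y_mm[i],
               mean = ra$mean, sd = ra$sd, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
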