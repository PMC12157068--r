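make_model <- function(nugget = 0, psill = 100, range_major = 400,
                       range_minor = 250, angle_deg = 20) {
  structure(list(nugget = nugget, psill = psill, range_major = range_major,
                 range_minor = range_minor, angle_deg = angle_deg,
                 family = "spherical", wls = 0, degenerate = FALSE),
            class = "variogram_model")
}

test_that("empirical variogram: definition cases and sector bookkeeping", {
  const <- par_measurements(c(0, 10, 20, 5), c(0, 5, 10, 15), rep(7, 4))
  ev <- empirical_variogram(const, n_bins = 3, directions = NULL)
  expect_true(all(ev$gamma[ev$n_pairs > 0] == 0))

  two <- par_measurements(c(0, 3), c(0, 4), c(10, 4))
  ev2 <- empirical_variogram(two, n_bins = 1, max_lag = 10, directions = NULL)
  expect_equal(ev2$gamma, 0.5 * (10 - 4)^2)
  expect_equal(ev2$n_pairs, 1L)

  # empty bins are kept, flagged by n_pairs = 0, gamma NA
  ev3 <- empirical_variogram(two, n_bins = 4, max_lag = 20, directions = NULL)
  expect_true(any(ev3$n_pairs == 0 & is.na(ev3$gamma)))
  expect_error(empirical_variogram(two[1, ], n_bins = 2), "at least 2")
})

test_that("empirical variogram tracks the generating spherical model", {
  set.seed(21)
  x <- runif(65, 0, 1000)
  y <- runif(65, 0, 600)
  z <- sim_spherical_field(x, y, nugget = 0, psill = 100, range_major = 300,
                           range_minor = 300, angle_deg = 0, seed = 21)
  m <- par_measurements(x, y, z)
  ev <- empirical_variogram(m, n_bins = 8, directions = NULL)
  truth <- make_model(0, 100, 300, 300, 0)
  keep <- ev$n_pairs >= 40
  gam_mod <- semivariance(truth, ev$lag[keep], 0)
  # one 65-point realization: Monte-Carlo agreement, not convergence
  expect_lt(mean(abs(ev$gamma[keep] - gam_mod)) / 100, 0.5)
  expect_gt(stats::cor(ev$gamma[keep], gam_mod), 0.6)
})

test_that("spherical variogram fit recovers known parameters from dense data", {
  # The WLS fitter is the unit under test, so it is fed a well-estimated
  # empirical variogram: lag bins pooled over independent replicate fields.
  # A single realization cannot identify the parameters to 15% no matter the
  # fitter -- the sampling SD of the empirical sill alone is ~13% on a domain
  # of this size (one basin spans only ~8 correlation ranges).
  gx <- seq(20, 980, length.out = 30)
  gy <- seq(15, 585, length.out = 24)
  pts <- expand.grid(x = gx, y = gy)
  pooled_ev <- function(range_major, range_minor, seeds) {
    evs <- lapply(seeds, function(s) {
      z <- sim_spherical_field(pts$x, pts$y, nugget = 0, psill = 100,
                               range_major = range_major,
                               range_minor = range_minor,
                               angle_deg = 0, seed = s)
      empirical_variogram(par_measurements(pts$x, pts$y, z), n_bins = 15,
                          max_lag = 300, angle_tol = 15)
    })
    ev <- evs[[1L]]
    ev$gamma <- rowMeans(vapply(evs, function(e) e$gamma,
                                numeric(nrow(ev))))
    ev$n_pairs <- ev$n_pairs * length(seeds)
    ev
  }

  fit <- fit_spherical_variogram(pooled_ev(120, 60, seeds = 4:13))
  expect_false(fit$degenerate)
  expect_equal(fit$psill, 100, tolerance = 0.15)
  expect_equal(fit$range_major, 120, tolerance = 0.15)
  expect_equal(fit$range_minor, 60, tolerance = 0.15)
  expect_lt(fit$nugget, 10)
  # true anisotropy axis is the x axis (0 mod 180 degrees)
  expect_lt(min(fit$angle_deg, 180 - fit$angle_deg), 15)
  # gamma(0) = 0 exactly; gamma(0+) -> nugget
  expect_equal(semivariance(fit, 0, 0), 0)
  expect_equal(semivariance(fit, 1e-9, 0), fit$nugget, tolerance = 1e-6)

  # isotropic data: fitted ranges agree within 10%
  fit_i <- fit_spherical_variogram(pooled_ev(80, 80, seeds = 6:17))
  expect_equal(fit_i$range_minor / fit_i$range_major, 1, tolerance = 0.1)
})

test_that("ordinary kriging: exactness, constancy, 3-point linear-solve oracle", {
  sv <- generate_light_survey(noise_sd = 0, seed = 8)
  model <- make_model(nugget = 0)

  # zero-nugget exactness at every data point (1x1 grids pinned to the data)
  for (i in seq_len(nrow(sv))) {
    f1 <- krige(sv, model, grid_dim = c(1L, 1L),
                bbox = c(sv$x_mm[i], sv$x_mm[i], sv$y_mm[i], sv$y_mm[i]))
    expect_equal(f1$values[1, 1], sv$intensity_umol_m2_s[i], tolerance = 1e-8)
  }

  # constant data krige to a constant field (weights sum to one)
  cm <- par_measurements(c(0, 100, 40, 80), c(0, 0, 90, 50), rep(55, 4))
  fc <- krige(cm, model, grid_dim = c(12L, 12L))
  expect_equal(as.vector(fc$values), rep(55, 144), tolerance = 1e-9)

  # 3-point configuration vs a directly assembled kriging system
  m3 <- par_measurements(c(0, 100, 50), c(0, 0, 80), c(10, 20, 17))
  node <- c(40, 30)
  A <- rbind(cbind(semivariance(model, outer(m3$x_mm, m3$x_mm, "-"),
                                outer(m3$y_mm, m3$y_mm, "-")), 1),
             c(1, 1, 1, 0))
  b <- c(semivariance(model, m3$x_mm - node[1], m3$y_mm - node[2]), 1)
  w <- solve(A, b)
  oracle <- sum(w[1:3] * m3$intensity_umol_m2_s)
  f3 <- krige(m3, model, grid_dim = c(1L, 1L),
              bbox = c(node[1], node[1], node[2], node[2]))
  expect_equal(f3$values[1, 1], oracle, tolerance = 1e-10)

  # nugget-0 predictions stay inside the data range on this fixture
  ff <- krige(m3, model, grid_dim = c(15L, 15L))
  expect_true(all(ff$values >= 10 - 1e-6 & ff$values <= 20 + 1e-6))

  dup <- par_measurements(c(0, 0, 50), c(0, 0, 80), c(1, 2, 3))
  expect_error(krige(dup, model), "duplicate")
})

test_that("kriging variance is zero at data points and positive away from them", {
  m3 <- par_measurements(c(0, 100, 50), c(0, 0, 80), c(10, 20, 17))
  model <- make_model(nugget = 0)
  f <- krige(m3, model, grid_dim = c(1L, 1L), bbox = c(0, 0, 0, 0),
             compute_variance = TRUE)
  expect_equal(f$variance[1, 1], 0, tolerance = 1e-10)
  g <- krige(m3, model, grid_dim = c(1L, 1L), bbox = c(200, 200, 200, 200),
             compute_variance = TRUE)
  expect_gt(g$variance[1, 1], 0)
})

test_that("ring averaging: constants, whole grid, gradients, rotation", {
  model <- make_model(nugget = 0, range_major = 500, range_minor = 500,
                      angle_deg = 0)
  cm <- par_measurements(c(0, 400, 100, 300), c(0, 0, 380, 350), rep(80, 4))
  field <- krige(cm, model, grid_dim = c(60L, 60L))
  ra <- ring_average(field, 200, 190, 120)
  expect_equal(ra$mean, 80, tolerance = 1e-9)
  expect_equal(ra$sd, 0, tolerance = 1e-9)

  # ring covering the whole grid reproduces the global mean/SD
  sv <- generate_light_survey(noise_sd = 0, seed = 12)
  ev <- empirical_variogram(sv)
  fld <- krige(sv, fit_spherical_variogram(ev), grid_dim = c(50L, 50L))
  big <- ring_average(fld, mean(fld$bbox[1:2]), mean(fld$bbox[3:4]), 1e9)
  expect_equal(big$mean, mean(fld$values), tolerance = 1e-12)
  expect_equal(big$sd, stats::sd(fld$values), tolerance = 1e-12)
  expect_equal(big$n_nodes, 2500L)

  # linear gradient: centred ring mean equals the centre value
  gm <- par_measurements(rep(seq(0, 400, 100), 5),
                         rep(seq(0, 400, 100), each = 5), 0)
  gm$intensity_umol_m2_s <- 50 + 0.1 * gm$x_mm
  gf <- krige(gm, model, grid_dim = c(81L, 81L))
  rg <- ring_average(gf, 200, 200, 150)
  expect_equal(rg$mean, 50 + 0.1 * 200, tolerance = 0.1 * 400 / 80)

  # rigid 90-degree rotation leaves ring means unchanged (isotropic model)
  rot <- par_measurements(200 + (gm$y_mm - 200), 200 - (gm$x_mm - 200),
                          gm$intensity_umol_m2_s)
  rf <- krige(rot, model, grid_dim = c(81L, 81L))
  rr <- ring_average(rf, 200, 200, 150)
  expect_equal(rr$mean, rg$mean, tolerance = 0.05)

  expect_error(ring_average(gf, 5000, 5000, 1), "no grid nodes")
})

test_that("survey CSV and ring table round-trip; field export writes geometry", {
  sv <- generate_light_survey(seed = 3)
  f <- tempfile(fileext = ".csv")
  write_light_survey(sv, f)
  back <- read_light_survey(f)
  expect_equal(back$intensity_umol_m2_s, sv$intensity_umol_m2_s)

  model <- make_model()
  fld <- krige(sv, model, grid_dim = c(30L, 30L))
  rings <- data.frame(ring_id = c("r1", "r2"),
                      center_x_mm = c(300, 600), center_y_mm = c(300, 300))
  tab <- ring_table(fld, rings)
  expect_equal(names(tab), c("ring_id", "center_x_mm", "center_y_mm",
                             "mean", "sd"))
  expect_equal(nrow(tab), 2L)

  write_field(fld, f)
  geom <- jsonlite::read_json(paste0(f, ".geometry.json"))
  expect_equal(geom$nx, 30L)
  unlink(c(f, paste0(f, ".geometry.json")))
})
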