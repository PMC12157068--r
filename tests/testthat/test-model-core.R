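test_that("mean limitation: trivial cases, closed form vs quadrature, branch continuity", {
  p <- ref_params()
  expect_equal(mean_photosynthesis_limitation(0, 50, p), 0)
  # Monod half-saturation at zero depth
  expect_equal(mean_photosynthesis_limitation(p$k, 1e-12, p), 0.5)
  # closed form equals adaptive quadrature of the integral form
  expect_equal(mean_photosynthesis_limitation(166.2, 170, p),
               quad_fbar(166.2, 170, p), tolerance = 1e-10)
  # small-D branch agrees with main branch at the switch threshold
  d_switch <- 1e-8 / p$eps_hat
  f_lo <- mean_photosynthesis_limitation(100, d_switch * 0.999, p)
  f_hi <- mean_photosynthesis_limitation(100, d_switch * 1.001, p)
  expect_equal(f_lo, f_hi, tolerance = 1e-8)
  expect_equal(f_lo, 100 / (p$k + 100), tolerance = 1e-7)
  expect_error(mean_photosynthesis_limitation(-1, 10, p), "I_S")
  expect_error(mean_photosynthesis_limitation(10, -1, p), "D")
})

test_that("mean limitation: range and monotonicity at random points", {
  p <- ref_params()
  set.seed(11)
  i_s <- runif(100, 1, 500)
  D <- runif(100, 0.01, 300)
  f <- mean_photosynthesis_limitation(i_s, D, p)
  expect_true(all(f >= 0 & f < 1))
  h <- 1e-5
  dfdD <- (mean_photosynthesis_limitation(i_s, D + h, p) - f) / h
  dfdI <- (mean_photosynthesis_limitation(i_s + h, D, p) - f) / h
  expect_true(all(dfdD < 0))
  expect_true(all(dfdI > 0))
  # closed form vs quadrature across the grid
  q <- mapply(quad_fbar, i_s, D, MoreArgs = list(params = p))
  expect_equal(f, q, tolerance = 1e-10)
})

test_that("depth-resolved limitation follows Beer-Lambert + Monod", {
  p <- ref_params()
  expect_equal(depth_resolved_limitation(80, 0, p), 80 / (p$k + 80))
  expect_equal(depth_resolved_limitation(0, 3, p), 0)
  # exponent ln 2 halves the intensity: Monod factor at I = 50
  expect_equal(depth_resolved_limitation(100, log(2), p), 50 / (p$k + 50))
  ex <- seq(0, 10, by = 0.5)
  expect_true(all(diff(depth_resolved_limitation(120, ex, p)) <= 0))
  expect_error(depth_resolved_limitation(100, -0.1, p), "depth")
})

test_that("growth rate: equilibria, dark respiration, dilute-bright limit", {
  p <- ref_params()
  expect_equal(growth_rate(0, 123.9, p), 0)
  expect_equal(growth_rate(40, 0, p), -40 * p$r_resp)
  d_l <- limit_density(100, p)
  expect_equal(growth_rate(d_l, 100, p), 0, tolerance = 1e-9)
  # per-capita rate at vanishing density and saturating light
  percap <- growth_rate(1e-9, 1e9, p) / 1e-9
  expect_equal(percap, 0.3480, tolerance = 1e-3)
})

test_that("comparator model growth rate", {
  q <- reference_vandyck_params()
  expect_equal(vandyck_growth_rate(0, 100, q), 0)
  expect_equal(vandyck_growth_rate(q$h_D, 100, q),
               -q$h_D * q$r_resp, tolerance = 1e-12)
  # per-capita at half-saturating light and dilute culture
  percap <- vandyck_growth_rate(1e-9, q$K_I, q) / 1e-9
  expect_equal(percap, 0.4602 * 0.5 * 0.5833 - 0.0788, tolerance = 1e-3)
  expect_error(vandyck_params(0.4, 0.08, -5, 50), "h_D")
})

test_that("simulation: fixed point, dark decay closed form, RK4 oracle, step halving", {
  p <- ref_params()
  d_l <- limit_density(140, p)
  tr <- simulate_growth(d_l, 140, p, t_end = 30)
  expect_equal(tr$density_gdw_m2, rep(d_l, nrow(tr)), tolerance = 1e-7)
  expect_equal(tr$density_gdw_m2[1L], d_l) # initial condition is exact

  # dark culture: pure exponential decay
  dark <- simulate_growth(100, 0, p, t_end = 7)
  expect_equal(dark$density_gdw_m2[nrow(dark)], 100 * exp(-7 * p$r_resp),
               tolerance = 1e-9)

  # adaptive DP45 vs independent fixed-step RK4
  d7 <- simulate_growth(10, 166.2, p, t_end = 7)
  expect_equal(d7$density_gdw_m2[nrow(d7)], rk4_terminal(10, 166.2, p, 7),
               tolerance = 1e-6)

  # reporting-grid refinement does not change the solution
  a <- simulate_growth(10, 123.9, p, t_end = 7, step = 0.05)
  b <- simulate_growth(10, 123.9, p, t_end = 7, step = 0.025)
  shared <- match(a$time_d, b$time_d)
  expect_equal(b$density_gdw_m2[shared], a$density_gdw_m2,
               tolerance = 1e-6)
  expect_error(simulate_growth(-1, 100, p, 7), "D_0")
})

test_that("simulation trajectories approach the limit density monotonically", {
  p <- ref_params()
  d_l <- limit_density(88.2, p)
  lo <- simulate_growth(0.5 * d_l, 88.2, p, t_end = 300)
  hi <- simulate_growth(2 * d_l, 88.2, p, t_end = 300)
  expect_true(all(diff(lo$density_gdw_m2) > -1e-9))
  expect_true(all(diff(hi$density_gdw_m2) < 1e-9))
  expect_equal(lo$density_gdw_m2[nrow(lo)], d_l, tolerance = 1e-4)
  expect_equal(hi$density_gdw_m2[nrow(hi)], d_l, tolerance = 1e-4)
})

test_that("limit density: compensation threshold, saturation oracle, monotonicity", {
  p <- ref_params()
  expect_equal(compensation_intensity(p), 2.892285, tolerance = 1e-6)
  expect_equal(limit_density(1, p), 0) # below compensation intensity
  expect_gt(limit_density(3, p), 0)

  # equals the plateau of a long-horizon simulation
  d_l <- limit_density(123.9, p)
  plateau <- simulate_growth(10, 123.9, p, t_end = 2000, step = 10)
  expect_equal(d_l, plateau$density_gdw_m2[nrow(plateau)], tolerance = 1e-3)

  expect_true(all(diff(limit_density(seq(5, 500, by = 15), p)) >= 0))

  # no respiration: no finite limit
  p0 <- growth_params(0.7, 0, 0.12, 17)
  expect_error(limit_density(100, p0), class = "lemnagrow_no_finite_limit")

  # comparator closed form agrees with its root
  q <- reference_vandyck_params()
  d_lv <- limit_density(100, q)
  expect_equal(vandyck_growth_rate(d_lv, 100, q), 0, tolerance = 1e-9)
})

test_that("dry-weight content and LAI conversions", {
  expect_equal(dry_weight_content(1.2, 20), 0.06)
  expect_error(dry_weight_content(1.2, 0), "fresh")
  expect_error(dry_weight_content(21, 20), "dry")
  expect_equal(lai_estimate(0), 0)
  expect_equal(lai_estimate(11.5, 11.5), 1)
  expect_error(lai_estimate(10, 0), "LMA")
})

test_that("parameter constructors enforce invariants; config round-trips", {
  expect_error(growth_params(-1, 0.05, 0.1, 20), "r_phot_i")
  expect_error(growth_params(0.7, 0.05, 0.1, 20, E = 1.5), "E")
  expect_error(growth_params(0.7, 0.05, -0.1, 20), "eps_hat")
  p <- ref_params()
  f <- tempfile(fileext = ".cfg")
  write_params(p, f)
  p2 <- read_params(f)
  expect_s3_class(p2, "growth_params")
  expect_equal(unclass(p2), unclass(p))
  q <- reference_vandyck_params()
  write_params(q, f)
  expect_equal(unclass(read_params(f)), unclass(q))
  unlink(f)
})
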