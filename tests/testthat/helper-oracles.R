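# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the quadrature oracle integrates the depth-resolved
# integrand numerically (vs the closed form), the RK4 oracle is a fixed-step
# pure-R integrator (vs the adaptive C++ Dormand-Prince), and the grid oracles
# are dense enumerations (vs bounded scalar optimization).

ref_params <- function() reference_growth_params()

# mean limitation by adaptive quadrature of the depth-resolved integrand
quad_fbar <- function(i_s, D, params) {
  x <- params$eps_hat * D
  f <- function(u) {
    I <- i_s * exp(-u)
    I / (params$k + I)
  }
  stats::integrate(f, 0, x, rel.tol = 1e-13, abs.tol = 1e-15)$value / x
}

# fixed-step classical RK4, pure R
rk4_terminal <- function(d0, i_s, params, t_end, h = 1e-3) {
  n <- ceiling(t_end / h)
  h <- t_end / n
  y <- d0
  for (i in seq_len(n)) {
    k1 <- growth_rate(y, i_s, params)
    k2 <- growth_rate(y + h / 2 * k1, i_s, params)
    k3 <- growth_rate(y + h / 2 * k2, i_s, params)
    k4 <- growth_rate(y + h * k3, i_s, params)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# dense grid search over residual densities
grid_cycle_opt <- function(delta_t, i_s, params, n = 10000L) {
  d_l <- limit_density(i_s, params)
  if (d_l <= 0) return(list(d_opt = 0, yield = 0))
  grid <- seq(d_l / n, d_l * (1 - 1e-9), length.out = n)
  y <- cycle_average_yield(grid, delta_t, i_s, params)
  i <- which.max(y)
  list(d_opt = grid[i], yield = y[i], step = grid[2] - grid[1])
}

# Gaussian random field with a spherical variogram (nugget + partial sill),
# simulated by Cholesky factorization of the implied covariance
sim_spherical_field <- function(x, y, nugget, psill, range_major, range_minor,
                                angle_deg, mean_value = 100, seed = 1) {
  set.seed(seed)
  al <- angle_deg * pi / 180
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  du <- cos(al) * dx + sin(al) * dy
  dv <- -sin(al) * dx + cos(al) * dy
  u <- sqrt((du / range_major)^2 + (dv / range_minor)^2)
  sph <- ifelse(u >= 1, 1, 1.5 * u - 0.5 * u^3)
  C <- psill * (1 - sph)
  diag(C) <- psill + nugget
  L <- chol(C + diag(1e-8 * (psill + nugget), length(x)))
  mean_value + drop(crossprod(L, stats::rnorm(length(x))))
}
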