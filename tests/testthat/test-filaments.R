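test_that("pool-limited growth speed follows the linear depletion law", {
  expect_equal(growth_speed(1.0, 0, 100), 1.0)
  expect_equal(growth_speed(1.0, 100, 100), 0.0)
  expect_equal(growth_speed(0.8, 50, 100), 0.4)
  expect_error(growth_speed(1.0, 101, 100), "conservation")
})

test_that("per-filament speed draws follow the folded-normal rule", {
  # oracle: numerical quadrature of E[ clip(a0 |1 + 0.25 Z|) ]
  a0 <- 0.05
  mean_th <- integrate(function(z) {
    pmin(pmax(a0 * abs(1 + 0.25 * z), 0), 2) * dnorm(z)
  }, -40, 40)$value
  set.seed(11)
  draws <- draw_max_speed(a0, 1e5)
  expect_true(all(draws >= 0 & draws <= 2))
  sd_th <- sqrt(integrate(function(z) {
    (pmin(a0 * abs(1 + 0.25 * z), 2) - mean_th)^2 * dnorm(z)
  }, -40, 40)$value)
  expect_equal(mean(draws), mean_th, tolerance = 4 * sd_th / sqrt(1e5) / mean_th)
})

test_that("lattice site arithmetic uses 8-nm bins from the minus end", {
  expect_identical(site_of_abscissa(0, 2.5), 0L)
  expect_identical(site_of_abscissa(0.0081, 2.5), 1L)
  expect_identical(site_of_abscissa(0.0239, 2.5), 2L)
  expect_error(site_of_abscissa(2.6, 2.5), "outside")
  expect_equal(abscissa_of_site(2L, 2.5), 0.02)
  expect_equal(abscissa_of_site(10000L, 2.5), 2.5) # clamped to the end
  # round trip: the site of a site center is that site
  for (i in c(0L, 1L, 7L, 200L)) {
    expect_identical(site_of_abscissa(abscissa_of_site(i, 100), 100), i)
  }
})

test_that("bending forces are the exact negative energy gradient", {
  set.seed(3)
  v <- cbind(cumsum(rep(0.5, 6)), rnorm(6, 0, 0.02), rnorm(6, 0, 0.02))
  f <- bending_forces(v, 20, 0.5)
  g <- fd_gradient(function(x) bending_energy(x, 20, 0.5), v)
  expect_equal(f, -g, tolerance = 1e-6)
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-12)
  # zero net torque about the origin
  tq <- colSums(cbind(v[, 2] * f[, 3] - v[, 3] * f[, 2],
                      v[, 3] * f[, 1] - v[, 1] * f[, 3],
                      v[, 1] * f[, 2] - v[, 2] * f[, 1]))
  expect_equal(tq, c(0, 0, 0), tolerance = 1e-10)
})

test_that("a straight filament carries no bending force; a small kink scales as kappa theta / l^2", {
  straight <- cbind(seq(0, 2.5, by = 0.5), 0, 0)
  expect_equal(bending_forces(straight, 20, 0.5),
               matrix(0, 6, 3))
  # apex force of a symmetric 3-vertex kink, against the analytic derivative
  kink_force <- function(theta, l, kappa) {
    d <- l * theta / 2 # transverse apex displacement for small theta
    v <- rbind(c(-l, 0, 0), c(0, d, 0), c(l, 0, 0))
    bending_forces(v, kappa, l)[2, 2]
  }
  for (l in c(0.25, 0.5)) {
    for (theta in c(1e-3, 2e-3)) {
      f <- kink_force(theta, l, 20)
      # linear in theta, inverse-square in l (magnitude ~ kappa theta / l^2)
      expect_equal(abs(f), 2 * 20 * theta / l^2, tolerance = 1e-3)
      expect_equal(kink_force(2 * theta, l, 20) / f, 2, tolerance = 1e-3)
    }
    expect_equal(kink_force(1e-3, l / 2, 20) / kink_force(1e-3, l, 20), 4,
                 tolerance = 1e-3)
  }
})

test_that("plus-end growth conserves tubulin and re-discretizes at 1.5x", {
  pool <- list(omega = 100, polymerized = 0)
  fil <- new_filament(c(0, 0, 0), c(1, 0, 0), 0.4)
  pool$polymerized <- 0.4
  r0 <- grow_plus_end(fil, 0, 0.005, pool)
  expect_equal(r0$filament$vertices, fil$vertices)
  r1 <- grow_plus_end(fil, 0.04, 0.005, pool)
  expect_equal(filament_length(r1$filament), 0.4002)
  expect_equal(r1$pool$polymerized, 0.4002)
  # grow past 1.5 x rest segment length: terminal segment splits
  f2 <- fil; p2 <- pool
  for (i in 1:100) {
    r <- grow_plus_end(f2, 1, 0.005, p2)
    f2 <- r$filament; p2 <- r$pool
  }
  expect_equal(filament_length(f2), 0.9, tolerance = 1e-12)
  expect_identical(nrow(f2$vertices), 3L)
  expect_true(all(abs(f2$seg_rests - c(0.5, 0.4)) < 1e-12))
  # polarity immutable: the minus end never moved
  expect_equal(f2$vertices[1, ], c(0, 0, 0))
  # conservation: length equals pool draw
  expect_equal(p2$polymerized, filament_length(f2), tolerance = 1e-12)
})

test_that("single-filament growth follows the closed-form pool ODE", {
  # dL/dt = alpha (1 - L / Omega)  =>  L(t) = Omega + (L0 - Omega) e^(-alpha t / Omega)
  alpha <- 0.05
  omega <- 2.5
  dt <- 0.005
  pool <- list(omega = omega, polymerized = 0.1)
  fil <- new_filament(c(0, 0, 0), c(1, 0, 0), 0.1)
  for (i in seq_len(20000)) {
    vg <- growth_speed(alpha, pool$polymerized, omega)
    r <- grow_plus_end(fil, vg, dt, pool)
    fil <- r$filament
    pool <- r$pool
  }
  t <- 20000 * dt
  want <- omega + (0.1 - omega) * exp(-alpha * t / omega)
  expect_equal(filament_length(fil), want, tolerance = 1e-4)
})

test_that("population growth exhausts the pool and equalizes mean length", {
  set.seed(5)
  n <- 50
  g <- growth_model(alpha0 = 0.05, omega = 2.5 * n)
  res <- simulate_growth_only(n, g, nucleation_rate = 0.1, dt = 0.05,
                              t_end = 4000)
  expect_equal(res$n_nucleated, n)
  # total length approaches Omega, mean approaches Omega/n, despite the
  # heterogeneous per-filament speeds
  expect_equal(mean(res$lengths), 2.5, tolerance = 0.01)
  expect_true(res$polymerized <= g$omega + 1e-9)
  # nucleation fraction at t = 60 s matches 1 - exp(-rate t)
  set.seed(6)
  res60 <- simulate_growth_only(1000, growth_model(omega = 1e5),
                                nucleation_rate = 0.1, dt = 0.005,
                                t_end = 60, plateau_rel = NULL)
  p <- 1 - exp(-0.1 * 60)
  expect_equal(res60$n_nucleated / 1000, p,
               tolerance = 4 * sqrt(p * (1 - p) / 1000) / p)
})
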