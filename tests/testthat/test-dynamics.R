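test_that("segment-length projection restores rest lengths minimally", {
  v <- cbind(seq(0, 2, by = 0.5), 0, 0)
  rests <- rep(0.5, 4)
  expect_equal(enforce_segment_lengths(v, rests), v) # already satisfied
  # uniform stretch contracts uniformly, direction preserved
  vs <- v * 1.01
  out <- enforce_segment_lengths(vs, rests)
  d <- diff(out[, 1])
  expect_equal(d, rests, tolerance = 1e-6)
  expect_equal(out[, 2], rep(0, 5))
  expect_equal(mean(out[, 1]), mean(vs[, 1]), tolerance = 1e-9) # centroid kept
  # random small perturbation: all residuals below tolerance, displacement
  # bounded by the perturbation scale
  set.seed(8)
  vp <- v + matrix(rnorm(15, 0, 0.004), 5, 3)
  out <- enforce_segment_lengths(vp, rests)
  seg <- sqrt(rowSums((out[-1, ] - out[-5, ])^2))
  expect_true(all(abs(seg - rests) / rests < 1e-6))
  expect_lt(max(abs(out - vp)), 0.02)
})

test_that("steric repulsion is perpendicular, pairwise balanced and short-ranged", {
  pp <- physics_params()
  # far apart: nothing
  a <- cbind(c(0, 0.5), 0, 0.1)
  a <- cbind(c(0, 0.5), c(0, 0), c(0.1, 0.1))
  b <- cbind(c(0, 0.5), c(1, 1), c(0.1, 0.1))
  f <- steric_forces(a, b, pp)
  expect_equal(f$f_a, matrix(0, 2, 3))
  # parallel filaments offset half the onset distance
  b2 <- cbind(c(0, 0.5), c(0.025, 0.025), c(0.1, 0.1))
  f2 <- steric_forces(a, b2, pp)
  tot_b <- colSums(f2$f_b)
  expect_equal(sqrt(sum(tot_b^2)), 0.5 * pp$k_steric * pp$d_steric,
               tolerance = 1e-9)
  expect_equal(tot_b[1], 0, tolerance = 1e-12)       # no axial push
  expect_gt(tot_b[2], 0)                             # pushes b away
  expect_equal(colSums(f2$f_a), -tot_b, tolerance = 1e-12)
  # filaments crossing at 90 degrees: axial components essentially zero
  cx <- cbind(c(-0.5, 0.5), c(0, 0), c(0.1, 0.1))
  cy <- cbind(c(0, 0), c(-0.5, 0.5), c(0.13, 0.13))
  f3 <- steric_forces(cx, cy, pp)
  tot <- colSums(f3$f_b)
  expect_gt(abs(tot[3]), 0)
  expect_lt(abs(tot[1]) / sqrt(sum(tot^2)), 1e-6)
  expect_lt(abs(tot[2]) / sqrt(sum(tot^2)), 1e-6)
})

test_that("engine and reference steric forces agree on a filament pair", {
  pp <- physics_params()
  box <- simulation_box(20, 20, 0.2)
  st <- new_system(box, pp)
  st <- add_filament(st, c(5, 5, 0.10), c(1, 0, 0), 1.5)
  st <- add_filament(st, c(5.2, 5.03, 0.10), c(1, 0, 0), 1.5)
  eng <- assemble_forces(st)
  ref <- steric_forces(st$fil$vertices[1:4, ], st$fil$vertices[5:8, ], pp, box)
  expect_equal(eng$steric[1:4, ], ref$f_a, tolerance = 1e-10)
  expect_equal(eng$steric[5:8, ], ref$f_b, tolerance = 1e-10)
  expect_equal(colSums(eng$steric), c(0, 0, 0), tolerance = 1e-10)
})

test_that("assembled forces are zero for isolated straight filaments and balanced overall", {
  st <- new_system(simulation_box(20, 20, 0.2), physics_params())
  st <- add_filament(st, c(2, 2, 0.1), c(1, 0, 0), 2.5)
  st <- add_filament(st, c(10, 10, 0.1), c(0, 1, 0), 2.0)
  f <- assemble_forces(st)
  expect_equal(f$total, matrix(0, nrow(st$fil$vertices), 3))

  # one doubly bound cross-linker: equal and opposite forces on the two
  # filaments, zero total
  st2 <- new_system(simulation_box(20, 20, 0.2), physics_params(),
                    linker_types = list(linker_catalog("kif11")))
  st2 <- add_filament(st2, c(5, 5.00, 0.1), c(1, 0, 0), 2.5)
  st2 <- add_filament(st2, c(5, 5.30, 0.1), c(1, 0, 0), 2.5)
  st2 <- add_linkers(st2, "kif11", 1, pos = matrix(c(5, 5, 0.1), 1),
                     anchors = list(fil = matrix(c(1L, 2L), 1),
                                    absc = matrix(c(0.8, 1.6), 1)))
  f2 <- assemble_forces(st2)
  expect_gt(max(abs(f2$spring)), 0)
  expect_equal(colSums(f2$spring[1:6, ]), -colSums(f2$spring[7:12, ]),
               tolerance = 1e-12)
  expect_equal(colSums(f2$total), c(0, 0, 0), tolerance = 1e-10)
})

test_that("bending + spring forces equal the negative energy gradient", {
  set.seed(12)
  st <- new_system(simulation_box(20, 20, 0.2), physics_params(),
                   linker_types = list(linker_catalog("hset")))
  st <- add_filament(st, c(5, 5.0, 0.10), c(1, 0, 0), 2.0)
  st <- add_filament(st, c(5, 5.5, 0.12), c(0.96, 0.28, 0), 2.0)
  st <- add_linkers(st, "hset", 2, pos = matrix(5, 2, 3),
                    anchors = list(fil = rbind(c(1L, 2L), c(2L, 1L)),
                                   absc = rbind(c(0.3, 0.9), c(1.7, 1.9))))
  # bend the filaments a little so the bending term is non-trivial
  st$fil$vertices <- st$fil$vertices + matrix(rnorm(30, 0, 0.01), 10, 3)
  f <- assemble_forces(st)
  g <- fd_gradient(function(v) {
    s <- st; s$fil$vertices <- v; system_energy(s)
  }, st$fil$vertices, h = 1e-5)
  expect_equal(f$bending + f$spring, -g, tolerance = 1e-4)
  # momentum neutrality of all deterministic forces
  tot <- colSums(f$total)
  expect_lt(max(abs(tot)) / max(abs(f$total)), 1e-10)
})

test_that("free cross-linker complexes diffuse with the expected MSD", {
  pp <- physics_params()
  st <- new_system(simulation_box(50, 50, 20), pp,
                   linker_types = list(linker_catalog("double_tail_hset")))
  n <- 4000
  st <- add_linkers(st, "double_tail_hset", n,
                    pos = matrix(rep(c(25, 25, 10), each = n), n, 3))
  p0 <- st$linkers$pos
  nstep <- 400
  res <- run_until(st, nstep * pp$dt)
  dx <- res$state$linkers$pos - p0
  msd <- mean(rowSums(dx^2))
  want <- 6 * pp$kBT * pp$dt * nstep / pp$gamma_linker
  expect_equal(msd, want, tolerance = 0.05)
})

test_that("a stretched cross-link relaxes monotonically toward its rest length at T ~ 0", {
  # two rigid 2-vertex filaments joined by one non-hopping, non-unbinding
  # link; the extension must decay monotonically to the rest length
  ua <- unit_spec("diffusive", D = 0, k_on = 0, k_off0 = 0, f_unb = 10,
                  end_policy = "hold")
  spec <- linker_spec("static_link", ua, ua, k_spring = 2, rest_length = 0.05)
  pp <- physics_params(kBT = 1e-16)
  st <- new_system(simulation_box(20, 20, 0.2), pp, linker_types = list(spec))
  st <- add_filament(st, c(5, 5.0, 0.1), c(1, 0, 0), 0.4)
  st <- add_filament(st, c(5, 5.8, 0.1), c(1, 0, 0), 0.4)
  st <- add_linkers(st, "static_link", 1, pos = matrix(c(5, 5, 0.1), 1),
                    anchors = list(fil = matrix(c(1L, 2L), 1),
                                   absc = matrix(c(0.2, 0.2), 1)))
  ext <- numeric(0)
  for (i in 1:12) {
    res <- run_until(st, st$time + 2)
    st <- res$state
    ext <- c(ext, abs(st$fil$vertices[1, 2] - st$fil$vertices[3, 2]))
  }
  expect_true(all(diff(ext) < 1e-6)) # monotone up to residual thermal noise
  expect_equal(ext[12], 0.05, tolerance = 0.01)
})

test_that("identical seeds give bitwise-identical trajectories", {
  mk <- function() {
    set.seed(99)
    st <- new_system(simulation_box(6, 6, 0.2), physics_params(),
                     growth = growth_config(omega = 60),
                     seeds = 24, seed = 7L,
                     linker_types = list(linker_catalog("hset")))
    add_linkers(st, "hset", 200)
  }
  r1 <- run_until(mk(), 5, frame_interval = 1)
  r2 <- run_until(mk(), 5, frame_interval = 1)
  expect_identical(r1$trajectory$frames, r2$trajectory$frames)
  expect_identical(r1$state$fil$vertices, r2$state$fil$vertices)
  # and a different seed diverges
  st3 <- mk(); st3$seed <- 8L
  r3 <- run_until(st3, 5, frame_interval = 1)
  expect_false(identical(r3$state$fil$vertices, r1$state$fil$vertices))
})

test_that("observers fire on the configured grid", {
  pp <- physics_params(dt = 0.05)
  st <- new_system(simulation_box(10, 10, 0.2), pp)
  st <- add_filament(st, c(5, 5, 0.1), c(1, 0, 0), 2.0)
  # zero-length run: no steps, state unchanged
  r0 <- run_until(st, st$time)
  expect_equal(r0$state$fil$vertices, st$fil$vertices)
  r <- run_until(st, 600, frame_interval = 60)
  expect_length(r$trajectory$frames, 11) # t = 0, 60, ..., 600
  expect_equal(vapply(r$trajectory$frames, `[[`, 0, "time"),
               seq(0, 600, by = 60))
  expect_error(run_until(st, 600, frame_interval = 0.12), "multiple of dt")
})

test_that("bending modes equilibrate to kBT/2 per transverse mode", {
  pp <- physics_params()
  st <- new_system(simulation_box(10, 10, 2), pp)
  st <- add_filament(st, c(4, 5, 1), c(1, 0, 0), 1.5) # 4 vertices, free in z
  res <- run_until(st, 1, frame_interval = 1) # burn-in
  r <- run_until(res$state, 17, frame_interval = 0.025)
  e <- vapply(r$trajectory$frames, function(f) {
    bending_energy(f$vertices, pp$rigidity, pp$rest_segment_length)
  }, 0)
  # 2 interior vertices x 2 transverse directions = 4 quadratic modes
  expect_equal(mean(e), 4 * pp$kBT / 2, tolerance = 0.1)
})

test_that("halving dt leaves the two-filament sliding speed unchanged within 5%", {
  sliding_speed <- function(dt) {
    u <- unit_spec("motor", "toward_plus", vm = 0.03, fs = 5, k_off0 = 0.005,
                   f_unb = 6, end_policy = "release")
    spec <- linker_spec("kif11_processive", u, u, k_spring = 10,
                        rest_length = 0.05)
    pp <- physics_params(dt = dt)
    set.seed(17)
    st <- new_system(simulation_box(12, 3, 0.2), pp,
                     linker_types = list(spec), seed = 17L)
    st <- add_filament(st, c(2.0, 1.45, 0.1), c(1, 0, 0), 2.5)
    st <- add_filament(st, c(4.5, 1.55, 0.1), c(-1, 0, 0), 2.5)
    st <- add_linkers(st, "kif11_processive", 200,
                      pos = cbind(runif(200, 2, 4.5), 1.5, 0.1))
    r <- run_until(st, 40, frame_interval = 5)
    signed_mt_speed(r$trajectory, 20)
  }
  v1 <- sliding_speed(0.005)
  v2 <- sliding_speed(0.0025)
  expect_gt(v1, 0) # minus-end-leading by the sign convention
  expect_equal(v1, v2, tolerance = 0.05)
  # and the sliding speed is near the motors' unloaded speed
  expect_equal(v1, 0.03, tolerance = 0.2)
})

test_that("conservation and anchor invariants hold through a network run", {
  sc <- build_scenario("fig5d_hset", scale = 0.25, seed = 2)
  r <- run_scenario(sc, t_end = 40, frame_interval = 10)
  frames <- r$trajectory$frames
  prev_len <- NULL
  for (f in frames) {
    expect_equal(f$polymerized, f$total_length, tolerance = 1e-6)
    expect_lte(f$polymerized, sc$config$omega_um + 1e-9)
    if (!is.null(prev_len)) {
      k <- length(prev_len)
      expect_true(all(f$length[seq_len(k)] >= prev_len - 1e-9))
    }
    prev_len <- f$length
    both <- f$linkers$fil_a > 0 & f$linkers$fil_b > 0
    expect_true(all(f$linkers$fil_a[both] != f$linkers$fil_b[both]))
    bound_a <- f$linkers$fil_a > 0
    expect_true(all(f$linkers$absc_a[bound_a] <=
                      f$length[f$linkers$fil_a[bound_a]] + 1e-9))
    expect_true(all(f$linkers$absc_a[bound_a] >= -1e-9))
  }
})

test_that("binding follows the configured rate and the same-filament exclusion", {
  # one long filament, many single-unit complexes within capture range:
  # after one step the bound fraction is 1 - exp(-k_on dt)
  ua <- unit_spec("diffusive", D = 0, k_on = 10, k_off0 = 0, f_unb = 10,
                  end_policy = "hold")
  spec <- linker_spec("sticky", ua, ua, k_spring = 10, rest_length = 0.05)
  pp <- physics_params()
  st <- new_system(simulation_box(20, 20, 0.2), pp, linker_types = list(spec),
                   seed = 5L)
  st <- add_filament(st, c(2, 10, 0.1), c(1, 0, 0), 16)
  n <- 4000
  st <- add_linkers(st, "sticky", n,
                    pos = cbind(runif(n, 3, 17), 10 + runif(n, -0.02, 0.02),
                                0.1))
  r <- run_until(st, pp$dt)
  p <- 1 - exp(-10 * pp$dt)
  frac <- mean(r$state$linkers$fil > 0) # either unit of each complex
  expect_equal(frac, p, tolerance = 4 * sqrt(p * (1 - p) / (2 * n)) / p)
  # partner exclusion: with a single filament in the box, no complex may
  # ever engage both units
  r2 <- run_until(r$state, 50 * pp$dt)
  both <- r2$state$linkers$fil[, 1] > 0 & r2$state$linkers$fil[, 2] > 0
  expect_false(any(both))
})

test_that("an unloaded motor advances by Poisson 8-nm stepping", {
  # minus-directed motor at vm = 0.08 um/s held for 10 s with unbinding
  # switched off: mean displacement 0.8 um toward the minus end, variance
  # v a t (Poisson step counting)
  um <- unit_spec("motor", "toward_minus", vm = 0.08, fs = 5, k_on = 0,
                  k_off0 = 0, f_unb = 10, end_policy = "hold")
  spec <- linker_spec("runner", um, um, k_spring = 10, rest_length = 0.05)
  pp <- physics_params(kBT = 1e-12) # quiet filament
  st <- new_system(simulation_box(20, 20, 0.2), pp, linker_types = list(spec),
                   seed = 9L)
  st <- add_filament(st, c(2, 10, 0.1), c(1, 0, 0), 4)
  n <- 500
  st <- add_linkers(st, "runner", n, pos = matrix(10, n, 3),
                    anchors = list(fil = cbind(rep(1L, n), rep(0L, n)),
                                   absc = cbind(rep(2, n), rep(0, n))))
  r <- run_until(st, 10)
  disp <- r$state$linkers$absc[, 1] - 2
  v <- 0.08; a <- 0.008; tt <- 10
  expect_equal(mean(disp), -v * tt, tolerance = 4 * sqrt(v * a * tt / n) / (v * tt))
  expect_equal(var(disp), v * a * tt, tolerance = 0.2)
  expect_true(all(r$state$linkers$fil[, 1] == 1)) # never unbinds, never released
})
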