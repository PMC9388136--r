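kBT <- 4.23e-3
a <- 0.008

test_that("the catalog encodes the complex designs", {
  k <- linker_catalog("kif11")
  expect_identical(k$unit_a$direction, "toward_plus")
  expect_identical(k$unit_b$direction, "toward_plus")
  expect_identical(k$unit_a$end_policy, "release")
  expect_identical(k$unit_a, k$unit_b) # symmetric complex
  expect_gt(k$rest_length, 0)

  h <- linker_catalog("hset")
  expect_identical(h$unit_a$kind, "motor")
  expect_identical(h$unit_a$direction, "toward_minus")
  expect_identical(h$unit_b$kind, "diffusive")
  expect_identical(h$unit_a$end_policy, "hold")
  expect_identical(h$unit_b$end_policy, "hold")
  # zero-force dwell ratio tail/motor = 500
  expect_equal((1 / h$unit_b$k_off0) / (1 / h$unit_a$k_off0), 500)
  # motor takes on average step_rate / k_off0 = 2 steps per engagement
  expect_equal((h$unit_a$vm / 0.008) / h$unit_a$k_off0, 2)

  expect_identical(linker_catalog("hset_plus")$unit_a$direction,
                   "toward_plus")
  expect_identical(linker_catalog("hset_stiff_tail")$unit_b$D, 0)
  dm <- linker_catalog("double_motor_hset")
  expect_identical(dm$unit_a, dm$unit_b)
  expect_identical(dm$unit_a$kind, "motor")
  dt_ <- linker_catalog("double_tail_end_release")
  expect_identical(dt_$unit_a$kind, "diffusive")
  expect_identical(apply_end_policy(dt_$unit_a), "release")
  expect_identical(apply_end_policy(linker_catalog("hset")$unit_a), "hold")
  sm <- linker_catalog("symmetric_minus")
  expect_identical(sm$unit_a, sm$unit_b)
  expect_identical(sm$unit_a$direction, "toward_minus")
  # mildly processive: more steps per engagement than hset's motor
  expect_gt((sm$unit_a$vm / 0.008) / sm$unit_a$k_off0, 2)
  expect_error(linker_catalog("dynein"), "catalog")
})

test_that("Bell unbinding is log-linear in load", {
  expect_equal(unbinding_rate(0.1, 6, 0), 0.1)
  expect_equal(unbinding_rate(0.1, 6, 6), 0.1 * exp(1))
  f <- 2.7
  expect_equal(unbinding_rate(0.1, 6, 2 * f) * unbinding_rate(0.1, 6, 0),
               unbinding_rate(0.1, 6, f)^2)
  expect_error(unbinding_rate(0.1, 6, -1), "non-negative")
})

test_that("force-velocity is linear with stall and a 2 vm cap", {
  expect_equal(motor_velocity(0.03, 5, 0), 0.03)
  expect_equal(motor_velocity(0.03, 5, -5), 0)
  expect_equal(motor_velocity(0.03, 5, -2.5), 0.015)
  expect_equal(motor_velocity(0.03, 5, 10), 0.06)  # assisting load caps
  expect_equal(motor_velocity(0.03, 5, -8), 0)     # super-stall: no reverse
})

test_that("hop rates satisfy detailed balance and the Einstein relation", {
  r0 <- diffusive_hop_rates(0.01, 0, kBT)
  expect_equal(unname(r0[1]), unname(r0[2]))
  expect_equal(unname(r0[1]), 0.01 / a^2)
  for (f in c(-2, -0.3, 0.5, 3)) {
    r <- diffusive_hop_rates(0.01, f, kBT)
    expect_equal(unname(r[1] / r[2]), exp(f * a / kBT), tolerance = 1e-12)
  }
  # small-force drift  a (r+ - r-)  ->  D f / kBT
  f <- 0.005
  r <- diffusive_hop_rates(0.01, f, kBT)
  expect_equal(unname(a * (r[1] - r[2])), 0.01 * f / kBT, tolerance = 0.02)
  # and the drift of simulated hops matches at small force
  set.seed(21)
  f <- 0.05
  r <- diffusive_hop_rates(0.01, f, kBT)
  nhop <- 1e6
  p <- unname(r[1] / sum(r))
  net <- sum(sample(c(1, -1), nhop, TRUE, c(p, 1 - p)))
  drift_sim <- net * a / (nhop / sum(r))
  se <- a * sum(r) * 2 * sqrt(p * (1 - p) / nhop)
  expect_equal(drift_sim, 0.01 * f / kBT,
               tolerance = (3 * se + 0.002 * 0.01 * f / kBT) / (0.01 * f / kBT))
})

test_that("the Hookean link has a force-free rest length and obeys action-reaction", {
  e <- 0.05; k <- 10
  pa <- c(0, 0, 0)
  expect_equal(link_force(pa, c(e, 0, 0), k, e), c(0, 0, 0))
  f <- link_force(pa, c(2 * e, 0, 0), k, e)
  expect_equal(f, c(k * e, 0, 0)) # pulls a toward b with magnitude k e
  # repulsive below rest length
  expect_lt(link_force(pa, c(e / 2, 0, 0), k, e)[1], 0)
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(3); y <- rnorm(3)
    expect_equal(link_force(x, y, k, e), -link_force(y, x, k, e),
                 tolerance = 1e-12)
  }
  # degenerate coincident anchors: zero force by convention
  expect_equal(link_force(pa, pa, k, e), c(0, 0, 0))
  # minimum image: anchors across the periodic boundary attract the short way
  box <- simulation_box(20, 20, 0.2)
  f <- link_force(c(0.1, 0, 0.1), c(19.9, 0, 0.1), k, e, box)
  expect_lt(f[1], 0)
})

test_that("dwell-time kinetic Monte Carlo recovers the 500x ratio and 2 steps", {
  h <- linker_catalog("hset")
  set.seed(31)
  motor <- simulate_unit_dwell(h$unit_a, 2e4)
  tail <- simulate_unit_dwell(h$unit_b, 2e4)
  ratio <- mean(tail$dwell) / mean(motor$dwell)
  expect_equal(ratio, 500, tolerance = 0.05)
  expect_equal(mean(motor$steps), 2, tolerance = 0.03)
  # stall: a motor loaded at exactly -fs never steps
  stalled <- simulate_unit_dwell(h$unit_a, 1000, f_par = -h$unit_a$fs)
  expect_true(all(stalled$steps == 0))
  # load accelerates unbinding per the Bell law
  loaded <- simulate_unit_dwell(h$unit_a, 2e4, f_par = -h$unit_a$f_unb)
  expect_equal(mean(motor$dwell) / mean(loaded$dwell), exp(1),
               tolerance = 0.06)
})

test_that("biased hopping reaches the Boltzmann distribution on a bounded lattice", {
  # 32-site lattice with a constant potential gradient dE = f a per site and
  # reflecting ends; stationary occupancy must be exp(-E_i/kBT), which is
  # what thermodynamic consistency of the hop-rate splitting guarantees.
  nsite <- 16
  f <- -0.1 # pN, pushing toward site 1; potential E_i = -f a i increases
  r <- diffusive_hop_rates(0.01, f, kBT)
  p_boltz <- exp(f * a * (seq_len(nsite) - 1) / kBT)
  p_boltz <- p_boltz / sum(p_boltz)
  set.seed(41)
  # uniformized jump chain (rejected end hops are self-loops, so every jump
  # carries the same exponential clock and jump-chain occupancy equals the
  # CTMC's); thinning far beyond the lattice mixing time gives near-iid
  # samples
  nsamp <- 2000
  thin <- 500
  site <- 8L
  occ <- integer(nsamp)
  pp <- unname(r[1] / sum(r))
  for (s in seq_len(nsamp)) {
    u <- runif(thin) < pp
    for (j in seq_len(thin)) {
      cand <- site + if (u[j]) 1L else -1L
      if (cand >= 1L && cand <= nsite) site <- cand # ends reject
    }
    occ[s] <- site
  }
  counts <- tabulate(occ, nbins = nsite)
  chi <- suppressWarnings(chisq.test(counts, p = p_boltz))
  expect_gt(chi$p.value, 0.01)
  # Kolmogorov-Smirnov distance against the discrete Boltzmann CDF, with a
  # Monte Carlo null at alpha = 0.01
  ks_stat <- function(cnt) max(abs(cumsum(cnt) / sum(cnt) - cumsum(p_boltz)))
  obs <- ks_stat(counts)
  null <- replicate(400, ks_stat(as.vector(rmultinom(1, nsamp, p_boltz))))
  expect_lt(obs, quantile(null, 0.99) * 1.5 + 0.03)
})
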