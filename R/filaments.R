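#' Pool-limited growth model
#'
#' Plus ends elongate at a speed throttled linearly by depletion of a shared,
#' finite tubulin pool: `vg(t) = alpha * (1 - sum(L_i(t)) / omega)`, where
#' `omega` is the total polymerizable material (expressed in micrometers of
#' polymer) and `alpha` is the filament's own maximum growth speed. Each
#' filament draws its `alpha` once at nucleation, producing the broad length
#' distribution seen in stabilized-microtubule experiments.
#'
#' @param alpha0 Reference maximum growth speed (um/s).
#' @param omega Tubulin pool size (um of polymer).
#' @param speed_sd_factor Multiplier on the standard-normal draw in the
#'   per-filament speed rule `alpha = alpha0 * |1 + speed_sd_factor * Z|`.
#' @param speed_clip Admissible per-filament speed range (um/s).
#' @return An object of class `growth_model`.
#' @export
growth_model <- function(alpha0 = 0.05, omega, speed_sd_factor = 0.25,
                         speed_clip = c(0, 2)) {
  stopifnot(alpha0 > 0, omega > 0, speed_clip[1] >= 0,
            speed_clip[2] > speed_clip[1])
  structure(list(alpha0 = alpha0, omega = omega,
                 speed_sd_factor = speed_sd_factor, speed_clip = speed_clip),
            class = "growth_model")
}

#' Instantaneous pool-limited growth speed
#'
#' @param alpha Per-filament maximum growth speed (um/s).
#' @param polymerized Total polymerized length over all filaments (um).
#' @param omega Pool size (um).
#' @return Growth speed `alpha * (1 - polymerized/omega)` (um/s).
#' @export
growth_speed <- function(alpha, polymerized, omega) {
  if (any(polymerized < 0) || any(polymerized > omega)) {
    stop("polymerized length outside [0, omega]: conservation violated upstream")
  }
  alpha * (1 - polymerized / omega)
}

#' Draw per-filament maximum growth speeds
#'
#' `alpha = clip(alpha0 * |1 + speed_sd_factor * Z|, speed_clip)` with
#' `Z ~ N(0,1)`. Uses R's RNG stream; seed with [set.seed()] for
#' reproducibility. The clip is a hard truncation applied after the
#' folded-normal draw.
#'
#' @param alpha0 Reference speed (um/s).
#' @param n Number of draws.
#' @param speed_sd_factor,speed_clip See [growth_model()].
#' @return Numeric vector of length `n`.
#' @export
draw_max_speed <- function(alpha0, n = 1, speed_sd_factor = 0.25,
                           speed_clip = c(0, 2)) {
  stopifnot(alpha0 > 0)
  a <- alpha0 * abs(1 + speed_sd_factor * stats::rnorm(n))
  pmin(pmax(a, speed_clip[1]), speed_clip[2])
}

#' Lattice site of an arc-length position
#'
#' Cross-linker units bind to discrete lattice sites of 8 nm along the
#' filament. Site `i` covers abscissae `[i*0.008, (i+1)*0.008)` measured from
#' the minus end.
#'
#' @param a Abscissa from the minus end (um), `0 <= a <= length`.
#' @param length Filament contour length (um).
#' @param site_size Lattice period (um), 0.008 by default.
#' @return Integer site index (0-based).
#' @export
site_of_abscissa <- function(a, length, site_size = 0.008) {
  if (any(a < 0) || any(a > length)) stop("abscissa outside filament")
  as.integer(floor(a / site_size))
}

#' Abscissa of a lattice site center
#'
#' Inverse of [site_of_abscissa()]: returns the site center `(i + 0.5) * 0.008`
#' clamped to `[0, length]`.
#'
#' @param i Site index (0-based).
#' @param length Filament contour length (um).
#' @param site_size Lattice period (um).
#' @return Abscissa (um).
#' @export
abscissa_of_site <- function(i, length, site_size = 0.008) {
  pmin(pmax((i + 0.5) * site_size, 0), length)
}

#' Discrete bending energy of a filament
#'
#' Linearized worm-like-chain bending energy on the vertex chain:
#' `E = kappa / (2 l^3) * sum_i |r_{i-1} - 2 r_i + r_{i+1}|^2`,
#' the standard second-difference discretization of
#' `(kappa/2) integral |d^2 r/ds^2|^2 ds` at segment length `l`. Quadratic in
#' positions, invariant under rigid translation and rotation.
#'
#' @param vertices n x 3 matrix of vertex positions (um), minus end first.
#' @param rigidity Flexural rigidity kappa (pN um^2).
#' @param segment_length Discretization segment length l (um).
#' @return Energy (pN um).
#' @export
bending_energy <- function(vertices, rigidity, segment_length) {
  n <- nrow(vertices)
  if (n < 3) return(0)
  d2 <- vertices[1:(n - 2), , drop = FALSE] -
    2 * vertices[2:(n - 1), , drop = FALSE] +
    vertices[3:n, , drop = FALSE]
  rigidity / (2 * segment_length^3) * sum(d2 * d2)
}

#' Bending forces on filament vertices
#'
#' Exact negative gradient of [bending_energy()]. For any configuration the
#' returned forces sum to zero and exert zero net torque (the energy is
#' invariant under rigid motions).
#'
#' @inheritParams bending_energy
#' @return n x 3 matrix of forces (pN).
#' @export
bending_forces <- function(vertices, rigidity, segment_length) {
  n <- nrow(vertices)
  f <- matrix(0, n, 3)
  if (n < 3) return(f)
  c0 <- rigidity / segment_length^3
  d2 <- vertices[1:(n - 2), , drop = FALSE] -
    2 * vertices[2:(n - 1), , drop = FALSE] +
    vertices[3:n, , drop = FALSE]
  for (i in seq_len(n - 2)) {
    g <- c0 * d2[i, ]
    f[i, ] <- f[i, ] - g
    f[i + 1, ] <- f[i + 1, ] + 2 * g
    f[i + 2, ] <- f[i + 2, ] - g
  }
  f
}

#' Pool-limited growth of an isolated population (mechanics disabled)
#'
#' Integrates seed nucleation and the pool-limited growth law for a
#' population of filaments without any mechanics, thermal motion or
#' cross-linkers. Nucleation fires each unused seed with probability
#' `1 - exp(-rate * dt)` per step; each new filament starts at
#' `initial_length` (drawn from the pool) with its own maximum speed from
#' [draw_max_speed()]. Growth stops globally at `growth_until` seconds or
#' when the pool is exhausted. Intended for studying the growth law itself
#' and for steady-state length calibration.
#'
#' @param n_seeds Number of nucleation seeds (at most one filament each).
#' @param growth A [growth_model()].
#' @param nucleation_rate Per-seed nucleation rate (1/s).
#' @param dt Time step (s). Mechanics-free, so this may be much larger than
#'   the Langevin step.
#' @param t_end Hard time limit (s).
#' @param growth_until Duration of the growth phase (s).
#' @param initial_length Length of a freshly nucleated filament (um).
#' @param plateau_rel Convergence criterion: stop when the relative change of
#'   total length per 100 s falls below this (and all seeds have fired or the
#'   pool is gone). Set `NULL` to always run to `t_end`.
#' @return List with `lengths` (um, one per nucleated filament), `time`,
#'   `polymerized`, and `n_nucleated`.
#' @export
simulate_growth_only <- function(n_seeds, growth, nucleation_rate = 0.1,
                                 dt = 0.05, t_end = 2000, growth_until = Inf,
                                 initial_length = 0.1, plateau_rel = 1e-4) {
  stopifnot(n_seeds >= 1, inherits(growth, "growth_model"))
  omega <- growth$omega
  p_nuc <- 1 - exp(-nucleation_rate * dt)
  lengths <- numeric(0)
  alphas <- numeric(0)
  unused <- n_seeds
  poly <- 0
  t <- 0
  check_every <- max(1L, round(100 / dt))
  last_total <- 0
  step <- 0L
  while (t < t_end && t < growth_until) {
    step <- step + 1L
    if (unused > 0 && poly < omega) {
      fired <- stats::rbinom(1, unused, p_nuc)
      if (fired > 0) {
        take <- min(fired * initial_length, omega - poly)
        k <- floor(take / initial_length)
        if (k > 0) {
          lengths <- c(lengths, rep(initial_length, k))
          alphas <- c(alphas, draw_max_speed(growth$alpha0, k,
                                            growth$speed_sd_factor,
                                            growth$speed_clip))
          unused <- unused - k
          poly <- poly + k * initial_length
        }
      }
    }
    if (length(lengths) > 0 && poly < omega) {
      vg <- growth_speed(alphas, poly, omega)
      dl <- vg * dt
      room <- omega - poly
      tot <- sum(dl)
      if (tot > room) dl <- dl * (room / tot)
      lengths <- lengths + dl
      poly <- poly + sum(dl)
    }
    t <- t + dt
    if (!is.null(plateau_rel) && step %% check_every == 0L) {
      if (unused == 0 && last_total > 0 &&
          (poly - last_total) / poly < plateau_rel) break
      last_total <- poly
    }
  }
  list(lengths = lengths, time = t, polymerized = poly,
       n_nucleated = length(lengths))
}

#' Create a filament
#'
#' A filament is a polar chain of vertices: vertex 1 is the minus end, the
#' last vertex the plus end. All segments have rest length
#' `rest_segment_length` except the terminal (plus-end) one, which carries
#' the growth remainder. Polarity is immutable.
#'
#' @param minus_end Length-3 position of the minus end (um).
#' @param direction Length-3 unit vector from minus toward plus end.
#' @param length Initial contour length (um).
#' @param alpha Per-filament maximum growth speed (um/s).
#' @param rest_segment_length Target segment length (um).
#' @param rigidity Flexural rigidity kappa (pN um^2).
#' @return An object of class `filament` with fields `vertices`,
#'   `seg_rests` (per-segment rest lengths), `alpha`, `rigidity`, `growing`.
#' @export
new_filament <- function(minus_end, direction, length, alpha = 0.05,
                         rest_segment_length = 0.5, rigidity = 20) {
  stopifnot(length > 0)
  direction <- direction / sqrt(sum(direction^2))
  n_full <- floor(length / rest_segment_length)
  rem <- length - n_full * rest_segment_length
  if (rem > 1e-12) {
    rests <- c(rep(rest_segment_length, n_full), rem)
  } else if (n_full >= 1) {
    rests <- rep(rest_segment_length, n_full)
  } else {
    rests <- length
  }
  abscissae <- c(0, cumsum(rests))
  vertices <- outer(abscissae, direction) +
    matrix(minus_end, length(abscissae), 3, byrow = TRUE)
  structure(list(vertices = vertices, seg_rests = rests, alpha = alpha,
                 rest_segment_length = rest_segment_length,
                 rigidity = rigidity, growing = TRUE),
            class = "filament")
}

#' Contour length of a filament
#' @param fil A [new_filament()] object.
#' @return Length (um), the sum of segment rest lengths.
#' @export
filament_length <- function(fil) sum(fil$seg_rests)

#' Grow the plus end of a filament
#'
#' Extends the terminal segment along its current direction by
#' `min(vg * dt, omega - polymerized)` and draws the same amount from the
#' pool. When the terminal segment exceeds 1.5x the rest segment length it is
#' split in two (one full rest segment plus remainder), keeping segment
#' lengths near-uniform without global re-meshing. Minus ends never grow.
#'
#' @param fil A [new_filament()] object with `growing = TRUE`.
#' @param vg Growth speed (um/s), non-negative.
#' @param dt Time step (s).
#' @param pool List with `omega` and `polymerized` (um).
#' @return List `(filament, pool)` with updated copies.
#' @export
grow_plus_end <- function(fil, vg, dt, pool) {
  stopifnot(inherits(fil, "filament"), vg >= 0)
  if (pool$polymerized > pool$omega) stop("pool overdrawn")
  if (!fil$growing) return(list(filament = fil, pool = pool))
  dl <- min(vg * dt, pool$omega - pool$polymerized)
  if (dl <= 0) return(list(filament = fil, pool = pool))
  n <- nrow(fil$vertices)
  tangent <- fil$vertices[n, ] - fil$vertices[n - 1, ]
  tangent <- tangent / sqrt(sum(tangent^2))
  fil$vertices[n, ] <- fil$vertices[n, ] + dl * tangent
  k <- length(fil$seg_rests)
  fil$seg_rests[k] <- fil$seg_rests[k] + dl
  if (fil$seg_rests[k] > 1.5 * fil$rest_segment_length) {
    rem <- fil$seg_rests[k] - fil$rest_segment_length
    new_v <- fil$vertices[n - 1, ] + fil$rest_segment_length * tangent
    fil$vertices <- rbind(fil$vertices[1:(n - 1), , drop = FALSE], new_v,
                          fil$vertices[n, , drop = FALSE])
    fil$seg_rests <- c(fil$seg_rests[seq_len(k - 1)],
                       fil$rest_segment_length, rem)
  }
  pool$polymerized <- pool$polymerized + dl
  list(filament = fil, pool = pool)
}
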