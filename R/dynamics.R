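#' Physical parameters of the Langevin dynamics
#'
#' Per-vertex isotropic drag follows the slender-body scaling
#' `gamma = 3 pi eta l_seg / ln(l_seg / (2 r_mt))`; free cross-linker
#' complexes use a Stokes drag `6 pi eta r_linker`. The soft-core repulsion
#' stiffness and the spring stiffness defaults sit inside the stability
#' window of the explicit treatment of those force terms at the default time
#' step (the stiff bending term is integrated exactly, see the package
#' vignette).
#'
#' @param dt Time step (s).
#' @param kBT Thermal energy (pN um); default corresponds to 306 K (33 C).
#' @param eta Medium viscosity (pN s/um^2).
#' @param k_steric Soft-core repulsion stiffness (pN/um).
#' @param d_steric Repulsion onset distance (um).
#' @param rigidity Flexural rigidity kappa (pN um^2).
#' @param rest_segment_length Filament discretization length (um).
#' @param r_mt Microtubule radius (um), used in the drag formula.
#' @param r_linker Effective complex radius (um), for free-complex drag.
#' @param gamma_vertex,gamma_linker Optional drag overrides (pN s/um).
#' @return An object of class `physics_params`.
#' @export
physics_params <- function(dt = 0.005, kBT = 4.23e-3, eta = 0.1,
                           k_steric = 20, d_steric = 0.05, rigidity = 20,
                           rest_segment_length = 0.5, r_mt = 0.0125,
                           r_linker = 0.025, gamma_vertex = NULL,
                           gamma_linker = NULL) {
  stopifnot(dt > 0, kBT > 0, eta > 0, d_steric > 0, rigidity >= 0,
            rest_segment_length > 0)
  if (is.null(gamma_vertex)) {
    gamma_vertex <- 3 * pi * eta * rest_segment_length /
      log(rest_segment_length / (2 * r_mt))
  }
  if (is.null(gamma_linker)) gamma_linker <- 6 * pi * eta * r_linker
  structure(list(dt = dt, kBT = kBT, eta = eta, k_steric = k_steric,
                 d_steric = d_steric, rigidity = rigidity,
                 rest_segment_length = rest_segment_length, r_mt = r_mt,
                 gamma_vertex = gamma_vertex, gamma_linker = gamma_linker),
            class = "physics_params")
}

#' Growth configuration for a simulated system
#'
#' Couples a [growth_model()] with nucleation parameters. Nucleation fires
#' each unused seed with probability `1 - exp(-rate dt)` per step; most
#' filaments therefore nucleate within the first few tens of seconds at the
#' default rate. Growth stops globally at `growth_until` (the filaments then
#' keep a fixed length; there is no catastrophe).
#'
#' @param alpha0,omega,speed_sd_factor,speed_clip See [growth_model()].
#' @param nucleation_rate Per-seed rate (1/s).
#' @param growth_until End of the growth phase (s of simulated time).
#' @param initial_length Length of a freshly nucleated filament (um).
#' @return A list suitable for [new_system()]'s `growth` argument.
#' @export
growth_config <- function(alpha0 = 0.05, omega, speed_sd_factor = 0.25,
                          speed_clip = c(0, 2), nucleation_rate = 0.1,
                          growth_until = 600, initial_length = 0.1) {
  gm <- growth_model(alpha0, omega, speed_sd_factor, speed_clip)
  c(unclass(gm), list(nucleation_rate = nucleation_rate,
                      growth_until = growth_until,
                      initial_length = initial_length))
}

#' Create a simulation system state
#'
#' The state bundles the box, physics, optional growth/nucleation setup,
#' filaments, cross-linkers and the RNG stream. Advance it with
#' [run_until()]; inspect forces with [assemble_forces()].
#'
#' @param box A [simulation_box()].
#' @param physics A [physics_params()].
#' @param growth A [growth_config()] list, or `NULL` for no growth.
#' @param seeds Matrix of nucleation seed positions (n x 3, um), or an
#'   integer count (positions then drawn uniformly in X/Y at mid-Z using the
#'   current R RNG stream), or `NULL`.
#' @param linker_types List of [linker_spec()] objects used by this system.
#' @param pool Optional list `(omega, polymerized)`; defaults to the growth
#'   model's pool or an effectively infinite pool when `growth` is `NULL`.
#' @param seed Integer seed for the engine's own RNG stream.
#' @return An object of class `mt_system`.
#' @export
new_system <- function(box, physics = physics_params(), growth = NULL,
                       seeds = NULL, linker_types = list(), pool = NULL,
                       seed = 1L) {
  stopifnot(inherits(box, "simulation_box"),
            inherits(physics, "physics_params"))
  if (is.numeric(seeds) && length(seeds) == 1) {
    n <- as.integer(seeds)
    seeds <- cbind(stats::runif(n, 0, box$size_x),
                   stats::runif(n, 0, box$size_y),
                   rep(box$size_z / 2, n))
  }
  if (!is.null(seeds)) {
    seeds <- list(pos = as.matrix(seeds), used = rep(FALSE, nrow(seeds)))
  }
  if (is.null(pool)) {
    pool <- if (!is.null(growth)) list(omega = growth$omega, polymerized = 0)
            else list(omega = Inf, polymerized = 0)
  }
  if (length(linker_types) > 0 && inherits(linker_types, "linker_spec")) {
    linker_types <- list(linker_types)
  }
  structure(list(
    box = c(box$size_x, box$size_y, box$size_z),
    time = 0,
    pool = pool,
    physics = unclass(physics),
    growth = growth,
    seeds = seeds,
    fil = list(nv = integer(0), vertices = matrix(0, 0, 3),
               alpha = numeric(0), last_rest = numeric(0),
               length = numeric(0)),
    linker_types = linker_types,
    linkers = NULL,
    rng = NULL,
    seed = as.integer(seed)
  ), class = "mt_system")
}

#' @export
print.mt_system <- function(x, ...) {
  nl <- if (is.null(x$linkers)) 0 else length(x$linkers$type)
  cat(sprintf(
    "mt_system: t = %g s, %d filaments, %d cross-linkers, box %g x %g x %g um\n",
    x$time, length(x$fil$nv), nl, x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Add a filament to a system
#'
#' @param state An `mt_system`.
#' @param minus_end,direction,length,alpha See [new_filament()]. The segment
#'   rest length and rigidity come from the system's physics.
#' @return Updated state.
#' @export
add_filament <- function(state, minus_end, direction, length, alpha = 0.05) {
  fil <- new_filament(minus_end, direction, length, alpha,
                      state$physics$rest_segment_length,
                      state$physics$rigidity)
  nv <- nrow(fil$vertices)
  state$fil$nv <- c(state$fil$nv, nv)
  state$fil$vertices <- rbind(state$fil$vertices, fil$vertices)
  state$fil$alpha <- c(state$fil$alpha, alpha)
  state$fil$last_rest <- c(state$fil$last_rest,
                           fil$seg_rests[length(fil$seg_rests)])
  state$fil$length <- c(state$fil$length, sum(fil$seg_rests))
  state$pool$polymerized <- state$pool$polymerized + sum(fil$seg_rests)
  state
}

#' Add cross-linker complexes to a system
#'
#' @param state An `mt_system`.
#' @param type Name of one of the system's `linker_types`, or its index.
#' @param n Number of complexes to add.
#' @param pos Optional n x 3 matrix of complex positions (um); defaults to
#'   uniform placement in the box using the current R RNG stream.
#' @param anchors Optional list `(fil = n x 2 matrix, absc = n x 2 matrix)`
#'   of initial anchors (filament index, 0 for unbound; abscissa in um), for
#'   constructing test systems with pre-bound linkers.
#' @return Updated state.
#' @export
add_linkers <- function(state, type, n = 1, pos = NULL, anchors = NULL) {
  if (is.character(type)) {
    type <- match(type, vapply(state$linker_types, `[[`, "", "name"))
    if (is.na(type)) stop("linker type not registered in this system")
  }
  if (is.null(pos)) {
    pos <- cbind(stats::runif(n, 0, state$box[1]),
                 stats::runif(n, 0, state$box[2]),
                 stats::runif(n, 0, state$box[3]))
  }
  fil <- if (is.null(anchors)) matrix(0L, n, 2) else anchors$fil
  absc <- if (is.null(anchors)) matrix(0, n, 2) else anchors$absc
  storage.mode(fil) <- "integer"
  if (is.null(state$linkers)) {
    state$linkers <- list(type = rep(as.integer(type), n), fil = fil,
                          absc = absc, pos = pos)
  } else {
    state$linkers$type <- c(state$linkers$type, rep(as.integer(type), n))
    state$linkers$fil <- rbind(state$linkers$fil, fil)
    state$linkers$absc <- rbind(state$linkers$absc, absc)
    state$linkers$pos <- rbind(state$linkers$pos, pos)
  }
  state
}

#' Advance a system to a target time
#'
#' Repeats the Langevin step (deterministic forces, vertex update with exact
#' Ornstein-Uhlenbeck handling of the bending term, segment-length
#' constraint projection, Z reflection, then cross-linker kinetics) until
#' `t_end`. Fully reproducible for a fixed seed and configuration; calling
#' repeatedly continues the same RNG stream.
#'
#' @param state An `mt_system`.
#' @param t_end Target time (s), `>= state$time`.
#' @param frame_interval Observer interval (s) at which snapshots are
#'   captured (must be a multiple of `dt`); the initial state is always
#'   frame 1. `NULL` records no frames.
#' @return List with the advanced `state` and `trajectory` (class
#'   `mt_trajectory`, possibly with zero frames).
#' @export
run_until <- function(state, t_end, frame_interval = NULL) {
  stopifnot(inherits(state, "mt_system"), t_end >= state$time)
  dt <- state$physics$dt
  n_steps <- round((t_end - state$time) / dt)
  if (abs(n_steps * dt - (t_end - state$time)) > 1e-9 * max(1, t_end)) {
    stop("t_end - time must be a multiple of dt")
  }
  record <- !is.null(frame_interval)
  stride <- 0L
  if (record) {
    stride <- round(frame_interval / dt)
    if (abs(stride * dt - frame_interval) > 1e-9) {
      stop("frame_interval must be a multiple of dt")
    }
  }
  res <- engine_run(state, as.integer(n_steps), as.integer(stride), record)
  st <- res$state
  class(st) <- "mt_system"
  traj <- structure(list(
    meta = list(
      linker_type_names = vapply(state$linker_types, `[[`, "", "name"),
      frame_interval = if (record) frame_interval else NA_real_,
      seed = state$seed,
      format_version = 1L
    ),
    frames = res$frames
  ), class = "mt_trajectory")
  list(state = st, trajectory = traj)
}

#' Assemble deterministic forces on all vertices
#'
#' Returns bending, cross-link spring and steric force components per vertex
#' (thermal noise excluded), and the per-unit projected loads used by the
#' kinetics. Bending and spring forces are exact negative gradients of
#' [system_energy()]'s corresponding terms; the steric force is deliberately
#' non-conservative (its axial component is projected out so repulsion does
#' not resist sliding).
#'
#' @param state An `mt_system`.
#' @return List with matrices `total`, `bending`, `spring`, `steric` (one row
#'   per vertex, stacked in filament order) and `load_par` (n_linkers x 2),
#'   `load_mag`.
#' @export
assemble_forces <- function(state) {
  stopifnot(inherits(state, "mt_system"))
  f <- engine_forces(state)
  total <- f$spring + f$steric + f$bending
  if (!all(is.finite(total))) stop("non-finite force in assembly")
  list(total = total, bending = f$bending, spring = f$spring,
       steric = f$steric, load_par = f$load_par, load_mag = f$load_mag)
}

# world position of an anchor (filament index 1-based, abscissa um)
anchor_position <- function(state, fil, absc) {
  offs <- cumsum(c(0, state$fil$nv))
  nv <- state$fil$nv[fil]
  lseg <- state$physics$rest_segment_length
  nseg <- nv - 1
  j <- min(max(floor(absc / lseg), 0), nseg - 1)
  rest <- if (j == nseg - 1) state$fil$last_rest[fil] else lseg
  w <- min(max((absc - j * lseg) / rest, 0), 1)
  v0 <- state$fil$vertices[offs[fil] + j + 1, ]
  v1 <- state$fil$vertices[offs[fil] + j + 2, ]
  v0 + w * (v1 - v0)
}

#' Total potential energy of bending and cross-link springs
#'
#' `E = sum_f E_bend(f) + sum_linkers k/2 (|u| - e)^2` over doubly bound
#' linkers, with `u` the minimum-image anchor separation. The soft-core
#' steric term is excluded: its force is projected perpendicular to the
#' filament axes and is therefore not a gradient field.
#'
#' @param state An `mt_system`.
#' @return Energy (pN um).
#' @export
system_energy <- function(state) {
  stopifnot(inherits(state, "mt_system"))
  lseg <- state$physics$rest_segment_length
  box <- simulation_box(state$box[1], state$box[2], state$box[3])
  offs <- cumsum(c(0, state$fil$nv))
  e <- 0
  for (i in seq_along(state$fil$nv)) {
    v <- state$fil$vertices[(offs[i] + 1):offs[i + 1], , drop = FALSE]
    e <- e + bending_energy(v, state$physics$rigidity, lseg)
  }
  if (!is.null(state$linkers)) {
    for (i in seq_along(state$linkers$type)) {
      fa <- state$linkers$fil[i, 1]
      fb <- state$linkers$fil[i, 2]
      if (fa == 0 || fb == 0) next
      spec <- state$linker_types[[state$linkers$type[i]]]
      pa <- anchor_position(state, fa, state$linkers$absc[i, 1])
      pb <- anchor_position(state, fb, state$linkers$absc[i, 2])
      u <- minimum_image(pb - pa, box)
      e <- e + spec$k_spring / 2 * (sqrt(sum(u^2)) - spec$rest_length)^2
    }
  }
  e
}

#' Restore segment rest lengths by iterative projection
#'
#' Gauss-Seidel projection: each segment's two endpoints are moved toward or
#' away from each other along the bond by half the length error, repeatedly,
#' until all relative errors fall below `tol`. Displaces the filament
#' centroid as little as the per-bond symmetric correction permits.
#'
#' @param vertices n x 3 vertex matrix.
#' @param rest_lengths Length n-1 vector of segment rest lengths (um).
#' @param tol Relative tolerance.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return Corrected vertex matrix.
#' @export
enforce_segment_lengths <- function(vertices, rest_lengths, tol = 1e-6,
                                    max_iter = 100) {
  n <- nrow(vertices)
  stopifnot(length(rest_lengths) == n - 1)
  for (it in seq_len(max_iter)) {
    maxrel <- 0
    for (j in seq_len(n - 1)) {
      d <- vertices[j + 1, ] - vertices[j, ]
      dist <- sqrt(sum(d^2))
      err <- dist - rest_lengths[j]
      maxrel <- max(maxrel, abs(err) / rest_lengths[j])
      if (dist > 1e-12) {
        corr <- 0.5 * err / dist * d
        vertices[j, ] <- vertices[j, ] + corr
        vertices[j + 1, ] <- vertices[j + 1, ] - corr
      }
    }
    if (maxrel < tol) return(vertices)
  }
  stop("segment-length projection did not converge in ", max_iter,
       " iterations")
}

#' Soft-core steric forces between two filaments (reference implementation)
#'
#' For every pair of segments closer than `d_steric` (minimum image), a
#' Hookean repulsion `k_steric * (d_steric - r)` acts along the closest
#' approach direction with the components parallel to either filament's
#' local axis removed, so that contact does not resist sliding. Forces are
#' distributed to the bounding vertices and are equal and opposite by
#' construction. This R implementation mirrors the engine's and serves as
#' its small-system oracle.
#'
#' @param verts_a,verts_b Vertex matrices of the two filaments.
#' @param params A [physics_params()].
#' @param box A [simulation_box()] or `NULL`.
#' @return List of force matrices `(f_a, f_b)`.
#' @export
steric_forces <- function(verts_a, verts_b, params, box = NULL) {
  na <- nrow(verts_a); nb <- nrow(verts_b)
  fa <- matrix(0, na, 3); fb <- matrix(0, nb, 3)
  for (i in seq_len(na - 1)) {
    for (j in seq_len(nb - 1)) {
      p1 <- verts_a[i, ]; q1 <- verts_a[i + 1, ]
      p2 <- verts_b[j, ]; q2 <- verts_b[j + 1, ]
      if (!is.null(box)) {
        m1 <- (p1 + q1) / 2; m2 <- (p2 + q2) / 2
        sh <- minimum_image(m2 - m1, box) - (m2 - m1)
        p2 <- p2 + sh; q2 <- q2 + sh
      }
      cp <- closest_segment_points(p1, q1, p2, q2)
      r <- sqrt(sum((cp$c2 - cp$c1)^2))
      if (r >= params$d_steric || r < 1e-12) next
      n <- (cp$c2 - cp$c1) / r
      ta <- (q1 - p1); ta <- ta / sqrt(sum(ta^2))
      tb <- (q2 - p2); tb <- tb / sqrt(sum(tb^2))
      np <- n - sum(n * ta) * ta - sum(n * tb) * tb
      nn <- sqrt(sum(np^2))
      if (nn < 1e-9) next
      np <- np / nn
      mag <- params$k_steric * (params$d_steric - r)
      fb[j, ] <- fb[j, ] + (1 - cp$t) * mag * np
      fb[j + 1, ] <- fb[j + 1, ] + cp$t * mag * np
      fa[i, ] <- fa[i, ] - (1 - cp$s) * mag * np
      fa[i + 1, ] <- fa[i + 1, ] - cp$s * mag * np
    }
  }
  list(f_a = fa, f_b = fb)
}

# closest points between two segments; returns list(s, t, c1, c2)
closest_segment_points <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  clamp <- function(x) min(1, max(0, x))
  if (a <= 1e-18 && e <= 1e-18) { s <- 0; t <- 0 }
  else if (a <= 1e-18) { s <- 0; t <- clamp(f / e) }
  else {
    cc <- sum(d1 * r)
    if (e <= 1e-18) { t <- 0; s <- clamp(-cc / a) }
    else {
      b <- sum(d1 * d2); den <- a * e - b * b
      s <- if (den > 1e-18) clamp((b * f - cc * e) / den) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- clamp(-cc / a) }
      else if (t > 1) { t <- 1; s <- clamp((b - cc) / a) }
    }
  }
  list(s = s, t = t, c1 = p1 + s * d1, c2 = p2 + t * d2)
}
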