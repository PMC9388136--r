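#' Cross-linker unit specification
#'
#' A cross-linker complex is built from two microtubule-binding units joined
#' by a Hookean spring. A unit is either a `motor` (directed stochastic
#' stepper with a linear force-velocity relation) or `diffusive` (hops to
#' neighboring 8-nm lattice sites at rates biased by the projected load in a
#' thermodynamically consistent way). Units bind within `binding_range` at
#' rate `k_on` and unbind with the force-dependent (Bell) rate
#' `k_off0 * exp(f / f_unb)`. On reaching a filament end, a unit either
#' releases instantly or holds there (`end_policy`); end-holding is what lets
#' asymmetric minus-directed cross-linkers cluster microtubule ends.
#'
#' @param kind `"motor"` or `"diffusive"`.
#' @param direction `"toward_plus"` or `"toward_minus"` (motors only).
#' @param vm Unloaded speed (um/s, motors only).
#' @param fs Stall force (pN, motors only).
#' @param D Lattice diffusion coefficient (um^2/s, diffusive only).
#' @param k_on Binding rate within range (1/s); the 2.5/s default is
#'   calibrated at network level: faster capture welds crossing filaments
#'   into static clusters before they can remodel.
#' @param binding_range Capture distance (um); defaults to 0.1 um, the
#'   length scale of the extended complex, and deliberately exceeds the
#'   steric gap between cross-linked filaments.
#' @param k_off0 Zero-force unbinding rate (1/s).
#' @param f_unb Characteristic unbinding force (pN).
#' @param end_policy `"release"` or `"hold"`.
#' @return An object of class `unit_spec`.
#' @export
unit_spec <- function(kind = c("motor", "diffusive"),
                      direction = c("toward_plus", "toward_minus"),
                      vm = 0, fs = 5, D = 0, k_on = 2.5, binding_range = 0.1,
                      k_off0 = 0.1, f_unb = 6,
                      end_policy = c("release", "hold")) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  end_policy <- match.arg(end_policy)
  stopifnot(vm >= 0, fs > 0, D >= 0, k_on >= 0, binding_range > 0,
            k_off0 >= 0, f_unb > 0)
  structure(list(kind = kind, direction = direction, vm = vm, fs = fs, D = D,
                 k_on = k_on, binding_range = binding_range, k_off0 = k_off0,
                 f_unb = f_unb, end_policy = end_policy),
            class = "unit_spec")
}

#' Cross-linker complex specification
#'
#' @param name Catalog label.
#' @param unit_a,unit_b [unit_spec()] objects.
#' @param k_spring Spring stiffness k (pN/um).
#' @param rest_length Spring rest length e (um), non-zero for real complexes.
#' @return An object of class `linker_spec`.
#' @export
linker_spec <- function(name, unit_a, unit_b, k_spring = 10,
                        rest_length = 0.05) {
  stopifnot(inherits(unit_a, "unit_spec"), inherits(unit_b, "unit_spec"),
            k_spring > 0, rest_length >= 0)
  structure(list(name = name, unit_a = unit_a, unit_b = unit_b,
                 k_spring = k_spring, rest_length = rest_length),
            class = "linker_spec")
}

# Default kinetic reconstruction, derived from printed constraints:
# - HSET motor: vm = 0.08 um/s  =>  step rate vm/0.008 = 10/s;
#   nonprocessive, mean 2 steps per engagement  =>  k_off0 = 10/2 = 5/s
#   (mean dwell 0.2 s).
# - HSET diffusive tail: dwell 500x the motor's  =>  k_off0 = 0.01/s
#   (dwell 100 s). D = 2e-4 um^2/s sets the tail's protein friction to
#   kBT/D ~ 21 pN s/um, the value implied by the network-level force
#   balance: a handful of tails per filament must let the plus-directed
#   linker slide filaments with only mild resistance, while tens of tails
#   per filament must collectively stall it.
# - KIF11 unit: vm = 0.03 um/s per complex, processive (k_off0 = 0.1/s),
#   releases instantly at the plus end.
# All values overridable per scenario.
.hset_motor <- function() unit_spec("motor", "toward_minus", vm = 0.08,
                                    fs = 5, k_off0 = 5, f_unb = 6,
                                    end_policy = "hold")
.hset_tail <- function(end_policy = "hold", D = 2e-4, k_off0 = 0.01)
  unit_spec("diffusive", D = D, k_off0 = k_off0, f_unb = 1000,
            end_policy = end_policy)

#' Catalog of cross-linker complexes
#'
#' Returns the fully parameterized specification of a named complex:
#' \describe{
#'   \item{kif11}{Symmetric: two processive plus-end-directed motor units
#'     (unloaded complex speed 0.03 um/s); units release immediately at the
#'     plus end, suppressing end accumulation so that nematic networks can
#'     form with short filaments.}
#'   \item{hset}{Asymmetric: one nonprocessive minus-end-directed motor unit
#'     (0.08 um/s, on average two steps per engagement) and one diffusive
#'     tail unit whose zero-force dwell is 500x the motor's; both units hold
#'     at filament ends, allowing end clustering.}
#'   \item{hset_plus}{hset with the motor direction flipped toward the plus
#'     end (hypothetical construct).}
#'   \item{hset_stiff_tail}{hset with the diffusive tail replaced by a
#'     non-hopping unit (D = 0) of matched dwell.}
#'   \item{double_motor_hset}{Symmetric: two hset motor units.}
#'   \item{double_tail_hset}{Symmetric: two diffusive tail units, holding at
#'     ends.}
#'   \item{double_tail_end_release}{Two diffusive tail units that unbind
#'     immediately on reaching a filament end.}
#'   \item{symmetric_minus}{Hypothetical symmetric minus-end-directed motor:
#'     two mildly processive (mean 10 steps) minus-directed units, holding
#'     at ends.}
#' }
#'
#' @param name Catalog label (see Details).
#' @return A [linker_spec()].
#' @export
linker_catalog <- function(name) {
  specs <- list(
    kif11 = function() {
      u <- unit_spec("motor", "toward_plus", vm = 0.03, fs = 5, k_off0 = 0.1,
                     f_unb = 6, end_policy = "release")
      linker_spec("kif11", u, u)
    },
    hset = function() linker_spec("hset", .hset_motor(), .hset_tail()),
    hset_plus = function() {
      m <- .hset_motor(); m$direction <- "toward_plus"
      linker_spec("hset_plus", m, .hset_tail())
    },
    hset_stiff_tail = function()
      linker_spec("hset_stiff_tail", .hset_motor(), .hset_tail(D = 0)),
    double_motor_hset = function()
      linker_spec("double_motor_hset", .hset_motor(), .hset_motor()),
    double_tail_hset = function()
      linker_spec("double_tail_hset", .hset_tail(), .hset_tail()),
    double_tail_end_release = function()
      linker_spec("double_tail_end_release", .hset_tail("release"),
                  .hset_tail("release")),
    symmetric_minus = function() {
      m <- .hset_motor(); m$k_off0 <- 1
      linker_spec("symmetric_minus", m, m)
    }
  )
  if (!name %in% names(specs)) {
    stop("unknown cross-linker '", name, "'; catalog: ",
         paste(names(specs), collapse = ", "))
  }
  specs[[name]]()
}

#' Force-dependent (Bell) unbinding rate
#'
#' `k_off(f) = k_off0 * exp(f / f_unb)`, monotone increasing in the load
#' magnitude `f`.
#'
#' @param k_off0 Zero-force unbinding rate (1/s).
#' @param f_unb Characteristic unbinding force (pN).
#' @param f Load magnitude (pN), non-negative.
#' @return Unbinding rate (1/s).
#' @export
unbinding_rate <- function(k_off0, f_unb, f) {
  if (any(f < 0)) stop("load magnitude must be non-negative")
  k_off0 * exp(f / f_unb)
}

#' Linear force-velocity relation of a motor unit
#'
#' `v = vm * (1 + f_par / fs)` clipped to `[0, 2 vm]`: antagonistic load
#' (`f_par < 0`, projection of the spring force on the motion direction)
#' slows the motor linearly to stall at `-fs`; assisting load can at most
#' double the speed; super-stall load gives zero rather than reverse
#' stepping.
#'
#' @param vm Unloaded speed (um/s).
#' @param fs Stall force (pN), positive.
#' @param f_par Signed load along the motion direction (pN).
#' @return Speed (um/s).
#' @export
motor_velocity <- function(vm, fs, f_par) {
  stopifnot(fs > 0)
  pmin(pmax(vm * (1 + f_par / fs), 0), 2 * vm)
}

#' Force-biased lattice hopping rates of a diffusive unit
#'
#' Hops between adjacent 8-nm sites at rates
#' `r_pm = (D / a^2) * exp(+- f_par * a / (2 kBT))`, the symmetric-splitting
#' discretization that satisfies detailed balance
#' `r_plus / r_minus = exp(f_par * a / kBT)` exactly and reproduces the
#' Einstein drift `D * f_par / kBT` at small force.
#'
#' @param D Lattice diffusion coefficient (um^2/s).
#' @param f_par Signed load along the plus direction (pN).
#' @param kBT Thermal energy (pN um).
#' @param a Lattice spacing (um).
#' @return Named vector `c(toward_plus =, toward_minus =)` (1/s).
#' @export
diffusive_hop_rates <- function(D, f_par, kBT, a = 0.008) {
  stopifnot(D >= 0, kBT > 0)
  r0 <- D / a^2
  c(toward_plus = r0 * exp(f_par * a / (2 * kBT)),
    toward_minus = r0 * exp(-f_par * a / (2 * kBT)))
}

#' Hookean link force with non-zero rest length
#'
#' Force on unit a at `pos_a` from the spring to unit b at `pos_b`:
#' `f_a = k * (1 - e / |u|) * u` with `u = minimum_image(pos_b - pos_a)`.
#' Attractive for `|u| > e`, repulsive for `|u| < e`; the force on b is the
#' exact negation. The joint rotates freely: no torque constraint. The
#' measure-zero degenerate case `|u| = 0` with `e > 0` returns zero force.
#'
#' @param pos_a,pos_b Length-3 positions (um).
#' @param k Stiffness (pN/um).
#' @param e Rest length (um).
#' @param box A [simulation_box()] for the minimum-image displacement, or
#'   `NULL` for open space.
#' @return Length-3 force on unit a (pN).
#' @export
link_force <- function(pos_a, pos_b, k, e, box = NULL) {
  u <- pos_b - pos_a
  if (!is.null(box)) u <- minimum_image(u, box)
  nu <- sqrt(sum(u^2))
  if (nu == 0) {
    if (e > 0) return(c(0, 0, 0))
    return(c(0, 0, 0))
  }
  k * (1 - e / nu) * u
}

#' End policy decision for a unit at a filament end
#'
#' @param unit A [unit_spec()].
#' @return `"release"` (unbind instantly) or `"hold"` (stay at the end; motor
#'   stepping past the end is suppressed and diffusive hops off the end are
#'   rejected).
#' @export
apply_end_policy <- function(unit) {
  stopifnot(inherits(unit, "unit_spec"))
  unit$end_policy
}

#' Kinetic Monte Carlo of single-unit engagement episodes
#'
#' Simulates independent bind-to-unbind episodes of one unit at a fixed load,
#' with competing exponential clocks for movement events (motor steps at rate
#' `v(f)/a`; diffusive hops at the two rates of [diffusive_hop_rates()]) and
#' unbinding at the Bell rate. For each episode the dwell time is the
#' (exponential) waiting time of the unbinding clock and the step count is
#' the number of movement events won before it fires (geometric with success
#' probability `k_off / (k_off + k_move)`), sampled exactly.
#'
#' @param unit A [unit_spec()].
#' @param n_episodes Number of independent episodes.
#' @param f_par Signed load along the motion direction (pN); its magnitude
#'   enters the unbinding rate.
#' @param kBT Thermal energy (pN um), used for diffusive hop rates.
#' @param a Lattice spacing (um).
#' @return List with numeric vectors `dwell` (s) and `steps` (signed net
#'   displacement in steps for diffusive units, step count for motors).
#' @export
simulate_unit_dwell <- function(unit, n_episodes = 10000, f_par = 0,
                                kBT = 4.23e-3, a = 0.008) {
  stopifnot(inherits(unit, "unit_spec"), n_episodes >= 1)
  k_off <- unbinding_rate(unit$k_off0, unit$f_unb, abs(f_par))
  if (k_off <= 0) stop("unit never unbinds at this load (k_off0 = 0)")
  dwell <- stats::rexp(n_episodes, rate = k_off)
  if (unit$kind == "motor") {
    v <- motor_velocity(unit$vm, unit$fs, f_par)
    k_move <- v / a
    steps <- if (k_move > 0) {
      stats::rgeom(n_episodes, prob = k_off / (k_off + k_move))
    } else {
      rep(0, n_episodes)
    }
  } else {
    r <- diffusive_hop_rates(unit$D, f_par, kBT, a)
    k_move <- sum(r)
    if (k_move > 0) {
      n_hops <- stats::rgeom(n_episodes, prob = k_off / (k_off + k_move))
      steps <- stats::rbinom(n_episodes, n_hops, r[1] / k_move) * 2 - n_hops
    } else {
      steps <- rep(0, n_episodes)
    }
  }
  list(dwell = dwell, steps = steps)
}
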