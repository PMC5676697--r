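#' Integrator parameters
#'
#' Parameters of the Langevin velocity-Verlet (BAOAB) integrator.  The
#' equation of motion per bead is
#' \deqn{m \ddot r = -\gamma \dot r - \nabla U + \xi(t),}
#' with unit mass, friction \eqn{\gamma} and Gaussian noise satisfying the
#' fluctuation-dissipation relation
#' \eqn{\langle\xi\xi'\rangle = 2\gamma k_B T_L \delta(t - t')}.  With
#' \eqn{\gamma = 1} and \eqn{T_L = 1} one LJ time unit equals one Brownian
#' time \eqn{\tau_{Br} = \sigma^2\gamma/k_B T_L}, so all times are quoted in
#' \eqn{\tau_{Br}}.  The default timestep \eqn{dt = 0.01} is stable for the
#' stiffest term of the force field (bond \eqn{\kappa = 100}).
#'
#' @param dt Timestep (LJ time units); must satisfy `dt <= 0.012`.
#' @param gamma Friction coefficient.
#' @param T_L Thermostat temperature.
#' @param seed Integer seed for the engine's thermal-noise stream (the
#'   recolouring stream is decorrelated automatically).
#' @return An object of class `integrator_params`.
#' @export
integrator_params <- function(dt = 0.01, gamma = 1, T_L = 1, seed = 1L) {
  stopifnot(dt > 0, dt <= 0.012, gamma >= 0, T_L > 0)
  structure(list(dt = dt, gamma = gamma, T_L = T_L, seed = as.integer(seed)),
            class = "integrator_params")
}

#' Terminal stretching protocol
#'
#' The two terminal macro-beads are pulled apart with force \eqn{\pm f}
#' along a fixed axis (a force-clamp tweezer ensemble; no positional
#' tethering).  Net external force is zero.
#'
#' @param force_magnitude Force \eqn{f} in \eqn{k_B T_L/\sigma}.
#' @param axis Pulling direction (normalised internally).
#' @param attraction_on_time Time at which colour attractions activate (the
#'   "flooding" with reader/writer proteins); time 0 by convention.
#' @return An object of class `stretch_protocol`.
#' @export
stretch_protocol <- function(force_magnitude = 0, axis = c(0, 0, 1),
                             attraction_on_time = 0) {
  stopifnot(length(axis) == 3, sum(axis^2) > 0, force_magnitude >= 0)
  structure(list(force_magnitude = force_magnitude,
                 axis = axis / sqrt(sum(axis^2)),
                 attraction_on_time = attraction_on_time),
            class = "stretch_protocol")
}

#' Run Langevin dynamics
#'
#' Advances the chain by `nsteps` timesteps of BAOAB Langevin dynamics under
#' the conservative force field, friction, thermal noise and the terminal
#' stretching forces, optionally interleaved with Metropolis recolouring
#' sweeps (one sweep of L single-bead attempts every \eqn{\tau_R} of
#' simulated time).
#'
#' @param state A [chain_state()].
#' @param ff A [forcefield_params()].
#' @param ip An [integrator_params()].
#' @param sp A [stretch_protocol()] or `NULL` (no external force).
#' @param nsteps Number of timesteps.
#' @param save_every Record a trajectory frame every this many steps.
#' @param recolour A [recolour_params()] or `NULL` (recolouring off).
#' @param attract_on If `FALSE`, colour attractions are disabled (all pair
#'   cutoffs \eqn{2^{1/6}\sigma}).
#' @param pairs_on,bonds_on Interaction switches (see [total_energy()]).
#' @return A list with the advanced `state`, and a `trajectory` object of
#'   class `chrom_trajectory` holding `times`, a positions array
#'   (n x 3 x frames), a colour matrix (frames x n), bead metadata, and
#'   recolouring acceptance counts.
#' @export
run_dynamics <- function(state, ff = forcefield_params(),
                         ip = integrator_params(), sp = NULL,
                         nsteps = 1000L, save_every = nsteps,
                         recolour = NULL, attract_on = TRUE,
                         pairs_on = TRUE, bonds_on = TRUE) {
  stopifnot(nsteps >= 1, save_every >= 1)
  f <- if (is.null(sp)) 0 else sp$force_magnitude
  ax <- if (is.null(sp)) c(0, 0, 1) else sp$axis
  recolour_on <- !is.null(recolour)
  tauR_steps <- if (recolour_on) max(1L, as.integer(round(recolour$tau_R / ip$dt))) else 0L
  TR <- if (recolour_on) recolour$T_R else 1
  res <- cpp_run_dynamics(state$positions, state$velocities, state$colours,
                          state$bead_diameter, end_flags(state), unclass(ff),
                          attract_on, pairs_on, bonds_on, f, ax, ip$dt,
                          ip$gamma, ip$T_L, as.integer(nsteps),
                          as.integer(save_every), tauR_steps, recolour_on,
                          TR, ip$seed, state$time)
  new_state <- chain_state(res$positions, res$colours, res$velocities,
                           state$bead_diameter, state$end_beads,
                           time = res$time)
  traj <- structure(list(
    times = res$times,
    positions = res$trajectory,
    colours = res$kymograph,
    bead_diameter = state$bead_diameter,
    end_beads = state$end_beads,
    recolour_attempts = res$recolour_attempts,
    recolour_accepts = res$recolour_accepts
  ), class = "chrom_trajectory")
  list(state = new_state, trajectory = traj)
}

#' @export
print.chrom_trajectory <- function(x, ...) {
  cat(sprintf("chrom_trajectory: %d frames x %d beads, t in [%g, %g] tau_Br\n",
              length(x$times), dim(x$positions)[1],
              min(x$times), max(x$times)))
  invisible(x)
}

#' Advance the chain by a single timestep
#'
#' Thin wrapper around [run_dynamics()] for one BAOAB step.
#'
#' @inheritParams run_dynamics
#' @return The advanced [chain_state()].
#' @export
step <- function(state, ff = forcefield_params(), ip = integrator_params(),
                 sp = NULL, attract_on = TRUE) {
  run_dynamics(state, ff, ip, sp, nsteps = 1L, save_every = 1L,
               attract_on = attract_on)$state
}

#' Pre-flooding equilibration with purely repulsive interactions
#'
#' Equilibrates the chain under the stretching force in an athermal (good)
#' solvent: every pair cutoff is lowered to \eqn{2^{1/6}\sigma} so that all
#' bead-bead interactions are purely repulsive, and recolouring is disabled.
#' This is the protocol phase before the system is flooded with reader/writer
#' proteins at t = 0.
#'
#' @inheritParams run_dynamics
#' @param duration Equilibration time in \eqn{\tau_{Br}}.
#' @return The equilibrated [chain_state()] (with `time` reset so that
#'   production starts at 0).
#' @export
equilibrate_repulsive <- function(state, ff = forcefield_params(),
                                  ip = integrator_params(), sp = NULL,
                                  duration = 100) {
  stopifnot(duration > 0)
  nsteps <- max(1L, as.integer(round(duration / ip$dt)))
  out <- run_dynamics(state, ff, ip, sp, nsteps = nsteps,
                      save_every = nsteps, attract_on = FALSE)$state
  out$time <- 0
  out
}

#' Map simulation units to physical units
#'
#' The Brownian time of a bead of diameter \eqn{\sigma} in a solvent of
#' viscosity \eqn{\eta} follows from the Einstein relation
#' \eqn{D_{self} = k_B T / 3\pi\eta\sigma}:
#' \deqn{\tau_{Br} = \frac{\sigma^2}{D_{self}} =
#'       \frac{3\pi\eta\sigma^3}{k_B T}.}
#' With \eqn{\sigma = 30} nm and an effective viscosity of 150 cP at room
#' temperature this gives \eqn{\tau_{Br} \simeq 0.01} s.  Each bead
#' coarse-grains about 3 kb of chromatin at the reference bead size.
#'
#' @param sigma_nm Bead diameter in nanometres.
#' @param eta_cP Solvent viscosity in centipoise.
#' @param T_kelvin Temperature in kelvin.
#' @return List with `tau_br_seconds`, `sigma_bp` (base pairs per bead,
#'   scaled linearly from 3 kb at 30 nm) and `tau_r_seconds`
#'   (the recolouring interval \eqn{10^3 \tau_{Br}}).
#' @examples
#' map_units(30, 150, 300)$tau_br_seconds  # ~0.0092 s
#' @export
map_units <- function(sigma_nm = 30, eta_cP = 150, T_kelvin = 300) {
  stopifnot(sigma_nm > 0, eta_cP > 0, T_kelvin > 0)
  kB <- 1.380649e-23
  sigma <- sigma_nm * 1e-9
  eta <- eta_cP * 1e-3
  tau_br <- 3 * pi * eta * sigma^3 / (kB * T_kelvin)
  list(tau_br_seconds = tau_br,
       sigma_bp = 3000 * sigma_nm / 30,
       tau_r_seconds = 1e3 * tau_br)
}
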