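#' Recolouring (writer-activity) parameters
#'
#' The epigenetic read-write dynamics is a Metropolis Monte Carlo process
#' interleaved with the 3D motion: every \eqn{\tau_R} of simulated time each
#' polymer bead is, on average, attempted once to change colour (L uniformly
#' random single-bead attempts are batched into one sweep).  The attempt is
#' accepted with probability \eqn{\min(1, \exp(-\Delta U / k_B T_R))}, where
#' \eqn{\Delta U} involves only the colour-dependent pair terms of the
#' selected bead.
#'
#' @param T_R Recolouring temperature; equal to the solution temperature
#'   \eqn{T_L} by default, which makes the coupled dynamics obey detailed
#'   balance.
#' @param tau_R Recolouring interval in \eqn{\tau_{Br}}; default
#'   \eqn{10^3 \tau_{Br}} (about 10 s in physical units).
#' @param enabled_from Time from which recolouring is active (the flooding
#'   time, 0).
#' @return An object of class `recolour_params`.
#' @export
recolour_params <- function(T_R = 1, tau_R = 1000, enabled_from = 0) {
  stopifnot(T_R > 0, tau_R > 0)
  structure(list(T_R = T_R, tau_R = tau_R, enabled_from = enabled_from),
            class = "recolour_params")
}

#' Propose a new colour
#'
#' Symmetric proposal: the colour is changed into one of the two remaining
#' colours, each with probability 1/2.  Uses R's RNG (seed with
#' [set.seed()]).
#'
#' @param current Current colour code (scalar).
#' @return A colour code different from `current`.
#' @export
propose_colour <- function(current) {
  others <- setdiff(0:2, as.integer(current))
  others[sample.int(2L, 1L)]
}

#' Energy change of a recolouring move
#'
#' \eqn{\Delta U = \sum_b U_{LJ}^{ab}} difference between the proposed and
#' current colour of bead `bead`, summed over all pair interactions of that
#' bead (bond and bending terms are colour-independent and cancel exactly).
#'
#' @param state A [chain_state()].
#' @param bead Polymer bead index (end beads are rejected).
#' @param new_colour Proposed colour code.
#' @param ff A [forcefield_params()].
#' @return Energy difference in \eqn{k_B T_L}.
#' @export
recolour_delta_energy <- function(state, bead, new_colour,
                                  ff = forcefield_params()) {
  if (bead %in% state$end_beads)
    stop("end beads carry no epigenetic state and cannot be recoloured")
  stopifnot(bead >= 1, bead <= nrow(state$positions), new_colour %in% 0:2)
  cpp_recolour_delta(state$positions, state$colours, state$bead_diameter,
                     end_flags(state), unclass(ff), TRUE,
                     as.integer(bead), as.integer(new_colour))
}

#' Single Metropolis recolouring attempt
#'
#' Proposes a colour via [propose_colour()] and accepts with probability
#' \eqn{\min(1, \exp(-\Delta U/k_B T_R))}.  Positions are never altered.
#'
#' @inheritParams recolour_delta_energy
#' @param rp A [recolour_params()].
#' @return List with the (possibly updated) `state`, the `accepted` flag,
#'   the `proposed` colour and `dU`.
#' @export
recolour_attempt <- function(state, bead, ff = forcefield_params(),
                             rp = recolour_params()) {
  prop <- propose_colour(state$colours[bead])
  dU <- recolour_delta_energy(state, bead, prop, ff)
  accepted <- dU <= 0 || runif(1) < exp(-dU / rp$T_R)
  if (accepted) state$colours[bead] <- prop
  list(state = state, accepted = accepted, proposed = prop, dU = dU)
}

#' One recolouring sweep
#'
#' Performs L single-bead attempts (L = number of polymer beads) on beads
#' drawn uniformly with replacement, matching the average attempt rate of one
#' per bead per \eqn{\tau_R}.  A no-op before `rp$enabled_from` (protein
#' flooding).
#'
#' @inheritParams recolour_attempt
#' @return List with the updated `state` and the number of `accepted` moves.
#' @export
recolour_sweep <- function(state, ff = forcefield_params(),
                           rp = recolour_params()) {
  if (state$time < rp$enabled_from)
    return(list(state = state, accepted = 0L))
  poly <- polymer_beads(state)
  acc <- 0L
  for (bead in poly[sample.int(length(poly), length(poly), replace = TRUE)]) {
    res <- recolour_attempt(state, bead, ff, rp)
    state <- res$state
    acc <- acc + res$accepted
  }
  list(state = state, accepted = acc)
}

#' Recolouring-only run at frozen positions
#'
#' Runs the Metropolis colour dynamics with the 3D configuration frozen,
#' using the compiled engine (the same acceptance rule as the coupled
#' dynamics).  Useful for equilibrium checks against exact Boltzmann
#' enumeration on small systems.
#'
#' @inheritParams recolour_attempt
#' @param nsweeps Number of sweeps.
#' @param record_every Record the colour state every this many sweeps.
#' @param seed Engine RNG seed.
#' @return Integer matrix (records x n) of colour codes.
#' @export
recolour_run_frozen <- function(state, ff = forcefield_params(),
                                rp = recolour_params(), nsweeps = 1000L,
                                record_every = 1L, seed = 1L) {
  cpp_recolour_run(state$positions, state$colours, state$bead_diameter,
                   end_flags(state), unclass(ff), TRUE, rp$T_R,
                   as.integer(nsweeps), as.integer(record_every),
                   as.integer(seed))
}
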