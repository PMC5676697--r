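#' Colour codes for epigenetic marks
#'
#' Each chromatin bead carries one of three colours representing its epigenetic
#' state: `COL_UNMARKED` (0, grey, no mark), `COL_RED` (1, e.g. an excess of
#' H3K27me3) and `COL_BLUE` (2, e.g. an excess of H3K9me3).  The colour enters
#' the model in two places: the pair potential becomes attractive only between
#' like-coloured, non-grey beads (reader-protein bridging), and the Metropolis
#' recolouring moves flip colours at a fixed attempt rate (writer activity).
#'
#' @format Integer scalars 0, 1 and 2.
#' @export
COL_UNMARKED <- 0L

#' @rdname COL_UNMARKED
#' @export
COL_RED <- 1L

#' @rdname COL_UNMARKED
#' @export
COL_BLUE <- 2L

# cutoffs of the two interaction channels (in units of sigma)
CUTOFF_SAME <- 1.8
CUTOFF_WCA <- 2^(1 / 6)

#' Force-field parameters of the recolourable chromatin model
#'
#' Collects every interaction parameter of the bead-spring model.  All
#' energies are in units of \eqn{k_B T_L}, lengths in units of the bead size
#' \eqn{\sigma}.  Defaults follow the standard parametrisation of this model
#' family: harmonic bonds with \eqn{\kappa = 100\,k_B T_L/\sigma^2} and rest
#' length \eqn{x_0 = 1.1\sigma}, a Kratky-Porod bending term with persistence
#' length \eqn{l_p = 3\sigma}, and a truncated-and-shifted Lennard-Jones pair
#' potential whose cutoff depends on the colours of the interacting beads:
#' \eqn{1.8\sigma} for equal non-grey colours (attractive branch present) and
#' \eqn{2^{1/6}\sigma} (purely repulsive WCA) otherwise.
#'
#' The normalisation \eqn{\mathcal{N}} of the pair potential is chosen per
#' channel so that the attractive like-colour channel has well depth exactly
#' \eqn{-\varepsilon}: \eqn{\mathcal{N} = 4\,|\mathrm{min}|} of the
#' unnormalised bracket.  The WCA channel, whose minimum is zero, uses
#' \eqn{\mathcal{N} = 1}, i.e. the conventional WCA form with energy scale
#' \eqn{1\,k_B T_L}.
#'
#' @param epsilon Like-colour binding affinity \eqn{\varepsilon}
#'   (\eqn{k_B T_L}); the free parameter of the model.
#' @param T_L Solution temperature regulating the 3D Langevin dynamics
#'   (LJ units; default 1).
#' @param bond_k Harmonic bond stiffness \eqn{\kappa}
#'   (\eqn{k_B T_L/\sigma^2}).
#' @param bond_x0 Bond rest length (\eqn{\sigma}).
#' @param persistence_lp Persistence length \eqn{l_p} of the bending term
#'   (\eqn{\sigma}).
#' @param gamma Friction coefficient of the Langevin thermostat (LJ units).
#' @return An object of class `ff_params`.
#' @examples
#' p <- forcefield_params(epsilon = 2)
#' pair_cutoff(COL_RED, COL_RED, p)   # 1.8
#' pair_cutoff(COL_RED, COL_BLUE, p)  # 2^(1/6)
#' @export
forcefield_params <- function(epsilon = 1, T_L = 1, bond_k = 100,
                              bond_x0 = 1.1, persistence_lp = 3, gamma = 1) {
  stopifnot(epsilon >= 0, T_L > 0, bond_k >= 0, bond_x0 > 0,
            persistence_lp >= 0, gamma >= 0)
  S_same <- CUTOFF_SAME^-12 - CUTOFF_SAME^-6
  p <- list(
    epsilon = epsilon,
    epsilon_cross = 1,
    cutoff_same = CUTOFF_SAME,
    cutoff_cross = CUTOFF_WCA,
    bond_k = bond_k,
    bond_x0 = bond_x0,
    persistence_lp = persistence_lp,
    gamma = gamma,
    T_L = T_L,
    # per-channel normalisation: depth of the attractive channel is -epsilon
    norm_same = 4 * (0.25 + S_same),
    norm_cross = 1
  )
  class(p) <- "ff_params"
  p
}

#' @export
print.ff_params <- function(x, ...) {
  cat("Force field (recolourable chromatin model)\n")
  cat(sprintf("  epsilon (like-colour affinity): %g k_B T_L\n", x$epsilon))
  cat(sprintf("  cutoffs: same %g sigma, cross/grey %g sigma\n",
              x$cutoff_same, x$cutoff_cross))
  cat(sprintf("  bonds: kappa = %g, x0 = %g; bending l_p = %g sigma\n",
              x$bond_k, x$bond_x0, x$persistence_lp))
  cat(sprintf("  T_L = %g, gamma = %g\n", x$T_L, x$gamma))
  invisible(x)
}

#' Colour-dependent pair cutoff
#'
#' Returns the interaction cutoff between two beads given their colours:
#' \eqn{1.8\sigma} if the colours are equal and non-grey, otherwise
#' \eqn{2^{1/6}\sigma}.
#'
#' @param qa,qb Integer colour codes (vectors recycle).
#' @param p A [forcefield_params()] object.
#' @return Cutoff distance(s) in \eqn{\sigma}.
#' @export
pair_cutoff <- function(qa, qb, p = forcefield_params()) {
  ifelse(qa == qb & qa != COL_UNMARKED, p$cutoff_same, p$cutoff_cross)
}

#' Colour-dependent pair potential
#'
#' The truncated-and-shifted Lennard-Jones potential between two beads at
#' centre distance `x` with colours `qa`, `qb`:
#' \deqn{U(x) = \frac{4\epsilon_{ab}}{\mathcal{N}}\left[
#'   \left(\frac{\sigma}{x}\right)^{12} - \left(\frac{\sigma}{x}\right)^{6}
#'   - \left(\frac{\sigma}{x_c}\right)^{12}
#'   + \left(\frac{\sigma}{x_c}\right)^{6}\right]}
#' for \eqn{x \le x_c}, and exactly zero beyond.  The shift makes the
#' potential continuous at the cutoff.  \eqn{\epsilon_{ab} = \varepsilon} for
#' equal non-grey colours and \eqn{1\,k_B T_L} otherwise.
#'
#' @inheritParams pair_cutoff
#' @param x Centre-centre distance(s) in \eqn{\sigma}; must be positive.
#' @return Energy in \eqn{k_B T_L} (scaled by `p$T_L`).
#' @export
pair_potential <- function(x, qa, qb, p = forcefield_params()) {
  if (any(x <= 0)) stop("pair distance must be positive (invalid geometry)")
  same <- qa == qb & qa != COL_UNMARKED
  xc <- ifelse(same, p$cutoff_same, p$cutoff_cross)
  eps <- ifelse(same, p$epsilon, p$epsilon_cross)
  nrm <- ifelse(same, p$norm_same, p$norm_cross)
  S <- xc^-12 - xc^-6
  u <- p$T_L * (4 * eps / nrm) * (x^-12 - x^-6 - S)
  ifelse(x <= xc, u, 0)
}

#' Harmonic bond potential
#'
#' \eqn{U_H(x) = \kappa k_B T_L (x - x_0)^2 / 2}, applied between
#' nearest-neighbour beads along the backbone.
#'
#' @param x Bond length(s) in \eqn{\sigma}.
#' @param p A [forcefield_params()] object.
#' @return Energy in \eqn{k_B T_L}.
#' @export
bond_potential <- function(x, p = forcefield_params()) {
  stopifnot(all(x >= 0))
  0.5 * p$bond_k * p$T_L * (x - p$bond_x0)^2
}

#' Kratky-Porod bending potential
#'
#' Bending energy of a triplet of consecutive beads with tangent vectors
#' \eqn{t_1, t_2} forming angle \eqn{\theta}
#' (\eqn{\cos\theta = t_1 \cdot t_2 / |t_1||t_2|}):
#' \deqn{U_{KP} = k_B T_L \frac{l_p}{\sigma} (1 - \cos\theta).}
#' The convention is fixed so a straight chain (\eqn{\cos\theta = 1}) has zero
#' bending energy, the physically meaningful minimum for a stiffness term with
#' persistence length \eqn{l_p}; a hairpin costs \eqn{2 l_p/\sigma}.
#'
#' @param theta_cos Cosine(s) of the tangent-tangent angle, in \eqn{[-1, 1]}.
#' @param p A [forcefield_params()] object.
#' @return Energy in \eqn{k_B T_L}.
#' @export
bending_potential <- function(theta_cos, p = forcefield_params()) {
  if (any(abs(theta_cos) > 1 + 1e-8))
    stop("|cos(theta)| > 1: invalid tangent vectors")
  theta_cos <- pmin(1, pmax(-1, theta_cos))
  p$T_L * p$persistence_lp * (1 - theta_cos)
}

#' Chain state of the recolourable polymer
#'
#' The complete dynamical state: bead positions, velocities, colours, per-bead
#' diameters and the indices of the two terminal macroscopic beads (the
#' tweezer handles, diameter \eqn{5\sigma}, unit mass, always unmarked and
#' never recoloured).
#'
#' @param positions Numeric matrix (n x 3) of bead positions in \eqn{\sigma}.
#' @param colours Integer vector of colour codes (length n); defaults to all
#'   unmarked.
#' @param velocities Numeric matrix (n x 3); defaults to zero.
#' @param bead_diameter Per-bead diameter in \eqn{\sigma}; defaults to 1 for
#'   polymer beads and 5 for end beads.
#' @param end_beads Integer vector (usually length 2) of terminal macro-bead
#'   indices; may be empty for bare chains or free-bead ensembles.
#' @param time Simulation time in \eqn{\tau_{Br}}.
#' @return An object of class `chain_state`.
#' @seealso [build_open_chain()], [run_dynamics()]
#' @export
chain_state <- function(positions, colours = NULL, velocities = NULL,
                        bead_diameter = NULL, end_beads = integer(0),
                        time = 0) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) >= 1)
  n <- nrow(positions)
  if (is.null(colours)) colours <- rep(COL_UNMARKED, n)
  colours <- as.integer(colours)
  stopifnot(length(colours) == n, all(colours %in% 0:2))
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  velocities <- as.matrix(velocities)
  stopifnot(all(dim(velocities) == c(n, 3)))
  if (is.null(bead_diameter)) {
    bead_diameter <- rep(1, n)
    bead_diameter[end_beads] <- 5
  }
  stopifnot(length(bead_diameter) == n, all(bead_diameter > 0))
  end_beads <- as.integer(end_beads)
  stopifnot(all(end_beads >= 1 & end_beads <= n))
  if (any(colours[end_beads] != COL_UNMARKED))
    stop("end beads must be unmarked")
  s <- list(positions = positions, velocities = velocities,
            colours = colours, bead_diameter = bead_diameter,
            end_beads = end_beads, time = time)
  class(s) <- "chain_state"
  s
}

#' @export
print.chain_state <- function(x, ...) {
  np <- length(polymer_beads(x))
  cat(sprintf(
    "chain_state: %d beads (%d polymer + %d end), t = %g tau_Br\n",
    nrow(x$positions), np, length(x$end_beads), x$time))
  tab <- table(factor(x$colours[polymer_beads(x)], levels = 0:2,
                      labels = c("grey", "red", "blue")))
  cat("  colours:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Indices of polymer (non-end) beads
#'
#' @param state A [chain_state()].
#' @return Integer vector of bead indices excluding the terminal macro-beads.
#' @export
polymer_beads <- function(state) {
  setdiff(seq_len(nrow(state$positions)), state$end_beads)
}

# logical end-bead flag vector, and 0/1 integer version for the C++ engine
end_flags <- function(state) {
  f <- integer(nrow(state$positions))
  f[state$end_beads] <- 1L
  f
}

#' Total potential energy of a chain state
#'
#' Sum of all pair (colour-resolved LJ/WCA), bond and bending contributions;
#' each unordered pair counted once, bonded neighbours still feel the pair
#' potential.  End beads interact through the repulsive channel with the
#' radial shift of additive-radius mixing.
#'
#' @param state A [chain_state()].
#' @param p A [forcefield_params()].
#' @param attract_on If `FALSE`, all pair cutoffs are forced to
#'   \eqn{2^{1/6}\sigma} (the colour-blind, purely repulsive pre-flooding
#'   condition).
#' @param pairs_on,bonds_on Include pair / bond+bending terms (disabled for
#'   free-bead ensembles).
#' @return Energy in \eqn{k_B T_L}.
#' @export
total_energy <- function(state, p = forcefield_params(), attract_on = TRUE,
                         pairs_on = TRUE, bonds_on = TRUE) {
  u <- cpp_total_energy(state$positions, state$colours, state$bead_diameter,
                        end_flags(state), unclass(p), attract_on, pairs_on,
                        bonds_on)
  if (!is.finite(u)) stop("total energy overflow (overlapping beads?)")
  u
}

#' Forces on all beads
#'
#' Analytic gradient \eqn{-\nabla U} of [total_energy()], plus the optional
#' terminal stretching forces \eqn{\pm f} applied along `stretch$axis` to the
#' two end beads.
#'
#' @inheritParams total_energy
#' @param stretch Optional [stretch_protocol()]; `NULL` means no external
#'   force.
#' @return Numeric matrix (n x 3) of forces in \eqn{k_B T_L/\sigma}.
#' @export
forces <- function(state, p = forcefield_params(), stretch = NULL,
                   attract_on = TRUE, pairs_on = TRUE, bonds_on = TRUE) {
  f <- if (is.null(stretch)) 0 else stretch$force_magnitude
  ax <- if (is.null(stretch)) c(0, 0, 1) else stretch$axis
  cpp_forces(state$positions, state$colours, state$bead_diameter,
             end_flags(state), unclass(p), attract_on, pairs_on, bonds_on,
             f, ax)
}
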