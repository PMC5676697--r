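#' Epigenetic magnetisation
#'
#' Global order parameter of mark coherence:
#' \eqn{m = |n_{red} - n_{blue}| / L} over the polymer beads.
#'
#' @param colours Integer colour vector (polymer beads only).
#' @return Value in \eqn{[0, 1]}.
#' @export
magnetisation <- function(colours) {
  abs(signed_magnetisation(colours))
}

#' Signed epigenetic magnetisation
#'
#' \eqn{\tilde m = (n_{red} - n_{blue}) / L}; red counts positive.
#'
#' @inheritParams magnetisation
#' @return Value in \eqn{[-1, 1]}.
#' @export
signed_magnetisation <- function(colours) {
  stopifnot(length(colours) >= 1)
  (sum(colours == COL_RED) - sum(colours == COL_BLUE)) / length(colours)
}

#' Radius of gyration
#'
#' \eqn{R_g = [\frac{1}{L}\sum_i (r_i - r_{CM})^2]^{1/2}} over the polymer
#' beads (unweighted).
#'
#' @param positions Numeric matrix (L x 3).
#' @return Length in \eqn{\sigma}.
#' @export
radius_of_gyration <- function(positions) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) >= 1)
  cm <- colMeans(positions)
  sqrt(mean(rowSums(sweep(positions, 2, cm)^2)))
}

#' Per-frame observables of a trajectory
#'
#' Computes the magnetisation and radius of gyration (polymer beads only)
#' for every saved frame.
#'
#' @param traj A `chrom_trajectory` from [run_dynamics()].
#' @return Data frame with columns `time`, `m`, `m_signed`, `rg`.
#' @export
trajectory_observables <- function(traj) {
  poly <- setdiff(seq_len(dim(traj$positions)[1]), traj$end_beads)
  nf <- length(traj$times)
  m <- ms <- rg <- numeric(nf)
  for (i in seq_len(nf)) {
    cols <- traj$colours[i, poly]
    ms[i] <- signed_magnetisation(cols)
    m[i] <- abs(ms[i])
    rg[i] <- radius_of_gyration(traj$positions[poly, , i])
  }
  data.frame(time = traj$times, m = m, m_signed = ms, rg = rg)
}

#' Steady-state averages of a trajectory
#'
#' Time-averages \eqn{\langle m\rangle} and
#' \eqn{\langle R_g\rangle \equiv \langle R_g^2\rangle^{1/2}} over the final
#' fraction of frames (the steady-state / out-of-equilibrium averaging
#' window).
#'
#' @inheritParams trajectory_observables
#' @param window Final fraction of frames to average over (default 0.2).
#' @return List with `mean_m`, `sd_m`, `mean_rg`, `sd_rg`, `n_frames`.
#' @export
steady_state_averages <- function(traj, window = 0.2) {
  obs <- trajectory_observables(traj)
  nf <- nrow(obs)
  keep <- obs[seq.int(max(1, ceiling(nf * (1 - window))), nf), ]
  if (nrow(keep) < 2)
    warning("fewer than 2 steady-state frames; averages are unreliable")
  list(mean_m = mean(keep$m), sd_m = sd(keep$m),
       mean_rg = sqrt(mean(keep$rg^2)), sd_rg = sd(keep$rg),
       n_frames = nrow(keep))
}

#' Classify the phase of a simulated state point
#'
#' Labels a parameter point as compact-ordered (`"CO"`:
#' \eqn{\langle m\rangle} large, \eqn{\langle R_g\rangle} on the globular
#' \eqn{L^{1/3}} scale), stretched-disordered (`"SD"`:
#' \eqn{\langle m\rangle \simeq 0}, \eqn{\langle R_g\rangle} on the extended
#' \eqn{L} scale), or `"MULTI"` (compact with at least two opposite-sign
#' near-pure domains).  Thresholds are package conventions; the underlying
#' transition is located by the abrupt concurrent jumps of both observables.
#'
#' @param mean_m,mean_rg Steady-state averages (see
#'   [steady_state_averages()]).
#' @param L Polymer length in beads.
#' @param n_opposite_domains Number of adjacent opposite-sign domain pairs
#'   (from [find_domains()]/[find_boundaries()]); used for the MULTI label.
#' @param m_hi,m_lo Magnetisation thresholds for CO / SD.
#' @param c_globule CO compactness: \eqn{\langle R_g\rangle <
#'   c\,L^{1/3}\sigma}.
#' @param c_extended SD extension: \eqn{\langle R_g\rangle > c' L\sigma}.
#' @return A one-row data frame (class `phase_point`) with the inputs and a
#'   `label` in `{"CO", "SD", "MULTI", "AMBIGUOUS"}`.
#' @export
classify_phase <- function(mean_m, mean_rg, L, n_opposite_domains = 0,
                           m_hi = 0.5, m_lo = 0.2, c_globule = 1.5,
                           c_extended = 0.1) {
  stopifnot(mean_m >= 0, mean_m <= 1, mean_rg > 0, L >= 1)
  compact <- mean_rg < c_globule * L^(1 / 3)
  extended <- mean_rg > c_extended * L
  label <- if (compact && n_opposite_domains >= 1) "MULTI"
    else if (mean_m > m_hi && compact) "CO"
    else if (mean_m < m_lo && extended) "SD"
    else "AMBIGUOUS"
  out <- data.frame(mean_m = mean_m, mean_rg = mean_rg, L = L,
                    label = label, stringsAsFactors = FALSE)
  class(out) <- c("phase_point", class(out))
  out
}

#' Kymograph: per-bead colour versus time
#'
#' Assembles the (frames x L) matrix of polymer-bead colours from a
#' trajectory; the basis for all 1D analyses (domains, boundaries,
#' solitons).
#'
#' @inheritParams trajectory_observables
#' @return Object of class `kymograph`: list with `times` (strictly
#'   increasing) and `colours` (frames x L integer matrix, polymer beads
#'   only).
#' @export
kymograph_from_trajectory <- function(traj) {
  poly <- setdiff(seq_len(dim(traj$positions)[1]), traj$end_beads)
  k <- list(times = traj$times,
            colours = traj$colours[, poly, drop = FALSE])
  class(k) <- "kymograph"
  k
}

#' Construct a kymograph from raw components
#'
#' @param times Frame times (strictly increasing).
#' @param colours Integer matrix (frames x L) of colour codes.
#' @return A `kymograph` object.
#' @export
kymograph <- function(times, colours) {
  colours <- as.matrix(colours)
  stopifnot(length(times) == nrow(colours), all(colours %in% 0:2),
            all(diff(times) > 0))
  structure(list(times = as.numeric(times), colours = colours),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d frames x %d beads, t in [%g, %g]\n",
              nrow(x$colours), ncol(x$colours), min(x$times), max(x$times)))
  invisible(x)
}

#' Write / read a kymograph as TSV
#'
#' Plain-text interchange format: a header row of bead indices, first column
#' `time`, cells are integer colour codes in `{0, 1, 2}`.
#'
#' @param k A [kymograph()].
#' @param path Output file.
#' @export
write_kymograph <- function(k, path) {
  df <- data.frame(time = k$times, k$colours)
  names(df) <- c("time", paste0("bead", seq_len(ncol(k$colours))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (names(df)[1] != "time") stop("not a kymograph TSV: first column must be 'time'")
  kymograph(df[[1]], as.matrix(df[, -1, drop = FALSE]))
}

#' Plot a kymograph
#'
#' Base-graphics image of the colour field: bead index on the y axis, time
#' on the x axis; grey/red/blue cells.
#'
#' @param x A [kymograph()].
#' @param ... Passed to [graphics::image()].
#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(x = x$times, y = seq_len(ncol(x$colours)),
                  z = x$colours, col = c("grey80", "firebrick", "steelblue"),
                  zlim = c(0, 2), xlab = "time [tau_Br]", ylab = "bead", ...)
  invisible(x)
}
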