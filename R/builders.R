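#' Build a straight open chain with terminal macro-beads
#'
#' L polymer beads collinear along the z axis at the given spacing, with two
#' macroscopic end beads (diameter \eqn{5\sigma}) appended beyond the termini
#' at the rest length of the end bond (\eqn{x_0} plus the additive-radius
#' shift \eqn{2\sigma}).  All colours unmarked.
#'
#' @param L Number of polymer beads (>= 3).
#' @param spacing Bond spacing in \eqn{\sigma}.
#' @return A [chain_state()] with `L + 2` beads; `end_beads = c(1, L + 2)`.
#' @export
build_open_chain <- function(L, spacing = 1.1) {
  stopifnot(L >= 3)
  z <- (seq_len(L) - 1) * spacing
  end_rest <- spacing + 2   # x0 + (5 + 1)/2 - 1
  pos <- rbind(c(0, 0, -end_rest),
               cbind(0, 0, z),
               c(0, 0, max(z) + end_rest))
  chain_state(pos, end_beads = c(1L, L + 2L))
}

#' Build a compact (coiled) chain
#'
#' Polymer beads arranged on a boustrophedon path through a cubic lattice of
#' pitch `spacing`, giving a dense, overlap-free globular initial condition
#' (useful for collapsed-chain studies where starting from a stretched
#' configuration would waste a long collapse transient).  End beads are
#' placed outward along the local chain direction.
#'
#' @inheritParams build_open_chain
#' @return A [chain_state()] with `L + 2` beads.
#' @export
build_compact_chain <- function(L, spacing = 1.1) {
  stopifnot(L >= 3)
  m <- max(2, ceiling(L^(1 / 3)))
  pos <- matrix(0, L, 3)
  x <- y <- z <- 0
  dx <- dy <- 1
  for (k in seq_len(L)) {
    pos[k, ] <- c(x, y, z) * spacing
    if (k == L) break
    if (x + dx >= 0 && x + dx < m) {
      x <- x + dx
    } else if (y + dy >= 0 && y + dy < m) {
      y <- y + dy
      dx <- -dx
    } else {
      z <- z + 1
      dy <- -dy
      dx <- -dx
    }
  }
  # the first bead lies in the bottom layer, the last in the top layer, so
  # the +/- z directions above them are free of lattice beads: the macro
  # end beads (contact distance 3 sigma) attach there without overlap
  end_rest <- spacing + 2
  pos_all <- rbind(pos[1, ] - c(0, 0, end_rest),
                   pos,
                   pos[L, ] + c(0, 0, end_rest))
  chain_state(pos_all, end_beads = c(1L, L + 2L))
}

# closed parametric space curves for the supported knot types, sampled at
# npts points; radii chosen so strands keep a comfortable mutual distance
knot_curve <- function(type, npts = 2000) {
  s <- seq(0, 2 * pi, length.out = npts + 1)[- (npts + 1)]
  switch(type,
    "3_1" = cbind((2 + cos(3 * s)) * cos(2 * s),
                  (2 + cos(3 * s)) * sin(2 * s),
                  sin(3 * s)),
    "5_1" = cbind((2 + cos(5 * s)) * cos(2 * s),
                  (2 + cos(5 * s)) * sin(2 * s),
                  sin(5 * s)),
    "4_1" = cbind((2 + cos(2 * s)) * cos(3 * s),
                  (2 + cos(2 * s)) * sin(3 * s),
                  sin(4 * s)),
    stop("unsupported knot type: ", type)
  )
}

# resample a polyline to n points equally spaced in arc length
resample_polyline <- function(pts, n) {
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  tgt <- seq(0, cum[length(cum)], length.out = n)
  out <- matrix(0, n, 3)
  for (k in 1:3) out[, k] <- approx(cum, pts[, k], xout = tgt)$y
  out
}

#' Tie a knot into an open chain
#'
#' Replaces the polymer arc of `extent_beads` beads centred at
#' `centre_fraction` of the chain with an arc-length-resampled parametric
#' knotted curve ((2,3) and (2,5) torus curves for the trefoil and pentafoil,
#' the standard figure-eight space curve for 4_1), rigidly oriented so its
#' chord lies along the stretching axis and scaled so consecutive beads sit
#' about one bond length apart.  Beads outside the arc keep their identities;
#' the downstream flank is translated to meet the arc exit.  Upon closure
#' (see [minimal_knotted_arc()]) the resulting open chain has the requested
#' knot type.
#'
#' @param state A [chain_state()] built by [build_open_chain()].
#' @param type One of `"unknot"` (no-op), `"3_1"`, `"4_1"`, `"5_1"`.
#' @param centre_fraction Centre of the knotted arc as a fraction of the
#'   polymer length.
#' @param extent_beads Number of polymer beads used for the knotted arc
#'   (>= 30 for geometric feasibility).
#' @return The modified [chain_state()].
#' @export
tie_knot <- function(state, type = "3_1", centre_fraction = 0.5,
                     extent_beads = 80L) {
  if (type == "unknot") return(state)
  stopifnot(extent_beads >= 30, centre_fraction > 0, centre_fraction < 1)
  poly <- polymer_beads(state)
  L <- length(poly)
  n_arc <- as.integer(extent_beads)
  ctr <- round(centre_fraction * L)
  a <- ctr - n_arc %/% 2
  b <- a + n_arc - 1
  if (a < 2 || b > L - 1)
    stop("knot extent does not fit within the chain interior")
  spacing <- 1.1

  # open parametric curve: drop a short arc so the endpoints sit on the
  # outermost part of the curve, where the chord leaves the knotted core
  crv <- knot_curve(type, 2000)
  gap <- 60  # points removed around s = 0 (the outer equator)
  crv <- crv[seq(gap + 1, nrow(crv) - gap), ]

  # lead the chain into the knot from outside its body: straight tails grow
  # radially outward from the opening, so the flanks cannot thread a loop
  ctr <- colMeans(crv)
  e1 <- crv[1, ]; e2 <- crv[nrow(crv), ]
  out1 <- (e1 - ctr) / sqrt(sum((e1 - ctr)^2))
  out2 <- (e2 - ctr) / sqrt(sum((e2 - ctr)^2))
  ext <- 1.5
  crv <- rbind(e1 + out1 * ext, crv, e2 + out2 * ext)

  # orient chord along +z, then scale so that n_arc beads at ~spacing cover it
  e1 <- crv[1, ]; e2 <- crv[nrow(crv), ]
  chord <- e2 - e1
  crv <- sweep(crv, 2, e1)
  crv <- rotate_onto_z(crv, chord)
  seg <- sqrt(rowSums(diff(crv)^2))
  lambda <- spacing * (n_arc - 1) / sum(seg)
  crv <- crv * lambda
  arc <- resample_polyline(crv, n_arc)

  bond <- sqrt(rowSums(diff(arc)^2))
  if (any(bond > 1.3 * spacing) || min_self_distance(arc) < 0.8)
    stop("infeasible knot extent: resampled arc violates bond/overlap limits")

  pos <- state$positions
  ia <- poly[a]; ib <- poly[b]
  entry <- pos[ia, ]
  new_arc <- sweep(arc, 2, entry, FUN = "+")
  pos[poly[a:b], ] <- new_arc
  # translate the downstream flank to continue from the arc exit along +z
  exit_pt <- new_arc[n_arc, ]
  down <- c(if (b < L) poly[(b + 1):L] else integer(0),
            state$end_beads[state$end_beads > ib])
  if (length(down) > 0) {
    old_anchor <- state$positions[ib, ]
    shift <- exit_pt - old_anchor
    pos[down, ] <- sweep(state$positions[down, , drop = FALSE], 2, shift,
                         FUN = "+")
  }
  chain_state(pos, state$colours, bead_diameter = state$bead_diameter,
              end_beads = state$end_beads, time = state$time)
}

# rotate points so that vector v maps onto +z
rotate_onto_z <- function(pts, v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  ax <- c(v[2] * z[3] - v[3] * z[2],
          v[3] * z[1] - v[1] * z[3],
          v[1] * z[2] - v[2] * z[1])
  s <- sqrt(sum(ax^2))
  co <- sum(v * z)
  if (s < 1e-12) {
    if (co > 0) return(pts)
    return(pts %*% diag(c(1, -1, -1)))  # v = -z: rotate pi about x
  }
  ax <- ax / s
  K <- matrix(c(0, -ax[3], ax[2],
                ax[3], 0, -ax[1],
                -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + s * K + (1 - co) * (K %*% K)
  t(R %*% t(pts))
}

# minimum distance between non-bonded bead pairs of a polyline
min_self_distance <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(Inf)
  d <- as.matrix(dist(pts))
  d[cbind(1:n, 1:n)] <- Inf
  d[cbind(1:(n - 1), 2:n)] <- Inf
  d[cbind(2:n, 1:(n - 1))] <- Inf
  min(d)
}

#' Deterministic colour-string fixtures
#'
#' Builds colour sequences for unit tests and analysis fixtures: homogeneous
#' blocks, alternating patterns, or seeded uniform-random strings.
#'
#' @param lengths Integer vector of block lengths.
#' @param colours Colour code per block (recycled against `lengths`).
#' @return Integer colour vector of length `sum(lengths)`.
#' @examples
#' make_fixture_colours(c(60, 60), c(COL_RED, COL_BLUE))
#' @export
make_fixture_colours <- function(lengths, colours) {
  stopifnot(length(lengths) >= 1)
  colours <- rep_len(as.integer(colours), length(lengths))
  stopifnot(all(colours %in% 0:2))
  rep(colours, times = lengths)
}

#' @rdname make_fixture_colours
#' @param L String length.
#' @param prob Probabilities of grey/red/blue.
#' @param seed RNG seed (restores the caller's RNG state on exit).
#' @export
make_random_colours <- function(L, prob = c(1, 1, 1) / 3, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample(0:2, L, replace = TRUE, prob = prob)
}
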