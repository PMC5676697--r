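#' Close an open sub-chain into a ring
#'
#' Deterministic outward closure: the two endpoints are joined through a
#' single auxiliary point placed far outside the arc (at 10 times the arc
#' radius along the direction from the arc centroid through the endpoint
#' midpoint), so that the closure path cannot thread the arc.  Degenerate
#' (collinear) arcs are closed endpoint-to-endpoint.
#'
#' @param positions Numeric matrix (m x 3), m >= 5.
#' @param scheme `"axis"` (default): elongated arcs are closed by prolonging
#'   both ends along the end-to-end axis and reconnecting through a far
#'   lateral point, falling back to the radial rule for compact arcs;
#'   `"radial"`: always close through the single outward point.
#' @return Numeric matrix of ring vertices (the closing edges connect the
#'   last row back to the first).
#' @export
close_chain <- function(positions, scheme = c("axis", "radial")) {
  scheme <- match.arg(scheme)
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) >= 5, ncol(positions) == 3)
  ctr <- colMeans(positions)
  e1 <- positions[1, ]; e2 <- positions[nrow(positions), ]
  rad <- max(sqrt(rowSums(sweep(positions, 2, ctr)^2)))
  ee <- e2 - e1
  nee <- sqrt(sum(ee^2))
  if (scheme == "axis" && nee > 0.5 * rad) {
    # elongated arc (the generic stretched-chain case): prolong both ends
    # along the end-to-end axis and reconnect through a far lateral point,
    # so the closure cannot thread the chain body
    u <- ee / nee
    far <- 10 * rad
    A <- e2 + u * far
    B <- e1 - u * far
    perp <- c(-u[2], u[1], 0)
    if (sum(perp^2) < 1e-12) perp <- c(1, 0, 0)
    perp <- perp / sqrt(sum(perp^2))
    M <- (e1 + e2) / 2 + perp * 2 * far
    return(rbind(positions, A, M, B))
  }
  # compact arc (or radial scheme): close through a point far outside along
  # the outward bisector from the centroid through the endpoint midpoint
  mid <- (e1 + e2) / 2
  dir <- mid - ctr
  nd <- sqrt(sum(dir^2))
  if (nd < 1e-9 * max(1, rad)) return(positions)  # degenerate/symmetric arc
  rbind(positions, mid + dir / nd * 10 * rad)
}

# --- KMT chain simplification -----------------------------------------------
# Removes ring vertex i whenever the triangle (i-1, i, i+1) is not pierced by
# any other segment; preserves ring topology, drastically reduces crossing
# counts before invariant computation.  Conservative on degenerate geometry.

# does any of the segments P[k, ] -> Q[k, ] intersect triangle (A, B, C)?
segments_hit_triangle <- function(A, B, C, P, Q) {
  if (nrow(P) == 0) return(FALSE)
  N <- c((B[2] - A[2]) * (C[3] - A[3]) - (B[3] - A[3]) * (C[2] - A[2]),
         (B[3] - A[3]) * (C[1] - A[1]) - (B[1] - A[1]) * (C[3] - A[3]),
         (B[1] - A[1]) * (C[2] - A[2]) - (B[2] - A[2]) * (C[1] - A[1]))
  nn <- sqrt(sum(N^2))
  if (nn < 1e-12) return(TRUE)  # degenerate triangle: be conservative
  N <- N / nn
  dP <- (P[, 1] - A[1]) * N[1] + (P[, 2] - A[2]) * N[2] + (P[, 3] - A[3]) * N[3]
  dQ <- (Q[, 1] - A[1]) * N[1] + (Q[, 2] - A[2]) * N[2] + (Q[, 3] - A[3]) * N[3]
  coplanar <- abs(dP) < 1e-10 & abs(dQ) < 1e-10
  if (any(coplanar)) return(TRUE)
  cand <- which(dP * dQ < 0)
  if (length(cand) == 0) return(FALSE)
  t <- dP[cand] / (dP[cand] - dQ[cand])
  inside_seg <- t > 1e-9 & t < 1 - 1e-9
  cand <- cand[inside_seg]; t <- t[inside_seg]
  if (length(cand) == 0) return(FALSE)
  X <- P[cand, , drop = FALSE] + t * (Q[cand, , drop = FALSE] - P[cand, , drop = FALSE])
  # barycentric coordinates of X in the triangle
  v0 <- C - A; v1 <- B - A
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  inv <- 1 / (d00 * d11 - d01 * d01)
  w0 <- sweep(X, 2, A)
  d02 <- w0 %*% v0; d12 <- w0 %*% v1
  u <- (d11 * d02 - d01 * d12) * inv
  v <- (d00 * d12 - d01 * d02) * inv
  any(u >= -1e-12 & v >= -1e-12 & (u + v) <= 1 + 1e-12)
}

#' Simplify a closed ring by triangle elimination
#'
#' Iteratively deletes any vertex whose flanking triangle is not intersected
#' by the rest of the ring, leaving a topologically equivalent polygon with
#' far fewer vertices.
#'
#' @param ring Numeric matrix (n x 3) of ring vertices.
#' @return Simplified ring matrix (>= 3 vertices).
#' @export
kmt_simplify <- function(ring) {
  ring <- as.matrix(ring)
  repeat {
    n <- nrow(ring)
    if (n <= 4) return(ring)
    removed_any <- FALSE
    i <- 1
    while (i <= nrow(ring) && nrow(ring) > 4) {
      n <- nrow(ring)
      ip <- if (i == 1) n else i - 1
      inx <- if (i == n) 1 else i + 1
      A <- ring[ip, ]; B <- ring[i, ]; C <- ring[inx, ]
      # all segments except the two triangle edges (ip->i, i->inx)
      starts <- seq_len(n)
      ends <- c(2:n, 1)
      keep <- !(starts == ip | starts == i)
      P <- ring[starts[keep], , drop = FALSE]
      Q <- ring[ends[keep], , drop = FALSE]
      if (!segments_hit_triangle(A, B, C, P, Q)) {
        ring <- ring[-i, , drop = FALSE]
        removed_any <- TRUE
      } else {
        i <- i + 1
      }
    }
    if (!removed_any) return(ring)
  }
}

# --- crossing structure and Alexander matrix --------------------------------

# 2D crossing data of a ring projected along z; returns NULL if the
# projection is degenerate (tangencies, parallel overlaps, coincident
# heights) and a rotated retry is needed.
ring_crossings <- function(ring) {
  n <- nrow(ring)
  nxt <- c(2:n, 1)
  x <- ring[, 1]; y <- ring[, 2]; z <- ring[, 3]
  scale <- max(stats::dist(rbind(range(x), range(y)))) + 1e-30
  under_pos <- over_pos <- sgn <- numeric(0)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next  # adjacent segments
      d1x <- x[nxt[i]] - x[i]; d1y <- y[nxt[i]] - y[i]
      d2x <- x[nxt[j]] - x[j]; d2y <- y[nxt[j]] - y[j]
      denom <- d1x * d2y - d1y * d2x
      rx <- x[j] - x[i]; ry <- y[j] - y[i]
      if (abs(denom) < 1e-12 * scale^2) {
        # parallel: degenerate only if the supporting lines coincide and
        # the segments actually overlap (collinear disjoint segments, e.g.
        # straight chain flanks, are harmless)
        if (abs(rx * d1y - ry * d1x) < 1e-10 * scale^2) {
          l1 <- d1x * d1x + d1y * d1y
          s0 <- rx * d1x + ry * d1y
          s1 <- s0 + d2x * d1x + d2y * d1y
          if (max(0, min(s0, s1)) <= min(l1, max(s0, s1)) + 1e-12 * scale^2)
            return(NULL)
        }
        next
      }
      t <- (rx * d2y - ry * d2x) / denom
      u <- (rx * d1y - ry * d1x) / denom
      eps <- 1e-9
      if (t <= -eps || t >= 1 + eps || u <= -eps || u >= 1 + eps) next
      if (t < eps || t > 1 - eps || u < eps || u > 1 - eps) return(NULL)
      zi <- z[i] + t * (z[nxt[i]] - z[i])
      zj <- z[j] + u * (z[nxt[j]] - z[j])
      if (abs(zi - zj) < 1e-9 * (1 + abs(zi))) return(NULL)
      if (zi < zj) {  # segment i passes under
        under_pos <- c(under_pos, i - 1 + t)
        over_pos <- c(over_pos, j - 1 + u)
        sgn <- c(sgn, sign(d2x * d1y - d2y * d1x))
      } else {
        under_pos <- c(under_pos, j - 1 + u)
        over_pos <- c(over_pos, i - 1 + t)
        sgn <- c(sgn, sign(d1x * d2y - d1y * d2x))
      }
    }
  }
  list(under = under_pos, over = over_pos, sign = sgn)
}

# |det| of the Alexander matrix at parameter t for a crossing structure
alexander_det <- function(cr, t) {
  c_n <- length(cr$under)
  if (c_n <= 2) return(1)
  ord <- order(cr$under)
  su <- cr$under[ord]
  so <- cr$over[ord]
  sg <- cr$sign[ord]
  # generator j is the arc ending at underpass j: position s between
  # underpasses k and k+1 lies on generator k+1 (wrapping to 1 past the last)
  gen_of <- function(s) {
    (findInterval(s, su) %% c_n) + 1L
  }
  A <- matrix(0, c_n, c_n)
  for (k in seq_len(c_n)) {
    k1 <- if (k == c_n) 1 else k + 1
    i <- gen_of(so[k])
    if (i == k || i == k1) {
      A[k, k] <- -1
      A[k, k1] <- A[k, k1] + 1
    } else if (sg[k] > 0) {
      A[k, k] <- 1; A[k, k1] <- -t; A[k, i] <- t - 1
    } else {
      A[k, k] <- -t; A[k, k1] <- 1; A[k, i] <- t - 1
    }
  }
  abs(det(A[-c_n, -c_n, drop = FALSE]))
}

# deterministic sequence of rotations used when a projection is degenerate
rotation_attempt <- function(pts, attempt) {
  if (attempt == 1) return(pts)
  a <- attempt * 0.7639320225  # golden-angle-like increments
  b <- attempt * 1.2360679775
  Rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3,
               byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
               byrow = TRUE)
  pts %*% t(Ry %*% Rx)
}

#' Alexander invariants of a closed ring
#'
#' Simplifies the ring ([kmt_simplify()]), projects it onto a plane
#' (rotating deterministically past degenerate projections), builds the
#' Alexander matrix from the underpass/overpass crossing structure and
#' returns the absolute Alexander-polynomial determinants
#' \eqn{|\Delta(-1)|} and \eqn{|\Delta(-2)|} (the latter also reduced to its
#' odd part, which removes the \eqn{t^k} normalisation ambiguity and
#' distinguishes 4_1 from 5_1).
#'
#' @param ring Numeric matrix of ring vertices.
#' @param simplify Apply [kmt_simplify()] first (recommended).
#' @return List with `delta1`, `delta2`, `delta2_odd` and `n_crossings`.
#' @export
alexander_invariants <- function(ring, simplify = TRUE) {
  ring <- as.matrix(ring)
  if (simplify) ring <- kmt_simplify(ring)
  if (nrow(ring) <= 3)
    return(list(delta1 = 1, delta2 = 1, delta2_odd = 1, n_crossings = 0))
  for (attempt in 1:40) {
    cr <- ring_crossings(rotation_attempt(ring, attempt))
    if (!is.null(cr)) {
      d1 <- alexander_det(cr, -1)
      d2 <- alexander_det(cr, -2)
      return(list(delta1 = d1, delta2 = d2, delta2_odd = odd_part(d2),
                  n_crossings = length(cr$under)))
    }
  }
  stop("no generic projection found after 40 rotations")
}

# odd part of a (floating-point) integer: strip factors of two; NA if the
# value is too large to round exactly
odd_part <- function(v) {
  v <- abs(v)
  if (!is.finite(v) || v > 2^49) return(NA_real_)
  v <- round(v)
  if (v == 0) return(0)
  while (v %% 2 == 0) v <- v / 2
  v
}

#' Classify a knot from its Alexander invariants
#'
#' Uses \eqn{|\Delta(-1)|} (the knot determinant) and the odd part of
#' \eqn{|\Delta(-2)|}: unknot (1), trefoil 3_1 (3, odd 7), figure-eight 4_1
#' (5, odd 11), pentafoil 5_1 (5, odd 31), and the composite 3_1#5_1
#' (15, odd 217).
#'
#' @param inv Output of [alexander_invariants()], or a ring matrix.
#' @return Character label; `"unknown"` when the invariant pair matches no
#'   supported type.
#' @export
classify_knot <- function(inv) {
  if (is.matrix(inv)) inv <- alexander_invariants(inv)
  d1 <- round(inv$delta1)
  d2o <- inv$delta2_odd
  if (d1 == 1) return("unknot")
  if (d1 == 3) return("3_1")
  if (d1 == 5) {
    if (!is.na(d2o) && d2o == 11) return("4_1")
    if (!is.na(d2o) && d2o == 31) return("5_1")
    return("unknown")
  }
  if (d1 == 9 && !is.na(d2o) && d2o == 49) return("3_1#3_1")
  if (d1 == 15 && !is.na(d2o) && d2o == 217) return("3_1#5_1")
  "unknown"
}

#' Locate the minimal knotted arc of an open chain
#'
#' Top-down search for the smallest sub-chain that, upon the deterministic
#' outward closure, carries the same knot type as the whole chain: the arc is
#' shrunk from both ends by bisection (assuming the type is stable until the
#' knotted core is cut), with a final left-end re-check.
#'
#' @param positions Polymer bead positions (L x 3), end beads excluded.
#' @return `NULL` if the chain is unknotted; otherwise a list (class
#'   `knot_record`) with `start`, `end`, `l_K = end - start`,
#'   `c_K = (start + end)/2` and `type`.
#' @export
minimal_knotted_arc <- function(positions) {
  positions <- as.matrix(positions)
  L <- nrow(positions)
  whole <- classify_knot(close_chain(positions))
  if (whole == "unknot") return(NULL)
  # consensus predicate: a spurious knot completion by one closure path is
  # rarely reproduced by the other, so demand agreement of both schemes
  pred <- function(l, r) {
    if (r - l < 4) return(FALSE)
    sub <- positions[l:r, , drop = FALSE]
    tryCatch(
      classify_knot(close_chain(sub, "axis")) == whole &&
        classify_knot(close_chain(sub, "radial")) == whole,
      error = function(e) FALSE)  # unresolvable projection: claim nothing
  }
  # Shrink the ends alternately, always bisecting against the already
  # tightened opposite end: cutting into the knotted core with a long
  # opposite tail can be spuriously "re-completed" by the closure, so each
  # end is searched with the other end as tight as currently known.
  left <- 1; right <- L
  for (pass in 1:2) {
    lo <- left + 5; hi <- right
    while (lo < hi) {             # smallest right end keeping the type
      mid <- (lo + hi) %/% 2
      if (pred(left, mid)) hi <- mid else lo <- mid + 1
    }
    right <- lo
    lo <- left; hi <- right - 5
    while (lo < hi) {             # largest left end keeping the type
      mid <- (lo + hi + 1) %/% 2
      if (pred(mid, right)) lo <- mid else hi <- mid - 1
    }
    left <- lo
  }
  # single-bead tightening catches residual non-monotonicity near the core
  while (right > left + 5 && pred(left, right - 1)) right <- right - 1
  while (left < right - 5 && pred(left + 1, right)) left <- left + 1
  if (!pred(left, right)) return(NULL)  # closure instability; no arc claimed
  structure(list(start = left, end = right, l_K = right - left,
                 c_K = (left + right) / 2, type = whole),
            class = "knot_record")
}

#' Knot records along a trajectory
#'
#' Runs [minimal_knotted_arc()] on every analysed frame of a trajectory.
#'
#' @param traj A `chrom_trajectory` (see [run_dynamics()]).
#' @param frames Frame indices to analyse (default: all).
#' @return Data frame with columns `frame`, `time`, `start`, `end`, `l_K`,
#'   `c_K`, `type` (`NA` rows for unknotted frames).
#' @export
analyse_knot_trajectory <- function(traj, frames = NULL) {
  poly <- setdiff(seq_len(dim(traj$positions)[1]), traj$end_beads)
  if (is.null(frames)) frames <- seq_along(traj$times)
  rows <- lapply(frames, function(fr) {
    rec <- minimal_knotted_arc(traj$positions[poly, , fr])
    if (is.null(rec))
      data.frame(frame = fr, time = traj$times[fr], start = NA_integer_,
                 end = NA_integer_, l_K = NA_real_, c_K = NA_real_,
                 type = NA_character_, stringsAsFactors = FALSE)
    else
      data.frame(frame = fr, time = traj$times[fr], start = rec$start,
                 end = rec$end, l_K = rec$l_K, c_K = rec$c_K,
                 type = rec$type, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# signed magnetisation of the knotted arc per record row
knot_arc_signed_m <- function(kymo_row, start, end) {
  signed_magnetisation(kymo_row[start:end])
}

# switching analysis: sign flips of the knot-arc signed magnetisation with a
# +/- 0.5 hysteresis band
detect_switches <- function(s, times) {
  state <- 0
  switch_times <- numeric(0)
  boundaries <- integer(0)  # frame index where each switch registers
  for (i in seq_along(s)) {
    if (is.na(s[i])) next
    new_state <- if (s[i] > 0.5) 1 else if (s[i] < -0.5) -1 else state
    if (state != 0 && new_state != 0 && new_state != state) {
      switch_times <- c(switch_times, times[i])
      boundaries <- c(boundaries, i)
    }
    state <- new_state
  }
  list(times = switch_times, frames = boundaries)
}

#' Epigenetic-soliton coherence profile
#'
#' Time-averaged local epigenetic coherence \eqn{\bar m(x)} at bead offset
#' \eqn{x} from the knotted-arc centre \eqn{c_K}: the local signed
#' magnetisation (sliding window of `window` beads) is averaged over the
#' frames of each inter-switch window, its magnitude taken (so that red and
#' blue epochs do not cancel), and the per-window profiles combined with
#' weights proportional to their frame counts.  A soliton shows a broad peak
#' centred at \eqn{x = 0}.
#'
#' @param kymo A [kymograph()].
#' @param records Output of [analyse_knot_trajectory()] aligned to the
#'   kymograph frames.
#' @param window Width (odd) of the sliding local-magnetisation window.
#' @param max_offset Profile half-range in beads (default: L/2).
#' @return List with `profile` (data frame `offset`, `m_bar`),
#'   `switch_times` and `delta_tau` (mean inter-switch time).
#' @export
soliton_profile <- function(kymo, records, window = 11, max_offset = NULL) {
  L <- ncol(kymo$colours)
  if (is.null(max_offset)) max_offset <- L %/% 2
  half <- window %/% 2
  ok <- which(!is.na(records$c_K))
  if (length(ok) == 0) stop("no knotted frames in the records")
  s <- rep(NA_real_, nrow(records))
  for (i in ok)
    s[i] <- knot_arc_signed_m(kymo$colours[records$frame[i], ],
                              records$start[i], records$end[i])
  sw <- detect_switches(s, records$time)
  # inter-switch windows over the analysed frames
  cuts <- c(1, sw$frames, nrow(records) + 1)
  offsets <- -max_offset:max_offset
  acc <- numeric(length(offsets))
  wt <- numeric(length(offsets))
  # precompute local signed magnetisation for all beads and frames used
  sgn_code <- matrix(0, nrow(kymo$colours), L)
  sgn_code[kymo$colours == COL_RED] <- 1
  sgn_code[kymo$colours == COL_BLUE] <- -1
  for (w in seq_len(length(cuts) - 1)) {
    fr_idx <- intersect(seq.int(cuts[w], cuts[w + 1] - 1), ok)
    if (length(fr_idx) < 3) next
    win_sum <- matrix(0, length(fr_idx), length(offsets))
    win_n <- matrix(0, length(fr_idx), length(offsets))
    for (r in seq_along(fr_idx)) {
      i <- fr_idx[r]
      ck <- round(records$c_K[i])
      row <- sgn_code[records$frame[i], ]
      cums <- c(0, cumsum(row))
      for (oi in seq_along(offsets)) {
        l <- ck + offsets[oi]
        a <- max(1, l - half); b <- min(L, l + half)
        if (a > b) next
        win_sum[r, oi] <- (cums[b + 1] - cums[a]) / (b - a + 1)
        win_n[r, oi] <- 1
      }
    }
    nval <- colSums(win_n)
    prof_w <- abs(ifelse(nval > 0, colSums(win_sum) / pmax(nval, 1), NA))
    use <- nval > 0
    acc[use] <- acc[use] + prof_w[use] * length(fr_idx)
    wt[use] <- wt[use] + length(fr_idx)
  }
  profile <- data.frame(offset = offsets,
                        m_bar = ifelse(wt > 0, acc / pmax(wt, 1), NA))
  delta_tau <- if (length(sw$times) >= 2) mean(diff(sw$times)) else NA_real_
  list(profile = profile, switch_times = sw$times, delta_tau = delta_tau)
}

#' Write a soliton coherence profile as TSV
#'
#' Two-column plain-text export (`offset`, `m_bar`) of the profile returned
#' by [soliton_profile()].
#'
#' @param profile The `profile` data frame of [soliton_profile()].
#' @param path Output file.
#' @export
write_soliton_profile <- function(profile, path) {
  stopifnot(all(c("offset", "m_bar") %in% names(profile)))
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Soliton diffusion and switching statistics
#'
#' Applies the boundary-MSD machinery to the knotted-arc centre
#' \eqn{c_K(t)}: time-averaged MSD, diffusion coefficient \eqn{D_K}
#' (half the long-time MSD slope), and epigenetic switch statistics if a
#' kymograph is supplied.
#'
#' @param records Output of [analyse_knot_trajectory()].
#' @param kymo Optional [kymograph()] for switch detection.
#' @param smooth Half-width-2 median filter applied to the \eqn{c_K} track
#'   before the MSD (in frames; 1 disables).  Arc detection carries
#'   frame-to-frame jitter from marginal closures; a short median filter
#'   suppresses these isolated jumps without biasing the long-time slope.
#' @param localized_max Frames whose detected arc exceeds this length (in
#'   beads) are treated as transient delocalisation of the knot: their
#'   \eqn{c_K} is linearly interpolated from the flanking well-localized
#'   frames, since the centre of a momentarily inflated arc does not track
#'   the soliton position.
#' @return List with `msd`, `D_K`, `diffusive`, `switch_times`,
#'   `delta_tau`.
#' @export
soliton_dynamics <- function(records, kymo = NULL, smooth = 5,
                             localized_max = 60) {
  ok <- !is.na(records$c_K)
  track <- data.frame(time = records$time[ok], position = records$c_K[ok],
                      l_K = records$l_K[ok])
  if (nrow(track) < 20) stop("too few knotted frames for soliton dynamics")
  loc <- track$l_K <= localized_max
  if (any(loc) && any(!loc) && sum(loc) >= 2) {
    track$position[!loc] <- approx(track$time[loc], track$position[loc],
                                   xout = track$time[!loc], rule = 2)$y
  }
  if (smooth > 1) {
    h <- smooth %/% 2
    n <- nrow(track)
    track$position <- vapply(seq_len(n), function(i)
      median(track$position[max(1, i - h):min(n, i + h)]), 0)
  }
  msd <- boundary_msd(track)
  dc <- diffusion_coefficient(msd)
  switch_times <- numeric(0); delta_tau <- NA_real_
  if (!is.null(kymo)) {
    s <- rep(NA_real_, nrow(records))
    for (i in which(ok))
      s[i] <- knot_arc_signed_m(kymo$colours[records$frame[i], ],
                                records$start[i], records$end[i])
    sw <- detect_switches(s, records$time)
    switch_times <- sw$times
    if (length(switch_times) >= 2) delta_tau <- mean(diff(switch_times))
  }
  list(msd = msd, D_K = dc$D, diffusive = dc$diffusive,
       switch_times = switch_times, delta_tau = delta_tau)
}
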