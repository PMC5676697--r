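#' Epigenetic-domain detection parameters
#'
#' A domain is a macroscopic region of at least `w_min` beads over which more
#' than a fraction `theta` of the beads share one colour.  A boundary between
#' adjacent red/blue domains requires their signed magnetisations to be
#' opposite and to differ by more than `2 * theta`.
#'
#' @param w_min Minimum domain width in beads (default 50).
#' @param theta Homogeneity threshold (default 0.90).
#' @return An object of class `domain_params`.
#' @export
domain_params <- function(w_min = 50, theta = 0.90) {
  stopifnot(w_min >= 2, theta > 0.5, theta <= 1)
  structure(list(w_min = w_min, theta = theta,
                 boundary_threshold = 2 * theta),
            class = "domain_params")
}

# per-colour union of all qualifying windows [i, j] (j - i + 1 >= w_min,
# fraction of colour c strictly > theta), returned as an interval matrix.
# For fixed start i only the largest qualifying end j matters, because all
# [i, j'] with j' qualifying are contained in [i, jmax]... (every covered
# bead is covered by some [i, jmax(i)]).
colour_window_union <- function(is_c, w_min, theta) {
  L <- length(is_c)
  if (L < w_min) return(matrix(numeric(0), 0, 2))
  cum <- c(0, cumsum(is_c))
  starts <- integer(0); ends <- integer(0)
  cur_end <- 0L
  for (i in seq_len(L - w_min + 1)) {
    j <- seq.int(i + w_min - 1, L)
    frac <- (cum[j + 1] - cum[i]) / (j - i + 1)
    ok <- which(frac > theta)
    if (length(ok) == 0) next
    jmax <- j[ok[length(ok)]]
    if (length(starts) > 0 && i <= cur_end + 1L) {
      # extend current merged interval
      if (jmax > cur_end) {
        ends[length(ends)] <- jmax
        cur_end <- jmax
      }
    } else {
      starts <- c(starts, i); ends <- c(ends, jmax)
      cur_end <- jmax
    }
  }
  cbind(starts, ends)
}

#' Find epigenetic domains in a colour string
#'
#' Detects, for each colour, the union of all windows of length >= `w_min`
#' whose majority-colour fraction exceeds `theta`; overlapping regions
#' claimed by different colours are resolved in favour of the purer domain
#' (ties to the leftmost).  Reports per-domain signed magnetisation.
#'
#' @param colours Integer colour vector.
#' @param p A [domain_params()].
#' @return Data frame with columns `start`, `end` (1-based, inclusive),
#'   `colour`, `m_signed`, `purity`; zero rows if no domain qualifies.
#' @export
find_domains <- function(colours, p = domain_params()) {
  L <- length(colours)
  stopifnot(L >= p$w_min)
  rows <- list()
  for (cc in 0:2) {
    iv <- colour_window_union(as.integer(colours == cc), p$w_min, p$theta)
    if (nrow(iv) == 0) next
    for (r in seq_len(nrow(iv))) {
      seg <- colours[iv[r, 1]:iv[r, 2]]
      rows[[length(rows) + 1]] <- data.frame(
        start = iv[r, 1], end = iv[r, 2], colour = cc,
        m_signed = signed_magnetisation(seg),
        purity = mean(seg == cc))
    }
  }
  if (length(rows) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      colour = integer(0), m_signed = numeric(0),
                      purity = numeric(0)))
  d <- do.call(rbind, rows)
  d <- d[order(d$start, d$end), , drop = FALSE]
  # resolve cross-colour overlaps: place the cut where the combined purity
  # of the two domains is maximal (ties to the leftmost cut), so clean
  # colour blocks split exactly at their interface
  repeat {
    changed <- FALSE
    if (nrow(d) >= 2) {
      for (i in seq_len(nrow(d) - 1)) {
        a <- d[i, ]; b <- d[i + 1, ]
        if (b$start <= a$end) {
          cuts <- (b$start - 1L):a$end
          score <- vapply(cuts, function(cc) {
            pa <- if (cc >= a$start) mean(colours[a$start:cc] == a$colour) else 0
            pb <- if (cc < b$end) mean(colours[(cc + 1):b$end] == b$colour) else 0
            pa + pb
          }, 0)
          cut <- cuts[which.max(score)]
          d$end[i] <- cut
          d$start[i + 1] <- cut + 1L
          changed <- TRUE
        }
      }
    }
    keep <- (d$end - d$start + 1) >= p$w_min
    d <- d[keep, , drop = FALSE]
    if (!changed) break
    d <- d[order(d$start, d$end), , drop = FALSE]
  }
  # refresh statistics after trimming
  if (nrow(d) > 0) {
    for (i in seq_len(nrow(d))) {
      seg <- colours[d$start[i]:d$end[i]]
      d$m_signed[i] <- signed_magnetisation(seg)
      d$purity[i] <- mean(seg == d$colour[i])
    }
  }
  rownames(d) <- NULL
  d
}

#' Find boundaries between opposite-colour domains
#'
#' Adjacent red/blue domain pairs whose signed magnetisations differ by more
#' than `2 * theta` yield one boundary at the interface midpoint
#' (half-integer positions for touching domains).
#'
#' @param domains Output of [find_domains()].
#' @param p A [domain_params()].
#' @return Numeric vector of boundary positions (bead coordinates).
#' @export
find_boundaries <- function(domains, p = domain_params()) {
  if (nrow(domains) < 2) return(numeric(0))
  d <- domains[order(domains$start), , drop = FALSE]
  out <- numeric(0)
  for (i in seq_len(nrow(d) - 1)) {
    a <- d[i, ]; b <- d[i + 1, ]
    opposite <- (a$colour == COL_RED && b$colour == COL_BLUE) ||
      (a$colour == COL_BLUE && b$colour == COL_RED)
    if (opposite && abs(a$m_signed - b$m_signed) > p$boundary_threshold)
      out <- c(out, (a$end + b$start) / 2)
  }
  out
}

#' Link per-frame boundaries into tracks
#'
#' Nearest-neighbour frame-to-frame linking with a maximum-jump gate; tracks
#' end when unmatched, and pairs of tracks that approach within
#' `merge_dist` are both terminated (merge/annihilation events).
#'
#' @param boundaries List (one element per frame) of numeric boundary
#'   positions.
#' @param times Frame times (same length as `boundaries`).
#' @param max_jump Maximum allowed |position change| per frame (beads).
#' @param merge_dist Distance below which two tracks are considered merged.
#' @return List of data frames (`track_id`, `time`, `position`), one per
#'   track.
#' @export
link_boundaries <- function(boundaries, times, max_jump = 10,
                            merge_dist = 25) {
  stopifnot(length(boundaries) == length(times), length(times) >= 2)
  tracks <- list()        # finished + active track data
  active <- integer(0)    # indices into tracks
  next_id <- 1L
  for (fr in seq_along(boundaries)) {
    det <- boundaries[[fr]]
    matched_det <- rep(FALSE, length(det))
    still <- integer(0)
    if (length(active) > 0 && length(det) > 0) {
      last_pos <- vapply(tracks[active], function(t) t$position[nrow(t)], 0)
      dm <- abs(outer(last_pos, det, "-"))
      repeat {
        if (all(!is.finite(dm)) || min(dm) > max_jump) break
        ij <- arrayInd(which.min(dm), dim(dm))
        ti <- active[ij[1]]; dj <- ij[2]
        tracks[[ti]] <- rbind(tracks[[ti]],
                              data.frame(track_id = tracks[[ti]]$track_id[1],
                                         time = times[fr],
                                         position = det[dj]))
        matched_det[dj] <- TRUE
        still <- c(still, ti)
        dm[ij[1], ] <- Inf
        dm[, ij[2]] <- Inf
      }
    }
    # unmatched detections start new tracks
    for (dj in which(!matched_det)) {
      tracks[[length(tracks) + 1]] <- data.frame(
        track_id = next_id, time = times[fr], position = det[dj])
      still <- c(still, length(tracks))
      next_id <- next_id + 1L
    }
    # merge rule: active tracks too close end together (drop from active)
    if (length(still) >= 2) {
      pos_now <- vapply(tracks[still], function(t) t$position[nrow(t)], 0)
      drop <- rep(FALSE, length(still))
      for (i in seq_along(still)) {
        for (j in seq_along(still)) {
          if (i < j && abs(pos_now[i] - pos_now[j]) < merge_dist)
            drop[i] <- drop[j] <- TRUE
        }
      }
      still <- still[!drop]
    }
    active <- still
  }
  tracks
}

#' Time-averaged mean squared displacement of a track
#'
#' Discrete form of the time-averaged MSD
#' \deqn{\delta^2 x(t) = \frac{1}{T - t}\int_0^{T-t}
#'       [x(t_0 + t) - x(t_0)]^2 \, dt_0}
#' over all start times at each lag.  Multiple tracks are aggregated with
#' weights equal to their number of start times per lag.
#'
#' @param track A track data frame (`time`, `position`) from
#'   [link_boundaries()], or a list of such tracks.
#' @param frame_dt Frame spacing (inferred from the track times if `NULL`).
#' @return Data frame with columns `lag` (time units), `msd`, `n` (number
#'   of averaged start times).
#' @export
boundary_msd <- function(track, frame_dt = NULL) {
  if (is.data.frame(track)) track <- list(track)
  stopifnot(length(track) >= 1)
  if (is.null(frame_dt)) {
    dts <- unlist(lapply(track, function(t) diff(t$time)))
    frame_dt <- if (length(dts) > 0) stats::median(dts) else 1
  }
  acc <- list()
  for (tr in track) {
    x <- tr$position
    n <- length(x)
    if (n < 2) next
    for (lag in 1:(n - 1)) {
      d2 <- mean((x[(1 + lag):n] - x[1:(n - lag)])^2)
      key <- as.character(lag)
      prev <- acc[[key]]
      w <- n - lag
      if (is.null(prev)) acc[[key]] <- c(sum = d2 * w, n = w)
      else acc[[key]] <- c(sum = unname(prev["sum"]) + d2 * w,
                           n = unname(prev["n"]) + w)
    }
  }
  if (length(acc) == 0)
    return(data.frame(lag = numeric(0), msd = numeric(0), n = numeric(0)))
  lags <- sort(as.integer(names(acc)))
  data.frame(
    lag = lags * frame_dt,
    msd = vapply(as.character(lags), function(k) acc[[k]][["sum"]] / acc[[k]][["n"]], 0),
    n = vapply(as.character(lags), function(k) acc[[k]][["n"]], 0))
}

#' Diffusion coefficient from an MSD curve
#'
#' One-dimensional convention \eqn{D = \lim_{t\to\infty} \delta^2x(t)/2t},
#' estimated as half the least-squares slope of the MSD over a long-time fit
#' window (by default lags between 10% and 50% of the maximum lag: long-time
#' but still well-averaged).  A log-log slope outside \eqn{[0.8, 1.2]} in the
#' window flags the motion as non-diffusive; D is still reported.
#'
#' @param msd Data frame from [boundary_msd()].
#' @param fit_window Fractions `c(lo, hi)` of the maximum lag.
#' @return List with `D`, `slope_loglog`, `diffusive` flag and `n_lags`.
#' @export
diffusion_coefficient <- function(msd, fit_window = c(0.1, 0.5)) {
  stopifnot(nrow(msd) >= 2)
  tmax <- max(msd$lag)
  sel <- msd$lag >= fit_window[1] * tmax & msd$lag <= fit_window[2] * tmax
  if (sum(sel) < 10)
    stop("fewer than 10 lags in the fit window; extend the track")
  # weight by the number of averaged start times: long lags of short tracks
  # carry few pairs and would otherwise dominate the fit noise
  df <- data.frame(lag = msd$lag[sel], msd = msd$msd[sel], w = msd$n[sel])
  fit <- lm(msd ~ lag, data = df, weights = w)
  D <- unname(coef(fit)[2]) / 2
  pos <- msd$msd[sel] > 0
  slope_ll <- if (sum(pos) >= 2) {
    unname(coef(lm(log(msd$msd[sel][pos]) ~ log(msd$lag[sel][pos])))[2])
  } else NA_real_
  list(D = D, slope_loglog = slope_ll,
       diffusive = is.finite(slope_ll) && slope_ll >= 0.8 && slope_ll <= 1.2,
       n_lags = sum(sel))
}

#' Boundary analysis of a kymograph
#'
#' Convenience pipeline: per-frame domains and boundaries, linking, and
#' per-track MSDs.
#'
#' @param kymo A [kymograph()].
#' @param p A [domain_params()].
#' @param max_jump,merge_dist See [link_boundaries()].
#' @param min_track_frames Discard shorter tracks.
#' @return List with `tracks`, aggregated `msd`, and the per-frame
#'   `boundaries`.
#' @export
analyse_boundaries <- function(kymo, p = domain_params(), max_jump = 10,
                               merge_dist = 25, min_track_frames = 20) {
  per_frame <- lapply(seq_len(nrow(kymo$colours)), function(i) {
    find_boundaries(find_domains(kymo$colours[i, ], p), p)
  })
  tracks <- link_boundaries(per_frame, kymo$times, max_jump, merge_dist)
  tracks <- Filter(function(t) nrow(t) >= min_track_frames, tracks)
  msd <- if (length(tracks) > 0) boundary_msd(tracks) else
    data.frame(lag = numeric(0), msd = numeric(0), n = numeric(0))
  list(tracks = tracks, msd = msd, boundaries = per_frame)
}
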