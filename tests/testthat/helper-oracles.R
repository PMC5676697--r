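# Independent reference implementations used as oracles.  These deliberately
# use plain double loops and closed forms, not the package's code paths.

# brute-force total energy: O(L^2) pair loop + bond + bending loops
oracle_total_energy <- function(state, p, attract_on = TRUE) {
  pos <- state$positions
  n <- nrow(pos)
  col <- state$colours
  diam <- state$bead_diameter
  is_end <- seq_len(n) %in% state$end_beads
  U <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      delta <- (diam[i] + diam[j]) / 2 - 1
      x <- r - delta
      same <- attract_on && !is_end[i] && !is_end[j] &&
        col[i] != 0 && col[i] == col[j]
      xc <- if (same) 1.8 else 2^(1 / 6)
      eps <- if (same) p$epsilon else 1
      S <- xc^-12 - xc^-6
      nrm <- if (same) 4 * (0.25 + S) else 1
      if (x < xc) {
        if (x < 0.3) x <- 0.3
        U <- U + p$T_L * (4 * eps / nrm) * (x^-12 - x^-6 - S)
      }
    }
  }
  for (i in 1:(n - 1)) {
    r <- sqrt(sum((pos[i, ] - pos[i + 1, ])^2))
    x0 <- p$bond_x0 + (diam[i] + diam[i + 1]) / 2 - 1
    U <- U + 0.5 * p$bond_k * p$T_L * (r - x0)^2
  }
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      t1 <- pos[i, ] - pos[i - 1, ]
      t2 <- pos[i + 1, ] - pos[i, ]
      cc <- sum(t1 * t2) / sqrt(sum(t1^2) * sum(t2^2))
      U <- U + p$T_L * p$persistence_lp * (1 - cc)
    }
  }
  U
}

# exhaustive window-scan domain oracle: every [i, j] with j-i+1 >= w_min and
# strict majority fraction > theta marks its beads as covered for colour c
oracle_domain_coverage <- function(colours, w_min, theta, colour) {
  L <- length(colours)
  covered <- rep(FALSE, L)
  for (i in seq_len(L)) {
    for (j in i:L) {
      if (j - i + 1 < w_min) next
      if (mean(colours[i:j] == colour) > theta) covered[i:j] <- TRUE
    }
  }
  covered
}

# random small thermalised chain for force/energy comparisons
random_chain <- function(L, seed, jitter = 0.1, with_ends = TRUE) {
  set.seed(seed)
  st <- build_open_chain(L)
  st$positions <- st$positions +
    matrix(rnorm(nrow(st$positions) * 3, 0, jitter), ncol = 3)
  st$colours[polymer_beads(st)] <- sample(0:2, L, replace = TRUE)
  st
}

# closed parametric knot rings (independent of the builders module) for
# invariant checks
oracle_knot_ring <- function(type, npts = 150) {
  s <- seq(0, 2 * pi, length.out = npts + 1)[-(npts + 1)]
  switch(type,
    unknot = cbind(cos(s), sin(s), 0.1 * sin(2 * s)),
    "3_1" = cbind(sin(s) + 2 * sin(2 * s), cos(s) - 2 * cos(2 * s),
                  -sin(3 * s)),
    "4_1" = cbind((2 + cos(2 * s)) * cos(3 * s),
                  (2 + cos(2 * s)) * sin(3 * s), sin(4 * s)),
    "5_1" = cbind((2 + cos(5 * s)) * cos(2 * s),
                  (2 + cos(5 * s)) * sin(2 * s), sin(5 * s)),
    stop("unknown type"))
}

random_rotation <- function(seed) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rz <- matrix(c(cos(th[1]), -sin(th[1]), 0,
                 sin(th[1]), cos(th[1]), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[2]), -sin(th[2]),
                 0, sin(th[2]), cos(th[2])), 3, 3, byrow = TRUE)
  Rx %*% Rz
}
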