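test_that("pair cutoff follows the colour rule", {
  p <- forcefield_params()
  expect_equal(pair_cutoff(COL_RED, COL_RED, p), 1.8)
  expect_equal(pair_cutoff(COL_BLUE, COL_BLUE, p), 1.8)
  expect_equal(pair_cutoff(COL_RED, COL_BLUE, p), 2^(1 / 6))
  expect_equal(pair_cutoff(COL_UNMARKED, COL_UNMARKED, p), 2^(1 / 6))
  expect_equal(pair_cutoff(COL_UNMARKED, COL_RED, p), 2^(1 / 6))
})

test_that("pair potential is continuous at both cutoffs and exactly zero beyond", {
  p <- forcefield_params(epsilon = 3)
  expect_lt(abs(pair_potential(1.8 - 1e-9, COL_RED, COL_RED, p)), 1e-8)
  expect_identical(pair_potential(1.8 + 1e-12, COL_RED, COL_RED, p), 0)
  xc <- 2^(1 / 6)
  expect_lt(abs(pair_potential(xc - 1e-9, COL_RED, COL_BLUE, p)), 1e-7)
  expect_identical(pair_potential(xc + 1e-12, COL_RED, COL_BLUE, p), 0)
  expect_identical(pair_potential(3, COL_RED, COL_RED, p), 0)
  expect_error(pair_potential(0, COL_RED, COL_RED, p), "positive")
})

test_that("like-colour well depth equals -epsilon under the chosen normalisation", {
  # oracle: numeric minimisation of the unnormalised bracket, then divide by
  # its |minimum| -- the normalisation must make the depth exactly -epsilon
  S <- 1.8^-12 - 1.8^-6
  om <- optimize(function(x) x^-12 - x^-6 - S, c(0.8, 1.8))
  for (eps in c(0.5, 1, 2.7)) {
    p <- forcefield_params(epsilon = eps)
    m <- optimize(function(x) pair_potential(x, COL_RED, COL_RED, p),
                  c(0.9, 1.8))
    expect_equal(m$objective, -eps, tolerance = 1e-9)
    expect_equal(m$minimum, 2^(1 / 6), tolerance = 1e-4)
    # and the normalised potential is the unnormalised one / |min|
    expect_equal(pair_potential(1.05, COL_RED, COL_RED, p),
                 eps * (1.05^-12 - 1.05^-6 - S) / abs(om$objective),
                 tolerance = 1e-6)   # limited by optimize()'s precision
  }
})

test_that("cross and grey channels are non-negative WCA", {
  p <- forcefield_params(epsilon = 5)
  xs <- seq(0.85, 2.5, by = 0.001)
  for (qq in list(c(COL_RED, COL_BLUE), c(COL_UNMARKED, COL_RED),
                  c(COL_UNMARKED, COL_UNMARKED))) {
    u <- pair_potential(xs, qq[1], qq[2], p)
    expect_true(all(u >= 0))
    expect_true(all(u[xs > 2^(1 / 6)] == 0))
  }
  # WCA contact energy is epsilon_cross = 1 k_B T_L at x = sigma
  expect_equal(pair_potential(1, COL_RED, COL_BLUE, p), 1)
})

test_that("bond potential is harmonic about x0", {
  p <- forcefield_params()
  expect_equal(bond_potential(1.1, p), 0)
  expect_equal(bond_potential(1.2, p), 0.5)
  expect_equal(bond_potential(1.0, p), 0.5)
})

test_that("bending potential vanishes for straight triplets and is 2 lp for hairpins", {
  p <- forcefield_params()
  expect_equal(bending_potential(1, p), 0)
  expect_equal(bending_potential(-1, p), 6)      # 2 * lp / sigma at lp = 3
  p0 <- forcefield_params(persistence_lp = 0)
  expect_equal(bending_potential(runif(5, -1, 1), p0), rep(0, 5))
  expect_error(bending_potential(1.5, p), "cos")
})

test_that("total energy matches the brute-force oracle on random chains", {
  p <- forcefield_params(epsilon = 2)
  for (seed in 1:5) {
    st <- random_chain(12, seed)
    expect_equal(total_energy(st, p), oracle_total_energy(st, p),
                 tolerance = 1e-10)
    expect_equal(total_energy(st, p, attract_on = FALSE),
                 oracle_total_energy(st, p, attract_on = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("isolated beads beyond all cutoffs have zero energy and force", {
  p <- forcefield_params(epsilon = 2)
  st <- chain_state(rbind(c(0, 0, 0), c(0, 0, 3), c(0, 0, 6)),
                    colours = c(1, 1, 1))
  expect_equal(total_energy(st, p, bonds_on = FALSE), 0)
  expect_equal(max(abs(forces(st, p, bonds_on = FALSE))), 0)
})

test_that("straight 3-bead chain energy is twice the WCA bond-distance value", {
  p <- forcefield_params()
  st <- chain_state(rbind(c(0, 0, 0), c(0, 0, 1.1), c(0, 0, 2.2)))
  # bonds at rest, straight: only the two nearest-neighbour WCA contacts at
  # 1.1 sigma contribute (1.1 < 2^(1/6))
  expect_equal(total_energy(st, p),
               2 * pair_potential(1.1, COL_UNMARKED, COL_UNMARKED, p),
               tolerance = 1e-12)
})

test_that("forces equal the central-difference gradient of the energy", {
  p <- forcefield_params(epsilon = 2)
  h <- 1e-6
  for (seed in c(3, 11)) {
    st <- random_chain(9, seed)
    f <- forces(st, p)
    num <- matrix(0, nrow(st$positions), 3)
    for (i in seq_len(nrow(st$positions))) {
      for (k in 1:3) {
        s1 <- st; s1$positions[i, k] <- s1$positions[i, k] + h
        s2 <- st; s2$positions[i, k] <- s2$positions[i, k] - h
        num[i, k] <- -(total_energy(s1, p) - total_energy(s2, p)) / (2 * h)
      }
    }
    expect_lt(max(abs(f - num)) / max(abs(f)), 1e-6)
  }
})

test_that("internal forces conserve momentum and angular momentum", {
  p <- forcefield_params(epsilon = 2)
  st <- random_chain(15, 7)
  f <- forces(st, p)
  expect_lt(max(abs(colSums(f))), 1e-10)
  # net torque about the origin
  tq <- colSums(cbind(
    st$positions[, 2] * f[, 3] - st$positions[, 3] * f[, 2],
    st$positions[, 3] * f[, 1] - st$positions[, 1] * f[, 3],
    st$positions[, 1] * f[, 2] - st$positions[, 2] * f[, 1]))
  expect_lt(max(abs(tq)), 1e-9)
})

test_that("terminal stretching forces are equal and opposite on the end beads", {
  p <- forcefield_params()
  st <- build_open_chain(10)
  f0 <- forces(st, p)
  f1 <- forces(st, p, stretch_protocol(2.5))
  df <- f1 - f0
  expect_equal(df[1, ], c(0, 0, -2.5))
  expect_equal(df[12, ], c(0, 0, 2.5))
  expect_lt(max(abs(df[2:11, ])), 1e-12)
})

test_that("chain_state validates its invariants", {
  expect_error(chain_state(matrix(0, 3, 2)), "ncol")
  expect_error(chain_state(matrix(0, 3, 3), colours = c(1, 2)), "length")
  expect_error(chain_state(matrix(0, 3, 3), colours = c(5, 0, 0)))
  st <- build_open_chain(5)
  expect_equal(st$bead_diameter[st$end_beads], c(5, 5))
  expect_equal(length(polymer_beads(st)), 5)
  expect_error(chain_state(matrix(0, 3, 3), colours = c(1, 0, 0),
                           end_beads = 1L), "unmarked")
})
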