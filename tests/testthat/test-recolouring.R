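test_that("colour proposal is symmetric over the two remaining colours", {
  set.seed(1)
  draws <- replicate(4000, propose_colour(COL_RED))
  expect_false(any(draws == COL_RED))
  frac <- mean(draws == COL_BLUE)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 4000))
  # proposal matrix symmetric: every ordered pair (a, b != a) reachable
  for (a in 0:2) {
    d <- replicate(200, propose_colour(a))
    expect_setequal(unique(d), setdiff(0:2, a))
  }
})

test_that("recolouring energy difference matches the total-energy oracle", {
  p <- forcefield_params(epsilon = 2)
  for (seed in 1:4) {
    st <- random_chain(10, seed)
    bead <- sample(polymer_beads(st), 1)
    new_col <- propose_colour(st$colours[bead])
    dU <- recolour_delta_energy(st, bead, new_col, p)
    st2 <- st
    st2$colours[bead] <- new_col
    dU_oracle <- oracle_total_energy(st2, p) - oracle_total_energy(st, p)
    expect_equal(dU, dU_oracle, tolerance = 1e-10)
    # reversibility: reverting gives the opposite difference
    expect_equal(recolour_delta_energy(st2, bead, st$colours[bead], p), -dU,
                 tolerance = 1e-10)
  }
})

test_that("end beads cannot be recoloured", {
  st <- build_open_chain(5)
  expect_error(recolour_delta_energy(st, 1, COL_RED), "end bead")
})

test_that("isolated bead recolours with zero energy difference", {
  st <- chain_state(rbind(c(0, 0, 0), c(0, 0, 5), c(0, 0, 10)),
                    colours = c(1, 1, 1))
  expect_equal(recolour_delta_energy(st, 2, COL_BLUE), 0)
})

test_that("a RED contact at the well minimum costs exactly epsilon to leave", {
  p <- forcefield_params(epsilon = 1.7)
  st <- chain_state(rbind(c(0, 0, 0), c(0, 0, 2^(1 / 6))), colours = c(1, 1))
  dU <- recolour_delta_energy(st, 2, COL_BLUE, p)
  # loses the full bond depth (epsilon), gains the WCA value at 2^(1/6) (= 0)
  expect_equal(dU, 1.7, tolerance = 1e-9)
})

test_that("Metropolis acceptance matches exp(-dU/T_R) at dU = k_B T_R", {
  # two beads pinned at a distance where the like-colour loss is exactly 1
  p <- forcefield_params(epsilon = 1)
  st <- chain_state(rbind(c(0, 0, 0), c(0, 0, 2^(1 / 6))), colours = c(1, 1))
  expect_equal(recolour_delta_energy(st, 2, COL_BLUE, p), 1, tolerance = 1e-9)
  n <- 1e5
  set.seed(42)
  acc <- 0L
  for (i in seq_len(n)) {
    # force the unfavourable proposal by attempting until proposed != grey
    res <- recolour_attempt(st, 2, p, recolour_params(T_R = 1))
    if (res$proposed == COL_BLUE) acc <- acc + res$accepted
  }
  # among BLUE proposals, acceptance should be e^-1
  nblue <- n / 2
  se <- sqrt(exp(-1) * (1 - exp(-1)) / nblue)
  expect_lt(abs(acc / nblue - exp(-1)), 3.5 * se)
})

test_that("frozen two-bead system reaches the exact Boltzmann colour law", {
  # two polymer beads at the like-colour minimum: 9 colour microstates with
  # energy -eps for the two like-coloured non-grey states, ~0 otherwise
  p <- forcefield_params(epsilon = 1.5)
  st <- chain_state(rbind(c(0, 0, 0), c(0, 0, 2^(1 / 6))), colours = c(0, 0))
  # exact enumeration oracle
  energies <- matrix(0, 3, 3)
  for (a in 0:2) for (b in 0:2) {
    s2 <- st; s2$colours <- c(a, b)
    energies[a + 1, b + 1] <- total_energy(s2, p, bonds_on = FALSE)
  }
  w <- exp(-energies)
  w <- w / sum(w)
  nsweeps <- 2e5
  trace <- recolour_run_frozen(st, p, recolour_params(T_R = 1),
                               nsweeps = nsweeps, record_every = 10,
                               seed = 3)
  counts <- table(factor(trace[, 1], levels = 0:2),
                  factor(trace[, 2], levels = 0:2))
  chi <- chisq.test(as.vector(counts), p = as.vector(w))
  expect_gt(chi$p.value, 0.01)
})

test_that("sweeps preserve positions and respect the enabled_from gate", {
  p <- forcefield_params(epsilon = 2)
  st <- random_chain(10, 5)
  st$time <- -1
  set.seed(8)
  out <- recolour_sweep(st, p, recolour_params(enabled_from = 0))
  expect_identical(out$state$colours, st$colours)  # gated off before t = 0
  st$time <- 1
  out <- recolour_sweep(st, p, recolour_params(enabled_from = 0))
  expect_identical(out$state$positions, st$positions)
  expect_identical(out$state$colours[st$end_beads], st$colours[st$end_beads])
})

test_that("infinite-temperature sweeps randomise colours uniformly", {
  p <- forcefield_params(epsilon = 3)
  st <- chain_state(rbind(c(0, 0, 0), c(0, 0, 1.1), c(0, 0, 2.2)),
                    colours = c(1, 1, 1))
  trace <- recolour_run_frozen(st, p, recolour_params(T_R = 1e8),
                               nsweeps = 3e4, record_every = 10, seed = 5)
  fr <- colMeans(trace == 1)
  expect_true(all(abs(fr - 1 / 3) < 0.03))
})

test_that("deep-quench compact homopolymer seed absorbs to full magnetisation", {
  # compact all-RED cluster with strong attraction: the ordered state is
  # absorbing for T_R much smaller than epsilon
  st <- build_compact_chain(50)
  st$colours[polymer_beads(st)] <- COL_RED
  p <- forcefield_params(epsilon = 10)
  trace <- recolour_run_frozen(st, p, recolour_params(T_R = 1),
                               nsweeps = 200, record_every = 200, seed = 1)
  final <- trace[nrow(trace), polymer_beads(st)]
  expect_gt(magnetisation(final), 0.95)
})
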