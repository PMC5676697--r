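test_that("Alexander invariants identify the supported knot types", {
  # frozen expected values: |Delta(-1)|, odd part of |Delta(-2)| from the
  # Alexander polynomials Delta_31 = t - 1 + 1/t, Delta_41 = -t + 3 - 1/t,
  # Delta_51 = t^2 - t + 1 - 1/t + 1/t^2
  expected <- list("3_1" = c(3, 7), "4_1" = c(5, 11), "5_1" = c(5, 31))
  for (ty in names(expected)) {
    inv <- alexander_invariants(oracle_knot_ring(ty))
    expect_equal(round(inv$delta1), expected[[ty]][1])
    expect_equal(inv$delta2_odd, expected[[ty]][2])
    expect_equal(classify_knot(inv), ty)
  }
  inv <- alexander_invariants(oracle_knot_ring("unknot"))
  expect_equal(round(inv$delta1), 1)
  expect_equal(classify_knot(inv), "unknot")
})

test_that("invariants are rotation, translation and resolution invariant", {
  for (ty in c("unknot", "3_1", "4_1", "5_1")) {
    base <- classify_knot(alexander_invariants(oracle_knot_ring(ty, 120)))
    dense <- classify_knot(alexander_invariants(oracle_knot_ring(ty, 240)))
    expect_equal(dense, base)
    for (seed in 1:5) {
      R <- random_rotation(seed * 17)
      ring <- oracle_knot_ring(ty, 150) %*% R
      ring <- sweep(ring, 2, c(3, -7, 2), "+")
      expect_equal(classify_knot(alexander_invariants(ring)), base)
    }
  }
})

test_that("KMT simplification preserves topology while reducing vertices", {
  for (ty in c("3_1", "4_1", "5_1")) {
    ring <- oracle_knot_ring(ty, 200)
    simp <- kmt_simplify(ring)
    expect_lt(nrow(simp), nrow(ring) / 2)
    expect_equal(classify_knot(alexander_invariants(simp, simplify = FALSE)),
                 ty)
  }
})

test_that("closures of planar and straight arcs are unknots", {
  s <- seq(0, 1.8 * pi, length.out = 60)
  arc <- cbind(cos(s), sin(s), 0 * s)       # almost-closed planar circle arc
  expect_equal(classify_knot(close_chain(arc)), "unknot")
  seg <- cbind(0, 0, seq(0, 10, length.out = 20))   # straight segment
  expect_equal(classify_knot(close_chain(seg)), "unknot")
  # open parametric trefoil (cut on the outer equator, where the opening
  # does not participate in any crossing) keeps its type upon closure
  so <- seq(0.3, 2 * pi - 0.3, length.out = 140)
  tre <- cbind((2 + cos(3 * so)) * cos(2 * so),
               (2 + cos(3 * so)) * sin(2 * so), sin(3 * so))
  expect_equal(classify_knot(close_chain(tre)), "3_1")
})

test_that("minimal knotted arc finds spliced knots near their extent", {
  st <- tie_knot(build_open_chain(200), "3_1", centre_fraction = 0.3,
                 extent_beads = 80)   # splice occupies beads ~[20, 99]
  rec <- minimal_knotted_arc(st$positions[polymer_beads(st), ])
  expect_equal(rec$type, "3_1")
  expect_gte(rec$start, 15)
  expect_lte(rec$end, 105)
  expect_equal(rec$c_K, (rec$start + rec$end) / 2)
  expect_equal(rec$l_K, rec$end - rec$start)
  # idempotence: the arc of the arc is (essentially) the whole arc
  sub <- st$positions[polymer_beads(st), ][rec$start:rec$end, ]
  rec2 <- minimal_knotted_arc(sub)
  expect_equal(rec2$type, "3_1")
  expect_gt(rec2$l_K, 0.8 * rec$l_K)
  # unknotted chains yield no record
  expect_null(minimal_knotted_arc(build_open_chain(100)$positions[2:101, ]))
})

test_that("soliton profile peaks where an ordered block co-moves with the arc", {
  # synthetic kymograph: RED block of width 40 riding on an injected centre
  set.seed(9)
  L <- 200
  nf <- 80
  ck <- round(100 + cumsum(sample(c(-2, 0, 2), nf, TRUE)))
  cols <- matrix(sample(0:2, nf * L, TRUE), nf, L)
  recs <- data.frame(frame = 1:nf, time = 1:nf,
                     start = ck - 20, end = ck + 20,
                     l_K = 40, c_K = ck, type = "4_1",
                     stringsAsFactors = FALSE)
  for (i in 1:nf) cols[i, (ck[i] - 20):(ck[i] + 20)] <- COL_RED
  k <- kymograph(1:nf, cols)
  sp <- soliton_profile(k, recs)
  pr <- sp$profile
  centre <- pr$m_bar[pr$offset == 0]
  far <- mean(pr$m_bar[abs(pr$offset) > 60], na.rm = TRUE)
  expect_gt(centre, 0.9)
  expect_gt(pr$m_bar[pr$offset == -15], 0.8)
  expect_lt(far, 0.2)
  # uniform random kymograph: no peak anywhere
  cols2 <- matrix(sample(0:2, nf * L, TRUE), nf, L)
  sp2 <- soliton_profile(kymograph(1:nf, cols2), recs)
  expect_lt(max(sp2$profile$m_bar, na.rm = TRUE), 0.35)
})

test_that("soliton dynamics recovers injected diffusion and detects switches", {
  set.seed(2)
  nf <- 400
  steps <- sample(c(-1, 1), nf - 1, TRUE)
  ck <- cumsum(c(100, steps))
  recs <- data.frame(frame = 1:nf, time = 1:nf, start = ck - 15,
                     end = ck + 15, l_K = 30, c_K = ck, type = "3_1",
                     stringsAsFactors = FALSE)
  dyn <- soliton_dynamics(recs)
  expect_lt(abs(dyn$D_K - 0.5), 0.15)
  # frozen arc: D = 0
  recs0 <- recs
  recs0$c_K <- 100; recs0$start <- 85; recs0$end <- 115
  expect_equal(soliton_dynamics(recs0)$D_K, 0, tolerance = 1e-12)
  # switching: signed arc magnetisation flips sign with hysteresis
  L <- 200
  cols <- matrix(COL_UNMARKED, nf, L)
  state <- rep(rep(c(COL_RED, COL_BLUE), each = 100), length.out = nf)
  for (i in 1:nf) cols[i, (recs0$start[i]):(recs0$end[i])] <- state[i]
  dyn2 <- soliton_dynamics(recs0, kymograph(1:nf, cols))
  expect_length(dyn2$switch_times, 3)
})
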