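test_that("shell lattice places points exactly on the shell, quasi-uniformly", {
  expect_equal(nrow(sample_shell_points(0, 1)), 0)
  expect_error(sample_shell_points(-1, 1), "non-negative")

  # degenerate hemisphere lattice: single point sits on the pole
  p1 <- sample_shell_points(1, 2.5, "hemisphere", pole = c(0, 0, 1))
  expect_equal(as.numeric(p1), c(0, 0, 2.5), tolerance = 1e-12)

  p <- sample_shell_points(500, 2.9, "hemisphere")
  expect_equal(sqrt(rowSums(p^2)), rep(2.9, 500), tolerance = 1e-12)
  expect_true(all(p[, 3] >= 0))
  # near-uniform coverage: nearest-neighbour spacing CV below 0.3
  d2 <- as.matrix(dist(p))
  diag(d2) <- Inf
  nn <- apply(d2, 1, min)
  expect_lt(sd(nn) / mean(nn), 0.3)

  # full-sphere region covers both hemispheres and respects an arbitrary pole
  ph <- sample_shell_points(64, 1, "hemisphere", pole = c(1, 1, 0))
  expect_true(all(ph %*% c(1, 1, 0) >= -1e-12))
  pf <- sample_shell_points(64, 1, "sphere")
  expect_true(any(pf[, 3] > 0) && any(pf[, 3] < 0))
})

test_that("coverage fraction and E2 count convert consistently", {
  expect_identical(ne2_from_phi(0), 0L)
  expect_identical(ne2_from_phi(1.0, 0.2, 4.2), 700L)
  expect_identical(ne2_from_phi(0.8, 0.2, 4.2), 560L)
  expect_equal(phi_from_ne2(0), 0)
  # monotone in NE2 and round-trip identity on integers
  n <- 0:700
  phi <- phi_from_ne2(n, 0.2, 4.2)
  expect_true(all(diff(phi) > 0))
  expect_identical(ne2_from_phi(phi, 0.2, 4.2), n)
  expect_error(ne2_from_phi(1.2), "\\[0, 1\\]")
})

test_that("built motor satisfies mass, placement and orientation invariants", {
  cfg0 <- simulation_config(phi = 0, total_time = 1)
  m0 <- cached("motor_phi0", build_motor(cfg0))
  expect_identical(m0$NE0 + m0$NE1 + m0$NE2, 1000L)
  expect_equal(m0$M, 2681 * 0.44 + 1000 * 1.50)  # 2679.64, exact bookkeeping

  cfg1 <- simulation_config(phi = 1, total_time = 1)
  m1 <- cached("motor_phi1", build_motor(cfg1))
  expect_identical(m1$NE0 + m1$NE1 + m1$NE2, 1700L)
  expect_equal(m1$M, 2679.64 + 700 * 0.64)       # 3127.64

  for (m in list(m0, m1)) {
    expect_equal(sum(m$u^2), 1, tolerance = 1e-12)
    # u is anti-parallel to the E1 hemisphere centre-of-mass direction
    e1_com <- colMeans(m$pos[m$species == "E1", ])
    expect_lt(sum(m$u * e1_com), 0)
    # strict hemisphere separation along u
    expect_true(all(m$pos[m$species == "E0", ] %*% m$u > 0))
    expect_true(all(m$pos[m$species == "E1", ] %*% m$u < 0))
    # beads on their shells, internals inside the ball
    r_in <- sqrt(rowSums(m$pos[m$species %in% c("E0", "E1"), ]^2))
    expect_equal(r_in, rep(cfg0$R1, length(r_in)), tolerance = 1e-12)
    expect_true(all(rowSums(m$pos[m$species == "IN", ]^2) <= cfg0$R1^2))
  }
  r_e2 <- sqrt(rowSums(m1$pos[m1$species == "E2", ]^2))
  expect_equal(r_e2, rep(4.2, 700), tolerance = 1e-12)
  # E2 shell sits over the E1 hemisphere
  expect_true(all(m1$pos[m1$species == "E2", ] %*% m1$u < 0))

  expect_error(build_motor(simulation_config(R2 = 3.0, total_time = 1)),
               "interpenetrate")
})

test_that("spring graph is connected across the coverage range", {
  skip_if_not_installed("igraph")
  # full-scale geometry at a few coverages, the whole grid at desk scale
  for (ph in c(0, 0.5, 1)) {
    m <- if (ph %in% c(0, 1)) {
      cached(paste0("motor_phi", ph), build_motor(
        simulation_config(phi = ph, total_time = 1)))
    } else build_motor(simulation_config(phi = ph, total_time = 1))
    g <- igraph::graph_from_edgelist(m$springs, directed = FALSE)
    expect_equal(igraph::components(g)$no, 1)
  }
  for (ph in seq(0, 1, by = 0.1)) {
    m <- build_motor(make_fixture_scenario("tiny", phi = ph))
    g <- igraph::graph_from_edgelist(m$springs, directed = FALSE)
    expect_equal(igraph::components(g)$no, 1)
    expect_equal(m$M, sum(m$mass))
  }
})

test_that("opening a polar cap removes exactly the E2 beads near the pole", {
  m <- cached("motor_phi1", build_motor(simulation_config(phi = 1,
                                                          total_time = 1)))
  expect_identical(open_polar_cap(m, 0), m)

  # cap angle chosen between the 140th and 141st sorted polar angle (about
  # the centre of mass, as the cap is defined) removes exactly 140 beads:
  # phi drops from 1.0 to 0.8 (700 -> 560 beads)
  com <- colSums(m$pos * m$mass) / sum(m$mass)
  e2 <- sweep(m$pos[m$species == "E2", ], 2, com)
  ct <- (e2 %*% (-m$u)) / sqrt(rowSums(e2^2))
  th <- sort(acos(pmin(1, ct)))
  cap <- mean(th[140:141])
  m8 <- open_polar_cap(m, cap)
  expect_identical(m8$NE2, 560L)
  expect_equal(m8$phi, phi_from_ne2(560, 0.2, 4.2))
  expect_equal(m8$M, m$M - 140 * 0.64)
  # surviving springs keep their rest lengths
  d <- sqrt(rowSums((m8$pos[m8$springs[, 1], ] - m8$pos[m8$springs[, 2], ])^2))
  expect_equal(d, m8$r0, tolerance = 1e-12)

  m_none <- open_polar_cap(m, pi / 2)
  expect_identical(m_none$NE2, 0L)
  expect_equal(m_none$phi, 0)
  expect_error(open_polar_cap(m_none, 0.3), "no E2")
  expect_error(open_polar_cap(m, 2), "cap half-angle")
})

test_that("motor geometry exports as extended XYZ", {
  m <- build_motor(make_fixture_scenario("tiny", phi = 0.5))
  f <- tempfile(fileext = ".xyz")
  write_motor_xyz(m, f)
  lines <- readLines(f)
  expect_identical(as.integer(lines[1]), nrow(m$pos))
  expect_identical(length(lines), nrow(m$pos) + 2L)
  first <- strsplit(lines[3], " ")[[1]]
  expect_identical(first[1], m$species[1])
})
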