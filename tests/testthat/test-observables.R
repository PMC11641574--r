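make_frame <- function(pos, species, center = c(0, 0, 0), u = c(0, 0, 1),
                       vel = NULL, vcom = c(0, 0, 0)) {
  pos <- matrix(pos, ncol = 3)
  list(time = 0, pos = pos,
       vel = if (is.null(vel)) matrix(0, nrow(pos), 3) else matrix(vel, ncol = 3),
       species = match(species, c("A", "I", "B")) - 1L,
       center = center, u = u, vcom = vcom)
}

test_that("axial velocity statistics average the projected velocity", {
  df <- data.frame(time = 1:100, vu = 0)
  st <- axial_velocity_stats(df)
  expect_identical(st$mean, 0)
  expect_identical(st$se, 0)
  df2 <- data.frame(time = 1:100, vu = 0.042)
  st2 <- axial_velocity_stats(df2, bin_width = 0.01)
  expect_equal(st2$mean, 0.042)
  # histogram integrates to one
  expect_equal(sum(st2$histogram$density) * 0.01, 1)
  expect_identical(st2$n, 80L)  # default 20% burn-in
  expect_error(axial_velocity_stats(data.frame(time = 1, vu = 1),
                                    burnin_frac = 0.999999),
               NA)  # single sample still averages
})

test_that("radial profiles equal hand-computed densities", {
  # 8 particles at radii filling two bins; one frame
  r <- c(1.2, 1.3, 1.4, 1.6, 1.7, 1.8, 1.9, 2.4)
  dir <- rbind(diag(3), -diag(3), c(1, 1, 1) / sqrt(3), c(1, -1, 0) / sqrt(2))
  fr <- make_frame(dir * r, rep("A", 8))
  prof <- radial_concentration_profile(list(fr), "A", box = c(30, 30, 30),
                                       breaks = c(1, 1.5, 2, 2.5))
  vol <- 4 / 3 * pi * diff(c(1, 1.5, 2, 2.5)^3)
  expect_equal(prof$count, c(3, 4, 1))
  expect_equal(prof$density, c(3, 4, 1) / vol)

  # catalytic sector: theta measured from -u, so points with z < 0
  prof_cat <- radial_concentration_profile(list(fr), "A", box = c(30, 30, 30),
                                           breaks = c(1, 2.5),
                                           sector = "catalytic")
  n_cat <- sum(dir[, 3] < 0)
  expect_equal(prof_cat$count, n_cat)
  expect_equal(prof_cat$density,
               n_cat / (4 / 3 * pi * (2.5^3 - 1^3) * 0.5))

  # species absent from the frame: identically zero
  profB <- radial_concentration_profile(list(fr), "B", box = c(30, 30, 30),
                                        breaks = c(1, 2, 3))
  expect_true(all(profB$count == 0) && all(profB$density == 0))
})

test_that("a uniform ideal gas gives a flat radial profile at bulk density", {
  set.seed(31)
  L <- 20; n <- 40000
  fr <- make_frame(matrix(runif(3 * n, 0, L), ncol = 3), rep("A", n),
                   center = c(L / 2, L / 2, L / 2))
  breaks <- seq(1, 5, by = 1)
  prof <- radial_concentration_profile(list(fr), "A", box = c(L, L, L),
                                       breaks = breaks)
  rho <- n / L^3
  vol <- 4 / 3 * pi * diff(breaks^3)
  se <- sqrt(rho * vol) / vol   # Poisson counting error
  expect_true(all(abs(prof$density - rho) < 3.5 * se))
})

test_that("angular profiles respect the -u polar convention", {
  # single particle exactly on the -u axis falls in the theta = 0 bin
  fr <- make_frame(c(0, 0, -3.3), "I")
  prof <- angular_concentration_profile(list(fr), "I", shell = c(3.2, 3.5),
                                        box = c(30, 30, 30), n_bins = 6)
  expect_equal(prof$count, c(1, 0, 0, 0, 0, 0))

  # hand-built set at known angles: bin counts match a hand count
  ct <- c(0.95, 0.9, 0.2, -0.2, -0.9, -0.95, -0.99)  # cos(theta) values
  st <- sqrt(1 - ct^2)
  pos <- 3.35 * cbind(st, 0, -ct)   # theta measured from -u = (0,0,-1)
  fr2 <- make_frame(pos, rep("A", 7))
  prof2 <- angular_concentration_profile(list(fr2), "A", shell = c(3.2, 3.5),
                                         box = c(30, 30, 30), n_bins = 4)
  # equal-cos bins: edges at cos = 1, .5, 0, -.5, -1
  expect_equal(prof2$count, c(2, 1, 1, 3))
  vol <- 2 * pi * (3.5^3 - 3.2^3) / 3 * 0.5
  expect_equal(prof2$density, c(2, 1, 1, 3) / vol)
  expect_error(angular_concentration_profile(list(fr2), "B",
                                             shell = c(3.2, 3.5),
                                             box = c(30, 30, 30)),
               "insufficient")
})

test_that("uniform gas angular profile is flat by construction", {
  set.seed(32)
  n <- 60000
  fr <- make_frame(matrix(runif(3 * n, -6, 6), ncol = 3), rep("A", n))
  prof <- angular_concentration_profile(list(fr), "A", shell = c(3, 4),
                                        box = c(30, 30, 30), n_bins = 8)
  expect_lt(max(abs(prof$density / mean(prof$density) - 1)), 0.15)
})

test_that("flow fields subtract the motor frame and average by hand", {
  set.seed(33)
  n <- 5000
  pos <- matrix(runif(3 * n, -5, 5), ncol = 3)
  # solvent co-moving with the motor: zero field everywhere sampled
  w <- c(0.1, -0.2, 0.05)
  fr <- make_frame(pos, rep("A", n), vel = matrix(w, n, 3, byrow = TRUE),
                   vcom = w)
  ff <- flow_field_map(list(fr), r_edges = seq(1, 5, 1),
                       theta_edges = seq(0, pi, length.out = 5),
                       box = c(30, 30, 30))
  expect_lt(max(abs(ff$v_axial), na.rm = TRUE), 1e-13)
  expect_lt(max(abs(ff$v_radial), na.rm = TRUE), 1e-13)

  # static motor, uniform drift along +u: axial component is |w| everywhere
  fr2 <- make_frame(pos, rep("A", n),
                    vel = matrix(c(0, 0, 0.3), n, 3, byrow = TRUE),
                    vcom = c(0, 0, 0))
  ff2 <- flow_field_map(list(fr2), r_edges = seq(1, 5, 1),
                        theta_edges = seq(0, pi, length.out = 5),
                        box = c(30, 30, 30))
  expect_equal(ff2$v_axial[ff2$n_samples > 0],
               rep(0.3, sum(ff2$n_samples > 0)), tolerance = 1e-12)

  # two-frame hand oracle on a single cell
  fa <- make_frame(c(2, 0, 0), "A", vel = c(0.4, 0, 0.1), vcom = c(0, 0, 0))
  fb <- make_frame(c(2.2, 0, 0), "A", vel = c(0.2, 0, 0.3),
                   vcom = c(0.1, 0, 0.1))
  ff3 <- flow_field_map(list(fa, fb), r_edges = c(1.5, 2.5),
                        theta_edges = c(1.5, 1.65),
                        box = c(30, 30, 30))
  # both samples lie at theta = pi/2; motor-frame velocities are
  # (0.4,0,0.1) and (0.1,0,0.2); axial = v_z, radial = v_x
  expect_identical(ff3$n_samples, 2L)
  expect_equal(ff3$v_axial, (0.1 + 0.2) / 2)
  expect_equal(ff3$v_radial, (0.4 + 0.1) / 2)
  # unvisited cells are missing, not zero
  ff4 <- flow_field_map(list(fa), r_edges = c(3, 4), theta_edges = c(0, 0.5),
                        box = c(30, 30, 30))
  expect_true(is.na(ff4$v_axial))
})

test_that("power-law fit recovers exact and noisy synthetic sweeps", {
  phi <- seq(0, 1, by = 0.1)
  f <- fit_power_law(phi, 0.01 * phi^4 + 0.0029)
  expect_equal(f$A, 0.01, tolerance = 1e-10)
  expect_equal(f$Vu0, 0.0029, tolerance = 1e-10)
  expect_equal(f$exponent_free, 4, tolerance = 1e-8)

  # constant data: zero amplitude, baseline equals the constant
  fc <- fit_power_law(phi, rep(0.005, 11))
  expect_equal(fc$A, 0)
  expect_equal(fc$Vu0, 0.005)

  expect_error(fit_power_law(c(0.5, 0.5, 0.5, 0.5), 1:4), "distinct")

  # Monte-Carlo exponent recovery under 5% noise
  set.seed(41)
  A <- 0.01; v0 <- 0.0029
  ex <- replicate(100, {
    vu <- A * phi^4 + v0 + rnorm(11, sd = 0.05 * A)
    fit_power_law(phi, vu)$exponent_free
  })
  expect_lt(abs(mean(ex, na.rm = TRUE) - 4), 0.3)
})

test_that("amplitude-radius line recovers its generating constants", {
  r2 <- c(3.95, 4.2, 4.35)
  f <- fit_amplitude_vs_R2(r2, 5.05e-2 - 0.98e-2 * r2)
  expect_equal(f$a, 5.05e-2, tolerance = 1e-12)
  expect_equal(f$b, 0.98e-2, tolerance = 1e-12)
  # two points: exact interpolation
  f2 <- fit_amplitude_vs_R2(c(4, 4.4), c(0.012, 0.008))
  expect_equal(f2$a, 0.012 + 0.01 * 4, tolerance = 1e-12)
  expect_equal(f2$b, 0.01, tolerance = 1e-12)
  # flat line: zero decay slope
  f3 <- fit_amplitude_vs_R2(c(3.9, 4.2, 4.5), rep(0.01, 3))
  expect_equal(f3$b, 0)
  expect_error(fit_amplitude_vs_R2(c(4, 4), c(1, 2)), "distinct")
})

test_that("radial profiles close the books on particle counts", {
  run <- cached("run_tiny_short", {
    cfg <- make_fixture_scenario("tiny", phi = 0.5, seed = 8, total_time = 5)
    run_simulation(cfg)
  })
  run$config$snapshot_stride <- 1L
  run2 <- run_simulation(run$config, n_cycles = 4)
  # bins out to the maximum minimum-image distance catch every particle
  breaks <- seq(0, sqrt(3) * 6.001, length.out = 25)
  total <- 0
  for (sp in c("A", "I", "B")) {
    prof <- radial_concentration_profile(run2, sp, breaks = breaks)
    total <- total + sum(prof$count)
  }
  expect_equal(total, length(run2$snapshots) * run2$manifest$n_solvent)
})
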