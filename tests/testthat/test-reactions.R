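rc1 <- 2^(1 / 6) * 0.3
rc2 <- 2^(1 / 6) * 0.2

test_that("surface rules are species- and enzyme-specific", {
  # A inside an E1 cutoff (fresh crossing) is committed; the flip lands once
  # the particle is outside every cutoff, with velocity untouched
  sys <- fake_system(c(10, 10, 10), "E1",
                     c(10 + rc1 + 0.05, 10, 10), "A",
                     solvent_vel = c(-0.1, 0.02, 0))
  sys$solvent$pos[1, 1] <- 10 + rc1 - 0.01   # moved inside the cutoff
  s1 <- surface_reaction_step(sys)
  expect_identical(unname(s1$counters["rxn1"]), 1)
  expect_identical(solvent_species(s1), "A")  # still inside: flip pending
  expect_equal(s1$solvent$vel, sys$solvent$vel)
  s1$solvent$pos[1, 1] <- 10 + rc1 + 0.2      # left the cutoff
  s2 <- surface_reaction_step(s1)
  expect_identical(solvent_species(s2), "I")
  expect_equal(s2$solvent$vel, sys$solvent$vel)
  expect_identical(unname(s2$counters["rxn1"]), 1)  # one flip per crossing

  # I near E1 does not react; B near anything does not react
  for (sp in c("I", "B")) {
    sysx <- fake_system(c(10, 10, 10), "E1", c(10 + rc1 + 0.05, 10, 10), sp)
    sysx$solvent$pos[1, 1] <- 10 + rc1 - 0.01
    sx <- surface_reaction_step(sysx)
    sx$solvent$pos[1, 1] <- 12
    sx <- surface_reaction_step(sx)
    expect_identical(solvent_species(sx), sp)
    expect_identical(unname(sx$counters["rxn1"] + sx$counters["rxn2"]), 0)
  }

  # A is not E2's substrate; I at E2 becomes B
  sysa <- fake_system(c(10, 10, 10), "E2", c(10 + rc2 + 0.05, 10, 10), "A")
  sysa$solvent$pos[1, 1] <- 10 + rc2 - 0.01
  sa <- surface_reaction_step(sysa)
  sa$solvent$pos[1, 1] <- 12
  sa <- surface_reaction_step(sa)
  expect_identical(solvent_species(sa), "A")

  sysi <- fake_system(c(10, 10, 10), "E2", c(10 + rc2 + 0.05, 10, 10), "I")
  sysi$solvent$pos[1, 1] <- 10 + rc2 - 0.01
  si <- surface_reaction_step(sysi)
  si$solvent$pos[1, 1] <- 12
  si <- surface_reaction_step(si)
  expect_identical(solvent_species(si), "B")
  expect_identical(unname(si$counters["rxn2"]), 1)
})

test_that("a particle resident inside a cutoff does not re-react", {
  sys <- fake_system(c(10, 10, 10), "E1", c(10 + rc1 - 0.02, 10, 10), "A")
  # inside at initialisation: the flag is set, so no crossing is seen
  s1 <- surface_reaction_step(sys)
  expect_identical(unname(s1$counters["rxn1"]), 0)
  expect_identical(solvent_species(s1), "A")
})

test_that("bulk regeneration follows the first-order Poisson probability", {
  cfg_args <- list(k_bI = 0, k_bB = 0)
  n <- 4000
  set.seed(14)
  pos <- cbind(runif(n, 0, 20), runif(n, 0, 20), runif(n, 0, 20))
  # keep everything far from the motor at the centre
  far <- sqrt(rowSums(sweep(pos, 2, c(10, 10, 10))^2)) > 6
  pos <- pos[far, ][seq_len(3000), ]
  sys <- fake_system(c(10, 10, 10), "E1", pos, rep("I", 3000),
                     cfg_args = cfg_args)

  # zero rates: identity
  expect_identical(solvent_species(bulk_regeneration_step(sys)),
                   rep("I", 3000))

  # k dt chosen so p = 1 - exp(-0.2): binomial count within 4 sigma
  sys$config$k_bI <- 0.4
  out <- bulk_regeneration_step(sys, dt = 0.5)
  p <- 1 - exp(-0.2)
  conv <- sum(out$solvent$species == 0L)
  expect_lt(abs(conv - 3000 * p), 4 * sqrt(3000 * p * (1 - p)))
  # particle count unchanged
  expect_identical(nrow(out$solvent$pos), 3000L)

  # expected conversions per step at the reference rate: 1000 * (1 - e^-5e-4)
  expect_equal(1000 * (1 - exp(-0.001 * 0.5)), 0.49988, tolerance = 1e-4)
})

test_that("regeneration never fires inside the exclusion zone", {
  sys <- fake_system(c(10, 10, 10), "E1",
                     rbind(c(10.8, 10, 10),    # close to the motor
                           c(18, 18, 18)),     # far away
                     c("I", "I"),
                     cfg_args = list(k_bI = 50))  # p ~ 1 per step
  out <- bulk_regeneration_step(sys, dt = 1)
  expect_identical(solvent_species(out), c("I", "A"))
})

test_that("species bookkeeping closes over a reacting run", {
  cfg <- make_fixture_scenario("tiny", phi = 0.5, seed = 8, total_time = 5)
  run <- cached("run_tiny_short", run_simulation(cfg))
  s <- run$scalars
  n0 <- s$n_A[1] + s$n_I[1] + s$n_B[1]
  expect_true(all(s$n_A + s$n_I + s$n_B == n0))
  expect_identical(n0, run$manifest$n_solvent)
  expect_true(all(diff(s$rxn1_cum) >= 0) && all(diff(s$rxn2_cum) >= 0))

  # no E2 shell: B can never appear
  cfg0 <- make_fixture_scenario("tiny", phi = 0, seed = 8, total_time = 5)
  run0 <- run_simulation(cfg0)
  expect_true(all(run0$scalars$n_B == 0))
  expect_true(all(run0$scalars$rxn2_cum == 0))
})
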