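# System state: motor + solvent + box + clock + RNG streams.

SOLVENT_SPECIES <- c("A", "I", "B")
MOTOR_CLASSES <- c(E0 = 0L, E1 = 1L, E2 = 2L, IN = 3L)

#' Assemble a full simulation state
#'
#' Builds the motor at the box centre, fills the box with fuel (species A)
#' solvent particles at density `ns` placed uniformly outside every bead
#' cutoff, draws Maxwell--Boltzmann velocities at the configured temperature
#' with the total momentum zeroed, and initialises the named RNG substreams.
#'
#' @param config an [simulation_config()] object.
#' @param motor optional pre-built / modified motor (e.g. from
#'   [open_polar_cap()]); built from `config` when `NULL`.
#' @return An object of class `ecr_system`.
#' @export
new_system <- function(config, motor = NULL) {
  config <- validate_config(config)
  if (is.null(motor)) motor <- build_motor(config)
  center <- c(config$Lx, config$Ly, config$Lz) / 2
  motor$pos <- sweep(motor$pos, 2, center, "+")
  streams <- make_streams(config$seed)
  box <- c(config$Lx, config$Ly, config$Lz)

  n <- round(config$ns * prod(box))
  st <- stream_run(streams, "solvent", function() {
    init_solvent(n, box, center, motor, config)
  })
  streams <- st$streams
  solvent <- st$value

  sys <- structure(list(
    motor = motor,
    mvel = matrix(0, nrow(motor$pos), 3),
    solvent = solvent,
    box = box, time = 0,
    config = config, streams = streams,
    counters = c(rxn1 = 0, rxn2 = 0, regen_I = 0, regen_B = 0)
  ), class = "ecr_system")
  fl <- compute_forces(sys)
  sys$solvent$inside1 <- fl$inside1
  sys$solvent$inside2 <- fl$inside2
  sys
}

# rejection-sample n solvent positions outside all bead cutoffs, plus
# Maxwell-Boltzmann velocities with zero net momentum
init_solvent <- function(n, box, center, motor, config) {
  rc1 <- 2^(1 / 6) * config$sigma1
  rc2 <- 2^(1 / 6) * config$sigma2
  e2 <- motor$pos[motor$species == "E2", , drop = FALSE]
  pos <- matrix(numeric(0), 0, 3)
  while (nrow(pos) < n) {
    m <- ceiling((n - nrow(pos)) * 1.4) + 64
    cand <- cbind(stats::runif(m, 0, box[1]), stats::runif(m, 0, box[2]),
                  stats::runif(m, 0, box[3]))
    rel <- sweep(cand, 2, center)
    r <- sqrt(rowSums(rel^2))
    ok <- r > motor$R1 + rc1
    near2 <- ok & abs(r - motor$R2) <= rc2
    if (any(near2) && nrow(e2) > 0) {
      d2 <- outer_dist2(cand[near2, , drop = FALSE], e2)
      ok[near2] <- apply(d2, 1, min) > rc2^2
    }
    pos <- rbind(pos, cand[ok, , drop = FALSE])
  }
  pos <- pos[seq_len(n), , drop = FALSE]
  vel <- matrix(stats::rnorm(3 * n, sd = sqrt(config$temperature / config$ms)),
                ncol = 3)
  vel <- sweep(vel, 2, colMeans(vel))
  list(pos = pos, vel = vel, species = integer(n),  # all fuel A
       inside1 = integer(n), inside2 = integer(n), pending = integer(n))
}

motor_class_codes <- function(motor) {
  unname(MOTOR_CLASSES[motor$species])
}

#' Solvent species labels
#'
#' @param sys an `ecr_system`.
#' @return Character vector of `"A"`, `"I"`, `"B"` per solvent particle.
#' @export
solvent_species <- function(sys) SOLVENT_SPECIES[sys$solvent$species + 1L]

#' Motor centre of mass, axis and velocity
#'
#' @param sys an `ecr_system`.
#' @return List with `com`, `vcom`, `u` and `vu = vcom . u`.
#' @export
motor_state <- function(sys) {
  m <- sys$motor$mass
  com <- colSums(sys$motor$pos * m) / sum(m)
  vcom <- colSums(sys$mvel * m) / sum(m)
  mm <- sys$motor
  mm$pos <- sys$motor$pos
  u <- motor_axis(mm)
  list(com = com, vcom = vcom, u = u, vu = sum(vcom * u))
}

#' Compute all forces of the current state
#'
#' Sums (i) solvent-bead WCA pairs (species-dependent well depth, bead-class
#' size parameter, minimum-image convention, cell-list search) and (ii) all
#' harmonic spring pairs. Solvent-solvent and bead-bead non-bonded forces are
#' identically zero in this model: the solvent couples to itself only through
#' MPC collisions and the spring network maintains the motor geometry.
#'
#' @param sys an `ecr_system`.
#' @return List with `motor` and `solvent` force matrices, potential energies
#'   `pe_wca` and `pe_spring`, and the per-particle cutoff-occupancy flags
#'   `inside1` / `inside2` (inside any E1 / E2 bead cutoff).
#' @export
compute_forces <- function(sys) {
  cfg <- sys$config
  ecr_forces_cpp(sys$motor$pos, sys$motor$mass, sys$motor$sigma,
                 motor_class_codes(sys$motor), sys$motor$springs,
                 sys$motor$r0, cfg$ks, sys$solvent$pos,
                 sys$solvent$species, cfg$eps, sys$box)
}

#' Velocity-Verlet MD steps
#'
#' Advances the coupled motor + solvent system by `n_steps` MD steps of the
#' standard two-half-kick / one-drift velocity-Verlet scheme. Solvent
#' positions are wrapped by the periodic boundaries; motor positions are kept
#' unwrapped so the centre of mass and axis remain well defined. With
#' `reactions = TRUE` the enzyme-cascade species flips are evaluated once per
#' step after the position update.
#'
#' @param sys an `ecr_system`.
#' @param n_steps number of MD steps.
#' @param dt time step (defaults to the configured `t_md`).
#' @param reactions evaluate surface reactions each step?
#' @param log_every record energies/momentum every this many steps into the
#'   `elog` attribute (0 = off; columns step, ke, pe_wca, pe_spring, px, py,
#'   pz).
#' @return The advanced `ecr_system`; diagnostics in attributes `elog`,
#'   `pe`, `ke`.
#' @export
velocity_verlet_step <- function(sys, n_steps = 1L, dt = NULL,
                                 reactions = TRUE, log_every = 0L) {
  cfg <- sys$config
  if (is.null(dt)) dt <- cfg$t_md
  stopifnot(dt > 0)
  seed <- 1
  if (reactions && cfg$react_prob < 1) {
    st <- stream_run(sys$streams, "react",
                     function() sample.int(.Machine$integer.max, 1))
    sys$streams <- st$streams
    seed <- st$value
  }
  out <- ecr_md_cycle_cpp(sys$motor$pos, sys$mvel, sys$motor$mass,
                          sys$motor$sigma, motor_class_codes(sys$motor),
                          sys$motor$springs, sys$motor$r0, cfg$ks,
                          sys$solvent$pos, sys$solvent$vel,
                          sys$solvent$species, cfg$ms,
                          sys$solvent$inside1, sys$solvent$inside2,
                          sys$solvent$pending,
                          cfg$eps, sys$box, dt, as.integer(n_steps),
                          reactions, cfg$react_prob, seed,
                          as.integer(log_every))
  sys$motor$pos <- out$mpos
  sys$mvel <- out$mvel
  sys$solvent$pos <- out$spos
  sys$solvent$vel <- out$svel
  sys$solvent$species <- out$sspec
  sys$solvent$inside1 <- out$inside1
  sys$solvent$inside2 <- out$inside2
  sys$solvent$pending <- out$pending
  sys$time <- sys$time + n_steps * dt
  sys$counters["rxn1"] <- sys$counters["rxn1"] + out$n_rxn1
  sys$counters["rxn2"] <- sys$counters["rxn2"] + out$n_rxn2
  attr(sys, "elog") <- out$elog
  attr(sys, "pe") <- out$pe
  attr(sys, "ke") <- out$ke
  sys
}

#' Surface enzyme-cascade reaction step
#'
#' Applies the two surface rules to the current positions: a fuel particle A
#' newly entering the cutoff of a catalytic E1 bead is committed to become
#' intermediate I, and an intermediate I newly entering the cutoff of an E2
#' bead to become product B (E1 rule before E2, so a single pass can chain
#' A -> I -> B only when both crossings genuinely occurred). The committed
#' species flip materialises as soon as the particle sits outside every bead
#' cutoff, where the pair potential is exactly zero for both the old and new
#' species -- so the reactions conserve energy and momentum to machine
#' precision. Particle count, positions and velocities are never altered; a
#' particle inside a cutoff does not react again until it leaves and
#' re-enters.
#'
#' @param sys an `ecr_system`.
#' @return The updated `ecr_system`; reaction counts accumulate in
#'   `sys$counters`.
#' @export
surface_reaction_step <- function(sys) {
  cfg <- sys$config
  seed <- 1
  if (cfg$react_prob < 1) {
    st <- stream_run(sys$streams, "react",
                     function() sample.int(.Machine$integer.max, 1))
    sys$streams <- st$streams
    seed <- st$value
  }
  out <- ecr_surface_reaction_cpp(sys$motor$pos, sys$mvel, sys$motor$mass,
                                  sys$motor$sigma,
                                  motor_class_codes(sys$motor),
                                  sys$motor$springs, sys$motor$r0, cfg$ks,
                                  sys$solvent$pos, sys$solvent$vel,
                                  sys$solvent$species, cfg$ms,
                                  sys$solvent$inside1, sys$solvent$inside2,
                                  sys$solvent$pending,
                                  cfg$eps, sys$box, cfg$react_prob, seed)
  sys$mvel <- out$mvel
  sys$solvent$vel <- out$svel
  sys$solvent$species <- out$sspec
  sys$solvent$inside1 <- out$inside1
  sys$solvent$inside2 <- out$inside2
  sys$solvent$pending <- out$pending
  sys$counters["rxn1"] <- sys$counters["rxn1"] + out$n_rxn1
  sys$counters["rxn2"] <- sys$counters["rxn2"] + out$n_rxn2
  sys
}

#' Bulk fuel-regeneration step
#'
#' Far from the motor, intermediate (I) and product (B) particles convert
#' back to fuel (A) independently with first-order probabilities
#' `1 - exp(-k * dt)`, sustaining the nonequilibrium steady state. Particles
#' within the exclusion radius of the motor centre never convert, so a flip
#' can only happen at zero pair potential and total energy is conserved
#' exactly.
#'
#' @param sys an `ecr_system`.
#' @param dt elapsed time for the conversion probabilities (defaults to the
#'   configured MPC interval).
#' @return The updated `ecr_system`.
#' @export
bulk_regeneration_step <- function(sys, dt = NULL) {
  cfg <- sys$config
  if (is.null(dt)) dt <- cfg$t_mpc
  if (cfg$k_bI == 0 && cfg$k_bB == 0) return(sys)
  ms <- motor_state(sys)
  rel <- sweep(sys$solvent$pos, 2, ms$com)
  rel <- rel - sweep(round(sweep(rel, 2, sys$box, "/")), 2, sys$box, "*")
  far <- rowSums(rel^2) > cfg$excl_radius^2
  spec <- sys$solvent$species
  idx_i <- which(far & spec == 1L)
  idx_b <- which(far & spec == 2L)
  st <- stream_run(sys$streams, "react", function() {
    list(ui = stats::runif(length(idx_i)), ub = stats::runif(length(idx_b)))
  })
  sys$streams <- st$streams
  flip_i <- idx_i[st$value$ui < 1 - exp(-cfg$k_bI * dt)]
  flip_b <- idx_b[st$value$ub < 1 - exp(-cfg$k_bB * dt)]
  spec[flip_i] <- 0L
  spec[flip_b] <- 0L
  sys$solvent$species <- spec
  sys$counters["regen_I"] <- sys$counters["regen_I"] + length(flip_i)
  sys$counters["regen_B"] <- sys$counters["regen_B"] + length(flip_b)
  sys
}

#' MPC collision step for the embedded-motor system
#'
#' Draws a fresh grid shift and per-cell rotation axes from the MPC stream
#' and applies the stochastic-rotation collision to the solvent particles.
#' Motor beads and internal particles are excluded from the collision cells;
#' the solvent-motor coupling is solely the MD (WCA) interaction.
#'
#' @param sys an `ecr_system`.
#' @return The updated `ecr_system`.
#' @export
mpc_step <- function(sys) {
  cfg <- sys$config
  st <- stream_run(sys$streams, "mpc", function() {
    shift <- stats::runif(3, -cfg$a0 / 2, cfg$a0 / 2)
    cells <- assign_cells(sys$solvent$pos, shift, cfg$a0, sys$box)
    list(vel = mpc_collision_step(sys$solvent$vel, cells, cfg$rot_angle))
  })
  sys$streams <- st$streams
  sys$solvent$vel <- st$value$vel
  sys
}

#' @export
print.ecr_system <- function(x, ...) {
  ns <- table(factor(solvent_species(x), levels = SOLVENT_SPECIES))
  cat("MD-MPC system state\n")
  cat(sprintf("  t = %.3f, box %g x %g x %g\n", x$time,
              x$box[1], x$box[2], x$box[3]))
  cat(sprintf("  solvent: %d particles (A: %d, I: %d, B: %d)\n",
              nrow(x$solvent$pos), ns[["A"]], ns[["I"]], ns[["B"]]))
  cat(sprintf("  motor: %d beads + %d internal, phi = %.3f\n",
              x$motor$NE0 + x$motor$NE1 + x$motor$NE2, x$motor$Nin,
              x$motor$phi))
  cat(sprintf("  cumulative reactions: E1 %d, E2 %d; regenerated %d\n",
              as.integer(x$counters["rxn1"]), as.integer(x$counters["rxn2"]),
              as.integer(x$counters["regen_I"] + x$counters["regen_B"])))
  invisible(x)
}
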