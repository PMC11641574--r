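# Shared test fixtures: hand-buildable systems, an independent brute-force
# force oracle, and a per-file cache for expensive runs.

.ecr_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .ecr_cache)) assign(key, force(expr), .ecr_cache)
  get(key, envir = .ecr_cache)
}

# minimal hand-built system: explicit bead positions/species and solvent
# positions/species, no springs unless given
fake_system <- function(bead_pos, bead_species, solvent_pos, solvent_species,
                        box = c(20, 20, 20), springs = NULL, r0 = NULL,
                        solvent_vel = NULL, cfg_args = list()) {
  cfg <- do.call(simulation_config,
                 utils::modifyList(list(Lx = box[1], Ly = box[2], Lz = box[3],
                                        total_time = 1), cfg_args))
  bead_pos <- matrix(bead_pos, ncol = 3)
  nb <- nrow(bead_pos)
  sigma <- ifelse(bead_species == "E2", cfg$sigma2,
                  ifelse(bead_species == "IN", 0, cfg$sigma1))
  mass <- ifelse(bead_species == "E2", cfg$m2,
                 ifelse(bead_species == "IN", cfg$m_in, cfg$m_out))
  motor <- structure(list(
    pos = bead_pos, species = bead_species, mass = mass, sigma = sigma,
    springs = if (is.null(springs)) matrix(integer(0), 0, 2) else springs,
    r0 = if (is.null(r0)) numeric(0) else r0,
    NE0 = sum(bead_species == "E0"), NE1 = sum(bead_species == "E1"),
    NE2 = sum(bead_species == "E2"), Nin = sum(bead_species == "IN"),
    R1 = cfg$R1, R2 = cfg$R2, sigma1 = cfg$sigma1, sigma2 = cfg$sigma2,
    phi = 0, M = sum(mass)), class = "ecr_motor")
  solvent_pos <- matrix(solvent_pos, ncol = 3)
  n <- nrow(solvent_pos)
  solvent_vel <- if (is.null(solvent_vel)) matrix(0, n, 3)
                 else matrix(solvent_vel, ncol = 3)
  sys <- structure(list(
    motor = motor, mvel = matrix(0, nb, 3),
    solvent = list(pos = solvent_pos, vel = solvent_vel,
                   species = match(solvent_species, c("A", "I", "B")) - 1L,
                   inside1 = integer(n), inside2 = integer(n),
                   pending = integer(n)),
    box = box, time = 0, config = cfg, streams = make_streams_for_test(1L),
    counters = c(rxn1 = 0, rxn2 = 0, regen_I = 0, regen_B = 0)
  ), class = "ecr_system")
  fl <- compute_forces(sys)
  sys$solvent$inside1 <- fl$inside1
  sys$solvent$inside2 <- fl$inside2
  sys
}

make_streams_for_test <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  out <- list()
  for (nm in c("geometry", "solvent", "mpc", "react")) {
    set.seed(seed)
    out[[nm]] <- get(".Random.seed", globalenv())
  }
  out
}

outer_dist2_test <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

# independent O(N^2) double-loop force oracle (no cell list)
bf_forces <- function(sys) {
  cfg <- sys$config
  box <- sys$box
  mpos <- sys$motor$pos
  spos <- sys$solvent$pos
  nm <- nrow(mpos); n <- nrow(spos)
  fm <- matrix(0, nm, 3); fs <- matrix(0, n, 3)
  pe_w <- 0
  for (p in seq_len(n)) {
    for (b in seq_len(nm)) {
      if (sys$motor$species[b] == "IN") next
      d <- spos[p, ] - mpos[b, ]
      d <- d - box * round(d / box)
      r <- sqrt(sum(d^2))
      sig <- sys$motor$sigma[b]
      if (r < 2^(1 / 6) * sig) {
        cls <- match(sys$motor$species[b], c("E0", "E1", "E2"))
        eps <- cfg$eps[sys$solvent$species[p] + 1L, cls]
        pe_w <- pe_w + wca_potential(r, eps, sig)
        f <- wca_force(r, eps, sig) * d / r
        fs[p, ] <- fs[p, ] + f
        fm[b, ] <- fm[b, ] - f
      }
    }
  }
  pe_s <- 0
  sp <- sys$motor$springs
  for (e in seq_len(nrow(sp))) {
    out <- spring_force(mpos[sp[e, 1], ], mpos[sp[e, 2], ], cfg$ks,
                        sys$motor$r0[e])
    fm[sp[e, 1], ] <- fm[sp[e, 1], ] + out$fi
    fm[sp[e, 2], ] <- fm[sp[e, 2], ] + out$fj
    pe_s <- pe_s + out$energy
  }
  list(f_motor = fm, f_solvent = fs, pe_wca = pe_w, pe_spring = pe_s)
}

# random desk-scale mixed state for oracle-equivalence checks
random_fixture_system <- function(seed, n_solvent = 150) {
  set.seed(seed)
  cfg <- make_fixture_scenario("tiny", phi = 0.6, seed = seed)
  motor <- build_motor(cfg)
  keep_in <- which(motor$species == "IN")[seq_len(40)]  # trim internals
  keep <- c(which(motor$species != "IN"), keep_in)
  # rebuild springs among kept only
  ok <- motor$springs[, 1] %in% keep & motor$springs[, 2] %in% keep
  remap <- integer(nrow(motor$pos)); remap[keep] <- seq_along(keep)
  springs <- matrix(remap[motor$springs[ok, ]], ncol = 2)
  center <- c(6, 6, 6)
  bead_pos <- sweep(motor$pos[keep, , drop = FALSE], 2, center, "+")
  # solvent scattered, biased near the motor so many pairs are in range, but
  # never deep inside a bead core (divergent forces would swamp the check)
  spos <- matrix(numeric(0), 0, 3)
  sig <- ifelse(motor$species[keep] == "E2", 0.18, 0.27)
  while (nrow(spos) < n_solvent) {
    r <- runif(2 * n_solvent, 1.2, 4)
    dir <- matrix(rnorm(6 * n_solvent), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    cand <- sweep(dir * r, 2, center, "+")
    d2 <- t(t(outer_dist2_test(cand, bead_pos)) / sig^2)
    spos <- rbind(spos, cand[apply(d2, 1, min) > 1, , drop = FALSE])
  }
  spos <- spos[seq_len(n_solvent), , drop = FALSE]
  fake_system(bead_pos, motor$species[keep], spos,
              sample(c("A", "I", "B"), n_solvent, replace = TRUE),
              box = c(12, 12, 12), springs = springs,
              r0 = motor$r0[ok],
              cfg_args = list(R1 = cfg$R1, R2 = cfg$R2, ns = 5))
}
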