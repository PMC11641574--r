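#' Simulation configuration
#'
#' Build and validate the full parameter set of the hybrid MD--MPC motor
#' simulation. All quantities are in reduced units: energy in units of the
#' Lennard-Jones well depth scale, mass in units of the solvent particle mass,
#' length in units of the MPC cell size, with Boltzmann's constant kB = 1.
#'
#' Defaults are the reference parameter set of the model: a cubic box of side
#' 30 filled with an MPC solvent of number density 20 at temperature 1/6,
#' collision angle pi/2 and collision interval 0.5, coupled every 100 MD steps
#' (dt = 0.005) to a bead-spring Janus sphere (inner shell radius 2.9 with
#' 500 + 500 beads of radius 0.3, 2681 internal mass particles) carrying an
#' outer E2 shell at radius 4.2 with beads of radius 0.2.
#'
#' @param Lx,Ly,Lz box edge lengths.
#' @param ns solvent number density (particles per unit volume).
#' @param ms solvent particle mass.
#' @param temperature system temperature (kB = 1).
#' @param a0 MPC collision cell size.
#' @param t_mpc MPC collision interval; must equal `n_md * t_md`.
#' @param rot_angle MPC rotation angle (radians).
#' @param t_md MD time step.
#' @param n_md number of MD steps between consecutive MPC collisions.
#' @param ks harmonic spring constant of the motor's bead-spring network.
#' @param R1 radius of the inner bead shell.
#' @param sigma1 LJ size parameter of E0/E1 beads.
#' @param NE0,NE1 number of inert (E0) and catalytic (E1) beads.
#' @param Nin number of internal mass particles.
#' @param m_in,m_out,m2 masses of internal particles, E0/E1 beads, E2 beads.
#' @param R2 radius of the outer E2 shell.
#' @param sigma2 LJ size parameter of E2 beads.
#' @param phi E2 surface coverage fraction in `[0, 1]`.
#' @param eps 3 x 3 interaction well-depth matrix, rows = solvent species
#'   (A, I, B), columns = bead species (E0, E1, E2).
#' @param k_bI,k_bB bulk regeneration rate constants for I -> A and B -> A.
#' @param react_prob probability that a surface reaction fires on an inward
#'   cutoff crossing (1 = always, the reference behaviour).
#' @param excl_radius bulk-regeneration exclusion radius measured from the
#'   motor centre; `NULL` selects `R2 + sigma2 + 2^(1/6) * max(sigma1, sigma2)`
#'   so a species flip can never occur at nonzero pair potential.
#' @param seed master RNG seed; three named substreams (MD initialisation,
#'   MPC shifts/axes, reactions) are derived from it.
#' @param total_time total simulated time per run.
#' @param burnin_frac fraction of the run discarded before time averaging.
#' @param snapshot_stride MPC cycles between stored solvent snapshots
#'   (0 disables snapshots).
#'
#' @return An object of class `ecr_config` (a validated named list).
#' @seealso [make_fixture_scenario()] for desk-scale variants,
#'   [build_motor()], [run_simulation()].
#' @export
#' @examples
#' cfg <- simulation_config(phi = 0.8, total_time = 5)
#' cfg$phi
simulation_config <- function(Lx = 30, Ly = 30, Lz = 30,
                              ns = 20, ms = 1, temperature = 1 / 6,
                              a0 = 1, t_mpc = 0.5, rot_angle = pi / 2,
                              t_md = 0.005, n_md = 100,
                              ks = 60,
                              R1 = 2.9, sigma1 = 0.3, NE0 = 500, NE1 = 500,
                              Nin = 2681,
                              m_in = 0.44, m_out = 1.50, m2 = 0.64,
                              R2 = 4.2, sigma2 = 0.2, phi = 0,
                              eps = default_eps_matrix(),
                              k_bI = 0.001, k_bB = 0.001,
                              react_prob = 1,
                              excl_radius = NULL,
                              seed = 1L,
                              total_time = 50,
                              burnin_frac = 0.2,
                              snapshot_stride = 0L) {
  cfg <- list(Lx = Lx, Ly = Ly, Lz = Lz, ns = ns, ms = ms,
              temperature = temperature, a0 = a0, t_mpc = t_mpc,
              rot_angle = rot_angle, t_md = t_md, n_md = as.integer(n_md),
              ks = ks, R1 = R1, sigma1 = sigma1,
              NE0 = as.integer(NE0), NE1 = as.integer(NE1),
              Nin = as.integer(Nin),
              m_in = m_in, m_out = m_out, m2 = m2,
              R2 = R2, sigma2 = sigma2, phi = phi, eps = eps,
              k_bI = k_bI, k_bB = k_bB, react_prob = react_prob,
              excl_radius = excl_radius, seed = as.integer(seed),
              total_time = total_time, burnin_frac = burnin_frac,
              snapshot_stride = as.integer(snapshot_stride))
  class(cfg) <- "ecr_config"
  validate_config(cfg)
}

#' Default interaction well-depth matrix
#'
#' Rows are solvent species (A, I, B), columns bead species (E0, E1, E2).
#' The contrast eps_I,beta = eps_B,E0 = eps_B,E1 = eps_A,E2 = 5.0 >
#' eps_A,E0 = eps_A,E1 = 0.2 > eps_B,E2 = 0.1 is what powers
#' self-diffusiophoresis: products are repelled from the surfaces that make
#' them more strongly than the fuel is.
#'
#' @return A named 3 x 3 numeric matrix.
#' @export
default_eps_matrix <- function() {
  m <- matrix(5.0, 3, 3, dimnames = list(c("A", "I", "B"), c("E0", "E1", "E2")))
  m["A", "E0"] <- 0.2
  m["A", "E1"] <- 0.2
  m["B", "E2"] <- 0.1
  m
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "ecr_config"))
  pos <- c("Lx", "Ly", "Lz", "ns", "ms", "temperature", "a0", "t_mpc",
           "t_md", "ks", "R1", "sigma1", "m_in", "m_out", "m2", "R2",
           "sigma2", "total_time")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      stop("config field '", f, "' must be a positive scalar", call. = FALSE)
    }
  }
  if (cfg$NE0 < 0L || cfg$NE1 < 0L || cfg$Nin < 0L)
    stop("bead/particle counts must be non-negative", call. = FALSE)
  if (!is.numeric(cfg$phi) || cfg$phi < 0 || cfg$phi > 1)
    stop("coverage fraction phi must lie in [0, 1]", call. = FALSE)
  if (cfg$k_bI < 0 || cfg$k_bB < 0)
    stop("regeneration rates must be non-negative", call. = FALSE)
  if (cfg$react_prob < 0 || cfg$react_prob > 1)
    stop("react_prob must lie in [0, 1]", call. = FALSE)
  if (!is.matrix(cfg$eps) || !identical(dim(cfg$eps), c(3L, 3L)) ||
      any(!is.finite(cfg$eps)))
    stop("eps must be a fully populated 3 x 3 numeric matrix", call. = FALSE)
  if (cfg$R2 <= cfg$R1 + cfg$sigma1 + cfg$sigma2)
    stop("outer shell interpenetrates inner shell: need R2 > R1 + sigma1 + sigma2",
         call. = FALSE)
  for (L in c("Lx", "Ly", "Lz")) {
    ncell <- cfg[[L]] / cfg$a0
    if (abs(ncell - round(ncell)) > 1e-9)
      stop("MPC cell size a0 must divide box length ", L, " exactly",
           call. = FALSE)
  }
  if (min(cfg$Lx, cfg$Ly, cfg$Lz) < 4 * (cfg$R2 + cfg$sigma2))
    stop("box too small for minimum-image convention: need box >= 4*(R2 + sigma2)",
         call. = FALSE)
  if (abs(cfg$n_md * cfg$t_md - cfg$t_mpc) > 1e-9)
    stop("t_mpc must equal n_md * t_md", call. = FALSE)
  if (cfg$rot_angle <= 0 || cfg$rot_angle >= 2 * pi)
    stop("rotation angle must lie in (0, 2*pi)", call. = FALSE)
  if (cfg$burnin_frac < 0 || cfg$burnin_frac >= 1)
    stop("burnin_frac must lie in [0, 1)", call. = FALSE)
  if (is.null(cfg$excl_radius)) {
    cfg$excl_radius <- cfg$R2 + cfg$sigma2 +
      2^(1 / 6) * max(cfg$sigma1, cfg$sigma2)
  }
  cfg
}

#' Desk-scale fixture scenarios
#'
#' Scaled-down configurations that run the complete MD--MPC--reaction loop in
#' seconds ("tiny") or minutes ("small") while keeping every physical constant
#' (temperature, masses, interaction matrix, time steps, spring constant) at
#' its reference value. The motor geometry is shrunk together with the box so
#' that the minimum-image requirement box >= 4*(R2 + sigma2) holds and the
#' areal bead density on the shells matches the full-scale motor.
#'
#' @param scale `"tiny"` (box 12^3, ns = 5, ~8640 solvent particles) or
#'   `"small"` (box 16^3, ns = 10, ~40960 solvent particles).
#' @param ... overrides passed on to [simulation_config()] (e.g. `phi`,
#'   `seed`, `total_time`).
#' @return An `ecr_config`.
#' @export
#' @examples
#' cfg <- make_fixture_scenario("tiny", phi = 0.5)
#' round(cfg$ns * cfg$Lx * cfg$Ly * cfg$Lz)  # solvent particle count
make_fixture_scenario <- function(scale = c("tiny", "small"), ...) {
  scale <- match.arg(scale)
  base <- switch(scale,
    tiny = list(Lx = 12, Ly = 12, Lz = 12, ns = 5,
                R1 = 1.1, R2 = 1.7, NE0 = 80L, NE1 = 80L, Nin = 200L,
                total_time = 25),
    small = list(Lx = 16, Ly = 16, Lz = 16, ns = 10,
                 R1 = 2.0, R2 = 2.9, NE0 = 240L, NE1 = 240L, Nin = 880L,
                 total_time = 50))
  args <- utils::modifyList(base, list(...))
  do.call(simulation_config, args)
}

#' @export
print.ecr_config <- function(x, ...) {
  nsolv <- round(x$ns * x$Lx * x$Ly * x$Lz)
  cat("Hybrid MD-MPC motor simulation configuration\n")
  cat(sprintf("  box %g x %g x %g, solvent density %g (%d particles), T = %.4g\n",
              x$Lx, x$Ly, x$Lz, x$ns, nsolv, x$temperature))
  cat(sprintf("  MPC: a0 = %g, t_mpc = %g, rotation angle = %.4g\n",
              x$a0, x$t_mpc, x$rot_angle))
  cat(sprintf("  MD:  dt = %g, %d steps per MPC collision, ks = %g\n",
              x$t_md, x$n_md, x$ks))
  cat(sprintf("  motor: R1 = %g (NE0 = %d, NE1 = %d, sigma1 = %g), R2 = %g (phi = %g, sigma2 = %g), Nin = %d\n",
              x$R1, x$NE0, x$NE1, x$sigma1, x$R2, x$phi, x$sigma2, x$Nin))
  cat(sprintf("  reactions: surface prob = %g, bulk k_bI = %g, k_bB = %g\n",
              x$react_prob, x$k_bI, x$k_bB))
  cat(sprintf("  run: total_time = %g, burn-in fraction = %g, seed = %d\n",
              x$total_time, x$burnin_frac, x$seed))
  invisible(x)
}

#' Read a configuration from a flat key-value YAML file
#'
#' Keys must be names of [simulation_config()] arguments; unknown keys are an
#' error. The `eps` entry, if present, is a list of three rows (A, I, B) of
#' three values (E0, E1, E2).
#'
#' @param path file path.
#' @return An `ecr_config`.
#' @export
read_config_file <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(vals$eps)) {
    vals$eps <- matrix(unlist(vals$eps), 3, 3, byrow = TRUE,
                       dimnames = list(c("A", "I", "B"), c("E0", "E1", "E2")))
  }
  do.call(simulation_config, vals)
}
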