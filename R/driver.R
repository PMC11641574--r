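#' Run the full hybrid MD--MPC--reaction loop
#'
#' The cycle is: `n_md` velocity-Verlet steps with per-step surface
#' reactions, then one grid-shifted MPC collision, then the bulk
#' regeneration step, repeated until `total_time`. Per-cycle scalars
#' (kinetic temperature, total energy, momentum, motor centre of mass, axial
#' velocity, species census, cumulative reaction counts) are recorded;
#' solvent snapshots are stored every `snapshot_stride` cycles. Runs are
#' bit-reproducible from the configuration seed, including across
#' checkpoint/restart.
#'
#' @param config an [simulation_config()] object.
#' @param motor optional pre-built motor (e.g. from [open_polar_cap()]).
#' @param reactions master switch for the surface reactions (the bulk
#'   regeneration is inert without them).
#' @param resume a checkpoint (the `$checkpoint` element of a previous
#'   `ecr_run`, possibly read back with [load_checkpoint()]) to continue
#'   from; `config` must match the checkpointed one.
#' @param n_cycles run this many MPC cycles instead of
#'   `total_time / t_mpc` (counted from the checkpoint when resuming).
#' @param progress print a line every 50 cycles.
#' @return An object of class `ecr_run` with elements `scalars` (data
#'   frame), `snapshots` (list), `config`, `manifest` and `checkpoint`.
#' @export
run_simulation <- function(config, motor = NULL, reactions = TRUE,
                           resume = NULL, n_cycles = NULL,
                           progress = FALSE) {
  config <- validate_config(config)
  if (is.null(n_cycles)) n_cycles <- round(config$total_time / config$t_mpc)
  n_cycles <- as.integer(n_cycles)
  if (is.null(resume)) {
    sys <- new_system(config, motor)
    scalars <- list()
    snapshots <- list()
    cycle0 <- 0L
  } else {
    sys <- resume$system
    scalars <- resume$scalars
    snapshots <- resume$snapshots
    cycle0 <- as.integer(resume$cycle)
  }
  t_start <- Sys.time()
  e_ref <- if (is.null(resume) || length(scalars) == 0) NULL
           else scalars[[1]]$e_total
  for (cyc in seq_len(n_cycles - cycle0) + cycle0) {
    sys <- velocity_verlet_step(sys, n_steps = config$n_md,
                                reactions = reactions)
    sys <- mpc_step(sys)
    if (reactions) sys <- bulk_regeneration_step(sys)
    ms <- motor_state(sys)
    ke <- attr(sys, "ke"); pe <- attr(sys, "pe")
    svel <- sys$solvent$vel
    pvec <- colSums(svel) * config$ms + colSums(sys$mvel * sys$motor$mass)
    if (is.null(e_ref)) e_ref <- ke + pe
    if (!is.finite(ke + pe) || abs(ke + pe - e_ref) / abs(e_ref) > 0.02 ||
        max(abs(pvec)) > 1e-6 * sqrt(e_ref)) {
      diag_path <- tempfile("ecrmotor_diag_", fileext = ".rds")
      saveRDS(sys, diag_path)
      stop(sprintf(paste("conservation violation at cycle %d (E = %.6g vs",
                         "%.6g, |P| = %.3g); diagnostic state saved to %s"),
                   cyc, ke + pe, e_ref, max(abs(pvec)), diag_path),
           call. = FALSE)
    }
    census <- tabulate(sys$solvent$species + 1L, nbins = 3L)
    nsv <- nrow(sys$solvent$pos)
    scalars[[length(scalars) + 1L]] <- data.frame(
      cycle = cyc, time = sys$time,
      temp_solvent = sum(svel^2) * config$ms / (3 * nsv),
      ke = ke, pe = pe, e_total = ke + pe,
      px = pvec[1], py = pvec[2], pz = pvec[3],
      com_x = ms$com[1], com_y = ms$com[2], com_z = ms$com[3],
      vu = ms$vu,
      n_A = census[1], n_I = census[2], n_B = census[3],
      rxn1_cum = unname(sys$counters["rxn1"]),
      rxn2_cum = unname(sys$counters["rxn2"]),
      regen_cum = unname(sys$counters["regen_I"] + sys$counters["regen_B"]))
    if (config$snapshot_stride > 0L && cyc %% config$snapshot_stride == 0L) {
      snapshots[[length(snapshots) + 1L]] <- list(
        time = sys$time, pos = sys$solvent$pos, vel = sys$solvent$vel,
        species = sys$solvent$species,
        center = ms$com, u = ms$u, vcom = ms$vcom)
    }
    if (progress && cyc %% 50L == 0L)
      message(sprintf("cycle %d / %d, t = %.1f", cyc, n_cycles, sys$time))
  }
  scalars <- do.call(rbind, scalars)
  structure(list(
    scalars = scalars,
    snapshots = snapshots,
    config = config,
    manifest = list(
      seed = config$seed,
      stream_seeds = derive_stream_seeds(config$seed),
      n_cycles = n_cycles,
      n_solvent = nrow(sys$solvent$pos),
      n_motor = nrow(sys$motor$pos),
      reactions = reactions,
      package_version = as.character(utils::packageVersion("ecrmotor")),
      started = t_start, finished = Sys.time()),
    checkpoint = list(system = sys, scalars = split_rows(scalars),
                      snapshots = snapshots, cycle = n_cycles)
  ), class = "ecr_run")
}

split_rows <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(list())
  lapply(seq_len(nrow(df)), function(i) df[i, , drop = FALSE])
}

#' @export
print.ecr_run <- function(x, ...) {
  cat("MD-MPC motor run\n")
  cat(sprintf("  %d MPC cycles, final t = %.2f, %d solvent particles\n",
              nrow(x$scalars), max(x$scalars$time), x$manifest$n_solvent))
  stats <- axial_velocity_stats(x)
  cat(sprintf("  mean Vu (post burn-in) = %.5f +/- %.5f\n",
              stats$mean, stats$se))
  cat(sprintf("  final census A/I/B: %d / %d / %d\n",
              utils::tail(x$scalars$n_A, 1), utils::tail(x$scalars$n_I, 1),
              utils::tail(x$scalars$n_B, 1)))
  invisible(x)
}

#' Save / load a run checkpoint
#'
#' The checkpoint carries the complete system state including the RNG
#' substreams, so a resumed run reproduces an uninterrupted one bit-exactly.
#'
#' @param checkpoint the `$checkpoint` element of an `ecr_run`.
#' @param path file path.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   the checkpoint object.
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Write the per-cycle scalar log as CSV
#'
#' @param run an `ecr_run`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scalar_log <- function(run, path) {
  utils::write.csv(run$scalars, path, row.names = FALSE)
  invisible(path)
}

#' Write a solvent + motor snapshot as extended XYZ
#'
#' @param run an `ecr_run` with stored snapshots.
#' @param frame snapshot index.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snapshot_xyz <- function(run, frame, path) {
  fr <- run$snapshots[[frame]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(fr$pos)), con)
  writeLines(sprintf("time=%.4f center=%.4f,%.4f,%.4f", fr$time,
                     fr$center[1], fr$center[2], fr$center[3]), con)
  writeLines(sprintf("%s %.6f %.6f %.6f %.6f %.6f %.6f",
                     SOLVENT_SPECIES[fr$species + 1L],
                     fr$pos[, 1], fr$pos[, 2], fr$pos[, 3],
                     fr$vel[, 1], fr$vel[, 2], fr$vel[, 3]), con)
  invisible(path)
}

#' Coverage / outer-radius parameter sweep
#'
#' Runs (or delegates to `runner`) one simulation per (R2, phi, seed) grid
#' point and collects the post-burn-in mean axial velocity, the input to
#' [fit_power_law()] and [fit_amplitude_vs_R2()]. Failed runs are recorded
#' with `status = "error"` and the sweep continues.
#'
#' @param template an [simulation_config()] used for every point.
#' @param phi_values coverage fractions.
#' @param R2_values outer shell radii (default: the template's).
#' @param seeds one run per seed per grid point.
#' @param runner optional function `config -> mean Vu` replacing the full
#'   simulation (testing hook / injected backend).
#' @return A data frame with columns `R2`, `phi`, `seed`, `mean_vu`,
#'   `se_vu`, `status`.
#' @export
sweep_coverage <- function(template, phi_values, R2_values = NULL,
                           seeds = 1L, runner = NULL) {
  stopifnot(length(phi_values) >= 1)
  if (is.null(R2_values)) R2_values <- template$R2
  grid <- expand.grid(seed = as.integer(seeds), phi = phi_values,
                      R2 = R2_values)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cfg <- template
    cfg$phi <- g$phi; cfg$R2 <- g$R2; cfg$seed <- g$seed
    out <- tryCatch({
      cfg <- validate_config(cfg)
      if (!is.null(runner)) {
        data.frame(mean_vu = runner(cfg), se_vu = NA_real_, status = "ok")
      } else {
        run <- run_simulation(cfg)
        st <- axial_velocity_stats(run)
        data.frame(mean_vu = st$mean, se_vu = st$se, status = "ok")
      }
    }, error = function(e) {
      data.frame(mean_vu = NA_real_, se_vu = NA_real_,
                 status = paste("error:", conditionMessage(e)))
    })
    cbind(data.frame(R2 = g$R2, phi = g$phi, seed = g$seed), out)
  })
  do.call(rbind, rows)
}
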