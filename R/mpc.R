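#' Assign particles to MPC collision cells
#'
#' Cells are the cubic lattice of side `a0` shifted by `shift` (grid shifting
#' restores Galilean invariance at small mean free path), with periodic wrap.
#' The index is `floor((position + shift) / a0)` per axis, combined into a
#' single 1-based cell id.
#'
#' @param pos `n x 3` positions.
#' @param shift length-3 grid shift vector.
#' @param a0 cell size; must divide each box length exactly.
#' @param box length-3 box edge lengths.
#' @return Integer vector of cell ids in `1..prod(box/a0)`.
#' @export
assign_cells <- function(pos, shift, a0, box) {
  ncell <- round(box / a0)
  if (any(abs(box / a0 - ncell) > 1e-9))
    stop("a0 must divide each box length exactly", call. = FALSE)
  ix <- floor((pos[, 1] + shift[1]) / a0) %% ncell[1]
  iy <- floor((pos[, 2] + shift[2]) / a0) %% ncell[2]
  iz <- floor((pos[, 3] + shift[3]) / a0) %% ncell[3]
  as.integer(1 + ix + ncell[1] * (iy + ncell[2] * iz))
}

#' Stochastic-rotation (MPC) collision step
#'
#' Within each occupied cell the particle velocities relative to the cell
#' centre-of-mass velocity are rotated by a fixed angle about an independent
#' random unit axis (Rodrigues' formula). Per-cell momentum and kinetic
#' energy are conserved exactly; cells holding a single particle are
#' unchanged. All particles are assumed to carry equal mass.
#'
#' @param vel `n x 3` velocities.
#' @param cells integer cell ids from [assign_cells()].
#' @param rot_angle rotation angle (radians).
#' @param axes optional matrix of unit rotation axes, one row per *distinct*
#'   cell id in sorted order; drawn uniformly on the sphere from the current
#'   RNG stream when `NULL`.
#' @return The post-collision `n x 3` velocity matrix.
#' @export
mpc_collision_step <- function(vel, cells, rot_angle, axes = NULL) {
  uc <- sort(unique(cells))
  m <- match(cells, uc)
  cnt <- tabulate(m, nbins = length(uc))
  vcm <- rowsum(vel, m) / cnt
  dv <- vel - vcm[m, , drop = FALSE]
  if (is.null(axes)) {
    axes <- matrix(stats::rnorm(3 * length(uc)), ncol = 3)
    axes <- axes / sqrt(rowSums(axes^2))
  }
  k <- axes[m, , drop = FALSE]
  kd <- rowSums(k * dv)
  kx <- cbind(k[, 2] * dv[, 3] - k[, 3] * dv[, 2],
              k[, 3] * dv[, 1] - k[, 1] * dv[, 3],
              k[, 1] * dv[, 2] - k[, 2] * dv[, 1])
  ca <- cos(rot_angle); sa <- sin(rot_angle)
  out <- vcm[m, , drop = FALSE] + ca * dv + sa * kx + (1 - ca) * k * kd
  dimnames(out) <- NULL
  out
}

#' Pure-solvent MPC run and measured self-diffusion
#'
#' Evolves a periodic box of MPC solvent (ballistic streaming alternated with
#' grid-shifted stochastic-rotation collisions, no embedded motor) and
#' measures the self-diffusion coefficient from the slope of the
#' mean-squared displacement, for comparison with
#' [analytic_diffusion_coefficient()].
#'
#' @param ns solvent number density.
#' @param box length-3 box edge lengths.
#' @param temperature system temperature.
#' @param t_mpc collision interval.
#' @param rot_angle rotation angle.
#' @param ms particle mass.
#' @param a0 cell size.
#' @param n_steps number of MPC steps after equilibration.
#' @param n_equil equilibration MPC steps before the MSD origin.
#' @param seed RNG seed.
#' @return A list with `D_measured`, `D_analytic`, the `msd` data frame
#'   (time, msd) and the final velocity matrix `vel`.
#' @export
measure_diffusion <- function(ns, box = c(12, 12, 12), temperature = 1 / 6,
                              t_mpc = 0.5, rot_angle = pi / 2, ms = 1,
                              a0 = 1, n_steps = 300L, n_equil = 50L,
                              seed = 1L) {
  n <- round(ns * prod(box))
  set.seed(seed)
  pos <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
               stats::runif(n, 0, box[3]))
  vel <- matrix(stats::rnorm(3 * n, sd = sqrt(temperature / ms)), ncol = 3)
  vel <- sweep(vel, 2, colMeans(vel))  # zero total momentum
  step <- function(pos, vel) {
    pos <- pos + vel * t_mpc
    shift <- stats::runif(3, -a0 / 2, a0 / 2)
    wrapped <- sweep(pos, 2, box, "%%")
    cells <- assign_cells(wrapped, shift, a0, box)
    list(pos = pos, vel = mpc_collision_step(vel, cells, rot_angle))
  }
  for (i in seq_len(n_equil)) {
    st <- step(pos, vel); pos <- st$pos; vel <- st$vel
  }
  origin <- pos
  times <- numeric(n_steps); msd <- numeric(n_steps)
  for (i in seq_len(n_steps)) {
    st <- step(pos, vel); pos <- st$pos; vel <- st$vel
    times[i] <- i * t_mpc
    msd[i] <- mean(rowSums((pos - origin)^2))
  }
  # discard the short ballistic transient before fitting MSD = 6 D t + c
  keep <- times > 5 * t_mpc
  fit <- stats::lm(msd[keep] ~ times[keep])
  list(D_measured = unname(stats::coef(fit)[2]) / 6,
       D_analytic = analytic_diffusion_coefficient(temperature, t_mpc, ms,
                                                   ns, rot_angle),
       msd = data.frame(time = times, msd = msd),
       vel = vel)
}
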