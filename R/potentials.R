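#' Repulsive shifted-truncated Lennard-Jones (WCA) interaction
#'
#' V(r) = 4*eps*((sigma/r)^12 - (sigma/r)^6 + 1/4) for r below the cutoff
#' rc = 2^(1/6)*sigma, and exactly 0 beyond it. The potential and its
#' derivative are both continuous at rc (the cutoff sits at the LJ minimum),
#' so the force is purely repulsive and vanishes smoothly at the cutoff.
#'
#' @param r pair distance(s), > 0.
#' @param eps well depth.
#' @param sigma size parameter; the cutoff is `2^(1/6) * sigma`.
#' @return `wca_potential()` the energy; `wca_force()` the radial force
#'   magnitude `-dV/dr` (>= 0), both vectorised over `r`.
#' @export
#' @examples
#' wca_potential(2^(1/6) * 0.3, 5, 0.3)  # zero at the cutoff
#' wca_potential(0.3, 5, 0.3)            # 4*eps/4 = eps at r = sigma
wca_potential <- function(r, eps, sigma) {
  if (any(r <= 0)) stop("overlap: pair distance must be positive", call. = FALSE)
  rc <- 2^(1 / 6) * sigma
  s6 <- (sigma / r)^6
  ifelse(r < rc, 4 * eps * (s6^2 - s6 + 0.25), 0)
}

#' @rdname wca_potential
#' @export
wca_force <- function(r, eps, sigma) {
  if (any(r <= 0)) stop("overlap: pair distance must be positive", call. = FALSE)
  rc <- 2^(1 / 6) * sigma
  s6 <- (sigma / r)^6
  ifelse(r < rc, 24 * eps * (2 * s6^2 - s6) / r, 0)
}

#' Harmonic spring force between two particles
#'
#' U = ks/2 * (r - r0)^2. Forces are equal and opposite along the connecting
#' line with magnitude `ks * |r - r0|`.
#'
#' @param ri,rj positions (length-3 vectors).
#' @param ks spring constant (> 0).
#' @param r0 rest length (>= 0).
#' @return A list with `fi`, `fj` (forces on i and j) and `energy`.
#' @export
spring_force <- function(ri, rj, ks, r0) {
  stopifnot(ks > 0, r0 >= 0)
  d <- ri - rj
  r <- sqrt(sum(d^2))
  if (r == 0 && r0 > 0)
    stop("coincident endpoints: spring direction undefined", call. = FALSE)
  fi <- if (r == 0) c(0, 0, 0) else -ks * (r - r0) * d / r
  list(fi = fi, fj = -fi, energy = 0.5 * ks * (r - r0)^2)
}

#' Analytic MPC solvent self-diffusion coefficient
#'
#' Kinetic-theory (molecular chaos) closed form for stochastic rotation
#' dynamics:
#' D = (kB*T*t_mpc / (2*ms)) * (3*ns / ((ns - 1 + exp(-ns)) * (1 - cos(phi)))
#'     - 1),
#' with `ns` the mean particles per collision cell and `phi` the rotation
#' angle. At the reference solvent parameters (T = 1/6, t_mpc = 0.5, ms = 1,
#' ns = 20, phi = pi/2) this evaluates to 0.0899.
#'
#' @param temperature system temperature (kB = 1).
#' @param t_mpc collision interval.
#' @param ms solvent particle mass.
#' @param ns mean particles per cell (> 1).
#' @param rot_angle rotation angle in (0, 2*pi).
#' @return The diffusion coefficient (cell-size^2 per time unit).
#' @export
#' @examples
#' analytic_diffusion_coefficient(1/6, 0.5, 1, 20, pi/2)
analytic_diffusion_coefficient <- function(temperature, t_mpc, ms, ns,
                                           rot_angle) {
  stopifnot(temperature > 0, t_mpc > 0, ms > 0)
  if (ns <= 1) stop("ns must exceed 1", call. = FALSE)
  if (rot_angle <= 0 || rot_angle >= 2 * pi)
    stop("rotation angle must lie in (0, 2*pi): the collision operator is singular",
         call. = FALSE)
  pref <- temperature * t_mpc / (2 * ms)
  pref * (3 * ns / ((ns - 1 + exp(-ns)) * (1 - cos(rot_angle))) - 1)
}
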