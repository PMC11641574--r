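#' Deterministic quasi-uniform points on a sphere or hemisphere
#'
#' Places `n` points on a spherical shell using a Fibonacci (golden-angle)
#' lattice, which gives near-uniform area coverage deterministically, i.e.
#' independent of any RNG seed. For the hemisphere region the first point sits
#' exactly on the pole and all points satisfy `point . pole >= 0`.
#'
#' @param n number of points (>= 0).
#' @param radius shell radius (> 0).
#' @param region `"sphere"` for the full shell or `"hemisphere"` for the half
#'   shell around `pole`.
#' @param pole pole axis for the hemisphere region (any nonzero vector).
#' @return An `n x 3` matrix of coordinates at distance `radius` from the
#'   origin.
#' @export
#' @examples
#' p <- sample_shell_points(500, 2.9, "hemisphere")
#' range(sqrt(rowSums(p^2)))  # all exactly 2.9
sample_shell_points <- function(n, radius,
                                region = c("sphere", "hemisphere"),
                                pole = c(0, 0, 1)) {
  region <- match.arg(region)
  if (length(n) != 1L || is.na(n) || n < 0)
    stop("n must be a non-negative count", call. = FALSE)
  n <- as.integer(n)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  i <- seq_len(n) - 1
  ga <- pi * (3 - sqrt(5))  # golden angle
  if (region == "sphere") {
    z <- 1 - (2 * i + 1) / n
  } else {
    # pole-inclusive ladder: z = 1 at i = 0, strictly positive throughout
    z <- 1 - i / n
  }
  rho <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(rho * cos(i * ga), rho * sin(i * ga), z)
  if (region == "hemisphere" && !isTRUE(all.equal(pole / sqrt(sum(pole^2)),
                                                  c(0, 0, 1)))) {
    pts <- pts %*% t(rotation_to_pole(pole))
  }
  pts * radius
}

# orthonormal rotation carrying +z onto the (normalised) pole axis
rotation_to_pole <- function(pole) {
  w <- pole / sqrt(sum(pole^2))
  seed <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seed - sum(seed * w) * w
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  cbind(u, v, w)
}

#' Convert between E2 coverage fraction and bead count
#'
#' The coverage fraction of the outer shell is defined as
#' `phi = NE2 * (2^(1/6) * sigma2)^2 / (2 * R2^2)`: each E2 bead is assigned
#' the square of its WCA interaction diameter as footprint area, and the shell
#' area is that of a hemisphere of radius `R2` (`2 * pi * R2^2` divided by
#' `pi`). At the reference geometry (`sigma2 = 0.2`, `R2 = 4.2`) full coverage
#' corresponds to 700 beads.
#'
#' @param phi coverage fraction in `[0, 1]`.
#' @param ne2 bead count (non-negative integer).
#' @param sigma2 E2 bead LJ size parameter.
#' @param R2 outer shell radius.
#' @return `ne2_from_phi()` the nearest integer bead count;
#'   `phi_from_ne2()` the exact fraction.
#' @export
ne2_from_phi <- function(phi, sigma2 = 0.2, R2 = 4.2) {
  stopifnot(sigma2 > 0, R2 > 0)
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]", call. = FALSE)
  n <- as.integer(round(phi * 2 * R2^2 / (2^(1 / 6) * sigma2)^2))
  # hexagonal close packing of discs of radius 2^(1/6)*sigma2/2 on the shell
  nmax <- 0.9069 * 2 * R2^2 / ((2^(1 / 6) * sigma2 / 2)^2)
  if (any(n > nmax))
    warning("requested E2 count exceeds geometric packing on the shell")
  n
}

#' @rdname ne2_from_phi
#' @export
phi_from_ne2 <- function(ne2, sigma2 = 0.2, R2 = 4.2) {
  stopifnot(sigma2 > 0, R2 > 0)
  if (any(ne2 < 0)) stop("ne2 must be non-negative", call. = FALSE)
  ne2 * (2^(1 / 6) * sigma2)^2 / (2 * R2^2)
}

#' Build the bead-spring Janus motor
#'
#' Constructs the motor body: an inner shell of radius `R1` carrying `NE0`
#' inert beads (E0) on one hemisphere and `NE1` catalytic beads (E1) on the
#' other, `Nin` internal mass particles distributed uniformly through the
#' interior ball, and an outer hemispherical shell of radius `R2` over the E1
#' side carrying `NE2 = ne2_from_phi(phi)` beads of the second enzyme (E2).
#' Bead placement on the shells is a deterministic Fibonacci lattice;
#' internal particles are sampled from the configuration's geometry RNG
#' stream. All particles are tied into one connected harmonic spring network:
#' each particle is bonded to its 10 nearest neighbours (union over both
#' endpoints, local rigidity) and to the 12 particles nearest its reflection
#' through the centre (near-diametral struts that stiffen the breathing and
#' bending modes a purely local network leaves floppy), and each E2 bead
#' additionally to its 3 nearest inner beads so the outer shell co-moves.
#' Rest lengths equal the build-time separations, so the assembly fluctuates
#' about its build geometry and moves as a nearly rigid body at the reference
#' spring constant.
#'
#' The motor symmetry axis `u` is the unit vector from the centre of mass of
#' the E1 hemisphere to that of the E0 hemisphere; the build aligns it
#' with +z.
#'
#' @param config an [simulation_config()] object.
#' @return An object of class `ecr_motor`.
#' @export
#' @examples
#' m <- build_motor(make_fixture_scenario("tiny", phi = 0.5))
#' m$M  # closed-form total mass
build_motor <- function(config) {
  config <- validate_config(config)
  if (config$R2 <= config$R1 + config$sigma1)
    stop("shells interpenetrate: need R2 > R1 + sigma1", call. = FALSE)
  ne2 <- ne2_from_phi(config$phi, config$sigma2, config$R2)

  p_e0 <- sample_shell_points(config$NE0, config$R1, "hemisphere", c(0, 0, 1))
  p_e1 <- sample_shell_points(config$NE1, config$R1, "hemisphere", c(0, 0, 1))
  p_e1[, 3] <- -p_e1[, 3]  # mirror onto the -z hemisphere
  p_e2 <- sample_shell_points(ne2, config$R2, "hemisphere", c(0, 0, -1))

  seeds <- derive_stream_seeds(config$seed)
  p_in <- with_seed(seeds[["geometry"]], {
    if (config$Nin > 0L) {
      d <- matrix(stats::rnorm(3 * config$Nin), ncol = 3)
      d <- d / sqrt(rowSums(d^2))
      r <- config$R1 * stats::runif(config$Nin)^(1 / 3)
      d * r
    } else matrix(numeric(0), 0, 3)
  })

  pos <- rbind(p_e0, p_e1, p_e2, p_in)
  species <- c(rep("E0", config$NE0), rep("E1", config$NE1),
               rep("E2", ne2), rep("IN", config$Nin))
  mass <- c(rep(config$m_out, config$NE0 + config$NE1),
            rep(config$m2, ne2), rep(config$m_in, config$Nin))
  sigma <- c(rep(config$sigma1, config$NE0 + config$NE1),
             rep(config$sigma2, ne2), rep(0, config$Nin))

  springs <- build_spring_network(pos, species)
  r0 <- sqrt(rowSums((pos[springs[, 1], , drop = FALSE] -
                      pos[springs[, 2], , drop = FALSE])^2))

  motor <- structure(list(
    pos = pos, species = species, mass = mass, sigma = sigma,
    springs = springs, r0 = r0,
    NE0 = config$NE0, NE1 = config$NE1, NE2 = ne2, Nin = config$Nin,
    R1 = config$R1, R2 = config$R2,
    sigma1 = config$sigma1, sigma2 = config$sigma2,
    phi = phi_from_ne2(ne2, config$sigma2, config$R2)
  ), class = "ecr_motor")
  motor$M <- sum(mass)
  com <- colSums(pos * mass) / motor$M
  motor$I <- (2 / 3) * sum(mass * rowSums(sweep(pos, 2, com)^2))
  motor$u <- motor_axis(motor)
  motor
}

# Spring graph: 6-nearest-neighbour union (local rigidity) plus one
# antipodal strut per particle -- the particle closest to its reflection
# through the build centre -- which stiffens the soft breathing/bending
# modes a purely local network leaves floppy; plus 3 struts from each E2
# bead to its nearest inner beads so the outer shell co-moves. Repaired to
# a single connected component if necessary.
build_spring_network <- function(pos, species, k_nn = 10L, k_strut = 3L,
                                 k_anti = 12L) {
  n <- nrow(pos)
  if (n < 2L) return(matrix(integer(0), 0, 2))
  k <- min(k_nn, n - 1L)
  nn <- nearest_neighbours(pos, k)
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  anti <- antipodal_partners(pos, k_anti)
  edges <- rbind(edges, cbind(rep(seq_len(n), each = ncol(anti)),
                              as.vector(t(anti))))
  inner <- which(species %in% c("E0", "E1"))
  outer <- which(species == "E2")
  if (length(outer) > 0 && length(inner) > 0) {
    ks <- min(k_strut, length(inner))
    d2 <- outer_dist2(pos[outer, , drop = FALSE], pos[inner, , drop = FALSE])
    strut <- t(apply(d2, 1, function(row) inner[order(row)[seq_len(ks)]]))
    edges <- rbind(edges, cbind(rep(outer, each = ks), as.vector(t(strut))))
  }
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)
  while (comp$no > 1L) {
    main <- which(comp$membership == which.max(comp$csize))
    other <- which(comp$membership != comp$membership[main[1]])
    d2 <- outer_dist2(pos[other, , drop = FALSE], pos[main, , drop = FALSE])
    hit <- arrayInd(which.min(d2), dim(d2))
    edges <- rbind(edges, sort(c(other[hit[1]], main[hit[2]])))
    g <- igraph::add_edges(g, c(other[hit[1]], main[hit[2]]))
    comp <- igraph::components(g)
  }
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# indices of the k particles nearest to each particle's reflection through
# the centroid (never the particle itself)
antipodal_partners <- function(pos, k = 1L) {
  n <- nrow(pos)
  k <- min(k, n - 1L)
  ctr <- colMeans(pos)
  refl <- sweep(-sweep(pos, 2, ctr), 2, ctr, "+")
  out <- matrix(0L, n, k)
  chunk <- max(1L, as.integer(2e7 / n))
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    d2 <- outer_dist2(refl[idx, , drop = FALSE], pos)
    d2[cbind(seq_along(idx), idx)] <- Inf
    out[idx, ] <- t(apply(d2, 1, function(row) order(row)[seq_len(k)]))
  }
  out
}

# k nearest neighbours by chunked exact search (no external dependency)
nearest_neighbours <- function(pos, k) {
  n <- nrow(pos)
  out <- matrix(0L, n, k)
  chunk <- max(1L, as.integer(2e7 / n))
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    d2 <- outer_dist2(pos[idx, , drop = FALSE], pos)
    d2[cbind(seq_along(idx), idx)] <- Inf
    out[idx, ] <- t(apply(d2, 1, function(row) order(row)[seq_len(k)]))
  }
  out
}

outer_dist2 <- function(a, b) {
  sa <- rowSums(a^2); sb <- rowSums(b^2)
  d2 <- outer(sa, sb, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Motor symmetry axis
#'
#' Unit vector from the centre of mass of the E1 (catalytic) hemisphere beads
#' to that of the E0 (inert) hemisphere beads, recomputed from the current
#' bead positions.
#'
#' @param motor an `ecr_motor`.
#' @return A length-3 unit vector.
#' @export
motor_axis <- function(motor) {
  e0 <- motor$species == "E0"
  e1 <- motor$species == "E1"
  d <- colMeans(motor$pos[e0, , drop = FALSE]) -
       colMeans(motor$pos[e1, , drop = FALSE])
  d / sqrt(sum(d^2))
}

#' Remove E2 beads from a polar cap
#'
#' Deletes every E2 bead whose polar angle, measured from the outer-shell pole
#' `-u` at the motor centre of mass, is below `cap_angle`, reproducing the
#' "opened shell" geometry used to probe how an aperture near the pole lets
#' solvent vent through the second enzyme layer. Springs among the surviving
#' particles are untouched and the coverage fraction is recomputed.
#'
#' @param motor an `ecr_motor` with at least one E2 bead (unless
#'   `cap_angle = 0`).
#' @param cap_angle cap half-angle in radians, in `[0, pi/2]`.
#' @return The modified `ecr_motor`.
#' @export
open_polar_cap <- function(motor, cap_angle) {
  stopifnot(inherits(motor, "ecr_motor"))
  if (cap_angle < 0 || cap_angle > pi / 2)
    stop("cap half-angle must lie in [0, pi/2]", call. = FALSE)
  if (cap_angle == 0) return(motor)
  if (motor$NE2 == 0L)
    stop("motor has no E2 beads to remove", call. = FALSE)
  u <- motor_axis(motor)
  com <- colSums(motor$pos * motor$mass) / sum(motor$mass)
  e2 <- which(motor$species == "E2")
  if (cap_angle >= pi / 2 - 1e-12) {
    # the cap spans the whole hemispherical shell
    drop_idx <- e2
  } else {
    rel <- sweep(motor$pos[e2, , drop = FALSE], 2, com)
    ct <- (rel %*% (-u)) / sqrt(rowSums(rel^2))
    drop_idx <- e2[ct > cos(cap_angle)]  # theta < cap_angle
  }
  if (length(drop_idx) == 0L) return(motor)
  keep <- setdiff(seq_len(nrow(motor$pos)), drop_idx)
  remap <- integer(nrow(motor$pos)); remap[keep] <- seq_along(keep)
  keep_spring <- !(motor$springs[, 1] %in% drop_idx |
                   motor$springs[, 2] %in% drop_idx)
  motor$springs <- matrix(remap[motor$springs[keep_spring, , drop = FALSE]],
                          ncol = 2)
  motor$r0 <- motor$r0[keep_spring]
  motor$pos <- motor$pos[keep, , drop = FALSE]
  motor$species <- motor$species[keep]
  motor$mass <- motor$mass[keep]
  motor$sigma <- motor$sigma[keep]
  motor$NE2 <- motor$NE2 - length(drop_idx)
  motor$phi <- phi_from_ne2(motor$NE2, motor$sigma2, motor$R2)
  motor$M <- sum(motor$mass)
  com <- colSums(motor$pos * motor$mass) / motor$M
  motor$I <- (2 / 3) * sum(motor$mass * rowSums(sweep(motor$pos, 2, com)^2))
  motor$u <- motor_axis(motor)
  motor
}

#' @export
print.ecr_motor <- function(x, ...) {
  cat("Janus bead-spring motor\n")
  cat(sprintf("  beads: %d E0 + %d E1 on R1 = %g, %d E2 on R2 = %g (phi = %.3f)\n",
              x$NE0, x$NE1, x$R1, x$NE2, x$R2, x$phi))
  cat(sprintf("  internal particles: %d; springs: %d\n",
              x$Nin, nrow(x$springs)))
  cat(sprintf("  total mass M = %.4f, moment of inertia I = %.2f\n",
              x$M, x$I))
  cat(sprintf("  axis u = (%.3f, %.3f, %.3f)\n", x$u[1], x$u[2], x$u[3]))
  invisible(x)
}

#' Write motor geometry as extended XYZ
#'
#' One record per bead/particle: species tag and coordinates, readable by
#' standard molecular visualisation tools.
#'
#' @param motor an `ecr_motor`.
#' @param path output file.
#' @param comment second-line comment string.
#' @return `path`, invisibly.
#' @export
write_motor_xyz <- function(motor, path, comment = "ecrmotor geometry") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(motor$pos)), con)
  writeLines(comment, con)
  writeLines(sprintf("%s %.8f %.8f %.8f", motor$species,
                     motor$pos[, 1], motor$pos[, 2], motor$pos[, 3]), con)
  invisible(path)
}
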