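#' Axial velocity statistics
#'
#' Time average and normalised histogram of the projected motor velocity
#' Vu = V(t) . u(t) over the post-burn-in window. Propulsion along +u means
#' the inert hemisphere leads.
#'
#' @param x an `ecr_run`, or a data frame with columns `time` and `vu`.
#' @param burnin_frac fraction of the run discarded before averaging
#'   (defaults to the run's configured value, else 0.2).
#' @param bin_width histogram bin width (default: Freedman--Diaconis style
#'   automatic choice).
#' @param n_blocks number of contiguous blocks used for the standard error:
#'   consecutive Vu samples are autocorrelated (the motor velocity decorrelates
#'   over roughly its momentum-relaxation time), so the SE is estimated from
#'   block means rather than raw samples. Falls back to the naive SE when too
#'   few samples are available.
#' @return A list with `mean`, `se` (block standard error of the mean), `n`,
#'   `block_means`, and `histogram` (data frame `vu_mid`, `density`; the
#'   density integrates to 1).
#' @export
axial_velocity_stats <- function(x, burnin_frac = NULL, bin_width = NULL,
                                 n_blocks = 20L) {
  if (inherits(x, "ecr_run")) {
    if (is.null(burnin_frac)) burnin_frac <- x$config$burnin_frac
    df <- x$scalars[, c("time", "vu")]
  } else {
    if (is.null(burnin_frac)) burnin_frac <- 0.2
    df <- x
  }
  stopifnot(all(c("time", "vu") %in% names(df)), !is.unsorted(df$time))
  cut <- min(df$time) + burnin_frac * (max(df$time) - min(df$time))
  v <- df$vu[df$time >= cut]
  if (length(v) == 0) stop("insufficient data: empty post-burn-in window",
                           call. = FALSE)
  if (is.null(bin_width)) {
    spread <- diff(range(v))
    bin_width <- if (spread == 0) 1 else spread / max(10, ceiling(sqrt(length(v))))
  }
  breaks <- seq(floor(min(v) / bin_width) * bin_width,
                max(v) + bin_width, by = bin_width)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  nb <- min(as.integer(n_blocks), length(v) %/% 4L)
  if (nb >= 4L) {
    blk <- tapply(v, cut(seq_along(v), nb), mean)
    se <- stats::sd(blk) / sqrt(nb)
  } else {
    blk <- v
    se <- stats::sd(v) / sqrt(length(v))
  }
  list(mean = mean(v),
       se = se,
       n = length(v),
       block_means = as.numeric(blk),
       histogram = data.frame(vu_mid = h$mids, density = h$density))
}

# frames accessor: accept an ecr_run or a bare list of snapshot frames
get_frames <- function(x) {
  if (inherits(x, "ecr_run")) {
    if (length(x$snapshots) == 0)
      stop("run has no stored snapshots (set snapshot_stride > 0)",
           call. = FALSE)
    x$snapshots
  } else x
}

# minimum-image displacement of frame positions from the frame's motor centre
frame_rel <- function(frame, box) {
  rel <- sweep(frame$pos, 2, frame$center)
  rel - sweep(round(sweep(rel, 2, box, "/")), 2, box, "*")
}

species_code <- function(species) {
  code <- match(species, SOLVENT_SPECIES) - 1L
  if (any(is.na(code))) stop("species must be one of A, I, B", call. = FALSE)
  code
}

#' Radial concentration profile around the motor
#'
#' Bins the minimum-image distances of solvent particles of one species from
#' the motor centre, restricted to an angular sector, and normalises by
#' frames times the shell-sector volume, yielding a number density per bin.
#' Far-field bins approach the bulk density of the species. Profiles are
#' accumulated in the co-moving motor frame.
#'
#' @param x an `ecr_run` with snapshots, or a list of snapshot frames (each
#'   a list with `pos`, `species`, `center`, `u`).
#' @param species `"A"`, `"I"` or `"B"`.
#' @param box box edge lengths (taken from the run when `x` is an
#'   `ecr_run`).
#' @param breaks radial bin edges; default 30 bins from 0 to a quarter box.
#' @param sector `"catalytic"` (polar angle from -u below pi/2), `"inert"`
#'   (above pi/2) or `"full"`.
#' @return A data frame with bin edges/midpoints, raw counts, densities and
#'   an `interior` flag for bins overlapping the motor body (flagged, not
#'   dropped).
#' @export
radial_concentration_profile <- function(x, species, box = NULL,
                                         breaks = NULL,
                                         sector = c("full", "catalytic",
                                                    "inert")) {
  sector <- match.arg(sector)
  frames <- get_frames(x)
  if (is.null(box)) {
    if (!inherits(x, "ecr_run"))
      stop("box must be given when x is a plain frame list", call. = FALSE)
    box <- c(x$config$Lx, x$config$Ly, x$config$Lz)
  }
  if (is.null(breaks)) breaks <- seq(0, min(box) / 4, length.out = 31)
  code <- species_code(species)
  counts <- numeric(length(breaks) - 1L)
  for (fr in frames) {
    rel <- frame_rel(fr, box)
    sel <- fr$species == code
    rel <- rel[sel, , drop = FALSE]
    r <- sqrt(rowSums(rel^2))
    if (sector != "full") {
      ct <- (rel %*% (-fr$u)) / pmax(r, .Machine$double.eps)
      keep <- if (sector == "catalytic") ct > 0 else ct <= 0
      r <- r[keep]
    }
    r <- r[r >= breaks[1] & r <= breaks[length(breaks)]]
    if (length(r) > 0)
      counts <- counts + graphics::hist(r, breaks = breaks,
                                        plot = FALSE)$counts
  }
  frac <- if (sector == "full") 1 else 0.5
  vol <- 4 / 3 * pi * diff(breaks^3) * frac
  r_body <- if (inherits(x, "ecr_run"))
    x$config$R2 + x$config$sigma2 else max(breaks)  # conservative default
  out <- data.frame(r_lo = utils::head(breaks, -1),
                    r_hi = utils::tail(breaks, -1),
                    r_mid = (utils::head(breaks, -1) +
                             utils::tail(breaks, -1)) / 2,
                    species = species, count = counts,
                    density = counts / (length(frames) * vol))
  out$interior <- inherits(x, "ecr_run") & out$r_lo < r_body
  out
}

#' Angular concentration profile in a spherical shell
#'
#' Bins the polar angle theta of solvent particles of one species inside the
#' shell `r_lo < r < r_hi`, where theta is the angle between the vector from
#' the motor centre to the particle and the axis -u (so theta = 0 points at
#' the outer-shell pole on the catalytic side and theta = pi at the inert
#' pole). Bins are uniform in cos(theta) (equal solid angle), so a uniform
#' gas gives a flat profile by construction; densities are counts per frame
#' per bin volume.
#'
#' @inheritParams radial_concentration_profile
#' @param shell radial window `c(r_lo, r_hi)`.
#' @param n_bins number of equal-cos(theta) bins.
#' @return A data frame with `theta_lo`, `theta_hi`, `theta_mid`, `count`,
#'   `density`; the attribute `monotone_increasing` reports whether the
#'   binned density increases with theta.
#' @export
angular_concentration_profile <- function(x, species, shell = c(3.2, 3.5),
                                          box = NULL, n_bins = 18L) {
  frames <- get_frames(x)
  if (is.null(box)) {
    if (!inherits(x, "ecr_run"))
      stop("box must be given when x is a plain frame list", call. = FALSE)
    box <- c(x$config$Lx, x$config$Ly, x$config$Lz)
  }
  stopifnot(length(shell) == 2, shell[1] >= 0, shell[2] > shell[1])
  code <- species_code(species)
  # equal-cos bins: cos runs 1 -> -1 so theta bins run 0 -> pi
  cos_edges <- seq(1, -1, length.out = n_bins + 1L)
  counts <- numeric(n_bins)
  for (fr in frames) {
    rel <- frame_rel(fr, box)
    sel <- fr$species == code
    rel <- rel[sel, , drop = FALSE]
    r <- sqrt(rowSums(rel^2))
    keep <- r > shell[1] & r < shell[2]
    if (!any(keep)) next
    ct <- (rel[keep, , drop = FALSE] %*% (-fr$u)) / r[keep]
    ct <- pmin(1, pmax(-1, ct))
    # bin k holds cos in (cos_edges[k+1], cos_edges[k]]
    bin <- findInterval(-ct, -cos_edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    counts <- counts + tabulate(bin, nbins = n_bins)
  }
  if (sum(counts) == 0)
    stop("insufficient data: shell contains no particles of species ",
         species, call. = FALSE)
  vol <- 2 * pi * (shell[2]^3 - shell[1]^3) / 3 * abs(diff(cos_edges))
  theta <- acos(cos_edges)
  dens <- counts / (length(frames) * vol)
  out <- data.frame(theta_lo = utils::head(theta, -1),
                    theta_hi = utils::tail(theta, -1),
                    theta_mid = (utils::head(theta, -1) +
                                 utils::tail(theta, -1)) / 2,
                    species = species, count = counts, density = dens)
  attr(out, "monotone_increasing") <- !is.unsorted(dens)
  out
}

#' Motor-frame flow field on an (r, theta) grid
#'
#' Azimuthally averaged mean solvent velocity relative to the motor centre
#' of mass, decomposed into the axial component (along u) and the
#' cylindrical-radial component (away from the axis) in the meridional plane.
#' Cells never visited are reported as `NA`, not zero.
#'
#' @inheritParams radial_concentration_profile
#' @param r_edges radial cell edges.
#' @param theta_edges polar-angle cell edges (theta measured from -u).
#' @return A data frame with cell midpoints, sample counts and mean
#'   `v_axial`, `v_radial`.
#' @export
flow_field_map <- function(x, r_edges = NULL, theta_edges = NULL,
                           box = NULL) {
  frames <- get_frames(x)
  if (is.null(box)) {
    if (!inherits(x, "ecr_run"))
      stop("box must be given when x is a plain frame list", call. = FALSE)
    box <- c(x$config$Lx, x$config$Ly, x$config$Lz)
  }
  if (is.null(r_edges)) r_edges <- seq(0, min(box) / 4, length.out = 13)
  if (is.null(theta_edges)) theta_edges <- seq(0, pi, length.out = 10)
  nr <- length(r_edges) - 1L; nt <- length(theta_edges) - 1L
  s_ax <- matrix(0, nr, nt); s_rad <- matrix(0, nr, nt)
  cnt <- matrix(0L, nr, nt)
  for (fr in frames) {
    if (is.null(fr$vel))
      stop("frames must store velocities for flow fields", call. = FALSE)
    rel <- frame_rel(fr, box)
    r <- sqrt(rowSums(rel^2))
    keep <- r > 0 & r >= r_edges[1] & r <= r_edges[nr + 1L]
    rel <- rel[keep, , drop = FALSE]; r <- r[keep]
    w <- sweep(fr$vel[keep, , drop = FALSE], 2, fr$vcom)  # motor frame
    u <- fr$u
    ct <- pmin(1, pmax(-1, (rel %*% (-u)) / r))
    theta <- acos(ct)
    axial <- rel %*% u
    e_rho <- rel - axial %*% t(u)
    rho_n <- sqrt(rowSums(e_rho^2))
    ok_rho <- rho_n > 1e-12
    e_rho[ok_rho, ] <- e_rho[ok_rho, , drop = FALSE] / rho_n[ok_rho]
    e_rho[!ok_rho, ] <- 0  # on-axis: no radial direction
    v_ax <- w %*% u
    v_rad <- rowSums(w * e_rho)
    ir <- findInterval(r, r_edges, rightmost.closed = TRUE, all.inside = TRUE)
    it <- findInterval(theta, theta_edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
    idx <- cbind(ir, it)
    for (j in seq_along(r)) {
      s_ax[idx[j, 1], idx[j, 2]] <- s_ax[idx[j, 1], idx[j, 2]] + v_ax[j]
      s_rad[idx[j, 1], idx[j, 2]] <- s_rad[idx[j, 1], idx[j, 2]] + v_rad[j]
      cnt[idx[j, 1], idx[j, 2]] <- cnt[idx[j, 1], idx[j, 2]] + 1L
    }
  }
  grid <- expand.grid(ir = seq_len(nr), it = seq_len(nt))
  n <- cnt[cbind(grid$ir, grid$it)]
  data.frame(
    r_mid = (r_edges[grid$ir] + r_edges[grid$ir + 1L]) / 2,
    theta_mid = (theta_edges[grid$it] + theta_edges[grid$it + 1L]) / 2,
    n_samples = n,
    v_axial = ifelse(n > 0, s_ax[cbind(grid$ir, grid$it)] / pmax(n, 1), NA),
    v_radial = ifelse(n > 0, s_rad[cbind(grid$ir, grid$it)] / pmax(n, 1), NA))
}

#' Coverage power-law fit of the propulsion velocity
#'
#' Fits the quartic coverage law Vu = A * phi^4 + Vu0 by least squares
#' (linear in A and Vu0), and additionally a free-exponent model
#' Vu = A * phi^p + Vu0 by nonlinear least squares as an exponent-recovery
#' diagnostic.
#'
#' @param phi coverage fractions (>= 4 distinct values).
#' @param vu mean axial velocities.
#' @return An object of class `ecr_fit_power`: amplitude `A`, baseline
#'   `Vu0`, their standard errors, the free-exponent estimates, residuals
#'   and goodness of fit.
#' @export
#' @examples
#' phi <- seq(0, 1, 0.1)
#' f <- fit_power_law(phi, 0.01 * phi^4 + 0.0029)
#' coef(f)
fit_power_law <- function(phi, vu) {
  stopifnot(length(phi) == length(vu))
  if (length(unique(phi)) < 4)
    stop("need at least 4 distinct coverage values", call. = FALSE)
  x4 <- phi^4
  fit4 <- stats::lm(vu ~ x4)
  sm <- summary(fit4)
  A <- unname(stats::coef(fit4)[2])
  V0 <- unname(stats::coef(fit4)[1])
  free <- tryCatch({
    f <- minpack.lm::nlsLM(vu ~ A * phi^p + v0,
                           start = list(A = if (abs(A) > 0) A else 1e-3,
                                        v0 = V0, p = 3),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-15, ptol = 1e-15))
    cf <- summary(f)$coefficients
    list(A = cf["A", 1], v0 = cf["v0", 1], exponent = cf["p", 1],
         exponent_se = cf["p", 2])
  }, error = function(e) list(A = NA_real_, v0 = NA_real_,
                              exponent = NA_real_, exponent_se = NA_real_))
  structure(list(
    A = A, Vu0 = V0,
    A_se = sm$coefficients[2, 2], Vu0_se = sm$coefficients[1, 2],
    exponent_free = free$exponent, exponent_free_se = free$exponent_se,
    A_free = free$A, Vu0_free = free$v0,
    r_squared = sm$r.squared,
    residuals = stats::residuals(fit4),
    fit = fit4), class = "ecr_fit_power")
}

#' @export
coef.ecr_fit_power <- function(object, ...) {
  c(A = object$A, Vu0 = object$Vu0, exponent_free = object$exponent_free)
}

#' @export
print.ecr_fit_power <- function(x, ...) {
  cat("Coverage power law: Vu = A * phi^4 + Vu0\n")
  cat(sprintf("  A   = %.5g (se %.2g)\n", x$A, x$A_se))
  cat(sprintf("  Vu0 = %.5g (se %.2g)\n", x$Vu0, x$Vu0_se))
  cat(sprintf("  free exponent = %.4g (se %.2g), R^2 (fixed) = %.4f\n",
              x$exponent_free, x$exponent_free_se, x$r_squared))
  invisible(x)
}

#' Linear dependence of the power-law amplitude on the outer radius
#'
#' Ordinary least squares of the per-R2 amplitudes on R2, parameterised as
#' A(R2) = a - b * R2.
#'
#' @param R2 outer shell radii (>= 2 distinct values).
#' @param A fitted amplitudes at each radius.
#' @return An object of class `ecr_fit_amp` with intercept `a`, decay slope
#'   `b` (so the fitted slope is `-b`) and standard errors.
#' @export
#' @examples
#' r2 <- c(3.95, 4.2, 4.35)
#' f <- fit_amplitude_vs_R2(r2, 5.05e-2 - 0.98e-2 * r2)
#' coef(f)
fit_amplitude_vs_R2 <- function(R2, A) {
  stopifnot(length(R2) == length(A))
  if (length(unique(R2)) < 2)
    stop("need at least 2 distinct R2 values", call. = FALSE)
  fit <- stats::lm(A ~ R2)
  cf <- summary(fit)$coefficients
  structure(list(a = unname(stats::coef(fit)[1]),
                 b = -unname(stats::coef(fit)[2]),
                 a_se = cf[1, 2],
                 b_se = if (nrow(cf) > 1) cf[2, 2] else NA_real_,
                 fit = fit), class = "ecr_fit_amp")
}

#' @export
coef.ecr_fit_amp <- function(object, ...) c(a = object$a, b = object$b)

#' @export
print.ecr_fit_amp <- function(x, ...) {
  cat("Amplitude vs outer radius: A(R2) = a - b * R2\n")
  cat(sprintf("  a = %.5g (se %.2g), b = %.5g (se %.2g)\n",
              x$a, x$a_se, x$b, x$b_se))
  invisible(x)
}

#' Export a fit report as JSON
#'
#' @param fit an `ecr_fit_power` or `ecr_fit_amp`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  vals <- unclass(fit)
  vals$fit <- NULL
  vals$residuals <- unname(vals$residuals)
  jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
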