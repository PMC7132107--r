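## Crick parameterization: a minor alpha-helix wound on a superhelix.
## Angles are degrees in user-facing objects, radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into (-180, 180]
#'
#' @param x Numeric vector of angles in degrees.
#' @return Wrapped angles in degrees.
#' @export
#' @examples
#' wrap_angle(c(270, -180, 540))
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

rot_z <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  matrix(c(cos(t), -sin(t), 0,
           sin(t),  cos(t), 0,
           0,       0,      1), 3, 3, byrow = TRUE)
}

#' Crick parameters for one helix of a bundle
#'
#' Describes an idealized alpha-helix wound on a superhelix whose axis is the
#' z axis: superhelical radius `r0` and twist `omega0`, minor-helix radius
#' `r1` and twist `omega1`, the two phases, the rise per residue along the
#' bundle axis, an axial offset, and the helix orientation. With `r0 = 0` and
#' `omega0 = 0` the trace degenerates to a straight ideal alpha-helix on the
#' z axis.
#'
#' @param r0 Superhelical radius (Angstrom, >= 0).
#' @param omega0 Superhelical twist (degrees per residue).
#' @param omega1 Minor-helix twist (degrees per residue).
#' @param phi0 Superhelical phase (degrees).
#' @param phi1 Minor-helix phase (degrees).
#' @param r1 Minor-helix radius (Angstrom, > 0).
#' @param delta_z Rise per residue along the bundle axis (Angstrom).
#' @param z_offset Translation along the bundle axis (Angstrom).
#' @param orientation `"up"` or `"down"`; `"down"` applies a 180-degree
#'   rotation about the x axis after generation.
#' @param n_res Number of residues (integer >= 2).
#' @return An object of class `crick_params` (a named list).
#' @export
#' @examples
#' crick_params(r0 = 5, omega0 = -2.85, n_res = 28)
crick_params <- function(r0 = 0, omega0 = 0, omega1 = HS_HELIX$twist,
                         phi0 = 0, phi1 = 0, r1 = HS_HELIX$r1,
                         delta_z = HS_HELIX$rise, z_offset = 0,
                         orientation = c("up", "down"), n_res = 18L) {
  orientation <- match.arg(orientation)
  p <- list(r0 = r0, omega0 = omega0, omega1 = omega1, phi0 = phi0,
            phi1 = phi1, r1 = r1, delta_z = delta_z, z_offset = z_offset,
            orientation = orientation, n_res = as.integer(n_res))
  validate_crick_params(p)
  structure(p, class = "crick_params")
}

validate_crick_params <- function(p) {
  stopifnot(is.numeric(p$r0), is.numeric(p$r1), is.numeric(p$n_res) || is.integer(p$n_res))
  if (p$r0 < 0) stop("invalid Crick parameters: r0 must be >= 0", call. = FALSE)
  if (p$r1 <= 0) stop("invalid Crick parameters: r1 must be > 0", call. = FALSE)
  if (p$n_res < 2) stop("invalid Crick parameters: n_res must be >= 2", call. = FALSE)
  if (!p$orientation %in% c("up", "down")) {
    stop("invalid Crick parameters: orientation must be 'up' or 'down'", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.crick_params <- function(x, ...) {
  cat("<crick_params>\n")
  cat(sprintf("  r0 %.3f A  omega0 %.3f deg/res  phi0 %.2f deg\n", x$r0, x$omega0, x$phi0))
  cat(sprintf("  r1 %.3f A  omega1 %.3f deg/res  phi1 %.2f deg\n", x$r1, x$omega1, x$phi1))
  cat(sprintf("  delta_z %.3f A/res  z_offset %.2f A  %s  n_res %d\n",
              x$delta_z, x$z_offset, x$orientation, x$n_res))
  invisible(x)
}

## Core evaluation: CA coordinates for residue indices t (0-based), with an
## optional per-residue superhelical radius (used by the state builder's
## tapered extension). The superhelix pitch angle alpha couples the minor
## helix to the local superhelical frame.
crick_xyz <- function(p, t = seq_len(p$n_res) - 1, r0 = NULL) {
  r0 <- if (is.null(r0)) rep(p$r0, length(t)) else rep_len(r0, length(t))
  w0 <- deg2rad(p$omega0)
  phi <- w0 * t + deg2rad(p$phi0)
  psi <- deg2rad(p$omega1) * t + deg2rad(p$phi1)
  alpha <- atan2(r0 * w0, p$delta_z)
  x <- r0 * cos(phi) + p$r1 * cos(phi) * cos(psi) -
    p$r1 * cos(alpha) * sin(phi) * sin(psi)
  y <- r0 * sin(phi) + p$r1 * sin(phi) * cos(psi) +
    p$r1 * cos(alpha) * cos(phi) * sin(psi)
  z <- p$delta_z * t - p$r1 * sin(alpha) * sin(psi)
  m <- cbind(x = x, y = y, z = z)
  if (p$orientation == "down") m <- m %*% diag(c(1, -1, -1))
  m[, "z"] <- m[, "z"] + p$z_offset
  m
}

#' Generate a CA trace from Crick parameters
#'
#' Evaluates the minor-helix-on-superhelix parameterization at integer
#' residue positions and returns the ordered CA coordinates. With standard
#' alpha-helical defaults, consecutive CA-CA distances are ~3.8 Angstrom and
#' all points lie within `r0 + r1` of the z axis.
#'
#' @param params A [crick_params()] object.
#' @return A tibble with columns `resno`, `x`, `y`, `z` (Angstrom).
#' @export
#' @examples
#' helix <- generate_helix(crick_params(n_res = 18))
#' range(dist_consecutive(as.matrix(helix[, c("x", "y", "z")])))
generate_helix <- function(params) {
  if (!inherits(params, "crick_params")) params <- do.call(crick_params, params)
  validate_crick_params(params)
  m <- crick_xyz(params)
  tibble::tibble(resno = seq_len(params$n_res),
                 x = m[, 1], y = m[, 2], z = m[, 3])
}

#' Consecutive-point distances of a coordinate matrix
#'
#' @param m Numeric matrix with 3 columns (x, y, z).
#' @return Vector of distances between consecutive rows.
#' @export
dist_consecutive <- function(m) {
  m <- as.matrix(m)
  sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
}

#' Apply C3 symmetry to a monomer
#'
#' Rotates a monomer CA trace by 120 and 240 degrees about the z axis to
#' produce a trimer. The trimer centroid lies on the z axis and all
#' intra-monomer distances are preserved exactly.
#'
#' @param monomer A data frame with columns `x`, `y`, `z` (and optionally
#'   `resno` and annotation columns, which are carried over per chain).
#' @param chain_ids Chain identifiers for the three copies.
#' @return A tibble with a `chain` column prepended to the monomer columns.
#' @export
#' @examples
#' tri <- apply_c3(generate_helix(crick_params(r0 = 5, n_res = 10)))
#' table(tri$chain)
apply_c3 <- function(monomer, chain_ids = c("A", "B", "C")) {
  monomer <- tibble::as_tibble(monomer)
  if (nrow(monomer) == 0) stop("apply_c3: empty monomer", call. = FALSE)
  stopifnot(all(c("x", "y", "z") %in% names(monomer)))
  xyz <- as.matrix(monomer[, c("x", "y", "z")])
  purrr::map2_dfr(chain_ids, c(0, 120, 240), function(ch, ang) {
    rot <- xyz %*% t(rot_z(ang))
    out <- monomer
    out$x <- rot[, 1]; out$y <- rot[, 2]; out$z <- rot[, 3]
    dplyr::bind_cols(tibble::tibble(chain = ch), out)
  })
}

crick_par_vec <- function(p) {
  c(r0 = p$r0, omega0 = p$omega0, omega1 = p$omega1, phi0 = p$phi0,
    phi1 = p$phi1, r1 = p$r1, delta_z = p$delta_z, z_offset = p$z_offset)
}

vec_to_crick <- function(v, orientation, n_res) {
  crick_params(r0 = abs(v[["r0"]]), omega0 = v[["omega0"]], omega1 = v[["omega1"]],
               phi0 = wrap_angle(v[["phi0"]]), phi1 = wrap_angle(v[["phi1"]]),
               r1 = abs(v[["r1"]]), delta_z = v[["delta_z"]],
               z_offset = v[["z_offset"]], orientation = orientation,
               n_res = n_res)
}

#' Fit Crick parameters to an ordered CA trace
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of the Crick
#' parameterization to an ordered CA coordinate list assumed to be expressed
#' in the bundle frame (superhelical axis = z). Initialization is
#' moment-based (mean axial radius, axial rise, azimuthal drift) with a fixed
#' multi-start grid over the minor-helix phase; both orientations are tried.
#' On traces produced by [generate_helix()] the fit RMSD is below 1e-3
#' Angstrom and parameters are recovered to ~1e-3 in their units.
#'
#' @param coords Data frame or matrix of at least 8 ordered CA positions.
#' @param max_rmsd Convergence criterion: if no start reaches this residual
#'   RMSD times 100 (a loose sanity bound), a fit error is raised carrying
#'   the best residual.
#' @return An object of class `crick_fit`: list with elements `params`
#'   (a [crick_params()] object), `rmsd` (Angstrom) and `fitted` (tibble).
#' @export
#' @examples
#' p <- crick_params(r0 = 5, omega0 = -3, phi0 = 30, n_res = 28)
#' fit <- fit_crick(generate_helix(p))
#' fit$rmsd
fit_crick <- function(coords, max_rmsd = 10) {
  m <- as.matrix(as.data.frame(coords)[, c("x", "y", "z")])
  n <- nrow(m)
  if (n < 8) stop("fit_crick: need at least 8 points", call. = FALSE)
  t <- seq_len(n) - 1

  residual_fun <- function(v, orientation) {
    p <- list(r0 = abs(v[1]), omega0 = v[2], omega1 = v[3], phi0 = v[4],
              phi1 = v[5], r1 = abs(v[6]), delta_z = v[7], z_offset = v[8],
              orientation = orientation, n_res = n)
    as.vector(crick_xyz(p, t) - m)
  }

  # Moment-based initial estimates. Two candidate superhelical radii: the
  # mean axial distance (good for supercoils) and the centroid offset (which
  # correctly degenerates to ~0 for a straight centered helix).
  rad <- sqrt(m[, 1]^2 + m[, 2]^2)
  az <- atan2(m[, 2], m[, 1])
  az_unwrap <- az + 2 * pi * cumsum(c(0, diff(az) < -pi)) -
    2 * pi * cumsum(c(0, diff(az) > pi))
  dz_up <- (m[n, 3] - m[1, 3]) / (n - 1)
  orientations <- if (dz_up >= 0) c("up", "down") else c("down", "up")

  best <- NULL
  for (orient in orientations) {
    sgn <- if (orient == "up") 1 else -1
    drift <- rad2deg(stats::coef(stats::lm(az_unwrap ~ t))[2]) * sgn
    phi0_init <- rad2deg(az[1]) * sgn
    # Two start families: a supercoil hypothesis (mean axial radius, azimuth
    # drift) and a straight-helix hypothesis (centroid offset, no twist) --
    # the latter avoids a degenerate branch where r0 absorbs the minor helix.
    starts_r0_w0 <- list(
      c(max(mean(rad), 0.1), drift),
      c(max(sqrt(mean(m[, 1])^2 + mean(m[, 2])^2), 0.01), 0))
    for (fam in starts_r0_w0) {
      r0_init <- fam[1]; omega0_init <- fam[2]
      for (phi1_start in c(0, 90, 180, 270)) {
        start <- c(r0_init, omega0_init, HS_HELIX$twist * 1, phi0_init,
                   phi1_start, HS_HELIX$r1, abs(dz_up), sgn * m[1, 3])
        fit <- tryCatch(
          minpack.lm::nls.lm(par = start, fn = residual_fun, orientation = orient,
                             control = minpack.lm::nls.lm.control(maxiter = 400)),
          error = function(e) NULL)
        if (is.null(fit)) next
        rmsd <- sqrt(mean(matrix(fit$fvec, ncol = 3)^2) * 3)
        # on residual ties (degenerate straight helices) prefer the smaller,
        # more parsimonious superhelical radius
        better <- is.null(best) || rmsd < best$rmsd - 1e-9 ||
          (rmsd < best$rmsd + 1e-9 && abs(fit$par[1]) < abs(best$par[1]))
        if (better) best <- list(par = fit$par, rmsd = rmsd, orientation = orient)
      }
    }
    if (!is.null(best) && best$rmsd < 1e-10) break
  }
  if (is.null(best) || best$rmsd > max_rmsd) {
    stop(sprintf("fit_crick: did not converge (best residual RMSD %.3f A)",
                 if (is.null(best)) Inf else best$rmsd), call. = FALSE)
  }
  v <- best$par
  names(v) <- c("r0", "omega0", "omega1", "phi0", "phi1", "r1", "delta_z", "z_offset")
  params <- vec_to_crick(v, best$orientation, n)
  fitted <- generate_helix(params)
  structure(list(params = params, rmsd = best$rmsd, fitted = fitted,
                 n = n), class = "crick_fit")
}

#' @export
print.crick_fit <- function(x, ...) {
  cat(sprintf("<crick_fit>  n = %d  rmsd = %.4g A\n", x$n, x$rmsd))
  print(x$params)
  invisible(x)
}

#' Serialize Crick parameters to JSON
#'
#' @param params A [crick_params()] object.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return The JSON string, invisibly if written to a file.
#' @export
crick_to_json <- function(params, path = NULL) {
  js <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read Crick parameters from JSON
#'
#' @param x A JSON string or file path.
#' @return A [crick_params()] object.
#' @export
crick_from_json <- function(x) {
  lst <- jsonlite::fromJSON(x)
  do.call(crick_params, lst)
}
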