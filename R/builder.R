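## Build short- and long-state trimer backbones from an architecture spec.
##
## Both states share the same base: an inner helix (N-terminal segment) and
## an outer helix, both running N->C along +z. The inner/outer connector of
## the real helical-hairpin designs is not modeled at this resolution (the CA
## trace jumps between the two base segments). The hinge sits at the top of
## the outer helix: in the long state it continues helically while the
## superhelical radius tapers to the packing radius of the three flipping
## helices; in the short state a fixed ABEGO turn template folds the flipping
## helix back down against the inner helices.

## ---- NeRF internal-coordinate backbone builder -------------------------

# Ideal backbone internal coordinates (Engh-Huber-like).
NERF_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
  a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7
)

# Place atom D given positions of A, B, C, a bond length C-D, the angle
# B-C-D and the dihedral A-B-C-D (degrees).
nerf_place <- function(a, b, c, bond, angle, dihedral) {
  ang <- deg2rad(angle); dih <- deg2rad(dihedral)
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m2 + d2[3] * n
}

# Build an ideal-geometry backbone from per-residue torsions and return the
# CA trace. `torsions` is a data frame with columns phi, psi, omega; phi of
# the first residue and psi/omega beyond the last are ignored.
nerf_ca_trace <- function(torsions) {
  n <- nrow(torsions)
  g <- NERF_GEOM
  N <- matrix(0, n, 3); CA <- matrix(0, n, 3); C <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- deg2rad(g$a_n_ca_c)
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (k in seq_len(n - 1)) {
    N[k + 1, ] <- nerf_place(N[k, ], CA[k, ], C[k, ], g$b_c_n, g$a_ca_c_n,
                             torsions$psi[k])
    CA[k + 1, ] <- nerf_place(CA[k, ], C[k, ], N[k + 1, ], g$b_n_ca, g$a_c_n_ca,
                              torsions$omega[k + 1])
    C[k + 1, ] <- nerf_place(C[k, ], N[k + 1, ], CA[k + 1, ], g$b_ca_c,
                             g$a_n_ca_c, torsions$phi[k + 1])
  }
  CA
}

template_torsions <- function(abego) {
  letters1 <- strsplit(abego, "")[[1]]
  do.call(rbind, lapply(letters1, function(l) HS_ABEGO_TORSIONS[[l]]))
}

## Ideal CA trace of a hinge template flanked by one helical residue on each
## side (the anchors). Returns the (hinge_len + 2) x 3 CA matrix.
turn_template_trace <- function(abego) {
  tor <- rbind(HS_HELICAL_TORSION, template_torsions(abego), HS_HELICAL_TORSION)
  nerf_ca_trace(as.data.frame(tor))
}

rotation_about_axis <- function(axis, theta_deg) {
  u <- axis / sqrt(sum(axis^2))
  t <- deg2rad(theta_deg); ct <- cos(t); st <- sin(t)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), 3, 3, byrow = TRUE)
}

## Place the hinge CAs of the best-matching turn template between two anchor
## CAs. The template end-to-end vector is aligned to the anchor gap and the
## roll angle about it is chosen (deterministically) to push the turn
## radially outward, away from the bundle axis.
build_turn <- function(anchor_a, anchor_b, hinge_len) {
  gap_vec <- anchor_b - anchor_a
  gap <- sqrt(sum(gap_vec^2))
  if (gap > hinge_len * HS_HELIX$ca_ca) {
    stop(sprintf(
      "turn closure failure: hinge endpoints %.2f A apart exceed hinge_len x 3.8 = %.2f A",
      gap, hinge_len * HS_HELIX$ca_ca), call. = FALSE)
  }
  templates <- HS_TURN_TEMPLATES[[as.character(hinge_len)]]
  if (is.null(templates)) stop("no turn templates for hinge length ", hinge_len,
                               call. = FALSE)
  traces <- lapply(templates, turn_template_trace)
  ee <- vapply(traces, function(m) sqrt(sum((m[nrow(m), ] - m[1, ])^2)), numeric(1))
  pick <- which.min(abs(ee - gap))
  trace <- traces[[pick]]
  n <- nrow(trace)
  # Align template end-to-end direction onto the anchor gap.
  u <- (trace[n, ] - trace[1, ]); u <- u / sqrt(sum(u^2))
  v <- gap_vec / gap
  axis <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(axis^2)); ct <- sum(u * v)
  R1 <- if (s < 1e-12) {
    if (ct > 0) diag(3) else rotation_about_axis(c(0, 0, 1) - u * u[3], 180)
  } else {
    rotation_about_axis(axis, rad2deg(atan2(s, ct)))
  }
  local <- sweep(trace, 2, trace[1, ]) %*% t(R1)
  hinge_rows <- 2:(n - 1)
  best <- NULL
  for (theta in seq(0, 359, by = HS_BUILDER$turn_roll_step_deg)) {
    R2 <- rotation_about_axis(v, theta)
    pts <- sweep(local %*% t(R2), 2, anchor_a, "+")
    score <- sum(sqrt(pts[hinge_rows, 1]^2 + pts[hinge_rows, 2]^2))
    if (is.null(best) || score > best$score) best <- list(score = score, pts = pts)
  }
  list(ca = best$pts[hinge_rows, , drop = FALSE],
       abego = templates[[pick]],
       torsions = template_torsions(templates[[pick]]),
       end_mismatch = abs(ee[pick] - gap))
}

## ---- Monomer assembly ---------------------------------------------------

base_sequence <- function(n) rep("A", n)

build_base_monomer <- function(spec) {
  inner <- generate_helix(spec$inner_helix)
  outer <- generate_helix(spec$outer_helix)
  n_in <- spec$inner_helix$n_res
  ht <- HS_HELICAL_TORSION
  dplyr::bind_rows(
    tibble::tibble(resno = inner$resno, segment = "base_inner",
                   aa = base_sequence(n_in),
                   x = inner$x, y = inner$y, z = inner$z,
                   phi = ht[["phi"]], psi = ht[["psi"]], omega = ht[["omega"]]),
    tibble::tibble(resno = n_in + outer$resno, segment = "base_outer",
                   aa = base_sequence(spec$outer_helix$n_res),
                   x = outer$x, y = outer$y, z = outer$z,
                   phi = ht[["phi"]], psi = ht[["psi"]], omega = ht[["omega"]])
  )
}

hinge_flip_sequence <- function(spec) {
  hs <- strsplit(spec$hinge_sequence, "")[[1]]
  c(hs[seq_len(spec$hinge_len)],                        # hinge residues
    hs[spec$hinge_len + 1L],                            # backup = first flipping
    base_sequence(spec$flipping_helix_len - 1L))
}

#' Build the long (extended) state of a design
#'
#' The hinge residues are assigned helical torsions and the flipping helix
#' continues the outer helix past the hinge: the superhelical radius tapers
#' from the outer-ring radius to the packing radius at which the three
#' flipping helices meet across the symmetry axis, so that they extend to
#' form interactions with each other. The resulting trimer is exactly
#' C3-symmetric and is checked for inter-chain CA clashes.
#'
#' @param spec An [architecture_spec()].
#' @return A [bundle_model()] with `state_tag = "long"`.
#' @export
#' @examples
#' long <- build_long_state(default_architecture())
#' measure_height(long)
build_long_state <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  base <- build_base_monomer(spec)
  n_in <- spec$inner_helix$n_res
  n_out <- spec$outer_helix$n_res
  n_ext <- spec$hinge_len + spec$flipping_helix_len
  t_ext <- seq(n_out, n_out + n_ext - 1)
  taper <- pmax(
    HS_BUILDER$long_pack_radius,
    spec$outer_helix$r0 - (t_ext - (n_out - 1)) *
      (spec$outer_helix$r0 - HS_BUILDER$long_pack_radius) / (spec$hinge_len + 1)
  )
  ext <- crick_xyz(spec$outer_helix, t = t_ext, r0 = taper)
  ht <- HS_HELICAL_TORSION
  ext_tbl <- tibble::tibble(
    resno = n_in + n_out + seq_len(n_ext),
    segment = rep(c("hinge", "flipping"),
                  c(spec$hinge_len, spec$flipping_helix_len)),
    aa = hinge_flip_sequence(spec),
    x = ext[, 1], y = ext[, 2], z = ext[, 3],
    phi = ht[["phi"]], psi = ht[["psi"]], omega = ht[["omega"]]
  )
  model <- bundle_model(apply_c3(dplyr::bind_rows(base, ext_tbl)),
                        state_tag = "long")
  check_clashes(model, what = "long state")
  model
}

#' Build the short (compact) state of a design
#'
#' Requires `hinge_mode = "turn"`. The flipping helix folds back antiparallel
#' to the inner helix of the same monomer and packs against it; the hinge is
#' closed with the fixed ABEGO turn template whose ideal end-to-end CA
#' distance best matches the anchor gap, so the hinge torsion string always
#' contains non-helical (non-A) bins.
#'
#' @param spec An [architecture_spec()].
#' @return A [bundle_model()] with `state_tag = "short"`.
#' @export
#' @examples
#' short <- build_short_state(default_architecture())
#' measure_height(short)
build_short_state <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  if (spec$hinge_mode != "turn") {
    stop("build_short_state: spec must have hinge_mode = 'turn'", call. = FALSE)
  }
  base <- build_base_monomer(spec)
  n_in <- spec$inner_helix$n_res
  n_out <- spec$outer_helix$n_res
  bp <- HS_BUILDER
  outer_top_z <- max(base$z[base$segment == "base_outer"])

  # Folded-back flipping helix: vertical axis at the short-state packing
  # radius, descending (antiparallel to the inner helix), minor phase chosen
  # so the first CA points inward toward the turn.
  L <- spec$flipping_helix_len
  k <- seq_len(L) - 1
  az <- deg2rad(bp$short_flip_azimuth)
  psi <- deg2rad(-HS_HELIX$twist * k + 180)
  radial <- bp$short_flip_radius + HS_HELIX$r1 * cos(psi)
  tang <- HS_HELIX$r1 * sin(psi)
  z_top <- outer_top_z - (bp$short_flip_drop_base +
                            bp$short_flip_drop_res * spec$hinge_len)
  flip <- cbind(
    x = radial * cos(az) - tang * sin(az),
    y = radial * sin(az) + tang * cos(az),
    z = z_top - HS_HELIX$rise * k
  )

  anchor_a <- unlist(base[base$resno == n_in + n_out, c("x", "y", "z")])
  turn <- build_turn(anchor_a, flip[1, ], spec$hinge_len)

  ht <- HS_HELICAL_TORSION
  ext_tbl <- tibble::tibble(
    resno = n_in + n_out + seq_len(spec$hinge_len + L),
    segment = rep(c("hinge", "flipping"), c(spec$hinge_len, L)),
    aa = hinge_flip_sequence(spec),
    x = c(turn$ca[, 1], flip[, 1]),
    y = c(turn$ca[, 2], flip[, 2]),
    z = c(turn$ca[, 3], flip[, 3]),
    phi = c(turn$torsions[, "phi"], rep(ht[["phi"]], L)),
    psi = c(turn$torsions[, "psi"], rep(ht[["psi"]], L)),
    omega = c(turn$torsions[, "omega"], rep(ht[["omega"]], L))
  )
  model <- bundle_model(apply_c3(dplyr::bind_rows(base, ext_tbl)),
                        state_tag = "short")
  check_clashes(model, what = "short state")
  model
}

#' Axial height of a model
#'
#' Maximum minus minimum CA z coordinate along the C3 axis.
#'
#' @param model A [bundle_model()] or any data frame with a `z` column.
#' @return Height in Angstrom (non-negative).
#' @export
#' @examples
#' measure_height(build_long_state(default_architecture()))
measure_height <- function(model) {
  if (is.null(model$z) || length(model$z) == 0) {
    stop("measure_height: empty model", call. = FALSE)
  }
  diff(range(model$z))
}

#' Check hinge ion-coordination-site feasibility
#'
#' Approximates the three symmetry-related coordinating side chains by
#' pseudo-atoms offset a fixed distance from the CA toward the bundle axis,
#' and reports whether they form a plausible coordination triad: their common
#' centroid must lie on the axis and each pseudo-atom must sit within the
#' coordination distance window of the centroid (defaults mimic Ca2+-O
#' coordination).
#'
#' @param model A three-chain [bundle_model()].
#' @param residue_index 1-based per-chain residue number (defaults to
#'   nothing; pass the design's key hinge residue).
#' @param window Coordination distance window `[min, max]` in Angstrom.
#' @param offset Pseudo side-chain offset from CA toward the axis (Angstrom).
#' @param axis_tol Tolerance for the centroid-on-axis check (Angstrom).
#' @return An `ion_site_report` list: `feasible`, `triad_radius`,
#'   `centroid_z`, `coordination_distance_window`, `residue_index`.
#' @export
#' @examples
#' long <- build_long_state(default_architecture())
#' check_ion_site(long, default_architecture()$key_hinge_index)
check_ion_site <- function(model, residue_index,
                           window = HS_BUILDER$ion_window,
                           offset = HS_BUILDER$ion_offset,
                           axis_tol = 0.1) {
  chains <- sort(unique(model$chain))
  if (length(chains) != 3) stop("check_ion_site: model must have 3 chains", call. = FALSE)
  ca <- lapply(chains, function(ch) {
    row <- model[model$chain == ch & model$resno == residue_index, ]
    if (nrow(row) != 1) {
      stop(sprintf("check_ion_site: residue %d missing on chain %s",
                   residue_index, ch), call. = FALSE)
    }
    unlist(row[, c("x", "y", "z")])
  })
  pseudo <- do.call(rbind, lapply(ca, function(p) {
    r <- sqrt(p[1]^2 + p[2]^2)
    if (r < 1e-9) return(p)
    shift <- min(offset, r)  # never push past the axis
    p - c(p[1], p[2], 0) / r * shift
  }))
  centroid <- colMeans(pseudo)
  d <- sqrt(rowSums(sweep(pseudo, 2, centroid)^2))
  on_axis <- sqrt(sum(centroid[1:2]^2)) <= axis_tol
  feasible <- on_axis && all(d >= window[1]) && all(d <= window[2])
  structure(list(
    feasible = feasible,
    triad_radius = mean(d),
    centroid_z = unname(centroid[3]),
    coordination_distance_window = window,
    residue_index = residue_index
  ), class = "ion_site_report")
}

#' @export
print.ion_site_report <- function(x, ...) {
  cat(sprintf(
    "<ion_site_report>  residue %d: %s (triad radius %.2f A, window [%.1f, %.1f] A, centroid z %.2f A)\n",
    x$residue_index, if (x$feasible) "feasible" else "infeasible",
    x$triad_radius, x$coordination_distance_window[1],
    x$coordination_distance_window[2], x$centroid_z))
  invisible(x)
}
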