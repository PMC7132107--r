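## Shrake-Rupley solvent-accessible surface area on a coarse-grained CA
## pseudo-residue model: every residue is a sphere of uniform radius rolled
## by a water-sized probe, sampled on a deterministic Fibonacci sphere.

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley, CA pseudo-residues)
#'
#' Deterministic Shrake-Rupley SASA with uniform per-residue sphere radii and
#' a fixed Fibonacci point set. A single isolated sphere recovers the
#' analytic area `4 * pi * (radius + probe)^2` to within the quadrature
#' resolution.
#'
#' @param coords Data frame or matrix of CA coordinates (columns x, y, z).
#' @param radius Pseudo-residue sphere radius (Angstrom).
#' @param probe Probe radius (Angstrom).
#' @param n_points Number of quadrature points per sphere.
#' @return Numeric vector of per-residue SASA (Angstrom^2).
#' @export
#' @examples
#' sasa_shrake_rupley(data.frame(x = 0, y = 0, z = 0))
#' 4 * pi * (3.0 + 1.4)^2
sasa_shrake_rupley <- function(coords, radius = HS_SASA$radius,
                               probe = HS_SASA$probe,
                               n_points = HS_SASA$n_points) {
  m <- as.matrix(as.data.frame(coords)[, c("x", "y", "z")])
  n <- nrow(m)
  r_ext <- radius + probe
  sphere <- fibonacci_sphere(n_points) * r_ext
  area_per_point <- 4 * pi * r_ext^2 / n_points
  d2 <- outer(rowSums(m^2), rowSums(m^2), "+") - 2 * m %*% t(m)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (2 * r_ext)^2 & seq_len(n) != i)
    pts <- sweep(sphere, 2, m[i, ], "+")
    if (length(nb) == 0) {
      out[i] <- n_points * area_per_point
      next
    }
    nb_m <- m[nb, , drop = FALSE]
    pd2 <- outer(rowSums(pts^2), rowSums(nb_m^2), "+") - 2 * pts %*% t(nb_m)
    exposed <- rowSums(pd2 < r_ext^2) == 0
    out[i] <- sum(exposed) * area_per_point
  }
  out
}

#' Per-layer burial difference between the two states
#'
#' For every interface layer, computes the summed per-residue SASA change
#' from the short to the long state (`SASA_long - SASA_short`). Layer
#' residues on the inner helix become more exposed when the flipping helix
#' leaves in the long state, so their deltas are non-negative; the quantity
#' is additive over disjoint residue sets.
#'
#' @param short_model,long_model [bundle_model()]s of the same design (shared
#'   residue numbering).
#' @param assignment A [assign_layers()] result.
#' @return A tibble with columns `layer`, `side`, `delta_sasa` (Angstrom^2).
#' @export
#' @examples
#' spec <- default_architecture()
#' s <- build_short_state(spec); l <- build_long_state(spec)
#' burial_delta(s, l, assign_layers(s))
burial_delta <- function(short_model, long_model, assignment) {
  per_res <- function(model) {
    tibble::tibble(chain = model$chain, resno = model$resno,
                   sasa = sasa_shrake_rupley(model[, c("x", "y", "z")]))
  }
  s_sasa <- per_res(short_model)
  l_sasa <- per_res(long_model)
  missing <- setdiff(assignment$resno, intersect(s_sasa$resno, l_sasa$resno))
  if (length(missing) > 0) {
    stop("burial_delta: residues missing from models: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  assignment |>
    dplyr::rowwise() |>
    dplyr::mutate(delta_sasa =
      sum(l_sasa$sasa[l_sasa$resno == .data$resno]) -
      sum(s_sasa$sasa[s_sasa$resno == .data$resno])) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$layer, .data$side) |>
    dplyr::summarise(delta_sasa = sum(.data$delta_sasa), .groups = "drop")
}
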