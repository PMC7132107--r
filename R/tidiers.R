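## broom-style tidiers for the package's fitted objects.

#' Tidy a Crick fit
#'
#' @param x A [fit_crick()] result.
#' @param ... Ignored.
#' @return One row per fitted parameter (`term`, `estimate`, `unit`).
#' @export
tidy.crick_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("r0", "omega0", "omega1", "phi0", "phi1", "r1", "delta_z", "z_offset"),
    estimate = c(p$r0, p$omega0, p$omega1, p$phi0, p$phi1, p$r1, p$delta_z, p$z_offset),
    unit = c("A", "deg/res", "deg/res", "deg", "deg", "A", "A/res", "A")
  )
}

#' @rdname tidy.crick_fit
#' @export
glance.crick_fit <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, n = x$n, orientation = x$params$orientation)
}

#' Tidy a Guinier fit
#'
#' @param x A [guinier_fit()] result.
#' @param ... Ignored.
#' @return Tidy parameter table / one-row model summary.
#' @export
tidy.guinier_fit <- function(x, ...) {
  tibble::tibble(term = c("Rg", "I0"), estimate = c(x$Rg, x$I0),
                 unit = c("A", "a.u."))
}

#' @rdname tidy.guinier_fit
#' @export
glance.guinier_fit <- function(x, ...) {
  tibble::tibble(Rg = x$Rg, I0 = x$I0, n_points = x$n_points,
                 q_min = x$window[1], q_max = x$window[2],
                 r_squared = x$r_squared)
}

#' Tidy a two-state profile fit
#'
#' @param x A [fit_states()] result.
#' @param ... Ignored.
#' @return One row per state with chi and scale.
#' @export
tidy.state_fit <- function(x, ...) {
  tibble::tibble(state = names(x$chi), chi = unname(x$chi),
                 scale = unname(x$scale[names(x$chi)]),
                 dominant = names(x$chi) == x$dominant)
}

#' @rdname tidy.state_fit
#' @export
glance.state_fit <- function(x, ...) {
  tibble::tibble(dominant = x$dominant, chi_short = x$chi[["short"]],
                 chi_long = x$chi[["long"]], chi_ratio = x$chi_ratio, n = x$n)
}

#' Tidy a state classification
#'
#' @param x A [classify_state()] result.
#' @param ... Ignored.
#' @return A one-row tibble.
#' @export
tidy.classification_result <- function(x, ...) {
  tibble::tibble(label = x$label, rmsd_short = x$rmsd_short,
                 rmsd_long = x$rmsd_long, threshold = x$threshold,
                 chain_mapping = paste(x$chain_mapping, collapse = ""))
}

#' Tidy an ion-site report
#'
#' @param x A [check_ion_site()] result.
#' @param ... Ignored.
#' @return A one-row tibble.
#' @export
tidy.ion_site_report <- function(x, ...) {
  tibble::tibble(residue = x$residue_index, feasible = x$feasible,
                 triad_radius = x$triad_radius, centroid_z = x$centroid_z,
                 window_min = x$coordination_distance_window[1],
                 window_max = x$coordination_distance_window[2])
}
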