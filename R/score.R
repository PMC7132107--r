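## State-preference scoring of layer configurations, and a geometric
## stand-in for hydrogen-bond-network feasibility.

#' Score the state preference of a layer configuration
#'
#' Transparent linear proxy for the relative short/long preference of an
#' interface configuration. Each hydrogen-bond layer ("A") pushes toward the
#' long state (its polar network is buried in the short state but tolerates
#' the partial exposure of the long state), each hydrophobic layer ("X")
#' rewards burial in the short state; both contributions carry frozen
#' position weights, hinge-proximal first. Negative scores favor the short
#' state, positive the long state. Under the frozen default weights the score
#' is strictly monotone in the number of A layers and reproduces the observed
#' state pattern (XXA, XAX, XAA short; AAA long).
#'
#' @param config A [layer_config()] or code string.
#' @param burial_deltas Optional per-layer relative burial factors (length 3,
#'   hinge-proximal first); defaults to 1 for every layer. When supplied
#'   (e.g. normalized [burial_delta()] magnitudes) they modulate the layer
#'   contributions.
#' @param weights List with elements `w_A` and `w_X` (length-3 position
#'   weights); defaults to the frozen calibration.
#' @return A single signed score.
#' @export
#' @examples
#' score_state_preference("XAX")  # negative: short-favoring
#' score_state_preference("AAA")  # positive: long-favoring
score_state_preference <- function(config, burial_deltas = NULL,
                                   weights = HS_SCORE_WEIGHTS) {
  if (is.character(config)) config <- layer_config(config)
  k <- length(config$layers)
  e <- if (is.null(burial_deltas)) rep(1, k) else {
    b <- abs(as.numeric(burial_deltas))
    if (length(b) != k) stop("burial_deltas must have one value per layer", call. = FALSE)
    if (mean(b) > 0) b / mean(b) else rep(0, k)
  }
  is_a <- config$layers == "A"
  sum(ifelse(is_a, weights$w_A * e, -weights$w_X * e))
}

#' Score every layer configuration
#'
#' @inheritParams score_state_preference
#' @return A tibble with `code`, `n_networks`, `score` and the implied
#'   `preference` (`short`/`long`), sorted by score.
#' @export
#' @examples
#' score_all_configs()
score_all_configs <- function(burial_deltas = NULL, weights = HS_SCORE_WEIGHTS) {
  enumerate_configs() |>
    dplyr::mutate(score = purrr::map_dbl(.data$code, score_state_preference,
                                         burial_deltas = burial_deltas,
                                         weights = weights),
                  preference = ifelse(.data$score < 0, "short", "long")) |>
    dplyr::arrange(.data$score)
}

#' Geometric check of a symmetric polar network triad
#'
#' Stand-in for rotamer-level hydrogen-bond-network search: for each given
#' layer residue, the three symmetry-related pseudo donor/acceptor points
#' (CA offset toward the bundle axis) must admit pairwise distances within
#' the hydrogen-bond window of a cyclic network.
#'
#' @param model A three-chain [bundle_model()].
#' @param layer_residues Residue numbers to test.
#' @param window Pairwise distance window (Angstrom).
#' @param offset Pseudo-atom offset from CA toward the axis (Angstrom).
#' @return A list with `feasible` (TRUE if any residue admits a cyclic
#'   network) and `report` (per-residue tibble with the pairwise distance
#'   range and verdict; empty for an empty residue set).
#' @export
polar_triad_check <- function(model, layer_residues,
                              window = HS_INTERFACE$hbond_window,
                              offset = HS_INTERFACE$hbond_offset) {
  if (length(layer_residues) == 0) {
    return(list(feasible = FALSE,
                report = tibble::tibble(resno = integer(), d_min = numeric(),
                                        d_max = numeric(), cyclic = logical())))
  }
  chains <- sort(unique(model$chain))
  rows <- purrr::map_dfr(layer_residues, function(res) {
    pts <- do.call(rbind, lapply(chains, function(ch) {
      row <- model[model$chain == ch & model$resno == res, ]
      if (nrow(row) != 1) {
        stop(sprintf("polar_triad_check: residue %d missing on chain %s", res, ch),
             call. = FALSE)
      }
      p <- unlist(row[, c("x", "y", "z")])
      r <- sqrt(p[1]^2 + p[2]^2)
      if (r > 1e-9) p <- p - c(p[1], p[2], 0) / r * min(offset, r)
      p
    }))
    d <- as.numeric(stats::dist(pts))
    tibble::tibble(resno = res, d_min = min(d), d_max = max(d),
                   cyclic = all(d >= window[1] & d <= window[2]))
  })
  list(feasible = any(rows$cyclic), report = rows)
}
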