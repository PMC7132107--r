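# Shared fixtures, built once per test run.

hs_spec <- default_architecture()
hs_short <- build_short_state(hs_spec)
hs_long <- build_long_state(hs_spec)

# Smallest angular difference in degrees.
ang_diff <- function(a, b) abs(wrap_angle(a - b))

# Random valid Crick parameters in the design-relevant range.
random_crick <- function(n_res = NULL) {
  crick_params(
    r0 = runif(1, 3, 9),
    omega0 = runif(1, -4, -0.5),
    omega1 = runif(1, 95, 105),
    phi0 = runif(1, -179, 179),
    phi1 = runif(1, -179, 179),
    r1 = runif(1, 2.0, 2.5),
    delta_z = runif(1, 1.4, 1.6),
    z_offset = runif(1, -5, 5),
    n_res = n_res %||% sample(24:34, 1)
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny three-chain model with one residue per chain at the given axis
# radius (used for ion-site and polar-triad geometry checks).
triad_model <- function(radius, z = 0) {
  bundle_model(apply_c3(tibble::tibble(resno = 1L, segment = "hinge",
                                       aa = "G", x = radius, y = 0, z = z)))
}

# Axis direction of one segment of one chain.
chain_segment_axis <- function(model, ch, seg) {
  d <- model[model$chain == ch & model$segment == seg, ]
  segment_axis(as.matrix(d[, c("x", "y", "z")]))
}

# Minimum CA-CA distance between two coordinate subsets of a model.
min_dist_between <- function(a, b) {
  ma <- as.matrix(a[, c("x", "y", "z")]); mb <- as.matrix(b[, c("x", "y", "z")])
  sqrt(min(outer(rowSums(ma^2), rowSums(mb^2), "+") - 2 * ma %*% t(mb)))
}
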