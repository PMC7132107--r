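test_that("degenerate supercoil reduces to a straight ideal alpha-helix", {
  p <- crick_params(r0 = 0, omega0 = 0, r1 = 2.26, n_res = 18)
  h <- generate_helix(p)
  expect_equal(nrow(h), 18)
  # axis is z: xy stays on the minor circle, rise is delta_z per residue
  expect_equal(sqrt(h$x^2 + h$y^2), rep(2.26, 18), tolerance = 1e-12)
  expect_equal(diff(h$z), rep(1.51, 17), tolerance = 1e-12)
})

test_that("generated helices have alpha-helical CA spacing and bounded radius", {
  set.seed(41)
  for (i in 1:20) {
    p <- random_crick()
    h <- generate_helix(p)
    d <- dist_consecutive(as.matrix(h[, c("x", "y", "z")]))
    # random parameters stray from the ideal constants, so the band is wider
    # than the canonical one but spacing must stay alpha-helix-like
    expect_true(all(d >= 3.0 & d <= 4.5))
    expect_true(all(sqrt(h$x^2 + h$y^2) <= p$r0 + p$r1 + 1e-9))
  }
  # standard defaults: spacing within the canonical 3.6-4.0 A band
  h <- generate_helix(crick_params(r0 = 5, omega0 = -3, n_res = 30))
  d <- dist_consecutive(as.matrix(h[, c("x", "y", "z")]))
  expect_true(all(d >= 3.6 & d <= 4.0))
})

test_that("invalid Crick parameters are rejected", {
  expect_error(crick_params(n_res = 1), "n_res")
  expect_error(crick_params(r1 = 0), "r1")
  expect_error(crick_params(r0 = -1), "r0")
})

test_that("apply_c3 produces an exact, isometric C3 trimer", {
  # axis fixed point: all three images coincide
  axis_pt <- tibble::tibble(x = 0, y = 0, z = 5)
  tri <- apply_c3(axis_pt)
  expect_equal(unlist(tri[1, c("x", "y", "z")]), unlist(tri[2, c("x", "y", "z")]))
  expect_equal(unlist(tri[2, c("x", "y", "z")]), unlist(tri[3, c("x", "y", "z")]))

  set.seed(7)
  mono <- generate_helix(random_crick(12))
  tri <- apply_c3(mono)
  # group closure: three successive 120-degree rotations are the identity
  m <- as.matrix(mono[, c("x", "y", "z")])
  r120 <- rot_z(120)
  expect_lt(max(abs(m %*% t(r120) %*% t(r120) %*% t(r120) - m)), 1e-9)
  # centroid on the axis
  expect_lt(abs(mean(tri$x)), 1e-9)
  expect_lt(abs(mean(tri$y)), 1e-9)
  # isometry: intra-monomer distances preserved exactly
  for (ch in c("B", "C")) {
    mc <- as.matrix(tri[tri$chain == ch, c("x", "y", "z")])
    expect_equal(as.numeric(dist(mc)), as.numeric(dist(m)), tolerance = 1e-12)
  }
  expect_error(apply_c3(tibble::tibble(x = numeric(), y = numeric(), z = numeric())),
               "empty")
})

test_that("fit_crick round-trips generated parameters", {
  set.seed(11)
  for (i in 1:25) {
    p <- random_crick()
    fit <- fit_crick(generate_helix(p))
    expect_lt(fit$rmsd, 1e-3)
    q <- fit$params
    expect_lt(abs(q$r0 - p$r0), 1e-3)
    expect_lt(abs(q$omega0 - p$omega0), 1e-3)
    expect_lt(abs(q$omega1 - p$omega1), 1e-3)
    expect_lt(abs(q$r1 - p$r1), 1e-3)
    expect_lt(abs(q$delta_z - p$delta_z), 1e-3)
    expect_lt(abs(q$z_offset - p$z_offset), 1e-3)
    expect_lt(ang_diff(q$phi0, p$phi0), 1e-3)
    expect_lt(ang_diff(q$phi1, p$phi1), 1e-3)
  }
})

test_that("fit_crick handles the straight-helix and noisy cases", {
  straight <- generate_helix(crick_params(r0 = 0, omega0 = 0, n_res = 20))
  fit <- fit_crick(straight)
  expect_lt(fit$params$r0, 1e-3)

  set.seed(5)
  p <- crick_params(r0 = 6, omega0 = -2.5, phi0 = 40, phi1 = -100, n_res = 30)
  h <- generate_helix(p)
  # 0.2 A rms displacement noise (per coordinate: 0.2 / sqrt(3))
  sd <- 0.2 / sqrt(3)
  noisy <- h
  noisy$x <- h$x + rnorm(30, 0, sd)
  noisy$y <- h$y + rnorm(30, 0, sd)
  noisy$z <- h$z + rnorm(30, 0, sd)
  expect_lte(fit_crick(noisy)$rmsd, 0.3)

  expect_error(fit_crick(h[1:5, ]), "at least 8")
})

test_that("rotation about the bundle axis changes only the phase parameters", {
  set.seed(23)
  for (i in 1:5) {
    p <- random_crick(28)
    h <- generate_helix(p)
    beta <- runif(1, 10, 350)
    m <- as.matrix(h[, c("x", "y", "z")]) %*% t(rot_z(beta))
    fit <- fit_crick(tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3]))
    q <- fit$params
    expect_lt(abs(q$r0 - p$r0), 1e-6)
    expect_lt(abs(q$omega0 - p$omega0), 1e-6)
    expect_lt(abs(q$omega1 - p$omega1), 1e-6)
    expect_lt(abs(q$delta_z - p$delta_z), 1e-6)
    expect_lt(ang_diff(q$phi0, p$phi0 + beta), 1e-5)
  }
})

test_that("ABEGO classification matches the bin definitions", {
  expect_equal(classify_abego(-57, -47, 180), "A")
  expect_equal(classify_abego(-120, 135, 180), "B")
  expect_equal(classify_abego(60, 40, 180), "G")
  expect_equal(classify_abego(75, 160, 180), "E")
  # cis peptide takes precedence whatever phi/psi
  expect_equal(classify_abego(c(-57, 120, -120), c(-47, 0, 135), 0),
               c("O", "O", "O"))
})

test_that("ABEGO bins partition the torsion torus", {
  grid <- expand.grid(phi = seq(-175, 180, by = 17),
                      psi = seq(-175, 180, by = 17),
                      omega = c(0, 45, -89, 91, 180, -120))
  bins <- classify_abego(grid$phi, grid$psi, grid$omega)
  expect_true(all(bins %in% c("A", "B", "E", "G", "O")))
  expect_true(all(nchar(bins) == 1))
  # region consistency: trans + negative phi is never G/E, positive never A/B
  trans <- abs(wrap_angle(grid$omega)) >= 90
  expect_false(any(bins[trans & grid$phi < 0] %in% c("G", "E")))
  expect_false(any(bins[trans & grid$phi >= 0] %in% c("A", "B")))
  # the same input always maps to the same single bin (deterministic, total)
  expect_identical(bins, classify_abego(grid$phi, grid$psi, grid$omega))
})

test_that("Crick JSON serialization round-trips with the canonical field names", {
  p <- crick_params(r0 = 5.5, omega0 = -2.85, phi0 = 12, phi1 = -34,
                    n_res = 21, z_offset = 3)
  js <- crick_to_json(p)
  expect_true(all(c("r0", "omega0", "omega1", "phi0", "phi1", "r1",
                    "delta_z", "z_offset", "orientation", "n_res") %in%
                    names(jsonlite::fromJSON(js))))
  q <- crick_from_json(js)
  expect_equal(unclass(q), unclass(p))
})
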