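test_that("Debye profile obeys its analytic limits", {
  # N unit scatterers: I(0) = N^2
  set.seed(53)
  cloud <- data.frame(x = rnorm(17), y = rnorm(17), z = rnorm(17))
  prof <- debye_profile(cloud, c(0, 0.05, 0.1))
  expect_equal(prof$I[1], 17^2)

  # two unit points at distance d: I(q) = 2 (1 + sin(qd)/(qd))
  d <- 10
  two <- data.frame(x = c(0, d), y = 0, z = 0)
  q <- c(0.05, 0.1, 0.25)
  got <- debye_profile(two, q)$I
  expect_equal(got, 2 * (1 + sin(q * d) / (q * d)), tolerance = 1e-12)

  # rigid motion leaves the profile unchanged
  m <- as.matrix(cloud) %*% t(rotation_about_axis(c(1, 1, 0), 63))
  rot <- data.frame(x = m[, 1] + 5, y = m[, 2], z = m[, 3] - 2)
  expect_equal(debye_profile(rot, q)$I, debye_profile(cloud, q)$I,
               tolerance = 1e-9)

  # I(q) <= I(0) on a compact body
  full <- debye_profile(cloud)
  expect_true(all(full$I <= full$I[1] + 1e-9))

  expect_error(debye_profile(cloud, c(-0.1, 0.1)), "negative q")
})

test_that("radius of gyration matches closed forms and orders the states", {
  expect_equal(radius_of_gyration(data.frame(x = 1, y = 2, z = 3)), 0)
  expect_equal(radius_of_gyration(data.frame(x = c(-1, 1), y = 0, z = 0)), 1)
  expect_gt(radius_of_gyration(hs_long[, c("x", "y", "z")]),
            radius_of_gyration(hs_short[, c("x", "y", "z")]))
})

test_that("Guinier fits recover Rg from profiles", {
  # exact Guinier curve: parameters recovered to machine-level accuracy
  q <- default_q_grid()[-1]
  ideal <- scattering_profile(q, 42 * exp(-q^2 * 20^2 / 3))
  g <- guinier_fit(ideal)
  expect_equal(g$Rg, 20, tolerance = 1e-6)
  expect_equal(g$I0, 42, tolerance = 1e-6)

  # self-consistency: Debye profile of the short state reproduces its
  # coordinate Rg within 2%
  rg_s <- radius_of_gyration(hs_short[, c("x", "y", "z")])
  expect_equal(guinier_fit(debye_profile(hs_short))$Rg, rg_s,
               tolerance = 0.02)

  # 2% multiplicative noise: within 5%
  set.seed(59)
  prof <- debye_profile(hs_short)
  noisy <- scattering_profile(prof$q, prof$I * (1 + rnorm(nrow(prof), 0, 0.02)))
  expect_equal(guinier_fit(noisy)$Rg, rg_s, tolerance = 0.05)

  # seeded random compact point clouds: 2% self-consistency
  for (i in 1:20) {
    cloud <- data.frame(x = rnorm(60, 0, 8), y = rnorm(60, 0, 8),
                        z = rnorm(60, 0, 8))
    rg <- radius_of_gyration(cloud)
    expect_equal(guinier_fit(debye_profile(cloud))$Rg, rg, tolerance = 0.02)
  }

  expect_error(guinier_fit(scattering_profile(c(0.01, 0.02, 0.03),
                                              c(3, 2, 1))), "points")
})

test_that("normalized Kratky analysis locates the compactness peak", {
  # ideal Guinier scatterer peaks at x = sqrt(3), y = 3/e
  q <- seq(0.001, 0.4, length.out = 1001)
  ideal <- scattering_profile(q, 50 * exp(-q^2 * 400 / 3))
  k <- normalized_kratky(ideal, Rg = 20, I0 = 50)
  pk <- kratky_peak(k)
  expect_equal(pk[["x"]], sqrt(3), tolerance = 1e-6)
  expect_equal(pk[["y"]], 3 / exp(1), tolerance = 1e-6)

  # elongation shifts the peak right: long state peaks at larger qRg
  pk_s <- kratky_peak(normalized_kratky(debye_profile(hs_short)))
  pk_l <- kratky_peak(normalized_kratky(debye_profile(hs_long)))
  expect_gt(pk_l[["x"]], pk_s[["x"]])

  # intensity rescaling leaves the normalized curve unchanged
  k2 <- normalized_kratky(scattering_profile(q, 7.3 * (50 * exp(-q^2 * 400 / 3))),
                          Rg = 20, I0 = 7.3 * 50)
  expect_equal(k2$y, k$y, tolerance = 1e-12)
})

test_that("two-state profile fitting identifies the dominant state", {
  prof_s <- debye_profile(hs_short)
  prof_l <- debye_profile(hs_long)

  exact <- fit_states(prof_s, prof_s, prof_l)
  expect_equal(exact$chi[["short"]], 0, tolerance = 1e-9)
  expect_equal(exact$dominant, "short")

  set.seed(61)
  noisy <- scattering_profile(prof_l$q, prof_l$I * (1 + rnorm(nrow(prof_l), 0, 0.02)))
  expect_equal(fit_states(noisy, prof_s, prof_l)$dominant, "long")

  # 50/50 mixture: both fits comparably poor, no confident call
  mix <- scattering_profile(prof_s$q, 0.5 * prof_s$I + 0.5 * prof_l$I)
  fmix <- fit_states(mix, prof_s, prof_l)
  expect_lt(fmix$chi_ratio, 2)

  # dominant label is invariant to rescaling the experimental profile
  scaled <- scattering_profile(noisy$q, 123 * noisy$I, 123 * noisy$sigma)
  expect_equal(fit_states(scaled, prof_s, prof_l)$dominant, "long")

  far <- scattering_profile(seq(2, 3, length.out = 20), rep(1, 20))
  expect_error(fit_states(far, prof_s, prof_l), "disjoint")
})

test_that("combined chemical-shift deviations match the standard formulas", {
  expect_equal(csd_methyl(0, 0), 0)
  expect_equal(csd_methyl(0.1, 0.2), 0.1)
  expect_equal(csd_methyl(0, 0.2), sqrt(0.5 * 0.01), tolerance = 1e-12)
  expect_equal(csd_methyl(0, 0.2), 0.0707, tolerance = 1e-3)
  expect_equal(csd_amide(0, 0), 0)
  expect_equal(csd_amide(0.1, 0.5), 0.1)
  expect_equal(csd_amide(0.2, 0), 0.1414, tolerance = 1e-3)
  # symmetric in sign, zero only at zero
  expect_equal(csd_methyl(-0.1, -0.2), csd_methyl(0.1, 0.2))
  expect_gt(csd_amide(1e-6, 0), 0)

  tab <- csd_table(data.frame(atom_group = c("methyl", "amide"),
                              delta_H = c(0.1, 0.1),
                              delta_C = c(0.2, NA),
                              delta_N = c(NA, 0.5)))
  expect_equal(tab$csd, c(0.1, 0.1))
  expect_error(csd_table(data.frame(atom_group = "ring", delta_H = 1)),
               "atom_group")
})

test_that("tidiers return broom-shaped summaries", {
  fit <- fit_crick(generate_helix(crick_params(r0 = 5, omega0 = -3, n_res = 25)))
  td <- tidy(fit)
  expect_equal(names(td), c("term", "estimate", "unit"))
  expect_equal(nrow(td), 8)
  expect_equal(glance(fit)$n, 25)

  g <- guinier_fit(debye_profile(hs_short))
  expect_equal(tidy(g)$term, c("Rg", "I0"))
  expect_true(glance(g)$r_squared > 0.99)

  f <- fit_states(debye_profile(hs_short), debye_profile(hs_short),
                  debye_profile(hs_long))
  expect_equal(tidy(f)$state, c("short", "long"))
  expect_equal(glance(f)$dominant, "short")

  cls <- classify_state(hs_short, hs_short, hs_long)
  expect_equal(tidy(cls)$label, "short")
  expect_true(tidy(check_ion_site(hs_long, hs_spec$key_hinge_index))$feasible)
})
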