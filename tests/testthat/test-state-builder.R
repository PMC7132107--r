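test_that("default architecture reproduces the design heights", {
  expect_equal(measure_height(hs_short), 66, tolerance = 5 / 66)
  expect_equal(measure_height(hs_long), 100, tolerance = 5 / 100)
  expect_lt(measure_height(hs_short), measure_height(hs_long))
})

test_that("built states satisfy the geometric design contracts", {
  # exact C3 symmetry
  expect_lt(c3_deviation(hs_short), 1e-6)
  expect_lt(c3_deviation(hs_long), 1e-6)
  # no inter-chain clashes
  expect_gt(min_interchain_distance(hs_short)$min_dist, 2.5)
  expect_gt(min_interchain_distance(hs_long)$min_dist, 2.5)
  # long state: flipping continues the outer helix and the three flipping
  # helices approach each other across the axis
  expect_lt(axis_angle_deg(chain_segment_axis(hs_long, "A", "flipping"),
                           chain_segment_axis(hs_long, "A", "base_outer")), 15)
  fl_a <- hs_long[hs_long$chain == "A" & hs_long$segment == "flipping", ]
  fl_b <- hs_long[hs_long$chain == "B" & hs_long$segment == "flipping", ]
  expect_lt(min_dist_between(fl_a, fl_b), 12)
  # short state: flipping folds back antiparallel to, and packed against,
  # the inner helix of the same monomer
  expect_gt(axis_angle_deg(chain_segment_axis(hs_short, "A", "flipping"),
                           chain_segment_axis(hs_short, "A", "base_inner")), 150)
  fs_a <- hs_short[hs_short$chain == "A" & hs_short$segment == "flipping", ]
  in_a <- hs_short[hs_short$chain == "A" & hs_short$segment == "base_inner", ]
  expect_lt(min_dist_between(fs_a, in_a), 10)
  # segment labels partition every residue
  expect_true(all(hs_short$segment %in%
                    c("base_inner", "base_outer", "hinge", "flipping")))
})

test_that("hinge torsions are helical in the long state, non-helical in the turn", {
  hinge_long <- hs_long[hs_long$chain == "A" & hs_long$segment == "hinge", ]
  expect_equal(abego_string(hinge_long), strrep("A", nrow(hinge_long)))
  hinge_short <- hs_short[hs_short$chain == "A" & hs_short$segment == "hinge", ]
  expect_true(grepl("[^A]", abego_string(hinge_short)))
})

test_that("both states build cleanly across flipping and hinge lengths", {
  for (flip_len in c(15L, 21L, 24L)) {
    for (hinge_len in c(2L, 4L, 7L)) {
      spec <- architecture_spec(
        inner_helix = hs_spec$inner_helix, outer_helix = hs_spec$outer_helix,
        flipping_helix_len = flip_len, hinge_len = hinge_len)
      s <- build_short_state(spec)
      l <- build_long_state(spec)
      expect_lt(c3_deviation(s), 1e-6)
      expect_lt(c3_deviation(l), 1e-6)
      expect_gt(measure_height(l) - measure_height(s), 15)
      hinge <- s[s$chain == "A" & s$segment == "hinge", ]
      expect_true(grepl("[^A]", abego_string(hinge)))
    }
  }
})

test_that("spec invariants are enforced", {
  expect_error(architecture_spec(hs_spec$inner_helix, hs_spec$outer_helix,
                                 flipping_helix_len = 0), "flipping_helix_len")
  expect_error(architecture_spec(hs_spec$inner_helix, hs_spec$outer_helix,
                                 hinge_len = 8), "hinge_len")
  helical <- architecture_spec(hs_spec$inner_helix, hs_spec$outer_helix,
                               hinge_mode = "helical")
  expect_error(build_short_state(helical), "turn")
})

test_that("measure_height behaves as max-minus-min of z", {
  single <- bundle_model(tibble::tibble(chain = "A", resno = 1,
                                        x = 1, y = 2, z = 3))
  expect_equal(measure_height(single), 0)
  # straight 66-residue ideal helix: (n - 1) x rise
  h66 <- generate_helix(crick_params(n_res = 66))
  expect_equal(measure_height(h66), 65 * 1.51, tolerance = 1e-12)
  # invariance under rotation about z
  rot <- hs_short
  m <- as.matrix(rot[, c("x", "y", "z")]) %*% t(rot_z(77))
  rot$x <- m[, 1]; rot$y <- m[, 2]; rot$z <- m[, 3]
  expect_equal(measure_height(rot), measure_height(hs_short))
  expect_error(measure_height(tibble::tibble(z = numeric())), "empty")
})

test_that("ion-site feasibility separates the two states at the key residue", {
  key <- hs_spec$key_hinge_index
  expect_true(check_ion_site(hs_long, key)$feasible)
  expect_false(check_ion_site(hs_short, key)$feasible)
  # synthetic triads: pseudo-atoms 2.4 A from an axial point are feasible,
  # a 6 A triad radius is not
  expect_true(check_ion_site(triad_model(4.8), 1)$feasible)
  near <- check_ion_site(triad_model(4.8), 1)
  expect_equal(near$triad_radius, 2.4, tolerance = 1e-9)
  far <- check_ion_site(triad_model(8.4), 1)
  expect_false(far$feasible)
  expect_equal(far$triad_radius, 6, tolerance = 1e-9)
  expect_error(check_ion_site(hs_long, 9999), "missing")
})

test_that("mutate_hinge swaps exactly the hinge window", {
  v <- mutate_hinge(hs_spec, "GVDQ")
  expect_equal(v$hinge_sequence, "GVDQ")
  same <- setdiff(names(unclass(hs_spec)), "hinge_sequence")
  expect_equal(unclass(v)[same], unclass(hs_spec)[same])
  expect_equal(hs_spec$hinge_sequence, "GGGT")  # parent untouched (pure)
  expect_s3_class(mutate_hinge(hs_spec, "GGHN"), "architecture_spec")
  expect_error(mutate_hinge(hs_spec, "GGG"), "length")
  expect_error(mutate_hinge(hs_spec, "GGZQ"), "invalid amino-acid")
})

test_that("the mutated hinge sequence propagates into built models", {
  m <- build_long_state(mutate_hinge(hs_spec, "GGHN"))
  ch <- m[m$chain == "A", ]
  win <- ch$aa[ch$resno %in% (hs_spec$key_hinge_index - 2):(hs_spec$key_hinge_index + 1)]
  expect_equal(paste(win, collapse = ""), "GGHN")
})
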