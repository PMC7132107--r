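test_that("Kabsch superposition recovers exact transforms and stays proper", {
  set.seed(19)
  P <- matrix(rnorm(60), 20, 3)
  self <- kabsch_superpose(P, P)
  expect_lt(self$rmsd, 1e-12)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)

  # construct-and-recover: rotate 37 degrees about a random axis + translate
  axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
  R <- rotation_about_axis(axis, 37)
  Q <- P %*% t(R) + matrix(c(3, -2, 7), 20, 3, byrow = TRUE)
  fit <- kabsch_superpose(P, Q)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$rotation, R, tolerance = 1e-7)

  # reflection-related sets: proper rotation enforced, so RMSD stays > 0
  M <- P %*% diag(c(1, 1, -1))
  ref <- kabsch_superpose(P, M)
  expect_gt(ref$rmsd, 0.1)
  expect_equal(det(ref$rotation), 1, tolerance = 1e-9)

  # independent cross-check against bio3d's superposition RMSD
  set.seed(20)
  A <- matrix(rnorm(45), 15, 3)
  B <- A %*% t(rotation_about_axis(c(0, 1, 1), 70)) + matrix(rnorm(45, 0, 0.5), 15, 3)
  expect_equal(kabsch_superpose(A, B)$rmsd,
               as.numeric(bio3d::rmsd(as.vector(t(B)), as.vector(t(A)), fit = TRUE)),
               tolerance = 1e-4)

  expect_error(kabsch_superpose(P, P[1:10, ]), "mismatch")
  line <- cbind(1:10, 0, 0)
  expect_error(kabsch_superpose(line, line), "rank-deficient")
})

test_that("symmetric RMSD absorbs cyclic relabeling and matches brute force", {
  relabeled <- hs_long
  relabeled$chain <- c(A = "B", B = "C", C = "A")[relabeled$chain]
  expect_lt(symmetric_rmsd(relabeled, hs_long)$rmsd, 1e-9)

  set.seed(29)
  for (i in 1:5) {
    decoy <- perturb_model(hs_long, runif(1, 0.3, 2))
    got <- symmetric_rmsd(decoy, hs_long)
    # independent brute-force oracle over the three cyclic chain mappings
    perms <- list(c("A", "B", "C"), c("B", "C", "A"), c("C", "A", "B"))
    oracle <- min(vapply(perms, function(pm) {
      m <- do.call(rbind, lapply(pm, function(ch) {
        as.matrix(decoy[decoy$chain == ch, c("x", "y", "z")])
      }))
      r <- do.call(rbind, lapply(c("A", "B", "C"), function(ch) {
        as.matrix(hs_long[hs_long$chain == ch, c("x", "y", "z")])
      }))
      kabsch_superpose(m, r)$rmsd
    }, numeric(1)))
    expect_equal(got$rmsd, oracle, tolerance = 1e-12)
    # never worse than the identity mapping
    id_rmsd <- kabsch_superpose(
      do.call(rbind, lapply(c("A", "B", "C"), function(ch)
        as.matrix(decoy[decoy$chain == ch, c("x", "y", "z")]))),
      do.call(rbind, lapply(c("A", "B", "C"), function(ch)
        as.matrix(hs_long[hs_long$chain == ch, c("x", "y", "z")]))))$rmsd
    expect_lte(got$rmsd, id_rmsd + 1e-12)
  }
})

test_that("noise of known magnitude produces the expected RMSD scale", {
  set.seed(31)
  rmsds <- replicate(5, symmetric_rmsd(perturb_model(hs_long, 1.0), hs_long)$rmsd)
  # isotropic per-coordinate sd 1 A gives ~sqrt(3) A; superposition absorbs a
  # little of it
  expect_true(all(rmsds > 1.45 & rmsds < 1.95))
})

test_that("RMSD behaves as a pseudo-metric on superposed structures", {
  set.seed(37)
  a <- perturb_model(hs_short, 0.8)
  b <- perturb_model(hs_short, 0.8)
  c <- perturb_model(hs_short, 0.8)
  rab <- symmetric_rmsd(a, b)$rmsd
  rba <- symmetric_rmsd(b, a)$rmsd
  expect_equal(rab, rba, tolerance = 1e-9)
  expect_lt(symmetric_rmsd(a, a)$rmsd, 1e-12)
  rac <- symmetric_rmsd(a, c)$rmsd
  rbc <- symmetric_rmsd(b, c)$rmsd
  expect_lte(rac, rab + rbc + 1e-9)
})

test_that("classify_state labels short, long, other and handles ties", {
  expect_equal(classify_state(hs_short, hs_short, hs_long)$label, "short")
  expect_equal(classify_state(hs_short, hs_short, hs_long)$rmsd_short, 0)

  set.seed(43)
  noisy_long <- perturb_model(hs_long, 0.5)
  res <- classify_state(noisy_long, hs_short, hs_long, threshold = 3)
  expect_equal(res$label, "long")

  # an unrelated extended trace is neither state
  n_per <- nrow(hs_short) / 3
  stretched <- hs_short
  stretched$x <- rep(seq(0, by = 3.8, length.out = n_per), 3)
  stretched$y <- 0
  stretched$z <- rep(c(0, 5, 10), each = n_per)
  expect_equal(classify_state(stretched, hs_short, hs_long)$label, "other")

  # exact tie: identical references make both RMSDs equal
  expect_equal(classify_state(hs_short, hs_short, hs_short)$label, "other")

  # invariance to a global rigid motion of the candidate
  moved <- noisy_long
  m <- as.matrix(moved[, c("x", "y", "z")]) %*% t(rotation_about_axis(c(1, 2, 3), 55))
  moved$x <- m[, 1] + 12; moved$y <- m[, 2] - 4; moved$z <- m[, 3] + 100
  res2 <- classify_state(moved, hs_short, hs_long, threshold = 3)
  expect_equal(res2$label, res$label)
  expect_equal(res2$rmsd_long, res$rmsd_long, tolerance = 1e-6)
})

test_that("state fractions recover the decoy mixing proportions", {
  ten_short <- replicate(10, hs_short, simplify = FALSE)
  expect_equal(as.numeric(state_fractions(ten_short, hs_short, hs_long)[1, 1:3]),
               c(1, 0, 0))
  set.seed(47)
  decoys <- c(replicate(5, perturb_model(hs_short, 0.5), simplify = FALSE),
              replicate(5, perturb_model(hs_long, 0.5), simplify = FALSE))
  fr <- state_fractions(decoys, hs_short, hs_long, threshold = 3)
  expect_equal(as.numeric(fr[1, 1:3]), c(0.5, 0.5, 0))
  expect_equal(fr$f_short + fr$f_long + fr$f_other, 1)
  # degenerate threshold: nothing resembles anything
  fr0 <- state_fractions(decoys, hs_short, hs_long, threshold = 0)
  expect_equal(as.numeric(fr0[1, 1:3]), c(0, 0, 1))
  expect_error(state_fractions(list(), hs_short, hs_long), "empty")
})
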