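test_that("superposition recovers exact transforms and degenerate inputs error", {
  set.seed(7)
  A <- matrix(stats::rnorm(60), 20, 3)
  # self-superposition: identity, rmsd 0
  k <- kabsch_superpose(A, A)
  expect_equal(k$rotation, diag(3), tolerance = 1e-9)
  expect_lt(max(abs(k$translation)), 1e-9)
  expect_lt(k$rmsd, 1e-12)
  # forced known transform
  rot <- random_rigid_transform()
  tr <- c(4, -2, 9)
  B <- sweep(A %*% t(rot), 2, -tr)
  k2 <- kabsch_superpose(B, A)
  expect_equal(k2$rotation, rot, tolerance = 1e-9)
  expect_equal(as.vector(k2$translation), tr, tolerance = 1e-9)
  expect_lt(k2$rmsd, 1e-9)
  expect_equal(det(k2$rotation), 1, tolerance = 1e-9)
  # inverse composes to identity
  inv <- invert_transform(k2)
  expect_equal(apply_transform(inv, apply_transform(k2, A)), A,
               tolerance = 1e-9)
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]),
               class = "underdetermined_superposition")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line),
               class = "underdetermined_superposition")
  expect_error(kabsch_superpose(A, A[1:10, ]),
               class = "underdetermined_superposition")
})

test_that("Kabsch and quaternion solvers agree and RMSD is rigid-invariant", {
  set.seed(12)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    A <- matrix(stats::rnorm(3 * n, sd = 5), n, 3)
    B <- matrix(stats::rnorm(3 * n, sd = 5), n, 3)
    expect_equal(kabsch_superpose(A, B)$rmsd, quaternion_superpose(A, B)$rmsd,
                 tolerance = 1e-9)
  }
  A <- matrix(stats::rnorm(60, sd = 5), 20, 3)
  B <- matrix(stats::rnorm(60, sd = 5), 20, 3)
  r0 <- kabsch_superpose(A, B)$rmsd
  # symmetry in the arguments
  expect_equal(kabsch_superpose(B, A)$rmsd, r0, tolerance = 1e-9)
  # invariance under rigid pre-transforms of either set
  for (i in 1:5) {
    rot <- random_rigid_transform()
    shift <- stats::rnorm(3, sd = 10)
    expect_equal(kabsch_superpose(sweep(A %*% t(rot), 2, shift), B)$rmsd, r0,
                 tolerance = 1e-9)
    expect_equal(kabsch_superpose(A, sweep(B %*% t(rot), 2, shift))$rmsd, r0,
                 tolerance = 1e-9)
  }
})

test_that("backbone + retinal correspondence follows the intersection rule", {
  scene <- build_scene(scene_spec(seed = 4L))
  s <- scene$structure
  corr <- pair_backbone_retinal(s, s)
  n_res <- nrow(unique(s$atoms[!s$atoms$het, c("chain", "resno")]))
  expect_identical(corr$n_backbone, 4L * n_res)
  expect_identical(corr$n_retinal, 12L)
  expect_identical(s$atoms$atom[corr$ref_idx], s$atoms$atom[corr$mob_idx])
  # unshared termini are excluded
  b <- s
  drop <- b$atoms$resno %in% c(1:5)
  b$atoms <- b$atoms[!drop, , drop = FALSE]
  corr2 <- pair_backbone_retinal(s, b)
  expect_identical(corr2$n_backbone, 4L * (n_res - 5L))
  # offset numbering with no shared residue numbers
  c_ <- s
  c_$atoms$resno[!c_$atoms$het] <- c_$atoms$resno[!c_$atoms$het] + 10000L
  c_$atoms <- c_$atoms[!c_$atoms$het, , drop = FALSE]  # drop RET too
  expect_error(pair_backbone_retinal(s, c_), class = "empty_correspondence")
})

test_that("frame assignment places the origin at the boundary midpoint", {
  scene <- build_scene(scene_spec(seed = 4L))
  f <- assign_frame(scene$structure, boundaries = c(-15, 15))
  expect_equal(f$z_upper - f$z_lower, 30)
  expect_equal(f$z_origin, 0, tolerance = 1e-9)
  expect_equal(sqrt(sum(f$normal^2)), 1, tolerance = 1e-9)
  # asymmetric boundaries shift the origin to the median
  f2 <- assign_frame(scene$structure, boundaries = c(-10, 20))
  expect_equal(f2$z_origin, 5)
  expect_equal(c(f2$z_lower, f2$z_upper), c(-15, 15))
  expect_error(assign_frame(scene$structure, boundaries = c(5, -5)),
               class = "invalid_boundaries")
})

test_that("the slab estimator recovers the hydrophobic belt of a synthetic bundle", {
  scene <- build_scene(scene_spec(seed = 4L, boundaries = c(-16, 16)))
  f <- assign_frame(scene$structure)  # estimate
  est <- f$z_origin + c(f$z_lower, f$z_upper)
  expect_lt(abs(est[1] - (-16)), 2)
  expect_lt(abs(est[2] - 16), 2)
  # the bundle normal is the z axis
  expect_gt(abs(sum(membrane_normal(scene$structure) * c(0, 0, 1))), 0.99)
  # too-small proteins refuse to estimate
  tiny <- read_structure(write_mini_pdb())
  expect_error(assign_frame(tiny, normal = c(0, 0, 1)),
               class = "insufficient_data")
})

test_that("depths transform exactly with the frame", {
  scene <- build_scene(scene_spec(seed = 4L))
  f <- scene$frame
  # an atom at the median has depth 0; displacement along the normal adds
  probe <- rbind(f$z_origin * f$normal, (f$z_origin + 7) * f$normal)
  expect_equal(depths_of(probe, f), c(0, 7), tolerance = 1e-9)
  # co-transforming structure and frame preserves all depths
  set.seed(33)
  d0 <- depths_of(scene$structure$atoms, f)
  for (i in 1:5) {
    tr <- annulipid:::new_transform(random_rigid_transform(),
                                    stats::rnorm(3, sd = 30))
    s2 <- apply_transform(tr, scene$structure)
    f2 <- transform_frame(f, tr)
    expect_equal(depths_of(s2$atoms, f2), d0, tolerance = 1e-9)
  }
})

test_that("helical RMSD matches the closed form for a single displaced helix", {
  scene <- build_scene(scene_spec(seed = 4L))
  s <- scene$structure
  expect_equal(as.numeric(helical_rmsd(s, s)), 0, tolerance = 1e-12)
  # displace exactly one of the 7 equal helices by 2 A; with the
  # superposition frozen to the identity the rmsd is 2/sqrt(7)
  b <- s
  hx <- b$atoms$resno >= 301L & b$atoms$resno <= 324L & !b$atoms$het
  b$atoms$x[hx] <- b$atoms$x[hx] + 2
  r <- helical_rmsd(s, b, superpose = FALSE)
  expect_equal(as.numeric(r), 2 / sqrt(7), tolerance = 1e-9)
  # free superposition can only reduce it
  expect_lte(as.numeric(helical_rmsd(s, b)), as.numeric(r) + 1e-12)
  # no helix ranges -> error
  s_nohelix <- s
  s_nohelix$helix <- s$helix[0, ]
  expect_error(helical_rmsd(s_nohelix, b), class = "empty_correspondence")
})
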