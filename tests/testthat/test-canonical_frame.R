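rz <- function(deg) {
  a <- deg * pi / 180
  rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
}

test_that("kabsch_rotation recovers known rotations and rejects degeneracy", {
  P <- rbind(c(0, 0, 0), c(1.2, 0.3, 0.1), c(-0.4, 1.1, 0.6))
  expect_equal(kabsch_rotation(P, P), diag(3), tolerance = 1e-9)

  Q <- P %*% t(rz(90))
  R <- kabsch_rotation(P, Q)
  expect_lt(max(abs(P %*% t(R) - Q)), 1e-9)

  set.seed(42)
  for (k in 1:25) {
    tr <- random_rigid_transform(k)
    P <- matrix(stats::rnorm(15), ncol = 3)
    R <- kabsch_rotation(P, P %*% t(tr$rotation))
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
    expect_lt(max(abs(R - tr$rotation)), 1e-8)
  }

  coll <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  expect_error(kabsch_rotation(coll, coll), "collinear")
  expect_error(kabsch_rotation(coll[1:2, ], coll[1:2, ]), "3 points")
})

test_that("kabsch rotation matches the bio3d superposition on a fixture", {
  skip_if_not_installed("bio3d")
  set.seed(8)
  P <- matrix(stats::rnorm(30), ncol = 3)
  Q <- P %*% t(rz(37)) # pure rotation, no translation, zero-mean not needed
  # centred problem so both routes solve the same superposition
  Pc <- scale(P, scale = FALSE)
  Qc <- scale(Q, scale = FALSE)
  ours <- Pc %*% t(kabsch_rotation(Pc, Qc))
  fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(Qc)), mobile = as.vector(t(Pc))))
  expect_equal(as.vector(t(ours)), as.vector(fit), tolerance = 1e-6)
})

test_that("canonical transform reproduces the printed reference anchors", {
  frames <- default_frames()
  for (seed in c(11L, 23L, 307L)) {
    tr <- random_rigid_transform(seed)

    arg <- apply_transform(tr, build_ideal_residue("ARG", bond_scale = 1))
    can <- to_canonical_frame(arg)$central
    expect_equal(unname(residue_xyz(can, "CZ")[1, ]), c(0, 0, 0),
                 tolerance = 1e-6)
    expect_equal(unname(residue_xyz(can, "NH1")[1, ]), c(0.5, 0.87, 0),
                 tolerance = 1e-6)
    expect_equal(unname(residue_xyz(can, "NH2")[1, ]), c(0.5, -0.87, 0),
                 tolerance = 1e-6)

    lys <- apply_transform(tr, build_ideal_residue("LYS", bond_scale = 1))
    canl <- to_canonical_frame(lys)$central
    expect_equal(unname(residue_xyz(canl, "NZ")[1, ]), c(0, 0, 0),
                 tolerance = 1e-6)
    expect_equal(unname(residue_xyz(canl, "CE")[1, ]), c(-1, 0, 0),
                 tolerance = 1e-6)
    expect_equal(unname(residue_xyz(canl, "CD")[1, ]), c(-1.34, 0.94, 0),
                 tolerance = 1e-6)
  }
})

test_that("already-canonical residues give the identity transform", {
  for (scale in c(1, 1.33, 2.5)) {
    can <- to_canonical_frame(build_ideal_residue("ARG", bond_scale = scale))
    expect_lt(max(abs(can$transform$rotation - diag(3))), 1e-9)
    expect_lt(max(abs(can$transform$translation)), 1e-9)
  }
})

test_that("missing anchors raise a classed skip condition", {
  arg <- build_ideal_residue("ARG")
  arg$atoms <- arg$atoms[arg$atoms$name != "NH2", ]
  expect_error(to_canonical_frame(arg), class = "scpolar_missing_anchor")
  expect_error(to_canonical_frame(arg), "NH2")
})

test_that("frame handedness is fixed: guanidinium in-plane, NH1 at +y", {
  for (seed in 1:10) {
    tr <- random_rigid_transform(seed * 13L)
    arg <- apply_transform(tr, build_ideal_residue("ARG"))
    can <- to_canonical_frame(arg)$central
    A <- residue_xyz(can, c("CZ", "NH1", "NH2"))
    expect_lt(max(abs(A[, 3])), 1e-6)   # planar, z = 0
    expect_gt(A["NH1", 2], 0)
    expect_lt(A["NH2", 2], 0)
  }
})

test_that("the transform is rigid and pose-invariant", {
  pp <- plant_pair("ARG", "ASP", "OD1", r = 3.4, theta = 88, psi = 55,
                   pose_seed = 5L)
  central <- pp$residues[[1]]
  nb <- pp$residues[[2]]
  can <- to_canonical_frame(central, list(nb))

  all_before <- rbind(residue_xyz(central), residue_xyz(nb))
  all_after <- rbind(residue_xyz(can$central),
                     residue_xyz(can$neighbors[[1]]))
  expect_lt(max(abs(dist(all_before) - dist(all_after))), 1e-9)

  # any extra rigid motion composed onto the input changes nothing
  for (seed in c(2L, 71L, 501L)) {
    tr <- random_rigid_transform(seed)
    can2 <- to_canonical_frame(apply_transform(tr, central),
                               list(apply_transform(tr, nb)))
    expect_lt(max(abs(residue_xyz(can2$central) -
                        residue_xyz(can$central))), 1e-6)
    expect_lt(max(abs(residue_xyz(can2$neighbors[[1]]) -
                        residue_xyz(can$neighbors[[1]]))), 1e-6)
  }
})

test_that("centroid-centered variant orients anchors without pinning", {
  tr <- random_rigid_transform(99L)
  arg <- apply_transform(tr, build_ideal_residue("ARG", bond_scale = 1))
  can <- to_canonical_frame(arg, method = "centroid")
  A <- residue_xyz(can$central, c("CZ", "NH1", "NH2"))
  ref <- rbind(c(0, 0, 0), c(0.5, 0.87, 0), c(0.5, -0.87, 0))
  expect_lt(max(abs(A - ref)), 1e-6)  # exact here: anchors equal reference
  expect_equal(det(can$transform$rotation), 1, tolerance = 1e-9)
})
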