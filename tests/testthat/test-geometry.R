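# Volumes, meshes, and the voxel <-> mesh bridges

test_that("label_volume validates its invariants", {
  arr <- array(0L, c(4, 4, 4)); arr[2, 2, 2] <- 1L
  expect_error(label_volume(arr, -1), "positive")
  expect_error(label_volume(array(0L, c(4, 4)), 1), "3D")
  arr[3, 3, 3] <- 9L
  expect_error(label_volume(arr, 1), "absent from label_map")
})

test_that("resampling to identical spacing is the identity", {
  arr <- array(0L, c(6, 6, 6)); arr[2:4, 2:4, 2:4] <- 1L
  v <- label_volume(arr, 0.7)
  expect_identical(resample_isotropic(v, 0.7)$array, v$array)
  expect_error(resample_isotropic(v, -0.5), "positive")
})

test_that("resampling preserves the volume of a smooth cube mask", {
  # 10 mm cube at 1 mm spacing (11^3 grid of voxel centers 0..20)
  arr <- array(0L, c(21, 21, 21))
  arr[6:16, 6:16, 6:16] <- 1L   # 11 voxel centers -> ~10 mm cube + half-voxel rind
  v <- label_volume(arr, 1.0)
  v2 <- resample_isotropic(v, 0.5)
  expect_equal(v2$spacing, 0.5)
  vol1 <- sum(v$array == 1L) * 1.0^3
  vol2 <- sum(v2$array == 1L) * 0.5^3
  expect_lt(abs(vol2 - vol1) / vol1, 0.05)
  # all-background stays all-background
  empty <- label_volume(array(0L, c(5, 5, 5)), 1.0)
  expect_true(all(resample_isotropic(empty, 0.5)$array == 0L))
})

test_that("mesh_volume is exact on the unit cube and reflection-invariant", {
  cube <- unit_cube_mesh()
  expect_true(is_watertight(cube))
  expect_equal(mesh_volume(cube), 1.0, tolerance = 1e-12)
  expect_equal(mesh_volume(mirror_sagittal(cube)), 1.0, tolerance = 1e-12)
  open_mesh <- surface_mesh(cube$vertices, cube$faces[-1, ])
  expect_error(mesh_volume(open_mesh), "watertight")
})

test_that("mirroring is an involution and preserves volume on random bones", {
  for (seed in c(2, 9)) {
    b <- make_healthy_bone(synthetic_case_spec(seed = seed))
    mm <- mirror_sagittal(mirror_sagittal(b))
    expect_lt(max(abs(mm$vertices - b$vertices)), 1e-12)
    expect_lt(abs(mesh_volume(mirror_sagittal(b)) - mesh_volume(b)), 1e-9)
  }
})

test_that("principal_axis finds an elongated axis and rejects degenerate clouds", {
  b <- make_healthy_bone(synthetic_case_spec(seed = 4))
  ax <- principal_axis(b, proximal = "-z")
  expect_equal(abs(ax$axis[3]), max(abs(ax$axis)))  # dominated by z
  expect_gt(ax$axis[3], 0)                          # points proximal -> distal
  expect_equal(ax$extent, 120, tolerance = 1)
  # rotating the mesh rotates the axis accordingly
  R <- rot_axis_angle(c(1, 1, 0) / sqrt(2), 0.5)
  br <- transform_mesh(b, rigid_from_rt(R))
  axr <- principal_axis(br, proximal = colMeans(br$vertices) -
                          as.numeric(R %*% ax$axis))
  expect_lt(max(abs(axr$axis - as.numeric(R %*% ax$axis))), 1e-3)
  # a near-isotropic cloud has no stable axis
  cube <- unit_cube_mesh()
  expect_error(principal_axis(cube), "principal axis")
})

test_that("mesh_from_labels produces watertight surfaces with correct volumes", {
  # 20-voxel cube at 0.5 mm: analytic volume of the 0.5-level surface
  arr <- array(0L, c(26, 26, 26))
  arr[4:23, 4:23, 4:23] <- 1L
  v <- label_volume(arr, 0.5)
  m <- mesh_from_labels(v, "radius")
  expect_true(is_watertight(m))
  # iso-surface at 0.5 sits half a voxel outside the outermost centers:
  # edge = (20-1)*0.5 + 2*0.25 = 10 mm
  expect_lt(abs(mesh_volume(m) - 10^3) / 10^3, 0.05)
  # vertices are in physical coordinates
  expect_equal(min(m$vertices), 3 * 0.5 - 0.25, tolerance = 1e-9)

  # single voxel: volume near spacing^3/... iso-surface of one sample
  arr1 <- array(0L, c(5, 5, 5)); arr1[3, 3, 3] <- 1L
  m1 <- mesh_from_labels(label_volume(arr1, 0.5), "radius")
  expect_true(is_watertight(m1))
  expect_lte(abs(mesh_volume(m1) - 0.125) / 0.125, 0.5)

  expect_error(mesh_from_labels(label_volume(array(0L, c(4, 4, 4)), 0.5),
                                "radius"), "empty segmentation")
})

test_that("mesh_from_labels keeps the largest component with a warning", {
  arr <- array(0L, c(12, 6, 6))
  arr[2:6, 2:4, 2:4] <- 1L    # 45 voxels
  arr[9:10, 2:3, 2:3] <- 1L   # 8 voxels, disconnected
  v <- label_volume(arr, 1)
  expect_warning(m <- mesh_from_labels(v, "radius"), "largest")
  expect_lt(mesh_volume(m), 46)
  expect_gt(mesh_volume(m), 20)
})

test_that("voxelization agrees with mesh volume", {
  b <- make_healthy_bone(synthetic_case_spec(seed = 6))
  v <- voxelize_mesh(b, 0.5, pad = 3)
  expect_lt(abs(sum(v$array) * 0.5^3 - mesh_volume(b)) / mesh_volume(b), 0.02)
})
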