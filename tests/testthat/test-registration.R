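# Initial alignment, fragment isolation, and ICP registration

test_that("initial_align is the identity for identical meshes", {
  b <- make_healthy_bone(synthetic_case_spec(seed = 2))
  t0 <- initial_align(b, b)
  expect_lt(rotation_angle(t0), 1e-4)
  expect_lt(sqrt(sum(t0$matrix[1:3, 4]^2)), 1e-3)
})

test_that("initial_align recovers a known displacement", {
  b <- make_healthy_bone(synthetic_case_spec(seed = 8))
  set.seed(4)
  disp <- random_rigid(max_angle = 0.5, max_trans = 15)
  moved <- transform_mesh(b, disp)
  t0 <- initial_align(moved, b)
  resid <- compose(t0, disp)
  expect_lt(rotation_angle(resid), 1e-4)
  expect_lt(sqrt(sum(resid$matrix[1:3, 4]^2)), 1e-3)
})

test_that("initial_align tolerates vertex jitter", {
  b <- make_healthy_bone(synthetic_case_spec(seed = 12))
  set.seed(9)
  noisy <- surface_mesh(b$vertices + matrix(rnorm(length(b$vertices), 0, 0.5),
                                            ncol = 3), b$faces)
  t0 <- initial_align(noisy, b)
  moved <- transform_mesh(noisy, t0)
  expect_lt(masd(moved, b), 2)
})

test_that("end fragments partition the faces at fraction 0.5", {
  b <- make_healthy_bone(synthetic_case_spec(seed = 2))
  fp <- isolate_end_fragment(b, "proximal", 0.5)
  fd <- isolate_end_fragment(b, "distal", 0.5)
  expect_gte(nrow(fp$mesh$faces) + nrow(fd$mesh$faces), nrow(b$faces))
  expect_error(isolate_end_fragment(b, "proximal", 0), "fraction")
  expect_error(isolate_end_fragment(b, "proximal", 0.6), "fraction")
})

test_that("proximal fragment vertices stay within the declared axial band", {
  b <- make_healthy_bone(synthetic_case_spec(seed = 2))
  fr <- isolate_end_fragment(b, "proximal", 0.2)
  ax <- principal_axis(b, proximal = "-z")
  s <- as.numeric(sweep(fr$mesh$vertices, 2, ax$proximal_anchor) %*% ax$axis)
  # within the band plus one face diameter of slack
  expect_lt(max(s), 0.2 * ax$extent + 3)
  expect_equal(fr$end, "proximal")
})

test_that("a too-small fragment fraction raises a helpful error", {
  b <- make_healthy_bone(synthetic_case_spec(seed = 2))
  expect_error(isolate_end_fragment(b, "distal", 0.005), "fraction|vertices")
})

test_that("ICP on a surface already in place converges immediately", {
  b <- make_healthy_bone(synthetic_case_spec(seed = 2))
  fr <- isolate_end_fragment(b, "distal", 0.2)
  out <- icp_register(fr, b)
  expect_true(out$converged)
  expect_lte(out$iterations, 2)
  expect_lt(out$rms_residual, 1e-9)
  expect_lt(rotation_angle(out$transform), 1e-9)
})

test_that("ICP recovers planted fragment displacements to high accuracy", {
  b <- make_healthy_bone(synthetic_case_spec(seed = 5))
  frag <- isolate_end_fragment(b, "distal", 0.2)
  target <- isolate_end_fragment(b, "distal", 0.3)
  set.seed(21)
  for (i in 1:5) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    cen <- colMeans(frag$mesh$vertices)
    disp <- compose(rigid_from_rt(diag(3), cen + runif(3, -5, 5)),
                    compose(rigid_from_rt(rot_axis_angle(ax, runif(1, -0.25, 0.25))),
                            rigid_from_rt(diag(3), -cen)))
    out <- icp_register(transform_mesh(frag$mesh, disp), target$mesh)
    resid <- compose(out$transform, disp)
    expect_lt(rotation_angle(resid) * 180 / pi, 0.5)
    expect_lt(sqrt(sum(resid$matrix[1:3, 4]^2)), 0.5)
    # monotone RMS history
    expect_true(all(diff(out$rms_history) <= 1e-9))
  }
})

test_that("ICP respects the iteration cap and flags non-convergence", {
  b <- make_healthy_bone(synthetic_case_spec(seed = 5))
  frag <- isolate_end_fragment(b, "distal", 0.2)
  disp <- rigid_from_rt(rot_z(0.3), c(8, -5, 3))
  out <- icp_register(transform_mesh(frag$mesh, disp), b, max_iter = 1)
  expect_identical(out$iterations, 1L)
  expect_false(out$converged)
  expect_error(icp_register(frag, b, max_iter = 0), "max_iter")
  expect_error(icp_register(frag, b, tol = 0), "tol")
})

test_that("far-apart surfaces raise a registration failure", {
  b <- make_healthy_bone(synthetic_case_spec(seed = 5))
  frag <- isolate_end_fragment(b, "distal", 0.2)
  far <- transform_mesh(frag$mesh, rigid_from_rt(diag(3), c(500, 0, 0)))
  expect_error(icp_register(far, b), "registration failure")
})

test_that("register_joint_ends returns identity for an undeformed pair", {
  b <- make_healthy_bone(synthetic_case_spec(seed = 6))
  reg <- register_joint_ends(b, b)
  expect_lt(rotation_angle(reg$m_prox) * 180 / pi, 1e-4)
  expect_lt(rotation_angle(reg$m_dist) * 180 / pi, 1e-4)
  M <- relative(reg$m_prox, reg$m_dist)
  expect_lt(rotation_angle(M) * 180 / pi, 1e-4)
})

test_that("register_joint_ends recovers a planted wedge angle", {
  tb <- test_bone(seed = 3)
  t0 <- initial_align(tb$deformed, tb$healthy)
  reg <- register_joint_ends(transform_mesh(tb$deformed, t0), tb$healthy)
  M <- relative(reg$m_prox, reg$m_dist)
  expect_lt(abs(rotation_angle(M) - tb$spec$wedge_angle) * 180 / pi, 0.5)
  # both fragments sit essentially on their counterparts
  expect_lt(reg$prox_outcome$rms_residual, 1e-6)
  expect_lt(reg$dist_outcome$rms_residual, 1e-6)
})

test_that("registration is deterministic", {
  tb <- test_bone(seed = 3)
  t0 <- initial_align(tb$deformed, tb$healthy)
  al <- transform_mesh(tb$deformed, t0)
  r1 <- register_joint_ends(al, tb$healthy)
  r2 <- register_joint_ends(al, tb$healthy)
  expect_identical(r1$m_prox$matrix, r2$m_prox$matrix)
  expect_identical(r1$m_dist$matrix, r2$m_dist$matrix)
})
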