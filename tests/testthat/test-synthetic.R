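# Synthetic bone phantom generator

test_that("spec validation catches invalid parameters", {
  expect_error(synthetic_case_spec(length = -1), "positive")
  expect_error(synthetic_case_spec(wedge_station = 0), "inside the bone")
  expect_error(synthetic_case_spec(wedge_angle = pi / 2), "45")
  expect_error(synthetic_case_spec(wedge_axis = c(0, 0, 1)), "perpendicular")
})

test_that("healthy bones are watertight, correctly sized, and seed-deterministic", {
  spec <- synthetic_case_spec(seed = 10)
  b1 <- make_healthy_bone(spec)
  expect_true(is_watertight(b1))
  expect_equal(diff(range(b1$vertices[, 3])), spec$length, tolerance = 0.5)
  b2 <- make_healthy_bone(spec)
  expect_identical(b1$vertices, b2$vertices)
  expect_identical(b1$faces, b2$faces)
  b3 <- make_healthy_bone(synthetic_case_spec(seed = 11))
  expect_false(identical(b1$vertices, b3$vertices))
})

test_that("zero wedge angle leaves the bone untouched", {
  spec <- synthetic_case_spec(seed = 4, wedge_angle = 0)
  b <- make_healthy_bone(spec)
  wd <- apply_wedge(b, spec)
  expect_lt(max(abs(wd$deformed$vertices - b$vertices)), 1e-12)
  expect_lt(rotation_angle(wd$truth$true_realignment), 1e-12)
})

test_that("the planted wedge angle appears between the shaft halves", {
  for (ang in c(10, 25) * pi / 180) {
    spec <- synthetic_case_spec(seed = 4, wedge_angle = ang)
    b <- make_healthy_bone(spec)
    wd <- apply_wedge(b, spec)
    # Procrustes oracle on corresponding vertices beyond the blend band:
    # the distal part is an exact rigid copy of the healthy distal part
    sel <- b$vertices[, 3] > spec$wedge_station + 2.5
    P <- scale(b$vertices[sel, ], scale = FALSE)
    Q <- scale(wd$deformed$vertices[sel, ], scale = FALSE)
    sv <- svd(crossprod(P, Q))
    R <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
    measured <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
    expect_lt(abs(measured - ang) * 180 / pi, 1e-6)
    # truth transform has exactly the commanded rotation magnitude
    expect_equal(rotation_angle(wd$truth$true_realignment), ang,
                 tolerance = 1e-12)
  }
})

test_that("the same wedge angle about different axes gives equal rotation but
          different components", {
  s1 <- synthetic_case_spec(seed = 4, wedge_axis = c(1, 0, 0))
  s2 <- synthetic_case_spec(seed = 4, wedge_axis = c(0, 1, 0))
  b <- make_healthy_bone(s1)
  t1 <- apply_wedge(b, s1)$truth
  t2 <- apply_wedge(make_healthy_bone(s2), s2)$truth
  expect_equal(rotation_angle(t1$true_realignment),
               rotation_angle(t2$true_realignment), tolerance = 1e-12)
  d1 <- decompose_euler(t1$true_realignment)
  d2 <- decompose_euler(t2$true_realignment)
  expect_gt(abs(d1$phi_x - d2$phi_x), 0.1)
})

test_that("cartilage caps grow monotonically with thickness", {
  spec <- synthetic_case_spec(seed = 5)
  b <- make_healthy_bone(spec)
  v <- voxelize_mesh(b, 0.8, pad = 4)
  v <- label_volume(v$array, v$spacing, v$origin, c(radius = 1, cartilage = 2))
  v0 <- add_cartilage_caps(v, 0)
  expect_equal(sum(v0$array == 2L), 0)
  v1 <- add_cartilage_caps(v, 1)
  v2 <- add_cartilage_caps(v, 2)
  expect_gt(sum(v1$array == 2L), 0)
  expect_gt(sum(v2$array == 2L), sum(v1$array == 2L))
  # bone label untouched
  expect_identical(v1$array == 1L, v$array == 1L)
})

test_that("boundary perturbation hits the commanded MASD and is deterministic", {
  spec <- synthetic_case_spec(seed = 6)
  b <- make_healthy_bone(spec)
  v <- voxelize_mesh(b, 0.7, pad = 4)
  v <- label_volume(v$array, v$spacing, v$origin, c(radius = 1, cartilage = 2))
  expect_identical(perturb_segmentation(v, 0, seed = 1)$array, v$array)
  p1 <- perturb_segmentation(v, 0.4, seed = 9)
  achieved <- masd(v, p1, role = "radius")
  expect_gt(achieved, 0.3)
  expect_lt(achieved, 0.5)
  p2 <- perturb_segmentation(v, 0.4, seed = 9)
  expect_identical(p1$array, p2$array)
  # one connected component
  cc <- osteoplanr:::cpp_largest_component(as.logical(p1$array == 1L),
                                           dim(p1$array))
  expect_identical(cc$n_components, 1L)
})

test_that("cohorts are deterministic and their RCV falls with age", {
  c1 <- generate_cohort(4, seed = 3, make_volumes = FALSE)
  c2 <- generate_cohort(4, seed = 3, make_volumes = FALSE)
  expect_identical(lapply(c1, function(x) x$deformed$vertices),
                   lapply(c2, function(x) x$deformed$vertices))
  ages <- vapply(c1, `[[`, numeric(1), "age")
  expect_true(all(ages >= 6 & ages <= 19))
  th <- vapply(c1, function(x) x$spec$cartilage_thickness, numeric(1))
  expect_lt(cor(ages, th), 0)   # thickness decreases with age by design
})
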