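# Centerline, plane cutting, objective, exhaustive search, plane comparison

test_that("centerline of a straight tube lies on its axis", {
  spec <- synthetic_case_spec(seed = 2)
  spec$bow <- 0  # straight variant
  b <- make_healthy_bone(spec)
  cl <- centerline(b, 40)
  # the k=1 modulation and the epiphyseal lobes shift cross-section
  # centroids off the loft axis by up to ~amp * r
  expect_lt(max(abs(cl$points[, 1:2])), 3)
  expect_true(all(diff(cl$stations) > 0))
  expect_error(centerline(unit_cube_mesh()), "elongated|principal axis")
})

test_that("centerline tracks the bow of a bent shaft", {
  spec <- synthetic_case_spec(seed = 2)
  b <- make_healthy_bone(spec)
  cl <- centerline(b, 60)
  mid <- which.min(abs(cl$stations - 60))
  expect_gt(cl$points[mid, 1], 0.5 * spec$bow)
})

test_that("cut_with_plane conserves volume and splits at the right ratio", {
  b <- make_healthy_bone(synthetic_case_spec(seed = 3))
  vol <- mesh_volume(b)
  for (st in c(50, 36)) {
    pl <- osteotomy_plane(c(0, 0, st), c(0, 0, 1), station = st)
    frags <- cut_with_plane(b, pl)
    expect_true(is_watertight(frags$proximal))
    expect_true(is_watertight(frags$distal))
    vp <- mesh_volume(frags$proximal); vd <- mesh_volume(frags$distal)
    expect_lt(abs(vp + vd - vol) / vol, 1e-3)
    expect_gt(length(frags$proximal$cut_faces), 0)
    expect_gt(length(frags$distal$cut_faces), 0)
  }
  # ratio check on a flare-free prism so the analytic ratio is exact
  prism <- unit_cube_mesh(edge = 1)
  prism$vertices[, 3] <- prism$vertices[, 3] * 100  # 1x1x100 column
  pl <- osteotomy_plane(c(0.5, 0.5, 30), c(0, 0, 1))
  fr <- cut_with_plane(prism, pl)
  expect_equal(mesh_volume(fr$proximal) / 100, 0.30, tolerance = 5e-3)
  expect_equal(mesh_volume(fr$distal) / 100, 0.70, tolerance = 5e-3)
  # non-intersecting plane
  expect_error(cut_with_plane(prism, osteotomy_plane(c(0, 0, 500), c(0, 0, 1))),
               "does not intersect")
})

test_that("reconstruct applies the matrices exactly", {
  b <- make_healthy_bone(synthetic_case_spec(seed = 3))
  pl <- osteotomy_plane(c(0, 0, 50), c(0, 0, 1))
  frags <- cut_with_plane(b, pl)
  set.seed(2)
  mp <- random_rigid(); md <- random_rigid()
  rec <- reconstruct(frags$proximal, frags$distal, mp, md)
  oracle <- sweep(frags$proximal$vertices %*% t(mp$matrix[1:3, 1:3]), 2,
                  mp$matrix[1:3, 4], `+`)
  expect_lt(max(abs(rec$proximal$vertices - oracle)), 1e-12)
  # identity transforms change nothing
  rec_id <- reconstruct(frags$proximal, frags$distal, rigid_transform(),
                        rigid_transform())
  expect_identical(rec_id$proximal$vertices, frags$proximal$vertices)
  # equal transforms keep the relative pose: realignment identity
  expect_lt(max(abs(relative(mp, mp)$matrix - diag(4))), 1e-12)
})

test_that("the gap objective is zero for mated fragments and exact for offsets", {
  b <- make_healthy_bone(synthetic_case_spec(seed = 3))
  pl <- osteotomy_plane(c(0, 0, 50), c(0, 0, 1))
  frags <- cut_with_plane(b, pl)
  expect_equal(plan_objective(frags$proximal, frags$distal), 0, tolerance = 1e-12)
  # translate the distal fragment 2 mm along the cut normal
  off <- rigid_from_rt(diag(3), c(0, 0, 2))
  rec <- reconstruct(frags$proximal, frags$distal, rigid_transform(), off)
  expect_equal(plan_objective(rec$proximal, rec$distal), 2, tolerance = 1e-6)
  # the overlap term can only lower the objective
  tpl <- b
  with_overlap <- plan_objective(rec$proximal, rec$distal, tpl,
                                 overlap_weight = 0.5)
  expect_lte(with_overlap, 2 + 1e-9)
  # cut-face tags are required
  naked <- surface_mesh(frags$proximal$vertices, frags$proximal$faces)
  expect_error(plan_objective(naked, rec$distal), "cut-face")
})

test_that("exhaustive_search equals a naive full re-evaluation on a small grid", {
  tb <- test_bone(seed = 3)
  t0 <- initial_align(tb$deformed, tb$healthy)
  al <- transform_mesh(tb$deformed, t0)
  reg <- register_joint_ends(al, tb$healthy)
  grid <- search_grid(station_step = 6, station_band = c(0.3, 0.7),
                      tilt_max = 20 * pi / 180, tilt_step = 10 * pi / 180)
  res <- exhaustive_search(al, tb$healthy, reg$m_prox, reg$m_dist, grid = grid)
  # naive oracle: re-evaluate every node independently
  frame <- bone_frame(al)
  stations <- seq(0.3 * frame$extent, 0.7 * frame$extent, by = grid$station_step)
  tilts <- seq(-grid$tilt_max, grid$tilt_max, by = grid$tilt_step)
  nodes <- expand.grid(station = stations, tilt_a = tilts, tilt_z = tilts)
  expect_lte(nrow(nodes), 500)
  vals <- mapply(function(st, ta, tz) {
    pl <- osteoplanr:::node_plane(al, frame, st, ta, tz)
    if (is.null(pl)) return(NA_real_)
    osteoplanr:::node_objective(al, pl, reg$m_prox, reg$m_dist)
  }, nodes$station, nodes$tilt_a, nodes$tilt_z)
  expect_equal(res$objective, min(vals, na.rm = TRUE))
  best <- which(vals == min(vals, na.rm = TRUE))
  expect_true(res$plane$station %in% nodes$station[best])
})

test_that("a single-node grid returns that node's plane", {
  tb <- test_bone(seed = 3)
  t0 <- initial_align(tb$deformed, tb$healthy)
  al <- transform_mesh(tb$deformed, t0)
  reg <- register_joint_ends(al, tb$healthy)
  frame <- bone_frame(al)
  grid <- search_grid(station_step = 1000, station_band = c(0.5, 0.5),
                      tilt_max = 0, tilt_step = 1)
  res <- exhaustive_search(al, tb$healthy, reg$m_prox, reg$m_dist, grid = grid)
  expect_equal(res$plane$station, 0.5 * frame$extent)
  expect_equal(res$plane$tilt_a, 0)
  expect_equal(res$plane$tilt_z, 0)
})

test_that("null deformity plans to identity realignment and near-zero objective", {
  b <- make_healthy_bone(synthetic_case_spec(seed = 14))
  res <- run_pipeline(case_bundle(b, mirror_sagittal(b)))
  expect_lt(rotation_angle(res$realignment) * 180 / pi, 0.1)
  expect_lt(sqrt(sum(res$realignment$matrix[1:3, 4]^2)), 0.1)
  expect_lt(res$objective, 0.1)
  expect_identical(res$wedge_type, "opening")
  expect_null(res$secondary_plane)
})

test_that("secondary cut of a planted closing wedge matches a polygon oracle", {
  tb <- test_bone(seed = 3)
  t0 <- initial_align(tb$deformed, tb$healthy)
  al <- transform_mesh(tb$deformed, t0)
  reg <- register_joint_ends(al, tb$healthy)
  # force a transverse (perpendicular) cut at the apex: a closing wedge with
  # the apex line inside the bone -> the secondary cut must cross the
  # primary polygon (red)
  grid <- search_grid(station_step = 1000, station_band = c(0.5, 0.5),
                      tilt_max = 0, tilt_step = 1)
  res <- exhaustive_search(al, tb$healthy, reg$m_prox, reg$m_dist, grid = grid)
  expect_identical(res$wedge_type, "closing")
  expect_false(is.null(res$secondary_plane))
  # oracle: dense points along the primary cut polygon, signed distance to
  # the secondary plane; straddling <=> intersection
  poly <- transform_points(invert(res$m_prox),
                           osteoplanr:::cut_face_vertices(res$proximal_fragment))
  dense <- do.call(rbind, lapply(seq_len(nrow(poly)), function(i) {
    j <- if (i == nrow(poly)) 1 else i + 1
    t <- seq(0, 1, length.out = 10)
    outer(1 - t, poly[i, ]) + outer(t, poly[j, ])
  }))
  s <- as.numeric(sweep(dense, 2, res$secondary_plane$p1p) %*%
                    res$secondary_plane$normal)
  oracle_red <- min(s) < -1e-6 && max(s) > 1e-6
  expect_identical(res$secondary_intersects_primary, oracle_red)
  expect_true(oracle_red)
})

test_that("compare_planes reports axial offsets and tilt differences", {
  tb <- test_bone(seed = 3)
  t0 <- initial_align(tb$deformed, tb$healthy)
  al <- transform_mesh(tb$deformed, t0)
  reg <- register_joint_ends(al, tb$healthy)
  grid1 <- search_grid(station_step = 1000, station_band = c(0.4, 0.4),
                       tilt_max = 0, tilt_step = 1)
  grid2 <- search_grid(station_step = 1000, station_band = c(0.5, 0.5),
                       tilt_max = 0, tilt_step = 1)
  r1 <- exhaustive_search(al, tb$healthy, reg$m_prox, reg$m_dist, grid = grid1)
  r2 <- exhaustive_search(al, tb$healthy, reg$m_prox, reg$m_dist, grid = grid2)
  pc_same <- compare_planes(r1, r1)
  expect_equal(pc_same$delta_z, 0)
  expect_equal(pc_same$psi_a, 0)
  expect_equal(pc_same$psi_z, 0)
  pc <- compare_planes(r1, r2)
  frame <- r1$frame
  expect_equal(pc$delta_z, 0.1 * frame$extent, tolerance = 0.3)
  expect_gt(pc$delta_z, 0)  # distal shift is positive
  # constructed tilt: rotate r2's plane normal by 10 degrees about e1
  r3 <- r2
  r3$plane <- osteotomy_plane(
    r2$plane$p1p,
    as.numeric(rot_axis_angle(frame$e1, -10 * pi / 180) %*% r2$plane$normal))
  pc3 <- compare_planes(r2, r3)
  expect_equal(abs(pc3$psi_a) * 180 / pi, 10, tolerance = 1e-6)
  expect_equal(pc3$psi_z, 0, tolerance = 1e-6)
})
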