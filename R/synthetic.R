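#' Synthetic paired healthy/deformed long-bone phantoms
#'
#' Geometric phantoms that exercise the full planning pipeline with known
#' ground truth: a lofted tube with flared epiphyseal ends and a
#' seed-specific azimuthal radius modulation (so surfaces are not surfaces
#' of revolution and ICP cannot slide), a planted wedge deformity of known
#' angle, axis and station, optional cartilage caps of controllable
#' thickness, and smooth boundary perturbations emulating the difference
#' between CT- and MRI-derived segmentations. The healthy contralateral
#' side is the pre-deformation bone mirrored sagittally, so the mirrored
#' template is exactly congruent to the correctable deformity.
#'
#' @name synthetic-bones
NULL

# run an expression under a fixed RNG seed, restoring the caller's RNG state
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

#' Specification of one synthetic case
#'
#' @param seed integer driving the seed-specific shape modulation.
#' @param length bone length, mm.
#' @param shaft_radius mid-shaft radius, mm.
#' @param epiphysis_radius radius at the flared ends, mm.
#' @param wedge_angle planted deformity angle, radians (in [0, 45 deg]).
#' @param wedge_axis unit vector perpendicular to the long (z) axis.
#' @param wedge_station deformity apex, mm from the proximal (z = 0) end;
#'   NULL places it mid-shaft.
#' @param cartilage_thickness articular cartilage cap thickness, mm.
#' @param age_proxy years; cohort generation decreases cartilage thickness
#'   with age.
#' @param noise_masd_target commanded boundary-perturbation MASD, mm.
#' @return A `synthetic_case_spec` list.
#' @export
synthetic_case_spec <- function(seed = 1, length = 120, shaft_radius = 6,
                                epiphysis_radius = 10,
                                wedge_angle = 20 * pi / 180,
                                wedge_axis = c(1, 0, 0), wedge_station = NULL,
                                cartilage_thickness = 1.5, age_proxy = 12,
                                noise_masd_target = 0.4) {
  if (length <= 0 || shaft_radius <= 0 || epiphysis_radius <= 0)
    stop("lengths and radii must be positive", call. = FALSE)
  if (is.null(wedge_station)) wedge_station <- length / 2
  if (wedge_station <= 0 || wedge_station >= length)
    stop("wedge_station must lie inside the bone", call. = FALSE)
  if (wedge_angle < 0 || wedge_angle > pi / 4)
    stop("wedge_angle must lie in [0, 45 degrees]", call. = FALSE)
  wedge_axis <- wedge_axis / sqrt(sum(wedge_axis^2))
  if (abs(wedge_axis[3]) > 1e-6)
    stop("wedge_axis must be perpendicular to the long (z) axis", call. = FALSE)
  structure(list(seed = as.integer(seed), length = length,
                 bow = 0.025 * length,
                 shaft_radius = shaft_radius,
                 epiphysis_radius = epiphysis_radius,
                 wedge_angle = wedge_angle, wedge_axis = wedge_axis,
                 wedge_station = wedge_station,
                 cartilage_thickness = cartilage_thickness,
                 age_proxy = age_proxy,
                 noise_masd_target = noise_masd_target),
            class = "synthetic_case_spec")
}

#' Generate the healthy bone of a case
#'
#' Lofted circular cross-sections along z with flared ends, a gentle planar
#' bow of the shaft, a slightly smaller proximal than distal epiphysis, and
#' a seed-specific azimuthal radius modulation; proximal end at z = 0.
#' The asymmetries matter: they break the rotational, end-swap and mirror
#' degeneracies that would otherwise let rigid registration slide or flip.
#' Deterministic per seed.
#'
#' @param spec a [synthetic_case_spec()].
#' @param n_seg circumferential segments.
#' @param axial_step axial loft step, mm.
#' @return A watertight `surface_mesh` named `"radius"`.
#' @export
make_healthy_bone <- function(spec, n_seg = 24, axial_step = 2) {
  stopifnot(inherits(spec, "synthetic_case_spec"))
  # azimuthal profile dominated by the k = 1 harmonic (egg-shaped section
  # with a slow helical twist): unlike pure k >= 2 harmonics it has a
  # unique azimuthal registration optimum
  local_seed(spec$seed, {
    amp <- c(stats::runif(1, 0.12, 0.18), stats::runif(1, 0.04, 0.08),
             stats::runif(1, 0.02, 0.04))
    phase <- stats::runif(3, 0, 2 * pi)
    lobe_amp <- stats::runif(2, 0.20, 0.30)
    lobe_phase <- stats::runif(2, 0, 2 * pi)
    crest_amp <- stats::runif(1, 0.08, 0.12)
    crest_phase <- stats::runif(1, 0, 2 * pi)
  })
  zs <- seq(0, spec$length, by = axial_step)
  if (zs[length(zs)] < spec$length) zs <- c(zs, spec$length)
  flare_len <- 0.15 * spec$length
  phis <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
  nz <- length(zs)
  bow_x <- function(z) spec$bow * sin(pi * z / spec$length)
  verts <- matrix(0, nz * n_seg + 2, 3)
  for (i in seq_len(nz)) {
    z <- zs[i]
    flare_p <- smoothstep((flare_len - z) / flare_len)
    flare_d <- smoothstep((z - (spec$length - flare_len)) / flare_len)
    # proximal epiphysis slightly smaller than distal
    r0 <- spec$shaft_radius +
      (0.85 * spec$epiphysis_radius - spec$shaft_radius) * flare_p +
      (spec$epiphysis_radius - spec$shaft_radius) * flare_d
    mod <- 1 + amp[1] * cos(phis + phase[1] + 0.01 * z) +
      amp[2] * cos(2 * phis + phase[2]) +
      amp[3] * cos(3 * phis + phase[3] + 0.02 * z)
    # one-sided bony process on each epiphysis (styloid-like) plus a
    # narrow full-length ridge (interosseous-crest-like): azimuthal
    # landmarks that rigid registration cannot absorb into a shift or an
    # axial slide, unlike smooth low-order harmonics
    mod <- mod +
      lobe_amp[1] * exp(-(z / (0.12 * spec$length))^2) *
        pmax(0, cos(phis - lobe_phase[1]))^3 +
      lobe_amp[2] * exp(-((spec$length - z) / (0.12 * spec$length))^2) *
        pmax(0, cos(phis - lobe_phase[2]))^3 +
      crest_amp * pmax(0, cos(phis - crest_phase - 0.005 * z))^6
    r <- r0 * mod
    verts[(i - 1) * n_seg + seq_len(n_seg), ] <-
      cbind(bow_x(z) + r * cos(phis), r * sin(phis), z)
  }
  c_lo <- nz * n_seg + 1
  c_hi <- nz * n_seg + 2
  verts[c_lo, ] <- c(0, 0, 0)
  verts[c_hi, ] <- c(bow_x(spec$length), 0, spec$length)
  faces <- matrix(0L, 0, 3)
  ring <- function(i) (i - 1) * n_seg + seq_len(n_seg)
  for (i in seq_len(nz - 1)) {
    a <- ring(i); b <- ring(i + 1)
    j2 <- c(seq_len(n_seg)[-1], 1L)
    faces <- rbind(faces,
                   cbind(a, b, b[j2]),
                   cbind(a, b[j2], a[j2]))
  }
  j2 <- c(seq_len(n_seg)[-1], 1L)
  faces <- rbind(faces,
                 cbind(rep(c_lo, n_seg), ring(1), ring(1)[j2]),
                 cbind(rep(c_hi, n_seg), ring(nz)[j2], ring(nz)))
  mesh <- surface_mesh(verts, faces, name = "radius")
  if (signed_mesh_volume(mesh) < 0)
    mesh <- surface_mesh(verts, faces[, c(1, 3, 2)], name = "radius")
  mesh
}

#' Plant a wedge deformity into a healthy bone
#'
#' Rotates the distal portion by `wedge_angle` about `wedge_axis`, anchored
#' at the centerline point at `wedge_station`, with a smooth blend band of
#' +/- `blend` mm. The ground truth records the exact inverse correction
#' (what a perfect realignment must recover) and the ideal cutting plane:
#' at the wedge station, tilted to bisect the wedge.
#'
#' @param healthy `surface_mesh` from [make_healthy_bone()].
#' @param spec the case's [synthetic_case_spec()].
#' @param blend half-width of the blend band, mm.
#' @return List with `deformed` (a `surface_mesh`) and `truth` (a
#'   `ground_truth`: `true_realignment`, `true_plane`, `true_angle`,
#'   `true_station`).
#' @export
apply_wedge <- function(healthy, spec, blend = 2) {
  anchor <- c(spec$bow * sin(pi * spec$wedge_station / spec$length), 0,
              spec$wedge_station)
  theta <- spec$wedge_angle
  v <- healthy$vertices
  frac <- smoothstep((v[, 3] - (spec$wedge_station - blend)) / (2 * blend))
  out <- v
  for (f in unique(frac[frac > 0])) {
    R <- rot_axis_angle(spec$wedge_axis, theta * f)
    rows <- which(frac == f)
    out[rows, ] <- sweep(sweep(v[rows, , drop = FALSE], 2, anchor) %*% t(R),
                         2, anchor, `+`)
  }
  deformed <- surface_mesh(out, healthy$faces, name = healthy$name)
  wt <- is_watertight(deformed)
  if (!wt)
    stop("wedge deformation broke the mesh: ", attr(wt, "why"), call. = FALSE)
  true_realign <- compose(
    rigid_from_rt(diag(3), anchor),
    compose(rigid_from_rt(rot_axis_angle(spec$wedge_axis, -theta)),
            rigid_from_rt(diag(3), -anchor)))
  bis_normal <- as.numeric(rot_axis_angle(spec$wedge_axis, theta / 2) %*%
                             c(0, 0, 1))
  truth <- structure(list(
    true_realignment = true_realign,
    true_plane = osteotomy_plane(anchor, bis_normal,
                                 station = spec$wedge_station),
    true_angle = theta, true_station = spec$wedge_station,
    true_axis = spec$wedge_axis
  ), class = "ground_truth")
  list(deformed = deformed, truth = truth)
}

#' Add articular cartilage caps to a bone volume
#'
#' Labels as cartilage every background voxel within `thickness` mm of the
#' bone whose axial position falls in the outer 10% of the bone's axial
#' span — a morphological shell over each articular end.
#'
#' @param bone_vol `label_volume` with a bone label.
#' @param thickness cap thickness, mm (>= 0).
#' @param bone_role the bone's label role.
#' @return The volume with a `cartilage` label added.
#' @export
add_cartilage_caps <- function(bone_vol, thickness, bone_role = "radius") {
  if (thickness < 0) stop("thickness must be >= 0", call. = FALSE)
  lm <- bone_vol$label_map
  if (!"cartilage" %in% names(lm)) lm <- c(lm, cartilage = max(lm) + 1L)
  if (thickness == 0)
    return(label_volume(bone_vol$array, bone_vol$spacing, bone_vol$origin, lm))
  mask <- label_mask(bone_vol, bone_role)
  d <- dim(mask)
  dist <- array(cpp_edt(as.logical(mask), d, bone_vol$spacing), d)
  kz <- which(apply(mask, 3, any))
  span <- range(kz)
  band <- max(1, round(0.1 * diff(span)))
  zidx <- rep(seq_len(d[3]), each = d[1] * d[2])
  end_zone <- zidx <= span[1] + band | zidx >= span[2] - band
  shell <- !mask & dist <= thickness & array(end_zone, d)
  arr <- bone_vol$array
  arr[shell] <- lm[["cartilage"]]
  label_volume(arr, bone_vol$spacing, bone_vol$origin, lm)
}

#' Perturb a segmentation boundary by a smooth random field
#'
#' The mask's signed distance field is offset by a smooth Gaussian random
#' field (coarse-grid noise, trilinearly upsampled) whose amplitude is
#' calibrated — including one measure-and-rescale pass — so that the
#' achieved mean absolute surface distance against the input approximates
#' `masd_target`. Internal holes are filled and only the largest connected
#' component is kept, preserving topology. Deterministic per seed.
#'
#' @param vol single-label `label_volume` (plus background).
#' @param masd_target commanded MASD, mm (>= 0).
#' @param seed RNG seed.
#' @param role label role to perturb.
#' @param corr_mm correlation length of the noise field, mm.
#' @return A perturbed `label_volume` on the same grid.
#' @export
perturb_segmentation <- function(vol, masd_target, seed = 1, role = "radius",
                                 corr_mm = 4) {
  if (masd_target < 0) stop("masd_target must be >= 0", call. = FALSE)
  if (masd_target == 0) return(vol)
  mask <- label_mask(vol, role)
  d <- dim(mask)
  d_out <- array(cpp_edt(as.logical(mask), d, vol$spacing), d)
  d_in <- array(cpp_edt(!as.logical(mask), d, vol$spacing), d)
  sdf <- d_out - d_in
  step <- max(2, round(corr_mm / vol$spacing))
  cd <- pmax(2L, as.integer(ceiling(d / step)) + 1L)
  noise <- local_seed(seed, array(stats::rnorm(prod(cd)), cd))
  idx <- cbind(rep((seq_len(d[1]) - 1) / step, times = d[2] * d[3]),
               rep(rep((seq_len(d[2]) - 1) / step, each = d[1]), times = d[3]),
               rep((seq_len(d[3]) - 1) / step, each = d[1] * d[2]))
  field <- array(trilinear_sample(noise, idx), d)
  field <- field / stats::sd(field)
  make_mask <- function(a) {
    m <- (sdf + a * field) < 0
    if (!any(m)) stop("perturbation erased the segmentation", call. = FALSE)
    m <- array(cpp_largest_component(as.logical(m), d)$mask, d)
    outside <- array(cpp_largest_component(as.logical(!m), d)$mask, d)
    m | !outside  # fill internal holes
  }
  wrap <- function(m) {
    arr <- array(0L, d)
    arr[m] <- vol$label_map[[role]]
    label_volume(arr, vol$spacing, vol$origin, vol$label_map)
  }
  # calibrate the field amplitude against the measured MASD: the voxel
  # quantization of the boundary makes the response nonlinear, so iterate
  # a proportional update a few times
  a <- masd_target * sqrt(pi / 2)
  m1 <- make_mask(a)
  for (pass in 1:4) {
    achieved <- masd(vol, wrap(m1), role = role)
    if (achieved == 0 || abs(achieved - masd_target) / masd_target <= 0.1)
      break
    a <- a * (masd_target / achieved)^0.8
    m1 <- make_mask(a)
  }
  wrap(m1)
}

#' Generate a seeded cohort of synthetic cases
#'
#' Each case carries a healthy bone, its sagittal mirror as the
#' contralateral side, a deformed bone with known wedge ground truth, and
#' three segmentation variants: clean voxelization (CT-bone-like), boundary
#' perturbed (MRI-bone-like), and perturbed plus cartilage caps
#' (MRI-bone-and-cartilage-like). Ages span 7-18 years with cartilage
#' thickness decreasing with age, so the cohort's relative cartilage volume
#' falls exponentially with age.
#'
#' @param n_cases number of cases (>= 1).
#' @param seed cohort seed.
#' @param voxel segmentation voxel edge, mm.
#' @param mesh_voxel voxel edge at which planning meshes are extracted, mm.
#' @param make_volumes generate the volumetric variants (slower); if FALSE
#'   only meshes and ground truth are produced.
#' @return List of case lists: `id`, `spec`, `age`, `healthy`,
#'   `contralateral`, `deformed`, `truth`, and with volumes: `volumes`
#'   (CTb/MRb/MRbc `label_volume`s), `meshes` (CTb/MRb/MRbc bone surfaces,
#'   MRbc the bone+cartilage union), `rcv`.
#' @export
generate_cohort <- function(n_cases = 10, seed = 1, voxel = 0.5,
                            mesh_voxel = 1, make_volumes = TRUE) {
  if (n_cases < 1) stop("n_cases must be >= 1", call. = FALSE)
  pars <- local_seed(seed, {
    ages <- seq(7, 18, length.out = n_cases) + stats::runif(n_cases, -0.4, 0.4)
    list(
      ages = ages,
      length = stats::runif(n_cases, 105, 135),
      shaft = stats::runif(n_cases, 5, 7),
      epi = stats::runif(n_cases, 8.5, 11),
      angle = stats::runif(n_cases, 10, 30) * pi / 180,
      axis_phi = stats::runif(n_cases, 0, 2 * pi),
      station_frac = stats::runif(n_cases, 0.4, 0.6),
      thick = pmax(0.6, 2.2 * exp(-0.10 * (ages - 7)) *
                     exp(stats::rnorm(n_cases, 0, 0.05))),
      masd = stats::runif(n_cases, 0.35, 0.45)
    )
  })
  lapply(seq_len(n_cases), function(i) {
    spec <- synthetic_case_spec(
      seed = seed * 1000L + i, length = pars$length[i],
      shaft_radius = pars$shaft[i], epiphysis_radius = pars$epi[i],
      wedge_angle = pars$angle[i],
      wedge_axis = c(cos(pars$axis_phi[i]), sin(pars$axis_phi[i]), 0),
      wedge_station = pars$station_frac[i] * pars$length[i],
      cartilage_thickness = pars$thick[i], age_proxy = pars$ages[i],
      noise_masd_target = pars$masd[i])
    healthy <- make_healthy_bone(spec)
    wd <- apply_wedge(healthy, spec)
    case <- list(id = sprintf("case%02d", i), spec = spec,
                 age = spec$age_proxy, healthy = healthy,
                 contralateral = mirror_sagittal(healthy),
                 deformed = wd$deformed, truth = wd$truth)
    if (make_volumes) {
      ctb <- voxelize_mesh(wd$deformed, voxel, pad = 4)
      ctb <- label_volume(ctb$array, ctb$spacing, ctb$origin,
                          label_map = c(radius = 1, cartilage = 2))
      mrb <- perturb_segmentation(ctb, spec$noise_masd_target,
                                  seed = spec$seed + 7)
      mrbc <- add_cartilage_caps(mrb, spec$cartilage_thickness)
      nb <- sum(mrbc$array == mrbc$label_map[["radius"]])
      nc <- sum(mrbc$array == mrbc$label_map[["cartilage"]])
      mesh_of <- function(v, union_cartilage = FALSE) {
        vv <- if (abs(v$spacing - mesh_voxel) > 1e-9)
          resample_isotropic(v, mesh_voxel) else v
        if (union_cartilage) {
          arr <- vv$array
          arr[arr != 0L] <- 1L
          vv <- label_volume(arr, vv$spacing, vv$origin, c(radius = 1))
        }
        mesh_from_labels(vv, "radius")
      }
      case$volumes <- list(CTb = ctb, MRb = mrb, MRbc = mrbc)
      case$meshes <- list(CTb = mesh_of(ctb), MRb = mesh_of(mrb),
                          MRbc = mesh_of(mrbc, union_cartilage = TRUE))
      case$rcv <- nc / nb
      # contralateral template per method: bone surface for CTb and MRb;
      # for MRbc the bone+cartilage union of the healthy side, since
      # cartilage-inclusive planning uses the union surface on both sides
      vh <- voxelize_mesh(healthy, voxel, pad = 4)
      vh <- label_volume(vh$array, vh$spacing, vh$origin,
                         label_map = c(radius = 1, cartilage = 2))
      vhc <- add_cartilage_caps(vh, spec$cartilage_thickness)
      case$contralateral_meshes <- list(
        CTb = case$contralateral, MRb = case$contralateral,
        MRbc = mirror_sagittal(mesh_of(vhc, union_cartilage = TRUE)))
    }
    case
  })
}
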