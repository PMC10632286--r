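#' Labelled segmentation volumes
#'
#' A `label_volume` is a 3D integer label grid with isotropic physical
#' spacing. Voxel (i,j,k) (1-based) has its center at
#' `origin + (i-1, j-1, k-1) * spacing`, in mm. The label map assigns roles
#' (radius, ulna, cartilage) to integer codes; 0 is always background.
#'
#' @param array 3D integer array of labels.
#' @param spacing scalar voxel edge length, mm (> 0).
#' @param origin length-3 mm position of the first voxel center.
#' @param label_map named integer vector, e.g. `c(radius = 1, ulna = 2,
#'   cartilage = 3)`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(array, spacing, origin = c(0, 0, 0),
                         label_map = c(radius = 1, ulna = 2, cartilage = 3)) {
  if (length(dim(array)) != 3 || any(dim(array) < 2))
    stop("label array must be 3D with each dimension >= 2", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0)
    stop("spacing must be a positive scalar (mm)", call. = FALSE)
  arr <- array
  storage.mode(arr) <- "integer"
  present <- setdiff(unique(as.vector(arr)), 0L)
  if (length(setdiff(present, as.integer(label_map))) > 0)
    stop("array contains labels absent from label_map", call. = FALSE)
  structure(list(array = arr, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 label_map = label_map),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels @ %.3g mm, labels: %s\n",
              paste(dim(x$array), collapse = "x"), x$spacing,
              paste(names(x$label_map), x$label_map, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Logical mask of one label role
#' @param vol a `label_volume`.
#' @param role role name in the label map, or an integer code.
#' @export
label_mask <- function(vol, role) {
  code <- if (is.character(role)) {
    if (!role %in% names(vol$label_map))
      stop("unknown label role '", role, "'", call. = FALSE)
    vol$label_map[[role]]
  } else as.integer(role)
  vol$array == code
}

# Trilinear sampling of a 3D array at continuous 0-based indices (Nx3),
# clamped to the grid.
trilinear_sample <- function(arr, idx) {
  d <- dim(arr)
  idx[, 1] <- pmin(pmax(idx[, 1], 0), d[1] - 1)
  idx[, 2] <- pmin(pmax(idx[, 2], 0), d[2] - 1)
  idx[, 3] <- pmin(pmax(idx[, 3], 0), d[3] - 1)
  i0 <- pmin(floor(idx), rep(d - 1L - 1L, each = nrow(idx)))
  i0 <- matrix(pmax(i0, 0), ncol = 3)
  fr <- idx - i0
  at <- function(ox, oy, oz)
    arr[cbind(i0[, 1] + ox + 1, i0[, 2] + oy + 1, i0[, 3] + oz + 1)]
  (1 - fr[, 1]) * (1 - fr[, 2]) * (1 - fr[, 3]) * at(0, 0, 0) +
    fr[, 1] * (1 - fr[, 2]) * (1 - fr[, 3]) * at(1, 0, 0) +
    (1 - fr[, 1]) * fr[, 2] * (1 - fr[, 3]) * at(0, 1, 0) +
    fr[, 1] * fr[, 2] * (1 - fr[, 3]) * at(1, 1, 0) +
    (1 - fr[, 1]) * (1 - fr[, 2]) * fr[, 3] * at(0, 0, 1) +
    fr[, 1] * (1 - fr[, 2]) * fr[, 3] * at(1, 0, 1) +
    (1 - fr[, 1]) * fr[, 2] * fr[, 3] * at(0, 1, 1) +
    fr[, 1] * fr[, 2] * fr[, 3] * at(1, 1, 1)
}

#' Resample a label volume to a new isotropic spacing
#'
#' Each label is resampled as an indicator function by trilinear
#' interpolation and re-thresholded at 0.5; where several labels exceed 0.5
#' the one with the largest interpolated weight wins. The default target of
#' 0.5 mm matches the working resolution of the planning pipeline.
#'
#' @param vol a `label_volume`.
#' @param target_spacing new voxel edge, mm (> 0).
#' @return A `label_volume` at the new spacing (same origin).
#' @export
resample_isotropic <- function(vol, target_spacing = 0.5) {
  if (!is.numeric(target_spacing) || length(target_spacing) != 1 ||
      target_spacing <= 0)
    stop("target_spacing must be a positive scalar (mm)", call. = FALSE)
  if (target_spacing == vol$spacing) return(vol)
  d <- dim(vol$array)
  # edge-aligned grid: the new voxel lattice tiles the same physical block
  # (old extent d * spacing), so voxel-counting volumes are unbiased
  nd <- pmax(2L, as.integer(round(d * vol$spacing / target_spacing)))
  new_origin <- vol$origin - (vol$spacing - target_spacing) / 2
  # continuous 0-based indices of the new centers in the old lattice
  gx <- ((seq_len(nd[1]) - 1) * target_spacing +
           new_origin[1] - vol$origin[1]) / vol$spacing
  gy <- ((seq_len(nd[2]) - 1) * target_spacing +
           new_origin[2] - vol$origin[2]) / vol$spacing
  gz <- ((seq_len(nd[3]) - 1) * target_spacing +
           new_origin[3] - vol$origin[3]) / vol$spacing
  idx <- cbind(rep(gx, times = nd[2] * nd[3]),
               rep(rep(gy, each = nd[1]), times = nd[3]),
               rep(gz, each = nd[1] * nd[2]))
  out <- array(0L, nd)
  bestw <- array(0.5, nd)  # a label must exceed 0.5 to claim a voxel
  for (role in names(vol$label_map)) {
    code <- vol$label_map[[role]]
    if (!any(vol$array == code)) next
    ind <- array(as.numeric(vol$array == code), d)
    w <- array(trilinear_sample(ind, idx), nd)
    claim <- w > bestw
    out[claim] <- code
    bestw[claim] <- w[claim]
  }
  label_volume(out, target_spacing, new_origin, vol$label_map)
}

#' Read / write a label volume as NIfTI
#'
#' Integer-labelled NIfTI volumes only. Anisotropic inputs are automatically
#' resampled to the smallest voxel edge with a warning; non-integer data is
#' an error.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param label_map role -> integer code mapping to attach.
#' @export
read_label_volume <- function(path,
                              label_map = c(radius = 1, ulna = 2, cartilage = 3)) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- as.array(img)
  arr <- array(as.vector(arr), dim(arr)[1:3])  # strip NIfTI attributes
  if (max(abs(arr - round(arr))) > 1e-9)
    stop("NIfTI file does not contain integer label data", call. = FALSE)
  org <- attr(img, ".origin")
  if (is.null(org)) {
    xf <- try(RNifti::xform(img), silent = TRUE)
    org <- if (inherits(xf, "try-error")) c(0, 0, 0) else xf[1:3, 4]
  }
  vol <- label_volume(round(arr), max(sp), origin = org, label_map = label_map)
  if (diff(range(sp)) > 1e-6) {
    warning("anisotropic spacing ", paste(signif(sp, 4), collapse = "x"),
            "; resampling to isotropic ", signif(min(sp), 4), " mm")
    # rebuild at the coarsest axis first is wrong; interpolate per axis scale
    vol <- resample_anisotropic(arr, sp, org, label_map, min(sp))
  }
  vol
}

# anisotropic -> isotropic resampling used by the NIfTI reader only
resample_anisotropic <- function(arr, sp, origin, label_map, target) {
  d <- dim(arr)
  nd <- pmax(2L, as.integer(round(d * sp / target)))
  new_origin <- origin - (sp - target) / 2
  gx <- ((seq_len(nd[1]) - 1) * target - (sp[1] - target) / 2) / sp[1]
  gy <- ((seq_len(nd[2]) - 1) * target - (sp[2] - target) / 2) / sp[2]
  gz <- ((seq_len(nd[3]) - 1) * target - (sp[3] - target) / 2) / sp[3]
  idx <- cbind(rep(gx, times = nd[2] * nd[3]),
               rep(rep(gy, each = nd[1]), times = nd[3]),
               rep(gz, each = nd[1] * nd[2]))
  out <- array(0L, nd)
  bestw <- array(0.5, nd)
  for (role in names(label_map)) {
    code <- label_map[[role]]
    if (!any(arr == code)) next
    ind <- array(as.numeric(arr == code), d)
    w <- array(trilinear_sample(ind, idx), nd)
    claim <- w > bestw
    out[claim] <- code
    bestw[claim] <- w[claim]
  }
  label_volume(out, target, new_origin, label_map)
}

#' @rdname read_label_volume
#' @param vol a `label_volume`.
#' @export
write_label_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$array)
  RNifti::pixdim(img) <- rep(vol$spacing, 3)
  mat <- diag(4)
  diag(mat)[1:3] <- vol$spacing
  mat[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(mat, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
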