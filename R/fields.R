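#' Displacement field on the reference grid
#'
#' A per-voxel 3-vector field realizing the phase mapping: a reference-grid
#' point at 0-based voxel coordinate `x` maps to `x + vox[x]` in the target
#' phase (voxel units). World-mm vectors are obtained through the affine's
#' linear part.
#'
#' @param vox 4D array `c(nx, ny, nz, 3)` of displacements in voxel units.
#' @param affine 4x4 voxel-to-world matrix of the reference grid.
#' @param phase_percent target phase label.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vox, affine = diag(4), phase_percent = NA_integer_) {
  d <- dim(vox)
  if (length(d) != 4L || d[4] != 3L)
    stop("'vox' must be an (nx, ny, nz, 3) array", call. = FALSE)
  if (!all(is.finite(vox)))
    stop("displacement field must be finite everywhere", call. = FALSE)
  structure(list(vox = vox, affine = unname(as.matrix(affine)),
                 phase_percent = as.integer(phase_percent)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$vox)
  mag <- sqrt(x$vox[, , , 1]^2 + x$vox[, , , 2]^2 + x$vox[, , , 3]^2)
  cat(sprintf("<displacement_field> %dx%dx%d, phase %s%%, |u| mean %.3f / max %.3f voxels\n",
              d[1], d[2], d[3],
              ifelse(is.na(x$phase_percent), "?", x$phase_percent),
              mean(mag), max(mag)))
  invisible(x)
}

#' Zero (identity) displacement field on a volume's grid
#' @param volume a [ct_volume] (or [binary_mask]) providing grid and affine.
#' @param phase_percent phase label for the identity field.
#' @return A [displacement_field] of zeros.
#' @export
identity_field <- function(volume, phase_percent = NA_integer_) {
  d <- dim(volume$voxels)
  displacement_field(array(0, c(d, 3)), volume$affine, phase_percent)
}

#' Build a displacement field from a world-coordinate function
#'
#' Evaluates `fun` (mapping an n x 3 matrix of world points to an n x 3
#' matrix of world-mm displacements) at every voxel centre of `volume`'s
#' grid. Used to construct analytic ground-truth fields.
#'
#' @param fun displacement function in world mm.
#' @param volume grid/affine provider.
#' @param phase_percent phase label.
#' @return A [displacement_field].
#' @export
field_from_function <- function(fun, volume, phase_percent = NA_integer_) {
  d <- dim(volume$voxels)
  vox_idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                                   k = 0:(d[3] - 1)))
  world <- voxel_to_world(vox_idx, volume$affine)
  disp_mm <- fun(world)
  A_inv <- solve(volume$affine[1:3, 1:3])
  disp_vox <- t(A_inv %*% t(disp_mm))
  displacement_field(array(disp_vox, c(d, 3)), volume$affine, phase_percent)
}

# world-mm displacement vectors of a field at world-coordinate points
# (trilinear in voxel space, nearest-edge extrapolation)
sample_field_mm <- function(field, points_world) {
  pts_vox <- world_to_voxel(points_world, field$affine)
  d <- dim(field$vox)[1:3]
  v_vox <- cpp_sample_field(as.numeric(field$vox), as.integer(d), pts_vox)
  t(field$affine[1:3, 1:3] %*% t(v_vox))
}

#' Jacobian statistics of a displacement field
#'
#' Determinants of the Jacobian of the realized mapping `x + u(x)` (voxel
#' units, central differences). The fraction of positive determinants is the
#' diffeomorphism proxy used for registration quality control.
#'
#' @param field a [displacement_field].
#' @return list with `min`, `frac_positive`, and the determinant array `det`.
#' @export
jacobian_stats <- function(field) {
  d <- dim(field$vox)[1:3]
  dets <- cpp_jacobian_det(as.numeric(field$vox), as.integer(d))
  list(min = min(dets), frac_positive = mean(dets > 0),
       det = array(dets, d))
}

#' Invert a displacement field
#'
#' Fixed-point iteration for the inverse mapping: returns `v` such that
#' `(y + v(y)) + u(y + v(y)) = y` up to `tol` voxels.
#'
#' @param field a [displacement_field].
#' @param iters maximum iterations.
#' @param tol convergence tolerance in voxels (default 0.05).
#' @return The inverse [displacement_field].
#' @export
invert_field <- function(field, iters = 30, tol = 0.05) {
  d <- dim(field$vox)[1:3]
  inv <- cpp_invert_field(as.numeric(field$vox), as.integer(d),
                          as.integer(iters), tol)
  displacement_field(array(inv, c(d, 3)), field$affine, field$phase_percent)
}

#' Propagate a reference-grid region to a phase
#'
#' Realizes the deformed region `phi_t(Omega_ref)` on the reference grid
#' resolution: a target voxel `y` belongs to the deformed region when the
#' inverse-mapped point `phi_t^{-1}(y)` falls inside the input mask
#' (trilinear mask interpolation, 0.5 threshold). The output inherits the
#' grid and affine of the input.
#'
#' @param mask_ref a [binary_mask] on the reference grid.
#' @param field the [displacement_field] mapping reference to phase-t
#'   coordinates.
#' @return The deformed [binary_mask].
#' @export
propagate_region <- function(mask_ref, field) {
  if (!any(mask_ref$voxels))
    stop("empty region: input mask has no foreground voxels", call. = FALSE)
  d <- dim(mask_ref$voxels)
  inv <- cpp_invert_field(as.numeric(field$vox), as.integer(d), 30L, 0.05)
  vox_idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                                   k = 0:(d[3] - 1)))
  inv_vec <- cpp_sample_field(inv, as.integer(d), vox_idx)
  src <- vox_idx + inv_vec
  vals <- cpp_sample_scalar(as.numeric(mask_ref$voxels), as.integer(d), src)
  binary_mask(array(vals >= 0.5, d), mask_ref$affine, mask_ref$label)
}

#' Write a displacement field as 4D NIfTI (mm vectors, vector dim last)
#' @param field a [displacement_field].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  d <- dim(field$vox)
  flat <- matrix(field$vox, ncol = 3)
  mm <- t(field$affine[1:3, 1:3] %*% t(flat))
  im <- RNifti::asNifti(array(mm, d))
  sp <- sqrt(colSums(field$affine[1:3, 1:3]^2))
  RNifti::pixdim(im) <- c(sp, 1)
  im <- RNifti::`sform<-`(im, structure(field$affine, code = 2L))
  im <- RNifti::`qform<-`(im, structure(field$affine, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}
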