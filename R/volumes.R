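#' CT volume container
#'
#' A single 3D CT volume in Hounsfield units with its voxel-to-world affine
#' (mm) and an R-R phase label. The affine maps 0-based voxel indices to
#' world coordinates in mm (NIfTI convention); voxel values must be finite
#' and the affine invertible.
#'
#' @param voxels 3D numeric array of HU values.
#' @param affine 4x4 voxel-to-world matrix (mm), 0-based voxel indices.
#' @param phase_percent R-R phase label in `{10, 20, ..., 90}`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, affine = diag(4), phase_percent = NA_integer_) {
  if (length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array", call. = FALSE)
  if (!all(is.finite(voxels)))
    stop("HU values must be finite", call. = FALSE)
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("'affine' must be an invertible 4x4 matrix", call. = FALSE)
  structure(list(voxels = voxels, affine = unname(affine),
                 phase_percent = as.integer(phase_percent)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %dx%dx%d voxels, phase %s%%, HU range [%.0f, %.0f]\n",
              d[1], d[2], d[3],
              ifelse(is.na(x$phase_percent), "?", x$phase_percent),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary mask aligned with a CT volume
#'
#' @param voxels 3D logical (or 0/1) array.
#' @param affine 4x4 voxel-to-world matrix (mm).
#' @param label one of `"pericardium"`, `"EAT"`, `"ROI"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, affine = diag(4),
                        label = c("pericardium", "EAT", "ROI")) {
  label <- match.arg(label)
  if (length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array", call. = FALSE)
  voxels <- array(as.logical(voxels), dim = dim(voxels))
  if (anyNA(voxels)) stop("mask voxels must be TRUE/FALSE", call. = FALSE)
  structure(list(voxels = voxels, affine = unname(as.matrix(affine)),
                 label = label),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> label '%s', %d foreground voxels of %s\n",
              x$label, sum(x$voxels), paste(dim(x$voxels), collapse = "x")))
  invisible(x)
}

#' Ordered series of cardiac phases
#'
#' Bundles the nine phase volumes (10--90% R-R in 10% steps) with the index
#' of the 50% reference phase and normalized times `t_k = k/9`, `k = 0..8`.
#' Phases 10% and 90% are treated as cyclic neighbours when inter-phase
#' displacements are formed.
#'
#' @param volumes list of [ct_volume] objects, any order; phase labels must
#'   be exactly `{10, ..., 90}`.
#' @param ref_phase reference phase percent (default 50).
#' @return An object of class `phase_series` with elements `volumes` (sorted
#'   by phase), `ref_index`, `normalized_times`.
#' @export
phase_series <- function(volumes, ref_phase = 50) {
  phases <- vapply(volumes, function(v) v$phase_percent, integer(1))
  expected <- seq(10L, 90L, by = 10L)
  if (length(volumes) != 9L || !setequal(phases, expected))
    stop("incomplete series: need exactly the nine phases 10..90%",
         call. = FALSE)
  ord <- order(phases)
  volumes <- volumes[ord]
  d0 <- dim(volumes[[1]]$voxels)
  a0 <- volumes[[1]]$affine
  for (v in volumes) {
    if (!identical(dim(v$voxels), d0) || max(abs(v$affine - a0)) > 1e-6)
      stop("grid incompatibility: all phases must share shape and affine",
           call. = FALSE)
  }
  ref_index <- match(as.integer(ref_phase), sort(phases))
  if (is.na(ref_index))
    stop("reference phase not present in the series", call. = FALSE)
  structure(list(volumes = volumes, ref_index = ref_index,
                 normalized_times = (0:8) / 9),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> 9 phases 10..90%%, reference %d%% (index %d), grid %s\n",
              x$volumes[[x$ref_index]]$phase_percent, x$ref_index,
              paste(dim(x$volumes[[1]]$voxels), collapse = "x")))
  invisible(x)
}

#' Reference volume of a series
#' @param series a [phase_series].
#' @return The reference-phase [ct_volume].
#' @export
ref_volume <- function(series) series$volumes[[series$ref_index]]

#' Read a nine-phase NIfTI series
#'
#' Reads one NIfTI volume per cardiac phase. Phase labels are taken from the
#' names of `paths` when given, otherwise parsed from the file names (the
#' first 10..90 multiple-of-ten integer found).
#'
#' @param paths character vector of 9 NIfTI file paths, optionally named by
#'   phase percent.
#' @param ref_phase reference phase percent (default 50).
#' @return A [phase_series].
#' @export
read_phase_series <- function(paths, ref_phase = 50) {
  if (!is.null(names(paths)) && all(nzchar(names(paths)))) {
    phases <- as.integer(names(paths))
  } else {
    phases <- vapply(basename(paths), function(f) {
      m <- regmatches(f, gregexpr("[0-9]+", f))[[1]]
      m <- as.integer(m)
      m <- m[m %in% seq(10, 90, 10)]
      if (length(m) == 0) NA_integer_ else m[1]
    }, integer(1))
  }
  if (anyNA(phases))
    stop("could not determine phase labels from file names; name 'paths' by percent",
         call. = FALSE)
  vols <- lapply(seq_along(paths), function(i) {
    im <- RNifti::readNifti(paths[i])
    aff <- unname(unclass(RNifti::xform(im)))[1:4, 1:4]
    ct_volume(nifti_array(im), aff, phases[i])
  })
  phase_series(vols, ref_phase = ref_phase)
}

#' Write a volume or mask as NIfTI-1
#'
#' @param x a [ct_volume] or [binary_mask].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  arr <- if (inherits(x, "binary_mask")) array(as.numeric(x$voxels), dim(x$voxels)) else x$voxels
  im <- RNifti::asNifti(arr)
  sp <- sqrt(colSums(x$affine[1:3, 1:3]^2))
  RNifti::pixdim(im) <- sp
  im <- RNifti::`sform<-`(im, structure(x$affine, code = 2L))
  im <- RNifti::`qform<-`(im, structure(x$affine, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#' @param path NIfTI file.
#' @param label mask label (see [binary_mask]).
#' @return A [binary_mask].
#' @export
read_mask <- function(path, label = "pericardium") {
  im <- RNifti::readNifti(path)
  aff <- unname(unclass(RNifti::xform(im)))[1:4, 1:4]
  binary_mask(nifti_array(im) > 0.5, aff, label)
}

# plain numeric array from an RNifti image (drop image attributes)
nifti_array <- function(im) {
  arr <- as.array(im)
  array(as.numeric(arr), dim = dim(arr))
}

# ---- grid / coordinate helpers ----------------------------------------------

# world mm -> 0-based voxel coordinates (n x 3)
world_to_voxel <- function(points, affine) {
  points <- matrix(points, ncol = 3)
  inv <- solve(affine)
  t(inv %*% rbind(t(points), 1))[, 1:3, drop = FALSE]
}

# 0-based voxel coordinates -> world mm
voxel_to_world <- function(vox, affine) {
  vox <- matrix(vox, ncol = 3)
  t(affine %*% rbind(t(vox), 1))[, 1:3, drop = FALSE]
}

# world coordinates (n x 3) of the centres of a mask's foreground voxels,
# ordered by linear (column-major) voxel index -- the point-id order used for
# correspondence tie-breaking.
mask_points <- function(mask) {
  idx <- which(mask$voxels)
  d <- dim(mask$voxels)
  i <- (idx - 1) %% d[1]
  j <- ((idx - 1) %/% d[1]) %% d[2]
  k <- (idx - 1) %/% (d[1] * d[2])
  voxel_to_world(cbind(i, j, k), mask$affine)
}

# boundary shell of a filled region mask: foreground voxels with at least one
# 6-neighbour outside the mask (or on the grid edge)
mask_boundary <- function(mask) {
  m <- mask$voxels
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  binary_mask(m & !core, mask$affine, mask$label)
}
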