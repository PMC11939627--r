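#' Build per-point trajectories across phases
#'
#' Transports a set of reference-grid points through the phase mappings:
#' position of point `p` at phase `k` is `p + u_k(p)` with `u_k` the
#' phase-`k` field sampled at the reference position (world mm). Point
#' identity is preserved across phases; points outside the field domain
#' take the nearest-edge field value (flagged with a warning).
#'
#' @param fields list of 9 [displacement_field]s from
#'   [register_to_reference()], ordered by phase.
#' @param points_ref n x 3 matrix of world-mm points on the reference grid.
#' @param tissue `"pericardium"` or `"EAT"`.
#' @return An object of class `trajectory`: `positions` (n x 3 x 9 array,
#'   mm), `delta_t` (1/9), `tissue`.
#' @export
build_trajectories <- function(fields, points_ref,
                               tissue = c("pericardium", "EAT")) {
  tissue <- match.arg(tissue)
  points_ref <- matrix(points_ref, ncol = 3)
  stopifnot(length(fields) == 9L)
  d <- dim(fields[[1]]$vox)[1:3]
  vox <- world_to_voxel(points_ref, fields[[1]]$affine)
  out_of_domain <- vox < -0.5 | sweep(vox, 2, d - 0.5, ">")
  if (any(out_of_domain))
    warning(sprintf("%d point(s) outside the field domain; nearest-edge values used",
                    sum(rowSums(out_of_domain) > 0)))
  pos <- array(NA_real_, c(nrow(points_ref), 3, 9))
  for (k in seq_len(9)) {
    disp <- sample_field_mm(fields[[k]], points_ref)
    pos[, , k] <- points_ref + disp
  }
  structure(list(positions = pos, delta_t = 1 / 9, tissue = tissue),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d %s points over 9 phases\n",
              dim(x$positions)[1], x$tissue))
  invisible(x)
}

#' Inter-phase displacement vectors at a phase
#'
#' The displacement assigned to phase `k` is the difference between the
#' positions at phase `k` and the previous phase; at the first phase the
#' previous phase is the last one, closing the cardiac cycle (so the nine
#' displacements of every point telescope to exactly zero).
#'
#' @param traj a [trajectory].
#' @param k phase index in 1..9 (1 = the 10% phase).
#' @return n x 3 matrix of displacement vectors (mm).
#' @export
displacement_at <- function(traj, k) {
  stopifnot(k %in% 1:9)
  prev <- if (k == 1) 9 else k - 1
  n <- dim(traj$positions)[1]
  matrix(traj$positions[, , k] - traj$positions[, , prev], nrow = n, ncol = 3)
}

#' Nearest-point correspondence between EAT and pericardial points
#'
#' Maps every EAT point to its exact Euclidean nearest pericardial point
#' (exhaustive search; ties broken by the smallest pericardial point index).
#'
#' @param eat_points n x 3 matrix of EAT point positions at a phase (mm).
#' @param peri_points m x 3 matrix of pericardial point positions at the
#'   same phase (mm).
#' @return A data.frame of class `correspondence` with columns `eat`
#'   (1..n), `peri` (matched index in 1..m), `distance` (mm).
#' @export
correspond <- function(eat_points, peri_points) {
  eat_points <- matrix(eat_points, ncol = 3)
  peri_points <- matrix(peri_points, ncol = 3)
  if (nrow(peri_points) == 0L)
    stop("empty region: no pericardial points", call. = FALSE)
  if (nrow(eat_points) == 0L)
    stop("empty region: no EAT points", call. = FALSE)
  nn <- cpp_nearest(eat_points, peri_points)
  out <- data.frame(eat = seq_len(nrow(eat_points)),
                    peri = nn$index, distance = nn$distance)
  class(out) <- c("correspondence", "data.frame")
  out
}
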