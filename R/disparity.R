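#' EAT-pericardium motion disparity at one phase
#'
#' For each corresponding pair `(p, q)` the relative displacement difference
#' is `D_EAT(p) - D_peri(q)`; its Euclidean norm is the scalar motion
#' disparity used downstream.
#'
#' @param d_eat n x 3 matrix of EAT point displacements at the phase (mm).
#' @param d_peri m x 3 matrix of pericardial point displacements at the same
#'   phase (mm).
#' @param corr a [correspond()] result pairing the n EAT points with
#'   pericardial indices in 1..m.
#' @return list with `diffs` (n x 3, mm) and `magnitudes` (length n, mm).
#' @export
motion_disparity <- function(d_eat, d_peri, corr) {
  d_eat <- matrix(d_eat, ncol = 3)
  d_peri <- matrix(d_peri, ncol = 3)
  if (nrow(corr) != nrow(d_eat))
    stop("pairing error: correspondence rows must match EAT points", call. = FALSE)
  if (max(corr$peri) > nrow(d_peri))
    stop("pairing error: pericardial index out of range", call. = FALSE)
  diffs <- d_eat - d_peri[corr$peri, , drop = FALSE]
  list(diffs = diffs, magnitudes = sqrt(rowSums(diffs^2)))
}

#' Study-level normalization of disparity magnitudes
#'
#' The study maximum `d_max` is taken over all point pairs and all cardiac
#' phases; every magnitude is divided by it so normalized disparities lie in
#' \[0, 1\] with maximum exactly 1. In the degenerate zero-motion limit
#' (`d_max = 0`) all normalized values are 0.
#'
#' @param magnitudes numeric vector or matrix (pairs x phases) of raw
#'   disparity magnitudes (mm).
#' @return list with `d_max` (mm) and `normalized` (same shape as input).
#' @export
normalize_study <- function(magnitudes) {
  if (length(magnitudes) == 0)
    stop("empty disparity: no magnitudes to normalize", call. = FALSE)
  d_max <- max(magnitudes)
  normalized <- if (d_max > 0) magnitudes / d_max else magnitudes * 0
  list(d_max = d_max, normalized = normalized)
}

#' Select EAT points inside the cylindrical LAD ROI
#'
#' A point belongs to the ROI when its minimum distance to the centerline
#' polyline, restricted to the configured arc-length window, is at most the
#' cylinder radius. The default window runs from the start of the middle
#' segment to the end of the centerline; `window = "mid_to_dist"` stops at
#' the start of the distal segment.
#'
#' @param eat_points n x 3 matrix of EAT point positions at a phase (mm).
#' @param cl a [centerline].
#' @param radius_r cylinder radius in mm (default the centerline's).
#' @param window `"mid_to_end"` or `"mid_to_dist"`.
#' @return An object of class `roi_selection`: `member_ids` (indices into
#'   `eat_points`), `window` (`c(s_lo, s_hi)` in mm), `radius_r`.
#' @export
select_roi <- function(eat_points, cl, radius_r = cl$radius_r,
                       window = c("mid_to_end", "mid_to_dist")) {
  window <- match.arg(window)
  s_lo <- cl$s_mid
  s_hi <- if (window == "mid_to_end") cl$length else cl$s_dist
  d <- centerline_distance(eat_points, cl, s_lo, s_hi)
  members <- which(d <= radius_r)
  if (length(members) == 0L)
    warning("empty ROI: no EAT points within the cylinder")
  structure(list(member_ids = members, window = c(s_lo, s_hi),
                 radius_r = radius_r),
            class = "roi_selection")
}

#' @export
print.roi_selection <- function(x, ...) {
  cat(sprintf("<roi_selection> %d members, window [%.1f, %.1f] mm, r = %.1f mm\n",
              length(x$member_ids), x$window[1], x$window[2], x$radius_r))
  invisible(x)
}

#' Per-phase disparity totals and the optimal phase
#'
#' The total motion disparity of phase `k` is the sum of normalized
#' disparities over the ROI members at that phase; the optimal phase `t*`
#' is the phase with the largest total (smallest index on ties).
#'
#' @param normalized n x 9 matrix of normalized disparities (pairs x phases).
#' @param roi a single [select_roi()] result applied to all phases, or a
#'   list of 9 phase-specific selections.
#' @return An object of class `phase_disparity`: `m_t` (length 9),
#'   `t_star` (index 1..9), `phase_percents`.
#' @export
phase_totals <- function(normalized, roi) {
  normalized <- as.matrix(normalized)
  stopifnot(ncol(normalized) == 9L)
  rois <- if (inherits(roi, "roi_selection")) rep(list(roi), 9) else roi
  stopifnot(length(rois) == 9L)
  if (all(vapply(rois, function(r) length(r$member_ids) == 0L, logical(1))))
    stop("empty ROI in every phase", call. = FALSE)
  m_t <- vapply(seq_len(9), function(k)
    sum(normalized[rois[[k]]$member_ids, k]), numeric(1))
  structure(list(m_t = m_t, t_star = which.max(m_t),
                 phase_percents = seq(10, 90, 10)),
            class = "phase_disparity")
}

#' @export
print.phase_disparity <- function(x, ...) {
  cat("<phase_disparity> total normalized disparity per phase:\n")
  v <- sprintf("%.2f", x$m_t)
  names(v) <- paste0(x$phase_percents, "%")
  print(v, quote = FALSE)
  cat(sprintf("optimal phase t* = %d%% (index %d)\n",
              x$phase_percents[x$t_star], x$t_star))
  invisible(x)
}
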