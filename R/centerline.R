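#' Coronary centerline polyline
#'
#' An ordered polyline of world-coordinate points (mm) parameterized by
#' cumulative arc length, with the arc-length boundaries of the middle and
#' distal vessel segments and the cylindrical assessment radius. When
#' `s_mid`/`s_dist` are not supplied they default to arc-length thirds of the
#' total length (no anatomical boundary rule is imposed).
#'
#' @param points n x 3 matrix of ordered points (mm), n >= 2.
#' @param s_mid arc length (mm) at which the middle segment starts.
#' @param s_dist arc length (mm) at which the distal segment starts.
#' @param radius_r cylinder radius in mm (default 6).
#' @return An object of class `centerline` with `points`, `arclengths`,
#'   `s_mid`, `s_dist`, `length`, `radius_r`.
#' @export
centerline <- function(points, s_mid = NULL, s_dist = NULL, radius_r = 6) {
  points <- as.matrix(points)
  if (nrow(points) < 2L || ncol(points) != 3L)
    stop("degenerate centerline: need >= 2 ordered 3D points", call. = FALSE)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0))
    warning("duplicated consecutive centerline point(s); arc length repeats")
  arclengths <- c(0, cumsum(seg))
  L <- arclengths[length(arclengths)]
  if (is.null(s_mid)) s_mid <- L / 3
  if (is.null(s_dist)) s_dist <- 2 * L / 3
  if (!(s_mid >= 0 && s_mid < s_dist && s_dist <= L))
    stop("need 0 <= s_mid < s_dist <= total length", call. = FALSE)
  structure(list(points = unname(points), arclengths = arclengths,
                 s_mid = s_mid, s_dist = s_dist, length = L,
                 radius_r = radius_r),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length %.1f mm, s_mid %.1f, s_dist %.1f, r %.1f mm\n",
              nrow(x$points), x$length, x$s_mid, x$s_dist, x$radius_r))
  invisible(x)
}

#' Read a centerline from JSON or CSV
#'
#' JSON files must contain a `points_mm` array of `[x, y, z]` triplets
#' (optionally `s_mid`, `s_dist`, `radius_r`); CSV files must have three
#' numeric columns x, y, z in mm.
#'
#' @param path file path (`.json`, or anything else parsed as CSV).
#' @param ... passed to [centerline()] (e.g. `radius_r`).
#' @return A [centerline].
#' @export
read_centerline <- function(path, ...) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    pts <- matrix(as.numeric(as.matrix(obj$points_mm)), ncol = 3)
    args <- list(points = pts, ...)
    for (f in c("s_mid", "s_dist", "radius_r"))
      if (!is.null(obj[[f]]) && is.null(args[[f]])) args[[f]] <- obj[[f]]
    do.call(centerline, args)
  } else {
    df <- read.csv(path)
    if (ncol(df) < 3) stop("centerline CSV needs 3 columns (x, y, z mm)", call. = FALSE)
    centerline(as.matrix(df[, 1:3]), ...)
  }
}

#' Write a centerline as JSON
#' @param cl a [centerline].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_centerline <- function(cl, path) {
  jsonlite::write_json(
    list(points_mm = unname(apply(cl$points, 1, as.numeric, simplify = FALSE)),
         s_mid = cl$s_mid, s_dist = cl$s_dist, radius_r = cl$radius_r),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Minimum distance from each point to the polyline restricted to the
# arc-length window [s_lo, s_hi]. Exact point-to-segment distances on every
# (clipped) polyline segment.
centerline_distance <- function(points, cl, s_lo, s_hi) {
  points <- matrix(points, ncol = 3)
  n <- nrow(points)
  dmin <- rep(Inf, n)
  s <- cl$arclengths
  for (i in seq_len(nrow(cl$points) - 1)) {
    s0 <- s[i]; s1 <- s[i + 1]
    if (s1 <= s_lo || s0 >= s_hi) next
    if (s1 == s0) next  # zero-length segment contributes nothing new
    a <- cl$points[i, ]; b <- cl$points[i + 1, ]
    # clip the segment to the window
    f0 <- max(0, (s_lo - s0) / (s1 - s0))
    f1 <- min(1, (s_hi - s0) / (s1 - s0))
    p0 <- a + f0 * (b - a)
    p1 <- a + f1 * (b - a)
    v <- p1 - p0
    vv <- sum(v^2)
    w <- sweep(points, 2, p0)
    tpar <- if (vv > 0) pmin(1, pmax(0, (w %*% v)[, 1] / vv)) else rep(0, n)
    proj <- cbind(p0[1] + tpar * v[1], p0[2] + tpar * v[2], p0[3] + tpar * v[3])
    d <- sqrt(rowSums((points - proj)^2))
    dmin <- pmin(dmin, d)
  }
  dmin
}
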