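#' Run the full motion-disparity adhesion analysis
#'
#' The core fitting routine of the package. Given a nine-phase cardiac CT
#' series, the expert pericardial region mask on the 50% reference phase and
#' the LAD centerline, it:
#' \enumerate{
#'   \item registers every phase to the reference (diffeomorphic demons
#'     fallback or a user backend),
#'   \item segments EAT inside the pericardial region on the reference phase
#'     (HU threshold, connected components),
#'   \item transports EAT points and pericardial boundary (membrane) points
#'     through the phase mappings to build trajectories,
#'   \item forms inter-phase displacements (cyclic at the first phase),
#'     pairs each EAT point with its nearest pericardial point per phase,
#'     and takes displacement differences (the motion disparity),
#'   \item normalizes all disparity magnitudes by the study maximum,
#'   \item restricts attention to the cylindrical ROI around the centerline,
#'     accumulates per-phase totals and finds the optimal phase `t*`,
#'   \item bins the `t*` ROI disparities and computes the peak ratio (PR)
#'     and distribution width index (DWI), the adhesion classification and
#'     the phase-wise KS matrix.
#' }
#'
#' @param series a [phase_series].
#' @param peri_mask pericardial region [binary_mask] on the reference grid.
#' @param cl a [centerline] (world mm).
#' @param config an [adhesion_config].
#' @param backend registration backend (see [register_to_reference()]).
#' @param keep_fields keep displacement fields and trajectories in the
#'   returned object (large; default FALSE).
#' @param verbose print stage progress.
#' @param ... further arguments passed to [register_to_reference()].
#' @return An object of class `adhesion_scan`; see [print.adhesion_scan()],
#'   [summary.adhesion_scan()], [coef.adhesion_scan()],
#'   [plot.adhesion_scan()].
#' @export
adhesion_scan <- function(series, peri_mask, cl, config = adhesion_config(),
                          backend = "demons", keep_fields = FALSE,
                          verbose = FALSE, ...) {
  stopifnot(inherits(series, "phase_series"), inherits(peri_mask, "binary_mask"),
            inherits(cl, "centerline"), inherits(config, "adhesion_config"))
  set.seed(config$rng_seed)
  stage <- function(name, expr) {
    if (verbose) message("[", name, "]")
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  fields <- stage("registration",
                  register_to_reference(series, backend = backend,
                                        verbose = verbose, ...))
  seg <- stage("eat_segmentation",
               segment_eat(ref_volume(series), peri_mask, config))
  eat_pts <- mask_points(seg$mask)
  peri_pts <- mask_points(mask_boundary(peri_mask))
  traj_eat <- stage("trajectories",
                    build_trajectories(fields, eat_pts, "EAT"))
  traj_peri <- build_trajectories(fields, peri_pts, "pericardium")

  n_pairs <- nrow(eat_pts)
  magnitudes <- matrix(NA_real_, n_pairs, 9)
  rois <- vector("list", 9)
  stage("disparity", {
    for (k in 1:9) {
      d_eat <- displacement_at(traj_eat, k)
      d_peri <- displacement_at(traj_peri, k)
      eat_pos <- traj_eat$positions[, , k]
      peri_pos <- traj_peri$positions[, , k]
      corr <- correspond(eat_pos, peri_pos)
      magnitudes[, k] <- motion_disparity(d_eat, d_peri, corr)$magnitudes
      rois[[k]] <- select_roi(eat_pos, cl, window = config$roi_window)
    }
  })

  norm <- stage("normalization", normalize_study(magnitudes))
  pt <- stage("phase_totals", phase_totals(norm$normalized, rois))

  t_star <- pt$t_star
  samples <- norm$normalized[rois[[t_star]]$member_ids, t_star]
  h <- stage("histogram",
             disparity_histogram(samples, config$n_bins, config$alpha_percent))
  pr <- peak_ratio(h)
  dwi <- distribution_width_index(h)
  cls <- classify_adhesion(pr, dwi, config)

  roi_samples <- lapply(1:9, function(k) {
    ids <- rois[[k]]$member_ids
    if (length(ids) == 0) norm$normalized[, k] else norm$normalized[ids, k]
  })
  ks <- stage("ks_matrix", ks_matrix(roi_samples))

  out <- list(pr = pr, dwi = dwi, classification = cls,
              t_star = t_star, t_star_percent = pt$phase_percents[t_star],
              m_t = pt$m_t, d_max = norm$d_max,
              histogram = h, ks = ks,
              n_pairs = n_pairs,
              n_roi = vapply(rois, function(r) length(r$member_ids), integer(1)),
              components = seg$components,
              config = config)
  if (keep_fields) {
    out$fields <- fields
    out$trajectories <- list(eat = traj_eat, pericardium = traj_peri)
    out$normalized <- norm$normalized
    out$rois <- rois
  }
  structure(out, class = "adhesion_scan")
}

#' @export
print.adhesion_scan <- function(x, ...) {
  cat("Pericardial adhesion motion-disparity analysis\n")
  cat(sprintf("  EAT points: %d; ROI members at t*: %d\n",
              x$n_pairs, x$n_roi[x$t_star]))
  cat(sprintf("  optimal phase t*: %d%% (M_t = %.1f)\n",
              x$t_star_percent, x$m_t[x$t_star]))
  cat(sprintf("  peak ratio (PR):               %.2f\n", x$pr))
  cat(sprintf("  distribution width index (DWI): %.3f\n", x$dwi))
  cat(sprintf("  classification: %s\n", x$classification))
  invisible(x)
}

#' @describeIn adhesion_scan PR and DWI as a named vector.
#' @param object,x an `adhesion_scan`.
#' @export
coef.adhesion_scan <- function(object, ...) {
  c(PR = object$pr, DWI = object$dwi)
}

#' @export
summary.adhesion_scan <- function(object, ...) {
  structure(list(scan = object), class = "summary.adhesion_scan")
}

#' @export
print.summary.adhesion_scan <- function(x, ...) {
  s <- x$scan
  print(s)
  cat(sprintf("  study maximum disparity D_max: %.2f mm\n", s$d_max))
  cat("  per-phase totals M_t:\n")
  v <- sprintf("%.1f", s$m_t)
  names(v) <- paste0(seq(10, 90, 10), "%")
  print(v, quote = FALSE)
  cat("  ROI members per phase:\n")
  names(s$n_roi) <- paste0(seq(10, 90, 10), "%")
  print(s$n_roi)
  cat(sprintf("  histogram: %d bins, Hmax %d, H_alpha %d, nonzero %d\n",
              s$histogram$n_total, s$histogram$h_max, s$histogram$h_alpha,
              s$histogram$n_nonzero))
  cat(sprintf("  EAT components: %d (largest %d voxels)\n",
              nrow(s$components), s$components$n_voxels[1]))
  invisible(x)
}

#' Plot an adhesion scan
#'
#' `type = "histogram"` draws the optimal-phase disparity frequency curve
#' (x: normalized motion difference 0--1, y: frequency), `type = "ks"` the
#' phase-by-phase KS statistic heatmap, `type = "phases"` the per-phase
#' disparity totals `M_t` with `t*` highlighted.
#'
#' @param x an `adhesion_scan`.
#' @param type plot type.
#' @param ... passed to the underlying base graphics call.
#' @export
plot.adhesion_scan <- function(x, type = c("histogram", "ks", "phases"), ...) {
  type <- match.arg(type)
  if (type == "histogram") {
    h <- x$histogram
    mids <- (h$edges[-1] + h$edges[-length(h$edges)]) / 2
    plot(mids, h$counts, type = "l", col = "firebrick", lwd = 2,
         xlab = "normalized motion difference", ylab = "frequency",
         main = sprintf("Disparity distribution at t* = %d%% (%s)",
                        x$t_star_percent, x$classification), ...)
  } else if (type == "ks") {
    plot(x$ks, ...)
  } else {
    bp <- barplot(x$m_t, names.arg = paste0(seq(10, 90, 10), "%"),
                  xlab = "cardiac phase", ylab = expression(M[t]),
                  col = ifelse(seq_len(9) == x$t_star, "firebrick", "grey70"),
                  main = "Total motion disparity per phase", ...)
    mtext(sprintf("t* = %d%%", x$t_star_percent), side = 3, line = 0)
  }
  invisible(x)
}

#' Plot a KS matrix as a heatmap
#' @param x a [ks_matrix()] result.
#' @param ... passed to [graphics::image].
#' @export
plot.ks_matrix <- function(x, ...) {
  n <- nrow(x$d)
  image(1:n, 1:n, t(x$d[n:1, ]), axes = FALSE, xlab = "phase", ylab = "phase",
        col = hcl.colors(64, "YlOrRd", rev = TRUE),
        main = "Phase-pairwise KS statistics", ...)
  axis(1, at = 1:n, labels = x$phase_labels)
  axis(2, at = 1:n, labels = rev(x$phase_labels))
  invisible(x)
}

#' Distribution-level adhesion metrics
#'
#' Computes the peak ratio, distribution width index and classification
#' directly from normalized disparity samples (e.g. an external per-case
#' sample file, or the output of [generate_disparity_samples()]), without
#' the imaging pipeline.
#'
#' @param samples normalized disparity values in \[0, 1\].
#' @param config an [adhesion_config].
#' @return An object of class `adhesion_metrics`: `pr`, `dwi`,
#'   `classification`, `histogram`.
#' @export
adhesion_metrics <- function(samples, config = adhesion_config()) {
  h <- disparity_histogram(samples, config$n_bins, config$alpha_percent)
  pr <- peak_ratio(h)
  dwi <- distribution_width_index(h)
  structure(list(pr = pr, dwi = dwi,
                 classification = classify_adhesion(pr, dwi, config),
                 histogram = h, config = config),
            class = "adhesion_metrics")
}

#' @export
print.adhesion_metrics <- function(x, ...) {
  cat(sprintf("<adhesion_metrics> PR %.2f, DWI %.3f -> %s (n = %d)\n",
              x$pr, x$dwi, x$classification, x$histogram$n_samples))
  invisible(x)
}

#' @export
plot.adhesion_metrics <- function(x, ...) {
  h <- x$histogram
  mids <- (h$edges[-1] + h$edges[-length(h$edges)]) / 2
  plot(mids, h$counts, type = "l", lwd = 2,
       col = if (x$classification == "adhesion") "firebrick" else "steelblue",
       xlab = "normalized motion difference", ylab = "frequency",
       main = sprintf("PR %.1f, DWI %.2f (%s)", x$pr, x$dwi,
                      x$classification), ...)
  invisible(x)
}

#' Per-case metrics and group test over a cohort
#'
#' Applies [adhesion_metrics()] to each case of a [generate_cohort()]-style
#' list and tests PR and DWI between the true-label groups with the exact
#' Mann-Whitney U test.
#'
#' @param cohort list of cases with `samples` and `label` elements.
#' @param config an [adhesion_config].
#' @return list with `cases` (data.frame: case_id, label, pr, dwi,
#'   classification) and `group_p` (named vector: p-values for PR and DWI).
#' @export
cohort_metrics <- function(cohort, config = adhesion_config()) {
  rows <- lapply(cohort, function(cs) {
    m <- adhesion_metrics(cs$samples, config)
    data.frame(case_id = cs$case_id, label = cs$label, pr = m$pr,
               dwi = m$dwi, classification = m$classification)
  })
  cases <- do.call(rbind, rows)
  a <- cases$label == "adhesion"
  group_p <- c(PR = NA_real_, DWI = NA_real_)
  if (sum(a) >= 2 && sum(!a) >= 2) {
    group_p["PR"] <- adhesion_group_test(cases$pr[a], cases$pr[!a])$p_value
    group_p["DWI"] <- adhesion_group_test(cases$dwi[a], cases$dwi[!a])$p_value
  }
  list(cases = cases, group_p = group_p)
}
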