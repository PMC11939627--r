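#' Analysis configuration
#'
#' Tunable parameters of the motion-disparity pipeline with the defaults used
#' throughout: the adipose HU window \[-190, -30\], 100 histogram bins on
#' \[0, 1\], the 25th-position bin for the peak-ratio denominator, and the
#' published classification cut-offs (adhesion: PR > 100 and DWI < 0.3;
#' non-adhesion: PR < 50 and DWI > 0.4; anything else indeterminate).
#'
#' @param hu_low,hu_high inclusive HU thresholds for EAT segmentation.
#' @param n_bins histogram bin count (>= 10).
#' @param alpha_percent percentile-position parameter for the peak ratio
#'   denominator bin, in (0, 100).
#' @param pr_adhesion_threshold PR above which (with low DWI) a case is
#'   called adhesion.
#' @param pr_nonadhesion_threshold PR below which (with high DWI) a case is
#'   called non-adhesion.
#' @param dwi_adhesion_threshold DWI below which (with high PR) a case is
#'   called adhesion.
#' @param dwi_nonadhesion_threshold DWI above which (with low PR) a case is
#'   called non-adhesion.
#' @param roi_window `"mid_to_end"` (default) restricts the cylindrical ROI to
#'   arc lengths `[s_mid, L]`; `"mid_to_dist"` uses `[s_mid, s_dist]`.
#' @param connectivity voxel connectivity for EAT components (26 or 6).
#' @param rng_seed integer seed used wherever the pipeline draws random
#'   numbers.
#' @return An object of class `adhesion_config`.
#' @export
adhesion_config <- function(hu_low = -190, hu_high = -30,
                            n_bins = 100, alpha_percent = 25,
                            pr_adhesion_threshold = 100,
                            pr_nonadhesion_threshold = 50,
                            dwi_adhesion_threshold = 0.3,
                            dwi_nonadhesion_threshold = 0.4,
                            roi_window = c("mid_to_end", "mid_to_dist"),
                            connectivity = 26,
                            rng_seed = 1L) {
  roi_window <- match.arg(roi_window)
  stopifnot(hu_low < hu_high, n_bins >= 10,
            alpha_percent > 0, alpha_percent < 100,
            connectivity %in% c(6, 26))
  structure(list(hu_low = hu_low, hu_high = hu_high, n_bins = as.integer(n_bins),
                 alpha_percent = alpha_percent,
                 pr_adhesion_threshold = pr_adhesion_threshold,
                 pr_nonadhesion_threshold = pr_nonadhesion_threshold,
                 dwi_adhesion_threshold = dwi_adhesion_threshold,
                 dwi_nonadhesion_threshold = dwi_nonadhesion_threshold,
                 roi_window = roi_window,
                 connectivity = as.integer(connectivity),
                 rng_seed = as.integer(rng_seed)),
            class = "adhesion_config")
}

#' @export
print.adhesion_config <- function(x, ...) {
  cat("<adhesion_config>\n")
  cat(sprintf("  EAT HU window: [%g, %g]\n", x$hu_low, x$hu_high))
  cat(sprintf("  histogram: %d bins on [0,1], alpha = %g\n", x$n_bins, x$alpha_percent))
  cat(sprintf("  classify: adhesion PR>%g & DWI<%g; non-adhesion PR<%g & DWI>%g\n",
              x$pr_adhesion_threshold, x$dwi_adhesion_threshold,
              x$pr_nonadhesion_threshold, x$dwi_nonadhesion_threshold))
  cat(sprintf("  ROI window: %s; connectivity %d; seed %d\n",
              x$roi_window, x$connectivity, x$rng_seed))
  invisible(x)
}

#' Read an analysis configuration from JSON or YAML
#'
#' Fields mirror the arguments of [adhesion_config()]; missing fields keep
#' their defaults.
#'
#' @param path a `.json` (or `.yaml`/`.yml`, requires the yaml package) file.
#' @return An [adhesion_config].
#' @export
read_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  keep <- intersect(names(obj), names(formals(adhesion_config)))
  do.call(adhesion_config, obj[keep])
}
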