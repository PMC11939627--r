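#' Histogram of normalized motion disparities
#'
#' Equal-width bins on \[0, 1\]: bin `b` covers `[(b-1)/n, b/n)` with the
#' last bin right-inclusive, so the counts always conserve the sample count.
#' Alongside the counts the object records the quantities entering the peak
#' ratio and distribution width index: the maximum count `h_max`, the count
#' `h_alpha` of the bin at fractional position `alpha_percent` along the bin
#' axis (the bin covering the normalized value `alpha/100`), the number of
#' nonzero bins `n_nonzero` and the total bin count `n_total`.
#'
#' @param samples normalized disparity values in \[0, 1\].
#' @param n_bins number of bins (default 100).
#' @param alpha_percent position parameter in (0, 100) (default 25).
#' @return An object of class `disparity_histogram`.
#' @export
disparity_histogram <- function(samples, n_bins = 100, alpha_percent = 25) {
  samples <- as.numeric(samples)
  if (length(samples) == 0)
    stop("empty histogram: no samples", call. = FALSE)
  if (any(!is.finite(samples)) || any(samples < 0 | samples > 1))
    stop("samples must lie in [0, 1]", call. = FALSE)
  n_bins <- as.integer(n_bins)
  bin <- pmin(floor(samples * n_bins) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  alpha_idx <- floor(alpha_percent / 100 * n_bins) + 1L
  structure(list(edges = seq(0, 1, length.out = n_bins + 1L),
                 counts = counts,
                 h_max = max(counts),
                 h_alpha = counts[alpha_idx],
                 alpha_index = alpha_idx,
                 alpha_percent = alpha_percent,
                 n_nonzero = sum(counts > 0),
                 n_total = n_bins,
                 n_samples = length(samples)),
            class = "disparity_histogram")
}

#' @export
print.disparity_histogram <- function(x, ...) {
  cat(sprintf("<disparity_histogram> %d samples in %d bins; Hmax %d, H_alpha(%g) %d, nonzero bins %d\n",
              x$n_samples, x$n_total, x$h_max, x$alpha_percent, x$h_alpha,
              x$n_nonzero))
  invisible(x)
}

#' Peak ratio of a disparity histogram
#'
#' `PR = Hmax / H_alpha`, where `Hmax` is the maximum bin count and
#' `H_alpha` the count at the alpha-position bin. A zero `H_alpha` (sharply
#' decayed histograms) is guarded by substituting a count of 1, so the
#' statistic stays finite; the raw zero remains visible in the histogram
#' object.
#'
#' @param h a [disparity_histogram].
#' @return The peak ratio (scalar, > 0).
#' @export
peak_ratio <- function(h) {
  stopifnot(inherits(h, "disparity_histogram"))
  h$h_max / max(h$h_alpha, 1)
}

#' Distribution width index of a disparity histogram
#'
#' `DWI = Nnonzero / Ntotal`: the fraction of occupied bins. Concentrated
#' (adhesion-like) distributions occupy few bins and give a low DWI; broad
#' (non-adhesion) distributions occupy many.
#'
#' @param h a [disparity_histogram].
#' @return The DWI in (0, 1].
#' @export
distribution_width_index <- function(h) {
  stopifnot(inherits(h, "disparity_histogram"))
  h$n_nonzero / h$n_total
}

#' Kolmogorov-Smirnov matrix across cardiac phases
#'
#' Pairwise two-sample KS statistics `D_ij = sup_x |F_i(x) - F_j(x)|`
#' between the empirical distributions of motion-disparity magnitudes at
#' phases i and j (statistic only; no p-values enter the matrix). The
#' matrix is symmetric with a zero diagonal and entries in \[0, 1\];
#' adjacent cardiac phases are expected to show small statistics.
#'
#' @param per_phase_samples list of 9 numeric vectors of magnitudes.
#' @return An object of class `ks_matrix`: `d` (9 x 9), `phase_labels`.
#' @export
ks_matrix <- function(per_phase_samples) {
  stopifnot(length(per_phase_samples) == 9L)
  if (any(vapply(per_phase_samples, length, integer(1)) == 0L))
    stop("insufficient samples: every phase needs at least one value", call. = FALSE)
  d <- matrix(0, 9, 9)
  for (i in 1:8) for (j in (i + 1):9) {
    stat <- suppressWarnings(
      ks.test(per_phase_samples[[i]], per_phase_samples[[j]])$statistic)
    d[i, j] <- d[j, i] <- unname(stat)
  }
  labels <- paste0(seq(10, 90, 10), "%")
  dimnames(d) <- list(labels, labels)
  structure(list(d = d, phase_labels = labels), class = "ks_matrix")
}

#' @export
print.ks_matrix <- function(x, ...) {
  cat("<ks_matrix> pairwise two-sample KS statistics across phases\n")
  print(round(x$d, 3))
  invisible(x)
}

#' Classify adhesion status from PR and DWI
#'
#' Adhesion: `PR > 100` and `DWI < 0.3`. Non-adhesion: `PR < 50` and
#' `DWI > 0.4`. Anything between is indeterminate. Cut-offs come from the
#' supplied configuration.
#'
#' @param pr peak ratio.
#' @param dwi distribution width index.
#' @param config an [adhesion_config].
#' @return `"adhesion"`, `"non-adhesion"` or `"indeterminate"`.
#' @export
classify_adhesion <- function(pr, dwi, config = adhesion_config()) {
  stopifnot(is.finite(pr), is.finite(dwi))
  if (pr > config$pr_adhesion_threshold && dwi < config$dwi_adhesion_threshold)
    "adhesion"
  else if (pr < config$pr_nonadhesion_threshold &&
           dwi > config$dwi_nonadhesion_threshold)
    "non-adhesion"
  else
    "indeterminate"
}

#' Exact two-sided Mann-Whitney U test between two groups
#'
#' Compares a per-case metric (PR or DWI) between cohorts. With no ties the
#' exact distribution from [stats::wilcox.test] is used; with ties and a
#' combined size of at most 25 the exact two-sided p-value is obtained by
#' full enumeration of group assignments; larger tied samples fall back to
#' the normal approximation with continuity correction. Degenerate all-tied
#' input returns p = 1 with a warning.
#'
#' @param group_a,group_b numeric vectors of per-case metric values
#'   (each of length >= 2).
#' @return list with `p_value`, `statistic` (U for group_a), `method`.
#' @export
adhesion_group_test <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (length(unique(c(group_a, group_b))) == 1L) {
    warning("degenerate input: all values tied; p = 1")
    return(list(p_value = 1, statistic = length(group_a) * length(group_b) / 2,
                method = "degenerate"))
  }
  ties <- any(duplicated(c(group_a, group_b)))
  n <- length(group_a) + length(group_b)
  u_stat <- function(a, b) {
    r <- rank(c(a, b))
    sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  }
  U <- u_stat(group_a, group_b)
  if (!ties) {
    wt <- wilcox.test(group_a, group_b, exact = TRUE, correct = FALSE)
    return(list(p_value = wt$p.value, statistic = unname(wt$statistic),
                method = "exact (distribution)"))
  }
  if (n <= 25) {
    pooled <- c(group_a, group_b)
    na <- length(group_a)
    combos <- utils::combn(n, na)
    mu <- na * (n - na) / 2
    obs_dev <- abs(U - mu)
    stats <- apply(combos, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
    p <- mean(abs(stats - mu) >= obs_dev - 1e-9)
    return(list(p_value = p, statistic = U, method = "exact (enumeration)"))
  }
  wt <- suppressWarnings(wilcox.test(group_a, group_b, exact = FALSE,
                                     correct = TRUE))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       method = "normal approximation")
}
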