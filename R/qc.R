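#' Drop sex-chromosome markers from a map and logR matrix
#'
#' Removes every marker whose chromosome label is X or Y (any case, with or
#' without a "chr" prefix), preserving autosome order. The operation is
#' idempotent and a no-op when no sex chromosome is present.
#'
#' @param map marker map data.frame (`chromosome`, `position`, ...).
#' @param logr optional markers x samples matrix aligned to `map`.
#' @return a list with the filtered `map` and `logr` (NULL if not supplied).
#' @export
exclude_sex_chromosomes <- function(map, logr = NULL) {
  chr <- toupper(norm_chrom(map$chromosome))
  keep <- !(chr %in% c("X", "Y"))
  if (!any(keep)) {
    warning("all markers are on sex chromosomes; result is empty")
  }
  list(map = map[keep, , drop = FALSE],
       logr = if (is.null(logr)) NULL else logr[keep, , drop = FALSE])
}

#' Derivative log ratio spread (dLRs)
#'
#' The per-sample noise metric based on adjacent-probe differences:
#' `median(|logR[i+1] - logR[i]|) / sqrt(2)`, with differences taken only
#' within chromosomes. Division by sqrt(2) converts the spread of a
#' difference of two independent noise terms back to per-probe scale, so
#' for iid Gaussian noise dLRs estimates 0.6745 * sd.
#'
#' @param x numeric logR vector (may contain NA, which are dropped).
#' @param chromosome optional chromosome label per marker; when supplied,
#'   differences never straddle a chromosome boundary.
#' @return a list with `median_abs_derivative` and `dlrs`.
#' @export
dlrs <- function(x, chromosome = NULL) {
  if (is.null(chromosome)) chromosome <- rep("1", length(x))
  diffs <- unlist(lapply(split(x, chromosome), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) numeric(0) else abs(diff(v))
  }), use.names = FALSE)
  if (length(diffs) == 0) {
    stop("no within-chromosome adjacent pairs to difference", call. = FALSE)
  }
  mad_deriv <- median(diffs)
  list(median_abs_derivative = mad_deriv, dlrs = mad_deriv / sqrt(2))
}

#' Flag noisy samples by the Tukey rule
#'
#' A sample is an outlier when its dLRs exceeds Q3 + k * IQR of the cohort.
#' With fewer than 4 samples the quartiles are too unstable to trust, so
#' nothing is flagged and a warning is emitted.
#'
#' @param dlrs_values numeric vector of per-sample dLRs.
#' @param k Tukey multiplier (default 1.5).
#' @return logical vector, TRUE for flagged samples.
#' @export
flag_noise_outliers <- function(dlrs_values, k = 1.5) {
  if (length(dlrs_values) < 4) {
    warning("fewer than 4 samples; no noise outliers flagged")
    return(rep(FALSE, length(dlrs_values)))
  }
  q <- quantile(dlrs_values, c(0.25, 0.75), names = FALSE)
  dlrs_values > q[2] + k * (q[2] - q[1])
}

#' Genomic-wave metric
#'
#' Screens a track for long-range waves by correlating per-window median
#' logR with a per-window covariate (true GC content if available, or the
#' simulator's wave covariate). Windows are fixed-width bp bins within each
#' chromosome. Returns the absolute Pearson correlation; by convention 0
#' when either side has zero variance, and NA with fewer than 3 windows.
#'
#' @param x logR vector.
#' @param map marker map aligned to `x`.
#' @param covariate per-marker covariate (same length as `x`).
#' @param window_bp window width in basepairs.
#' @return a single non-negative number (or NA).
#' @export
wave_metric <- function(x, map, covariate, window_bp = 1e6) {
  stopifnot(window_bp > 0, length(x) == nrow(map),
            length(covariate) == length(x))
  win <- paste(map$chromosome, floor(map$position / window_bp))
  med_x <- tapply(x, win, median, na.rm = TRUE)
  med_c <- tapply(covariate, win, median, na.rm = TRUE)
  if (length(med_x) < 3) return(NA_real_)
  if (sd(med_x) == 0 || sd(med_c) == 0) return(0)
  abs(cor(med_x, med_c))
}

#' PCA batch check with silhouette scores
#'
#' Principal component analysis of the marker-centered logR matrix
#' (samples as observations), plus the mean silhouette coefficient of each
#' provided sample labeling computed on the PC1-PC2 plane. Visual PCA
#' inspection for batch structure is thereby reduced to one number per
#' labeling: near 0 means no clustering by that factor.
#'
#' @param logr markers x samples matrix.
#' @param labelings named list of per-sample label vectors (e.g. time
#'   point, subject).
#' @param k number of principal components to keep; truncated to the rank
#'   bound `min(n_samples - 1, n_markers)`.
#' @return a list with `scores` (samples x k), `variance_explained`, and
#'   `silhouette` (named numeric, NA for labelings with < 2 groups).
#' @export
pca_batch_check <- function(logr, labelings = list(), k = 2) {
  n <- ncol(logr)
  if (n < 3) stop("need >= 3 samples for a PCA batch check", call. = FALSE)
  if (all(apply(logr, 1, var) == 0)) {
    stop("logR matrix is constant; PCA undefined", call. = FALSE)
  }
  k <- min(k, n - 1, nrow(logr))
  pr <- prcomp(t(logr), center = TRUE, scale. = FALSE)
  scores <- pr$x[, seq_len(k), drop = FALSE]
  ve <- (pr$sdev^2 / sum(pr$sdev^2))[seq_len(k)]
  plane <- scores[, seq_len(min(2, k)), drop = FALSE]
  sil <- vapply(labelings, function(lab) {
    f <- as.integer(factor(lab))
    if (length(unique(f)) < 2 || length(unique(f)) >= n) return(NA_real_)
    mean(silhouette(f, dist(plane))[, "sil_width"])
  }, numeric(1))
  list(scores = scores, variance_explained = ve, silhouette = sil)
}

#' Assemble a per-sample QC report
#'
#' Computes the derivative log ratio spread, wave metric and Tukey outlier
#' flag for every sample of a logR matrix.
#'
#' @param logr markers x samples matrix.
#' @param map marker map aligned to rows.
#' @param covariate optional per-marker wave covariate; when NULL the wave
#'   metric is NA.
#' @param window_bp wave-metric window width.
#' @param tukey_k Tukey rule multiplier for outlier flagging.
#' @return data.frame with one row per sample: `sample_id`,
#'   `median_abs_derivative`, `dlrs`, `wave_metric`, `is_outlier`.
#' @export
qc_report <- function(logr, map, covariate = NULL, window_bp = 1e6,
                      tukey_k = 1.5) {
  d <- apply(logr, 2, function(x) unlist(dlrs(x, map$chromosome)))
  wm <- if (is.null(covariate)) {
    rep(NA_real_, ncol(logr))
  } else {
    apply(logr, 2, wave_metric, map = map, covariate = covariate,
          window_bp = window_bp)
  }
  data.frame(sample_id = colnames(logr),
             median_abs_derivative = d["median_abs_derivative", ],
             dlrs = d["dlrs", ],
             wave_metric = wm,
             is_outlier = flag_noise_outliers(d["dlrs", ], k = tukey_k),
             row.names = NULL, stringsAsFactors = FALSE)
}
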