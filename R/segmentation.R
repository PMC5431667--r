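#' Segmentation parameters
#'
#' The calling criteria: a maximum pairwise segment p-value of 0.005, at
#' least 2 markers per segment, outlier removal on, and segment means
#' filtered at -0.35 / +0.35 logR units for losses / gains.
#'
#' @param max_pairwise_p maximum p-value allowed between adjacent segments
#'   (also the split acceptance level), in (0, 1).
#' @param min_markers minimum markers per segment and per CNV call.
#' @param loss_threshold,gain_threshold segment-mean cutoffs defining loss
#'   and gain calls.
#' @param outlier_removal mask single-marker spikes before segmenting?
#' @param outlier_mad_k spike threshold in running-MAD units.
#' @return an object of class `seg_params`.
#' @export
seg_params <- function(max_pairwise_p = 0.005, min_markers = 2,
                       loss_threshold = -0.35, gain_threshold = 0.35,
                       outlier_removal = TRUE, outlier_mad_k = 3) {
  if (max_pairwise_p <= 0 || max_pairwise_p >= 1)
    stop("max_pairwise_p must be in (0, 1)", call. = FALSE)
  if (min_markers < 1) stop("min_markers must be >= 1", call. = FALSE)
  if (loss_threshold >= 0 || gain_threshold <= 0)
    stop("loss_threshold must be < 0 < gain_threshold", call. = FALSE)
  structure(list(max_pairwise_p = max_pairwise_p,
                 min_markers = as.integer(min_markers),
                 loss_threshold = loss_threshold,
                 gain_threshold = gain_threshold,
                 outlier_removal = isTRUE(outlier_removal),
                 outlier_mad_k = outlier_mad_k),
            class = "seg_params")
}

# Welch two-sided p-value from summary statistics; exact-equality shortcut
# when both groups are constant.
welch_p_stats <- function(n1, m1, v1, n2, m2, v2) {
  if (n1 < 1 || n2 < 1) return(1)
  if (v1 == 0 && v2 == 0) {
    return(if (isTRUE(all.equal(m1, m2))) 1 else 0)
  }
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / max(n1 - 1, 1) + (v2 / n2)^2 / max(n2 - 1, 1))
  2 * pt(-abs(tstat), df)
}

#' Welch t-test p-value between two marker groups
#'
#' The pairwise segment criterion: a two-sided unequal-variance t-test,
#' with an exact-equality shortcut for zero-variance inputs (p = 1 when
#' both groups are constant with equal means, 0 when constant but unequal).
#'
#' @param x,y numeric vectors.
#' @return p-value in \[0, 1\].
#' @export
welch_p <- function(x, y) {
  welch_p_stats(length(x), mean(x), if (length(x) > 1) var(x) else 0,
                length(y), mean(y), if (length(y) > 1) var(y) else 0)
}

# Pooled-variance two-sided t p-value (used for split discovery, where the
# inside window's own variance is biased low by selection).
pooled_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  ss <- sum((x - m1)^2) + sum((y - m2)^2)
  df <- n1 + n2 - 2
  if (ss == 0 || df <= 0) {
    return(if (isTRUE(all.equal(m1, m2))) 1 else 0)
  }
  tstat <- (m1 - m2) / sqrt(ss / df * (1 / n1 + 1 / n2))
  2 * pt(-abs(tstat), df)
}

#' Mask single-marker outliers
#'
#' A marker is masked when it deviates from the running median (window 5)
#' by more than `outlier_mad_k` running MADs while neither neighbor lies on
#' its side of the running median — i.e. an isolated spike, not the edge of
#' a genuine shift. Masked markers are excluded from segment statistics but
#' remain in the coordinate system. An epsilon floor keeps a zero MAD (flat
#' regions) from masking everything or nothing spuriously.
#'
#' @param x logR vector of one chromosome.
#' @param params a [seg_params()].
#' @return logical mask, TRUE for outlier markers.
#' @export
remove_outliers <- function(x, params = seg_params()) {
  n <- length(x)
  mask <- rep(FALSE, n)
  if (!params$outlier_removal || n < 3) return(mask)
  med <- if (n >= 5) runmed(x, 5, endrule = "median") else rep(median(x), n)
  dev <- x - med
  rmad <- if (n >= 5) runmed(abs(dev), 5, endrule = "median") * 1.4826
          else rep(mad(x), n)
  rmad <- pmax(rmad, 1e-6)
  for (i in 2:(n - 1)) {
    if (abs(dev[i]) <= params$outlier_mad_k * rmad[i]) next
    side <- sign(dev[i])
    left_same <- sign(x[i - 1] - med[i]) == side && abs(x[i - 1] - med[i]) > 1e-12
    right_same <- sign(x[i + 1] - med[i]) == side && abs(x[i + 1] - med[i]) > 1e-12
    if (!left_same && !right_same) mask[i] <- TRUE
  }
  mask
}

# Best inside-window [i..j] by total within SSE (inside + outside), with
# flank-size constraints. Returns the window and the number of candidates.
best_window <- function(x, minm) {
  n <- length(x)
  if (n < 2 * minm) return(NULL)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  best <- NULL; best_sse <- Inf; n_win <- 0L
  for (i in seq_len(n - minm + 1)) {
    js <- (i + minm - 1):n
    nin <- js - i + 1
    ok <- (i == 1 | i - 1 >= minm) & (js == n | n - js >= minm) & nin < n
    js <- js[ok]
    if (length(js) == 0) next
    nin <- js - i + 1
    nout <- n - nin
    n_win <- n_win + length(js)
    s_in <- cs[js + 1] - cs[i]
    s2_in <- cs2[js + 1] - cs2[i]
    sse_in <- s2_in - s_in^2 / nin
    s_out <- cs[n + 1] - s_in
    s2_out <- cs2[n + 1] - s2_in
    sse_out <- s2_out - s_out^2 / nout
    tot <- sse_in + sse_out
    kk <- which.min(tot)
    if (tot[kk] < best_sse) {
      best_sse <- tot[kk]
      best <- c(i, js[kk])
    }
  }
  if (is.null(best)) NULL else list(window = best, n_candidates = n_win)
}

# Recursive CBS-style segmentation of a clean (unmasked) vector. Returns a
# 2-column matrix of [start, end] condensed indices partitioning 1..n.
segment_clean <- function(x, params) {
  n <- length(x)
  segs <- list()
  recurse <- function(lo, hi) {
    len <- hi - lo + 1
    if (len >= 2 * params$min_markers) {
      bw <- best_window(x[lo:hi], params$min_markers)
      if (!is.null(bw)) {
        i <- bw$window[1] + lo - 1
        j <- bw$window[2] + lo - 1
        inside <- x[i:j]
        outside <- c(if (i > lo) x[lo:(i - 1)], if (j < hi) x[(j + 1):hi])
        # Bonferroni over the candidate windows scanned: the split decision
        # tests the best of many windows, so the raw p is calibrated by the
        # number of candidates before comparing with max_pairwise_p.
        p <- min(1, pooled_p(inside, outside) * bw$n_candidates)
        if (p <= params$max_pairwise_p) {
          if (i > lo) recurse(lo, i - 1)
          if (i == lo && j == hi) {
            segs[[length(segs) + 1]] <<- c(i, j)
          } else {
            recurse(i, j)
          }
          if (j < hi) recurse(j + 1, hi)
          return(invisible())
        }
      }
    }
    segs[[length(segs) + 1]] <<- c(lo, hi)
  }
  recurse(1, n)
  m <- do.call(rbind, segs)
  m[order(m[, 1]), , drop = FALSE]
}

# Merge adjacent segments whose pairwise Welch p exceeds max_pairwise_p,
# most non-significant pair first, iterated to a fixed point.
prune_segments <- function(x, m, params) {
  repeat {
    if (nrow(m) < 2) break
    ps <- vapply(seq_len(nrow(m) - 1), function(r) {
      welch_p(x[m[r, 1]:m[r, 2]], x[m[r + 1, 1]:m[r + 1, 2]])
    }, numeric(1))
    k <- which.max(ps)
    if (ps[k] <= params$max_pairwise_p) break
    m[k, 2] <- m[k + 1, 2]
    m <- m[-(k + 1), , drop = FALSE]
  }
  m
}

#' Segment one chromosome of logR values
#'
#' Recursively searches for the marker window most distinct from its
#' neighborhood (minimum total within-segment sum of squares over all
#' candidate inside/outside splits), accepts a split only when the
#' multiplicity-corrected pooled t-test clears `max_pairwise_p` and all
#' resulting segments have at least `min_markers` markers, then merges
#' adjacent segments whose pairwise Welch p-value exceeds `max_pairwise_p`,
#' iterating to a fixed point. The output partitions the chromosome; masked
#' markers are excluded from all statistics but spanned by the containing
#' segment's coordinates.
#'
#' @param x logR vector of one chromosome, in map order.
#' @param params a [seg_params()].
#' @param mask optional logical vector of markers to exclude (e.g. from
#'   [remove_outliers()]); NA values in `x` are masked automatically.
#' @return data.frame with `start_index`, `end_index` (1-based, inclusive,
#'   within the chromosome), `n_markers`, `n_informative` (unmasked),
#'   `mean_logr`, `within_sse`.
#' @export
segment_chromosome <- function(x, params = seg_params(), mask = NULL) {
  n <- length(x)
  if (is.null(mask)) mask <- rep(FALSE, n)
  mask <- mask | is.na(x)
  idx <- which(!mask)
  if (length(idx) == 0) {
    return(data.frame(start_index = 1L, end_index = n, n_markers = n,
                      n_informative = 0L, mean_logr = NA_real_,
                      within_sse = NA_real_))
  }
  y <- x[idx]
  m <- if (length(y) < 2 * params$min_markers) {
    matrix(c(1L, length(y)), nrow = 1)
  } else {
    prune_segments(y, segment_clean(y, params), params)
  }
  k <- nrow(m)
  start_full <- integer(k); end_full <- integer(k)
  for (r in seq_len(k)) {
    start_full[r] <- if (r == 1) 1L else end_full[r - 1] + 1L
    end_full[r] <- if (r == k) n else idx[m[r, 2]]
  }
  data.frame(
    start_index = start_full,
    end_index = end_full,
    n_markers = end_full - start_full + 1L,
    n_informative = m[, 2] - m[, 1] + 1L,
    mean_logr = vapply(seq_len(k), function(r) mean(y[m[r, 1]:m[r, 2]]),
                       numeric(1)),
    within_sse = vapply(seq_len(k), function(r) {
      v <- y[m[r, 1]:m[r, 2]]; sum((v - mean(v))^2)
    }, numeric(1)))
}

#' Segment a whole track
#'
#' Applies [remove_outliers()] (when enabled) and [segment_chromosome()]
#' chromosome by chromosome.
#'
#' @param x logR vector aligned to `map`.
#' @param map marker map data.frame.
#' @param params a [seg_params()].
#' @return data.frame of segments with a `chromosome` column; indices are
#'   per-chromosome marker indices.
#' @export
segment_track <- function(x, map, params = seg_params()) {
  out <- lapply(unique(map$chromosome), function(chr) {
    sel <- map$chromosome == chr
    v <- x[sel]
    mask <- remove_outliers(v, params)
    seg <- segment_chromosome(v, params, mask)
    seg$chromosome <- chr
    seg
  })
  res <- do.call(rbind, out)
  res[, c("chromosome", "start_index", "end_index", "n_markers",
          "n_informative", "mean_logr", "within_sse")]
}

#' Call CNVs from segments
#'
#' Segments whose mean logR is below `loss_threshold` or above
#' `gain_threshold` and that contain at least `min_markers` markers become
#' CNV calls. Coordinates are half-open: `start_bp` is the position of the
#' first marker and `end_bp` the position of the last marker + 1, so length
#' is `end_bp - start_bp`.
#'
#' @param segments output of [segment_track()].
#' @param map the marker map the segments refer to.
#' @param params a [seg_params()].
#' @param sample_id,subject_id,time_point labels attached to each call.
#' @param id_prefix prefix for the `cnv_id` assigned in genome order.
#' @return data.frame of calls: `cnv_id`, `sample_id`, `subject_id`,
#'   `time_point`, `chromosome`, `start_bp`, `end_bp`, `n_markers`,
#'   `mean_logr`, `state`.
#' @export
call_cnvs <- function(segments, map, params = seg_params(),
                      sample_id = NA_character_, subject_id = NA_character_,
                      time_point = NA_integer_, id_prefix = "CNV-") {
  is_call <- !is.na(segments$mean_logr) &
    (segments$mean_logr < params$loss_threshold |
       segments$mean_logr > params$gain_threshold) &
    segments$n_markers >= params$min_markers
  hits <- segments[is_call, , drop = FALSE]
  pos <- split(map$position, map$chromosome)
  n <- nrow(hits)
  calls <- data.frame(
    cnv_id = if (n > 0) sprintf("%s%d", id_prefix, seq_len(n)) else character(0),
    sample_id = rep(sample_id, n),
    subject_id = rep(subject_id, n),
    time_point = rep(time_point, n),
    chromosome = hits$chromosome,
    start_bp = vapply(seq_len(n), function(r) {
      pos[[hits$chromosome[r]]][hits$start_index[r]]
    }, numeric(1)),
    end_bp = vapply(seq_len(n), function(r) {
      pos[[hits$chromosome[r]]][hits$end_index[r]] + 1
    }, numeric(1)),
    n_markers = hits$n_markers,
    mean_logr = hits$mean_logr,
    state = ifelse(hits$mean_logr < 0, "loss", "gain"),
    stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  calls
}

#' Mean and median CNV length
#'
#' @param calls a calls or trajectories data.frame with `start_bp`/`end_bp`.
#' @return a list with `n`, `mean_length`, `median_length` (bp).
#' @export
summarize_lengths <- function(calls) {
  if (nrow(calls) == 0) stop("no calls to summarize", call. = FALSE)
  len <- calls$end_bp - calls$start_bp
  list(n = length(len), mean_length = mean(len), median_length = median(len))
}

#' Compare two sets of CNV lengths (Kruskal-Wallis)
#'
#' @param lengths_a,lengths_b numeric length vectors.
#' @return the `htest` object from [stats::kruskal.test()].
#' @export
compare_lengths <- function(lengths_a, lengths_b) {
  kruskal.test(list(lengths_a, lengths_b))
}
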