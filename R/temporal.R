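#' Classify a three-time-point presence pattern
#'
#' Maps presence across the three samplings to a temporal class:
#' (1,1,1) is `constant`; (0,1,1) is `de_novo_23` (detected at the 2nd and
#' 3rd time points); (0,0,1) is `de_novo_3` (3rd only); every other nonzero
#' pattern is `inconsistent` — such events cannot be scored under the
#' constant/de-novo model and are excluded from headline statistics. The
#' (1,0,1) pattern, a detection gap rather than a disappearance, is flagged
#' in the `gap` attribute as a diagnostic.
#'
#' @param pattern a logical vector of length 3, or a 3-column logical
#'   matrix (one row per event).
#' @return character vector of classes, with a logical `gap` attribute of
#'   the same length.
#' @export
#' @examples
#' classify_pattern(c(FALSE, TRUE, TRUE))  # de_novo_23
classify_pattern <- function(pattern) {
  m <- if (is.matrix(pattern)) pattern else matrix(pattern, nrow = 1)
  stopifnot(ncol(m) == 3)
  if (any(rowSums(m) == 0)) {
    stop("presence pattern must have at least one TRUE entry", call. = FALSE)
  }
  key <- paste0(m[, 1] + 0, m[, 2] + 0, m[, 3] + 0)
  cls <- c("111" = "constant", "011" = "de_novo_23", "001" = "de_novo_3")[key]
  cls[is.na(cls)] <- "inconsistent"
  names(cls) <- NULL
  structure(cls, gap = key == "101")
}

# Single-linkage grouping of intervals under reciprocal overlap.
.link_groups <- function(start, end, min_ro) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    ir <- IRanges(start = as.integer(start), end = as.integer(end - 1))
    hits <- findOverlaps(ir, ir)
    qi <- queryHits(hits); si <- subjectHits(hits)
    keep <- qi < si
    qi <- qi[keep]; si <- si[keep]
    if (length(qi) > 0) {
      ov <- pmin(end[qi], end[si]) - pmax(start[qi], start[si])
      len_q <- end[qi] - start[qi]
      len_s <- end[si] - start[si]
      link <- ov >= min_ro * len_q & ov >= min_ro * len_s
      for (e in which(link)) {
        a <- find(qi[e]); b <- find(si[e])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Convert bp intervals to inclusive marker-index spans on a map. Returns a
# 2-column matrix (first, last global map row). Marker-index spans make the
# reciprocal-overlap predicate robust to heterogeneous inter-marker
# spacing: an interval off by one marker across a long gap still overlaps
# its mate by all but one probe.
.marker_spans <- function(chromosome, start_bp, end_bp, map) {
  out <- matrix(NA_integer_, nrow = length(start_bp), ncol = 2)
  for (chr in unique(chromosome)) {
    rows <- which(map$chromosome == chr)
    pos <- map$position[rows]
    sel <- which(chromosome == chr)
    first <- findInterval(start_bp[sel], pos + 1) + 1L
    last <- findInterval(end_bp[sel] - 1, pos)
    out[sel, 1] <- rows[pmin(pmax(first, 1L), length(rows))]
    out[sel, 2] <- rows[pmin(pmax(last, 1L), length(rows))]
  }
  out
}

#' Match CNV calls across time points into trajectories
#'
#' Within each subject, calls of the same state on the same chromosome are
#' grouped by single linkage under a reciprocal-overlap predicate: two
#' calls are linked when their overlap covers at least
#' `min_reciprocal_overlap` of each one's length. Each group becomes one
#' trajectory spanning the union of its members, with presence at a time
#' point wherever any member was called there, classified by
#' [classify_pattern()].
#'
#' @param calls data.frame of calls from [call_cnvs()] across all samples;
#'   needs `subject_id`, `time_point`, `chromosome`, `start_bp`, `end_bp`,
#'   `state`, `cnv_id`.
#' @param min_reciprocal_overlap fraction in (0, 1], default 0.5.
#' @param map optional marker map; when supplied the reciprocal-overlap
#'   predicate is evaluated on the marker spans covered by each call
#'   rather than raw basepairs, which is robust to uneven inter-marker
#'   spacing (a boundary off by one probe across a long gap still
#'   matches). Basepair lengths are used when `map` is NULL.
#' @param n_timepoints number of sampling time points (3).
#' @return data.frame of trajectories: `trajectory_id`, `subject_id`,
#'   `chromosome`, `start_bp`, `end_bp` (union of members), `state`,
#'   `t1`..`t3`, `temporal_class`, `gap_pattern`, `n_members`,
#'   `member_call_ids` (comma-separated). A warning is emitted when a group
#'   contains two calls from the same time point.
#' @export
match_calls <- function(calls, min_reciprocal_overlap = 0.5, map = NULL,
                        n_timepoints = 3) {
  stopifnot(min_reciprocal_overlap > 0, min_reciprocal_overlap <= 1)
  check_columns(calls, c("subject_id", "time_point", "chromosome",
                         "start_bp", "end_bp", "state", "cnv_id"), "calls")
  if (is.null(map)) {
    ov_start <- calls$start_bp
    ov_end <- calls$end_bp
  } else {
    spans <- .marker_spans(calls$chromosome, calls$start_bp, calls$end_bp,
                           map)
    ov_start <- spans[, 1]
    ov_end <- spans[, 2] + 1  # half-open in marker-index space
  }
  groups <- split(seq_len(nrow(calls)),
                  paste(calls$subject_id, calls$chromosome, calls$state,
                        sep = "\r"))
  rows <- list()
  dup_seen <- FALSE
  for (g in groups) {
    comp <- .link_groups(ov_start[g], ov_end[g], min_reciprocal_overlap)
    for (cid in unique(comp)) {
      members <- g[comp == cid]
      tp <- calls$time_point[members]
      if (anyDuplicated(tp)) dup_seen <- TRUE
      pres <- seq_len(n_timepoints) %in% tp
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = calls$subject_id[members[1]],
        chromosome = calls$chromosome[members[1]],
        start_bp = min(calls$start_bp[members]),
        end_bp = max(calls$end_bp[members]),
        state = calls$state[members[1]],
        t1 = pres[1], t2 = pres[2], t3 = pres[3],
        n_members = length(members),
        member_call_ids = paste(calls$cnv_id[members], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (dup_seen) {
    warning("some trajectories contain two calls from the same time point; ",
            "presence was collapsed per time point")
  }
  if (length(rows) == 0) {
    traj <- data.frame(subject_id = character(), chromosome = character(),
                       start_bp = numeric(), end_bp = numeric(),
                       state = character(), t1 = logical(), t2 = logical(),
                       t3 = logical(), n_members = integer(),
                       member_call_ids = character(),
                       stringsAsFactors = FALSE)
    traj$temporal_class <- character(0)
    traj$gap_pattern <- logical(0)
    traj$trajectory_id <- character(0)
    return(traj)
  }
  traj <- do.call(rbind, rows)
  ord <- order(traj$subject_id, traj$chromosome, traj$start_bp)
  traj <- traj[ord, , drop = FALSE]
  cls <- classify_pattern(as.matrix(traj[, c("t1", "t2", "t3")]))
  traj$temporal_class <- as.character(cls)
  traj$gap_pattern <- attr(cls, "gap")
  traj$trajectory_id <- sprintf("TRAJ-%d", seq_len(nrow(traj)))
  rownames(traj) <- NULL
  traj[, c("trajectory_id", "subject_id", "chromosome", "start_bp",
           "end_bp", "state", "t1", "t2", "t3", "temporal_class",
           "gap_pattern", "n_members", "member_call_ids")]
}

#' Cumulative genome coverage per subject and time point
#'
#' At time point t, a subject's coverage is the total length of the union
#' of intervals of its constant and de novo trajectories first present at
#' or before t (inconsistent trajectories are excluded). The union is taken
#' per chromosome, so overlapping intervals are not double counted; the
#' curve is non-decreasing in t by construction.
#'
#' @param trajectories output of [match_calls()].
#' @param n_timepoints number of time points.
#' @return data.frame `subject_id`, `time_point`, `coverage_bp`.
#' @export
genome_coverage <- function(trajectories, n_timepoints = 3) {
  keep <- trajectories$temporal_class %in% c("constant", "de_novo_23",
                                             "de_novo_3")
  tr <- trajectories[keep, , drop = FALSE]
  first_t <- ifelse(tr$t1, 1L, ifelse(tr$t2, 2L, 3L))
  subjects <- unique(trajectories$subject_id)
  out <- expand.grid(time_point = seq_len(n_timepoints),
                     subject_id = subjects, stringsAsFactors = FALSE)
  out <- out[, c("subject_id", "time_point")]
  out$coverage_bp <- vapply(seq_len(nrow(out)), function(r) {
    sel <- tr$subject_id == out$subject_id[r] & first_t <= out$time_point[r]
    if (!any(sel)) return(0)
    sum(vapply(split(which(sel), tr$chromosome[sel]), function(ix) {
      sum(width(reduce(IRanges(start = as.integer(tr$start_bp[ix]),
                               end = as.integer(tr$end_bp[ix] - 1)))))
    }, numeric(1)))
  }, numeric(1))
  out
}

#' Coverage statistic of a trajectory class
#'
#' The summary used for between-class coverage comparisons: median
#' trajectory length multiplied by the number of trajectories.
#'
#' @param trajectories output of [match_calls()].
#' @param class one of `"constant"`, `"de_novo"` (both de novo patterns),
#'   `"de_novo_23"`, `"de_novo_3"`.
#' @return coverage in bp.
#' @export
class_coverage_statistic <- function(trajectories, class) {
  cls <- trajectories$temporal_class
  sel <- if (class == "de_novo") cls %in% c("de_novo_23", "de_novo_3")
         else cls == class
  if (!any(sel)) stop("no trajectories in class ", class, call. = FALSE)
  coverage_statistic(trajectories$end_bp[sel] - trajectories$start_bp[sel])
}

#' Median-length-times-count coverage statistic
#'
#' @param lengths numeric vector of interval lengths (bp).
#' @return `median(lengths) * length(lengths)`.
#' @export
#' @examples
#' coverage_statistic(rep(36e3, 107)) # 3.852 Mbp, i.e. 3.9 Mbp at 2 s.f.
coverage_statistic <- function(lengths) {
  if (length(lengths) == 0) stop("no lengths supplied", call. = FALSE)
  median(lengths) * length(lengths)
}

#' Exact binomial comparison of two de novo proportions
#'
#' Tests whether the de novo fraction of the second group differs from the
#' first group's fraction, by an exact two-sided binomial test of
#' `k2` successes in `n2` trials against the null proportion `k1/n1`
#' (two-sided by summing the probabilities of all outcomes no more likely
#' than the observed one).
#'
#' @param k1,n1 de novo count and total in the reference group.
#' @param k2,n2 de novo count and total in the tested group.
#' @return two-sided p-value.
#' @export
#' @examples
#' denovo_proportion_test(107, 218, 21, 85) # < 1e-4
denovo_proportion_test <- function(k1, n1, k2, n2) {
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2, n1 > 0, n2 > 0)
  binom.test(k2, n2, p = k1 / n1)$p.value
}

#' De novo CNV rate per cell division
#'
#' @param n_denovo number of de novo CNVs.
#' @param n_divisions estimated number of cell divisions over the sampling
#'   period; must be positive.
#' @return the quotient (conventionally reported to one decimal,
#'   e.g. via [round_away()]).
#' @export
#' @examples
#' round_away(division_corrected_rate(107, 120), 1) # 0.9
division_corrected_rate <- function(n_denovo, n_divisions) {
  stopifnot(n_divisions > 0, n_denovo >= 0)
  n_denovo / n_divisions
}

#' Estimate in vitro cell divisions across passages
#'
#' @param n_passages number of passages spanned by the sampling scheme
#'   (e.g. 20 between P5 and P25).
#' @param doublings_per_passage average population doublings per passage
#'   (default 2.5).
#' @return estimated divisions.
#' @export
#' @examples
#' estimate_divisions_in_vitro(20, 2.5) # 50
estimate_divisions_in_vitro <- function(n_passages,
                                        doublings_per_passage = 2.5) {
  stopifnot(n_passages >= 0, doublings_per_passage >= 0)
  n_passages * doublings_per_passage
}

#' Cohort-level summary of CNV trajectories
#'
#' Aggregates the headline statistics of a longitudinal CNV analysis:
#' per-class totals, the de novo fraction, per-subject class counts with
#' means and medians, per-chromosome and loss/gain counts, the cumulative
#' coverage table and the per-class median-length-times-count coverage
#' statistics. Inconsistent trajectories are tallied but excluded from all
#' headline numbers.
#'
#' @param trajectories output of [match_calls()].
#' @param n_timepoints number of time points.
#' @return a list of class `cohort_summary`.
#' @export
cohort_summary <- function(trajectories, n_timepoints = 3) {
  cls <- trajectories$temporal_class
  scored <- trajectories[cls != "inconsistent", , drop = FALSE]
  n_const <- sum(cls == "constant")
  n_d23 <- sum(cls == "de_novo_23")
  n_d3 <- sum(cls == "de_novo_3")
  n_denovo <- n_d23 + n_d3
  n_scored <- n_const + n_denovo

  subjects <- sort(unique(scored$subject_id))
  count_cls <- function(cl) {
    as.integer(table(factor(scored$subject_id[scored$temporal_class == cl],
                            levels = subjects)))
  }
  subj_counts <- data.frame(subject_id = subjects,
                            constant = count_cls("constant"),
                            de_novo_23 = count_cls("de_novo_23"),
                            de_novo_3 = count_cls("de_novo_3"),
                            stringsAsFactors = FALSE)
  subj_counts$de_novo <- subj_counts$de_novo_23 + subj_counts$de_novo_3

  lens <- scored$end_bp - scored$start_bp
  class_cov <- list(
    constant = if (n_const > 0) class_coverage_statistic(trajectories, "constant") else NA_real_,
    de_novo = if (n_denovo > 0) class_coverage_statistic(trajectories, "de_novo") else NA_real_)

  structure(list(
    n_trajectories = nrow(trajectories),
    n_constant = n_const,
    n_de_novo_23 = n_d23,
    n_de_novo_3 = n_d3,
    n_de_novo = n_denovo,
    n_inconsistent = sum(cls == "inconsistent"),
    n_gap_pattern = sum(trajectories$gap_pattern),
    de_novo_fraction_pct = if (n_scored > 0) 100 * n_denovo / n_scored else NA_real_,
    per_subject = subj_counts,
    mean_constant_per_subject = mean(subj_counts$constant),
    median_constant_per_subject = median(subj_counts$constant),
    mean_de_novo_per_subject = mean(subj_counts$de_novo),
    median_de_novo_per_subject = median(subj_counts$de_novo),
    per_chromosome = as.data.frame(table(chromosome = scored$chromosome),
                                   stringsAsFactors = FALSE),
    n_loss = sum(scored$state == "loss"),
    n_gain = sum(scored$state == "gain"),
    mean_length_bp = if (length(lens) > 0) mean(lens) else NA_real_,
    median_length_bp = if (length(lens) > 0) median(lens) else NA_real_,
    coverage = genome_coverage(trajectories, n_timepoints),
    class_coverage = class_cov), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Longitudinal CNV cohort summary\n")
  cat(sprintf("  trajectories: %d (%d constant, %d de novo [%d at t2&t3, %d at t3], %d inconsistent)\n",
              x$n_trajectories, x$n_constant, x$n_de_novo, x$n_de_novo_23,
              x$n_de_novo_3, x$n_inconsistent))
  if (!is.na(x$de_novo_fraction_pct)) {
    cat(sprintf("  de novo fraction: %s%%\n",
                format(round_away(x$de_novo_fraction_pct))))
  }
  cat(sprintf("  per subject: %s constant / %s de novo on average\n",
              format(round_away(x$mean_constant_per_subject)),
              format(round_away(x$mean_de_novo_per_subject))))
  cat(sprintf("  losses/gains: %d/%d; median length %s kb\n", x$n_loss,
              x$n_gain, format(signif(x$median_length_bp / 1e3, 3))))
  invisible(x)
}
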