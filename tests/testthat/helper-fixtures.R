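# Shared builders for small in-code fixtures.

# A tiny ordered map with uniform spacing (chromosomes get `n` markers each).
tiny_map <- function(chromosomes = c("1", "2"), n = 50, spacing = 1000) {
  do.call(rbind, lapply(chromosomes, function(chr) {
    data.frame(marker_id = sprintf("SNP_%s_%03d", chr, seq_len(n)),
               chromosome = chr, position = seq_len(n) * spacing,
               stringsAsFactors = FALSE)
  }))
}

# A manual calls table row.
call_row <- function(subject, tp, chr, start, end, state = "loss",
                     id = NULL) {
  data.frame(cnv_id = if (is.null(id)) sprintf("%s_T%d-%d", subject, tp,
                                               start) else id,
             sample_id = sprintf("%s_T%d", subject, tp),
             subject_id = subject, time_point = tp, chromosome = chr,
             start_bp = start, end_bp = end, n_markers = 5L,
             mean_logr = if (state == "loss") -0.6 else 0.45, state = state,
             stringsAsFactors = FALSE)
}

# Manual trajectories table (for coverage / annotation tests).
traj_row <- function(subject, chr, start, end, class, state = "loss",
                     id = NULL) {
  pat <- switch(class,
                constant = c(TRUE, TRUE, TRUE),
                de_novo_23 = c(FALSE, TRUE, TRUE),
                de_novo_3 = c(FALSE, FALSE, TRUE),
                inconsistent = c(TRUE, FALSE, FALSE))
  data.frame(trajectory_id = if (is.null(id)) sprintf("%s-%s-%d", subject,
                                                      chr, start) else id,
             subject_id = subject, chromosome = chr, start_bp = start,
             end_bp = end, state = state, t1 = pat[1], t2 = pat[2],
             t3 = pat[3], temporal_class = class,
             gap_pattern = FALSE, n_members = sum(pat),
             member_call_ids = "x", stringsAsFactors = FALSE)
}

# Exhaustive minimum-SSE partition under the pairwise acceptance rule:
# every segment has >= minm markers and every adjacent pair of segments
# differs at Welch p <= maxp. Independent of the package's segmentation
# path (direct enumeration over all 2^(n-1) compositions).
dp_partition_oracle <- function(x, maxp = 0.005, minm = 2) {
  n <- length(x)
  best_sse <- Inf
  best_bounds <- NULL
  for (code in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(code, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    sizes <- diff(bounds)
    if (length(sizes) > 1 && any(sizes < minm)) next
    segs <- lapply(seq_along(sizes), function(k) x[(bounds[k] + 1):bounds[k + 1]])
    ok <- TRUE
    if (length(segs) > 1) {
      for (k in seq_len(length(segs) - 1)) {
        if (welch_p(segs[[k]], segs[[k + 1]]) > maxp) {
          ok <- FALSE
          break
        }
      }
    }
    if (!ok) next
    sse <- sum(vapply(segs, function(v) sum((v - mean(v))^2), numeric(1)))
    if (sse < best_sse) {
      best_sse <- sse
      best_bounds <- bounds
    }
  }
  list(sse = best_sse, bounds = best_bounds)
}

# Exact two-sided binomial p by full enumeration (sum of P(outcomes) with
# probability <= P(observed)), independent of stats::binom.test.
binom_two_sided_enum <- function(k, n, p0) {
  probs <- dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# Hypergeometric upper tail P(X >= o) by enumerating all k-subsets of a
# small universe.
hyper_upper_enum <- function(o, C, N, k) {
  subsets <- utils::combn(N, k)
  in_cat <- colSums(subsets <= C)
  mean(in_cat >= o)
}
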