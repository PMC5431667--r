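#' Simulation configuration for a synthetic longitudinal CNV cohort
#'
#' Defines the study conditions emulated by the generator: an autosome-only
#' marker map at roughly 50k-array density, per-sample Gaussian logR noise,
#' optional long-range waves and single-marker outliers, and planted CNV
#' segments whose presence across the three sampling time points follows the
#' constant / de novo (2nd & 3rd) / de novo (3rd only) / inconsistent
#' classes.
#'
#' Default per-subject class counts (14 constant, 4 + 9 de novo) mirror the
#' per-sample averages of a longitudinal in vivo SNP-array study of eight
#' subjects; the loss/gain shifts of -0.6 / +0.45 logR units are typical
#' one-copy Illumina magnitudes and clear the +/-0.35 segment-mean filter
#' with margin at the default noise level.
#'
#' @param n_subjects number of subjects (default 8).
#' @param n_timepoints sampling time points per subject (fixed design: 3).
#' @param n_chromosomes number of autosomes simulated.
#' @param markers_per_chromosome markers per chromosome.
#' @param mean_spacing_bp mean inter-marker spacing in basepairs (50 kb
#'   mimics a ~50k bovine array).
#' @param noise_sd standard deviation of the Gaussian logR noise.
#' @param loss_shift,gain_shift mean logR shift added inside planted losses
#'   and gains.
#' @param n_constant,n_denovo_23,n_denovo_3,n_inconsistent planted CNVs per
#'   subject in each presence class: patterns (1,1,1), (0,1,1), (0,0,1) and
#'   the inconsistent patterns respectively.
#' @param min_cnv_markers,max_cnv_markers planted CNV length range, in
#'   markers.
#' @param gain_fraction probability that a planted CNV is a gain rather than
#'   a loss (losses dominate real array CNV sets).
#' @param gc_wave_amplitude amplitude (logR units) of the long-period
#'   sinusoidal wave shared by all samples; 0 disables it.
#' @param gc_wave_period wave period in markers.
#' @param outlier_rate per-marker probability of an isolated +/-1.0 logR
#'   spike.
#' @param seed integer seed governing the whole simulation; per-subject and
#'   per-track sub-streams are derived from it deterministically.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [make_marker_map()], [plant_truth()], [render_logr()],
#'   [sim_cohort()]
#' @export
sim_config <- function(n_subjects = 8, n_timepoints = 3, n_chromosomes = 8,
                       markers_per_chromosome = 400, mean_spacing_bp = 50000,
                       noise_sd = 0.15, loss_shift = -0.6, gain_shift = 0.45,
                       n_constant = 14, n_denovo_23 = 4, n_denovo_3 = 9,
                       n_inconsistent = 0, min_cnv_markers = 5,
                       max_cnv_markers = 15, gain_fraction = 0.05,
                       gc_wave_amplitude = 0, gc_wave_period = 500,
                       outlier_rate = 0, seed = 1) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_timepoints = as.integer(n_timepoints),
              n_chromosomes = as.integer(n_chromosomes),
              markers_per_chromosome = as.integer(markers_per_chromosome),
              mean_spacing_bp = mean_spacing_bp,
              noise_sd = noise_sd,
              loss_shift = loss_shift, gain_shift = gain_shift,
              n_constant = as.integer(n_constant),
              n_denovo_23 = as.integer(n_denovo_23),
              n_denovo_3 = as.integer(n_denovo_3),
              n_inconsistent = as.integer(n_inconsistent),
              min_cnv_markers = as.integer(min_cnv_markers),
              max_cnv_markers = as.integer(max_cnv_markers),
              gain_fraction = gain_fraction,
              gc_wave_amplitude = gc_wave_amplitude,
              gc_wave_period = gc_wave_period,
              outlier_rate = outlier_rate,
              seed = as.integer(seed))
  if (cfg$n_subjects < 1) stop("n_subjects must be positive", call. = FALSE)
  if (cfg$n_timepoints != 3)
    stop("the longitudinal design is fixed at 3 time points", call. = FALSE)
  if (cfg$n_chromosomes < 1 || cfg$markers_per_chromosome < 2)
    stop("need >= 1 chromosome and >= 2 markers per chromosome", call. = FALSE)
  if (cfg$mean_spacing_bp <= 0) stop("mean_spacing_bp must be positive", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cfg$outlier_rate < 0 || cfg$outlier_rate > 1)
    stop("outlier_rate must be in [0, 1]", call. = FALSE)
  if (any(c(cfg$n_constant, cfg$n_denovo_23, cfg$n_denovo_3,
            cfg$n_inconsistent) < 0))
    stop("planted CNV counts must be >= 0", call. = FALSE)
  if (cfg$min_cnv_markers < 1 || cfg$max_cnv_markers < cfg$min_cnv_markers)
    stop("invalid planted CNV marker-length range", call. = FALSE)
  if (cfg$loss_shift >= 0 || cfg$gain_shift <= 0)
    stop("loss_shift must be negative and gain_shift positive", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate an ordered autosomal marker map
#'
#' Inter-marker spacings are drawn from an exponential distribution with the
#' configured mean (a Poisson-process stand-in for real array spacing), so
#' positions are strictly increasing within each chromosome.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` with columns `marker_id`, `chromosome`, `position`
#'   (1-based bp), ordered by (chromosome, position).
#' @export
make_marker_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$markers_per_chromosome
  maps <- lapply(seq_len(config$n_chromosomes), function(chr) {
    spacing <- pmax(1, round(rexp(n, rate = 1 / config$mean_spacing_bp)))
    data.frame(chromosome = as.character(chr),
               position = cumsum(spacing),
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  map$marker_id <- sprintf("SNP_%s_%06d", map$chromosome,
                           unlist(lapply(maps, function(m) seq_len(nrow(m)))))
  map[, c("marker_id", "chromosome", "position")]
}

# Presence patterns of the temporal classes, in planting order.
.pattern_table <- function(config) {
  pat <- list()
  add <- function(n, p) for (i in seq_len(n)) pat[[length(pat) + 1]] <<- p
  add(config$n_constant, c(TRUE, TRUE, TRUE))
  add(config$n_denovo_23, c(FALSE, TRUE, TRUE))
  add(config$n_denovo_3, c(FALSE, FALSE, TRUE))
  incons <- list(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
                 c(TRUE, TRUE, FALSE))
  for (i in seq_len(config$n_inconsistent)) {
    pat[[length(pat) + 1]] <- incons[[(i - 1) %% 3 + 1]]
  }
  pat
}

#' Plant truth CNVs on a marker map
#'
#' Places non-overlapping CNV segments (with a minimum 10-marker gap between
#' segments of the same subject, so that distinct events remain separable)
#' and assigns each a temporal presence pattern. The per-subject layout is
#' derived from the seed alone, so all subjects carry the same truth set up
#' to `subject_id` — a deterministic contract that makes cross-subject
#' comparisons exact.
#'
#' @param config a [sim_config()].
#' @param map a marker map from [make_marker_map()].
#' @return a `data.frame` with one row per planted CNV: `subject_id`,
#'   `chromosome`, `start_index`/`end_index` (row indices into `map`,
#'   inclusive), `start_bp`/`end_bp` (half-open), `n_markers`, `state`,
#'   `mean_shift`, presence flags `t1`,`t2`,`t3`.
#' @export
plant_truth <- function(config, map) {
  stopifnot(inherits(config, "sim_config"))
  patterns <- .pattern_table(config)
  n_cnv <- length(patterns)
  empty <- data.frame(subject_id = character(), chromosome = character(),
                      start_index = integer(), end_index = integer(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_markers = integer(), state = character(),
                      mean_shift = numeric(), t1 = logical(), t2 = logical(),
                      t3 = logical(), stringsAsFactors = FALSE)
  if (n_cnv == 0) return(empty)

  chrom_rows <- split(seq_len(nrow(map)), map$chromosome)
  gap <- 10L

  # one layout, reused for every subject (sub-stream depends on seed only)
  set.seed(derive_seed(config$seed, 2L))
  lens <- sample(config$min_cnv_markers:config$max_cnv_markers, n_cnv,
                 replace = TRUE)
  states <- ifelse(runif(n_cnv) < config$gain_fraction, "gain", "loss")
  occupied <- lapply(chrom_rows, function(x) integer(0))
  placement <- vector("list", n_cnv)
  for (k in seq_len(n_cnv)) {
    placed <- FALSE
    for (attempt in seq_len(500)) {
      chr <- sample(names(chrom_rows), 1)
      rows <- chrom_rows[[chr]]
      if (length(rows) < lens[k]) next
      s_local <- sample.int(length(rows) - lens[k] + 1, 1)
      span <- s_local:(s_local + lens[k] - 1)
      guard <- max(1, s_local - gap):min(length(rows), s_local + lens[k] - 1 + gap)
      if (any(guard %in% occupied[[chr]])) next
      occupied[[chr]] <- c(occupied[[chr]], span)
      placement[[k]] <- list(chr = chr, start = rows[span[1]],
                             end = rows[span[length(span)]])
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("marker map too small for the requested number of CNVs",
           call. = FALSE)
    }
  }

  one_subject <- data.frame(
    chromosome = vapply(placement, function(p) p$chr, character(1)),
    start_index = vapply(placement, function(p) p$start, numeric(1)),
    end_index = vapply(placement, function(p) p$end, numeric(1)),
    state = states,
    mean_shift = ifelse(states == "gain", config$gain_shift,
                        config$loss_shift),
    t1 = vapply(patterns, `[`, logical(1), 1),
    t2 = vapply(patterns, `[`, logical(1), 2),
    t3 = vapply(patterns, `[`, logical(1), 3),
    stringsAsFactors = FALSE)

  truth <- do.call(rbind, lapply(seq_len(config$n_subjects), function(s) {
    df <- one_subject
    df$subject_id <- sprintf("S%d", s)
    df
  }))
  truth$start_bp <- map$position[truth$start_index]
  truth$end_bp <- map$position[truth$end_index] + 1
  truth$n_markers <- truth$end_index - truth$start_index + 1L
  rownames(truth) <- NULL
  truth[, names(empty)]
}

#' Render noisy logR tracks from a truth CNV set
#'
#' Each track is baseline 0 plus Gaussian noise; markers inside a truth CNV
#' get its `mean_shift` added at every time point where the presence pattern
#' is true. An optional shared sinusoidal wave (emulating GC-correlated
#' genomic waves) and isolated +/-1.0 outlier spikes are superimposed.
#'
#' @param truth a truth set from [plant_truth()].
#' @param map the matching marker map.
#' @param config the [sim_config()] used to create both.
#' @return a list with elements `logr` (markers x samples matrix, columns
#'   named `<subject>_T<t>`), `samples` (data.frame with `sample_id`,
#'   `subject_id`, `time_point`) and `wave` (the shared wave covariate,
#'   one value per marker; all zero when the amplitude is 0).
#' @export
render_logr <- function(truth, map, config) {
  stopifnot(inherits(config, "sim_config"))
  n_mark <- nrow(map)
  subjects <- sprintf("S%d", seq_len(config$n_subjects))
  samples <- expand.grid(time_point = seq_len(config$n_timepoints),
                         subject_id = subjects, stringsAsFactors = FALSE)
  samples <- samples[, c("subject_id", "time_point")]
  samples$sample_id <- sprintf("%s_T%d", samples$subject_id,
                               samples$time_point)

  wave <- if (config$gc_wave_amplitude > 0) {
    config$gc_wave_amplitude * sin(2 * pi * seq_len(n_mark) / config$gc_wave_period)
  } else {
    numeric(n_mark)
  }

  logr <- matrix(0, nrow = n_mark, ncol = nrow(samples),
                 dimnames = list(map$marker_id, samples$sample_id))
  tp_col <- c("t1", "t2", "t3")
  for (i in seq_len(nrow(samples))) {
    s_idx <- match(samples$subject_id[i], subjects)
    t <- samples$time_point[i]
    set.seed(derive_seed(config$seed, 100L + s_idx, t))
    x <- rnorm(n_mark, 0, config$noise_sd) + wave
    if (config$outlier_rate > 0) {
      spikes <- which(rbinom(n_mark, 1, config$outlier_rate) == 1)
      if (length(spikes) > 0) {
        x[spikes] <- x[spikes] + sample(c(-1, 1), length(spikes),
                                        replace = TRUE)
      }
    }
    rows <- truth[truth$subject_id == samples$subject_id[i] &
                    truth[[tp_col[t]]], , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      span <- rows$start_index[j]:rows$end_index[j]
      x[span] <- x[span] + rows$mean_shift[j]
    }
    logr[, i] <- x
  }
  list(logr = logr, samples = samples, wave = wave)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [make_marker_map()], [plant_truth()] and
#' [render_logr()] under one configuration.
#'
#' @param config a [sim_config()].
#' @return a list of class `cnv_cohort` with elements `config`, `map`,
#'   `truth`, `logr`, `samples`, `wave`.
#' @export
#' @examples
#' cohort <- sim_cohort(sim_config(n_subjects = 2, n_chromosomes = 2,
#'                                 markers_per_chromosome = 150,
#'                                 n_constant = 2, n_denovo_23 = 1,
#'                                 n_denovo_3 = 1, seed = 42))
#' dim(cohort$logr)
sim_cohort <- function(config = sim_config()) {
  map <- make_marker_map(config)
  truth <- plant_truth(config, map)
  rend <- render_logr(truth, map, config)
  structure(list(config = config, map = map, truth = truth,
                 logr = rend$logr, samples = rend$samples,
                 wave = rend$wave),
            class = "cnv_cohort")
}

#' Score recovery of planted CNVs by called trajectories
#'
#' A truth CNV counts as recovered when some trajectory of the same subject,
#' state and chromosome overlaps it reciprocally by at least
#' `min_reciprocal_overlap` and carries the temporal class implied by the
#' planted presence pattern.
#'
#' @param truth a truth set from [plant_truth()].
#' @param trajectories trajectories from [match_calls()].
#' @param map optional marker map; when given, reciprocal overlap is
#'   evaluated on marker spans (robust to uneven spacing), otherwise on
#'   basepairs.
#' @param min_reciprocal_overlap reciprocal-overlap fraction in (0, 1].
#' @return a list with `n_truth`, `n_recovered` and `fraction`.
#' @export
score_recovery <- function(truth, trajectories, map = NULL,
                           min_reciprocal_overlap = 0.5) {
  if (nrow(truth) == 0) {
    return(list(n_truth = 0L, n_recovered = 0L, fraction = NA_real_))
  }
  truth_class <- classify_pattern(as.matrix(truth[, c("t1", "t2", "t3")]))
  if (is.null(map)) {
    t_start <- truth$start_bp; t_end <- truth$end_bp
    c_start <- trajectories$start_bp; c_end <- trajectories$end_bp
  } else {
    ts <- .marker_spans(truth$chromosome, truth$start_bp, truth$end_bp, map)
    cs <- .marker_spans(trajectories$chromosome, trajectories$start_bp,
                        trajectories$end_bp, map)
    t_start <- ts[, 1]; t_end <- ts[, 2] + 1
    c_start <- cs[, 1]; c_end <- cs[, 2] + 1
  }
  hit <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cand <- which(trajectories$subject_id == truth$subject_id[i] &
                    trajectories$chromosome == truth$chromosome[i] &
                    trajectories$state == truth$state[i] &
                    trajectories$temporal_class == truth_class[i])
    if (length(cand) == 0) next
    ov <- pmin(c_end[cand], t_end[i]) - pmax(c_start[cand], t_start[i])
    lt <- t_end[i] - t_start[i]
    lc <- c_end[cand] - c_start[cand]
    hit[i] <- any(ov >= min_reciprocal_overlap * lt &
                    ov >= min_reciprocal_overlap * lc)
  }
  list(n_truth = nrow(truth), n_recovered = sum(hit),
       fraction = mean(hit))
}
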