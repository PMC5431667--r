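#' The six major QTL trait classes
#'
#' @return character vector of class names.
#' @export
qtl_classes <- function() {
  c("Health", "Meat_and_carcass", "Milk", "Production", "Reproduction",
    "Exterior")
}

#' Overlap intervals with annotation features
#'
#' Reports every (interval, feature) pair sharing at least
#' `min_overlap_bp` bases. All coordinates are half-open `[start, end)`;
#' features of chromosomes absent from the query simply yield no pairs.
#'
#' @param intervals data.frame with `chromosome`, `start_bp`, `end_bp` and
#'   an id column (first of `trajectory_id`/`cnv_id`/`name` found, else row
#'   numbers).
#' @param features data.frame with `chromosome`, `start_bp`, `end_bp`,
#'   `name` (and optionally `trait_class`).
#' @param min_overlap_bp minimum shared bases (default 1, i.e. any
#'   overlap).
#' @return data.frame of pairs: `interval_id`, `feature_name`,
#'   `overlap_bp` plus `trait_class` when present in `features`; ordered by
#'   interval, stable in feature order.
#' @export
overlap_features <- function(intervals, features, min_overlap_bp = 1) {
  check_columns(intervals, c("chromosome", "start_bp", "end_bp"), "intervals")
  check_columns(features, c("chromosome", "start_bp", "end_bp", "name"),
                "features")
  id_col <- intersect(c("trajectory_id", "cnv_id", "name"), names(intervals))
  ids <- if (length(id_col) > 0) intervals[[id_col[1]]]
         else as.character(seq_len(nrow(intervals)))
  qchr <- norm_chrom(intervals$chromosome)
  schr <- norm_chrom(features$chromosome)
  out <- list()
  for (chr in unique(qchr)) {
    qi <- which(qchr == chr)
    si <- which(schr == chr)
    if (length(si) == 0) next
    q <- IRanges(start = as.integer(intervals$start_bp[qi]),
                 end = as.integer(intervals$end_bp[qi] - 1))
    s <- IRanges(start = as.integer(features$start_bp[si]),
                 end = as.integer(features$end_bp[si] - 1))
    hits <- findOverlaps(q, s, minoverlap = min_overlap_bp)
    if (length(hits) == 0) next
    a <- qi[queryHits(hits)]
    b <- si[subjectHits(hits)]
    df <- data.frame(interval_id = ids[a], feature_name = features$name[b],
                     overlap_bp = pmin(intervals$end_bp[a], features$end_bp[b]) -
                       pmax(intervals$start_bp[a], features$start_bp[b]),
                     stringsAsFactors = FALSE)
    if ("trait_class" %in% names(features)) df$trait_class <- features$trait_class[b]
    out[[length(out) + 1]] <- df
  }
  if (length(out) == 0) {
    df <- data.frame(interval_id = character(), feature_name = character(),
                     overlap_bp = numeric(), stringsAsFactors = FALSE)
    if ("trait_class" %in% names(features)) df$trait_class <- character(0)
    return(df)
  }
  res <- do.call(rbind, out)
  res[order(match(res$interval_id, ids)), , drop = FALSE]
}

#' Four-way Venn partition of gene sets
#'
#' Exact counts of every nonempty membership region of up to four named
#' gene sets (15 regions for four sets).
#'
#' @param gene_sets named list of character vectors (2 to 4 sets).
#' @return named integer vector; region names join set names with `&`.
#'   Counts sum to the size of the union.
#' @export
venn_partition <- function(gene_sets) {
  stopifnot(is.list(gene_sets), length(gene_sets) >= 2,
            length(gene_sets) <= 4, !is.null(names(gene_sets)))
  sets <- lapply(gene_sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  nm <- names(sets)
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  counts <- apply(combos, 1, function(inc) {
    sum(apply(member, 1, function(row) all(row == inc)))
  })
  names(counts) <- apply(combos, 1, function(inc) paste(nm[unlist(inc)],
                                                        collapse = "&"))
  counts[order(lengths(strsplit(names(counts), "&", fixed = TRUE)),
               names(counts))]
}

#' QTL-class enrichment of de novo versus constant CNVs
#'
#' For each trait class, counts the CNVs (trajectories) of each group that
#' overlap at least one QTL of that class — a CNV hitting several QTLs of
#' one class still counts once — and tests the de novo count against the
#' constant group's proportion with an exact two-sided binomial test. When
#' the constant proportion is degenerate (0 or 1) a continuity floor of
#' `0.5 / n_constant` keeps the null proportion inside (0, 1).
#'
#' @param trajectories_denovo,trajectories_constant trajectory data.frames
#'   (both nonempty).
#' @param qtl_features QTL data.frame with `chromosome`, `start_bp`,
#'   `end_bp`, `name`, `trait_class`.
#' @param classes trait classes to test (default [qtl_classes()]).
#' @param min_overlap_bp minimum overlap passed to [overlap_features()].
#' @return data.frame per class: `trait_class`, `n_denovo_overlap`,
#'   `n_constant_overlap`, `n_denovo`, `n_constant`, `null_proportion`,
#'   `p_value`.
#' @export
qtl_class_enrichment <- function(trajectories_denovo, trajectories_constant,
                                 qtl_features, classes = qtl_classes(),
                                 min_overlap_bp = 1) {
  if (nrow(trajectories_denovo) == 0 || nrow(trajectories_constant) == 0) {
    stop("both trajectory groups must be nonempty", call. = FALSE)
  }
  count_by_class <- function(traj) {
    ids <- traj$trajectory_id
    if (is.null(ids)) ids <- as.character(seq_len(nrow(traj)))
    ov <- overlap_features(traj, qtl_features, min_overlap_bp)
    vapply(classes, function(cl) {
      length(unique(ov$interval_id[ov$trait_class == cl]))
    }, integer(1))
  }
  o_d <- count_by_class(trajectories_denovo)
  o_c <- count_by_class(trajectories_constant)
  n_d <- nrow(trajectories_denovo)
  n_c <- nrow(trajectories_constant)
  floor_p <- 0.5 / n_c
  p0 <- pmin(pmax(o_c / n_c, floor_p), 1 - floor_p)
  pv <- vapply(seq_along(classes), function(i) {
    binom.test(o_d[i], n_d, p = p0[i])$p.value
  }, numeric(1))
  data.frame(trait_class = classes, n_denovo_overlap = o_d,
             n_constant_overlap = o_c, n_denovo = n_d, n_constant = n_c,
             null_proportion = p0, p_value = pv, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Hypergeometric gene-set enrichment
#'
#' For each category the statistics follow the usual over-representation
#' layout: C is the number of reference genes in the category, O the
#' observed overlap with the analyzed set, E = C * k / N the expected
#' overlap (k analyzed genes in a reference universe of N), R = O / E the
#' enrichment ratio, rawP the hypergeometric upper tail P(X >= O) and adjP
#' the Benjamini-Hochberg adjustment across categories.
#'
#' @param analyzed_genes character vector of analyzed gene names (assumed
#'   to lie inside the reference universe).
#' @param gene_sets named list of category member vectors (e.g. from
#'   [read_gmt()]).
#' @param reference_size N, the size of the reference universe; must be at
#'   least the analyzed set size.
#' @return data.frame per category: `category`, `C`, `O`, `E`, `R`,
#'   `raw_p`, `adj_p`, sorted by `raw_p`.
#' @export
geneset_enrichment <- function(analyzed_genes, gene_sets, reference_size) {
  analyzed <- unique(analyzed_genes)
  k <- length(analyzed)
  N <- reference_size
  if (N < k) stop("reference_size smaller than analyzed set", call. = FALSE)
  rows <- lapply(names(gene_sets), function(cat) {
    members <- unique(gene_sets[[cat]])
    C <- length(members)
    O <- length(intersect(analyzed, members))
    E <- C * k / N
    R <- if (E > 0) O / E else NA_real_
    if (O == 0) R <- 0
    raw_p <- if (O == 0) 1 else phyper(O - 1, C, N - C, k, lower.tail = FALSE)
    data.frame(category = cat, C = C, O = O, E = E, R = R, raw_p = raw_p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$adj_p <- p.adjust(res$raw_p, method = "BH")
  res[order(res$raw_p), , drop = FALSE]
}
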