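#' Write a logR matrix as a plain TSV
#'
#' Rows are markers (with `marker_id`, `chromosome`, `position` columns),
#' remaining columns one per sample.
#'
#' @param logr markers x samples matrix.
#' @param map marker map aligned to rows.
#' @param path output file.
#' @export
write_logr_tsv <- function(logr, map, path) {
  df <- cbind(map[, c("marker_id", "chromosome", "position")],
              as.data.frame(logr, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a logR TSV written by [write_logr_tsv()]
#'
#' @param path input file.
#' @return list with `map` and `logr` (markers sorted by chromosome,
#'   position).
#' @export
read_logr_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  check_columns(df, c("marker_id", "chromosome", "position"), basename(path))
  df$chromosome <- norm_chrom(df$chromosome)
  ord <- order(df$chromosome, df$position)
  df <- df[ord, , drop = FALSE]
  map <- df[, c("marker_id", "chromosome", "position")]
  rownames(map) <- NULL
  logr <- as.matrix(df[, setdiff(names(df), names(map)), drop = FALSE])
  rownames(logr) <- map$marker_id
  list(map = map, logr = logr)
}

#' Write logR tracks in a minimal GenomeStudio Final-Report dialect
#'
#' Emits a `[Header]` section followed by a tab-delimited `[Data]` section
#' with the columns `Sample ID`, `SNP Name`, `Chr`, `Position`,
#' `Log R Ratio`, one row per sample per marker.
#'
#' @param logr markers x samples matrix.
#' @param map marker map aligned to rows.
#' @param path output file.
#' @export
write_final_report <- function(logr, map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("[Header]",
               "GSGT Version\tsynthetic",
               sprintf("Num SNPs\t%d", nrow(map)),
               sprintf("Total Samples\t%d", ncol(logr)),
               "[Data]",
               paste("Sample ID", "SNP Name", "Chr", "Position",
                     "Log R Ratio", sep = "\t")), con)
  for (s in colnames(logr)) {
    writeLines(paste(s, map$marker_id, map$chromosome, map$position,
                     format(logr[, s], trim = TRUE, digits = 15),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a GenomeStudio-style Final Report
#'
#' Parses the tab-delimited `[Data]` section. Markers are sorted by
#' (chromosome, position); missing logR entries become NA (treated as
#' masked downstream). Errors name any absent mandatory column and list
#' samples whose marker sets disagree.
#'
#' @param path input file.
#' @return list with `map` (`marker_id`, `chromosome`, `position`) and
#'   `logr` (markers x samples matrix).
#' @export
read_final_report <- function(path) {
  lines <- readLines(path)
  data_at <- which(trimws(lines) == "[Data]")
  if (length(data_at) == 0) stop("no [Data] section in ", basename(path),
                                 call. = FALSE)
  df <- read.delim(text = paste(lines[(data_at[1] + 1):length(lines)],
                                collapse = "\n"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("Sample ID", "SNP Name", "Chr", "Position", "Log R Ratio")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("Final Report is missing column(s): ",
         paste(sprintf("'%s'", missing), collapse = ", "), call. = FALSE)
  }
  df$Chr <- norm_chrom(df$Chr)
  samples <- unique(df[["Sample ID"]])
  marker_sets <- split(df[["SNP Name"]], df[["Sample ID"]])
  ref_set <- sort(marker_sets[[1]])
  bad <- names(marker_sets)[!vapply(marker_sets, function(s) {
    identical(sort(s), ref_set)
  }, logical(1))]
  if (length(bad) > 0) {
    stop("inconsistent marker sets across samples: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  samples <- sort(samples)  # canonical column order
  first <- df[df[["Sample ID"]] == samples[1], ]
  ord <- order(first$Chr, first$Position)
  map <- data.frame(marker_id = first[["SNP Name"]][ord],
                    chromosome = first$Chr[ord],
                    position = first$Position[ord],
                    stringsAsFactors = FALSE)
  logr <- matrix(NA_real_, nrow = nrow(map), ncol = length(samples),
                 dimnames = list(map$marker_id, samples))
  for (s in samples) {
    sub <- df[df[["Sample ID"]] == s, ]
    logr[sub[["SNP Name"]], s] <- suppressWarnings(
      as.numeric(sub[["Log R Ratio"]]))
  }
  list(map = map, logr = logr)
}

#' Read a BED file
#'
#' BED coordinates are 0-based half-open; they are kept half-open in
#' `start_bp`/`end_bp`. Leading "chr" prefixes are stripped.
#'
#' @param path input file.
#' @return data.frame `chromosome`, `start_bp`, `end_bp` and `name` when a
#'   4th column exists. Empty files yield an empty data.frame.
#' @export
read_bed <- function(path) {
  empty <- data.frame(chromosome = character(), start_bp = numeric(),
                      end_bp = numeric(), name = character(),
                      stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) &
                   !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0) return(empty)
  parts <- strsplit(lines, "\t| +")
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    stop("malformed BED line(s) ", paste(bad, collapse = ", "), " in ",
         basename(path), call. = FALSE)
  }
  df <- data.frame(chromosome = norm_chrom(vapply(parts, `[`, "", 1)),
                   start_bp = as.numeric(vapply(parts, `[`, "", 2)),
                   end_bp = as.numeric(vapply(parts, `[`, "", 3)),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$start_bp)) || any(!is.finite(df$end_bp)) ||
      any(df$end_bp <= df$start_bp)) {
    stop("invalid BED coordinates (need numeric, end > start) in ",
         basename(path), call. = FALSE)
  }
  if (all(lengths(parts) >= 4)) df$name <- vapply(parts, `[`, "", 4)
  df
}

#' Write intervals as BED
#'
#' @param intervals data.frame with `chromosome`, `start_bp`, `end_bp` and
#'   optionally `name` (or an id column used as name).
#' @param path output file.
#' @param chr_prefix prepend "chr" to chromosome labels (BED convention).
#' @export
write_bed <- function(intervals, path, chr_prefix = TRUE) {
  chr <- norm_chrom(intervals$chromosome)
  if (chr_prefix) chr <- paste0("chr", chr)
  name_col <- intersect(c("name", "trajectory_id", "cnv_id"),
                        names(intervals))
  df <- data.frame(chr, format(intervals$start_bp, scientific = FALSE,
                               trim = TRUE),
                   format(intervals$end_bp, scientific = FALSE, trim = TRUE))
  if (length(name_col) > 0) df$name <- intervals[[name_col[1]]]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a planted truth set as BED plus a TSV sidecar
#'
#' The BED holds the 0-based half-open intervals named by subject and
#' index; the sidecar TSV carries subject, state and the presence pattern.
#'
#' @param truth truth set from [plant_truth()].
#' @param bed_path,tsv_path output files.
#' @export
write_truth_bed <- function(truth, bed_path, tsv_path) {
  truth$name <- sprintf("%s_cnv%d", truth$subject_id,
                        as.integer(stats::ave(seq_len(nrow(truth)),
                                              truth$subject_id,
                                              FUN = seq_along)))
  bed <- truth
  bed$start_bp <- bed$start_bp - 1  # BED is 0-based
  bed$end_bp <- bed$end_bp - 1
  write_bed(bed, bed_path)
  write.table(truth[, c("name", "subject_id", "chromosome", "start_bp",
                        "end_bp", "state", "t1", "t2", "t3")],
              tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(bed_path)
}

#' Read a GMT gene-set file
#'
#' One set per tab-delimited line: name, description, then members. Empty
#' files yield an empty list.
#'
#' @param path input file.
#' @return named list of character vectors of members.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(setNames(list(), character(0)))
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    stop("malformed GMT line(s) ", paste(bad, collapse = ", "), " in ",
         basename(path), call. = FALSE)
  }
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1)
  sets
}

#' Read a QTL interval table
#'
#' Tab-delimited with columns `chromosome`, `start_bp`, `end_bp`, `name`,
#' `trait_class` (AnimalQTLdb-style six major classes).
#'
#' @param path input file.
#' @return data.frame of QTL features.
#' @export
read_qtl_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("chromosome", "start_bp", "end_bp", "name",
                      "trait_class"), basename(path))
  df$chromosome <- norm_chrom(df$chromosome)
  df
}

#' Write a cohort summary as JSON
#'
#' @param summary a list (e.g. a `cohort_summary`).
#' @param path output file.
#' @export
write_json_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates a cohort, screens it (sex-chromosome exclusion, QC report),
#' segments every track, calls CNVs, matches them into trajectories and
#' assembles the cohort summary; optionally annotates trajectories with
#' genes and QTLs and runs the enrichment tests.
#'
#' @param config a [sim_config()].
#' @param params a [seg_params()].
#' @param min_reciprocal_overlap trajectory matching threshold.
#' @param genes optional gene feature data.frame (see
#'   [overlap_features()]).
#' @param qtl optional QTL feature data.frame.
#' @param gene_sets optional named list of gene sets for enrichment.
#' @param reference_size reference universe size for [geneset_enrichment()]
#'   (required with `gene_sets`).
#' @param out_dir optional directory; when given, calls, trajectories,
#'   coverage and the JSON summary are written there.
#' @return a list with `cohort`, `qc`, `calls`, `trajectories`, `summary`,
#'   `recovery` and (when requested) `gene_overlap`, `qtl_enrichment`,
#'   `set_enrichment`.
#' @export
run_report <- function(config = sim_config(), params = seg_params(),
                       min_reciprocal_overlap = 0.5, genes = NULL,
                       qtl = NULL, gene_sets = NULL, reference_size = NULL,
                       out_dir = NULL) {
  cohort <- sim_cohort(config)
  filt <- exclude_sex_chromosomes(cohort$map, cohort$logr)
  map <- filt$map
  logr <- filt$logr
  covar <- if (any(cohort$wave != 0)) cohort$wave else NULL
  qc <- qc_report(logr, map, covariate = covar)

  calls <- do.call(rbind, lapply(seq_len(ncol(logr)), function(i) {
    s <- cohort$samples[i, ]
    segs <- segment_track(logr[, i], map, params)
    call_cnvs(segs, map, params, sample_id = s$sample_id,
              subject_id = s$subject_id, time_point = s$time_point,
              id_prefix = sprintf("%s-", s$sample_id))
  }))
  traj <- match_calls(calls, min_reciprocal_overlap, map = map)
  summ <- cohort_summary(traj, config$n_timepoints)
  recovery <- score_recovery(cohort$truth, traj, map = map,
                             min_reciprocal_overlap = min_reciprocal_overlap)

  res <- list(cohort = cohort, qc = qc, calls = calls, trajectories = traj,
              summary = summ, recovery = recovery)

  denovo <- traj[traj$temporal_class %in% c("de_novo_23", "de_novo_3"), ,
                 drop = FALSE]
  constant <- traj[traj$temporal_class == "constant", , drop = FALSE]
  if (!is.null(genes)) {
    res$gene_overlap <- overlap_features(traj, genes)
  }
  if (!is.null(qtl) && nrow(denovo) > 0 && nrow(constant) > 0) {
    res$qtl_enrichment <- qtl_class_enrichment(denovo, constant, qtl)
  }
  if (!is.null(gene_sets)) {
    if (is.null(reference_size)) {
      stop("reference_size is required with gene_sets", call. = FALSE)
    }
    genes_hit <- if (!is.null(res$gene_overlap)) {
      unique(res$gene_overlap$feature_name[
        res$gene_overlap$interval_id %in% denovo$trajectory_id])
    } else character(0)
    res$set_enrichment <- geneset_enrichment(genes_hit, gene_sets,
                                             reference_size)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(calls, file.path(out_dir, "calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(traj, file.path(out_dir, "trajectories.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(summ$coverage, file.path(out_dir, "coverage.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(qc, file.path(out_dir, "qc.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_json_summary(summ, file.path(out_dir, "summary.json"))
  }
  res
}
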