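#' Relative quantity from Cq tables
#'
#' Efficiency-corrected relative quantification against a control sample
#' and two normalizer genes. For a target assay t and sample s,
#' `RQ = E_t^(Cq_control - Cq_s)` divided by the geometric mean of the same
#' quantity over the normalizer assays; replicate Cq values are averaged
#' before exponentiation. The control is typically a pool of all
#' first-time-point samples, taken to represent the diploid state at every
#' tested locus, and the normalizers are assumed copy-stable.
#'
#' @param cq long-format data.frame with columns `assay`, `sample_id`,
#'   `cq` (one row per replicate; a `time_point` column, if present, is
#'   carried through).
#' @param target the target assay (CNV locus) name.
#' @param normalizers character vector of exactly two normalizer assay
#'   names.
#' @param control_sample sample_id of the control.
#' @param efficiency named per-assay amplification factors in (1, 2];
#'   assays not named get `default_efficiency`.
#' @param default_efficiency amplification factor used when an assay has no
#'   entry in `efficiency` (2 = perfect doubling).
#' @return data.frame with `sample_id` (control excluded), `time_point`
#'   (when available) and `rq`.
#' @export
#' @examples
#' cq <- expand.grid(assay = c("LOC1", "SRY", "BTF3"),
#'                   sample_id = c("ctrl", "s1"), stringsAsFactors = FALSE)
#' cq$cq <- c(25, 22, 23, 26, 22, 23)  # target one cycle later in s1
#' relative_quantity(cq, "LOC1", c("SRY", "BTF3"), "ctrl")  # rq = 0.5
relative_quantity <- function(cq, target, normalizers, control_sample,
                              efficiency = NULL, default_efficiency = 2) {
  check_columns(cq, c("assay", "sample_id", "cq"), "Cq table")
  stopifnot(length(normalizers) == 2)
  eff <- function(a) {
    e <- if (!is.null(efficiency) && a %in% names(efficiency)) efficiency[[a]]
         else default_efficiency
    if (e <= 1 || e > 2) stop("efficiency for ", a, " must be in (1, 2]",
                              call. = FALSE)
    e
  }
  mean_cq <- function(a, s) {
    v <- cq$cq[cq$assay == a & cq$sample_id == s]
    if (length(v) == 0) return(NA_real_)
    mean(v)
  }
  for (a in c(target, normalizers)) {
    if (is.na(mean_cq(a, control_sample))) {
      stop("control sample is missing assay ", a, call. = FALSE)
    }
  }
  samples <- setdiff(unique(cq$sample_id), control_sample)
  rq <- vapply(samples, function(s) {
    ct <- mean_cq(target, s)
    if (is.na(ct)) return(NA_real_)
    num <- eff(target)^(mean_cq(target, control_sample) - ct)
    ref <- vapply(normalizers, function(a) {
      cs <- mean_cq(a, s)
      if (is.na(cs)) stop("sample ", s, " is missing normalizer ", a,
                          call. = FALSE)
      eff(a)^(mean_cq(a, control_sample) - cs)
    }, numeric(1))
    num / exp(mean(log(ref)))
  }, numeric(1))
  out <- data.frame(sample_id = samples, rq = rq, row.names = NULL,
                    stringsAsFactors = FALSE)
  if ("time_point" %in% names(cq)) {
    out$time_point <- cq$time_point[match(samples, cq$sample_id)]
    out <- out[, c("sample_id", "time_point", "rq")]
  }
  out
}

#' Copy-number status from time-point RQ ratios
#'
#' The ratio of the 2nd and 3rd time point relative quantity to the 1st
#' reveals copy number decrease or increase: status is `loss` when the
#' ratio is at or below `loss_cut` (inclusive boundary), `gain` at or above
#' `gain_cut`, otherwise `no_change`.
#'
#' @param rq_t1,rq_t2,rq_t3 relative quantities at the three time points
#'   (vectors recycle elementwise); `rq_t1` must be positive.
#' @param loss_cut,gain_cut ratio cutoffs (defaults 0.75 and 1.25).
#' @return data.frame with `ratio_t2`, `ratio_t3`, `status_t2`,
#'   `status_t3`.
#' @export
timepoint_ratio_call <- function(rq_t1, rq_t2, rq_t3, loss_cut = 0.75,
                                 gain_cut = 1.25) {
  if (any(rq_t1 <= 0)) stop("rq_t1 must be positive", call. = FALSE)
  call_one <- function(ratio) {
    ifelse(ratio <= loss_cut, "loss",
           ifelse(ratio >= gain_cut, "gain", "no_change"))
  }
  r2 <- rq_t2 / rq_t1
  r3 <- rq_t3 / rq_t1
  data.frame(ratio_t2 = r2, ratio_t3 = r3,
             status_t2 = call_one(r2), status_t3 = call_one(r3),
             stringsAsFactors = FALSE)
}

#' Agreement between qPCR and array status calls
#'
#' @param calls_qpcr,calls_array data.frames with `assay`, `sample_id`,
#'   `time_point`, `status`; pairs are matched on the first three columns.
#' @return percentage of matched pairs with identical status.
#' @export
qpcr_agreement <- function(calls_qpcr, calls_array) {
  for (df in list(calls_qpcr, calls_array)) {
    check_columns(df, c("assay", "sample_id", "time_point", "status"),
                  "status calls")
  }
  key <- function(df) paste(df$assay, df$sample_id, df$time_point,
                            sep = "\r")
  m <- match(key(calls_qpcr), key(calls_array))
  paired <- !is.na(m)
  if (!any(paired)) stop("no (assay, sample, time point) pairs in common",
                         call. = FALSE)
  100 * mean(calls_qpcr$status[paired] == calls_array$status[m[paired]])
}
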