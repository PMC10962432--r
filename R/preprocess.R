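#' Collapse duplicate ELISA readings to their mean
#'
#' Each serum sample is assayed in duplicate; the raw concentration used in
#' all downstream analysis is the arithmetic mean of the two readings
#' (averaged on the raw scale, then log-transformed — not the other way
#' round).
#'
#' @param reading_1,reading_2 non-negative finite raw concentrations
#'   (vectorised).
#' @return numeric vector of raw means.
#' @export
collapse_duplicates <- function(reading_1, reading_2) {
  r <- cbind(reading_1, reading_2)
  if (any(!is.finite(r)) || any(r < 0))
    stop("duplicate readings must be non-negative and finite", call. = FALSE)
  (reading_1 + reading_2) / 2
}

#' ln(y + 1) transform of a raw concentration
#'
#' @param raw_mean non-negative concentration(s).
#' @return `log(raw_mean + 1)`.
#' @export
log_transform <- function(raw_mean) {
  if (any(is.na(raw_mean)) || any(raw_mean < 0))
    stop("`raw_mean` must be non-negative", call. = FALSE)
  log1p(raw_mean)
}

#' Add raw means and log levels to a sample table
#'
#' Convenience wrapper: collapses the duplicate readings and applies the
#' `ln(y+1)` transform, adding `raw_mean` and `log_level` columns.
#'
#' @param samples sample table with `reading_1` and `reading_2` columns.
#' @return the table with `raw_mean` and `log_level` appended.
#' @export
preprocess_samples <- function(samples) {
  samples$raw_mean <- collapse_duplicates(samples$reading_1,
                                          samples$reading_2)
  samples$log_level <- log_transform(samples$raw_mean)
  samples
}

# 68.27th percentile of absolute residuals with a small-sample correction
# n/(n - k); the robust analogue of the residual SD used by robust
# regression + outlier removal procedures (k = 1: location-only fit).
rsdr <- function(resid, k = 1) {
  n <- length(resid)
  if (n <= k) return(NA_real_)
  unname(stats::quantile(abs(resid), 0.6827, type = 7)) * n / (n - k)
}

#' Flag outlying measurements per marker (ROUT-style)
#'
#' Robust outlier identification on the `ln(y+1)` levels of one or more
#' markers. Because each donor contributes only three samples, no
#' regression over time is fit; instead, levels are compared across donors
#' within each clinical time-point class (DB1/DB2/DB3) — the only strata in
#' which donors are directly comparable. The default `"rout"` method is:
#'
#' 1. robust location per time-point class: the median;
#' 2. robust scale: the 68.27th percentile of absolute residuals with an
#'    `n/(n-1)` small-sample correction (RSDR);
#' 3. each residual is converted to a t-like statistic `|r|/RSDR` with
#'    `n - 1` degrees of freedom; the resulting two-sided p values for all
#'    of the marker's samples are Benjamini-Hochberg adjusted and samples
#'    with adjusted p at or below the false-discovery rate `q` are
#'    discoveries (`q = 0` admits none).
#'
#' The `"mad"` alternative flags samples with `|r| > k * MAD` within each
#' time-point class (MAD with the usual 1.4826 consistency constant), a
#' simpler rule useful for sensitivity analysis.
#'
#' A (donor, marker) pair is flagged when any of its samples is a
#' discovery. Markers measured on fewer than `min_donors` donors are not
#' assessed (no flags, with a warning), as are classes whose levels are all
#' identical (zero robust scale).
#'
#' @param samples processed sample table (needs `donor_id`, `marker`,
#'   `timepoint`, `log_level`; see [preprocess_samples()]).
#' @param method `"rout"` (default) or `"mad"`.
#' @param q false-discovery rate for the `"rout"` method (default 0.01).
#' @param k MAD multiplier for the `"mad"` method (default 3.5).
#' @param min_donors minimum donors per marker to attempt flagging.
#' @return data.frame with one row per (donor, marker): `flagged` and the
#'   number of flagged samples `n_flagged_samples`. The method descriptor
#'   is attached as attribute `"method"`.
#' @export
flag_outliers <- function(samples, method = c("rout", "mad"),
                          q = 0.01, k = 3.5, min_donors = 5) {
  method <- match.arg(method)
  if (q < 0 || q > 1) stop("`q` must be in [0, 1]", call. = FALSE)
  if (!"log_level" %in% names(samples))
    stop("`samples` lacks a log_level column; run preprocess_samples()",
         call. = FALSE)
  samples$.flag <- FALSE
  for (m in unique(samples$marker)) {
    im <- which(samples$marker == m)
    sm <- samples[im, ]
    if (length(unique(sm$donor_id)) < min_donors) {
      warning("marker ", m, ": fewer than ", min_donors,
              " donors; no outlier flagging attempted", call. = FALSE)
      next
    }
    resid <- numeric(nrow(sm))
    scale_by_tp <- df_by_tp <- numeric(0)
    for (tp in unique(sm$timepoint)) {
      it <- sm$timepoint == tp
      resid[it] <- sm$log_level[it] - stats::median(sm$log_level[it])
      scale_by_tp[tp] <- if (method == "rout") rsdr(resid[it])
                         else stats::mad(resid[it])
      df_by_tp[tp] <- sum(it) - 1
    }
    if (all(resid == 0)) {
      warning("marker ", m, ": all levels identical within time points; ",
              "no outliers flagged", call. = FALSE)
      next
    }
    sc <- scale_by_tp[sm$timepoint]
    if (method == "rout") {
      tstat <- ifelse(sc > 0, abs(resid) / sc,
                      ifelse(resid == 0, 0, Inf))
      p <- 2 * stats::pt(-tstat, df = pmax(df_by_tp[sm$timepoint], 1))
      padj <- stats::p.adjust(p, method = "BH")
      samples$.flag[im] <- q > 0 & padj <= q
    } else {
      samples$.flag[im] <- ifelse(sc > 0, abs(resid) > k * sc, FALSE)
    }
  }
  agg <- stats::aggregate(.flag ~ donor_id + marker, data = samples,
                          FUN = function(z) c(any = any(z), n = sum(z)))
  flags <- data.frame(donor_id = agg$donor_id, marker = agg$marker,
                      flagged = as.logical(agg$.flag[, "any"]),
                      n_flagged_samples = as.integer(agg$.flag[, "n"]),
                      stringsAsFactors = FALSE)
  flags <- flags[order(flags$donor_id, flags$marker), ]
  rownames(flags) <- NULL
  attr(flags, "method") <- list(name = method,
                                q = if (method == "rout") q else NULL,
                                k = if (method == "mad") k else NULL)
  flags
}

#' Donor-level outlier report and exclusion set
#'
#' Applies the whole-donor exclusion rule: a donor is excluded when at
#' least `threshold` of the measured serum molecules are flagged as
#' outliers for that donor (default 4 of 5). `count_by = "sample"` instead
#' counts individual flagged samples against the threshold — an alternative
#' reading of "results" provided for sensitivity analysis.
#'
#' @param samples processed sample table.
#' @param threshold count of flagged markers (or samples) at or above which
#'   a donor is excluded; must be between 1 and the number of markers
#'   (respectively samples per donor).
#' @param count_by `"marker"` (default) or `"sample"`.
#' @inheritParams flag_outliers
#' @return object of class `outlier_report`: per-pair `flags`, per-donor
#'   `flagged_marker_count`, the `excluded_donors` set, the counting rule,
#'   and the method descriptor.
#' @export
outlier_report <- function(samples, method = c("rout", "mad"),
                           q = 0.01, k = 3.5, threshold = 4,
                           count_by = c("marker", "sample"),
                           min_donors = 5) {
  count_by <- match.arg(count_by)
  n_markers <- length(unique(samples$marker))
  max_thr <- if (count_by == "marker") n_markers
             else n_markers * length(unique(samples$timepoint))
  if (threshold < 1 || threshold > max_thr)
    stop("`threshold` must be in 1..", max_thr, call. = FALSE)
  flags <- flag_outliers(samples, method = method, q = q, k = k,
                         min_donors = min_donors)
  cnt <- if (count_by == "marker") {
    tapply(flags$flagged, flags$donor_id, sum)
  } else {
    tapply(flags$n_flagged_samples, flags$donor_id, sum)
  }
  cnt <- cnt[sort(names(cnt))]
  excluded <- names(cnt)[cnt >= threshold]
  structure(
    list(flags = flags, flagged_marker_count = cnt,
         excluded_donors = excluded, threshold = threshold,
         count_by = count_by, method = attr(flags, "method")),
    class = "outlier_report"
  )
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("Outlier report (", x$method$name, " method): ",
      sum(x$flags$flagged), " flagged (donor, marker) pairs; ",
      length(x$excluded_donors), " donor(s) excluded at threshold ",
      x$threshold, " (", x$count_by, " counting)\n", sep = "")
  if (length(x$excluded_donors))
    cat("Excluded:", paste(x$excluded_donors, collapse = ", "), "\n")
  invisible(x)
}

#' Apply the donor exclusion rule to a sample table
#'
#' Drops every sample row belonging to the donors excluded by an
#' [outlier_report()].
#'
#' @param samples processed sample table.
#' @param report an `outlier_report` (or a character vector of donor ids).
#' @return the sample table without the excluded donors' rows.
#' @export
exclude_outlier_donors <- function(samples, report) {
  ids <- if (inherits(report, "outlier_report")) report$excluded_donors
         else as.character(report)
  samples[!samples$donor_id %in% ids, , drop = FALSE]
}
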