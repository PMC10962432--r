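#' Align samples on the confirmation of brain death
#'
#' Computes the event-relative time `t_rel` of every sample as its clock
#' time minus the donor's brain-death confirmation time, so that DB2
#' (confirmation after the second brain-stem test) sits at exactly t = 0 in
#' every donor — the only clinically determined time point comparable
#' across donors. DB2 rows are forced to exactly 0 to avoid rounding
#' residue; provenance flags (such as an imputed DB1 admission time) are
#' carried through.
#'
#' @param samples sample table with `donor_id`, `timepoint`, `t_sample`.
#' @param donors donor table with `donor_id` and `t_bd_confirm`.
#' @return the sample table with a `t_rel` column (hours).
#' @export
align_to_bd <- function(samples, donors) {
  miss <- setdiff(unique(samples$donor_id), donors$donor_id)
  if (length(miss))
    stop("samples reference donors absent from the donor table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  no_anchor <- setdiff(unique(samples$donor_id),
                       unique(samples$donor_id[samples$timepoint == "DB2"]))
  if (length(no_anchor))
    stop("donor(s) without a DB2 anchor sample: ",
         paste(no_anchor, collapse = ", "), call. = FALSE)
  anchor <- donors$t_bd_confirm[match(samples$donor_id, donors$donor_id)]
  samples$t_rel <- samples$t_sample - anchor
  samples$t_rel[samples$timepoint == "DB2"] <- 0
  samples
}

# Moving-median of one marker's aligned samples over the evaluation grid.
# Strict pre/post separation: samples at t_rel = 0 contribute only to the
# t = 0 estimate; window boundaries are closed (|t_rel - t| <= W/2).
mov_median_one <- function(t_rel, log_level, grid, window_width,
                           min_window_n, post_window) {
  half <- window_width / 2
  med <- n_in <- numeric(length(grid))
  for (i in seq_along(grid)) {
    t0 <- grid[i]
    inw <- if (t0 < 0) {
      t_rel < 0 & abs(t_rel - t0) <= half
    } else if (t0 == 0) {
      t_rel == 0
    } else if (post_window == "centered") {
      t_rel > 0 & abs(t_rel - t0) <= half
    } else {
      t_rel > 0 & t_rel <= t0 & t_rel >= t0 - window_width
    }
    n_in[i] <- sum(inw)
    med[i] <- if (n_in[i] > 0 && (t0 == 0 || n_in[i] >= min_window_n))
      stats::median(log_level[inw]) else NA_real_
  }
  data.frame(t = grid, median = med, n = as.integer(n_in))
}

#' Event-aligned moving-median time courses
#'
#' Reconstructs, for each serum marker, a global time course over the
#' cohort by replacing the level at each grid time `t` with the median of
#' all donors' levels inside a `window_width`-hour window — using only
#' samples taken before the event for `t < 0`, only samples taken after the
#' event for `t > 0`, and for `t = 0` the median of all samples collected
#' at that clinical time point. This asymmetric windowing combines sparse
#' per-donor trajectories (three samples each, at donor-specific times)
#' into one trajectory per marker under the soft assumption that donors
#' follow qualitatively similar time courses.
#'
#' Grid medians supported by fewer than `min_window_n` samples are reported
#' as `NA` (with the occupancy still recorded), so sparsely covered stretches
#' of the timeline are not presented as trends. Even-count windows use the
#' midpoint of the two central order statistics.
#'
#' @param samples aligned, processed sample table (`marker`, `donor_id`,
#'   `t_rel`, `log_level`; see [align_to_bd()], [preprocess_samples()]).
#' @param window_width moving-window width in hours (default 20).
#' @param grid_step evaluation grid step in hours (default 1).
#' @param pre_extent,post_extent hours covered before (default 20) and
#'   after (default 40) the event.
#' @param min_window_n minimum window occupancy for a defined median
#'   (default 3; the t = 0 estimate is exempt).
#' @param post_window `"centered"` (default; `|t_rel - t| <= W/2`) or
#'   `"trailing"` (`t - W <= t_rel <= t`) windows for the post-event
#'   segment.
#' @param markers markers to fit (default: all in `samples`).
#' @return object of class `bd_timecourse`: per-marker grids of medians
#'   with occupancy counts, the value at t = 0, the aligned samples, and
#'   the configuration.
#' @seealso [classify_trend()], [predict.bd_timecourse()],
#'   [plot.bd_timecourse()]
#' @export
bd_timecourse <- function(samples, window_width = 20, grid_step = 1,
                          pre_extent = 20, post_extent = 40,
                          min_window_n = 3,
                          post_window = c("centered", "trailing"),
                          markers = NULL) {
  post_window <- match.arg(post_window)
  stopifnot(window_width > 0, grid_step > 0, pre_extent > 0,
            post_extent > 0, min_window_n >= 1)
  if (window_width > 2 * max(pre_extent, post_extent))
    stop("window_width must not exceed twice the larger extent",
         call. = FALSE)
  need <- c("marker", "donor_id", "t_rel", "log_level")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("`samples` lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(markers)) markers <- unique(samples$marker)
  grid <- sort(unique(c(seq(-pre_extent, post_extent, by = grid_step), 0)))

  courses <- list(); v0 <- numeric(0)
  for (m in markers) {
    sm <- samples[samples$marker == m, , drop = FALSE]
    seg <- c(pre = sum(sm$t_rel < 0), event = sum(sm$t_rel == 0),
             post = sum(sm$t_rel > 0))
    if (any(seg == 0))
      stop("marker ", m, ": empty segment(s): ",
           paste(names(seg)[seg == 0], collapse = ", "), call. = FALSE)
    courses[[m]] <- mov_median_one(sm$t_rel, sm$log_level, grid,
                                   window_width, min_window_n, post_window)
    v0[m] <- courses[[m]]$median[courses[[m]]$t == 0]
  }
  structure(
    list(courses = courses, value_at_zero = v0, samples = samples,
         config = list(window_width = window_width, grid_step = grid_step,
                       pre_extent = pre_extent, post_extent = post_extent,
                       min_window_n = min_window_n,
                       post_window = post_window),
         call = match.call()),
    class = "bd_timecourse"
  )
}

#' @export
print.bd_timecourse <- function(x, ...) {
  cfg <- x$config
  cat("Event-aligned moving-median time courses\n")
  cat(sprintf("  %d marker(s), %d donors, window %g h (%s post windows)\n",
              length(x$courses), length(unique(x$samples$donor_id)),
              cfg$window_width, cfg$post_window))
  cat(sprintf("  grid: %g..%g h, step %g h; medians defined at >= %d samples\n",
              -cfg$pre_extent, cfg$post_extent, cfg$grid_step,
              cfg$min_window_n))
  for (m in names(x$courses)) {
    co <- x$courses[[m]]
    cat(sprintf("  %-8s t=0 median %.3f; defined at %d/%d grid points\n",
                m, x$value_at_zero[m], sum(!is.na(co$median)), nrow(co)))
  }
  invisible(x)
}

#' @export
summary.bd_timecourse <- function(object, rel_threshold = 0.15, ...) {
  labs <- classify_trend(object, rel_threshold = rel_threshold)
  tab <- do.call(rbind, lapply(names(object$courses), function(m) {
    co <- object$courses[[m]]
    pre <- co$median[co$t < 0]
    post <- co$median[co$t > 0]
    data.frame(marker = m,
               pre_mean = mean(pre, na.rm = TRUE),
               value_at_zero = object$value_at_zero[m],
               post_mean = mean(post, na.rm = TRUE),
               trend = labs[m], stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(table = tab, config = object$config,
                 rel_threshold = rel_threshold),
            class = "summary.bd_timecourse")
}

#' @export
print.summary.bd_timecourse <- function(x, ...) {
  cat("Moving-median time-course summary (ln(y+1) scale)\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Evaluate a fitted time course at new event-relative times
#'
#' Applies the same asymmetric windowing rules as [bd_timecourse()] to the
#' stored samples at arbitrary times, so the moving median can be read off
#' between grid points.
#'
#' @param object a `bd_timecourse` fit.
#' @param t numeric vector of event-relative times (hours).
#' @param marker marker name (default: first fitted marker).
#' @param ... unused.
#' @return numeric vector of medians (`NA` where occupancy is below the
#'   fit's `min_window_n`).
#' @export
predict.bd_timecourse <- function(object, t, marker = names(object$courses)[1],
                                  ...) {
  sm <- object$samples[object$samples$marker == marker, , drop = FALSE]
  if (!nrow(sm)) stop("unknown marker: ", marker, call. = FALSE)
  cfg <- object$config
  mov_median_one(sm$t_rel, sm$log_level, t, cfg$window_width,
                 cfg$min_window_n, cfg$post_window)$median
}

#' @export
fitted.bd_timecourse <- function(object, ...) {
  out <- numeric(nrow(object$samples))
  for (m in names(object$courses)) {
    idx <- object$samples$marker == m
    out[idx] <- predict(object, object$samples$t_rel[idx], marker = m)
  }
  out
}

#' @export
residuals.bd_timecourse <- function(object, ...) {
  object$samples$log_level - fitted(object)
}

#' Classify the qualitative trend of a reconstructed time course
#'
#' Compares segment summaries of the moving-median curve — the mean of
#' defined pre-event medians, the value at t = 0, and the means of the
#' early and late halves of the defined post-event medians — and assigns
#' one of four labels:
#'
#' * `declining` — the curve falls from before the event through the end
#'   of donor management (late-post mean below the pre mean by more than
#'   the threshold, with the fall already under way at t = 0);
#' * `plateau_then_decline` — level around the event, with the decline
#'   confined to the post-event segment;
#' * `step_increase` — a jump at t = 0 to a sustained higher level;
#' * `constant_elevated` — none of the above: no change beyond the
#'   threshold.
#'
#' `rel_threshold` is a fraction of the marker's overall level (the mean
#' absolute defined median on the ln scale), so the rule adapts to markers
#' of different magnitudes; the comparisons happen on the `ln(y+1)` scale.
#'
#' @param x a `bd_timecourse` fit.
#' @param rel_threshold fraction of the overall level a segment difference
#'   must exceed to count as a change (default 0.15).
#' @param ... passed to methods.
#' @return named character vector of labels, one per marker.
#' @export
classify_trend <- function(x, rel_threshold = 0.15, ...) {
  UseMethod("classify_trend")
}

#' @export
classify_trend.bd_timecourse <- function(x, rel_threshold = 0.15, ...) {
  out <- vapply(names(x$courses), function(m)
    classify_course(x$courses[[m]], x$value_at_zero[m], rel_threshold),
    character(1))
  names(out) <- names(x$courses)
  out
}

classify_course <- function(course, value_at_zero, rel_threshold) {
  pre <- course[course$t < 0 & !is.na(course$median), , drop = FALSE]
  post <- course[course$t > 0 & !is.na(course$median), , drop = FALSE]
  if (nrow(pre) < 3 || nrow(post) < 3)
    stop("insufficient defined grid points for trend classification ",
         "(need >= 3 pre and >= 3 post)", call. = FALSE)
  m_pre <- mean(pre$median)
  split <- stats::median(post$t)
  m_early <- mean(post$median[post$t <= split])
  m_late <- mean(post$median[post$t > split])
  if (!is.finite(m_late)) m_late <- m_early  # single defined post point tail

  level_scale <- mean(abs(c(pre$median, value_at_zero, post$median)))
  thr <- rel_threshold * max(level_scale, .Machine$double.eps)
  total <- m_late - m_pre
  d_zero <- value_at_zero - m_pre
  d_early <- m_early - m_pre

  if (total < -thr) {
    if (d_zero < -thr) "declining" else "plateau_then_decline"
  } else if (d_zero > thr && d_early > thr && total > thr) {
    "step_increase"
  } else {
    "constant_elevated"
  }
}
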