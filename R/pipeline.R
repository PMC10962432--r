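#' Simulate a donor panel with the prescribed block design
#'
#' Draws a panel whose brain-death durations follow the study's stratified
#' design: `n_short` donors below 10 h, `group_size` donors in each of the
#' four core 5-h blocks (10-15, 15-20, 20-25, 25-30 h), and `n_long` donors
#' above 30 h — 27 donors with the defaults. Optionally injects
#' whole-donor outliers; with three outliers they are placed as one donor
#' in the 25-30 h block and two in the long-duration extreme, the
#' configuration in which the donor-level exclusion rule is typically
#' exercised.
#'
#' @param seed integer root seed (durations use `seed + 1`, the panel
#'   itself `seed`).
#' @param group_size donors per core 5-h block (default 5).
#' @param n_short,n_long donors in the short (< 10 h) and long (> 30 h)
#'   extremes (defaults 2 and 5).
#' @param extreme_range hours, `c(min, max)` limits for the short/long
#'   extreme durations (default 2 and 40).
#' @param n_outlier_donors whole-donor outliers to inject (default 0).
#' @param ... further arguments passed to [synthetic_config()] (noise,
#'   donor effect, shapes, ...).
#' @return a panel list as from [simulate_donor_panel()]; when outliers are
#'   injected, their donor ids are in `$outlier_donor_ids`.
#' @export
simulate_study_panel <- function(seed = 1L, group_size = 5, n_short = 2,
                                 n_long = 5, extreme_range = c(2, 40),
                                 n_outlier_donors = 0, ...) {
  n <- n_short + 4 * group_size + n_long
  durations <- with_seed(seed + 1L, c(
    runif(n_short, extreme_range[1], 10),
    runif(group_size, 10, 15), runif(group_size, 15, 20),
    runif(group_size, 20, 25), runif(group_size, 25, 30),
    runif(n_long, 30, extreme_range[2])
  ))
  cfg <- synthetic_config(n_donors = n, bd_durations = durations,
                          seed = seed, ...)
  panel <- simulate_donor_panel(cfg)
  if (n_outlier_donors > 0) {
    # mirror the usual exclusion pattern: oldest-block donors first
    block_2530 <- utils::tail(which(durations >= 25 & durations < 30), 1)
    long_ids <- utils::tail(which(durations >= 30), n_outlier_donors)
    pick <- unique(c(block_2530, rev(long_ids)))[seq_len(
      min(n_outlier_donors, n))]
    ids <- panel$donors$donor_id[sort(pick)]
    panel$samples <- inject_outlier_donors(
      panel$samples, ids, magnitude = cfg$outlier_magnitude,
      markers_affected = cfg$outlier_markers_affected)
    panel$outlier_donor_ids <- ids
  }
  panel
}

#' Write a simulated panel to CSV files
#'
#' @param panel a panel from [simulate_donor_panel()].
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths. The configuration (including
#'   the seed) is recorded alongside as JSON.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(donors = file.path(dir, "donors.csv"),
             samples = file.path(dir, "samples.csv"),
             config = file.path(dir, "panel_config.json"))
  utils::write.csv(panel$donors, paths["donors"], row.names = FALSE)
  utils::write.csv(panel$samples, paths["samples"], row.names = FALSE)
  cfg <- panel$config
  cfg$marker_shapes <- lapply(cfg$marker_shapes, unclass)
  jsonlite::write_json(unclass(cfg), paths["config"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

default_pipeline_config <- function() {
  list(
    simulate = list(design = "study", group_size = 5, n_short = 2,
                    n_long = 5, n_outlier_donors = 0,
                    outlier_magnitude = 6, outlier_markers_affected = 5,
                    noise_sd = 0.3, donor_effect_sd = 0.3,
                    duplicate_cv = 0.1, missing_db1_time_fraction = 6 / 27,
                    n_donors = 24),
    cohort = list(group_size = 5,
                  covariates = c("age", "bmi", "sex", "hypertension",
                                 "diabetes")),
    preprocess = list(method = "rout", q = 0.01, threshold = 4,
                      count_by = "marker"),
    timecourse = list(window_width = 20, grid_step = 1, pre_extent = 20,
                      post_extent = 40, min_window_n = 3,
                      post_window = "centered", rel_threshold = 0.15),
    report = list(figures = TRUE, format = "png")
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]]))
      merge_config(base[[nm]], user[[nm]]) else user[[nm]]
  }
  base
}

#' Run the full time-course pipeline
#'
#' Orchestrates simulate/ingest, cohort construction, preprocessing with
#' donor-level outlier exclusion, moving-median time-course reconstruction
#' and trend classification, and reporting, from a single configuration
#' and root seed. All stage outputs are written under `outdir` and a run
#' manifest (configuration snapshot, seed, stage donor counts, output file
#' digests, package version) is written last; stage failures abort with
#' the stage name, leaving earlier artifacts intact. Per-stage randomness
#' is derived from the root seed (simulation: `seed`; study-design
#' durations: `seed + 1`; cohort selection: `seed + 2`), so a rerun with
#' the same configuration and seed reproduces every CSV byte-identically.
#'
#' @param outdir output directory (created if absent).
#' @param config a nested list overriding parts of the default
#'   configuration, or the path of a YAML/JSON file containing one. Blocks:
#'   `simulate` (design `"study"` or `"uniform"`, sizes, noise, outlier
#'   injection), `cohort` (group size, covariates), `preprocess` (method,
#'   `q`, exclusion threshold), `timecourse` (window, grid, extents),
#'   `report` (figures on/off).
#' @param seed integer root seed.
#' @param simulate if `FALSE`, read `donors_file`/`samples_file` instead of
#'   simulating.
#' @param donors_file,samples_file CSV inputs for `simulate = FALSE`.
#' @return invisibly, the run manifest (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(outdir, config = list(), seed = 1L,
                         simulate = TRUE, donors_file = NULL,
                         samples_file = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- merge_config(default_pipeline_config(), config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  counts <- integer(0)

  # -- simulate / ingest ----------------------------------------------------
  panel <- stage("ingest", {
    if (simulate) {
      sc <- cfg$simulate
      if (identical(sc$design, "study")) {
        simulate_study_panel(seed = seed, group_size = sc$group_size,
                             n_short = sc$n_short, n_long = sc$n_long,
                             n_outlier_donors = sc$n_outlier_donors,
                             outlier_magnitude = sc$outlier_magnitude,
                             outlier_markers_affected = sc$outlier_markers_affected,
                             noise_sd = sc$noise_sd,
                             donor_effect_sd = sc$donor_effect_sd,
                             duplicate_cv = sc$duplicate_cv,
                             missing_db1_time_fraction = sc$missing_db1_time_fraction)
      } else {
        simulate_donor_panel(synthetic_config(
          n_donors = sc$n_donors, noise_sd = sc$noise_sd,
          donor_effect_sd = sc$donor_effect_sd,
          duplicate_cv = sc$duplicate_cv,
          missing_db1_time_fraction = sc$missing_db1_time_fraction,
          n_outlier_donors = sc$n_outlier_donors,
          outlier_magnitude = sc$outlier_magnitude,
          outlier_markers_affected = sc$outlier_markers_affected,
          seed = seed))
      }
    } else {
      for (f in c(donors_file, samples_file))
        if (is.null(f) || !file.exists(f))
          stop("input file missing: ", if (is.null(f)) "(unset)" else f)
      list(donors = utils::read.csv(donors_file, stringsAsFactors = FALSE),
           samples = utils::read.csv(samples_file, stringsAsFactors = FALSE))
    }
  })
  write_panel(c(panel[c("donors", "samples")],
                list(config = panel$config %||% list())), outdir)
  counts["input"] <- nrow(panel$donors)

  # -- cohort ---------------------------------------------------------------
  cohort <- stage("build-cohort", {
    elig <- apply_inclusion_exclusion(panel$donors, panel$samples)
    sel <- select_balanced(elig$eligible, covariates = cfg$cohort$covariates,
                           group_size = cfg$cohort$group_size,
                           seed = seed + 2L)
    list(eligible = elig$eligible, audit = elig$audit, definition = sel)
  })
  counts["eligible"] <- nrow(cohort$eligible)
  counts["cohort"] <- length(cohort$definition$selected_donor_ids)
  jsonlite::write_json(
    list(audit = cohort$audit,
         selected_donor_ids = cohort$definition$selected_donor_ids,
         block_assignment = cohort$definition$block_assignment,
         balance_stats = cohort$definition$balance_stats),
    file.path(outdir, "cohort.json"), auto_unbox = TRUE, digits = NA)

  # -- preprocess -----------------------------------------------------------
  pp <- stage("preprocess", {
    sel_ids <- cohort$definition$selected_donor_ids
    s <- panel$samples[panel$samples$donor_id %in% sel_ids, , drop = FALSE]
    s <- preprocess_samples(s)
    rep <- outlier_report(s, method = cfg$preprocess$method,
                          q = cfg$preprocess$q,
                          threshold = cfg$preprocess$threshold,
                          count_by = cfg$preprocess$count_by)
    list(samples = exclude_outlier_donors(s, rep), report = rep)
  })
  counts["post_exclusion"] <- length(unique(pp$samples$donor_id))
  jsonlite::write_json(
    list(method = pp$report$method, threshold = pp$report$threshold,
         count_by = pp$report$count_by,
         flagged_marker_count = as.list(pp$report$flagged_marker_count),
         excluded_donors = pp$report$excluded_donors),
    file.path(outdir, "outlier_report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(pp$samples, file.path(outdir, "processed_samples.csv"),
                   row.names = FALSE)

  # -- timecourse -----------------------------------------------------------
  fit <- stage("timecourse", {
    aligned <- align_to_bd(pp$samples, panel$donors)
    tc <- cfg$timecourse
    bd_timecourse(aligned, window_width = tc$window_width,
                  grid_step = tc$grid_step, pre_extent = tc$pre_extent,
                  post_extent = tc$post_extent,
                  min_window_n = tc$min_window_n,
                  post_window = tc$post_window)
  })
  long <- do.call(rbind, lapply(names(fit$courses), function(m)
    cbind(marker = m, fit$courses[[m]])))
  utils::write.csv(long, file.path(outdir, "timecourse.csv"),
                   row.names = FALSE)
  trends <- stage("report", classify_trend(fit, cfg$timecourse$rel_threshold))
  jsonlite::write_json(as.list(trends), file.path(outdir, "trends.json"),
                       auto_unbox = TRUE)
  figures <- character(0)
  if (isTRUE(cfg$report$figures))
    figures <- stage("report",
                     plot_timecourses(fit, outdir,
                                      format = cfg$report$format))

  # -- manifest -------------------------------------------------------------
  outputs <- c(file.path(outdir, c("donors.csv", "samples.csv",
                                   "processed_samples.csv", "cohort.json",
                                   "outlier_report.json", "timecourse.csv",
                                   "trends.json")), figures)
  manifest <- list(
    package_version = as.character(utils::packageVersion("bdtrace")),
    seed = seed,
    simulate = simulate,
    config = cfg,
    stage_donor_counts = as.list(counts),
    excluded_donors = pp$report$excluded_donors,
    trends = as.list(trends),
    outputs = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-panel time-course figures per marker
#'
#' For each fitted marker, writes a figure with (A) the individual donor
#' three-point trajectories on the `ln(y+1)` axis, connected per donor,
#' and (B) the reconstructed moving-median time course with shading where
#' the window occupancy is below the defined minimum. A time course that is
#' undefined everywhere is rendered as an annotated empty panel rather
#' than an error.
#'
#' @param fit a [bd_timecourse()] object.
#' @param outdir directory for the figure files.
#' @param format `"png"` or `"svg"`.
#' @param width,height device size in inches.
#' @return invisibly, the written file paths.
#' @export
plot_timecourses <- function(fit, outdir, format = c("png", "svg"),
                             width = 9, height = 4) {
  format <- match.arg(format)
  if (!length(fit$courses)) stop("no fitted markers to plot", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (m in names(fit$courses)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", m)
    path <- file.path(outdir, paste0("timecourse_", safe, ".", format))
    if (format == "png")
      grDevices::png(path, width = width, height = height, units = "in",
                     res = 150)
    else grDevices::svg(path, width = width, height = height)
    op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2.5, 1))
    plot(fit, marker = m)
    graphics::par(op)
    grDevices::dev.off()
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Plot one marker's donor trajectories and moving-median time course
#'
#' Draws panels A (individual donor trajectories) and B (moving median) on
#' the current device; [plot_timecourses()] wraps this per marker into
#' figure files.
#'
#' @param x a `bd_timecourse` fit.
#' @param marker marker to draw (default: first fitted marker).
#' @param ... unused.
#' @export
plot.bd_timecourse <- function(x, marker = names(x$courses)[1], ...) {
  if (!marker %in% names(x$courses))
    stop("unknown marker: ", marker, call. = FALSE)
  sm <- x$samples[x$samples$marker == marker, , drop = FALSE]
  co <- x$courses[[marker]]
  ylim <- range(c(sm$log_level, co$median), na.rm = TRUE, finite = TRUE)

  plot(NA, xlim = range(co$t), ylim = ylim, xlab = "time since BD (h)",
       ylab = "ln(level + 1)", main = paste0(marker, " — donors (A)"))
  graphics::abline(v = 0, lty = 3, col = "grey50")
  for (d in unique(sm$donor_id)) {
    sd_ <- sm[sm$donor_id == d, , drop = FALSE]
    sd_ <- sd_[order(sd_$t_rel), , drop = FALSE]
    graphics::lines(sd_$t_rel, sd_$log_level, col = "grey60")
    graphics::points(sd_$t_rel, sd_$log_level, pch = 16, cex = 0.6,
                     col = "grey30")
  }

  plot(NA, xlim = range(co$t), ylim = ylim, xlab = "time since BD (h)",
       ylab = "ln(level + 1)", main = paste0(marker, " — moving median (B)"))
  graphics::abline(v = 0, lty = 3, col = "grey50")
  if (all(is.na(co$median))) {
    graphics::text(mean(range(co$t)), mean(ylim),
                   "time course undefined everywhere\n(window occupancy below minimum)")
  } else {
    low <- co$n < x$config$min_window_n & co$t != 0
    if (any(low))
      graphics::rug(co$t[low], side = 1, col = "tomato")
    for (side in list(co[co$t < 0, ], co[co$t >= 0, ]))
      graphics::lines(side$t, side$median, lwd = 2, col = "steelblue4")
    graphics::points(0, x$value_at_zero[marker], pch = 18, cex = 1.2,
                     col = "steelblue4")
  }
  invisible(x)
}
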