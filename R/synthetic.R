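#' Configuration for the synthetic donor-panel generator
#'
#' Bundles and validates every knob of the simulator. Defaults describe the
#' study conditions the analysis is designed for: a cohort of two dozen
#' brain-dead donors dying of intracranial haemorrhage, three serum samples
#' per donor anchored at confirmation of brain death (admission DB1,
#' confirmation DB2 at t = 0, end of donor management DB3), brain-death
#' durations of 10-30 h, five markers with distinct qualitative shapes,
#' log-scale measurement noise, a shared per-donor random intercept,
#' duplicate ELISA readings, and a share of donors whose admission
#' (DB1) clock time is imputed from transport records rather than measured.
#'
#' @param n_donors number of donors to simulate (>= 1).
#' @param bd_duration_range hours, `c(min, max)` of brain-death duration
#'   (confirmation to organ recovery); durations drawn uniformly.
#' @param admission_lead_range hours before t = 0 at which the admission
#'   sample is drawn (uniform); DB1 time is `-lead`.
#' @param marker_shapes named list of [shape_params()], one per marker.
#' @param noise_sd measurement noise SD in ln units, applied per sample on
#'   the `ln(y+1)` scale (multiplicative on the raw scale).
#' @param donor_effect_sd SD (ln units) of a per-donor random intercept
#'   shared across all markers of that donor, so that anomalous donors are
#'   whole-donor anomalies.
#' @param duplicate_cv coefficient of variation of the two raw duplicate
#'   readings around their mean (symmetric split; the mean is preserved
#'   exactly).
#' @param missing_db1_time_fraction fraction in `[0, 1]` of donors whose DB1
#'   clock time is flagged as imputed (the value is still present; only the
#'   provenance flag is set).
#' @param n_outlier_donors number of whole-donor outliers to inject after
#'   generation (see [inject_outlier_donors()]); 0 leaves the panel clean.
#' @param outlier_magnitude ln-unit shift applied to injected outliers.
#' @param outlier_markers_affected number of markers (1..number of markers)
#'   shifted in each injected outlier donor; default: all of them.
#' @param age_bd_r target Pearson correlation between donor age and
#'   brain-death duration (negative: older donors get shorter management,
#'   reflecting clinical decision-making).
#' @param seed integer seed; identical configurations with identical seeds
#'   give bit-identical panels.
#' @param bd_durations optional numeric vector of length `n_donors` of
#'   explicit brain-death durations (hours, all positive), overriding the
#'   uniform draw from `bd_duration_range` — used to build cohorts with a
#'   prescribed block design.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_donors = 24,
                             bd_duration_range = c(10, 30),
                             admission_lead_range = c(2, 20),
                             marker_shapes = default_marker_shapes(),
                             noise_sd = 0.3,
                             donor_effect_sd = 0.3,
                             duplicate_cv = 0.1,
                             missing_db1_time_fraction = 6 / 27,
                             n_outlier_donors = 0,
                             outlier_magnitude = 6,
                             outlier_markers_affected = NULL,
                             age_bd_r = -0.57,
                             seed = 1L,
                             bd_durations = NULL) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(is.numeric(n_donors) && length(n_donors) == 1L && n_donors >= 1 &&
        n_donors == round(n_donors), "`n_donors` must be an integer >= 1")
  chk(is.numeric(bd_duration_range) && length(bd_duration_range) == 2L &&
        bd_duration_range[1] < bd_duration_range[2] &&
        bd_duration_range[1] >= 0,
      "`bd_duration_range` must be c(min, max) with 0 <= min < max")
  chk(is.numeric(admission_lead_range) && length(admission_lead_range) == 2L &&
        admission_lead_range[1] > 0 &&
        admission_lead_range[1] <= admission_lead_range[2],
      "`admission_lead_range` must be c(min, max) with 0 < min <= max")
  chk(is.list(marker_shapes) && length(marker_shapes) >= 1 &&
        !is.null(names(marker_shapes)) &&
        all(vapply(marker_shapes, inherits, logical(1), "shape_params")),
      "`marker_shapes` must be a named list of shape_params objects")
  for (nm in c("noise_sd", "donor_effect_sd", "duplicate_cv"))
    chk(is.numeric(get(nm)) && length(get(nm)) == 1L && get(nm) >= 0,
        paste0("`", nm, "` must be a single non-negative number"))
  chk(is.numeric(missing_db1_time_fraction) &&
        missing_db1_time_fraction >= 0 && missing_db1_time_fraction <= 1,
      "`missing_db1_time_fraction` must be in [0, 1]")
  chk(n_outlier_donors >= 0 && n_outlier_donors <= n_donors,
      "`n_outlier_donors` must be in 0..n_donors")
  if (is.null(outlier_markers_affected))
    outlier_markers_affected <- length(marker_shapes)
  chk(outlier_markers_affected >= 1 &&
        outlier_markers_affected <= length(marker_shapes),
      "`outlier_markers_affected` must be in 1..number of markers")
  chk(is.numeric(age_bd_r) && abs(age_bd_r) <= 1, "`age_bd_r` must be in [-1, 1]")
  chk(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
      "`seed` must be a single integer")
  if (!is.null(bd_durations))
    chk(is.numeric(bd_durations) && length(bd_durations) == n_donors &&
          all(is.finite(bd_durations)) && all(bd_durations > 0),
        "`bd_durations` must be n_donors positive durations")
  structure(
    list(n_donors = as.integer(n_donors),
         bd_duration_range = bd_duration_range,
         admission_lead_range = admission_lead_range,
         marker_shapes = marker_shapes,
         noise_sd = noise_sd, donor_effect_sd = donor_effect_sd,
         duplicate_cv = duplicate_cv,
         missing_db1_time_fraction = missing_db1_time_fraction,
         n_outlier_donors = as.integer(n_outlier_donors),
         outlier_magnitude = outlier_magnitude,
         outlier_markers_affected = as.integer(outlier_markers_affected),
         age_bd_r = age_bd_r,
         seed = as.integer(seed),
         bd_durations = bd_durations),
    class = "synthetic_config"
  )
}

# Run `expr` under the config seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

#' Simulate a donor metadata table and a serum sample table
#'
#' Generates `n_donors` donors and, for each donor and marker, three sample
#' rows labelled DB1/DB2/DB3 at event-relative times `-lead < 0`, `0`, and
#' `bd_duration > 0`. Observed log levels are
#' `trajectory_value(shape, t) + donor intercept + noise`; the raw
#' concentration is recovered as `exp(level) - 1` (floored at a tiny
#' positive value so duplicate readings are strictly positive) and split
#' into two duplicate readings symmetric around that mean. Donor age is
#' drawn anticorrelated with brain-death duration (target correlation
#' `age_bd_r`). If `n_outlier_donors > 0`, the last such donors are passed
#' through [inject_outlier_donors()] with the configured magnitude.
#'
#' Clock times are hours on an arbitrary admission week; `t_sample` carries
#' the clock time of each sample so that event alignment
#' ([align_to_bd()]) can recompute event-relative times from timestamps.
#'
#' @param config a [synthetic_config()] object.
#' @return list with elements `donors` (one row per donor: demographics,
#'   comorbidities, clinical timestamps, derived `bd_duration`, the donor
#'   random intercept as simulation truth, and provenance flags) and
#'   `samples` (one row per donor x marker x time point: duplicate raw
#'   readings and clock time), plus the `config` used.
#' @export
simulate_donor_panel <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop("`config` must be a synthetic_config object", call. = FALSE)
  with_seed(config$seed, {
    n <- config$n_donors
    markers <- names(config$marker_shapes)

    bd_duration <- if (is.null(config$bd_durations))
      runif(n, config$bd_duration_range[1], config$bd_duration_range[2])
    else config$bd_durations
    lead <- runif(n, config$admission_lead_range[1],
                  config$admission_lead_range[2])
    # age anticorrelated with BD duration: Gaussian copula-style construction
    z_bd <- as.numeric(scale(bd_duration))
    if (any(!is.finite(z_bd))) z_bd <- rep(0, n)  # degenerate: zero variance
    r <- config$age_bd_r
    age <- round(pmin(pmax(
      52 + 13 * (r * z_bd + sqrt(max(0, 1 - r^2)) * rnorm(n)), 18), 85))
    donors <- data.frame(
      donor_id = sprintf("D%03d", seq_len(n)),
      age = age,
      sex = sample(c("M", "F"), n, replace = TRUE),
      bmi = round(pmin(pmax(rnorm(n, 27, 5), 17), 45), 1),
      hypertension = runif(n) < 0.3,
      diabetes = runif(n) < 0.15,
      cause_of_death = "ICH",
      consent = TRUE,
      systemic_inflammation = FALSE,
      t_bd_confirm = round(runif(n, 24, 144), 2),
      stringsAsFactors = FALSE
    )
    donors$t_admission <- donors$t_bd_confirm - lead
    donors$t_recovery <- donors$t_bd_confirm + bd_duration
    donors$bd_duration <- bd_duration
    donors$db1_time_imputed <- FALSE
    n_imp <- round(config$missing_db1_time_fraction * n)
    if (n_imp > 0)
      donors$db1_time_imputed[sample.int(n, n_imp)] <- TRUE
    donors$donor_effect <- rnorm(n, 0, config$donor_effect_sd)
    donors$has_full_sample_set <- TRUE

    tp <- c("DB1", "DB2", "DB3")
    grid <- expand.grid(timepoint = tp, marker = markers,
                        donor = seq_len(n), stringsAsFactors = FALSE)
    grid <- grid[, c("donor", "marker", "timepoint")]
    t_rel <- ifelse(grid$timepoint == "DB1", -lead[grid$donor],
                    ifelse(grid$timepoint == "DB2", 0, bd_duration[grid$donor]))
    truth <- numeric(nrow(grid))
    for (m in markers) {
      idx <- grid$marker == m
      truth[idx] <- trajectory_value(config$marker_shapes[[m]], t_rel[idx])
    }
    level <- truth + donors$donor_effect[grid$donor] +
      rnorm(nrow(grid), 0, config$noise_sd)
    raw <- pmax(expm1(level), 1e-9)
    d <- pmin(pmax(rnorm(nrow(grid), 0, config$duplicate_cv), -0.99), 0.99)
    samples <- data.frame(
      donor_id = donors$donor_id[grid$donor],
      marker = grid$marker,
      timepoint = grid$timepoint,
      t_sample = donors$t_bd_confirm[grid$donor] + t_rel,
      reading_1 = raw * (1 + d),
      reading_2 = raw * (1 - d),
      db1_time_imputed = grid$timepoint == "DB1" &
        donors$db1_time_imputed[grid$donor],
      stringsAsFactors = FALSE
    )

    panel <- list(donors = donors, samples = samples, config = config)
    if (config$n_outlier_donors > 0) {
      ids <- utils::tail(donors$donor_id, config$n_outlier_donors)
      panel$samples <- inject_outlier_donors(
        panel$samples, ids, magnitude = config$outlier_magnitude,
        markers_affected = config$outlier_markers_affected)
      panel$outlier_donor_ids <- ids
    }
    panel
  })
}

#' Shift selected donors' levels to create whole-donor outliers
#'
#' Adds `magnitude` ln-units to the log level of every sample of the listed
#' donors in the first `markers_affected` markers (in order of appearance in
#' the table). Duplicate readings are rescaled proportionally so their mean
#' equals the shifted concentration; all other rows are returned
#' bit-identical. Used to build fixtures for the donor-level exclusion rule.
#'
#' @param samples a sample table as produced by [simulate_donor_panel()].
#' @param donor_ids character vector of donor ids present in `samples`.
#' @param magnitude shift in ln-units (0 returns the table unchanged).
#' @param markers_affected how many markers to shift (1..number of markers).
#' @return the modified sample table.
#' @export
inject_outlier_donors <- function(samples, donor_ids, magnitude = 6,
                                  markers_affected = 5) {
  missing_ids <- setdiff(donor_ids, samples$donor_id)
  if (length(missing_ids))
    stop("unknown donor id(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  markers <- unique(samples$marker)
  if (markers_affected < 1 || markers_affected > length(markers))
    stop("`markers_affected` must be in 1..", length(markers), call. = FALSE)
  if (magnitude == 0) return(samples)
  affected <- markers[seq_len(markers_affected)]
  idx <- samples$donor_id %in% donor_ids & samples$marker %in% affected
  raw <- (samples$reading_1[idx] + samples$reading_2[idx]) / 2
  new_raw <- expm1(log1p(raw) + magnitude)
  sc <- new_raw / raw
  samples$reading_1[idx] <- samples$reading_1[idx] * sc
  samples$reading_2[idx] <- samples$reading_2[idx] * sc
  samples
}
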