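#' Trajectory shape parameters for a serum marker
#'
#' A `shape_params` object encodes the deterministic "truth" curve of one
#' serum marker on the `ln(y+1)` scale as a function of time relative to
#' confirmation of brain death (t = 0, hours). Four qualitative shapes are
#' supported, matching the trajectory classes the time-course analysis is
#' designed to distinguish:
#'
#' * `"decline"` — linear decline `baseline + slope_pre * t` at all times
#'   (by convention `slope_pre < 0` for a marker falling from admission
#'   to the end of donor management);
#' * `"plateau_decline"` — constant at `baseline` until `plateau_end` hours
#'   after the event, then declining with `slope_post`;
#' * `"constant"` — flat at `baseline` (a constantly elevated marker);
#' * `"step"` — `baseline` before the event, `baseline + step_amplitude`
#'   from t = 0 onward (a step increase at brain-death confirmation).
#'
#' @param shape_kind one of `"decline"`, `"plateau_decline"`, `"constant"`,
#'   `"step"`.
#' @param baseline log-concentration (ln units) before/at the reference level.
#' @param slope_pre slope in ln-units/hour, used by `"decline"`.
#' @param slope_post slope in ln-units/hour after `plateau_end`, used by
#'   `"plateau_decline"`.
#' @param step_amplitude jump in ln-units applied at t = 0; must be 0 for
#'   any shape other than `"step"`.
#' @param plateau_end hours after t = 0 at which the plateau ends
#'   (`"plateau_decline"` only); must be non-negative.
#' @return an object of class `shape_params`.
#' @examples
#' sp <- shape_params("step", baseline = 1, step_amplitude = 2)
#' trajectory_value(sp, c(-5, 0, 5))
#' @export
shape_params <- function(shape_kind = c("decline", "plateau_decline",
                                        "constant", "step"),
                         baseline = 0, slope_pre = 0, slope_post = 0,
                         step_amplitude = 0, plateau_end = 0) {
  shape_kind <- match.arg(shape_kind)
  stopifnot(is.numeric(baseline), length(baseline) == 1L, is.finite(baseline))
  if (!is.finite(plateau_end) || plateau_end < 0)
    stop("`plateau_end` must be a non-negative finite number", call. = FALSE)
  if (shape_kind != "step" && step_amplitude != 0)
    stop("`step_amplitude` must be 0 unless shape_kind = \"step\"",
         call. = FALSE)
  structure(
    list(shape_kind = shape_kind, baseline = baseline,
         slope_pre = slope_pre, slope_post = slope_post,
         step_amplitude = step_amplitude, plateau_end = plateau_end),
    class = "shape_params"
  )
}

#' Evaluate a marker truth curve
#'
#' Deterministic log-concentration of a marker at event-relative time `t`
#' (hours; t = 0 is confirmation of brain death). Vectorised over `t`.
#'
#' @param shape a [shape_params()] object.
#' @param t numeric vector of event-relative times in hours; must be finite.
#' @return numeric vector of log-concentrations (ln units).
#' @export
trajectory_value <- function(shape, t) {
  if (!inherits(shape, "shape_params"))
    stop("`shape` must be a shape_params object", call. = FALSE)
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("`t` must be finite numeric", call. = FALSE)
  switch(shape$shape_kind,
    decline  = shape$baseline + shape$slope_pre * t,
    constant = rep_len(shape$baseline, length(t)),
    step     = shape$baseline + shape$step_amplitude * as.numeric(t >= 0),
    plateau_decline = ifelse(
      t < shape$plateau_end,
      shape$baseline,
      shape$baseline + shape$slope_post * (t - shape$plateau_end)
    ),
    stop("unknown shape_kind: ", shape$shape_kind, call. = FALSE)
  )
}

#' Default marker shapes for the five-marker serum panel
#'
#' The qualitative trajectory classes the panel is built around: TNF-a
#' declining from admission onward; IL-6 plateauing around confirmation of
#' brain death and declining afterwards; complement C5a and neuron-specific
#' enolase (NSE) constantly elevated; glial fibrillary acidic protein (GFAP)
#' stepping up at t = 0. Baselines are in ln units of arbitrary
#' concentration units (the `ln(y+1)` transform is unit-dependent; no
#' physical units are implied).
#'
#' @return named list of [shape_params()] objects, one per marker.
#' @export
default_marker_shapes <- function() {
  list(
    `TNF-a` = shape_params("decline", baseline = 3.0, slope_pre = -0.05),
    `IL-6`  = shape_params("plateau_decline", baseline = 4.0,
                           slope_post = -0.1, plateau_end = 10),
    C5a     = shape_params("constant", baseline = 5.0),
    NSE     = shape_params("constant", baseline = 4.0),
    GFAP    = shape_params("step", baseline = 1.5, step_amplitude = 2.0)
  )
}
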