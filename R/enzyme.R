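#' Spectrophotometric assay conditions
#'
#' Parameters of a chromogenic enzyme assay read by absorbance change:
#' the substrate's molar extinction coefficient, the cuvette path
#' length, reaction and enzyme-aliquot volumes, reaction duration and
#' any dilution of the enzyme prior to assay. The defaults describe a
#' laccase assay with 2,6-dimethoxyphenol monitored at 470 nm
#' (epsilon = 14,800 per molar per cm) over 5 minutes in a 1-mL
#' reaction containing a 0.1-mL enzyme aliquot; volumes and path
#' length are configurable, never hard-coded into results.
#'
#' @param epsilon Molar extinction coefficient, M^-1 cm^-1 (> 0).
#' @param path_length Optical path, cm (> 0).
#' @param reaction_volume Total reaction volume, mL (> 0).
#' @param enzyme_volume Enzyme aliquot volume, mL (> 0, <=
#'   `reaction_volume`).
#' @param duration Reaction time, seconds (> 0).
#' @param dilution Enzyme dilution factor (>= 1).
#' @param wavelength Monitoring wavelength, nm (informational).
#' @return A list of class `assay_conditions`.
#' @export
assay_conditions <- function(epsilon = 14800, path_length = 1,
                             reaction_volume = 1, enzyme_volume = 0.1,
                             duration = 300, dilution = 1,
                             wavelength = 470) {
  if (!is.finite(epsilon) || epsilon <= 0)
    stop("invalid conditions: epsilon must be > 0")
  if (!is.finite(duration) || duration <= 0)
    stop("invalid conditions: duration must be > 0")
  stopifnot(path_length > 0, reaction_volume > 0, enzyme_volume > 0,
            dilution >= 1)
  if (enzyme_volume > reaction_volume)
    stop("enzyme_volume cannot exceed reaction_volume")
  structure(list(epsilon = epsilon, path_length = path_length,
                 reaction_volume = reaction_volume,
                 enzyme_volume = enzyme_volume, duration = duration,
                 dilution = dilution, wavelength = wavelength),
            class = "assay_conditions")
}

#' Enzyme activity in nkat per mL from an absorbance change
#'
#' Beer-Lambert chain: the concentration change is
#' `delta_A / (epsilon * path_length)` mol/L, the product amount in the
#' reaction volume is converted to nmol, divided by the reaction time
#' to give nmol/s (nanokatal), and scaled by dilution per mL of enzyme.
#' One nanokatal converts one nmol of substrate per second.
#'
#' @param delta_A Absorbance change over the reaction (>= 0).
#' @param cond An [assay_conditions()] object.
#' @return Activity in nkat per mL of enzyme.
#' @examples
#' cond <- assay_conditions(epsilon = 14800, duration = 300)
#' activity_nkat_per_ml(0.148, cond)   # 0.333 nkat/mL
#' @export
activity_nkat_per_ml <- function(delta_A, cond) {
  stopifnot(inherits(cond, "assay_conditions"))
  delta_A <- as.numeric(delta_A)
  if (any(delta_A < 0)) stop("delta_A must be >= 0")
  delta_c <- delta_A / (cond$epsilon * cond$path_length)       # mol / L
  nmol <- delta_c * (cond$reaction_volume / 1000) * 1e9        # nmol formed
  rate <- nmol / cond$duration                                 # nmol / s
  rate * cond$dilution / cond$enzyme_volume                    # nkat / mL
}

#' Convert between nanokatal and enzyme units
#'
#' One enzyme unit (U) is 1 umol of substrate per minute, i.e.
#' 1000/60 = 16.667 nkat, so `nkat_to_units(x)` returns `x * 60/1000`
#' and `units_to_nkat()` is its exact inverse.
#'
#' @param x Activity (>= 0), in nkat or U respectively.
#' @return Converted activity.
#' @examples
#' nkat_to_units(18356)   # ~1101 U
#' @export
nkat_to_units <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0)) stop("activity must be >= 0")
  x * 60 / 1000
}

#' @rdname nkat_to_units
#' @export
units_to_nkat <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0)) stop("activity must be >= 0")
  x * 1000 / 60
}

#' Fold change of an activity relative to a baseline
#'
#' @param final Final value (> 0).
#' @param baseline Baseline value (> 0).
#' @return `final / baseline`.
#' @examples
#' fold_change(1514, 24)    # 63.08-fold after stepwise optimization
#' @export
fold_change <- function(final, baseline) {
  if (any(baseline <= 0)) stop("baseline must be > 0")
  as.numeric(final) / as.numeric(baseline)
}

#' Percent reduction or increase relative to a control
#'
#' `direction = "reduction"` returns `100 * (control - treated) /
#' control`; `"increase"` returns `100 * (treated - control) /
#' control`. Used for kappa-number reduction and ISO-brightness
#' increase of treated pulp.
#'
#' @param control Control value (> 0).
#' @param treated Treated value.
#' @param direction `"reduction"` or `"increase"`.
#' @return Percent change.
#' @examples
#' percent_change(12.71, 6.701, "reduction")  # kappa, laccase + mediator
#' percent_change(25, 28, "increase")         # brightness, % ISO
#' @export
percent_change <- function(control, treated,
                           direction = c("reduction", "increase")) {
  direction <- match.arg(direction)
  if (any(control <= 0)) stop("control must be > 0")
  control <- as.numeric(control); treated <- as.numeric(treated)
  if (direction == "reduction") 100 * (control - treated) / control
  else 100 * (treated - control) / control
}

#' Residual-activity profile relative to a reference
#'
#' Expresses each activity in a stability series (e.g. activity after
#' incubation at a range of temperatures or pH values) as a percent of
#' a reference activity: the first entry, the maximum, or an explicit
#' value.
#'
#' @param series Data frame or list with columns/fields `condition` and
#'   `activity`.
#' @param reference `"first"`, `"max"`, or a positive number.
#' @return Data frame with columns `condition`, `activity`, `percent`.
#' @export
residual_activity_profile <- function(series, reference = c("first", "max")) {
  df <- as.data.frame(series)
  stopifnot(all(c("condition", "activity") %in% names(df)))
  if (is.character(reference)) {
    reference <- match.arg(reference)
    ref <- if (reference == "first") df$activity[1L] else max(df$activity)
  } else ref <- as.numeric(reference)
  if (!is.finite(ref) || ref <= 0)
    stop("reference activity must be > 0")
  data.frame(condition = df$condition, activity = df$activity,
             percent = 100 * df$activity / ref)
}
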