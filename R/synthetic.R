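# Seeded generators with known ground truth. Each generator draws from
# its own substream: the user seed is combined with a fixed per-stream
# offset, so adding a generator never perturbs fixtures made by the
# others. Offsets keep derived seeds below 2^31.
.stream_seed <- function(seed, stream) {
  offs <- c(screening = 1000003L, surface = 2000003L, assay = 3000017L)
  (as.integer(seed) %% 1000000000L) + offs[[stream]]
}

#' Simulate responses for a two-level screening design
#'
#' Generates `intercept + sum(effects_i * coded_i / 2) + N(0, noise_sd)`
#' per run. The planted effect is divided by 2 so that the classical
#' contrast-mean estimator ([compute_effects()] with
#' `divisor = "half_N"`) is unbiased for the planted value: moving a
#' factor from -1 to +1 changes the mean response by exactly
#' `effects_i`.
#'
#' @param design A two-level `doe_design`.
#' @param effects Planted effect per factor (response units).
#' @param intercept Baseline mean response.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed; regeneration with identical arguments is
#'   bit-identical.
#' @return Numeric response vector, one value per run.
#' @export
gen_screening_responses <- function(design, effects, intercept = 0,
                                    noise_sd = 0, seed = 1L) {
  stopifnot(inherits(design, "doe_design"))
  effects <- as.numeric(effects)
  if (length(effects) != ncol(design$coded))
    stop("need one planted effect per factor (",
         ncol(design$coded), "), got ", length(effects))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  mu <- intercept + as.numeric(design$coded %*% (effects / 2))
  n <- length(mu)
  noise <- local({
    set.seed(.stream_seed(seed, "screening"))
    stats::rnorm(n, 0, noise_sd)
  })
  mu + noise
}

#' Simulate responses from a known quadratic surface
#'
#' Evaluates a ground-truth [quad_model()] at every coded design point
#' and adds Gaussian noise, mimicking replicate variation around a
#' smooth second-order response surface.
#'
#' @param design A `doe_design` (typically a CCD).
#' @param truth The generating `quad_model`.
#' @param noise_sd Gaussian noise standard deviation (>= 0). The
#'   default 50 matches the replicate-SD scale of typical activity
#'   measurements in the bundled study (about 25-50 nkat/mL across the
#'   whole response range).
#' @param seed Integer seed.
#' @return Numeric response vector.
#' @export
gen_surface_responses <- function(design, truth, noise_sd = 50,
                                  seed = 1L) {
  stopifnot(inherits(design, "doe_design"), inherits(truth, "quad_model"))
  if (truth$k != ncol(design$coded))
    stop("model dimension (", truth$k, ") does not match design (",
         ncol(design$coded), " factors)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  mu <- predict(truth, design$coded)
  noise <- local({
    set.seed(.stream_seed(seed, "surface"))
    stats::rnorm(length(mu), 0, noise_sd)
  })
  mu + noise
}

#' Simulate a linear absorbance time series for a known activity
#'
#' Inverts the Beer-Lambert activity computation: builds the absorbance
#' ramp whose total change over the assay duration back-computes to
#' `true_activity` under [activity_nkat_per_ml()], sampled at
#' `n_points` evenly spaced times, plus Gaussian absorbance noise.
#'
#' @param true_activity Ground-truth activity, nkat per mL (>= 0).
#' @param cond An [assay_conditions()] object.
#' @param n_points Number of time points (>= 2).
#' @param noise_sd Absorbance noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Data frame with columns `time` (s) and `absorbance`.
#' @export
gen_assay_series <- function(true_activity, cond, n_points = 10L,
                             noise_sd = 0, seed = 1L) {
  stopifnot(inherits(cond, "assay_conditions"))
  if (true_activity < 0) stop("true_activity must be >= 0")
  if (n_points < 2L) stop("need at least 2 time points")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  # delta_A producing true_activity over the full duration
  total_dA <- true_activity * cond$enzyme_volume * cond$duration *
    cond$epsilon * cond$path_length /
    (cond$dilution * (cond$reaction_volume / 1000) * 1e9)
  times <- seq(0, cond$duration, length.out = n_points)
  abs0 <- total_dA * times / cond$duration
  noise <- local({
    set.seed(.stream_seed(seed, "assay"))
    stats::rnorm(n_points, 0, noise_sd)
  })
  data.frame(time = times, absorbance = abs0 + noise)
}

#' Serialize a generator's ground truth beside its dataset
#'
#' @param kind `"screening"`, `"surface"` or `"assay"`.
#' @param parameters Planted effects / coefficient list / true
#'   activity.
#' @param noise_sd,seed Generator settings.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(kind, parameters, noise_sd, seed, path) {
  kind <- match.arg(kind, c("screening", "surface", "assay"))
  jsonlite::write_json(list(kind = kind, parameters = parameters,
                            noise_sd = noise_sd, seed = seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
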