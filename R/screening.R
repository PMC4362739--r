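#' Main effects from a two-level screening experiment
#'
#' For each factor i the effect is the difference between the summed
#' responses at its high and low settings,
#' \eqn{E_i = (\Sigma P_{i+} - \Sigma P_{i-}) / N}. With
#' `divisor = "as_printed_N"` the divisor is the total number of runs N;
#' `"half_N"` divides by N/2, giving the classical contrast mean
#' (difference between the high-level and low-level response means).
#' The two conventions differ by the positive constant 2, so signs and
#' rankings are identical; only the magnitude scale changes.
#'
#' @param design A balanced two-level `doe_design` (see
#'   [plackett_burman()]).
#' @param responses Numeric vector, one non-negative response per run.
#' @param divisor `"as_printed_N"` (divide by N, the default) or
#'   `"half_N"` (divide by N/2, the classical effect).
#' @return A data frame of class `effect_estimates` with columns
#'   `factor`, `effect`, `sign`, `rank` (1 = largest `|effect|`) and
#'   `significant` (`NA` until [classify_effects()] is applied).
#' @examples
#' pb <- plackett_burman(4, 8)
#' y <- gen_screening_responses(pb, effects = c(50, 0, -30, 0),
#'                              intercept = 100, noise_sd = 0, seed = 1)
#' compute_effects(pb, y, divisor = "half_N")
#' @export
compute_effects <- function(design, responses,
                            divisor = c("as_printed_N", "half_N")) {
  divisor <- match.arg(divisor)
  stopifnot(inherits(design, "doe_design"))
  m <- design$coded
  n <- nrow(m)
  if (n == 0L) stop("design has zero runs")
  responses <- as.numeric(responses)
  if (length(responses) != n)
    stop("need one response per run (", n, "), got ", length(responses))
  if (anyNA(responses)) stop("responses contain missing values")
  for (j in seq_len(ncol(m))) {
    if (!all(m[, j] %in% c(-1, 1)) || sum(m[, j]) != 0)
      stop("column '", colnames(m)[j], "' is not a balanced two-level contrast")
  }
  den <- if (divisor == "as_printed_N") n else n / 2
  eff <- as.numeric(crossprod(m, responses)) / den
  out <- data.frame(
    factor = colnames(m),
    effect = eff,
    sign = ifelse(eff > 0, "positive", ifelse(eff < 0, "negative", "zero")),
    rank = rank(-abs(eff), ties.method = "first"),
    significant = NA,
    stringsAsFactors = FALSE)
  attr(out, "divisor") <- divisor
  class(out) <- c("effect_estimates", "data.frame")
  out
}

#' Flag significant screening effects
#'
#' With `method = "lenth"` (the standard for unreplicated two-level
#' designs) a pseudo standard error is computed from the effects
#' themselves: `s0 = 1.5 * median(|E|)`, then
#' `PSE = 1.5 * median(|E| restricted to |E| < 2.5 * s0)`, and an
#' effect is significant when `|E|` exceeds the margin of error
#' `t(0.975, d/3) * PSE` where d is the number of effects. With
#' `method = "threshold"` an effect is significant when
#' `|E| >= threshold`.
#'
#' @param effects An `effect_estimates` data frame from
#'   [compute_effects()].
#' @param method `"lenth"` or `"threshold"`.
#' @param threshold Absolute-effect cutoff for `method = "threshold"`.
#' @param level Confidence level of the Lenth margin of error.
#' @return The `effect_estimates` with the `significant` column filled
#'   and (for Lenth) attributes `"pse"` and `"margin"`.
#' @export
classify_effects <- function(effects, method = c("lenth", "threshold"),
                             threshold = NULL, level = 0.95) {
  method <- match.arg(method)
  stopifnot(inherits(effects, "effect_estimates"))
  e <- abs(effects$effect)
  if (method == "threshold") {
    if (is.null(threshold) || !is.finite(threshold))
      stop("'threshold' required for method = \"threshold\"")
    effects$significant <- e >= threshold
    return(effects)
  }
  d <- length(e)
  if (d < 3L) stop("Lenth's method needs at least 3 effects")
  if (all(e == 0)) {
    effects$significant <- FALSE
    attr(effects, "pse") <- 0; attr(effects, "margin") <- 0
    return(effects)
  }
  s0 <- 1.5 * stats::median(e)
  pse <- 1.5 * stats::median(e[e < 2.5 * s0])
  # majority of effects exactly zero: the restricted median degenerates;
  # treat the pseudo-SE as zero so any nonzero effect stands out
  if (!is.finite(pse)) pse <- 0
  margin <- stats::qt(1 - (1 - level) / 2, df = d / 3) * pse
  effects$significant <- e > margin
  attr(effects, "pse") <- pse
  attr(effects, "margin") <- margin
  effects
}

#' Pareto table of screening effects
#'
#' Tabular analogue of the Pareto chart: effects sorted by descending
#' magnitude with sign and significance, ready to serialize as
#' delimited text.
#'
#' @param effects An `effect_estimates` data frame.
#' @return A plain data frame sorted by `abs_effect` descending.
#' @export
pareto_table <- function(effects) {
  stopifnot(inherits(effects, "effect_estimates"))
  if (nrow(effects) == 0L)
    return(data.frame(factor = character(), effect = numeric(),
                      abs_effect = numeric(), sign = character(),
                      rank = integer(), significant = logical()))
  out <- data.frame(
    factor = effects$factor, effect = effects$effect,
    abs_effect = abs(effects$effect), sign = effects$sign,
    rank = effects$rank, significant = effects$significant,
    stringsAsFactors = FALSE)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}
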