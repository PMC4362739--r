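#' Define a controllable experimental factor
#'
#' A factor is described by its name, unit, center level and half-range
#' step in actual units. The coded level \eqn{z} of an actual setting
#' \eqn{x} is \eqn{z = (x - center)/step}, so the low and high factorial
#' levels (coded -1 and +1) sit at `center - step` and `center + step`.
#'
#' @param name Factor name (e.g. `"MnSO4"`).
#' @param center Center level in actual units.
#' @param step Half-range between the high and low factorial levels, in
#'   actual units. Must be strictly positive.
#' @param unit Unit string for display (e.g. `"uM"`, `"%"`). Optional.
#' @return An object of class `doe_factor`.
#' @examples
#' mn <- doe_factor("MnSO4", center = 650, step = 350, unit = "uM")
#' code_value(1000, mn)   # +1
#' @export
doe_factor <- function(name, center, step, unit = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  center <- as.numeric(center); step <- as.numeric(step)
  if (!is.finite(center)) stop("'center' must be a finite number")
  if (!is.finite(step) || step <= 0) stop("invalid factor: 'step' must be > 0")
  structure(list(name = name, unit = as.character(unit),
                 center = center, step = step),
            class = "doe_factor")
}

#' @export
print.doe_factor <- function(x, ...) {
  cat(sprintf("Factor %s [%s]: center %g, step %g (levels -1/+1 at %g / %g)\n",
              x$name, x$unit, x$center, x$step,
              x$center - x$step, x$center + x$step))
  invisible(x)
}

#' Convert between actual and coded factor levels
#'
#' `code_value()` maps an actual setting to coded units,
#' `uncode_value()` is its exact inverse.
#'
#' @param x Actual value(s) in the factor's units.
#' @param z Coded value(s).
#' @param factor A [doe_factor()].
#' @return Numeric vector of the same length as the input.
#' @examples
#' mn <- doe_factor("MnSO4", 650, 350, "uM")
#' code_value(c(300, 650, 1000), mn)   # -1 0 +1
#' uncode_value(2^(3/4), mn)           # high axial level, 1238.63
#' @export
code_value <- function(x, factor) {
  stopifnot(inherits(factor, "doe_factor"))
  (as.numeric(x) - factor$center) / factor$step
}

#' @rdname code_value
#' @export
uncode_value <- function(z, factor) {
  stopifnot(inherits(factor, "doe_factor"))
  factor$center + factor$step * as.numeric(z)
}

# First rows of the classical cyclic Plackett-Burman generators.
# The design is built as: generator row, its n_runs - 2 cyclic right
# shifts, and a final all-low row. Any orthogonal PB design of the same
# order is statistically equivalent.
.pb_generators <- list(
  `4`  = c(1, 1, -1),
  `8`  = c(1, 1, 1, -1, 1, -1, -1),
  `12` = c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1),
  `16` = c(1, 1, 1, 1, -1, 1, -1, 1, 1, -1, -1, 1, -1, -1, -1),
  `20` = c(1, 1, -1, -1, 1, 1, 1, 1, -1, 1, -1, 1, -1, -1, -1, -1, 1, 1, -1),
  `24` = c(1, 1, 1, 1, 1, -1, 1, -1, 1, 1, -1, -1, 1, 1, -1, -1, 1, -1,
           1, -1, -1, -1, -1)
)

#' Plackett-Burman two-level screening design
#'
#' Builds an `n_runs`-run Plackett-Burman design for up to
#' `n_runs - 1` factors from the classical cyclic generator row for
#' that run count: the generator row, its cyclic right shifts, and a
#' final all-low run. Every column is balanced (equal numbers of high
#' and low settings) and distinct columns are mutually orthogonal, so
#' up to `n_runs - 1` main effects can be screened in `n_runs` runs.
#' Columns beyond `n_factors` are dropped.
#'
#' @param n_factors Number of factors, between 2 and `n_runs - 1`.
#' @param n_runs Number of runs; one of 4, 8, 12, 16, 20, 24.
#' @param factor_names Optional character vector of factor names;
#'   defaults to `F1`, `F2`, ...
#' @return A `doe_design` object; the coded matrix is in `$coded`, the
#'   per-run class label (all `"pb"`) in `$point_class`.
#' @examples
#' pb <- plackett_burman(19, 20)
#' colSums(pb$coded == 1)    # 10 highs in every column
#' @export
plackett_burman <- function(n_factors, n_runs, factor_names = NULL) {
  n_runs <- as.integer(n_runs); n_factors <- as.integer(n_factors)
  key <- as.character(n_runs)
  if (!key %in% names(.pb_generators))
    stop("no generator available for n_runs = ", n_runs,
         " (supported: ", paste(names(.pb_generators), collapse = ", "), ")")
  if (n_factors < 2L || n_factors > n_runs - 1L)
    stop("n_factors must be between 2 and n_runs - 1 (= ", n_runs - 1L, ")")
  gen <- .pb_generators[[key]]
  p <- n_runs - 1L
  m <- matrix(NA_real_, n_runs, p)
  row <- gen
  for (i in seq_len(n_runs - 1L)) {
    m[i, ] <- row
    row <- c(row[p], row[-p])  # cyclic right shift
  }
  m[n_runs, ] <- -1
  m <- m[, seq_len(n_factors), drop = FALSE]
  if (is.null(factor_names)) factor_names <- paste0("F", seq_len(n_factors))
  stopifnot(length(factor_names) == n_factors)
  colnames(m) <- factor_names
  structure(list(coded = m, factors = NULL, alpha = NA_real_,
                 n_center = 0L,
                 point_class = rep("pb", n_runs)),
            class = "doe_design")
}

#' Rotatable (or face-centered) central composite design
#'
#' Builds a central composite design for `k = length(factors)` factors:
#' all \eqn{2^k} factorial points at coded +/-1, \eqn{2k} axial points at
#' +/-alpha on one axis with the others at 0, and `n_center` replicated
#' center points, in that fixed block order. The rotatable axial
#' distance is \eqn{\alpha = (2^k)^{1/4}} (about 1.6818 for k = 3),
#' which gives constant prediction variance on spheres around the
#' center; `alpha = "face"` places the axial points on the faces of the
#' factorial cube (\eqn{\alpha = 1}).
#'
#' @param factors List of [doe_factor()] objects (k >= 2).
#' @param alpha `"rotatable"` (default), `"face"`, or a numeric axial
#'   distance >= 1.
#' @param n_center Number of replicated center points (>= 1).
#' @param floor Optional named numeric vector of physical lower bounds
#'   on actual levels (e.g. concentrations cannot be negative); levels
#'   pushed below a floor raise a warning, not an error.
#' @return A `doe_design` with coded matrix, factors, `alpha`,
#'   `n_center` and per-run `point_class` in
#'   `c("factorial", "axial", "center")`.
#' @examples
#' f <- list(doe_factor("MnSO4", 650, 350, "uM"),
#'           doe_factor("FeSO4", 350, 150, "uM"),
#'           doe_factor("ethanol", 3.5, 1.5, "%"))
#' d <- central_composite(f, n_center = 6)
#' nrow(d$coded)                # 20 runs: 8 factorial + 6 axial + 6 center
#' round(actual_levels(d), 2)[16, ]   # high MnSO4 axial run
#' @export
central_composite <- function(factors, alpha = "rotatable", n_center = 6L,
                              floor = NULL) {
  stopifnot(is.list(factors), length(factors) >= 2L)
  lapply(factors, function(f) {
    if (!inherits(f, "doe_factor")) stop("all factors must be doe_factor objects")
    if (f$step <= 0) stop("invalid factor '", f$name, "': step must be > 0")
  })
  k <- length(factors)
  n_center <- as.integer(n_center)
  if (n_center < 1L) stop("n_center must be >= 1")
  if (identical(alpha, "rotatable")) {
    a <- (2^k)^(1/4)
  } else if (identical(alpha, "face")) {
    a <- 1
  } else {
    a <- as.numeric(alpha)
    if (!is.finite(a) || a < 1) stop("numeric alpha must be >= 1")
  }
  fact <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, 2L * k, k)
  for (i in seq_len(k)) {
    axial[2L * i - 1L, i] <- -a
    axial[2L * i, i] <- a
  }
  ctr <- matrix(0, n_center, k)
  coded <- rbind(fact, axial, ctr)
  dimnames(coded) <- list(NULL, vapply(factors, `[[`, "", "name"))
  cls <- c(rep("factorial", nrow(fact)), rep("axial", nrow(axial)),
           rep("center", n_center))
  d <- structure(list(coded = coded, factors = factors, alpha = a,
                      n_center = n_center, point_class = cls),
                 class = "doe_design")
  act <- actual_levels(d)
  if (!is.null(floor)) {
    for (nm in names(floor)) {
      if (nm %in% colnames(act) && any(act[, nm] < floor[[nm]]))
        warning("axial level of '", nm, "' falls below the physical floor ",
                floor[[nm]])
    }
  }
  d
}

#' Actual (uncoded) settings of a design
#'
#' @param design A `doe_design` with factor coding information.
#' @return Matrix of actual levels, one row per run.
#' @export
actual_levels <- function(design) {
  stopifnot(inherits(design, "doe_design"))
  if (is.null(design$factors))
    stop("design carries no factor coding (a bare screening design); ",
         "attach doe_factor objects to uncode it")
  out <- design$coded
  for (j in seq_along(design$factors))
    out[, j] <- uncode_value(design$coded[, j], design$factors[[j]])
  out
}

#' @export
print.doe_design <- function(x, ...) {
  n <- nrow(x$coded); k <- ncol(x$coded)
  if (all(x$point_class == "pb")) {
    cat(sprintf("Plackett-Burman design: %d runs, %d factors\n", n, k))
  } else {
    cat(sprintf(
      "Central composite design: %d runs, %d factors (%d factorial, %d axial, %d center), alpha = %.4f\n",
      n, k, sum(x$point_class == "factorial"), sum(x$point_class == "axial"),
      x$n_center, x$alpha))
  }
  invisible(x)
}

#' Randomize the run order of a design
#'
#' Designs are emitted in a deterministic block order; this helper
#' applies a seeded permutation and records the seed on the result.
#'
#' @param design A `doe_design`.
#' @param seed Integer seed used for the permutation.
#' @return The design with permuted rows and attribute `"shuffle_seed"`.
#' @export
shuffle_runs <- function(design, seed) {
  stopifnot(inherits(design, "doe_design"))
  seed <- as.integer(seed)
  perm <- local({ set.seed(seed); sample.int(nrow(design$coded)) })
  design$coded <- design$coded[perm, , drop = FALSE]
  design$point_class <- design$point_class[perm]
  attr(design, "shuffle_seed") <- seed
  design
}

#' Write / read a design as delimited text with a JSON sidecar
#'
#' The CSV holds actual levels (coded levels for a bare screening
#' design) plus a `point_class` column; the sidecar `<path>.json`
#' stores the factor coding (name, unit, center, step), alpha and
#' n_center so the coded matrix is reconstructable bit-exactly.
#'
#' @param design A `doe_design`.
#' @param path Path of the CSV file to write/read; the sidecar lives at
#'   `paste0(path, ".json")`.
#' @return `write_design()` returns `path` invisibly; `read_design()`
#'   returns the reconstructed `doe_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "doe_design"))
  tab <- if (is.null(design$factors)) design$coded else actual_levels(design)
  df <- as.data.frame(tab)
  df$point_class <- design$point_class
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(
    factors = if (is.null(design$factors)) NULL else
      lapply(design$factors, function(f)
        list(name = f$name, unit = f$unit, center = f$center, step = f$step)),
    alpha = if (is.na(design$alpha)) NULL else design$alpha,
    n_center = design$n_center,
    coding = "coded = (actual - center)/step")
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  cls <- df$point_class
  df$point_class <- NULL
  m <- as.matrix(df)
  if (!is.null(meta$factors) && length(meta$factors)) {
    factors <- lapply(meta$factors, function(f)
      doe_factor(f$name, f$center, f$step, f$unit))
    for (j in seq_along(factors))
      m[, j] <- code_value(m[, j], factors[[j]])
  } else factors <- NULL
  structure(list(coded = m, factors = factors,
                 alpha = if (is.null(meta$alpha)) NA_real_ else
                   as.numeric(meta$alpha),
                 n_center = as.integer(meta$n_center),
                 point_class = cls),
            class = "doe_design")
}
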