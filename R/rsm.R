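#' Second-order (quadratic) response-surface model
#'
#' Container for the full quadratic polynomial in k coded variables,
#' \deqn{Y = \beta_0 + \Sigma \beta_i x_i + \Sigma \beta_{ii} x_i^2 +
#'   \Sigma \beta_{ij} x_i x_j ,}
#' i.e. 1 + k + k + k(k-1)/2 coefficients. Interactions are ordered
#' (1,2), (1,3), ..., (1,k), (2,3), ... When a list of [doe_factor()]
#' objects is attached, predictions can be located in actual units too.
#'
#' @param beta0 Intercept (response units).
#' @param linear Numeric vector of k linear coefficients.
#' @param quadratic Numeric vector of k pure-quadratic coefficients.
#' @param interaction Numeric vector of k(k-1)/2 interaction
#'   coefficients in the pair order above.
#' @param factors Optional list of [doe_factor()] giving the coding.
#' @param names Optional factor names (defaults to the factors' names,
#'   else `X1`, `X2`, ...).
#' @return An object of class `quad_model`.
#' @examples
#' # a paraboloid with its maximum at the origin
#' m <- quad_model(0, c(0, 0), c(-1, -1), 0)
#' predict(m, c(1, 1))
#' @export
quad_model <- function(beta0, linear, quadratic, interaction,
                       factors = NULL, names = NULL) {
  k <- length(linear)
  if (length(quadratic) != k) stop("quadratic must have k coefficients")
  npair <- k * (k - 1L) / 2L
  if (npair == 0L) interaction <- numeric(0)
  if (length(interaction) != npair)
    stop("interaction must have k(k-1)/2 = ", npair, " coefficients")
  if (is.null(names)) {
    names <- if (!is.null(factors)) vapply(factors, `[[`, "", "name")
             else paste0("X", seq_len(k))
  }
  stopifnot(length(names) == k)
  structure(list(beta0 = as.numeric(beta0), linear = as.numeric(linear),
                 quadratic = as.numeric(quadratic),
                 interaction = as.numeric(interaction),
                 k = k, names = names, factors = factors),
            class = "quad_model")
}

# pair index table in the canonical (1,2),(1,3),...,(2,3),... order
.pairs <- function(k) {
  if (k < 2L) return(matrix(integer(0), 0L, 2L))
  t(utils::combn(k, 2L))
}

# full quadratic model matrix from a coded run matrix
.quad_model_matrix <- function(coded) {
  coded <- as.matrix(coded)
  k <- ncol(coded)
  nm <- colnames(coded)
  if (is.null(nm)) nm <- paste0("X", seq_len(k))
  pr <- .pairs(k)
  inter <- if (nrow(pr)) coded[, pr[, 1L], drop = FALSE] *
                         coded[, pr[, 2L], drop = FALSE]
           else matrix(0, nrow(coded), 0L)
  Z <- cbind(1, coded, coded^2, inter)
  colnames(Z) <- c("(Intercept)", nm, paste0(nm, "^2"),
                   if (nrow(pr)) paste0(nm[pr[, 1L]], ":", nm[pr[, 2L]]))
  Z
}

#' Fit the quadratic model by ordinary least squares
#'
#' Builds the full second-order model matrix over the coded variables
#' and solves the least-squares problem by QR decomposition. The design
#' must span the quadratic model: at least as many runs as coefficients
#' and at least three distinct levels per factor (a CCD qualifies).
#'
#' @param design A `doe_design` (typically a [central_composite()]).
#' @param responses Numeric response vector, one value per run.
#' @return A `quad_model` additionally carrying the training data
#'   (`$design`, `$responses`), `$fitted` and `$residuals`.
#' @examples
#' f <- list(doe_factor("MnSO4", 650, 350, "uM"),
#'           doe_factor("FeSO4", 350, 150, "uM"),
#'           doe_factor("ethanol", 3.5, 1.5, "%"))
#' d <- central_composite(f, n_center = 6)
#' truth <- quad_model(100, c(10, 5, 2), c(-8, -6, -1), c(1, -2, 0.5),
#'                     factors = f)
#' y <- gen_surface_responses(d, truth, noise_sd = 0, seed = 1)
#' fit <- fit_quadratic(d, y)
#' max(abs(coef(fit) - coef(truth)))   # exact recovery
#' @export
fit_quadratic <- function(design, responses) {
  stopifnot(inherits(design, "doe_design"))
  y <- as.numeric(responses)
  m <- design$coded
  if (length(y) != nrow(m))
    stop("need one response per run (", nrow(m), "), got ", length(y))
  Z <- .quad_model_matrix(m)
  p <- ncol(Z)
  if (nrow(Z) < p)
    stop("need at least ", p, " runs to fit ", p, " coefficients")
  qr_z <- qr(Z)
  if (qr_z$rank < p) {
    bad <- colnames(Z)[qr_z$pivot[(qr_z$rank + 1L):p]]
    stop("singular model matrix; dependent columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_z, y)
  k <- ncol(m)
  mod <- quad_model(beta[1L], beta[2L:(k + 1L)],
                    beta[(k + 2L):(2L * k + 1L)],
                    beta[-seq_len(2L * k + 1L)],
                    factors = design$factors, names = colnames(m))
  mod$design <- design
  mod$responses <- y
  mod$fitted <- as.numeric(Z %*% beta)
  mod$residuals <- y - mod$fitted
  mod$qr <- qr_z
  mod
}

#' @export
coef.quad_model <- function(object, ...) {
  k <- object$k
  pr <- .pairs(k)
  nm <- object$names
  stats::setNames(
    c(object$beta0, object$linear, object$quadratic, object$interaction),
    c("(Intercept)", nm, paste0(nm, "^2"),
      if (nrow(pr)) paste0(nm[pr[, 1L]], ":", nm[pr[, 2L]])))
}

#' Predict from a quadratic model at coded points
#'
#' @param object A `quad_model`.
#' @param newdata Coded coordinates: a numeric vector of length k or a
#'   matrix/data frame with k columns. Omitted: the training fitted
#'   values are returned.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.quad_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$fitted)) stop("no training data stored; give newdata")
    return(object$fitted)
  }
  x <- if (is.null(dim(newdata))) matrix(as.numeric(newdata), nrow = 1L)
       else as.matrix(newdata)
  if (ncol(x) != object$k)
    stop("newdata must have ", object$k, " coded coordinates per point")
  colnames(x) <- object$names
  Z <- .quad_model_matrix(x)
  as.numeric(Z %*% c(object$beta0, object$linear, object$quadratic,
                     object$interaction))
}

#' @export
print.quad_model <- function(x, ...) {
  cat(sprintf("Quadratic response-surface model in %d coded variables\n", x$k))
  print(round(coef(x), 4))
  invisible(x)
}

# replicate groups by exact coded-vector equality after rounding to 6 dp
.replicate_groups <- function(coded) {
  key <- apply(round(coded, 6L), 1L, paste, collapse = "|")
  split(seq_len(nrow(coded)), key)
}

#' ANOVA of a fitted quadratic response-surface model
#'
#' Partitions the corrected total sum of squares into the model, its
#' nine (for k = 3) single-degree-of-freedom terms, and the residual;
#' when the design contains replicate runs the residual is further
#' split into pure error (within-replicate variation,
#' \eqn{\Sigma_g \Sigma (y - \bar y_g)^2}) and lack of fit. Per-term
#' sums of squares are partial (Type III); on an orthogonally coded CCD
#' the linear and interaction columns are mutually orthogonal so these
#' coincide with sequential SS for those terms. F ratios use the
#' residual mean square for model terms and the pure-error mean square
#' for lack of fit; p-values are upper tails of the F distribution.
#'
#' @param object A `quad_model` returned by [fit_quadratic()].
#' @param ... Unused.
#' @return A data frame of class `doe_anova` with columns `source`,
#'   `sum_sq`, `df`, `mean_sq`, `f_value`, `p_value`, `label`
#'   (`"Significant"` when p < 0.05).
#' @export
anova.quad_model <- function(object, ...) {
  if (is.null(object$responses))
    stop("model carries no training data; fit it with fit_quadratic()")
  y <- object$responses
  n <- length(y)
  Z <- .quad_model_matrix(object$design$coded)
  p <- ncol(Z)
  rss <- sum(object$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_model <- ss_tot - rss
  df_res <- n - p
  # partial SS for term j: beta_j^2 / [(Z'Z)^{-1}]_jj
  xtx_inv <- chol2inv(qr.R(object$qr))
  piv <- object$qr$pivot
  xtx_inv <- xtx_inv[order(piv), order(piv)]
  beta <- c(object$beta0, object$linear, object$quadratic, object$interaction)
  term_ss <- beta^2 / diag(xtx_inv)
  term_names <- colnames(Z)[-1L]
  term_ss <- term_ss[-1L]  # intercept row not reported

  groups <- .replicate_groups(object$design$coded)
  rep_groups <- groups[vapply(groups, length, 1L) > 1L]
  has_reps <- length(rep_groups) > 0L
  ss_pe <- if (has_reps)
    sum(vapply(rep_groups, function(i) sum((y[i] - mean(y[i]))^2), 0.0))
  else NA_real_
  df_pe <- if (has_reps)
    sum(vapply(rep_groups, length, 1L)) - length(rep_groups)
  else NA_integer_

  rows <- list()
  add <- function(source, ss, df, f_den_ms = NULL) {
    ms <- if (df > 0) ss / df else NA_real_
    fv <- pv <- NA_real_
    if (!is.null(f_den_ms) && is.finite(f_den_ms) && f_den_ms > 0 && df > 0) {
      fv <- ms / f_den_ms
      pv <- stats::pf(fv, df, attr(f_den_ms, "df"), lower.tail = FALSE)
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      source = source, sum_sq = ss, df = df, mean_sq = ms,
      f_value = fv, p_value = pv, stringsAsFactors = FALSE)
  }
  ms_res <- if (df_res > 0) structure(rss / df_res, df = df_res) else NULL
  add("model", ss_model, p - 1L, ms_res)
  for (j in seq_along(term_ss)) add(term_names[j], term_ss[j], 1L, ms_res)
  add("residual", rss, df_res)
  if (has_reps) {
    df_lof <- df_res - df_pe
    ss_lof <- rss - ss_pe
    ms_pe <- if (df_pe > 0) structure(ss_pe / df_pe, df = df_pe) else NULL
    if (df_lof > 0) add("lack_of_fit", ss_lof, as.integer(df_lof), ms_pe)
    add("pure_error", ss_pe, as.integer(df_pe))
  }
  add("corrected_total", ss_tot, n - 1L)
  out <- do.call(rbind, rows)
  out$label <- ifelse(is.na(out$p_value), "",
                      ifelse(out$p_value < 0.05, "Significant",
                             "Not significant"))
  attr(out, "has_replicates") <- has_reps
  class(out) <- c("doe_anova", "data.frame")
  out
}

#' Format a p-value in reporting style
#'
#' Four decimals, with values below 0.0001 shown as `"<0.0001"`.
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p)))
}

#' @export
print.doe_anova <- function(x, ...) {
  df <- as.data.frame(x)
  df$p_value <- format_pvalue(df$p_value)
  df$sum_sq <- signif(df$sum_sq, 6)
  df$mean_sq <- signif(df$mean_sq, 6)
  df$f_value <- round(df$f_value, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Goodness-of-fit diagnostics for a quadratic model
#'
#' Computes R-squared, adjusted R-squared, PRESS (the sum of squared
#' leave-one-out prediction residuals, \eqn{e_i/(1-h_{ii})}), the
#' derived predicted R-squared, and the coefficient of variation
#' \eqn{CV = 100 \sqrt{MS_{res}} / \bar y} in percent.
#'
#' @param model A `quad_model` returned by [fit_quadratic()].
#' @return A list with `r2`, `adj_r2`, `pred_r2`, `press`,
#'   `cv_percent`.
#' @export
diagnostics <- function(model) {
  stopifnot(inherits(model, "quad_model"))
  if (is.null(model$responses))
    stop("model carries no training data; fit it with fit_quadratic()")
  y <- model$responses
  n <- length(y)
  p <- length(coef(model))
  rss <- sum(model$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - rss / ss_tot
  adj_r2 <- if (n > p) 1 - (1 - r2) * (n - 1) / (n - p) else NA_real_
  h <- rowSums(qr.Q(model$qr)^2)
  press <- sum((model$residuals / (1 - h))^2)
  cv <- if (n > p) 100 * sqrt(rss / (n - p)) / mean(y) else NA_real_
  list(r2 = r2, adj_r2 = adj_r2, pred_r2 = 1 - press / ss_tot,
       press = press, cv_percent = cv)
}

# symmetric coefficient matrix of the quadratic form and linear vector:
# Y = beta0 + b'x + x'Qx with Q = diag(beta_ii), Q[i,j] = beta_ij / 2
.canonical_form <- function(model) {
  k <- model$k
  Q <- diag(model$quadratic, k)
  pr <- .pairs(k)
  for (r in seq_len(nrow(pr))) {
    i <- pr[r, 1L]; j <- pr[r, 2L]
    Q[i, j] <- Q[j, i] <- model$interaction[r] / 2
  }
  list(Q = Q, b = model$linear)
}

#' Stationary point of the fitted surface
#'
#' Solves the gradient equation \eqn{2 Q x = -b} of the canonical form
#' \eqn{Y = \beta_0 + b'x + x'Qx} and classifies the point by the
#' eigenvalues of Q: all negative is a maximum, all positive a minimum,
#' mixed signs a saddle.
#'
#' @param model A `quad_model`.
#' @return A list of class `stationary_point` with `coded`, `actual`
#'   (when the model carries factor coding, else `NULL`), `value`,
#'   `nature` and `eigenvalues`.
#' @export
stationary_point <- function(model) {
  stopifnot(inherits(model, "quad_model"))
  cf <- .canonical_form(model)
  qr_q <- qr(cf$Q)
  if (qr_q$rank < model$k)
    stop("quadratic coefficient matrix is singular (rank ", qr_q$rank,
         " of ", model$k, "); no unique stationary point")
  x <- as.numeric(solve(qr_q, -cf$b / 2))
  ev <- eigen(cf$Q, symmetric = TRUE, only.values = TRUE)$values
  nature <- if (all(ev < 0)) "maximum" else if (all(ev > 0)) "minimum"
            else "saddle"
  actual <- if (!is.null(model$factors))
    mapply(uncode_value, x, model$factors)
  else NULL
  structure(list(coded = stats::setNames(x, model$names), actual = actual,
                 value = predict(model, x), nature = nature,
                 eigenvalues = ev),
            class = "stationary_point")
}

#' @export
print.stationary_point <- function(x, ...) {
  cat(sprintf("Stationary point (%s), predicted response %.4f\n",
              x$nature, x$value))
  cat("  coded: ", paste(sprintf("%s = %.4f", names(x$coded), x$coded),
                         collapse = ", "), "\n")
  if (!is.null(x$actual))
    cat("  actual:", paste(sprintf("%s = %.4f", names(x$coded), x$actual),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Maximize the fitted surface inside a region
#'
#' Finds the maximizer of the quadratic surface within a coded box
#' (default the axial box \eqn{[-\alpha, \alpha]^k} that the design
#' probes) or within the sphere of radius alpha. If the interior
#' stationary point is a maximum and feasible it is returned directly;
#' otherwise the box case runs deterministic multi-start bounded
#' BFGS ascent from a fixed 3-level lattice of starts, and the sphere
#' case solves the trust-region equation exactly by bisection on the
#' Lagrange multiplier.
#'
#' @param model A `quad_model`.
#' @param lower,upper Numeric bounds per factor (recycled); default
#'   `-alpha`/`+alpha` from the model's design, else 1.6818.
#' @param region `"box"` (default) or `"sphere"`.
#' @param radius Sphere radius (defaults to the box half-width).
#' @return A list with `coded` (maximizer), `value`, `actual` (when
#'   coding is attached) and `boundary` (logical: was the constraint
#'   active).
#' @export
optimize_in_region <- function(model, lower = NULL, upper = NULL,
                               region = c("box", "sphere"), radius = NULL) {
  region <- match.arg(region)
  stopifnot(inherits(model, "quad_model"))
  k <- model$k
  a <- if (!is.null(model$design) && is.finite(model$design$alpha))
    model$design$alpha else (2^k)^(1/4)
  if (is.null(lower)) lower <- rep(-a, k) else lower <- rep_len(lower, k)
  if (is.null(upper)) upper <- rep(a, k) else upper <- rep_len(upper, k)
  if (any(lower >= upper)) stop("empty bounds: lower must be < upper")
  cf <- .canonical_form(model)
  sp <- tryCatch(stationary_point(model), error = function(e) NULL)

  if (region == "sphere") {
    if (is.null(radius)) radius <- a
    return(.maximize_on_ball(model, cf, sp, radius))
  }
  if (!is.null(sp) && sp$nature == "maximum" &&
      all(sp$coded >= lower & sp$coded <= upper)) {
    best_x <- as.numeric(sp$coded); best_v <- sp$value
    boundary <- FALSE
  } else {
    grid1 <- function(l, u) c(l, (l + u) / 2, u)
    starts <- as.matrix(expand.grid(
      lapply(seq_len(k), function(i) grid1(lower[i], upper[i]))))
    best_v <- -Inf; best_x <- NULL
    for (s in seq_len(nrow(starts))) {
      o <- stats::optim(starts[s, ],
                        fn = function(x) -predict(model, x),
                        gr = function(x) -(cf$b + 2 * as.numeric(cf$Q %*% x)),
                        method = "L-BFGS-B", lower = lower, upper = upper)
      if (-o$value > best_v) { best_v <- -o$value; best_x <- o$par }
    }
    boundary <- any(abs(best_x - lower) < 1e-6 | abs(best_x - upper) < 1e-6)
  }
  actual <- if (!is.null(model$factors))
    mapply(uncode_value, best_x, model$factors)
  else NULL
  list(coded = stats::setNames(best_x, model$names), value = best_v,
       actual = actual, boundary = boundary)
}

# exact trust-region maximization of beta0 + b'x + x'Qx over |x| <= r
.maximize_on_ball <- function(model, cf, sp, r) {
  if (!is.null(sp) && sp$nature == "maximum" &&
      sqrt(sum(sp$coded^2)) <= r) {
    return(list(coded = sp$coded, value = sp$value,
                actual = sp$actual, boundary = FALSE))
  }
  Q <- cf$Q; b <- cf$b; k <- model$k
  lam_max <- max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values)
  xr <- function(mu) -0.5 * solve(Q - mu * diag(k), b)  # on-sphere candidate
  lo <- lam_max + 1e-10; hi <- lam_max + 1
  while (sqrt(sum(xr(hi)^2)) > r) hi <- lam_max + (hi - lam_max) * 2
  nlo <- sqrt(sum(xr(lo)^2))
  if (is.finite(nlo) && nlo < r) {
    # hard case: solution includes a component along the top eigenvector
    v <- eigen(Q, symmetric = TRUE)$vectors[, 1L]
    x0 <- xr(lo)
    tau <- sqrt(max(r^2 - sum(x0^2), 0))
    cand <- list(x0 + tau * v, x0 - tau * v)
    vals <- vapply(cand, function(x) predict(model, x), 0.0)
    best_x <- cand[[which.max(vals)]]
  } else {
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (sqrt(sum(xr(mid)^2)) > r) lo <- mid else hi <- mid
    }
    best_x <- xr(hi)
    best_x <- best_x * (r / max(sqrt(sum(best_x^2)), 1e-300))
  }
  actual <- if (!is.null(model$factors))
    mapply(uncode_value, best_x, model$factors)
  else NULL
  list(coded = stats::setNames(as.numeric(best_x), model$names),
       value = predict(model, best_x), actual = actual, boundary = TRUE)
}

#' Rectangular prediction grid over two factors
#'
#' Evaluates the surface on a resolution-by-resolution grid over the
#' coded ranges of two factors, holding the others fixed; the long
#' format suits contour/perspective plotting and delimited-text export.
#'
#' @param model A `quad_model`.
#' @param pair Integer indices of the two factors to vary (distinct).
#' @param fixed Coded values for the remaining factors (recycled;
#'   default 0, the center).
#' @param resolution Grid points per axis (>= 2).
#' @param range Coded range per axis, default `c(-alpha, alpha)`.
#' @return Data frame with columns `x`, `y`, `z` plus the axis factor
#'   names as attributes `"xvar"`/`"yvar"`.
#' @export
surface_grid <- function(model, pair, fixed = 0, resolution = 21L,
                         range = NULL) {
  stopifnot(inherits(model, "quad_model"))
  pair <- as.integer(pair)
  if (length(pair) != 2L || pair[1L] == pair[2L])
    stop("'pair' must be two distinct factor indices")
  if (any(pair < 1L | pair > model$k)) stop("factor index out of range")
  if (resolution < 2L) stop("resolution must be >= 2")
  if (is.null(range)) {
    a <- if (!is.null(model$design) && is.finite(model$design$alpha))
      model$design$alpha else (2^model$k)^(1/4)
    range <- c(-a, a)
  }
  xs <- seq(range[1L], range[2L], length.out = resolution)
  grid <- expand.grid(x = xs, y = xs)
  others <- setdiff(seq_len(model$k), pair)
  fixed <- rep_len(fixed, length(others))
  pts <- matrix(0, nrow(grid), model$k)
  pts[, pair[1L]] <- grid$x
  pts[, pair[2L]] <- grid$y
  for (i in seq_along(others)) pts[, others[i]] <- fixed[i]
  grid$z <- predict(model, pts)
  attr(grid, "xvar") <- model$names[pair[1L]]
  attr(grid, "yvar") <- model$names[pair[2L]]
  grid
}

#' Export / import a quadratic model as JSON
#'
#' Coefficients are stored under their term names together with the
#' factor coding metadata so coded and actual predictions are both
#' reconstructable.
#'
#' @param model A `quad_model`.
#' @param path JSON file path.
#' @return `write_model()` returns `path` invisibly; `read_model()` a
#'   `quad_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "quad_model"))
  obj <- list(
    coefficients = as.list(coef(model)),
    names = model$names,
    factors = if (is.null(model$factors)) NULL else
      lapply(model$factors, function(f)
        list(name = f$name, unit = f$unit, center = f$center, step = f$step)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path)
  nm <- unlist(obj$names)
  k <- length(nm)
  cf <- unlist(obj$coefficients)
  factors <- if (!is.null(obj$factors) && length(obj$factors))
    lapply(obj$factors, function(f) doe_factor(f$name, f$center, f$step,
                                               f$unit))
  else NULL
  quad_model(cf[[1L]], cf[2L:(k + 1L)], cf[(k + 2L):(2L * k + 1L)],
             cf[-seq_len(2L * k + 1L)], factors = factors, names = nm)
}
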