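test_that("prediction from the published equation matches hand arithmetic", {
  m <- study_printed_model()
  expect_identical(predict(m, c(0, 0, 0)), 16696.86)
  # at (1,1,1) every term contributes once: the sum of all ten coefficients
  expect_equal(predict(m, c(1, 1, 1)), 11602.85, tolerance = 1e-10)
  zero <- quad_model(0, c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))
  expect_equal(predict(zero, c(1.3, -0.2, 5)), 0)
  expect_error(predict(m, c(1, 2)), "coded coordinates")
})

test_that("quadratic model constructor enforces coefficient counts", {
  expect_equal(length(coef(study_printed_model())), 10L)
  expect_error(quad_model(0, c(1, 2, 3), c(1, 2), c(1, 2, 3)), "quadratic")
  expect_error(quad_model(0, c(1, 2, 3), c(1, 2, 3), c(1, 2)), "interaction")
})

test_that("noiseless responses from a known surface are recovered exactly", {
  d <- central_composite(study_f, n_center = 6)
  truth <- study_printed_model()
  y <- gen_surface_responses(d, truth, noise_sd = 0, seed = 1)
  fit <- fit_quadratic(d, y)
  expect_equal(coef(fit), coef(truth), tolerance = 1e-8)
  expect_lt(max(abs(fit$residuals)), 1e-6)
  # idempotence: refitting the fitted values reproduces the coefficients
  refit <- fit_quadratic(d, fit$fitted)
  expect_equal(coef(refit), coef(fit), tolerance = 1e-10)
})

test_that("fit agrees with an independent least-squares oracle on the study data", {
  tab2 <- study_fixture("table2_ccd")
  coded <- cbind(code_value(tab2$MnSO4_uM, study_f[[1]]),
                 code_value(tab2$FeSO4_uM, study_f[[2]]),
                 code_value(tab2$ethanol_pct, study_f[[3]]))
  colnames(coded) <- c("MnSO4", "FeSO4", "ethanol")
  d <- central_composite(study_f, n_center = 6)
  d$coded <- coded
  d$point_class <- rep("", 20)
  fit <- fit_quadratic(d, tab2$actual)
  ora <- lm_quadratic_oracle(coded, tab2$actual)
  expect_equal(sort(unname(coef(fit))), sort(unname(coef(ora))),
               tolerance = 1e-8)
  expect_equal(diagnostics(fit)$r2, summary(ora)$r.squared,
               tolerance = 1e-8)
})

test_that("rank-deficient model matrices raise a singular-fit error naming columns", {
  d <- central_composite(study_f[1:2], n_center = 3)
  d$coded <- cbind(d$coded, d$coded[, 1])  # duplicated factor column
  colnames(d$coded)[3] <- "dup"
  d$factors <- c(d$factors, list(doe_factor("dup", 650, 350)))
  expect_error(fit_quadratic(d, rnorm(nrow(d$coded))), "singular")
  small <- central_composite(study_f, n_center = 6)
  expect_error(fit_quadratic(small, rnorm(5)), "one response per run")
})

test_that("ANOVA satisfies the additivity identities and splits pure error from lack of fit", {
  d <- central_composite(study_f, n_center = 6)
  truth <- study_printed_model()
  y <- gen_surface_responses(d, truth, noise_sd = 40, seed = 7)
  fit <- fit_quadratic(d, y)
  a <- anova(fit)
  get <- function(s, col) a[[col]][a$source == s]
  expect_equal(get("model", "sum_sq") + get("residual", "sum_sq"),
               get("corrected_total", "sum_sq"), tolerance = 1e-6)
  expect_equal(get("lack_of_fit", "sum_sq") + get("pure_error", "sum_sq"),
               get("residual", "sum_sq"), tolerance = 1e-6)
  expect_equal(get("lack_of_fit", "df") + get("pure_error", "df"),
               get("residual", "df"))
  expect_equal(get("model", "df") + get("residual", "df"),
               get("corrected_total", "df"))
  # on the orthogonally coded CCD, partial SS of the linear and
  # interaction terms equal their direct contrast form beta^2 * z'z
  Z <- cbind(d$coded, AB = d$coded[, 1] * d$coded[, 2])
  for (term in c("MnSO4", "FeSO4", "ethanol", "MnSO4:FeSO4")) {
    col <- if (term == "MnSO4:FeSO4") Z[, "AB"] else Z[, term]
    beta <- coef(fit)[[term]]
    expect_equal(a$sum_sq[a$source == term], beta^2 * sum(col^2),
                 tolerance = 1e-6)
  }
})

test_that("pure error over the six center replicates matches direct arithmetic", {
  tab2 <- study_fixture("table2_ccd")
  d <- central_composite(study_f, n_center = 6)
  idx_center <- which(round(code_value(tab2$MnSO4_uM, study_f[[1]]), 6) == 0 &
                      round(code_value(tab2$FeSO4_uM, study_f[[2]]), 6) == 0 &
                      round(code_value(tab2$ethanol_pct, study_f[[3]]), 6) == 0)
  y_center <- tab2$actual[idx_center]
  # frozen hand arithmetic on the six printed center activities
  expect_equal(sum((y_center - mean(y_center))^2), 15101.33,
               tolerance = 1e-2)
  fit <- fit_quadratic(reproduce_study()$design, tab2$actual)
  a <- anova(fit)
  expect_equal(a$sum_sq[a$source == "pure_error"], 15101.33,
               tolerance = 1e-2)
  expect_equal(a$df[a$source == "pure_error"], 5L)
})

test_that("designs without replicates omit the lack-of-fit split", {
  d <- central_composite(study_f, n_center = 1)
  y <- gen_surface_responses(d, study_printed_model(), noise_sd = 10,
                             seed = 5)
  a <- anova(fit_quadratic(d, y))
  expect_false(attr(a, "has_replicates"))
  expect_false(any(a$source %in% c("lack_of_fit", "pure_error")))
})

test_that("diagnostics: perfect fit gives R2 = 1 and PRESS dominates the residual SS elsewhere", {
  d <- central_composite(study_f, n_center = 6)
  y0 <- gen_surface_responses(d, study_printed_model(), noise_sd = 0,
                              seed = 1)
  dg0 <- diagnostics(fit_quadratic(d, y0))
  expect_equal(dg0$r2, 1, tolerance = 1e-10)
  expect_equal(dg0$adj_r2, 1, tolerance = 1e-10)
  for (seed in 1:5) {
    y <- gen_surface_responses(d, study_printed_model(), noise_sd = 100,
                               seed = seed)
    fit <- fit_quadratic(d, y)
    dg <- diagnostics(fit)
    expect_gte(dg$press, sum(fit$residuals^2))
    expect_lte(dg$adj_r2, dg$r2)
    expect_lte(dg$pred_r2, dg$r2)
  }
})

test_that("stationary points are located and classified by curvature", {
  bowl <- quad_model(0, c(0, 0, 0), c(-1, -1, -1), c(0, 0, 0))
  sp <- stationary_point(bowl)
  expect_equal(unname(sp$coded), c(0, 0, 0))
  expect_equal(sp$nature, "maximum")
  expect_equal(sp$value, 0)
  saddle <- stationary_point(quad_model(0, c(0, 0), c(1, -1), 0))
  expect_equal(saddle$nature, "saddle")
  minim <- stationary_point(quad_model(5, c(2, 0), c(1, 3), 0))
  expect_equal(minim$nature, "minimum")
  expect_error(stationary_point(quad_model(0, c(1, 1), c(0, 0), 0)),
               "singular")
})

test_that("the published surface is a near-singular saddle while the refit surface peaks inside the region", {
  # the published equation's weak C^2 term plus strong AC/BC interactions
  # tip its smallest curvature positive: the stationary point is a saddle
  m <- study_printed_model()
  sp <- stationary_point(m)
  expect_equal(sp$nature, "saddle")
  expect_true(any(sp$eigenvalues > 0) && any(sp$eigenvalues < 0))
  # gradient vanishes there: 2 Q x + b = 0 checked through predictions
  eps <- 1e-4
  for (i in 1:3) {
    dx <- rep(0, 3); dx[i] <- eps
    grad_i <- (predict(m, sp$coded + dx) - predict(m, sp$coded - dx)) /
      (2 * eps)
    expect_lt(abs(grad_i), 1e-4)
  }
  # the refit surface has an interior maximum that a dense grid confirms
  refit <- reproduce_study()$refit_model
  sp_r <- stationary_point(refit)
  expect_equal(sp_r$nature, "maximum")
  a <- 2^(3/4)
  oracle <- grid_max_oracle(refit, rep(-a, 3), rep(a, 3), step = 0.02)
  expect_equal(unname(sp_r$coded), unname(oracle$coded), tolerance = 0.021)
  expect_equal(sp_r$value, oracle$value, tolerance = 1e-3)
  # actual units recoverable through the attached coding
  expect_equal(unname(sp_r$actual),
               mapply(uncode_value, unname(sp_r$coded), study_f))
})

test_that("box optimization returns interior optima, corner optima and matches the grid oracle", {
  bowl <- quad_model(10, c(0, 0, 0), c(-2, -2, -2), c(0, 0, 0))
  opt <- optimize_in_region(bowl)
  expect_equal(unname(opt$coded), c(0, 0, 0), tolerance = 1e-8)
  expect_false(opt$boundary)
  lin <- quad_model(0, c(3, 2, 1), c(0, 0, 0), c(0, 0, 0))
  opt_lin <- optimize_in_region(lin, lower = -1, upper = 1)
  expect_equal(unname(opt_lin$coded), c(1, 1, 1), tolerance = 1e-6)
  expect_true(opt_lin$boundary)
  m <- study_printed_model()
  a <- 2^(3/4)
  opt_m <- optimize_in_region(m)
  oracle <- grid_max_oracle(m, rep(-a, 3), rep(a, 3), step = 0.01)
  expect_equal(unname(opt_m$coded), unname(oracle$coded), tolerance = 0.011)
  expect_lt(abs(opt_m$value - oracle$value) / abs(oracle$value), 1e-3)
})

test_that("spherical-region optimization stays on the ball and is consistent with the box", {
  m <- study_printed_model()
  a <- 2^(3/4)
  sph <- optimize_in_region(m, region = "sphere", radius = a)
  expect_lte(sqrt(sum(sph$coded^2)), a + 1e-8)
  box <- optimize_in_region(m)
  expect_lte(sph$value, box$value + 1e-6)
  # concave surface with interior maximum: identical answers
  bowl <- quad_model(10, c(1, 0, 0), c(-2, -2, -2), c(0, 0, 0))
  expect_equal(optimize_in_region(bowl, region = "sphere")$value,
               optimize_in_region(bowl)$value, tolerance = 1e-8)
  # linear surface: the sphere optimum sits on the boundary at radius a
  lin <- quad_model(0, c(3, 2, 1), c(0, 0, 0), c(1e-9, 0, 0))
  s <- optimize_in_region(lin, region = "sphere", radius = 1)
  expect_equal(sqrt(sum(s$coded^2)), 1, tolerance = 1e-6)
})

test_that("surface grids equal direct predictions and never beat the optimizer", {
  m <- study_printed_model()
  g2 <- surface_grid(m, c(1, 2), fixed = 0, resolution = 2,
                     range = c(-1, 1))
  corners <- cbind(g2$x, g2$y, 0)
  expect_equal(g2$z, predict(m, corners))
  zero <- quad_model(0, c(0, 0), c(0, 0), 0)
  expect_true(all(surface_grid(zero, c(1, 2), resolution = 5)$z == 0))
  g <- surface_grid(m, c(2, 3), fixed = 0.3, resolution = 31)
  opt <- optimize_in_region(m)
  expect_lte(max(g$z), opt$value + 1e-8)
  expect_error(surface_grid(m, c(2, 2)), "distinct")
})

test_that("model JSON exchange round-trips coefficients and coding", {
  m <- study_printed_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(coef(m2), coef(m))
  expect_equal(predict(m2, c(0.5, -1, 0.2)), predict(m, c(0.5, -1, 0.2)))
  expect_equal(vapply(m2$factors, `[[`, 0, "step"),
               vapply(m$factors, `[[`, 0, "step"))
})

test_that("p-values format in reporting style", {
  expect_identical(format_pvalue(c(0.61481, 2e-5, NA, 0.0499)),
                   c("0.6148", "<0.0001", "", "0.0499"))
})
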