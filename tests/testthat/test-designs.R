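test_that("coded/actual conversion round-trips and matches hand arithmetic", {
  mn <- study_f[[1]]
  expect_equal(code_value(650, mn), 0)
  expect_equal(code_value(1000, mn), 1)
  expect_equal(round(code_value(61.37, mn), 4), -1.6818)
  xs <- c(-123.4, 0, 61.37, 650, 1e6)
  expect_equal(uncode_value(code_value(xs, mn), mn), xs)
  for (f in study_f) {
    expect_equal(uncode_value(-1, f), f$center - f$step)
    expect_equal(uncode_value(1, f), f$center + f$step)
  }
})

test_that("factor construction rejects non-positive steps", {
  expect_error(doe_factor("x", 1, 0), "step")
  expect_error(doe_factor("x", 1, -2), "step")
})

test_that("Plackett-Burman designs are balanced and orthogonal for every supported run count", {
  for (n in c(4L, 8L, 12L, 16L, 20L, 24L)) {
    d <- plackett_burman(n - 1L, n)
    m <- d$coded
    expect_identical(dim(m), c(n, n - 1L))
    expect_true(all(m %in% c(-1, 1)))
    expect_true(all(colSums(m == 1) == n / 2),
                label = sprintf("balance at n = %d", n))
    g <- crossprod(m)
    expect_true(all(abs(g[upper.tri(g)]) < 1e-12),
                label = sprintf("orthogonality at n = %d", n))
  }
})

test_that("Plackett-Burman drops columns past n_factors and validates input", {
  d <- plackett_burman(19, 20)
  expect_identical(dim(d$coded), c(20L, 19L))
  d3 <- plackett_burman(3, 4)
  expect_true(all(colSums(d3$coded == 1) == 2))
  expect_error(plackett_burman(10, 10), "no generator")
  expect_error(plackett_burman(20, 20), "n_factors")
})

test_that("rotatable CCD reproduces the study's axial levels and 8/6/6 composition", {
  d <- central_composite(study_f, alpha = "rotatable", n_center = 6)
  expect_equal(nrow(d$coded), 20L)
  expect_equal(sum(d$point_class == "factorial"), 8L)
  expect_equal(sum(d$point_class == "axial"), 6L)
  expect_equal(sum(d$point_class == "center"), 6L)
  expect_equal(d$alpha, 2^(3/4))
  act <- actual_levels(d)
  axial <- round(act[d$point_class == "axial", ], 2)
  expect_setequal(axial[, "MnSO4"][axial[, "MnSO4"] != 650],
                  c(61.37, 1238.63))
  expect_setequal(axial[, "FeSO4"][axial[, "FeSO4"] != 350],
                  c(97.73, 602.27))
  expect_setequal(axial[, "ethanol"][axial[, "ethanol"] != 3.5],
                  c(0.98, 6.02))
})

test_that("CCD point count is 2^k + 2k + n_center and face-centered axials hit the factorial levels", {
  for (k in 2:4) for (nc in c(1L, 4L)) {
    fs <- lapply(seq_len(k), function(i) doe_factor(paste0("f", i), 10, 2))
    d <- central_composite(fs, n_center = nc)
    expect_equal(nrow(d$coded), 2^k + 2 * k + nc)
  }
  fs <- list(doe_factor("a", 5, 2), doe_factor("b", 1, 0.5))
  d <- central_composite(fs, alpha = "face", n_center = 1)
  act <- actual_levels(d)
  expect_setequal(unique(act[d$point_class == "axial", "a"]), c(3, 5, 7))
  expect_setequal(unique(act[d$point_class == "axial", "b"]), c(0.5, 1, 1.5))
})

test_that("a physical floor below an axial level warns instead of erroring", {
  fs <- list(doe_factor("conc", 1, 1), doe_factor("other", 10, 2))
  expect_warning(central_composite(fs, n_center = 1,
                                   floor = c(conc = 0)), "floor")
})

test_that("design CSV + JSON sidecar round-trips bit-exactly", {
  d <- central_composite(study_f, n_center = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_design(d, path)
  d2 <- read_design(path)
  expect_equal(d2$coded, d$coded)
  expect_equal(d2$alpha, d$alpha)
  expect_equal(d2$point_class, d$point_class)
  expect_equal(vapply(d2$factors, `[[`, 0, "center"),
               vapply(d$factors, `[[`, 0, "center"))
  pb <- plackett_burman(5, 8)
  write_design(pb, path)
  expect_equal(read_design(path)$coded, pb$coded)
})

test_that("seeded run shuffling is reproducible and records its seed", {
  d <- central_composite(study_f, n_center = 6)
  s1 <- shuffle_runs(d, 42)
  s2 <- shuffle_runs(d, 42)
  expect_identical(s1$coded, s2$coded)
  expect_identical(attr(s1, "shuffle_seed"), 42L)
  expect_setequal(apply(s1$coded, 1, paste, collapse = ","),
                  apply(d$coded, 1, paste, collapse = ","))
})
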