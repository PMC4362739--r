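# Shared fixtures and independent oracles for the suite.

# the bundled study's factor coding
study_f <- study_factors()

# dense grid-search oracle for the maximum of a quadratic surface over a
# coded box; chunked along the first axis to keep memory modest
grid_max_oracle <- function(model, lower, upper, step = 0.01) {
  ax1 <- seq(lower[1], upper[1], by = step)
  ax2 <- seq(lower[2], upper[2], by = step)
  ax3 <- if (model$k >= 3) seq(lower[3], upper[3], by = step) else 0
  best <- list(value = -Inf, coded = NULL)
  tail_grid <- as.matrix(expand.grid(ax2, ax3))
  for (a in ax1) {
    pts <- cbind(a, tail_grid)[, seq_len(model$k), drop = FALSE]
    z <- predict(model, pts)
    i <- which.max(z)
    if (z[i] > best$value) best <- list(value = z[i], coded = pts[i, ])
  }
  best
}

# independent least-squares oracle via stats::lm on the expanded terms
lm_quadratic_oracle <- function(coded, y) {
  df <- as.data.frame(coded)
  names(df) <- paste0("x", seq_len(ncol(coded)))
  form <- as.formula(paste(
    "y ~", paste(c(names(df), paste0("I(", names(df), "^2)"),
                   combn(names(df), 2, FUN = paste, collapse = ":")),
                 collapse = " + ")))
  lm(form, data = cbind(df, y = y))
}

# a balanced orthogonal 4-run two-level design built by hand
toy_design_4run <- function() {
  m <- cbind(F1 = c(1, 1, -1, -1), F2 = c(1, -1, 1, -1),
             F3 = c(1, -1, -1, 1))
  structure(list(coded = m, factors = NULL, alpha = NA_real_,
                 n_center = 0L, point_class = rep("pb", 4L)),
            class = "doe_design")
}
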