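test_that("a circular arc fits as a circle", {
  fit <- fit_lordosis_ellipse(sample_arc(1, 90, 13, scale = 150))
  expect_equal(ba_ratio(fit), 1, tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-6 * 150)
})

test_that("noise-free arcs are recovered across the axis-ratio sweep", {
  for (r in c(0.1, 0.3, 0.389, 0.5, 0.8, 1.2)) {
    arc <- sample_arc(r, 85, 13, scale = 180)
    fit <- fit_lordosis_ellipse(arc)
    expect_equal(ba_ratio(fit), r, tolerance = 1e-3)
    expect_lt(fit$rmse, 1e-6 * 180)
    expect_equal(fit$arc_extent, 85, tolerance = 0.1)
  }
})

test_that("the grid-refinement cross-check agrees with the direct method", {
  arc <- sample_arc(0.389, 85, 13, scale = 180)
  direct <- fit_lordosis_ellipse(arc)
  grid <- fit_lordosis_ellipse(arc, fit_options(method = "grid"))
  expect_equal(ba_ratio(grid), ba_ratio(direct), tolerance = 5e-3)
})

test_that("collinear points raise a no-curvature error", {
  expect_error(fit_lordosis_ellipse(cbind(1:13, 2 * (1:13) + 3)),
               "no curvature")
})

test_that("the fit is rigid-motion invariant and scale-invariant in b/a", {
  arc <- sample_arc(0.5, 85, 13, scale = 180)
  th <- 0.61
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  moved <- sweep(arc %*% t(R) * 2.3, 2L, c(41, -12), "+")
  fit <- fit_lordosis_ellipse(moved)
  expect_equal(ba_ratio(fit), 0.5, tolerance = 1e-6)
})

test_that("phase rotation of the sampled arc leaves the fitted ratio alone", {
  for (ph in c(-30, 20, 90)) {
    arc <- sample_arc(0.389, 85, 13, scale = 180, phase = ph)
    expect_equal(ba_ratio(fit_lordosis_ellipse(arc)), 0.389,
                 tolerance = 1e-3)
  }
})

test_that("sample_arc validates its parameters and honours the chord scale", {
  expect_error(sample_arc(0.01, 85, 13), "ba out of range")
  expect_error(sample_arc(0.5, 200, 13), "extent out of range")
  expect_error(sample_arc(0.5, 85, 4), "at least 6")
  arc <- sample_arc(0.7, 70, 9, scale = 144)
  expect_equal(sqrt(sum((arc[9L, ] - arc[1L, ])^2)), 144, tolerance = 1e-9)
  # quarter circle: six points at unit radius from the center
  qc <- sample_arc(1, 90, 6, scale = sqrt(2) * 100)
  expect_equal(unname(sqrt(rowSums(qc^2))), rep(100, 6L), tolerance = 1e-9)
})

test_that("model methods expose coefficients, residuals and predictions", {
  arc <- sample_arc(0.389, 85, 13, scale = 180)
  fit <- fit_lordosis_ellipse(arc)
  cf <- coef(fit)
  expect_named(cf, c("center_x", "center_y", "a", "b", "ba_ratio",
                     "rotation"))
  expect_equal(unname(cf["ba_ratio"]), cf[["b"]] / cf[["a"]])
  expect_length(residuals(fit), 13L)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  pred <- predict(fit, n = 50L)
  expect_equal(dim(pred), c(50L, 2L))
  # predicted curve passes through the data endpoints
  expect_equal(unname(pred[1L, ]), unname(arc[1L, ]), tolerance = 1e-6)
  expect_equal(unname(pred[50L, ]), unname(arc[13L, ]), tolerance = 1e-6)
  expect_output(print(fit), "b/a")
  expect_output(print(summary(fit)), "rmse")
})

test_that("noisy fits stay finite and within the admissible ratio bounds", {
  set.seed(99)
  for (i in 1:10) {
    arc <- sample_arc(0.389, 85, 13, scale = 180)
    noisy <- arc + rnorm(length(arc), sd = 0.5)
    fit <- fit_lordosis_ellipse(noisy)
    expect_true(is.finite(ba_ratio(fit)))
    expect_gt(ba_ratio(fit), 0.02)
    expect_lt(ba_ratio(fit), 1.6)
  }
})
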