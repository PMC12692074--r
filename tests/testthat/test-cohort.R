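test_that("the noise-free generator-measurement round trip is the identity
          on target angles", {
  sp <- spine_from_params(geometry_params(noise_sd = 0))
  rec <- measure_all(sp$set)
  for (v in c("SBA", "PT_S1", "Cobb_T12S1", "ARA_T12S1", "API"))
    expect_equal(rec[[v]], sp$truth[[v]], tolerance = 1e-6)
  expect_equal(rec$ba_ratio, sp$truth$ba_ratio, tolerance = 1e-3)
  expect_equal(rec$PT, sp$truth$PT, tolerance = 1e-6)
})

test_that("unconstructible parameter combinations are rejected", {
  expect_error(geometry_params(pelvic_incidence = 150,
                               sacral_orientation = 30),
               "unconstructible")
  expect_error(geometry_params(t12_tilt = -5))
})

test_that("cohort generation is deterministic given the seed", {
  spec <- cohort_spec(albp = list(SBA = c(44.5, 9.2)), n = 4L, seed = 31L,
                      noise_sd = 0.55)
  a <- generate_cohorts(spec)
  b <- generate_cohorts(spec)
  expect_identical(a$truth, b$truth)
  expect_identical(a$albp$albp_003$points, b$albp$albp_003$points)
  expect_identical(nrow(a$truth), 8L)  # two subjects per group x n
})

test_that("cohort_spec validates inputs", {
  expect_error(cohort_spec(n = 5L), "seed")
  expect_error(cohort_spec(albp = list(BAD = c(1, 1)), n = 5L, seed = 1L),
               "unknown generative variable")
  expect_error(cohort_spec(albp = list(SBA = c(44.5, -1)), n = 5L, seed = 1L),
               "sd >= 0")
  m <- matrix(c(1, 2, 2, 1), 2L, dimnames = list(c("SBA", "API"),
                                                 c("SBA", "API")))
  expect_error(cohort_spec(n = 5L, seed = 1L, correlation = m),
               "positive semi-definite")
})

test_that("measured cohort moments match the specified truncated
          distribution", {
  spec <- cohort_spec(albp = list(SBA = c(44.5, 9.2, 22, 68.2)),
                      n = 400L, seed = 5L, noise_sd = 0)
  coh <- generate_cohorts(spec)
  m <- measure_cohort(coh$albp, ellipse = FALSE)
  expect_equal(mean(m$SBA), 44.5, tolerance = 0.5)
  expect_equal(sd(m$SBA), 9.2, tolerance = 1.0)
  expect_true(all(m$SBA >= 22 & m$SBA <= 68.2))
})

test_that("direct summary draws reproduce their Gaussian model", {
  spec <- cohort_spec(normal = list(SBA = c(39.4, 7.2)),
                      albp = list(SBA = c(44.5, 9.2)),
                      n = 2e5L, seed = 9L)
  d <- summary_cohort(spec)
  expect_equal(mean(d$SBA[d$group == "normal"]), 39.4, tolerance = 0.05)
  expect_equal(sd(d$SBA[d$group == "albp"]), 9.2, tolerance = 0.05)
  # degenerate sd gives a constant column
  dc <- summary_cohort(cohort_spec(normal = list(SBA = c(40, 0)),
                                   albp = list(SBA = c(40, 0)),
                                   n = 10L, seed = 2L))
  expect_true(all(dc$SBA == 40))
})

test_that("the Gaussian copula reproduces the Pearson-to-Spearman map", {
  rho <- -0.73
  cm <- matrix(c(1, rho, rho, 1), 2L,
               dimnames = list(c("SBA", "Cobb_T12S1"),
                               c("SBA", "Cobb_T12S1")))
  spec <- cohort_spec(albp = list(SBA = c(44.5, 9.2),
                                  Cobb_T12S1 = c(-70, 10.1)),
                      normal = list(SBA = c(39.4, 7.2),
                                    Cobb_T12S1 = c(-65.4, 9.4)),
                      n = 2e5L, seed = 12L, correlation = cm)
  d <- summary_cohort(spec)
  got <- cor(d$SBA[d$group == "albp"], d$Cobb_T12S1[d$group == "albp"],
             method = "spearman")
  expect_equal(got, (6 / pi) * asin(rho / 2), tolerance = 0.01)
})

test_that("repeated noisy digitizations of one subject spread each angle by
          one to three degrees", {
  set.seed(11)
  p <- geometry_params()  # default calibrated digitization noise
  m <- do.call(rbind, lapply(1:200, function(i)
    measure_all(spine_from_params(p)$set, ellipse = FALSE)))
  sem <- vapply(m[, c("ARA_L1L5", "ARA_T12S1", "Cobb_T12S1", "SBA",
                      "PT_S1", "API", "PTPIA")], sd, numeric(1L))
  expect_true(all(sem >= 1 & sem <= 3))
})

test_that("generated cohorts at the published group parameters separate in
          the published direction", {
  spec <- reference_cohort_spec(n = 150L, seed = 77L, noise_sd = 0)
  coh <- generate_cohorts(spec)
  m <- rbind(measure_cohort(coh$normal, ellipse = FALSE),
             measure_cohort(coh$albp, ellipse = FALSE))
  sba_n <- mean(m$SBA[m$group == "normal"])
  sba_a <- mean(m$SBA[m$group == "albp"])
  expect_gt(sba_a, sba_n)
  expect_gt(abs(mean(m$Cobb_T12S1[m$group == "albp"])),
            abs(mean(m$Cobb_T12S1[m$group == "normal"])))
})
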