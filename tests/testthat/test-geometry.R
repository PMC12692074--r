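test_that("angle primitives follow their sign and range conventions", {
  expect_equal(angle_to_vertical(tangent_line(c(0, 0), c(0, 1))), 0)
  expect_equal(angle_to_vertical(tangent_line(c(0, 0),
                                              c(sin(pi / 4), cos(pi / 4)))),
               45)
  # posterior lean is negative; caudally supplied directions are re-oriented
  expect_equal(angle_to_vertical(tangent_line(c(1, 2), c(0.5, -1))),
               -atan2(0.5, 1) * 180 / pi)
  expect_error(tangent_line(c(0, 0), c(0, 0)), "degenerate")

  expect_equal(angle_to_horizontal(c(0, 0), c(10, 0)), 0)
  expect_equal(angle_to_horizontal(c(0, 0), c(cos(pi / 6), sin(pi / 6))), 30)
  expect_equal(angle_to_horizontal(c(0, 0), c(-3, 3)), 45)  # acute, unsigned
  expect_error(angle_to_horizontal(c(1, 1), c(1, 1)), "degenerate")
})

test_that("posterior tangents use the corner pair, and the endplate
          perpendicular at T12", {
  pts <- rbind(L3_ps = c(0, 30), L3_pi = c(0, 0),
               T12_pi = c(0, 100), T12_ai = c(35, 100))
  set <- landmark_set("t", "unknown", pts)
  expect_equal(posterior_tangent(set, "L3")$direction, c(0, 1))
  # horizontal T12 inferior endplate -> vertical tangent
  expect_equal(posterior_tangent(set, "T12")$direction, c(0, 1))
  expect_error(posterior_tangent(set, "L4"), "missing")
})

test_that("ARA is the tangent angle difference, negative for lordosis", {
  sp <- mean_normal_spine()
  expect_equal(ara(sp$set, "T12", "S1"), -76.3, tolerance = 1e-9)
  expect_equal(ara(sp$set, "T12", "S1"), -ara(sp$set, "S1", "T12"))
  # parallel tangents give zero
  pts <- rbind(L1_ps = c(0, 90), L1_pi = c(0, 60),
               L5_ps = c(5, 30), L5_pi = c(5, 0))
  set <- landmark_set("p", "unknown", pts)
  expect_equal(ara(set, "L1", "L5"), 0)
})

test_that("Cobb T12-S1 is signed, zero for parallel endplates, and obeys
          the SBA + T12-tilt additivity", {
  pts <- rbind(T12_pi = c(0, 100), T12_ai = c(35, 110),
               S1_ps = c(0, 0), S1_as = c(35, 10))
  expect_equal(cobb_t12_s1(landmark_set("p", "unknown", pts)), 0)

  sp <- mean_normal_spine()
  expect_equal(cobb_t12_s1(sp$set), -65.4, tolerance = 1e-9)
  expect_equal(abs(cobb_t12_s1(sp$set)),
               sacral_base_angle(sp$set) + 26.0, tolerance = 1e-9)

  albp <- spine_from_params(geometry_params(sacral_orientation = 44.5,
                                            t12_tilt = 70 - 44.5,
                                            noise_sd = 0))
  expect_equal(cobb_t12_s1(albp$set), -70.0, tolerance = 1e-9)
})

test_that("sacral and pelvic angles reproduce their construction targets", {
  sp <- mean_normal_spine()
  expect_equal(sacral_base_angle(sp$set), 39.4, tolerance = 1e-9)
  expect_equal(pt_s1(sp$set), 50.3, tolerance = 1e-9)
  expect_equal(api(sp$set), 56.8, tolerance = 1e-9)
  expect_equal(pelvic_tilt(sp$set), 56.8 - 39.4, tolerance = 1e-9)
  expect_equal(sacral_slope(sp$set), sacral_base_angle(sp$set))
})

test_that("the Legaye identity API = PT + SS and the PTPIA decomposition
          hold on random noise-free pelves", {
  set.seed(421)
  for (i in 1:250) {
    s <- spine_from_params(random_params())$set
    expect_lt(abs(api(s) - pelvic_tilt(s) - sacral_slope(s)), 1e-9)
    expect_lt(abs(ptpia(s) - pr_to_vertical(s) - pt_s1(s)), 1e-9)
  }
})

test_that("internal angles are rigid-motion invariant while gravity-referenced
          angles shift by the applied rotation", {
  set.seed(7)
  sp <- spine_from_params(random_params())$set
  moved <- transform_set(sp, ang = 8, shift = c(120, -45), scale = 1.7)
  for (f in list(ara_t12s1 = function(s) ara(s, "T12", "S1"),
                 cobb = cobb_t12_s1, api = api, ptpia = ptpia))
    expect_equal(f(moved), f(sp), tolerance = 1e-9)
  # rotation equivariance: a CCW (posterior) rotation flattens the sacral
  # base and the S1 tangent and tips the pelvis back, each by the applied
  # angle (small rotation, so no sign crossings)
  rot <- transform_set(sp, ang = 5)
  expect_equal(sacral_base_angle(rot), sacral_base_angle(sp) - 5,
               tolerance = 1e-9)
  expect_equal(pt_s1(rot), pt_s1(sp) - 5, tolerance = 1e-9)
  expect_equal(pelvic_tilt(rot), pelvic_tilt(sp) + 5, tolerance = 1e-9)
  # pure translation changes nothing
  shifted <- transform_set(sp, shift = c(-30, 55))
  expect_equal(pelvic_tilt(shifted), pelvic_tilt(sp), tolerance = 1e-12)
  expect_equal(sacral_base_angle(shifted), sacral_base_angle(sp),
               tolerance = 1e-12)
})

test_that("swapping the femoral head landmarks changes no pelvic measure", {
  sp <- mean_normal_spine()$set
  pts <- sp$points
  rownames(pts)[match(c("FEM_L", "FEM_R"), rownames(pts))] <-
    c("FEM_R", "FEM_L")
  swapped <- landmark_set(sp$subject_id, sp$group, pts)
  expect_equal(api(swapped), api(sp))
  expect_equal(pelvic_tilt(swapped), pelvic_tilt(sp))
  expect_equal(ptpia(swapped), ptpia(sp))
})

test_that("measure_all fills every field, computes the morphology-lordosis
          differences literally, and tolerates incomplete sets", {
  sp <- mean_normal_spine()
  rec <- measure_all(sp$set)
  expect_false(anyNA(rec))
  expect_equal(rec$API_minus_ARA_T12S1, rec$API + rec$ARA_T12S1)
  # 56.8 + (-76.3): subtracting a negative lordosis value
  expect_equal(rec$API_minus_ARA_T12S1, -19.5, tolerance = 1e-9)
  expect_equal(rec$sacral_tilt, rec$PT_S1)

  partial <- sp$set$points[setdiff(rownames(sp$set$points),
                                   c("FEM_L", "FEM_R")), ]
  rec2 <- measure_all(landmark_set("p", "normal", partial))
  expect_true(is.na(rec2$API) && is.na(rec2$PT))
  expect_equal(rec2$SBA, 39.4, tolerance = 1e-9)

  # the pubis feeds no angle
  nopub <- sp$set$points[setdiff(rownames(sp$set$points), "PUBIS"), ]
  rec3 <- measure_all(landmark_set("np", "normal", nopub))
  expect_equal(rec3$API, rec$API)
  expect_equal(rec3$ba_ratio, rec$ba_ratio)
})
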