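# Shared fixtures built in code.

# a complete noise-free subject at the asymptomatic-group mean alignment
mean_normal_spine <- function(subject_id = "s1", group = "normal") {
  spine_from_params(geometry_params(noise_sd = 0), subject_id = subject_id,
                    group = group)
}

# rigid motion of a landmark set: rotate by `ang` degrees CCW about the
# origin, then translate, then scale about the origin
transform_set <- function(set, ang = 0, shift = c(0, 0), scale = 1) {
  a <- ang * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L)
  pts <- set$points %*% t(R) * scale
  pts <- sweep(pts, 2L, shift, "+")
  colnames(pts) <- c("x", "y")
  landmark_set(set$subject_id, set$group, pts)
}

# random constructible geometry parameters with standard (posteriorly
# leaning pelvic radius) anatomy
random_params <- function() {
  s <- runif(1, 25, 65)
  geometry_params(
    ba = runif(1, 0.1, 1.2), arc_extent = runif(1, 60, 110),
    sacral_orientation = s, t12_tilt = runif(1, 5, 40),
    sacral_tilt = runif(1, 30, 65),
    pelvic_incidence = s + runif(1, 5, 30),
    pelvic_radius = runif(1, 100, 160), noise_sd = 0
  )
}

# brute-force Mann-Whitney U based AUC by exhaustive pair counting
pair_count_auc <- function(x0, x1) {
  (sum(outer(x1, x0, ">")) + 0.5 * sum(outer(x1, x0, "=="))) /
    (length(x0) * length(x1))
}

# directional two-sample K-S statistic max(F0 - F1) over all thresholds
directional_ks <- function(x0, x1) {
  g <- sort(unique(c(x0, x1)))
  max(ecdf(x0)(g) - ecdf(x1)(g))
}
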