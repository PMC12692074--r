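# Synthetic landmark-level subjects and two-group cohorts.
#
# The generator inverts the geometry module: it picks the primary generative
# parameters (sacral base angle, lordosis arc shape b/a and extent, pelvic
# incidence, sacral tilt, and optionally a Cobb target realized through the
# T12 endplate tilt) and constructs 18 named landmarks whose measured angles
# reproduce those targets exactly in the noise-free case.  Digitization error
# is modelled as i.i.d. isotropic Gaussian noise per coordinate.

# Relative arc-length positions of the 13 posterior corners along the
# lordotic arc, from alternating disc (10 units) and posterior body
# (28 units) spacings T12_pi -> S1_pi.
POSTERIOR_ARC_FRACTIONS <- local({
  steps <- rep(c(10, 28), 6L)
  cum <- cumsum(c(0, steps))
  cum / cum[length(cum)]
})

#' Geometric parameters of one synthetic subject
#'
#' Defaults are the asymptomatic-group mean alignment: sacral base angle
#' 39.4 deg, T12 inferior-endplate tilt 26 deg (so Cobb T12-S1 = -65.4 deg),
#' sacral tilt 50.3 deg (so ARA T12-S1 = -76.3 deg), pelvic incidence
#' 56.8 deg, and a lordotic arc with b/a = 0.389 spanning 85 deg.
#'
#' @param ba ellipse axis ratio of the lordotic arc.
#' @param arc_extent angular extent of the arc, degrees.
#' @param sacral_orientation target sacral base angle (SBA), degrees.
#' @param t12_tilt target anterior-superior tilt of the T12 inferior
#'   endplate, degrees; the noise-free Cobb T12-S1 equals
#'   `-(sacral_orientation + t12_tilt)`.
#' @param sacral_tilt target S1 posterior-tangent-to-vertical (PT-S1),
#'   degrees anterior lean.
#' @param pelvic_incidence target API, degrees.
#' @param pelvic_radius distance from the S1 mid-endplate to the hip axis, mm.
#' @param scale chord length T12_pi to S1_pi, mm.
#' @param body_depth sagittal endplate depth used for T12_ai and S1_as, mm.
#' @param noise_sd digitization noise SD per coordinate, mm.  The default
#'   0.55 mm is calibrated by first-order error propagation so the per-angle
#'   standard error of repeated digitizations lands in the 1-3 degree band
#'   reported for these measures.
#' @return list of class `geometry_params`.
#' @export
geometry_params <- function(ba = 0.389, arc_extent = 85,
                            sacral_orientation = 39.4, t12_tilt = 26.0,
                            sacral_tilt = 50.3, pelvic_incidence = 56.8,
                            pelvic_radius = 130, scale = 180,
                            body_depth = 35, noise_sd = 0.55) {
  p <- list(ba = ba, arc_extent = arc_extent,
            sacral_orientation = sacral_orientation, t12_tilt = t12_tilt,
            sacral_tilt = sacral_tilt, pelvic_incidence = pelvic_incidence,
            pelvic_radius = pelvic_radius, scale = scale,
            body_depth = body_depth, noise_sd = noise_sd)
  stopifnot(all(vapply(p, is.numeric, logical(1L))),
            scale > 0, body_depth > 0, pelvic_radius > 0, noise_sd >= 0,
            t12_tilt >= 0)
  if (abs(pelvic_incidence - sacral_orientation) >= 90)
    stop("unconstructible parameters: hip axis would sit above the S1 ",
         "endplate (|API - SBA| >= 90)", call. = FALSE)
  structure(p, class = "geometry_params")
}

# rotate points (n x 2) counter-clockwise by `ang` degrees about the origin
rotate_pts <- function(pts, ang) {
  a <- rad(ang); R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L)
  out <- pts %*% t(R)
  colnames(out) <- c("x", "y")
  out
}

#' Construct the 18 landmarks of one synthetic subject
#'
#' Deterministic given the parameters and the RNG state (noise only).  The
#' posterior corners are sampled on the elliptical arc at anatomical
#' disc/body spacings and rotated so the S1 posterior-tangent secant realizes
#' the `sacral_tilt` target; S1_as realizes the sacral base angle, T12_ai the
#' T12 endplate tilt, and the hip axis is placed on the ray from the S1
#' mid-endplate that realizes the pelvic incidence at distance
#' `pelvic_radius` (femoral heads split symmetrically about it; the pubis is
#' a decorative offset that feeds no angle).
#'
#' @param p a [geometry_params()] object.
#' @param subject_id,group identification carried into the landmark set.
#' @return list with `set` (a [landmark_set()]) and `truth` (one-row
#'   data.frame of the noise-free target angles).
#' @export
spine_from_params <- function(p, subject_id = "synthetic", group = "unknown") {
  stopifnot(inherits(p, "geometry_params"))
  arc <- sample_arc(p$ba, p$arc_extent, 13L, scale = p$scale,
                    spacing = POSTERIOR_ARC_FRACTIONS)
  # rotate so the S1 posterior-tangent secant (points 12-13) leans anterior
  # by sacral_tilt; a CCW rotation by r changes an angle-to-vertical by -r
  phi0 <- angle_to_vertical(tangent_line(arc[13L, ], arc[12L, ] - arc[13L, ]))
  arc <- rotate_pts(arc, phi0 - p$sacral_tilt)
  # anchor S1_ps at the origin (the frame origin is arbitrary)
  arc <- sweep(arc, 2L, arc[12L, ])
  rownames(arc) <- POSTERIOR_CORNERS

  s <- rad(p$sacral_orientation)
  s1_ps <- arc["S1_ps", ]
  s1_as <- s1_ps + p$body_depth * c(cos(s), -sin(s))
  tau <- rad(p$t12_tilt)
  t12_ai <- arc["T12_pi", ] + p$body_depth * c(cos(tau), sin(tau))
  s1_mid <- (s1_ps + s1_as) / 2
  beta <- rad(p$pelvic_incidence) - s
  ha <- s1_mid + p$pelvic_radius * c(sin(beta), -cos(beta))
  fem_off <- c(7, 0)
  pts <- rbind(arc,
               T12_ai = t12_ai, S1_as = s1_as,
               FEM_L = ha + fem_off, FEM_R = ha - fem_off,
               PUBIS = ha + c(70, -60))
  if (p$noise_sd > 0)
    pts <- pts + stats::rnorm(length(pts), sd = p$noise_sd)
  set <- landmark_set(subject_id, group, pts[LANDMARK_NAMES, ])

  truth <- data.frame(
    subject_id = subject_id, group = group,
    SBA = p$sacral_orientation,
    PT_S1 = p$sacral_tilt,
    Cobb_T12S1 = -(p$sacral_orientation + p$t12_tilt),
    ARA_T12S1 = -(p$t12_tilt + p$sacral_tilt),
    API = p$pelvic_incidence,
    PT = p$pelvic_incidence - p$sacral_orientation,
    ba_ratio = p$ba, arc_extent = p$arc_extent,
    stringsAsFactors = FALSE
  )
  list(set = set, truth = truth)
}

# -- truncated normal with moment matching -----------------------------------

trunc_moments <- function(mu, sig, lo, hi) {
  al <- (lo - mu) / sig; be <- (hi - mu) / sig
  Z <- stats::pnorm(be) - stats::pnorm(al)
  dm <- (stats::dnorm(al) - stats::dnorm(be)) / Z
  m <- mu + sig * dm
  al_t <- if (is.finite(al)) al * stats::dnorm(al) else 0
  be_t <- if (is.finite(be)) be * stats::dnorm(be) else 0
  v <- sig^2 * (1 + (al_t - be_t) / Z - dm^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Underlying (mu, sigma) such that the [lo, hi]-truncated normal has the
# requested mean and sd.  Identity when the bounds are effectively inactive.
match_trunc_params <- function(mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(c(mu = mean, sigma = max(sd, 0)))
  if (!is.finite(lo) && !is.finite(hi)) return(c(mu = mean, sigma = sd))
  obj <- function(par) {
    mm <- trunc_moments(par[1L], exp(par[2L]), lo, hi)
    (mm[1L] - mean)^2 + (mm[2L] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000L))
  got <- trunc_moments(fit$par[1L], exp(fit$par[2L]), lo, hi)
  if (abs(got[1L] - mean) > 0.05 * max(1, abs(mean)))
    warning("truncation bounds too tight to match the requested mean",
            call. = FALSE)
  c(mu = fit$par[1L], sigma = exp(fit$par[2L]))
}

qtruncnorm <- function(u, mu, sigma, lo = -Inf, hi = Inf) {
  if (sigma <= 0) return(rep(mu, length(u)))
  plo <- stats::pnorm(lo, mu, sigma); phi <- stats::pnorm(hi, mu, sigma)
  stats::qnorm(plo + u * (phi - plo), mu, sigma)
}

# -- cohort specification ----------------------------------------------------

#' Specification of a two-group synthetic cohort
#'
#' The primary generative parameters are the sacral base angle (`SBA`), the
#' Cobb target (`Cobb_T12S1`; realized through the T12 endplate tilt), the
#' ellipse ratio (`ba_ratio`), the pelvic incidence (`API`) and the sacral
#' tilt (`PT_S1`).  Each is described by `c(mean, sd)` or
#' `c(mean, sd, min, max)` (truncation bounds; the underlying Gaussian is
#' moment-matched so the truncated draw keeps the requested mean and SD).
#' Variables omitted from a group keep their [geometry_params()] defaults as
#' constants.
#'
#' @param normal,albp named lists of parameter vectors as above.
#' @param n subjects per group (>= 2).
#' @param seed integer seed; mandatory for reproducibility.
#' @param noise_sd digitization noise SD in mm applied to every coordinate.
#' @param correlation optional correlation matrix (Gaussian copula) whose
#'   dimnames are a subset of the generative variable names.
#' @param antithetic use antithetic inverse-CDF pairs so cohort-level moments
#'   are stable at moderate n (default `TRUE`).
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(normal = list(), albp = list(), n = 50L, seed,
                        noise_sd = 0, correlation = NULL, antithetic = TRUE) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(n >= 2L)
  known <- c("SBA", "Cobb_T12S1", "ba_ratio", "API", "PT_S1")
  for (g in list(normal = normal, albp = albp)) {
    bad <- setdiff(names(g), known)
    if (length(bad))
      stop("unknown generative variable(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (v in g)
      if (!length(v) %in% c(2L, 4L) || v[2L] < 0)
        stop("each variable needs c(mean, sd) or c(mean, sd, min, max) ",
             "with sd >= 0", call. = FALSE)
  }
  if (!is.null(correlation)) {
    stopifnot(is.matrix(correlation),
              nrow(correlation) == ncol(correlation),
              !is.null(rownames(correlation)))
    if (min(eigen(correlation, symmetric = TRUE,
                  only.values = TRUE)$values) < -1e-8)
      stop("correlation matrix is not positive semi-definite", call. = FALSE)
  }
  structure(list(normal = normal, albp = albp, n = as.integer(n),
                 seed = as.integer(seed), noise_sd = noise_sd,
                 correlation = correlation,
                 antithetic = isTRUE(antithetic)),
            class = "cohort_spec")
}

# Draw an n x length(vars) matrix of generative parameter values for one
# group.  Correlated via Gaussian copula; marginals are moment-matched
# truncated normals; antithetic pairing halves the Monte-Carlo error of the
# cohort moments.
draw_group_params <- function(gspec, n, correlation, antithetic) {
  vars <- names(gspec)
  if (!length(vars)) return(matrix(numeric(0), nrow = n, ncol = 0L))
  k <- length(vars)
  m <- if (antithetic) ceiling(n / 2) else n
  z <- matrix(stats::rnorm(m * k), m, k)
  if (!is.null(correlation)) {
    use <- intersect(vars, rownames(correlation))
    if (length(use) > 1L) {
      L <- chol(correlation[use, use])
      z[, match(use, vars)] <- z[, match(use, vars), drop = FALSE] %*% L
    }
  }
  u <- stats::pnorm(z)
  if (antithetic) u <- rbind(u, 1 - u)[seq_len(n), , drop = FALSE]
  out <- matrix(NA_real_, n, k, dimnames = list(NULL, vars))
  for (j in seq_len(k)) {
    v <- gspec[[j]]
    lo <- if (length(v) == 4L) v[3L] else -Inf
    hi <- if (length(v) == 4L) v[4L] else Inf
    if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
    mp <- match_trunc_params(v[1L], v[2L], lo, hi)
    out[, j] <- qtruncnorm(u[, j], mp[1L], mp[2L], lo, hi)
  }
  out
}

params_from_draw <- function(draw, noise_sd) {
  defaults <- geometry_params()
  sba <- if ("SBA" %in% names(draw)) draw[["SBA"]]
  else defaults$sacral_orientation
  t12 <- if ("Cobb_T12S1" %in% names(draw)) abs(draw[["Cobb_T12S1"]]) - sba
  else defaults$t12_tilt
  geometry_params(
    ba = if ("ba_ratio" %in% names(draw)) draw[["ba_ratio"]] else defaults$ba,
    sacral_orientation = sba,
    t12_tilt = t12,
    sacral_tilt = if ("PT_S1" %in% names(draw)) draw[["PT_S1"]]
    else defaults$sacral_tilt,
    pelvic_incidence = if ("API" %in% names(draw)) draw[["API"]]
    else defaults$pelvic_incidence,
    noise_sd = noise_sd
  )
}

#' Generate a two-group landmark-level cohort
#'
#' Draws per-subject generative parameters from the group models of the
#' spec (truncated, optionally correlated Gaussians), realizes each subject
#' via [spine_from_params()], and returns the landmark sets together with the
#' noise-free truth table.  Fully reproducible from the spec seed.
#'
#' Subjects whose draw is geometrically unconstructible (for example a Cobb
#' target whose magnitude falls below the drawn sacral base angle, leaving no
#' admissible T12 tilt) are redrawn; if more than half of all draws are
#' rejected the spec is declared infeasible.
#'
#' @param spec a [cohort_spec()].
#' @return list with `normal` and `albp` (lists of [landmark_set()]) and
#'   `truth` (data.frame of target angles for every subject).
#' @export
generate_cohorts <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  out <- list()
  truth <- list()
  for (grp in c("normal", "albp")) {
    draws <- draw_group_params(spec[[grp]], spec$n, spec$correlation,
                               spec$antithetic)
    total <- spec$n; rejected <- 0L
    if (ncol(draws)) {
      feasible <- function(d) {
        sba <- if ("SBA" %in% colnames(draws)) d[["SBA"]]
        else geometry_params()$sacral_orientation
        !("Cobb_T12S1" %in% colnames(draws)) || abs(d[["Cobb_T12S1"]]) > sba
      }
      for (i in seq_len(spec$n)) {
        tries <- 0L
        while (!feasible(draws[i, ]) && tries < 100L) {
          draws[i, ] <- draw_group_params(spec[[grp]], 1L, spec$correlation,
                                          antithetic = FALSE)
          rejected <- rejected + 1L; total <- total + 1L
          tries <- tries + 1L
        }
        if (!feasible(draws[i, ]))
          stop("infeasible cohort spec: could not draw constructible ",
               "parameters", call. = FALSE)
      }
      if (rejected / total > 0.5)
        stop("infeasible cohort spec: more than half of all draws rejected",
             call. = FALSE)
    }
    subjects <- vector("list", spec$n)
    truths <- vector("list", spec$n)
    for (i in seq_len(spec$n)) {
      d <- if (ncol(draws)) as.list(draws[i, ]) else list()
      sp <- spine_from_params(params_from_draw(d, spec$noise_sd),
                              subject_id = sprintf("%s_%03d", grp, i),
                              group = grp)
      subjects[[i]] <- sp$set
      truths[[i]] <- sp$truth
    }
    names(subjects) <- vapply(subjects, `[[`, "", "subject_id")
    out[[grp]] <- subjects
    truth[[grp]] <- do.call(rbind, truths)
  }
  out$truth <- do.call(rbind, truth)
  rownames(out$truth) <- NULL
  out
}

#' Draw measurement vectors directly from the group models
#'
#' Bypasses landmark construction: samples per-variable values from the
#' (optionally correlated) Gaussian model of each group -- the binormal
#' approximation used for distribution-level statistics such as ROC curves.
#' No truncation is applied.
#'
#' @param spec a [cohort_spec()]; each listed variable contributes a column.
#' @return data.frame with a `group` column and one column per variable.
#' @export
summary_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  rows <- lapply(c("normal", "albp"), function(grp) {
    gspec <- spec[[grp]]
    vars <- names(gspec)
    k <- length(vars)
    z <- matrix(stats::rnorm(spec$n * k), spec$n, k,
                dimnames = list(NULL, vars))
    if (!is.null(spec$correlation)) {
      use <- intersect(vars, rownames(spec$correlation))
      if (length(use) > 1L) {
        L <- chol(spec$correlation[use, use])
        z[, use] <- z[, use, drop = FALSE] %*% L
      }
    }
    for (j in seq_len(k))
      z[, j] <- gspec[[j]][1L] + gspec[[j]][2L] * z[, j]
    data.frame(group = grp, z, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
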