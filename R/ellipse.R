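# Least-squares elliptical modeling of the lumbar lordosis.
#
# The lordotic arc is represented by the 13 posterior vertebral body corners
# from T12_pi to S1_pi.  An ellipse is fitted to them in two stages: a direct
# (ellipse-specific) algebraic conic fit for the seed, followed by an
# orthogonal-distance polish over (center, semi-axes, rotation).  The shape
# descriptor is the b/a axis ratio, where "a" is the semi-axis most parallel
# to the T12-S1 chord and "b" the perpendicular one -- a labeling under which
# b/a may exceed 1 when the sagittal bulge exceeds the craniocaudal
# half-span.

#' Ellipse fitting options
#'
#' @param method `"direct"` (algebraic conic seed + orthogonal-distance
#'   polish, the default) or `"grid"` (deterministic multi-start refinement
#'   over a fixed lattice of orientations and axis ratios, retained as a
#'   cross-check oracle).
#' @param ba_bounds admissible axis-ratio interval; the default covers the
#'   observed clinical range.
#' @param tol relative convergence tolerance of the polish.
#' @param max_iter iteration cap per optimizer start.
#' @return list of class `fit_options`.
#' @export
fit_options <- function(method = c("direct", "grid"),
                        ba_bounds = c(0.02, 1.6),
                        tol = 1e-9, max_iter = 500L) {
  method <- match.arg(method)
  stopifnot(length(ba_bounds) == 2L, all(ba_bounds > 0),
            ba_bounds[1L] < ba_bounds[2L], tol > 0)
  structure(list(method = method, ba_bounds = ba_bounds,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "fit_options")
}

# -- point-to-ellipse orthogonal distance ------------------------------------

# Signed-free orthogonal distances of points to the ellipse
# (cx, cy, A, B, theta): rotate into the axis-aligned frame and, per point,
# find the parametric angle of the nearest ellipse point by Newton iteration
# with a golden-section fallback.
ellipse_distances <- function(pts, cx, cy, A, B, theta) {
  ct <- cos(theta); st <- sin(theta)
  p <- (pts[, 1L] - cx) * ct + (pts[, 2L] - cy) * st
  q <- -(pts[, 1L] - cx) * st + (pts[, 2L] - cy) * ct
  # vectorized Newton on the foot-point parameter of every point at once
  t0 <- atan2(q / B, p / A)
  t <- t0
  conv <- rep(FALSE, length(t))
  for (k in 1:40) {
    g <- (B^2 - A^2) * cos(t) * sin(t) + p * A * sin(t) - q * B * cos(t)
    dg <- (B^2 - A^2) * cos(2 * t) + p * A * cos(t) + q * B * sin(t)
    step <- g / dg
    step[!is.finite(step)] <- 0
    t <- t - step
    conv <- abs(step) < 1e-12
    if (all(conv)) break
  }
  d <- sqrt((A * cos(t) - p)^2 + (B * sin(t) - q)^2)
  # guard against convergence to the wrong critical point: the true foot
  # distance can never exceed the distance to the seed point on the ellipse
  d0 <- sqrt((A * cos(t0) - p)^2 + (B * sin(t0) - q)^2)
  bad <- !conv | d > d0 + 1e-12
  if (any(bad)) {
    for (i in which(bad)) d[i] <- point_ellipse_dist(p[i], q[i], A, B)
  }
  d
}

point_ellipse_dist <- function(p, q, A, B) {
  f <- function(t) (A * cos(t) - p)^2 + (B * sin(t) - q)^2
  g <- function(t) (B^2 - A^2) * cos(t) * sin(t) +
    p * A * sin(t) - q * B * cos(t)  # = f'(t)/2, zero at the foot point
  t <- atan2(q / B, p / A)
  ok <- FALSE
  for (k in 1:60) {
    gt <- g(t)
    dg <- (B^2 - A^2) * cos(2 * t) + p * A * cos(t) + q * B * sin(t)
    if (!is.finite(dg) || abs(dg) < 1e-300) break
    step <- gt / dg
    t <- t - step
    if (abs(step) < 1e-14) { ok <- TRUE; break }
  }
  if (!ok || !is.finite(t)) {
    # robust fallback: coarse scan + golden-section refinement
    ts <- seq(-pi, pi, length.out = 721L)
    t0 <- ts[which.min(f(ts))]
    opt <- stats::optimize(f, c(t0 - 0.02, t0 + 0.02), tol = 1e-12)
    t <- opt$minimum
  }
  sqrt(f(t))
}

# -- direct algebraic conic fit (stable ellipse-specific formulation) --------

direct_conic_fit <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)
  ev <- eigen(M)
  cond <- 4 * Re(ev$vectors[1L, ]) * Re(ev$vectors[3L, ]) -
    Re(ev$vectors[2L, ])^2
  idx <- which(cond > 0)
  if (!length(idx))
    stop("ellipse-specific conic fit found no elliptical solution",
         call. = FALSE)
  a1 <- Re(ev$vectors[, idx[1L]])
  c(a1, as.numeric(Tm %*% a1))  # (A, B, C, D, E, F)
}

conic_to_geometric <- function(co) {
  A <- co[1L]; B <- co[2L]; C <- co[3L]; D <- co[4L]; E <- co[5L]; F <- co[6L]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("conic is not an ellipse", call. = FALSE)
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  theta <- 0.5 * atan2(B, A - C)
  ct <- cos(theta); st <- sin(theta)
  Ar <- A * ct^2 + B * ct * st + C * st^2
  Cr <- A * st^2 - B * ct * st + C * ct^2
  if (Ar * Fc >= 0 || Cr * Fc >= 0)
    stop("degenerate conic", call. = FALSE)
  list(cx = cx, cy = cy, A = sqrt(-Fc / Ar), B = sqrt(-Fc / Cr),
       theta = theta)
}

# -- objective + polish ------------------------------------------------------

ellipse_objective <- function(par, pts) {
  A <- exp(par[3L]); B <- exp(par[4L])
  d <- ellipse_distances(pts, par[1L], par[2L], A, B, par[5L])
  sum(d^2)
}

polish_fit <- function(seed, pts, opts) {
  par0 <- unname(c(seed$cx, seed$cy, log(seed$A), log(seed$B), seed$theta))
  o1 <- tryCatch(
    stats::optim(par0, ellipse_objective, pts = pts, method = "BFGS",
                 control = list(maxit = opts$max_iter, reltol = opts$tol)),
    error = function(e) list(par = par0,
                             value = ellipse_objective(par0, pts),
                             convergence = 1L))
  best <- o1
  if (!identical(o1$convergence, 0L)) {
    o2 <- stats::optim(o1$par, ellipse_objective, pts = pts,
                       method = "Nelder-Mead",
                       control = list(maxit = opts$max_iter,
                                      reltol = opts$tol))
    if (o2$value <= o1$value) best <- o2
  }
  list(cx = best$par[1L], cy = best$par[2L],
       A = exp(best$par[3L]), B = exp(best$par[4L]),
       theta = best$par[5L], value = best$value)
}

# deterministic multi-start lattice (cross-check method)
grid_refine_fit <- function(pts, opts) {
  ch <- pts[nrow(pts), ] - pts[1L, ]
  span <- sqrt(sum(ch^2))
  mid <- (pts[nrow(pts), ] + pts[1L, ]) / 2
  chord_theta <- atan2(ch[2L], ch[1L])
  ratios <- c(0.1, 0.2, 0.389, 0.6, 0.8, 1.0, 1.3)
  offsets <- c(0.2, 0.5, 1.0) * span
  best <- NULL
  # perpendicular (pointing away from the data bulge) for center seeds
  perp <- c(-ch[2L], ch[1L]) / span
  bulge <- colMeans(pts) - mid
  if (sum(perp * bulge) > 0) perp <- -perp
  for (r in ratios) for (off in offsets) {
    seed <- list(cx = mid[1L] + perp[1L] * off,
                 cy = mid[2L] + perp[2L] * off,
                 A = max(span / 2, off * 1.2), B = max(span / 2, off * 1.2) * r,
                 theta = chord_theta)
    fit <- tryCatch(polish_fit(seed, pts, opts), error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("grid refinement failed to converge", call. = FALSE)
  best
}

# -- public fit --------------------------------------------------------------

#' Fit the lordosis ellipse
#'
#' Fits an ellipse to the 13 posterior vertebral body corners (T12_pi through
#' S1_pi) of a landmark set -- or to any n x 2 matrix of arc points --
#' minimizing the summed squared orthogonal distances of the points to the
#' ellipse over center, semi-axes and rotation.
#'
#' @param x a [landmark_set()] (its posterior corners are used) or a numeric
#'   matrix of points, ordered cranial to caudal.
#' @param opts a [fit_options()] object.
#' @return object of class `lordosis_ellipse` with components `center`,
#'   `a` and `b` (semi-axes, mm; `a` is the axis most parallel to the
#'   cranial-caudal chord), `rotation` (orientation of the `a` axis from
#'   vertical, degrees), `rmse` (root-mean-square orthogonal residual, mm),
#'   `arc_extent` (angular span of the data on the fitted ellipse, degrees),
#'   and the data `points`.
#' @examples
#' arc <- sample_arc(0.389, 85, 13, scale = 180)
#' fit <- fit_lordosis_ellipse(arc)
#' ba_ratio(fit)
#' @export
fit_lordosis_ellipse <- function(x, opts = fit_options()) {
  pts <- if (inherits(x, "landmark_set")) lm_pts(x, POSTERIOR_CORNERS)
  else as.matrix(x)
  if (nrow(pts) < 6L)
    stop("ellipse fitting needs at least 6 points", call. = FALSE)

  # collinearity check: orthogonal spread relative to the chord span
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, ctr))$d
  if (sv[2L] < 1e-8 * sv[1L])
    stop("no curvature: points are (near-)collinear, cannot fit an ellipse",
         call. = FALSE)

  # normalize for conditioning
  scl <- mean(sqrt(rowSums(sweep(pts, 2L, ctr)^2)))
  z <- sweep(pts, 2L, ctr) / scl

  fit <- if (opts$method == "direct") {
    seed <- conic_to_geometric(direct_conic_fit(z))
    if (ellipse_objective(c(seed$cx, seed$cy, log(seed$A), log(seed$B),
                            seed$theta), z) < (1e-10)^2 * nrow(z)) {
      seed$value <- sum(ellipse_distances(z, seed$cx, seed$cy, seed$A,
                                          seed$B, seed$theta)^2)
      seed
    } else polish_fit(seed, z, opts)
  } else grid_refine_fit(z, opts)

  # de-normalize
  cx <- unname(fit$cx * scl + ctr[1L]); cy <- unname(fit$cy * scl + ctr[2L])
  A <- unname(fit$A * scl); B <- unname(fit$B * scl)
  theta <- unname(fit$theta)

  d <- ellipse_distances(pts, cx, cy, A, B, theta)
  # parametric angles of the data in the (A, B) frame for the arc extent
  ct <- cos(theta); st <- sin(theta)
  p <- (pts[, 1L] - cx) * ct + (pts[, 2L] - cy) * st
  q <- -(pts[, 1L] - cx) * st + (pts[, 2L] - cy) * ct
  tt <- atan2(q / B, p / A)
  tt <- unwrap_angles(tt)
  extent <- deg(abs(tt[length(tt)] - tt[1L]))

  # axis labeling: "a" is the chordwise axis, "b" the one toward the
  # sagittal bulge, so b/a exceeds 1 when the bulge exceeds the chordwise
  # semi-axis.  Two complementary rules cover the eccentricity range:
  #   - clearly eccentric fits (axis ratio > 2): the chord of any sizeable
  #     arc necessarily runs along the major axis, so "a" is the axis most
  #     parallel to the craniocaudal chord -- stable even for razor-thin
  #     ellipses whose sharp vertex makes parametric angles noise-fragile;
  #   - near-circular fits: the chord of an arc ending at the bulge apex
  #     tips diagonally between the axes, so instead "b" is the axis whose
  #     vertex lies nearest the caudal (S1) end, where the lordotic apex
  #     sits (t = 0 is the A-axis vertex, t = +/-90 deg the B-axis vertex);
  #     a blunt vertex keeps that parametric angle stable under noise.
  ax1 <- c(cos(theta), sin(theta))           # direction of semi-axis A
  ax2 <- c(-sin(theta), cos(theta))          # direction of semi-axis B
  if (max(A, B) / min(A, B) > 2) {
    chord <- pts[nrow(pts), ] - pts[1L, ]
    if (abs(sum(chord * ax1)) >= abs(sum(chord * ax2))) {
      a <- A; b <- B; a_dir <- ax1
    } else {
      a <- B; b <- A; a_dir <- ax2
    }
  } else {
    t_end <- tt[length(tt)]
    if (abs(cos(t_end)) >= abs(sin(t_end))) {
      b <- A; a <- B; a_dir <- ax2           # caudal end near the A vertex
    } else {
      b <- B; a <- A; a_dir <- ax1
    }
  }
  ratio <- b / a
  if (ratio < fit_opts_lo(opts) || ratio > fit_opts_hi(opts))
    warning(sprintf("fitted b/a = %.3f outside the admissible bounds (%g, %g)",
                    ratio, fit_opts_lo(opts), fit_opts_hi(opts)),
            call. = FALSE)

  structure(
    list(center = c(x = cx, y = cy), a = a, b = b,
         rotation = axis_from_vertical(a_dir),
         rmse = sqrt(mean(d^2)), arc_extent = extent,
         A = A, B = B, theta = theta, points = pts,
         objective = sum(d^2), method = opts$method),
    class = "lordosis_ellipse"
  )
}

fit_opts_lo <- function(opts) opts$ba_bounds[1L]
fit_opts_hi <- function(opts) opts$ba_bounds[2L]

axis_from_vertical <- function(dir) {
  a <- deg(atan2(dir[1L], dir[2L]))
  if (a <= -90) a <- a + 180
  if (a > 90) a <- a - 180
  a
}

unwrap_angles <- function(t) {
  d <- diff(t)
  d <- d - round(d / (2 * pi)) * 2 * pi
  cumsum(c(t[1L], d))
}

#' Minor-to-major axis ratio of a fitted lordosis ellipse
#'
#' @param model a `lordosis_ellipse` fit.
#' @return dimensionless b/a ratio (may exceed 1; see
#'   [fit_lordosis_ellipse()] for the axis labeling).
#' @export
ba_ratio <- function(model) {
  stopifnot(inherits(model, "lordosis_ellipse"))
  model$b / model$a
}

# -- S3 methods --------------------------------------------------------------

#' @export
print.lordosis_ellipse <- function(x, ...) {
  cat("Lordosis ellipse fit (", x$method, " method)\n", sep = "")
  cat(sprintf("  center (%.1f, %.1f) mm; a = %.1f mm, b = %.1f mm\n",
              x$center[1L], x$center[2L], x$a, x$b))
  cat(sprintf("  b/a = %.3f; rotation %.1f deg from vertical\n",
              ba_ratio(x), x$rotation))
  cat(sprintf("  arc extent %.1f deg; rmse %.3g mm on %d points\n",
              x$arc_extent, x$rmse, nrow(x$points)))
  invisible(x)
}

#' @export
summary.lordosis_ellipse <- function(object, ...) {
  res <- residuals(object)
  out <- list(coef = coef(object), rmse = object$rmse,
              arc_extent = object$arc_extent, n = nrow(object$points),
              resid_range = range(res), method = object$method)
  class(out) <- "summary.lordosis_ellipse"
  out
}

#' @export
print.summary.lordosis_ellipse <- function(x, ...) {
  cat("Lordosis ellipse fit summary\n")
  print(round(x$coef, 4L))
  cat(sprintf("rmse %.3g mm over %d points; residual range [%.3g, %.3g] mm\n",
              x$rmse, x$n, x$resid_range[1L], x$resid_range[2L]))
  invisible(x)
}

#' @export
coef.lordosis_ellipse <- function(object, ...) {
  c(center_x = unname(object$center[1L]), center_y = unname(object$center[2L]),
    a = object$a, b = object$b, ba_ratio = ba_ratio(object),
    rotation = object$rotation)
}

#' @export
residuals.lordosis_ellipse <- function(object, ...) {
  ellipse_distances(object$points, object$center[1L], object$center[2L],
                    object$A, object$B, object$theta)
}

#' @export
predict.lordosis_ellipse <- function(object, n = 100L, ...) {
  ct <- cos(object$theta); st <- sin(object$theta)
  p <- (object$points[, 1L] - object$center[1L]) * ct +
    (object$points[, 2L] - object$center[2L]) * st
  q <- -(object$points[, 1L] - object$center[1L]) * st +
    (object$points[, 2L] - object$center[2L]) * ct
  tt <- unwrap_angles(atan2(q / object$B, p / object$A))
  ts <- seq(tt[1L], tt[length(tt)], length.out = n)
  x <- object$A * cos(ts); y <- object$B * sin(ts)
  cbind(x = object$center[1L] + x * ct - y * st,
        y = object$center[2L] + x * st + y * ct)
}

#' @export
plot.lordosis_ellipse <- function(x, ...) {
  curve_pts <- predict(x, n = 200L)
  rng <- apply(rbind(x$points, curve_pts), 2L, range)
  graphics::plot(x$points, asp = 1, xlab = "x (mm, anterior +)",
                 ylab = "y (mm, superior +)",
                 xlim = rng[, 1L], ylim = rng[, 2L],
                 main = sprintf("Lordosis ellipse (b/a = %.3f)", ba_ratio(x)),
                 ...)
  graphics::lines(curve_pts, col = "steelblue", lwd = 2)
  invisible(x)
}

# -- arc sampling oracle -----------------------------------------------------

#' Sample points on an elliptical arc
#'
#' Places `n` points exactly on an ellipse whose axis ratio is `ba`, on an
#' arc of the given angular extent ending at the minor-axis vertex (the apex
#' of the sagittal bulge), ordered cranial to caudal.  The parameterization
#' is `(x, y) = (b sin t, a cos t)` with the spine chord along y, so the
#' cranial end sits near the major-axis vertex.  The points are scaled so
#' that the chord from first to last point has length `scale`, then rotated
#' by `phase` about the ellipse center.  Shared oracle for the fitting tests
#' and the synthetic-spine generator.
#'
#' @param ba axis ratio b/a, in (0.02, 1.6).
#' @param extent angular extent of the arc in degrees, in (10, 180).
#' @param n number of points (>= 6).
#' @param scale chord length in mm.
#' @param phase rotation applied to the sampled points, degrees
#'   (counter-clockwise; 0 leaves the minor axis horizontal).
#' @param spacing `"uniform"` for uniform parametric spacing, or a numeric
#'   vector of `n` increasing arc-length fractions in \[0, 1\] giving each
#'   point's position along the arc (used by the spine generator to place
#'   vertebral corners at anatomical spacings).
#' @return an `n` x 2 matrix of (x, y) points with attributes `ba`,
#'   `extent`, `a`, `b`.
#' @export
sample_arc <- function(ba, extent, n, scale = 180, phase = 0,
                       spacing = "uniform") {
  if (ba < 0.02 || ba > 1.6) stop("ba out of range (0.02, 1.6)", call. = FALSE)
  if (extent <= 10 || extent >= 180)
    stop("extent out of range (10, 180)", call. = FALSE)
  if (n < 6L) stop("need at least 6 points", call. = FALSE)
  t1 <- pi / 2
  t0 <- t1 - rad(extent)
  if (identical(spacing, "uniform")) {
    tt <- seq(t0, t1, length.out = n)
  } else {
    frac <- as.numeric(spacing)
    if (length(frac) != n || is.unsorted(frac, strictly = TRUE) ||
        frac[1L] < 0 || frac[length(frac)] > 1)
      stop("spacing must be n strictly increasing fractions in [0, 1]",
           call. = FALSE)
    # invert cumulative arc length on a fine grid
    tg <- seq(t0, t1, length.out = 4001L)
    xg <- ba * sin(tg); yg <- cos(tg)
    s <- c(0, cumsum(sqrt(diff(xg)^2 + diff(yg)^2)))
    tt <- stats::approx(s / s[length(s)], tg, xout = frac, ties = "ordered")$y
  }
  pts <- cbind(x = ba * sin(tt), y = cos(tt))
  chord <- sqrt(sum((pts[n, ] - pts[1L, ])^2))
  pts <- pts * (scale / chord)
  if (phase != 0) {
    ph <- rad(phase); R <- matrix(c(cos(ph), sin(ph), -sin(ph), cos(ph)), 2L)
    pts <- pts %*% t(R)
    colnames(pts) <- c("x", "y")
  }
  attr(pts, "ba") <- ba
  attr(pts, "extent") <- extent
  attr(pts, "a") <- scale / chord
  attr(pts, "b") <- ba * scale / chord
  pts
}
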