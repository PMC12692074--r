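# Angle helpers --------------------------------------------------------------

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

#' Construct a tangent line
#'
#' @param anchor numeric length-2 point (x, y).
#' @param direction numeric length-2 direction; normalized internally and
#'   flipped if needed so the stored direction points cranially (y > 0, or
#'   x > 0 if exactly horizontal).
#' @return object of class `tangent_line` with unit `direction`.
#' @export
tangent_line <- function(anchor, direction) {
  n <- sqrt(sum(direction^2))
  if (!is.finite(n) || n < .Machine$double.eps)
    stop("degenerate geometry: zero-length tangent direction", call. = FALSE)
  d <- direction / n
  if (d[2L] < 0 || (d[2L] == 0 && d[1L] < 0)) d <- -d
  structure(list(anchor = as.numeric(anchor), direction = as.numeric(d)),
            class = "tangent_line")
}

#' Signed angle of a line to the vertical
#'
#' Positive when the cranial end of the line leans anterior (+x); value in
#' (-90, 90].  Invariant to translation and uniform scaling.
#'
#' @param line a [tangent_line()].
#' @return angle in degrees.
#' @export
angle_to_vertical <- function(line) {
  d <- line$direction
  a <- deg(atan2(d[1L], d[2L]))
  if (a <= -90) a <- a + 180
  if (a > 90) a <- a - 180
  unname(a)
}

#' Unsigned acute angle of the line through two points to the horizontal
#'
#' @param p1,p2 numeric length-2 points.
#' @return angle in degrees, in \[0, 90\].
#' @export
angle_to_horizontal <- function(p1, p2) {
  d <- p2 - p1
  if (sqrt(sum(d^2)) < .Machine$double.eps)
    stop("degenerate geometry: coincident points", call. = FALSE)
  unname(deg(atan2(abs(d[2L]), abs(d[1L]))))
}

# Signed slope of a directed endplate (posterior corner -> anterior corner)
# relative to the horizontal: positive when the anterior end is superior.
endplate_slope <- function(post, ant) {
  d <- ant - post
  if (sqrt(sum(d^2)) < .Machine$double.eps)
    stop("degenerate geometry: coincident endplate corners", call. = FALSE)
  if (d[1L] < 0) d <- -d  # orient anteriorly
  unname(deg(atan2(d[2L], d[1L])))
}

# Posterior tangents --------------------------------------------------------

#' Posterior body tangent of a vertebral level
#'
#' For L1-L5 and S1 this is the line through the two digitized posterior
#' body corners, oriented cranially.  T12 has no digitized posterior-superior
#' corner, so its tangent is constructed as the perpendicular to the T12
#' inferior endplate (T12_pi-T12_ai) through T12_pi; sagittal vertebral
#' bodies are close to rectangular, which makes the perpendicular the natural
#' surrogate for the posterior wall.
#'
#' @param set a [landmark_set()].
#' @param level one of `"T12"`, `"L1"` ... `"L5"`, `"S1"`.
#' @return a [tangent_line()].
#' @export
posterior_tangent <- function(set, level) {
  level <- match.arg(level, c("T12", "L1", "L2", "L3", "L4", "L5", "S1"))
  if (level == "T12") {
    p <- lm_pts(set, c("T12_pi", "T12_ai"))
    e <- p["T12_ai", ] - p["T12_pi", ]
    # perpendicular of the endplate, cranially oriented
    tangent_line(p["T12_pi", ], c(-e[2L], e[1L]))
  } else {
    nm <- paste0(level, c("_ps", "_pi"))
    p <- lm_pts(set, nm)
    tangent_line(p[nm[2L], ], p[nm[1L], ] - p[nm[2L], ])
  }
}

#' Absolute rotation angle between two posterior tangents
#'
#' The Harrison posterior-tangent lordosis measure: the angle-to-vertical of
#' the cranial level's tangent minus that of the caudal level's.  Lordotic
#' (extended) configurations give negative values.
#'
#' @param set a [landmark_set()].
#' @param cranial,caudal vertebral levels as in [posterior_tangent()].
#' @return angle in degrees.
#' @export
ara <- function(set, cranial, caudal) {
  angle_to_vertical(posterior_tangent(set, cranial)) -
    angle_to_vertical(posterior_tangent(set, caudal))
}

# Endplate angles ------------------------------------------------------------

#' Cobb angle from the inferior T12 endplate to the superior S1 endplate
#'
#' Signed angle between the two endplate lines; negative for lordosis.  On a
#' noise-free configuration `|Cobb| = SBA + t12_tilt` where `t12_tilt` is the
#' anterior-superior slope of the T12 inferior endplate.
#'
#' @param set a [landmark_set()].
#' @return angle in degrees.
#' @export
cobb_t12_s1 <- function(set) {
  t12 <- lm_pts(set, c("T12_pi", "T12_ai"))
  s1 <- lm_pts(set, c("S1_ps", "S1_as"))
  endplate_slope(s1["S1_ps", ], s1["S1_as", ]) -
    endplate_slope(t12["T12_pi", ], t12["T12_ai", ])
}

#' Sacral base angle
#'
#' Unsigned angle of the S1 superior endplate to the horizontal (equals the
#' sacral slope).
#'
#' @param set a [landmark_set()].
#' @return angle in degrees, in \[0, 90\].
#' @export
sacral_base_angle <- function(set) {
  p <- lm_pts(set, c("S1_ps", "S1_as"))
  angle_to_horizontal(p["S1_ps", ], p["S1_as", ])
}

#' S1 posterior tangent to vertical (sacral tilt)
#'
#' Reported as a positive magnitude; the S1 posterior tangent of a normal
#' upright sacrum leans anterior at its cranial end.
#'
#' @param set a [landmark_set()].
#' @return angle in degrees.
#' @export
pt_s1 <- function(set) {
  abs(angle_to_vertical(posterior_tangent(set, "S1")))
}

# Pelvic morphology ----------------------------------------------------------

#' Pelvic reference frame
#'
#' @param set a [landmark_set()].
#' @return list with `HA` (hip axis: midpoint of the femoral head points),
#'   `S1_mid` (midpoint of the S1 superior endplate) and `PR_anchor`
#'   (posterior-superior S1 corner, the pelvic-radius endpoint).
#' @export
pelvic_frame <- function(set) {
  fem <- lm_pts(set, c("FEM_L", "FEM_R"))
  s1 <- lm_pts(set, c("S1_ps", "S1_as"))
  list(HA = (fem["FEM_L", ] + fem["FEM_R", ]) / 2,
       S1_mid = (s1["S1_ps", ] + s1["S1_as", ]) / 2,
       PR_anchor = s1["S1_ps", ])
}

# unsigned angle between two vectors, degrees in [0, 180]
vec_angle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < .Machine$double.eps || nv < .Machine$double.eps)
    stop("degenerate geometry: zero-length vector", call. = FALSE)
  unname(deg(atan2(abs(u[1L] * v[2L] - u[2L] * v[1L]), sum(u * v))))
}

#' Angle of pelvic incidence (Legaye construction)
#'
#' Unsigned angle at the S1 mid-endplate between the perpendicular to the S1
#' superior endplate and the segment to the hip axis.  References no gravity
#' line, so it is invariant under rotation of the whole landmark set, and it
#' satisfies the identity API = PT + SS on noise-free anatomy.
#'
#' @param set a [landmark_set()].
#' @return angle in degrees.
#' @export
api <- function(set) {
  fr <- pelvic_frame(set)
  s1 <- lm_pts(set, c("S1_ps", "S1_as"))
  e <- s1["S1_as", ] - s1["S1_ps", ]
  perp <- c(e[2L], -e[1L])
  # orient the endplate normal caudally (into the sacrum): against the S1
  # body axis when the posterior-inferior corner is digitized (keeps the
  # angle rotation invariant), otherwise downward in the film frame
  if (lm_has(set, "S1_pi")) {
    cranial <- s1["S1_ps", ] - set$points["S1_pi", ]
    if (sum(perp * cranial) > 0) perp <- -perp
  } else if (perp[2L] > 0) perp <- -perp
  w <- fr$HA - fr$S1_mid
  if (sqrt(sum(w^2)) < .Machine$double.eps)
    stop("degenerate geometry: hip axis coincides with S1 mid-endplate",
         call. = FALSE)
  vec_angle(perp, w)
}

#' Pelvic tilt
#'
#' Signed angle at the hip axis between the vertical and the segment to the
#' S1 mid-endplate, positive when the S1 midpoint lies posterior to the
#' vertical through the hip axis.
#'
#' @param set a [landmark_set()].
#' @return angle in degrees.
#' @export
pelvic_tilt <- function(set) {
  fr <- pelvic_frame(set)
  v <- fr$S1_mid - fr$HA
  if (sqrt(sum(v^2)) < .Machine$double.eps)
    stop("degenerate geometry: hip axis coincides with S1 mid-endplate",
         call. = FALSE)
  unname(deg(atan2(-v[1L], v[2L])))
}

#' Sacral slope
#'
#' Synonym of [sacral_base_angle()]; provided so the pelvic parameter triple
#' PI = PT + SS can be read off directly.
#'
#' @param set a [landmark_set()].
#' @return angle in degrees.
#' @export
sacral_slope <- function(set) sacral_base_angle(set)

#' Posterior tangent pelvic incidence angle
#'
#' Unsigned angle between the pelvic radius line (hip axis to the
#' posterior-superior S1 corner) and the S1 posterior body tangent.  Like the
#' Legaye incidence it uses internal lines only and is rotation invariant;
#' on standard anatomy it decomposes as PTPIA = (PR-line lean from vertical)
#' + (S1 tangent lean from vertical).
#'
#' @param set a [landmark_set()].
#' @return angle in degrees.
#' @export
ptpia <- function(set) {
  fr <- pelvic_frame(set)
  pr <- fr$PR_anchor - fr$HA
  if (sqrt(sum(pr^2)) < .Machine$double.eps)
    stop("degenerate geometry: zero-length pelvic radius", call. = FALSE)
  tg <- posterior_tangent(set, "S1")
  vec_angle(pr, tg$direction)
}

#' Pelvic radius line lean from vertical
#'
#' Positive magnitude of the hip-axis-to-posterior-S1 line's angle to the
#' vertical (the PR line of a normal pelvis leans posterior at its cranial
#' end).  Used in the PTPIA decomposition.
#'
#' @param set a [landmark_set()].
#' @return angle in degrees.
#' @export
pr_to_vertical <- function(set) {
  fr <- pelvic_frame(set)
  abs(angle_to_vertical(tangent_line(fr$HA, fr$PR_anchor - fr$HA)))
}

# Full record ----------------------------------------------------------------

#' Measure every alignment variable of one subject
#'
#' Computes the full per-subject record: the three lordosis measures
#' (ARA L1-L5, ARA T12-S1, Cobb T12-S1; negative = lordosis), sacral base
#' angle, S1 posterior tangent to vertical, the two pelvic morphology angles
#' (API, PTPIA), the pelvic decomposition (PT, SS, sacral tilt), the ellipse
#' b/a ratio, and the morphology-minus-lordosis differences (literal
#' subtractions, so e.g. API 56.8 with ARA T12-S1 -76.3 gives -19.5).
#'
#' Missing landmarks never raise an error here: fields whose landmarks are
#' absent are returned as `NA` (per-op errors are caught and recorded).
#'
#' @param set a [landmark_set()].
#' @param ellipse logical; fit the lordosis ellipse for the b/a ratio
#'   (default `TRUE`).  Skipping it leaves `ba_ratio` as `NA`.
#' @param fit_options options for [fit_lordosis_ellipse()].
#' @return one-row data.frame with columns `subject_id`, `group` and the
#'   measurement variables.
#' @export
measure_all <- function(set, ellipse = TRUE, opts = fit_options()) {
  val <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  rec <- data.frame(subject_id = set$subject_id, group = set$group,
                    stringsAsFactors = FALSE)
  rec$ARA_L1L5 <- val(ara(set, "L1", "L5"))
  rec$ARA_T12S1 <- val(ara(set, "T12", "S1"))
  rec$Cobb_T12S1 <- val(cobb_t12_s1(set))
  rec$SBA <- val(sacral_base_angle(set))
  rec$PT_S1 <- val(pt_s1(set))
  rec$API <- val(api(set))
  rec$PTPIA <- val(ptpia(set))
  rec$ba_ratio <- if (ellipse)
    val(ba_ratio(fit_lordosis_ellipse(set, opts))) else NA_real_
  # lordosis values are negative, so "API minus lordosis" is the literal
  # subtraction of the magnitude: API + signed value (56.8 - 76.3 = -19.5)
  rec$API_minus_ARA_T12S1 <- rec$API + rec$ARA_T12S1
  rec$API_minus_ARA_L1L5 <- rec$API + rec$ARA_L1L5
  rec$API_minus_Cobb_T12S1 <- rec$API + rec$Cobb_T12S1
  rec$PT <- val(pelvic_tilt(set))
  rec$SS <- val(sacral_slope(set))
  rec$sacral_tilt <- rec$PT_S1
  rec[, c("subject_id", "group", MEASUREMENT_VARS)]
}

#' Measure a collection of subjects
#'
#' @param sets list of [landmark_set()] objects.
#' @inheritParams measure_all
#' @return data.frame with one row per subject.
#' @export
measure_cohort <- function(sets, ellipse = TRUE, opts = fit_options()) {
  do.call(rbind, lapply(sets, measure_all, ellipse = ellipse,
                        opts = opts))
}
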