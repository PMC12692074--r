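#' @keywords internal
"_PACKAGE"

# Canonical landmark names of a digitized lateral lumbar radiograph, in
# craniocaudal order.  ps/pi/as/ai = posterior-superior / posterior-inferior /
# anterior-superior / anterior-inferior vertebral body corner; FEM_* = superior
# aspect of each femoral head; PUBIS = pubic symphysis.
LANDMARK_NAMES <- c(
  "T12_pi", "T12_ai",
  "L1_ps", "L1_pi", "L2_ps", "L2_pi", "L3_ps", "L3_pi",
  "L4_ps", "L4_pi", "L5_ps", "L5_pi",
  "S1_ps", "S1_pi", "S1_as",
  "FEM_L", "FEM_R", "PUBIS"
)

# The 13 posterior body corners from T12 down to S1, cranial to caudal.
# These are the points the lordosis ellipse is fitted to.
POSTERIOR_CORNERS <- c(
  "T12_pi",
  "L1_ps", "L1_pi", "L2_ps", "L2_pi", "L3_ps", "L3_pi",
  "L4_ps", "L4_pi", "L5_ps", "L5_pi",
  "S1_ps", "S1_pi"
)

GROUP_LEVELS <- c("normal", "albp", "unknown")

#' Construct a landmark set for one subject
#'
#' A `landmark_set` holds the digitized x-y coordinates of (up to) 18 named
#' anatomical points on a lateral lumbar radiograph.  The coordinate frame is
#' x anterior-positive, y superior-positive, units mm; the y axis is assumed
#' to be the plumb vertical of the upright film, which is what the
#' gravity-referenced angles (sacral base angle, S1 tangent to vertical,
#' pelvic tilt) are measured against.
#'
#' @param subject_id character scalar identifying the subject.
#' @param group one of `"normal"`, `"albp"`, `"unknown"`.
#' @param points a 2-column numeric matrix (columns x, y, in mm) with
#'   rownames drawn from [landmark_names()].  A complete set has all 18.
#' @return an object of class `landmark_set` with elements `subject_id`,
#'   `group`, `points` and logical `complete`.
#' @examples
#' pts <- rbind(S1_ps = c(0, 0), S1_as = c(35, -25))
#' s <- landmark_set("demo", "unknown", pts)
#' s$complete
#' @export
landmark_set <- function(subject_id, group = "unknown", points) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  group <- match.arg(group, GROUP_LEVELS)
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop("`points` must be a 2-column (x, y) matrix", call. = FALSE)
  if (is.null(rownames(points)))
    stop("`points` must have landmark names as rownames", call. = FALSE)
  bad <- setdiff(rownames(points), LANDMARK_NAMES)
  if (length(bad))
    stop("unknown landmark name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(rownames(points)))
    stop("duplicated landmark name(s) for subject ", subject_id, call. = FALSE)
  if (!all(is.finite(points)))
    stop("landmark coordinates must be finite", call. = FALSE)
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y")
  complete <- all(LANDMARK_NAMES %in% rownames(points))
  structure(
    list(subject_id = subject_id, group = group,
         points = points, complete = complete),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> subject", x$subject_id,
      sprintf("(group: %s, %d/18 points%s)\n", x$group, nrow(x$points),
              if (x$complete) "" else ", incomplete"))
  invisible(x)
}

#' Canonical landmark names
#'
#' @return character vector of the 18 canonical landmark names in
#'   craniocaudal order.
#' @export
landmark_names <- function() LANDMARK_NAMES

# Fetch named points as an n x 2 matrix, erroring informatively if absent.
lm_pts <- function(set, names) {
  missing <- setdiff(names, rownames(set$points))
  if (length(missing))
    stop("incomplete landmark set for subject ", set$subject_id,
         ": missing ", paste(missing, collapse = ", "), call. = FALSE)
  set$points[names, , drop = FALSE]
}

lm_has <- function(set, names) all(names %in% rownames(set$points))

# Warn-level sanity check: posterior corner y-coordinates should decrease
# craniocaudally, and anterior corners should sit anterior to posterior ones.
check_landmark_sanity <- function(set) {
  ok <- TRUE
  pc <- intersect(POSTERIOR_CORNERS, rownames(set$points))
  if (length(pc) >= 2L) {
    y <- set$points[pc, "y"]
    if (any(diff(y) >= 0)) {
      warning("posterior corner y-coordinates not strictly decreasing ",
              "craniocaudally for subject ", set$subject_id, call. = FALSE)
      ok <- FALSE
    }
  }
  for (pair in list(c("T12_pi", "T12_ai"), c("S1_ps", "S1_as"))) {
    if (lm_has(set, pair)) {
      p <- set$points[pair, ]
      if (p[2L, "x"] <= p[1L, "x"]) {
        warning("anterior point ", pair[2L], " not anterior to ", pair[1L],
                " for subject ", set$subject_id, call. = FALSE)
        ok <- FALSE
      }
    }
  }
  invisible(ok)
}

#' Read digitized landmarks from a long-format CSV
#'
#' The file must have columns `subject_id`, `group`, `point`, `x_mm`, `y_mm`
#' (UTF-8, "." decimal separator, header mandatory), one row per landmark.
#' Subjects with fewer than the 18 canonical points are returned with
#' `complete = FALSE`; operations that need the missing points fail per-op.
#'
#' @param path path to the CSV file.
#' @return a named list of [landmark_set] objects, one per subject, in order
#'   of first appearance.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "point", "x_mm", "y_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("landmark CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!df$point %in% LANDMARK_NAMES)
  if (length(bad))
    stop("unknown landmark name(s) in rows ",
         paste(utils::head(bad, 5L), collapse = ", "), ": ",
         paste(unique(df$point[bad]), collapse = ", "), call. = FALSE)
  dup <- duplicated(df[c("subject_id", "point")])
  if (any(dup))
    stop("duplicate (subject, point) row(s), first at row ", which(dup)[1L],
         call. = FALSE)
  ids <- unique(df$subject_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$subject_id == id, , drop = FALSE]
    grp <- unique(sub$group)
    if (length(grp) != 1L)
      stop("subject ", id, " has conflicting group labels", call. = FALSE)
    pts <- cbind(x = sub$x_mm, y = sub$y_mm)
    rownames(pts) <- sub$point
    landmark_set(as.character(id), grp, pts)
  })
  names(out) <- as.character(ids)
  out
}

#' Write landmark sets to a long-format CSV
#'
#' Inverse of [read_landmarks()].
#'
#' @param sets a list of [landmark_set] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(sets, path) {
  rows <- lapply(sets, function(s) {
    data.frame(subject_id = s$subject_id, group = s$group,
               point = rownames(s$points),
               x_mm = s$points[, "x"], y_mm = s$points[, "y"],
               row.names = NULL)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# Measurement table column order: Table-1 variable order first, then the
# auxiliary pelvic decomposition angles.
MEASUREMENT_VARS <- c(
  "ARA_L1L5", "ARA_T12S1", "Cobb_T12S1", "SBA", "PT_S1", "API", "PTPIA",
  "ba_ratio", "API_minus_ARA_T12S1", "API_minus_ARA_L1L5",
  "API_minus_Cobb_T12S1", "PT", "SS", "sacral_tilt"
)

#' Write per-subject measurement records to a wide CSV
#'
#' One row per subject; angles rounded to 0.1 degree, the ellipse b/a ratio
#' to 0.001.
#'
#' @param records data.frame of measurement records (as from
#'   [measure_all()] / [measure_cohort()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  if (!nrow(records)) stop("no measurement records to write", call. = FALSE)
  cols <- c("subject_id", "group", MEASUREMENT_VARS)
  out <- records[, intersect(cols, names(records)), drop = FALSE]
  for (v in intersect(MEASUREMENT_VARS, names(out)))
    out[[v]] <- round(out[[v]], if (v == "ba_ratio") 3L else 1L)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wide measurement CSV
#'
#' @param path path to a CSV written by [write_measurements()].
#' @return data.frame with one row per subject.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df))
    stop("measurement CSV is missing the subject_id column", call. = FALSE)
  df
}
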