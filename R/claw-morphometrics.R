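# Ungual (claw) outer-arc geometry. A claw arc is operationalized as three
# planar landmarks - base, midpoint and tip of the outer arc - through which a
# unique circle is fitted. Near-collinear landmark sets (circumradius more
# than 1e6 x the base-tip chord) are treated as collinear: curvature 0 deg,
# arc length = chord length.

circumcircle <- function(arc) {
  p1 <- arc[1L, ]; p2 <- arc[2L, ]; p3 <- arc[3L, ]
  if (any(duplicated(arc))) stop("landmarks must be pairwise distinct", call. = FALSE)
  d <- 2 * (p1[1] * (p2[2] - p3[2]) + p2[1] * (p3[2] - p1[2]) + p3[1] * (p1[2] - p2[2]))
  chord <- sqrt(sum((p3 - p1)^2))
  if (abs(d) < .Machine$double.eps * 100) {
    return(list(collinear = TRUE, chord = chord))
  }
  s1 <- sum(p1^2); s2 <- sum(p2^2); s3 <- sum(p3^2)
  cx <- (s1 * (p2[2] - p3[2]) + s2 * (p3[2] - p1[2]) + s3 * (p1[2] - p2[2])) / d
  cy <- (s1 * (p3[1] - p2[1]) + s2 * (p1[1] - p3[1]) + s3 * (p2[1] - p1[1])) / d
  r <- sqrt((p1[1] - cx)^2 + (p1[2] - cy)^2)
  if (r > 1e6 * chord) return(list(collinear = TRUE, chord = chord))
  list(collinear = FALSE, center = c(cx, cy), radius = r, chord = chord)
}

as_arc <- function(arc) {
  arc <- as.matrix(arc)
  if (!all(dim(arc) == c(3L, 2L))) stop("an arc is 3 landmarks x 2 coordinates", call. = FALSE)
  storage.mode(arc) <- "double"
  arc
}

# central angle (radians) of the base -> tip arc passing through the midpoint
arc_angle <- function(arc, cc) {
  ang <- atan2(arc[, 2] - cc$center[2], arc[, 1] - cc$center[1])
  sweep_ccw <- (ang[3] - ang[1]) %% (2 * pi)
  mid_ccw <- (ang[2] - ang[1]) %% (2 * pi)
  if (mid_ccw <= sweep_ccw) sweep_ccw else 2 * pi - sweep_ccw
}

#' Outer-arc curvature of a claw
#'
#' Angle (degrees) subtended at the center of the circle through the three
#' landmarks by the base-to-tip arc that passes through the middle landmark.
#' Collinear landmarks give 0 degrees. Invariant to rotation, translation and
#' uniform scaling of the coordinates.
#'
#' @param arc 3 x 2 matrix of landmarks (base, midpoint, tip), pairwise
#'   distinct, any consistent planar units.
#' @return Curvature in degrees, in `[0, 360)`.
#' @examples
#' arc_curvature(rbind(c(-1, 0), c(0, 1), c(1, 0)))  # semicircle: 180
#' @export
arc_curvature <- function(arc) {
  arc <- as_arc(arc)
  cc <- circumcircle(arc)
  if (cc$collinear) return(0)
  arc_angle(arc, cc) * 180 / pi
}

#' Outer-arc length of a claw
#'
#' Length `r * theta` of the fitted circular arc (theta in radians); the
#' base-tip chord length when the landmarks are collinear.
#'
#' @inheritParams arc_curvature
#' @return Arc length in the landmark units.
#' @export
arc_length <- function(arc) {
  arc <- as_arc(arc)
  cc <- circumcircle(arc)
  if (cc$collinear) return(cc$chord)
  cc$radius * arc_angle(arc, cc)
}

#' Assemble the 7-variable claw record for one specimen
#'
#' Computes per-digit outer-arc curvature (degrees) for digits I-IV and the
#' outer-arc lengths of digits I, II and IV as ratios to digit III, the
#' variable set used for the traditional-morphometrics ordination. Specimens
#' missing any digit (e.g. a fossil preserving only the digit II ungual) get
#' an incomplete record, flagged so it can be excluded from ordination.
#' Precomputed curvature/length values may be supplied instead of landmarks.
#'
#' @param arcs Named list with elements `I`, `II`, `III`, `IV`; each either a
#'   3 x 2 landmark matrix or a list `list(curvature = deg, length = l)` of
#'   measured values. Missing digits may be `NULL` or absent.
#' @return Data frame row with `curvature_I..curvature_IV`, `ratio_I`,
#'   `ratio_II`, `ratio_IV` and logical `complete`.
#' @export
tm_record <- function(arcs) {
  digits <- c("I", "II", "III", "IV")
  curv <- len <- stats::setNames(rep(NA_real_, 4L), digits)
  for (d in digits) {
    a <- arcs[[d]]
    if (is.null(a)) next
    if (is.list(a) && !is.null(a$curvature)) {
      curv[d] <- a$curvature
      len[d] <- a$length
    } else {
      curv[d] <- arc_curvature(a)
      len[d] <- arc_length(a)
    }
  }
  complete <- !anyNA(curv) && !anyNA(len)
  if (complete && len[["III"]] <= 0) stop("digit III arc length must be positive", call. = FALSE)
  data.frame(curvature_I = curv[["I"]], curvature_II = curv[["II"]],
             curvature_III = curv[["III"]], curvature_IV = curv[["IV"]],
             ratio_I = len[["I"]] / len[["III"]],
             ratio_II = len[["II"]] / len[["III"]],
             ratio_IV = len[["IV"]] / len[["III"]],
             complete = complete)
}
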