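# Landmark-based measurement of serration shape in the 2D feather plane.
#
# Feather frame: the y-axis runs from the beginning of the calamus to the tip
# of the rachis; the x-axis is perpendicular, pointing towards the outer
# vane.  The frame is left-handed for right-wing feathers and right-handed
# for left-wing feathers; measurements re-express everything in a canonical
# right-wing frame (outer vane = +x), so "bent away from the rachis" is
# always +x.

#' Construct a feather coordinate frame
#'
#' @param calamus_start,rachis_tip 2D points (mm) defining the feather y-axis.
#' @param wing_side `"right"` or `"left"`; decides which perpendicular points
#'   towards the outer vane.
#' @return A `feather_frame` object.
#' @export
feather_frame <- function(calamus_start = c(0, 0), rachis_tip = c(0, 1),
                          wing_side = c("right", "left")) {
  wing_side <- match.arg(wing_side)
  calamus_start <- as.numeric(calamus_start)
  rachis_tip <- as.numeric(rachis_tip)
  if (length(calamus_start) != 2 || length(rachis_tip) != 2)
    stop("frame points must be 2D")
  if (all(calamus_start == rachis_tip))
    stop("calamus_start and rachis_tip must differ")
  structure(list(calamus_start = calamus_start, rachis_tip = rachis_tip,
                 wing_side = wing_side), class = "feather_frame")
}

#' Assemble a set of serration landmarks
#'
#' @param frame a [feather_frame()].
#' @param barb_origin 2D point (mm) where the barb shaft leaves the rachis.
#' @param separation_point 2D point (mm) where adjacent barbs detach (the
#'   boundary between the barb base and the serrated tip).
#' @param tip 2D point (mm), the serration tip.
#' @param path matrix of ordered 2D points (mm) tracing the serrated tip from
#'   the separation point to the tip; defaults to the straight chord.
#' @param detached logical: is the barb tip free-standing (detached from the
#'   adjoining barb)?
#' @return A `serration_landmarks` object.
#' @export
serration_landmarks <- function(frame, barb_origin, separation_point, tip,
                                path = NULL, detached = TRUE) {
  stopifnot(inherits(frame, "feather_frame"))
  barb_origin <- as.numeric(barb_origin)
  separation_point <- as.numeric(separation_point)
  tip <- as.numeric(tip)
  if (is.null(path)) path <- rbind(separation_point, tip)
  path <- as.matrix(path)
  if (ncol(path) != 2 || nrow(path) < 2)
    stop("path must be a matrix of >= 2 2D points")
  if (any(path[1, ] != separation_point) || any(path[nrow(path), ] != tip))
    stop("path must start at separation_point and end at tip")
  seg <- diff(path)
  if (any(rowSums(seg^2) == 0))
    stop("consecutive path points must be distinct")
  if (all(barb_origin == separation_point))
    stop("barb_origin and separation_point must differ (degenerate base)")
  structure(list(frame = frame, barb_origin = barb_origin,
                 separation_point = separation_point, tip = tip,
                 path = path, detached = isTRUE(detached)),
            class = "serration_landmarks")
}

#' @export
print.serration_landmarks <- function(x, ...) {
  cat("serration_landmarks (", x$frame$wing_side, " wing, ",
      nrow(x$path), " path points, ",
      if (x$detached) "detached" else "attached", ")\n", sep = "")
  invisible(x)
}

# Express a point in the canonical right-wing frame (y = rachis axis,
# +x = towards the outer vane).
canonical_coords <- function(frame, p) {
  u <- frame$rachis_tip - frame$calamus_start
  u <- u / sqrt(sum(u^2))
  v <- if (frame$wing_side == "right") c(u[2], -u[1]) else c(-u[2], u[1])
  d <- p - frame$calamus_start
  c(sum(d * v), sum(d * u))
}

canonical_path <- function(frame, path) {
  t(apply(path, 1, function(p) canonical_coords(frame, p)))
}

#' Inclination angle of a barb
#'
#' The unsigned angle, in degrees, between the rachis axis and the straight
#' base of the barb (barb origin to point of separation).
#'
#' @param landmarks a [serration_landmarks()] object.
#' @return Angle in \[0, 90\] degrees.
#' @export
inclination_angle <- function(landmarks) {
  stopifnot(inherits(landmarks, "serration_landmarks"))
  o <- canonical_coords(landmarks$frame, landmarks$barb_origin)
  s <- canonical_coords(landmarks$frame, landmarks$separation_point)
  b <- s - o
  nb <- sqrt(sum(b^2))
  if (nb == 0) stop("degenerate base segment")
  acos(pmin(1, abs(b[2]) / nb)) * 180 / pi
}

#' Tip-displacement angle of a serration
#'
#' The signed angle, in degrees, between the direction of the barb base and
#' the straight segment from the point of separation to the serration tip.
#' Positive when the tip is displaced away from the rachis (towards the outer
#' vane), negative when bent towards the rachis.
#'
#' @param landmarks a [serration_landmarks()] object.
#' @return Signed angle in degrees.
#' @export
tip_displacement_angle <- function(landmarks) {
  stopifnot(inherits(landmarks, "serration_landmarks"))
  o <- canonical_coords(landmarks$frame, landmarks$barb_origin)
  s <- canonical_coords(landmarks$frame, landmarks$separation_point)
  tp <- canonical_coords(landmarks$frame, landmarks$tip)
  b <- s - o
  ch <- tp - s
  if (all(ch == 0)) stop("tip coincides with the separation point")
  psi_b <- atan2(b[1], b[2])
  psi_c <- atan2(ch[1], ch[2])
  beta <- (psi_c - psi_b) * 180 / pi
  beta <- ((beta + 180) %% 360) - 180
  # "away from the rachis" means a larger angular offset from the rachis axis
  # on the barb's side; flip the sign for a barb pointing to -x
  if (psi_b < 0) beta <- -beta
  beta
}

#' Curved length of a serration
#'
#' Arc length, in mm, of the traced path from the point of separation to the
#' tip (piecewise-linear summation of the supplied path).
#'
#' @param landmarks a [serration_landmarks()] object.
#' @return Length in mm.
#' @export
serration_length <- function(landmarks) {
  stopifnot(inherits(landmarks, "serration_landmarks"))
  seg <- diff(landmarks$path)
  sum(sqrt(rowSums(seg^2)))
}

#' Classify a leading-edge element
#'
#' A leading-edge barb ending counts as a *serration* only when its tip is
#' both detached from the adjoining barb and bent away from the rachis; a
#' detached but straight tip, or one bent towards the rachis, is a
#' *denticulation* (spear-head-like, as in frogmouths, the kakapo and the
#' very tip of barn-owl primaries); an attached tip makes the edge *smooth*.
#'
#' @param landmarks a [serration_landmarks()] object.
#' @param away_threshold_deg non-negative guard (degrees) against
#'   digitization noise; default 2.
#' @return One of `"smooth"`, `"denticulation"`, `"serration"`.
#' @export
classify_edge_element <- function(landmarks, away_threshold_deg = 2) {
  stopifnot(inherits(landmarks, "serration_landmarks"),
            away_threshold_deg >= 0)
  if (!landmarks$detached) return("smooth")
  beta <- tip_displacement_angle(landmarks)
  if (beta > away_threshold_deg) "serration" else "denticulation"
}

#' Normalized vane position
#'
#' Maps a y-coordinate along the feather axis to the normalized outer-vane
#' coordinate: the beginning of the outer vane is 0 and its tip is 1.
#'
#' @param y_coord y-coordinate (mm) to map.
#' @param vane_start_y,vane_tip_y y-coordinates (mm) of the beginning and tip
#'   of the outer vane.
#' @return Fraction in \[0, 1\] (clamped); the attribute `"clamped"` is
#'   `TRUE` when the raw linear value fell outside \[0, 1\].
#' @export
normalized_vane_position <- function(y_coord, vane_start_y, vane_tip_y) {
  if (vane_start_y == vane_tip_y) stop("zero-length vane")
  raw <- (y_coord - vane_start_y) / (vane_tip_y - vane_start_y)
  out <- pmin(1, pmax(0, raw))
  attr(out, "clamped") <- any(raw < 0 | raw > 1)
  out
}

#' Synthesize serration landmarks from shape parameters
#'
#' Constructs a landmark set in the feather plane whose measured inclination
#' angle, tip-displacement angle and curved length reproduce the inputs: the
#' barb base leaves the rachis at `alpha_deg` from the feather axis, and the
#' serrated tip follows a circular arc whose tangent continues the base and
#' whose chord sits at `beta_deg` from the base (total turn `2 * beta_deg`).
#' Arc sample points are rescaled about the separation point so the polyline
#' length equals `length_mm` exactly.
#'
#' @param alpha_deg inclination angle, degrees, in (0, 90).
#' @param beta_deg tip-displacement angle, degrees, in \[0, 90).
#' @param length_mm curved serration length, mm, > 0.
#' @param n_path_points number of path points (>= 2; >= 50 recommended for
#'   smooth arcs).
#' @param wing_side `"right"` or `"left"` (left-wing output is the mirror
#'   image; measurements are unchanged).
#' @param base_length_mm length of the barb base segment, mm (geometry only;
#'   does not affect the measured parameters).
#' @return A [serration_landmarks()] object (flagged detached).
#' @export
#' @examples
#' lm <- synthesize_landmarks(20, 15, 2, n_path_points = 50)
#' inclination_angle(lm)      # 20
#' tip_displacement_angle(lm) # 15
#' serration_length(lm)       # 2
synthesize_landmarks <- function(alpha_deg, beta_deg, length_mm,
                                 n_path_points = 50L,
                                 wing_side = c("right", "left"),
                                 base_length_mm = max(length_mm, 0.5)) {
  wing_side <- match.arg(wing_side)
  if (!(alpha_deg > 0 && alpha_deg < 90))
    stop("alpha_deg must lie in (0, 90)")
  if (!(beta_deg >= 0 && beta_deg < 90))
    stop("beta_deg must lie in [0, 90)")
  if (length_mm <= 0) stop("length_mm must be > 0")
  n_path_points <- as.integer(n_path_points)
  if (n_path_points < 2) stop("n_path_points must be >= 2")

  a <- alpha_deg * pi / 180
  b <- beta_deg * pi / 180
  origin <- c(0, 0)
  dir_of <- function(psi) c(sin(psi), cos(psi)) # psi measured from the y-axis
  sep <- origin + base_length_mm * dir_of(a)

  if (beta_deg == 0) {
    t <- seq(0, 1, length.out = n_path_points)
    path <- t(vapply(t, function(tt) sep + tt * length_mm * dir_of(a),
                     numeric(2)))
  } else {
    # circular arc: tangent at the separation point = base direction,
    # total turn 2*b so the chord sits at a + b
    k <- 2 * b / length_mm
    s <- seq(0, length_mm, length.out = n_path_points)
    psi <- a + k * s
    path <- cbind(sep[1] + (cos(a) - cos(psi)) / k,
                  sep[2] + (sin(psi) - sin(a)) / k)
    # rescale about sep so the polyline (not the smooth arc) has the exact
    # requested length; scaling preserves every angle
    poly <- sum(sqrt(rowSums(diff(path)^2)))
    path <- sweep(sweep(path, 2, sep, "-") * (length_mm / poly), 2, sep, "+")
    path[1, ] <- sep
  }

  mirror <- function(p) if (wing_side == "left") c(-p[1], p[2]) else p
  frame <- feather_frame(calamus_start = c(0, -10), rachis_tip = c(0, 10),
                         wing_side = wing_side)
  if (wing_side == "left") path <- cbind(-path[, 1], path[, 2])
  serration_landmarks(frame,
                      barb_origin = mirror(origin),
                      separation_point = mirror(sep),
                      tip = path[nrow(path), ],
                      path = path, detached = TRUE)
}

#' Measure all three shape parameters at once
#'
#' @param landmarks a [serration_landmarks()] object.
#' @return Named numeric vector `inclination_deg`, `tip_displacement_deg`,
#'   `length_mm`.
#' @export
measure_serration <- function(landmarks) {
  c(inclination_deg = inclination_angle(landmarks),
    tip_displacement_deg = tip_displacement_angle(landmarks),
    length_mm = serration_length(landmarks))
}
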