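frame_r <- feather_frame(c(0, -10), c(0, 10), "right")

test_that("inclination angle covers the collinear, orthogonal and round-trip cases", {
  # base parallel to the rachis
  lm <- serration_landmarks(frame_r, c(1, 0), c(1, 2), c(1.5, 3))
  expect_equal(inclination_angle(lm), 0)
  # base perpendicular to the rachis
  lm <- serration_landmarks(frame_r, c(0, 1), c(2, 1), c(3, 1.5))
  expect_equal(inclination_angle(lm), 90)
  # synthesized round-trip
  lm <- synthesize_landmarks(27.4, 10, 1)
  expect_equal(inclination_angle(lm), 27.4, tolerance = 1e-9)
})

test_that("tip-displacement angle is signed away from the rachis", {
  # straight barb: tip on the extended base line
  lm <- synthesize_landmarks(30, 0, 1, n_path_points = 2)
  expect_equal(tip_displacement_angle(lm), 0, tolerance = 1e-9)
  expect_equal(tip_displacement_angle(synthesize_landmarks(20, 15, 2)), 15,
               tolerance = 1e-9)
  # bent towards the rachis: negative
  a <- 30 * pi / 180
  sep <- c(sin(a), cos(a))
  bent <- (30 - 15) * pi / 180
  tip <- sep + 0.5 * c(sin(bent), cos(bent))
  lm <- serration_landmarks(frame_r, c(0, 0), sep, tip)
  expect_equal(tip_displacement_angle(lm), -15, tolerance = 1e-9)
})

test_that("coincident tip and separation point is rejected", {
  sep <- c(1, 1)
  lm <- serration_landmarks(frame_r, c(0, 0), sep, c(2, 2))
  lm$tip <- sep # corrupt after construction
  expect_error(tip_displacement_angle(lm), "coincides")
})

test_that("serration length is the polyline arc length", {
  # straight two-point path of 1 mm
  lm <- serration_landmarks(frame_r, c(0, 0), c(0.6, 0.8), c(1.2, 1.6))
  expect_equal(serration_length(lm), 1, tolerance = 1e-12)
  # semicircle of radius 1: length pi within 0.1 %
  theta <- seq(0, pi, length.out = 200)
  path <- cbind(1 - cos(theta), sin(theta)) + 1 # offset from origin
  lm <- serration_landmarks(frame_r, c(0, 0), path[1, ], path[200, ],
                            path = path)
  expect_equal(serration_length(lm), pi, tolerance = 1e-3)
  # synthesized round-trip at 1e-6
  lm <- synthesize_landmarks(20, 15, 2, n_path_points = 50)
  expect_equal(serration_length(lm), 2, tolerance = 1e-6)
})

test_that("measurement round-trips synthesized landmarks over the parameter space", {
  set.seed(31)
  for (i in 1:40) {
    alpha <- runif(1, 5, 45)
    beta <- runif(1, 0.5, 40)
    len <- runif(1, 0.5, 8)
    for (side in c("right", "left")) {
      lm <- synthesize_landmarks(alpha, beta, len, n_path_points = 60,
                                 wing_side = side)
      m <- measure_serration(lm)
      expect_equal(unname(m["inclination_deg"]), alpha, tolerance = 1e-6)
      expect_equal(unname(m["tip_displacement_deg"]), beta, tolerance = 1e-6)
      expect_equal(unname(m["length_mm"]), len, tolerance = 1e-6)
    }
  }
})

test_that("curved length is never below the straight separation-tip distance", {
  set.seed(8)
  for (i in 1:20) {
    lm <- synthesize_landmarks(runif(1, 5, 45), runif(1, 0, 40),
                               runif(1, 0.5, 8), n_path_points = 40)
    chord <- sqrt(sum((lm$tip - lm$separation_point)^2))
    expect_gte(serration_length(lm) + 1e-12, chord)
  }
})

test_that("classification follows detachment plus bending away from the rachis", {
  away <- synthesize_landmarks(25, 15, 2)
  expect_identical(classify_edge_element(away), "serration")
  # detached but bent towards the rachis: denticulation
  a <- 25 * pi / 180
  sep <- c(sin(a), cos(a))
  bent <- (25 - 10) * pi / 180
  toward <- serration_landmarks(frame_r, c(0, 0), sep,
                                sep + 0.5 * c(sin(bent), cos(bent)))
  expect_identical(classify_edge_element(toward), "denticulation")
  # straight, detached tip is also only a denticulation
  straight <- synthesize_landmarks(25, 0, 2, n_path_points = 2)
  expect_identical(classify_edge_element(straight), "denticulation")
  # attached tip: smooth edge
  attached <- synthesize_landmarks(25, 15, 2)
  attached$detached <- FALSE
  expect_identical(classify_edge_element(attached), "smooth")
})

test_that("classification is invariant to rigid rotation and uniform scaling", {
  lm <- synthesize_landmarks(25, 8, 2)
  for (i in 1:5) {
    th <- runif(1, 0, 2 * pi)
    s <- runif(1, 0.2, 5)
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    tr <- function(p) as.vector(s * rot %*% p)
    frame2 <- feather_frame(tr(lm$frame$calamus_start),
                            tr(lm$frame$rachis_tip), lm$frame$wing_side)
    lm2 <- serration_landmarks(frame2, tr(lm$barb_origin),
                               tr(lm$separation_point), tr(lm$tip),
                               path = t(apply(lm$path, 1, tr)))
    expect_identical(classify_edge_element(lm2), classify_edge_element(lm))
    expect_equal(tip_displacement_angle(lm2), tip_displacement_angle(lm),
                 tolerance = 1e-9)
    expect_equal(inclination_angle(lm2), inclination_angle(lm),
                 tolerance = 1e-9)
  }
})

test_that("left-wing landmarks mirror the right-wing ones with identical measurements", {
  r <- synthesize_landmarks(20, 15, 2, wing_side = "right")
  l <- synthesize_landmarks(20, 15, 2, wing_side = "left")
  expect_equal(l$path[, 1], -r$path[, 1])
  expect_equal(l$path[, 2], r$path[, 2])
  expect_equal(measure_serration(l), measure_serration(r), tolerance = 1e-9)
})

test_that("normalized vane position maps the vane ends to 0 and 1", {
  expect_equal(as.numeric(normalized_vane_position(5, 5, 25)), 0)
  expect_equal(as.numeric(normalized_vane_position(25, 5, 25)), 1)
  expect_equal(as.numeric(normalized_vane_position(15, 5, 25)), 0.5)
  out <- normalized_vane_position(30, 5, 25)
  expect_true(attr(out, "clamped"))
  expect_equal(as.numeric(out), 1)
  expect_error(normalized_vane_position(1, 3, 3), "zero-length")
})

test_that("degenerate landmark inputs are rejected", {
  expect_error(synthesize_landmarks(95, 10, 1), "alpha")
  expect_error(synthesize_landmarks(20, -5, 1), "beta")
  expect_error(synthesize_landmarks(20, 5, 0), "length")
  expect_error(feather_frame(c(0, 0), c(0, 0)), "differ")
  expect_error(serration_landmarks(frame_r, c(1, 1), c(1, 1), c(2, 2)),
               "degenerate base")
})
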