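test_that("a score of 3 on any attribute removes a photo", {
  expect_true(grade_photo(c(focus = 1, posture = 2)))
  expect_false(grade_photo(c(focus = 1, posture = 3)))
  expect_true(grade_photo(c(a = 1, b = 1, c = 1)))
  expect_error(grade_photo(c(a = 4)), "1, 2 or 3")
  expect_error(grade_photo(numeric(0)), "no attribute")
})

test_that("rectification rotates by minus the ground angle and preserves distances", {
  m <- rbind(c(1, 0), c(0, 1), c(2, 3))
  expect_equal(rectify_landmarks(m, 0), m)
  expect_equal(rectify_landmarks(rbind(c(1, 0)), 90), rbind(c(0, -1)),
               tolerance = 1e-12)
  set.seed(8)
  cloud <- matrix(rnorm(20), ncol = 2)
  rot <- rectify_landmarks(cloud, 37.3)
  expect_equal(as.numeric(dist(rot)), as.numeric(dist(cloud)),
               tolerance = 1e-9)
})

test_that("TH:HTL is the ratio of replicate-mean vertical and horizontal separations", {
  reps <- replicate(3, make_replicate(100, 200), simplify = FALSE)
  expect_equal(measure_th_htl(reps)$th_htl, 0.5)
  reps <- lapply(c(99, 100, 101), make_replicate, htl = 200)
  expect_equal(measure_th_htl(reps)$th_htl, 0.5)
  # uniform rescaling leaves the ratio unchanged
  reps2 <- lapply(reps, function(m) m * 2)
  expect_equal(measure_th_htl(reps2)$th_htl, 0.5)
  expect_error(measure_th_htl(list(make_replicate(0, 200))), "degenerate")
})

test_that("the ratio is invariant under rigid rotation plus scaling with matching ground angle", {
  set.seed(21)
  for (i in 1:10) {
    th <- runif(1, 50, 150); htl <- runif(1, 200, 400)
    angle <- runif(1, -45, 45); scale <- runif(1, 0.5, 3)
    raw <- lapply(1:3, function(r)
      make_replicate(th, htl, angle = angle, origin = runif(2, -50, 50)) * scale)
    rect <- lapply(raw, rectify_landmarks, ground_angle_deg = angle)
    expect_equal(measure_th_htl(rect)$th_htl, th / htl, tolerance = 1e-9)
  }
})

test_that("session condition is the median of at least two photo ratios", {
  expect_equal(session_condition(c(0.60, 0.64, 0.70)), 0.64)
  expect_equal(session_condition(c(0.60, 0.70)), 0.65)
  expect_null(session_condition(0.62))
  # adding a duplicate of the median leaves it unchanged, and the median is
  # bounded by the contributing ratios
  x <- c(0.58, 0.62, 0.66, 0.71)
  m <- session_condition(x)
  expect_equal(session_condition(c(x, m)), m)
  expect_gte(m, min(x)); expect_lte(m, max(x))
})

test_that("observation building enforces the two-session rule and loss truncation", {
  cond <- data.frame(
    bear_id = c("A", "B", "B", "B", "B", "B", "C", "C"),
    year = 2015,
    session = c(1, 1, 2, 3, 4, 5, 1, 6),
    th_htl = 0.6, n_photos = 2L)
  repro <- data.frame(bear_id = c("A", "B", "C"), year = 2015,
                      status = c("solitary", "with_cubs", "solitary"),
                      loss_session = c(NA, 4, NA))
  obs <- build_observations(cond, repro)
  expect_false("A" %in% obs$bear_id)                       # single session
  expect_equal(sort(obs$session[obs$bear_id == "B"]), c(1, 2, 3))
  expect_equal(sort(obs$session[obs$bear_id == "C"]), c(1, 6))
  expect_equal(unique(obs$status[obs$bear_id == "B"]), "with_young")
  # exclusive rule keeps the loss session itself
  obs2 <- build_observations(cond, repro, loss_rule = "exclusive")
  expect_equal(sort(obs2$session[obs2$bear_id == "B"]), c(1, 2, 3, 4))
  # re-check of the two-session rule after truncation
  repro$loss_session[2] <- 2
  expect_false("B" %in% build_observations(cond, repro)$bear_id)
  # unknown reproductive record
  expect_error(build_observations(cond, repro[-1, ]), "no reproductive record")
  expect_error(build_observations(cond, within(repro, loss_session[1] <- 3)),
               "solitary")
})

test_that("rule pipeline matches a brute-force enumeration on a synthetic study", {
  cfg <- study_config(seed = 31)
  cond <- gen_condition(cfg)
  measured <- measure_photos(cond$photos)
  obs <- build_observations(session_conditions(measured), cond$repro)
  expect_equal(nrow(obs), oracle_observation_rows(measured, cond$repro))
  # every retained bear-year has between 2 and 8 sessions
  nsess <- tapply(obs$session, paste(obs$bear_id, obs$year),
                  function(s) length(unique(s)))
  expect_true(all(nsess >= 2 & nsess <= 8))
})
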