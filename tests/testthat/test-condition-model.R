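# one small synthetic observation set shared across model tests
cond_fixture <- local({
  cfg <- study_config(seed = 17)
  cond <- gen_condition(cfg)
  classes <- classify_years(cfg$pine_august, cfg$salmon_september)
  obs <- build_observations(session_conditions(measure_photos(cond$photos)),
                            cond$repro, classes)
  list(cfg = cfg, cond = cond, obs = obs)
})

test_that("the penalized fit equals the generalized-ridge closed form at fixed smoothing", {
  set.seed(1)
  n <- 20
  x <- seq(0, 1, length.out = n)
  y <- sin(2 * pi * x) + rnorm(n, 0, 0.2)
  lambda <- 0.7
  fit <- fit_session_smooth(x, y, k = 8, sp = lambda)
  # independent oracle: build the basis and penalty, then solve the
  # generalized-ridge normal equations directly
  sm <- mgcv::smoothCon(mgcv::s(x, k = 8, bs = "tp"),
                        data = data.frame(x = x), absorb.cons = TRUE)[[1]]
  X <- cbind(1, sm$X)
  S <- matrix(0, ncol(X), ncol(X))
  S[-1, -1] <- sm$S[[1]]
  beta <- solve(t(X) %*% X + lambda * S, t(X) %*% y)
  expect_lt(max(abs(coef(fit) - beta)), 1e-6)
  expect_lt(max(abs(fitted(fit) - drop(X %*% beta))), 1e-6)
})

test_that("heavy smoothing shrinks a thin-plate smooth to its linear null space", {
  x <- rep(session_codes(), each = 4)
  y <- 0.2 + 0.05 * x + rnorm(length(x), 0, 1e-8)
  heavy <- fit_session_smooth(x, y, k = 5, sp = 1e8)
  # fitted values are linear in x
  expect_gt(suppressWarnings(summary(lm(fitted(heavy) ~ x))$r.squared),
            0.999999)
  edf_heavy <- sum(heavy$edf) - 1   # minus intercept; centered null space
  expect_lt(edf_heavy, 1.05)
  light <- fit_session_smooth(x, y + rnorm(length(x), 0, 0.05), k = 5, sp = 1e-8)
  expect_gt(sum(light$edf) - 1, 3.5)   # approaches k - 1 after centering
  # edf is nonincreasing in the smoothing parameter
  sweep <- vapply(10^seq(-4, 4, by = 2), function(sp)
    sum(fit_session_smooth(x, y + 0.01 * sin(x), k = 5, sp = sp)$edf),
    numeric(1))
  expect_true(all(diff(sweep) <= 1e-8))
})

test_that("AICc follows the small-sample correction formula and its domain limits", {
  ll <- -123.4
  a <- aicc(ll, 5, 100)
  expect_equal(a, (-2 * ll + 10) + 60 / 94)
  expect_equal(aicc(ll, 5, 1e9), -2 * ll + 10, tolerance = 1e-6)
  expect_error(aicc(ll, 99, 100), "n must exceed")
})

test_that("model ranking yields zero minimum delta and normalized, monotone weights", {
  fake <- function(aicc, name) structure(list(aicc = aicc, name = name),
                                         class = "bear_gamm")
  one <- rank_models(list(fake(-100, "m1")))
  expect_equal(one$delta, 0)
  expect_equal(one$weight, 1)
  two <- rank_models(list(fake(-100, "m1"), fake(-100, "m2")))
  expect_equal(two$weight, c(0.5, 0.5))
  many <- rank_models(lapply(1:5, function(i) fake(-100 + 3 * i, paste0("m", i))))
  expect_equal(min(many$delta), 0)
  expect_equal(sum(many$weight), 1, tolerance = 1e-9)
  expect_true(all(diff(many$weight) <= 0))
})

test_that("published candidate-model AICc differences reproduce the published top weights", {
  ref <- shiretoko_reference()
  w <- akaike_weights(ref$delta_aicc)
  expect_equal(round(w[1:2], 1), ref$top_weights)
  expect_equal(sum(w), 1, tolerance = 1e-9)
})

test_that("a gamma/log GAMM on near-constant response recovers log(c) with vanishing variances", {
  df <- cond_fixture$obs
  set.seed(99)
  df$th_htl <- 0.65 * exp(rnorm(nrow(df), 0, 1e-4))
  fit <- fit_condition_gamm(df, fixed = NULL, k = 5)
  expect_equal(unname(coef(fit$gam)["(Intercept)"]), log(0.65),
               tolerance = 1e-3)
  expect_equal(unname(fitted(fit$gam)), rep(0.65, nrow(df)), tolerance = 1e-3)
  # random-intercept effective df collapse toward zero
  re <- vapply(fit$gam$smooth, function(s) inherits(s, "random.effect"),
               logical(1))
  blocks <- unlist(lapply(fit$gam$smooth[re],
                          function(s) s$first.para:s$last.para))
  # far below the 19 combined factor levels
  expect_lt(sum(fit$gam$edf[blocks]), 3)
})

test_that("by-factor smooths expand to one smooth per level and random blocks match factor sizes", {
  fit <- fit_condition_gamm(cond_fixture$obs, smooth_by = "diet1",
                            fixed = "status * diet1", k = 5)
  ss <- smooth_summary(fit)
  expect_equal(nrow(ss), 2L)
  expect_true(all(grepl("diet1", ss$term)))
  # 2 session smoothing parameters + 2 random-intercept variances
  expect_length(fit$gam$sp, 4L)
  re <- Filter(function(s) inherits(s, "random.effect"), fit$gam$smooth)
  widths <- sort(vapply(re, function(s) as.numeric(s$last.para - s$first.para + 1),
                        numeric(1)))
  expect_equal(widths, sort(as.numeric(c(length(unique(cond_fixture$obs$year)),
                                         length(unique(cond_fixture$obs$bear_id))))))
  expect_true(all(ss$edf >= 1 - 1e-6 & ss$edf <= 5))
  expect_error(fit_condition_gamm(cond_fixture$obs, smooth_by = "diet1", k = 2),
               "at least 3")
})

test_that("prediction curves bracket the mean, respect the link ordering and warn on extrapolation", {
  fit <- fit_condition_gamm(cond_fixture$obs, smooth_by = NULL,
                            fixed = "status", k = 5)
  cur <- predict_curve(fit, sessions = session_codes())
  expect_true(all(cur$lo95 <= cur$mean & cur$mean <= cur$hi95))
  expect_true(all(cur$mean > 0))
  expect_setequal(unique(as.character(cur$status)), c("solitary", "with_young"))
  expect_warning(predict_curve(fit, sessions = c(0.5, 3)), "outside")
  # population-level curve at a design point stays within the data range
  expect_true(all(cur$mean > min(cond_fixture$obs$th_htl) * 0.8 &
                    cur$mean < max(cond_fixture$obs$th_htl) * 1.2))
})

test_that("a generated reproductive-status offset is recovered with the right sign and covered CI", {
  fit <- fit_condition_gamm(cond_fixture$obs, smooth_by = NULL,
                            fixed = "status", k = 5)
  cs <- coef_summary(fit)
  row <- cs[cs$term == "statuswith_young", ]
  expect_lt(row$beta, 0)
  expect_true(abs(row$beta - cond_fixture$cfg$rst_offset) < 1.96 * row$se * 1.5)
  expect_true(fit$converged)
  # AICc exceeds plain AIC for finite n
  expect_gt(fit$aicc, -2 * as.numeric(logLik(fit$gam)) + 2 * fit$k_eff - 1e-9)
})

test_that("non-positive responses are rejected", {
  df <- cond_fixture$obs
  df$th_htl[1] <- 0
  expect_error(fit_condition_gamm(df, fixed = "status"), "strictly positive")
})
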