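test_that("the crossing model recovers known coefficients", {
  dep <- simulate_departures(200, c(2, 1, -2, -1), 0.5, 20, seed = 7)
  fit <- fit_crossing_model(dep, chains = 2, iter = 1200, seed = 1)
  est <- coef(fit)
  expect_lt(max(abs(est - c(2, 1, -2, -1))), 0.6)
  s <- fit$summary
  expect_true(all(s[, "l-95% CI"] <= s[, "Estimate"] &
                    s[, "Estimate"] <= s[, "u-95% CI"]))
  expect_true(all(is.finite(s[, "Rhat"])))
  expect_true(all(s[, "Bulk_ESS"] > 0))
})

test_that("predicted crossing probability falls as the ratio rises", {
  dep <- simulate_departures(200, c(2, 1, -2, -1), 0.5, 20, seed = 7)
  fit <- fit_crossing_model(dep, chains = 2, iter = 1000, seed = 2)
  grid <- data.frame(tailwind_ms = 0, ratio = seq(0.4, 1.1, length.out = 15),
                     night = FALSE)
  p <- predict(fit, grid)
  expect_true(all(diff(p) < 0))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("independent chains with different seeds agree", {
  dep <- simulate_departures(150, c(1, 0.8, -1.2, -0.5), 0.5, 15, seed = 3)
  f1 <- fit_crossing_model(dep, chains = 2, iter = 1200, seed = 11)
  f2 <- fit_crossing_model(dep, chains = 2, iter = 1200, seed = 22)
  for (pn in FIXED_EFFECT_NAMES) {
    mcse <- sqrt(f1$summary[pn, "Est.Error"]^2 / f1$summary[pn, "Bulk_ESS"] +
                   f2$summary[pn, "Est.Error"]^2 / f2$summary[pn, "Bulk_ESS"])
    expect_lt(abs(f1$summary[pn, "Estimate"] - f2$summary[pn, "Estimate"]),
              4 * mcse + 0.05)
  }
})

test_that("doubling the data contracts the posterior", {
  dep <- simulate_departures(100, c(1, 0.8, -1.2, -0.5), 0.5, 12, seed = 5)
  dep2 <- rbind(dep, dep)
  f1 <- fit_crossing_model(dep, chains = 2, iter = 1000, seed = 1)
  f2 <- fit_crossing_model(dep2, chains = 2, iter = 1000, seed = 1)
  w1 <- f1$summary[FIXED_EFFECT_NAMES, "u-95% CI"] -
    f1$summary[FIXED_EFFECT_NAMES, "l-95% CI"]
  w2 <- f2$summary[FIXED_EFFECT_NAMES, "u-95% CI"] -
    f2$summary[FIXED_EFFECT_NAMES, "l-95% CI"]
  expect_lt(mean(w2 / w1), 1)
})

test_that("degenerate designs are rejected or flagged", {
  dep <- simulate_departures(50, c(0, 0, 0, 0), 0.3, 8, seed = 2)
  all_cross <- dep; all_cross$decision <- "cross"
  expect_error(fit_crossing_model(all_cross), "identical")
  one_bird <- dep; one_bird$bird_id <- "B1"
  expect_error(fit_crossing_model(one_bird), "two birds")
  # complete separation proceeds with a message, regularised by the priors
  sep <- dep
  sep$decision <- ifelse(sep$ratio < stats::median(sep$ratio), "cross", "detour")
  expect_message(fit <- fit_crossing_model(sep, chains = 1, iter = 400,
                                           seed = 1), "separates")
  expect_true(all(is.finite(fit$summary[, "Estimate"])))
})

test_that("fixed effects agree with a likelihood-based mixed fit", {
  library(lme4)
  dep <- simulate_departures(300, c(1, 0.8, -1.2, -0.6), 0.4, 25, seed = 9)
  fit <- fit_crossing_model(dep, chains = 2, iter = 1200, seed = 4)
  g <- lme4::glmer(
    I(decision == "cross") ~ tw + ra + night + (1 | bird_id),
    data = transform(dep, tw = as.numeric(scale_center(tailwind_ms)),
                     ra = as.numeric(scale_center(ratio))),
    family = binomial())
  expect_lt(max(abs(coef(fit) - lme4::fixef(g))), 0.4)
})

test_that("Bayes R2 is a proportion with sensible extremes", {
  dep0 <- simulate_departures(150, c(0, 0, 0, 0), 0.01, 15, seed = 13)
  f0 <- fit_crossing_model(dep0, chains = 2, iter = 800, seed = 1)
  r0 <- bayes_r2(f0)
  expect_lt(r0[["mean"]], 0.15)          # null model explains ~nothing
  dep1 <- simulate_departures(150, c(0, 6, -6, 0), 0.01, 15, seed = 13)
  f1 <- fit_crossing_model(dep1, chains = 2, iter = 800, seed = 1)
  expect_gt(bayes_r2(f1)[["mean"]], 0.7) # near-deterministic outcomes
  for (f in list(f0, f1)) {
    r <- bayes_r2(f)
    expect_true(all(r[c("mean", "l95", "u95")] >= 0 &
                      r[c("mean", "l95", "u95")] <= 1))
  }
})

test_that("Bayes R2 is invariant to relabelling birds", {
  dep <- simulate_departures(120, c(1, 1, -1, -0.5), 0.5, 10, seed = 17)
  relab <- dep
  relab$bird_id <- paste0("X", dep$bird_id)
  f1 <- fit_crossing_model(dep, chains = 1, iter = 600, seed = 3)
  f2 <- fit_crossing_model(relab, chains = 1, iter = 600, seed = 3)
  expect_equal(bayes_r2(f1), bayes_r2(f2), tolerance = 1e-12)
})

test_that("model methods are coherent", {
  dep <- simulate_departures(100, c(1, 0.8, -1, -0.5), 0.4, 10, seed = 21)
  fit <- fit_crossing_model(dep, chains = 2, iter = 600, seed = 1)
  expect_output(print(fit), "Population-level effects")
  expect_output(print(summary(fit)), "Bayes R2")
  expect_length(coef(fit), 4)
  p <- predict(fit)
  expect_length(p, 100)
  expect_true(all(p > 0 & p < 1))
  r <- residuals(fit)
  expect_equal(r, fit$y - p, tolerance = 1e-12)
  y_rep <- simulate(fit, nsim = 5, seed = 2)
  expect_identical(dim(y_rep), c(5L, 100L))
  expect_true(all(y_rep %in% 0:1))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("the daylight regression recovers a known slope", {
  set.seed(31)
  n <- 200
  daylight <- pmin(pmax(rnorm(n, 67, 40), 4), 176)
  logd <- 1.5 + 0.013 * daylight + rnorm(n, 0, 0.4)
  segs <- data.frame(phase = "night", daylight_min = daylight,
                     distance_km = exp(logd) - 1)
  fit <- fit_daylight_regression(segs, "night")
  expect_equal(fit$n_segments, n)
  expect_true(fit$slope_ci[1] <= 0.013 && 0.013 <= fit$slope_ci[2])
  expect_lt(abs(fit$slope - 0.013), 0.004)
  expect_output(print(fit), "slope")
})

test_that("daylight regression handles exact and degenerate inputs", {
  segs <- data.frame(phase = "day", daylight_min = c(10, 50, 90, 130),
                     distance_km = exp(0.5 + 0.01 * c(10, 50, 90, 130)) - 1)
  # a perfect fit provokes lm's "essentially perfect fit" warning
  fit <- suppressWarnings(fit_daylight_regression(segs, "day"))
  expect_equal(fit$slope, 0.01, tolerance = 1e-9)
  expect_lt(diff(fit$slope_ci), 1e-6)
  flat <- data.frame(phase = "day", daylight_min = rep(60, 5),
                     distance_km = 1:5)
  expect_error(fit_daylight_regression(flat, "day"), "constant")
  expect_error(fit_daylight_regression(segs[1:2, ], "day"), "at least 3")
})
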