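# Penalized-likelihood LMS fitting.

test_that("a constant-curve fit recovers a known triple and matches a
           direct MLE oracle", {
  set.seed(301)
  n <- 5000
  tri <- lms_triple(1, 3000, 0.15)
  recs <- data.frame(sex = "male",
                     gest_weeks = sample(30:40, n, replace = TRUE),
                     weight_g = centile_value(tri, rnorm(n)))
  fit <- fit_lms(recs, fit_config(edf_L = 1, edf_M = 1, edf_S = 1,
                                  sex_offset = FALSE))
  expect_true(fit$converged)
  cv <- evaluate_model(fit, weeks = 35, digits = NULL, round_M = FALSE)
  Lhat <- cv$L[1]; Mhat <- cv$M[cv$sex == "male"]; Shat <- cv$S[1]
  expect_lt(abs(Mhat - 3000) / 3000, 0.01)
  expect_lt(abs(Shat - 0.15) / 0.15, 0.05)
  expect_lt(abs(Lhat - 1), 0.3)

  # independent oracle: direct 3-parameter BCCG maximum likelihood
  negll <- function(p) {
    L <- p[1]; M <- exp(p[2]); S <- exp(p[3])
    u <- log(recs$weight_g / M)
    z <- if (abs(L) < 1e-8) u / S else (exp(L * u) - 1) / (L * S)
    -sum(-z^2 / 2 + L * u - log(S))
  }
  o <- optim(c(1, log(3000), log(0.15)), negll, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 500))
  expect_lt(abs(Lhat - o$par[1]), 1e-3)
  expect_lt(abs(Mhat - exp(o$par[2])) / Mhat, 1e-3)
  expect_lt(abs(Shat - exp(o$par[3])), 1e-3)
})

test_that("sexes generated identically give a null sex offset", {
  set.seed(302)
  n <- 5000
  tri <- lms_triple(1, 3000, 0.15)
  recs <- data.frame(sex = rep(c("male", "female"), each = n / 2),
                     gest_weeks = sample(30:40, n, replace = TRUE),
                     weight_g = centile_value(tri, rnorm(n)))
  fit <- fit_lms(recs, fit_config(edf_L = 1, edf_M = 1, edf_S = 1))
  expect_lt(abs(fit$delta), 3 * fit$delta_se)
})

test_that("the penalized log-likelihood is monotone and training
           z-scores are close to standard normal", {
  reg <- simulate_register(simulation_config(seed = 1))
  fit <- fit_lms(reg, fit_config())
  expect_true(fit$converged)
  expect_true(all(diff(fit$pll_trace) >= -1e-8 * abs(fit$pll)))
  expect_lt(abs(mean(fit$zscores)), 0.05)
  expect_lt(abs(sd(fit$zscores) - 1), 0.05)
  # realized smoothness matches the requested degrees of freedom
  expect_equal(unname(fit$edf_actual), c(4, 6, 4), tolerance = 0.05)
})

test_that("evaluate_model tabulates the window requested", {
  reg <- simulate_register(small_config(seed = 5))
  fit <- fit_lms(reg, fit_config())
  tab <- evaluate_model(fit)
  expect_s3_class(tab, "lms_table")
  expect_equal(nrow(tab), 2 * 13) # 30..42 for both sexes
  expect_equal(sort(unique(tab$week)), 30:42)
  expect_error(evaluate_model(fit, weeks = 27), "window")

  # constant-curve models are constant across weeks
  set.seed(303)
  recs <- data.frame(sex = "male",
                     gest_weeks = sample(30:40, 2000, replace = TRUE),
                     weight_g = centile_value(lms_triple(1, 3000, 0.15),
                                              rnorm(2000)))
  fitc <- fit_lms(recs, fit_config(edf_L = 1, edf_M = 1, edf_S = 1,
                                   sex_offset = FALSE))
  tabc <- evaluate_model(fitc, weeks = 30:40, digits = NULL,
                         round_M = FALSE)
  m <- tabc[tabc$sex == "male", ]
  expect_equal(max(m$M) - min(m$M), 0)
  expect_equal(max(m$L) - min(m$L), 0)
  expect_equal(max(m$S) - min(m$S), 0)
})

test_that("sex_difference_percent transforms delta and its CI", {
  fake <- structure(list(delta = log(0.976), delta_se = 0.0035,
                         sex_offset = TRUE), class = "lms_fit")
  sd_ <- sex_difference_percent(fake)
  expect_equal(sd_$estimate, 2.4, tolerance = 1e-12)
  expect_lt(sd_$ci[1], 2.4)
  expect_gt(sd_$ci[2], 2.4)
  fake$sex_offset <- FALSE
  expect_error(sex_difference_percent(fake), "without a sex offset")
})

test_that("fitting rejects unusable inputs", {
  few <- data.frame(sex = "male", gest_weeks = 35, weight_g = 2500)
  expect_error(fit_lms(few, fit_config()), "insufficient data")
  one_sex <- data.frame(sex = "male",
                        gest_weeks = rep(30:40, 10),
                        weight_g = rep(2500, 110))
  expect_error(fit_lms(one_sex, fit_config()), "both sexes")
  # narrow span cannot support a wiggly curve
  narrow <- data.frame(sex = rep(c("male", "female"), 50),
                       gest_weeks = rep(38:39, 50),
                       weight_g = exp(rnorm(100, log(3000), 0.15)))
  expect_error(fit_lms(narrow, fit_config(week_range_fit = c(38, 39),
                                          week_range_report = c(38, 39))),
               "singular basis")
  expect_error(fit_config(edf_M = 0.5), "edf")
  expect_error(fit_config(week_range_report = c(20, 42)), "within")
})

test_that("records outside the fit window are excluded, not clamped", {
  set.seed(304)
  tri <- lms_triple(1, 3000, 0.15)
  inside <- data.frame(sex = rep(c("male", "female"), 500),
                       gest_weeks = sample(30:40, 1000, replace = TRUE),
                       weight_g = centile_value(tri, rnorm(1000)))
  outside <- data.frame(sex = "male", gest_weeks = c(20, 25, 45),
                        weight_g = c(300, 700, 3500))
  f1 <- fit_lms(inside, fit_config())
  f2 <- fit_lms(rbind(inside, outside), fit_config())
  expect_equal(f2$n, f1$n)
  expect_equal(f2$loglik, f1$loglik)
})
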