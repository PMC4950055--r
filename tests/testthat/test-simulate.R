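# Synthetic birth-register generator.

test_that("the default register reproduces the reference counts exactly", {
  reg <- simulate_register(simulation_config(seed = 10))
  expect_equal(nrow(reg), 8825)
  expect_equal(sum(reg$sex == "male"), 4760)
  expect_equal(sum(reg$sex == "female"), 4065)
  expect_true(all(reg$outcome == "live_birth"))
  expect_true(all(reg$karyotype == "free_trisomy_21"))
  expect_false(anyNA(reg$weight_g))
  expect_false(anyNA(reg$gest_weeks))
  expect_true(all(reg$year >= 1989 & reg$year <= 2011))
  # per-cell counts equal the configured table
  ref <- ds_reference()
  got <- as.data.frame(table(reg$gest_weeks, reg$sex),
                       stringsAsFactors = FALSE)
  key <- paste(got$Var1, got$Var2)
  want <- ref$counts$n[match(key, paste(ref$counts$week, ref$counts$sex))]
  expect_equal(got$Freq, want)
})

test_that("a fixed seed reproduces the register exactly", {
  a <- simulate_register(simulation_config(seed = 77))
  b <- simulate_register(simulation_config(seed = 77))
  expect_identical(a, b)
  # and the generator does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_register(small_config(seed = 77)))
  expect_identical(rnorm(1), before)
})

test_that("simulated weights follow the generating BCCG distribution", {
  tab <- ds_reference()$lms
  cfg <- simulation_config(
    count_table = data.frame(week = 38, sex = "male", n = 100000),
    lms_table = tab, seed = 20
  )
  reg <- simulate_register(cfg)
  tri <- interpolate_lms(tab, "male", 38)
  expect_lt(abs(median(reg$weight_g) - tri$M) / tri$M, 0.005)
  frac <- mean(reg$weight_g < centile_value(tri, -2))
  expect_lt(abs(frac - pnorm(-2)), 0.0015)
})

test_that("fitted z-scores of simulated cells pass a KS check against
           standard normal in nearly all replicates", {
  tab <- ds_reference()$lms
  tri <- interpolate_lms(tab, "female", 36)
  pvals <- vapply(1:20, function(i) {
    cfg <- simulation_config(
      count_table = data.frame(week = 36, sex = "female", n = 1000),
      lms_table = tab, seed = 400 + i
    )
    reg <- simulate_register(cfg)
    suppressWarnings(ks.test(zscore_value(reg$weight_g, tri),
                             "pnorm"))$p.value
  }, numeric(1))
  expect_gte(sum(pvals > 0.01), 19)
})

test_that("contamination and missingness are conserved and configurable", {
  cfg <- small_config(seed = 30, non_live_fraction = 0.05,
                      non_free_trisomy_fraction = 0.03,
                      missing_weight_rate = 0.1,
                      missing_gestation_rate = 0.05)
  reg <- simulate_register(cfg)
  n_clean_target <- sum(cfg$count_table$n)
  clean <- reg$outcome == "live_birth" & reg$karyotype == "free_trisomy_21"
  expect_equal(sum(clean), n_clean_target)
  expect_equal(nrow(reg), n_clean_target + round(0.05 * n_clean_target) +
                 round(0.03 * n_clean_target))
  expect_true(all(reg$outcome[!clean] %in%
                    c("stillbirth", "termination", "live_birth")))
  # missingness only hits the clean block and sits near its rate
  miss_w <- mean(is.na(reg$weight_g[clean]))
  expect_lt(abs(miss_w - 0.1), 3 * sqrt(0.1 * 0.9 / n_clean_target))
  miss_g <- mean(is.na(reg$gest_weeks[clean]))
  expect_lt(abs(miss_g - 0.05), 3 * sqrt(0.05 * 0.95 / n_clean_target))
})

test_that("a configured secular trend shifts weights; the default has
           no trend", {
  # zero-trend default: weight-on-year slope indistinguishable from 0
  reg <- simulate_register(simulation_config(seed = 50))
  fit <- lm(weight_g ~ year, data = reg)
  expect_lt(abs(coef(fit)[2]), 2 * summary(fit)$coefficients[2, 2])
  # a +20 g/year trend is recovered by the same regression
  reg2 <- simulate_register(simulation_config(seed = 50,
                                              trend_g_per_year = 20))
  fit2 <- lm(weight_g ~ year, data = reg2)
  expect_gt(coef(fit2)[2], 10)
})

test_that("configuration is validated", {
  expect_error(simulation_config(missing_weight_rate = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(year_range = c(2011, 1989)),
               "increasing")
  cnt <- data.frame(week = 27, sex = "male", n = 10)
  expect_error(simulation_config(count_table = cnt),
               "does not cover")
  cnt2 <- data.frame(week = 38, sex = "male", n = -1)
  expect_error(simulation_config(count_table = cnt2), "non-negative")
})
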