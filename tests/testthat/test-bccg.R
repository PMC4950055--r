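# BCCG distribution and centile/z-score arithmetic.

test_that("centile_value matches the closed forms and published cells", {
  # identity at the median, any triple
  tri <- random_triples(20, seed = 11)
  expect_equal(centile_value(tri, 0), tri$M)

  # L = 1 is exactly Normal: M * (1 + S*z)
  tri1 <- lms_triple(1, tri$M, tri$S)
  for (z in c(-2, -0.5, 0.7, 2)) {
    expect_equal(centile_value(tri1, z), tri$M * (1 + tri$S * z))
  }

  # L = 0 closed-form lognormal limit
  expect_equal(centile_value(lms_triple(0, 1000, 0.1), 1), 1000 * exp(0.1),
               tolerance = 1e-12)

  # published 40-week boys' parameters give the printed 2nd centile
  v <- centile_value(lms_triple(0.83, 3251, 0.150), -2)
  expect_lte(abs(round(v) - 2302), 3)
})

test_that("invalid parameters and out-of-domain evaluations error", {
  expect_error(lms_triple(0.5, -10, 0.1), "M must be > 0")
  expect_error(lms_triple(0.5, 3000, 0), "S must be > 0")
  # L*S*z pushes the Box-Cox argument non-positive
  expect_error(centile_value(lms_triple(-2, 3000, 0.25), 2.5),
               "1 \\+ L\\*S\\*z")
  expect_error(zscore_value(-5, lms_triple(1, 3000, 0.15)), "x must be > 0")
  expect_error(bccg_quantile(0, lms_triple(1, 3000, 0.15)), "p must be in")
  expect_error(bccg_quantile(1.2, lms_triple(1, 3000, 0.15)), "p must be in")
})

test_that("z <-> centile round trip holds to 1e-9 over random triples", {
  tri <- random_triples(200, seed = 42)
  set.seed(43)
  z <- runif(200, -3, 3)
  ok <- abs(tri$L) < 1e-8 | (1 + tri$L * tri$S * z) > 0
  z <- ifelse(ok, z, 0)
  x <- centile_value(tri, z)
  expect_lt(max(abs(zscore_value(x, tri) - z)), 1e-9)

  # spec'd derived case: weight at z = -2 for the 40-week boys' triple
  tri40 <- lms_triple(0.83, 3251, 0.150)
  x2 <- centile_value(tri40, -2)
  expect_equal(zscore_value(x2, tri40), -2, tolerance = 1e-9)
  # and the value itself rounds to the printed 2302 g
  expect_equal(round(x2), 2302)
})

test_that("centile_value is strictly increasing in z", {
  tri <- random_triples(50, seed = 7)
  z <- seq(-2.5, 2.5, length.out = 41)
  for (i in seq_len(20)) {
    t1 <- triple_at(tri, i)
    keep <- abs(t1$L) < 1e-8 | (1 + t1$L * t1$S * z) > 0
    v <- centile_value(t1, z[keep])
    expect_true(all(diff(v) > 0))
  }
})

test_that("the lognormal limit is continuous at L -> 0", {
  tri <- random_triples(50, seed = 9)
  z <- rep(c(-2, -1, 1, 2), length.out = 50)
  small <- lms_triple(1e-8, tri$M, tri$S)
  expect_lt(max(abs(centile_value(small, z) - tri$M * exp(tri$S * z)) /
                  tri$M), 1e-6)
})

test_that("CDF, quantile and density are mutually consistent", {
  tri <- lms_triple(0.69, 3019, 0.162) # published 38-week boys' triple
  expect_equal(bccg_cdf(3019, tri), 0.5)
  expect_equal(bccg_quantile(0.5, tri), 3019)
  for (p in c(0.02, 0.1, 0.5, 0.9, 0.98)) {
    expect_equal(bccg_cdf(bccg_quantile(p, tri), tri), p, tolerance = 1e-9)
  }
  # CDF against numeric integration of the density (independent oracle)
  for (x in c(2300, 3019, 3800)) {
    num <- integrate(function(y) exp(bccg_logdensity(y, tri)),
                     lower = 1, upper = x, rel.tol = 1e-10)$value
    expect_equal(bccg_cdf(x, tri), num, tolerance = 1e-6)
  }
})

test_that("centile specs validate ordering and labels", {
  expect_error(centile_spec(c("a", "a"), c(-1, 1)), "unique")
  expect_error(centile_spec(c("a", "b"), c(1, -1)), "strictly increasing")
  spec <- default_centile_spec()
  expect_equal(spec$z, c(-2, -4 / 3, -2 / 3, 0, 2 / 3, 4 / 3, 2))
  expect_equal(spec$label[4], "50th")
})

test_that("make_centile_table applies the formula cell-wise", {
  # single week, median-only spec returns the M column
  tab <- lms_table(data.frame(week = 35, sex = c("male", "female"),
                              L = 0.5, M = c(2333, 2277), S = 0.206))
  ct <- make_centile_table(tab, centile_spec("50th", 0))
  expect_equal(unname(ct$male[1, 1]), 2333)
  expect_equal(unname(ct$female[1, 1]), 2277)

  # L = 1 exact Normal arithmetic at z = +/- 2
  tab2 <- lms_table(data.frame(week = 35, sex = c("male", "female"),
                               L = 1, M = 3000, S = 0.15))
  ct2 <- make_centile_table(tab2, centile_spec(c("lo", "hi"), c(-2, 2)))
  expect_equal(unname(ct2$male[1, ]), c(2100, 3900))

  # rows strictly increase across centiles for the reference chart
  ct3 <- make_centile_table(ds_reference()$lms)
  for (s in c("male", "female")) {
    expect_true(all(apply(ct3[[s]], 1, function(r) all(diff(r) > 0))))
  }
  # columns non-decreasing over 28-41 weeks for this chart family
  sub <- ct3$male[as.integer(rownames(ct3$male)) <= 41, ]
  expect_true(all(apply(sub, 2, function(cc) all(diff(cc) >= 0))))
})

test_that("interpolate_lms is exact at knots and log-linear between", {
  tab <- ds_reference()$lms
  at38 <- interpolate_lms(tab, "male", 38)
  expect_equal(at38$M, 3019)
  expect_equal(at38$L, 0.69)
  expect_equal(at38$S, 0.162)
  # midpoint median is the geometric mean of the bracketing medians
  mid <- interpolate_lms(tab, "male", 38.5)
  expect_equal(mid$M, exp((log(3019) + log(3164)) / 2), tolerance = 1e-12)
  expect_equal(round(mid$M, 1), 3090.6)
  expect_error(interpolate_lms(tab, "male", 27.9), "week range")
  expect_error(interpolate_lms(tab, "female", 43.1), "week range")
})
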