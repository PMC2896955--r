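test_that("reduction proportion and halving distance follow their formulas", {
  expect_equal(reduction_proportion(5616, 4498), 2 * 4498 / (5616 + 4498))
  expect_equal(round(reduction_proportion(5616, 4498), 2), 0.89)
  expect_equal(reduction_proportion(10, 0), 0)
  expect_equal(reduction_proportion(10, 10), 1)
  expect_error(reduction_proportion(0, 0), "positive")
  expect_error(reduction_proportion(5, 6), "m <= n")

  expect_equal(round(normalized_halving_distance(135, 5616, 4498), 2), 0.24)
  expect_equal(round(normalized_halving_distance(686, 10077, 8495), 3), 0.867)
  expect_equal(normalized_halving_distance(0, 10, 4), 0)
  expect_error(normalized_halving_distance(3, 10, 10), "n > m")
  expect_error(normalized_halving_distance(-1, 10, 4), "non-negative")
})

test_that("geometric fit recovers parameters from near-exact model counts", {
  p <- 0.3
  s <- 1:15
  counts <- round(100 * (1 - p)^(s - 1))
  names(counts) <- s
  fit <- fit_geometric(counts)
  expect_lt(abs(fit$p - p), 0.02)
  expect_lt(abs(fit$N1 - 100), 3)
  expect_lt(fit$chi2, 1)          # only rounding noise remains
})

test_that("doubling all counts doubles N1 and leaves p unchanged", {
  p <- 0.4
  counts <- round(500 * (1 - p)^(0:9))
  names(counts) <- 1:10
  f1 <- fit_geometric(counts)
  f2 <- fit_geometric(counts * 2L)
  expect_equal(f2$p, f1$p, tolerance = 1e-6)
  expect_equal(f2$N1, 2 * f1$N1, tolerance = 1e-6)
})

test_that("degenerate histograms are rejected", {
  expect_error(fit_geometric(c(`0` = 5L, `1` = 100L)), "3 distinct")
  expect_error(fit_geometric(c(`1` = 100L, `2` = 0L, `3` = 0L)), "3 distinct")
})

test_that("extrapolation to s = 0 is N1/(1-p) and ignores observed N(0)", {
  fit <- structure(list(p = 0.5, N1 = 100), class = "geometric_fit")
  expect_equal(predict_N0(fit), 200)
  fit2 <- structure(list(p = 0.3, N1 = 70), class = "geometric_fit")
  expect_equal(predict_N0(fit2), 100)

  # reduction-resistant regions: inflate N(0) far above the geometric trend;
  # the fit must not move, and the observed N(0) must exceed the prediction
  p <- 0.4
  counts <- round(400 * (1 - p)^(0:11))
  names(counts) <- 1:12
  base <- c(`0` = 0L, counts)
  infl <- base
  infl["0"] <- round(2.5 * 400 / (1 - p))
  f_base <- fit_geometric(base)
  f_infl <- fit_geometric(infl)
  expect_identical(f_base[c("p", "N1", "chi2")], f_infl[c("p", "N1", "chi2")])
  expect_gt(infl[["0"]], predict_N0(f_infl))
})

test_that("tail pooling respects the minimum expected count", {
  p <- 0.6
  counts <- round(200 * (1 - p)^(0:14))
  names(counts) <- 1:15
  f1 <- fit_geometric(counts, min_expected = 1)
  f5 <- fit_geometric(counts, min_expected = 5)
  expect_lt(f5$df, f1$df)          # pooling merges tail bins
  expect_lt(abs(f5$p - p), 0.05)   # but barely moves the estimate
})

test_that("the folded binomial concentration model sums to one", {
  r2 <- concentration_cdf(2)
  expect_equal(r2$P, c(0.5, 0.5))
  r4 <- concentration_cdf(4)
  expect_equal(r4$B, c(2 / 16, 10 / 16, 1))
  for (s in 2:50) {
    r <- concentration_cdf(s)
    expect_lt(abs(r$B[length(r$B)] - 1), 1e-12)
    expect_true(all(r$P >= 0))
    # direct binomial-sum oracle
    oracle <- sapply(r$q, function(q) {
      if (q < s / 2) choose(s, q) / 2^s + choose(s, s - q) / 2^s
      else choose(s, q) / 2^s
    })
    expect_equal(r$P, oracle, tolerance = 1e-12)
  }
  expect_error(concentration_cdf(1), ">= 2")
})

test_that("empirical concentration uses minority counts and normalizes", {
  conc <- empirical_concentration(fake_aus(c(3, 3, 3, 3), c(0, 0, 1, 1)))
  expect_equal(conc$F[conc$s == 3 & conc$q == 0], 0.5)
  expect_equal(conc$Fhat[conc$s == 3 & conc$q == 1], 1)
  expect_identical(sort(unique(conc$s)), 3L)   # absent sizes absent
  # s < 2 excluded
  expect_identical(nrow(empirical_concentration(fake_aus(c(0, 1), c(0, 0)))),
                   0L)
  # sum_q F(s, q) = 1 for every present size, on simulated AUs
  case <- random_genome_case(2)
  aus <- extract_aus(case$genome, case$pmap)
  conc2 <- empirical_concentration(aus)
  if (nrow(conc2) > 0L) {
    sums <- tapply(conc2$F, conc2$s, sum)
    expect_equal(unname(sums), rep(1, length(sums)))
  }
})

test_that("self-comparison puts every point on the diagonal", {
  conc <- empirical_concentration(fake_aus(c(2, 2, 3, 4, 4, 5),
                                           c(0, 1, 1, 0, 2, 2)))
  comp <- diagonal_comparison(conc, list(conc, conc))
  expect_identical(comp$above, 0L)
  expect_identical(comp$below, 0L)
  expect_identical(comp$on, nrow(comp$points))
})

test_that("diagonal classification compares count fractions exactly", {
  real <- empirical_concentration(fake_aus(c(3, 3, 3), c(0, 0, 0)))
  sim <- empirical_concentration(fake_aus(c(3, 3, 3, 3, 3), c(0, 0, 1, 1, 1)))
  comp <- diagonal_comparison(real, list(sim))
  # q=0: real 1 vs sim 0.4 -> above; q=1: 1 vs 1 -> on
  expect_identical(comp$points$class, c("above", "on"))
  # thirds vs near-thirds must not be called equal
  real2 <- empirical_concentration(fake_aus(rep(3, 3), c(0, 1, 1)))
  sim2 <- empirical_concentration(fake_aus(rep(3, 10), c(0, 0, 0, rep(1, 7))))
  comp2 <- diagonal_comparison(real2, list(sim2))
  expect_identical(comp2$points$class[1], "above")  # 1/3 > 3/10
  # error when no size overlaps
  expect_error(
    diagonal_comparison(real, list(empirical_concentration(
      fake_aus(c(6, 6), c(1, 2))))),
    "no AU size"
  )
})

test_that("per-size proportions match a direct tally", {
  conc_r <- empirical_concentration(fake_aus(rep(c(2, 3, 4), 4),
                                             c(0, 0, 0, 1, 1, 1, 0, 1, 2,
                                               1, 0, 2)))
  set.seed(5)
  sims <- lapply(1:6, function(i) {
    empirical_concentration(fake_aus(rep(c(2, 3, 4), 5),
                                     sample(0:2, 15, TRUE) %% (rep(c(2, 3, 4), 5) %/% 2 + 1)))
  })
  comp <- diagonal_comparison(conc_r, sims)
  pa <- proportion_above_by_size(comp)
  po <- proportion_above_by_size(comp, exclude_on_diagonal = TRUE)
  for (s in names(pa)) {
    pts <- comp$points[comp$points$s == as.integer(s), ]
    expect_equal(pa[[s]], mean(pts$class == "above"))
    if (any(pts$class != "on")) {
      off <- pts[pts$class != "on", ]
      expect_equal(po[[s]], mean(off$class == "above"))
      expect_gte(po[[s]], pa[[s]] - 1e-12)  # smaller denominator
    }
  }
  # all-above edge case
  real1 <- empirical_concentration(fake_aus(c(2, 2), c(0, 0)))
  sim1 <- empirical_concentration(fake_aus(rep(2, 4), c(0, 1, 1, 1)))
  comp1 <- diagonal_comparison(real1, list(sim1))
  expect_true(all(proportion_above_by_size(comp1, TRUE) == 1))
})

test_that("descendant averaging is an unweighted mean on common sizes", {
  a <- c(`2` = 0.4, `3` = 0.6, `4` = 1.0)
  b <- c(`2` = 0.6, `3` = 0.4)
  expect_equal(average_over_descendants(list(a)), a)
  got <- average_over_descendants(list(a, b))
  expect_equal(got, c(`2` = 0.5, `3` = 0.5))  # size 4 missing from b: dropped
  expect_equal(average_over_descendants(list(a, a, a)), a)
})
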