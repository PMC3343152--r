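test_that("odds ratio matches hand arithmetic, including zero-cell rules", {
  expect_equal(as.numeric(odds_ratio(contingency_table(10, 10, 10, 10))), 1)
  expect_equal(as.numeric(odds_ratio(contingency_table(30, 10, 20, 40))), 6)
  t0 <- contingency_table(5, 0, 3, 7)
  expect_equal(as.numeric(odds_ratio(t0)), Inf)
  corr <- odds_ratio(t0, correction = TRUE)
  expect_equal(as.numeric(corr), 5.5 * 7.5 / (0.5 * 3.5))
  expect_true(attr(corr, "corrected"))
  expect_error(contingency_table(0, 0, 0, 0), "zero")
})

test_that("free-energy mapping reproduces direct evaluation", {
  d <- delta_delta_g(contingency_table(30, 10, 20, 40), temperature = 300)
  expect_equal(d$score, 0.5962 * log(6), tolerance = 1e-3)
  expect_equal(d$se, 0.5962 * sqrt(1 / 30 + 1 / 10 + 1 / 20 + 1 / 40),
               tolerance = 1e-3)
  # OR = 1 -> score 0 at any temperature
  expect_equal(delta_delta_g(contingency_table(7, 7, 7, 7),
                             temperature = 123)$score, 0)
  # recoding one variable negates the score, SE unchanged
  d2 <- delta_delta_g(contingency_table(10, 30, 40, 20))
  d3 <- delta_delta_g(contingency_table(30, 10, 20, 40))
  expect_equal(d2$score, -d3$score)
  expect_equal(d2$se, d3$se)
  expect_error(delta_delta_g(contingency_table(5, 0, 3, 7)), "n01")
})

test_that("odds-ratio transpose symmetry holds on random tables", {
  set.seed(51)
  for (i in 1:50) {
    n <- sample(1:200, 4, replace = TRUE)
    a <- odds_ratio(contingency_table(n[1], n[2], n[3], n[4]))
    b <- odds_ratio(contingency_table(n[1], n[3], n[2], n[4])) # swap X/Y roles
    expect_equal(as.numeric(a), as.numeric(b))
  }
})

test_that("pooled OR profile equals a manually summed table on a toy case", {
  mask <- rbind(c(1L, 0L, 1L, 0L, 1L),
                c(0L, 1L, 1L, 1L, 0L))
  p <- or_profile(mask, r_max = 2, trim = 0)
  # hand-pool r = 1: pairs (1,2),(2,3),(3,4),(4,5) over both conformations
  a <- c(mask[, 1:4]); b <- c(mask[, 2:5])
  tt <- contingency_table(sum(!a & !b), sum(!a & b), sum(a & !b), sum(a & b))
  d <- delta_delta_g(tt, correction = TRUE)
  expect_equal(p$value[p$r == 1], d$score)
  expect_equal(p$se[p$r == 1], d$se)
  expect_equal(p$n_pairs[p$r == 1], 4)
})

test_that("independent masks give null scores at the asymptotic rate", {
  set.seed(52)
  cover <- replicate(300, {
    m <- matrix(rbinom(2000 * 2, 1, 0.3), 2000, 2)
    t <- contingency_table(sum(!m[, 1] & !m[, 2]), sum(!m[, 1] & m[, 2]),
                           sum(m[, 1] & !m[, 2]), sum(m[, 1] & m[, 2]))
    d <- delta_delta_g(t, correction = TRUE)
    abs(d$score) < 2 * d$se
  })
  expect_gte(mean(cover), 0.93)
})

test_that("a duplicated mask column produces the perfect-dependence limit", {
  set.seed(53)
  mask <- matrix(rbinom(5000 * 12, 1, 0.4), 5000, 12)
  mask[, 9] <- mask[, 4]
  # with trim = 3 the only pair at r = 5 is the duplicated (4, 9)
  p <- or_profile(mask, r_max = 5, trim = 3)
  v5 <- p$value[p$r == 5]
  expect_true(p$corrected[p$r == 5])  # zero off-diagonal cells were corrected
  expect_gt(v5, 1)                    # strongly positive association
  expect_true(all(abs(p$value[p$r < 4]) < 4 * p$se[p$r < 4]))
  # uncorrected odds ratio of the duplicated pair alone is infinite
  a <- mask[, 4]; b <- mask[, 9]
  tt <- contingency_table(sum(!a & !b), sum(!a & b), sum(a & !b), sum(a & b))
  expect_equal(as.numeric(odds_ratio(tt)), Inf)
})

test_that("region masks agree with elementwise comparison", {
  lab <- labels_object(rbind(c("alphaR", "beta", NA),
                             c("PPII", "alphaR", "alphaL")))
  m <- region_mask(lab, "alphaR")
  expect_equal(m, rbind(c(1L, 0L, NA), c(0L, 1L, 0L)))
  expect_true(all(region_mask(labels_object(matrix("alphaR", 2, 3)),
                              "beta") == 0L))
  expect_error(region_mask(lab, "gamma"), "unknown region")
})

test_that("psi Pearson profile hits the exact dependence limits", {
  set.seed(54)
  n <- 2000; nres <- 11
  make_ens <- function(psi) {
    psi[, nres] <- NA
    conformation_ensemble(cbind(NA, matrix(-75, n, nres - 1)), psi,
                          cbind(matrix(180, n, nres - 1), NA),
                          rep("GLN", nres))
  }
  # with trim = 3 the only eligible pair at r = 4 is (4, 8)
  psi <- matrix(wrap_angle(rnorm(n * nres, 0, 40)), n, nres)
  psi[, 8] <- psi[, 4]
  p <- pearson_psi_profile(make_ens(psi), shift_deg = 0, trim = 3, r_max = 4)
  expect_equal(p$value[p$r == 4], 1)
  psi2 <- matrix(wrap_angle(rnorm(n * nres, 0, 40)), n, nres)
  psi2[, 8] <- -psi2[, 4]
  p2 <- pearson_psi_profile(make_ens(psi2), shift_deg = 0, trim = 3, r_max = 4)
  expect_equal(p2$value[p2$r == 4], -1)
})

test_that("independent psi angles give near-zero correlations", {
  set.seed(55)
  spec <- q40_like(10000, seed = 56)
  ens <- generate_ensemble(spec)$ensemble
  p <- pearson_psi_profile(ens)
  expect_true(all(abs(p$value) < 0.03))
})

test_that("profile similarity is an affine-invariant Pearson correlation", {
  p1 <- structure(data.frame(r = 1:10, value = sin(1:10), se = 0.1,
                             n_pairs = 10),
                  class = c("correlation_profile", "data.frame"))
  p2 <- p1; p2$value <- 2 * p1$value + 0.1
  expect_equal(profile_similarity(p1, p2), 1)
  p3 <- p1; p3$value <- -p1$value
  expect_equal(profile_similarity(p1, p3), -1)
  p4 <- p1[1:2, ]
  expect_error(profile_similarity(p1, p4), "fewer than 3")
})

test_that("dominant period recovers a pure tone and ignores pure trend", {
  tone <- structure(data.frame(r = 1:20, value = cos(2 * pi * (1:20) / 8),
                               se = 0.01, n_pairs = 20),
                    class = c("correlation_profile", "data.frame"))
  dp <- dominant_period(tone)
  expect_lt(abs(dp$period - 8), 0.5)
  trend <- tone; trend$value <- 0.2 * (1:20)
  expect_lt(dominant_period(trend)$power_fraction, 0.2)
})

test_that("long-range flag compares the tail mean with its uncertainty", {
  set.seed(57)
  noisy <- structure(data.frame(r = 1:25, value = rnorm(25, 0, 0.02),
                                se = 0.05, n_pairs = 20),
                     class = c("correlation_profile", "data.frame"))
  expect_false(long_range_flag(noisy)$flag)
  osc <- noisy
  osc$value <- 0.3 + 0.1 * cos(2 * pi * (1:25) / 7)
  expect_true(long_range_flag(osc)$flag)
  expect_error(long_range_flag(noisy, r_tail = 30), "extend")
})

test_that("alternation-favouring generators give positive alpha-tilde scores", {
  spec <- synthetic_spec(4000, 20,
                         region_marginals = c(alphaR = 0.45, alphaL = 0.45,
                                              PPII = 0.05, beta = 0.05),
                         kernel = list(a = 0.6, lambda = 5, period = 2),
                         seed = 58)
  lab <- sample_regions(spec)
  p <- or_profile(alpha_tilde_mask(lab), r_max = 6, trim = 2)
  expect_gt(p$value[p$r == 1], 0)
  expect_gt(p$value[p$r == 2], 0)
})
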