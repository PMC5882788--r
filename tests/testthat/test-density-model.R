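test_that("2-D KDE fit: guards, degenerate data, moment recovery", {
  fr <- simulate_fragments_binomial("t", 0.5, n = 1e4, seed = 1)
  expect_error(fit_length_gc_kde(new_env <- structure(
    list(taxon_id = "t", lengths = 1:10, gc = rep(0.5, 10), mode = "shotgun"),
    class = "fragment_set")), "30")
  kde <- fit_length_gc_kde(fr)
  rs <- resample_length_gc(kde, 1e4, seed = 2)
  se_len <- sd(fr$lengths) / sqrt(1e4)
  se_gc <- sd(fr$gc) / sqrt(1e4)
  expect_lt(abs(mean(rs[, "length"]) - mean(fr$lengths)), 3 * se_len * 2)
  expect_lt(abs(mean(rs[, "gc"]) - mean(fr$gc)), 3 * se_gc * 2)
  # degenerate: identical fragments concentrate at the point
  frd <- structure(list(taxon_id = "d", lengths = rep(8000, 50),
                        gc = rep(0.4, 50), mode = "shotgun"),
                   class = "fragment_set")
  kded <- fit_length_gc_kde(frd)
  rsd <- resample_length_gc(kded, 1000, seed = 3)
  expect_lt(max(abs(rsd[, "gc"] - 0.4)), 0.001)
  # correlation sign is preserved on correlated input
  set.seed(4)
  len <- runif(5000, 4000, 20000)
  gcc <- 0.3 + len / 1e5 + rnorm(5000, 0, 0.01)
  frc <- structure(list(taxon_id = "c", lengths = len, gc = gcc,
                        mode = "shotgun"), class = "fragment_set")
  rsc <- resample_length_gc(fit_length_gc_kde(frc), 1e4, seed = 5)
  expect_gt(cor(rsc[, "length"], rsc[, "gc"]), 0)
})

test_that("equilibrium profile: normalization, limits, variance", {
  p <- toy_profile(gc = 0.5, seed = 10)
  expect_equal(p$stage, "equilibrium")
  expect_equal(profile_mass(p, 1.60, 1.85), 1, tolerance = 1e-6)
  expect_equal(quad_mass(p, 1.66, 1.76), 1, tolerance = 1e-3)
  # single-point KDE: profile mean converges to gc_to_bd(gc)
  frd <- structure(list(taxon_id = "pt", lengths = rep(12000, 100),
                        gc = rep(0.55, 100), mode = "shotgun"),
                   class = "fragment_set")
  kded <- fit_length_gc_kde(frd)
  pp <- build_bd_profile(kded, n_mc = 1e5, seed = 11)
  sig <- fragment_sigma(gc_to_bd(0.55), 12000)
  expect_lt(abs(profile_mean(pp) - gc_to_bd(0.55)), 3 * sig / sqrt(1e5) + 1e-4)
  # G+C heterogeneity adds spread beyond the single-fragment band width
  expect_gt(sd(p$centers), sig * 0.9)
  expect_error(build_bd_profile(kded, n_mc = 100), "n_mc")
  # Scott's-rule default bandwidth is used when none is supplied
  expect_equal(pp$bw, sd(pp$centers) * 1e5^(-1 / 5), tolerance = 1e-8)
})

test_that("with no DBL and no label, mass far from the G+C range is ~0", {
  p <- toy_profile(gc = 0.5, seed = 12)
  sig_max <- fragment_sigma(1.709, 4000) + p$bw
  lo <- gc_to_bd(0.40) - 5 * sig_max
  hi <- gc_to_bd(0.60) + 5 * sig_max
  expect_lt(1 - profile_mass(p, lo, hi), 1e-7)
})

test_that("DBL smearing: identity, uniform limit, mixture arithmetic", {
  p <- toy_profile(gc = 0.5, seed = 13)
  p0 <- apply_dbl(p, dbl_params(0, 0), abundance = 0.2)
  expect_equal(profile_pdf(p0, seq(1.68, 1.75, 0.01)),
               profile_pdf(p, seq(1.68, 1.75, 0.01)))
  p1 <- apply_dbl(p, dbl_params(0, 1), abundance = 0)  # D = 1
  w <- p$span[2] - p$span[1]
  expect_equal(profile_pdf(p1, c(1.675, 1.70, 1.775)), rep(1 / w, 3),
               tolerance = 1e-4)
  # D = 0.05: far from the mode, density ~ D / span width
  p05 <- apply_dbl(p, dbl_params(0, 0.05), abundance = 0)
  x_far <- profile_mean(p) + 0.04
  expect_equal(profile_pdf(p05, x_far), 0.05 / w, tolerance = 0.02)
  expect_equal(quad_mass(p05, 1.66, 1.79), 1, tolerance = 1e-3)
  expect_gt(min(profile_pdf(p05, seq(1.671, 1.779, 0.002))), 0)
  # stage ordering is enforced
  expect_error(apply_dbl(p05, dbl_params(), 0.1), "equilibrium")
})

test_that("isotope incorporation: identity, full shift, linear mean shift", {
  p <- apply_dbl(toy_profile(gc = 0.5, seed = 14), dbl_params(0, 0.02), 0)
  m0 <- profile_mean(p)
  pA <- apply_incorporation(p, 0)
  expect_equal(profile_mean(pA), m0)
  p100 <- apply_incorporation(p, 100)
  expect_equal(p100$stage, "+incorporation")
  # mode shifts by the full 13C shift; DBL component is not shifted
  D <- p$dbl_frac
  expect_equal(profile_mean(p100) - m0, (1 - D) * 0.036, tolerance = 1e-10)
  p50 <- apply_incorporation(p, 50)
  expect_equal(profile_mean(p50) - m0, (1 - D) * 0.018, tolerance = 1e-10)
  expect_error(apply_incorporation(p, 150), "atom")
  expect_error(apply_incorporation(p100, 50), "stage|follow")
  # non-degenerate intra-population model: MC convolution widens the band
  pI <- apply_incorporation(p, 50, intra = function(n) runif(n, 0, 100),
                            seed = 3)
  expect_gt(sd(pI$centers), sd(p$centers))
})

test_that("profile sampling matches the analytic density", {
  p <- apply_incorporation(
    apply_dbl(toy_profile(gc = 0.45, seed = 15), dbl_params(0, 0.1), 0), 50)
  x <- sample_bd(p, 2e4, seed = 16)
  # compare empirical CDF to profile_mass at a few cut points
  for (q in c(1.70, 1.72, 1.74))
    expect_lt(abs(mean(x < q) - profile_mass(p, 1.60, q)), 0.015)
  expect_identical(sample_bd(p, 50, seed = 1), sample_bd(p, 50, seed = 1))
})
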