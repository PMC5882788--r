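test_that("fragment binning matches per-interval profile mass", {
  p <- apply_dbl(toy_profile(0.5, seed = 1), dbl_params(0, 0.05), 0)
  scheme <- simulate_fractions(seed = 2)
  com <- structure(c(tx = 1), class = "community")
  # exact multinomial path at 1e6 fragments: chi-square GOF vs quadrature
  tab <- build_otu_table(list(tx = p), com, scheme, total_fragments = 1e6,
                         seed = 3)
  expect_equal(tab$stage, "fragments")
  expected <- vapply(seq_len(nrow(scheme)), function(i)
    quad_mass(p, scheme$bd_low[i], scheme$bd_high[i]), 0)
  obs <- as.numeric(tab$counts)
  keep <- expected * 1e6 > 5
  gof <- suppressWarnings(
    chisq.test(obs[keep], p = expected[keep], rescale.p = TRUE))
  expect_gt(gof$p.value, 0.001)
  # Poisson path has the same expectation
  tabP <- build_otu_table(list(tx = p), com, scheme, total_fragments = 1e9,
                          seed = 4)
  expect_equal(as.numeric(tabP$counts) / 1e9, expected, tolerance = 0.02)
  # zero-abundance taxon contributes nothing; missing profile errors
  com2 <- structure(c(tx = 1, ghost = 0), class = "community")
  expect_error(build_otu_table(list(tx = p), com2, scheme), "ghost")
  tab2 <- build_otu_table(list(tx = p, ghost = p), com2, scheme,
                          total_fragments = 1e6, seed = 5)
  expect_equal(sum(tab2$counts["ghost", ]), 0)
})

test_that("PCR bias: identity, no-saturation limit, ratio compression", {
  counts <- matrix(c(9e4, 1e4, 0), nrow = 3,
                   dimnames = list(c("a", "b", "z"), "g_f01"))
  samples <- data.frame(sample_id = "g_f01", gradient_id = "g",
                        fraction_idx = 1, bd_low = 1.70, bd_high = 1.71,
                        treatment = TRUE)
  tab <- make_table(counts, samples, stage = "fragments")
  expect_identical(apply_pcr_bias(tab, cycles = 0,
                                  template_frac = NULL)$counts, counts)
  # K -> Inf: unbiased exponential growth, ratios unchanged
  free <- apply_pcr_bias(tab, cycles = 10, K = 1e18, total_max = Inf,
                         template_frac = NULL)
  expect_equal(free$counts["a", 1] / free$counts["b", 1], 9)
  expect_equal(free$counts["a", 1], 9e4 * 1.95^10)
  # saturating K: 9:1 strictly closer to 1:1, zeros stay zero
  sat <- apply_pcr_bias(tab, template_frac = NULL)
  r <- sat$counts["a", 1] / sat$counts["b", 1]
  expect_lt(r, 9); expect_gt(r, 1)
  expect_equal(sat$counts["z", 1], 0)
  expect_equal(sat$stage, "post-PCR")
  expect_error(apply_pcr_bias(sat), "fragment-stage")
  # template subsampling drops sub-molecule templates, keeps abundant ones
  sub <- apply_pcr_bias(tab, template_frac = 0.01, seed = 1)
  expect_gt(sub$counts["a", 1], 0)
})

test_that("read subsampling conserves depth and expected shares", {
  p1 <- apply_dbl(toy_profile(0.45, seed = 6), dbl_params(), 0.01)
  p2 <- apply_dbl(toy_profile(0.55, seed = 7), dbl_params(), 0.01)
  com <- structure(c(a = 0.3, b = 0.7), class = "community")
  scheme <- simulate_fractions(seed = 8)
  tab <- build_otu_table(list(a = p1, b = p2), com, scheme, 1e9, seed = 9)
  reads <- subsample_reads(tab, depth = 1000, seed = 10)
  expect_true(all(colSums(reads$counts) == 1000))
  expect_equal(reads$stage, "post-sequencing")
  # expected read share equals the input share (averaged over seeds)
  j <- which.max(colSums(tab$counts))
  share <- tab$counts["a", j] / sum(tab$counts[, j])
  obs <- vapply(1:100, function(s)
    subsample_reads(tab, 1000, seed = s)$counts["a", j] / 1000, 0)
  se <- sd(obs) / sqrt(100)
  expect_lt(abs(mean(obs) - share), 3 * se + 1e-4)
  # depth 0 -> all zeros; empty fractions warn
  expect_true(all(subsample_reads(tab, 0, seed = 1)$counts == 0))
  tab0 <- tab; tab0$counts[, 1] <- 0
  expect_warning(subsample_reads(tab0, 100, seed = 2), "zero")
})

test_that("qPCR noise reproduces the stated mean-variance relation", {
  expect_equal(qpcr_variance(0), 5889)
  expect_equal(qpcr_variance(100), 13129)
  expect_equal(qpcr_variance(1000), 720889)
  for (mu in c(1e2, 1e4, 1e6)) {
    counts <- matrix(rep(mu, 1e4), nrow = 1)
    samples <- data.frame(sample_id = sprintf("g_f%05d", 1:1e4),
                          gradient_id = "g", fraction_idx = 1:1e4,
                          bd_low = 1.70, bd_high = 1.71, treatment = TRUE)
    tab <- make_table(counts, samples, stage = "fragments")
    q <- simulate_qpcr(tab, seed = mu)
    expect_lt(abs(var(q$copies) / qpcr_variance(mu) - 1), 0.10)
    expect_lt(abs(mean(q$copies) / mu - 1), 0.05)
  }
  # mu = 0 fractions report zero copies
  tab0 <- make_table(matrix(0, 1, 3),
                     data.frame(sample_id = c("g_f1", "g_f2", "g_f3"),
                                gradient_id = "g", fraction_idx = 1:3,
                                bd_low = 1.7, bd_high = 1.71,
                                treatment = TRUE),
                     stage = "fragments")
  expect_true(all(simulate_qpcr(tab0, seed = 1)$copies == 0))
})
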