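test_that("Heavy-SIP presence rules on a constructed table", {
  sm <- even_samples(c("T1", "C1"), c(TRUE, FALSE))
  counts <- matrix(0, 4, nrow(sm),
                   dimnames = list(c("A", "B", "C", "D"), sm$sample_id))
  in_t <- sm$treatment; heavy <- sm$bd_low >= 1.71 & sm$bd_high <= 1.75
  light <- sm$bd_low >= 1.68 & sm$bd_high <= 1.70
  counts["A", which(in_t & sm$bd_low == 1.72)] <- 1      # T heavy only
  counts["B", which(heavy)[1:2]] <- 5                    # both arms heavy
  counts["B", which(!in_t & heavy)[1]] <- 5
  counts["D", which(in_t & heavy)[1]] <- 3               # T heavy + T light
  counts["D", which(in_t & light)[1]] <- 3
  tab <- make_table(counts, sm)
  expect_true(heavy_sip(tab, method = 1)$call[1])         # A called
  expect_false(heavy_sip(tab, method = 2)$call[2])        # B: control heavy
  expect_true(heavy_sip(tab, method = 1)$call[2])
  expect_false(heavy_sip(tab, method = 3)$call[4])        # D: light presence
  expect_false(any(heavy_sip(tab, method = 4)$call[c(2, 4)]))
  expect_false(heavy_sip(tab, method = 1)$call[3])        # all-zero taxon
  expect_error(heavy_sip(tab, heavy_window = c(1.80, 1.85)), "window")
})

test_that("HR-SIP: null table yields no calls; sparsity excludes rare taxa", {
  set.seed(5)
  sm <- even_samples(sprintf("%s%d", rep(c("T", "C"), each = 3), 1:3),
                     rep(c(TRUE, FALSE), each = 3))
  counts <- matrix(rnbinom(50 * nrow(sm), mu = 40, size = 5), 50,
                   dimnames = list(sprintf("t%02d", 1:50), sm$sample_id))
  tab <- make_table(counts, sm)
  res <- hr_sip(tab)
  expect_equal(sum(res$call), 0)
  # a taxon present in only 1 of 6 gradient samples fails the 0.25 cutoff
  counts2 <- counts; counts2[1, ] <- 0
  counts2[1, which(sm$gradient_id == "T1" & sm$bd_low == 1.72)] <- 50
  res2 <- hr_sip(make_table(counts2, sm))
  expect_false(res2$tested[1])
  expect_false(res2$call[1])
})

test_that("end-to-end: a fully labeled taxon is called by HR/MW-HR-SIP", {
  gcs <- seq(0.35, 0.62, length.out = 20)
  profs <- lapply(seq_along(gcs), function(i)
    toy_profile(gcs[i], seed = 100 + i, id = sprintf("t%02d", i)))
  names(profs) <- sprintf("t%02d", 1:20)
  truth <- structure(setNames(rep(0, 20), names(profs)),
                     class = "truth_table")
  truth["t10"] <- 100  # G+C 0.478 -> shifts into the heavy window
  sim <- simulate_sip_experiment(profs, truth, depth = 5000, sdlog = 1,
                                 seed = 31)
  expect_true(hr_sip(sim$table)$call[match("t10", rownames(sim$table$counts))])
  mw <- mw_hr_sip(sim$table)
  expect_true(mw$call[match("t10", mw$taxon)])
  # any-window rule: min padj and its window are reported for calls
  expect_false(any(is.na(mw$padj[mw$call])))
  expect_error(mw_hr_sip(sim$table, windows = list()), "window")
})

test_that("qSIP: weighted-BD arithmetic, calls, and conversion modes", {
  sm <- even_samples(c("T1", "C1"), c(TRUE, FALSE))
  counts <- matrix(0, 2, nrow(sm),
                   dimnames = list(c("a", "b"), sm$sample_id))
  counts["a", which(sm$treatment & abs(sm$bd_low - 1.74) < 1e-9)] <- 100
  counts["a", which(!sm$treatment & abs(sm$bd_low - 1.72) < 1e-9)] <- 100
  counts["b", which(abs(sm$bd_low - 1.70) < 1e-9)] <- c(50, 50)
  tab <- make_table(counts, sm)
  qp <- data.frame(sample_id = sm$sample_id, gradient_id = sm$gradient_id,
                   fraction_idx = sm$fraction_idx, copies = 1000)
  class(qp) <- c("qpcr_table", "data.frame")
  W <- sipbench:::qsip_weighted_bd(tab, qp)
  expect_equal(unname(W["a", "T1"]), 1.745)  # single-fraction mass -> midpoint
  expect_equal(unname(W["a", "C1"]), 1.725)
  res <- qsip(tab, qp, n_boot = 200, mode = "linear", seed = 1)
  i <- match(c("a", "b"), res$taxon)
  expect_equal(res$Z[i[1]], 0.02)
  expect_equal(res$atom_pct_est[i[1]], 100 * 0.02 / 0.036)
  # W equal in both arms: Z = 0, not called
  expect_equal(res$Z[i[2]], 0)
  expect_false(res$call[i[2]])
  # mw mode applies the molecular-weight calibration (lower estimate)
  res_mw <- qsip(tab, qp, n_boot = 200, mode = "mw", seed = 1)
  expect_lt(res_mw$atom_pct_est[i[1]], res$atom_pct_est[i[1]])
  expect_gt(res_mw$atom_pct_est[i[1]], 0)
})

test_that("qSIP is translation-consistent and flags one-arm taxa", {
  gcs <- rep(c(0.45, 0.50, 0.55), each = 4)
  profs <- lapply(seq_along(gcs), function(i)
    toy_profile(gcs[i], seed = 200 + i, id = sprintf("q%02d", i)))
  names(profs) <- sprintf("q%02d", seq_along(gcs))
  truth <- assign_incorporators(names(profs), 50, 50, seed = 41)
  sim <- simulate_sip_experiment(profs, truth, dbl = dbl_params(0, 0),
                                 pcr_cycles = 0, seed = 42)
  res <- qsip(sim$table, sim$qpcr, mode = "linear", n_boot = 300, seed = 43)
  lab <- names(which(unclass(sim$truth) > 0))
  est <- res$atom_pct_est[match(lab, res$taxon)]
  expect_lt(abs(mean(est) - 50), 10)
  expect_true(all(res$call[match(lab, res$taxon)]))
})

test_that("qSIP underestimates for left-skewed heavy distributions", {
  set.seed(7)
  span <- c(1.67, 1.78)
  mk <- function(centers, id)
    sipbench:::new_bd_profile(id, centers, bw = 5e-4, stage = "+DBL",
                              dbl_frac = 0, span = span)
  ctl <- mk(rnorm(4000, 1.710, 0.002), "s")
  shift <- 0.036
  skew <- 1.710 + shift - abs(rnorm(4000, 0, 0.004))  # left-skewed labeled
  trt <- mk(skew, "s")
  sch_t <- simulate_fractions(gradient_id = "T1", seed = 8)
  sch_c <- simulate_fractions(gradient_id = "C1", seed = 8)
  com <- structure(c(s = 1), class = "community")
  tabs <- list(build_otu_table(list(s = trt), com, sch_t, 1e8, seed = 9),
               build_otu_table(list(s = ctl), com, sch_c, 1e8, seed = 10))
  tab <- combine_otu_tables(tabs, c(TRUE, FALSE))
  qp <- simulate_qpcr(tab, seed = 11)
  tab$stage <- "post-sequencing"
  res <- qsip(tab, qp, mode = "linear", n_boot = 100, seed = 12)
  true_mode_shift <- shift
  expect_lt(res$atom_pct_est[1], 100 * true_mode_shift / 0.036)  # below 100
  expect_lt(res$atom_pct_est[1], 95)
})

test_that("delta-BD: null, translation, and an independent re-computation", {
  sm <- even_samples(c("T1", "C1"), c(TRUE, FALSE))
  set.seed(13)
  base <- rpois(nrow(sm) / 2, 300) + 1
  band <- c(0, 0, 0, 0, 200, 600, 200, 0, 0, 0, 0)
  counts <- matrix(c(base, base, band, band), 2, nrow(sm), byrow = TRUE,
                   dimnames = list(c("bg", "x"), sm$sample_id))
  tab <- make_table(counts, sm)
  res0 <- delta_bd(tab)
  expect_equal(res0$delta_bd, c(0, 0), tolerance = 1e-12)
  # one-fraction translation of the band taxon: CoM shift ~ one bin width
  counts2 <- counts
  tidx <- which(sm$treatment)
  counts2["x", tidx] <- c(band[-1], 0)  # move band one fraction heavier
  res1 <- delta_bd(make_table(counts2, sm))
  i <- match("x", res1$taxon)
  expect_gt(res1$delta_bd[i], 0)
  expect_equal(res1$delta_bd[i], 0.01, tolerance = 0.6)
  expect_lt(abs(res1$delta_bd[i] - 0.01), 0.006)
  # independent spreadsheet-style oracle on a random two-taxon table
  counts3 <- matrix(rpois(2 * nrow(sm), 200), 2,
                    dimnames = list(c("u", "v"), sm$sample_id))
  tab3 <- make_table(counts3, sm)
  res3 <- delta_bd(tab3, n_interp = 20)
  oracle_com <- function(g) {
    j <- which(sm$gradient_id == g)
    rel <- sweep(counts3[, j], 2, colSums(counts3[, j]), "/")
    mids <- (sm$bd_low[j] + sm$bd_high[j]) / 2
    ord <- order(mids)
    grid <- seq(min(sm$bd_low), max(sm$bd_high), length.out = 20)
    apply(rel, 1, function(y) {
      yi <- approx(mids[ord], y[ord], xout = grid, rule = 1)$y
      yi[is.na(yi)] <- 0
      sum(grid * yi) / sum(yi)
    })
  }
  expect_equal(res3$delta_bd, unname(oracle_com("T1") - oracle_com("C1")),
               tolerance = 1e-12)
  expect_equal(res3$atom_pct_est, res3$delta_bd * 100 / 0.036)
})
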