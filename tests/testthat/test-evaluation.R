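mk_result <- function(taxa, called) {
  sipbench:::new_detection_result("toy",
    data.frame(taxon = taxa, call = taxa %in% called,
               stringsAsFactors = FALSE))
}

test_that("confusion scoring arithmetic and edge cases", {
  taxa <- sprintf("t%03d", 1:100)
  truth <- structure(setNames(c(rep(50, 10), rep(0, 90)), taxa),
                     class = "truth_table")
  res <- mk_result(taxa, c(taxa[1:9], taxa[11:15]))  # 9 TP + 5 FP
  sc <- score(res, truth)
  expect_equal(sc$TP, 9); expect_equal(sc$FP, 5)
  expect_equal(sc$sensitivity, 0.9)
  expect_equal(sc$specificity, 85 / 90)
  expect_equal(sc$balanced_accuracy, (0.9 + 85 / 90) / 2)
  expect_equal(sc$precision, 9 / 14)
  expect_equal(score(res, truth, balanced = "product")$balanced_accuracy,
               0.9 * 85 / 90)
  # perfect detector
  perfect <- score(mk_result(taxa, taxa[1:10]), truth)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$balanced_accuracy, 1)
  # no calls: sens 0, spec 1, balanced 0.5; precision NA
  none <- score(mk_result(taxa, character()), truth)
  expect_equal(none$balanced_accuracy, 0.5)
  expect_true(is.na(none$precision))
  # zero truth positives: sensitivity NA
  truth0 <- structure(setNames(rep(0, 100), taxa), class = "truth_table")
  expect_true(is.na(score(mk_result(taxa, character()), truth0)$sensitivity))
  # mismatched universes error; permutation invariance
  expect_error(score(mk_result(taxa[1:99], character()), truth), "taxon")
  shuf <- mk_result(sample(taxa), c(taxa[1:9], taxa[11:15]))
  expect_equal(score(shuf, truth), sc)
})

test_that("estimation error aggregates match hand arithmetic", {
  taxa <- c("a", "b", "c")
  truth <- structure(setNames(c(100, 50, 0), taxa), class = "truth_table")
  est <- data.frame(taxon = taxa, atom_pct_est = c(65, 50, 3))
  ee <- estimation_error(est, truth)
  expect_equal(ee$per_taxon$error, c(-35, 0))
  expect_equal(ee$aggregate$mean_bias, -17.5)
  expect_equal(ee$aggregate$pct_underestimation, mean(c(35, 0)))
  exact <- estimation_error(data.frame(taxon = taxa,
                                       atom_pct_est = c(100, 50, 0)), truth)
  expect_equal(exact$aggregate$mean_bias, 0)
})

test_that("run_sweep: shape, determinism, NA sensitivity at 0 atom %", {
  gcs <- seq(0.40, 0.60, length.out = 12)
  profs <- lapply(seq_along(gcs), function(i)
    toy_profile(gcs[i], n_mc = 1000, seed = 300 + i,
                id = sprintf("s%02d", i)))
  names(profs) <- sprintf("s%02d", seq_along(gcs))
  grid <- data.frame(atom_pct = c(100, 0), pct_incorp = c(25, 0))
  sw <- run_sweep(profs, grid, methods = c("heavy1", "qsip"),
                  n_replicates = 2, depth = 2000, seed = 51)
  expect_null(sw$failures)
  expect_equal(nrow(sw$scores), 2 * 2 * 2)  # cells x replicates x methods
  z <- sw$scores[sw$scores$atom_pct == 0, ]
  expect_true(all(is.na(z$sensitivity)))
  expect_true(all(!is.na(z$specificity)))
  # bit-identical rerun under the same seed
  sw2 <- run_sweep(profs, grid, methods = c("heavy1", "qsip"),
                   n_replicates = 2, depth = 2000, seed = 51)
  expect_identical(sw$scores, sw2$scores)
  # streaming TSV output
  out <- tempfile(fileext = ".tsv")
  run_sweep(profs, grid[1, , drop = FALSE], methods = "heavy1",
            n_replicates = 1, depth = 2000, seed = 52, out = out)
  expect_true(file.exists(out))
  expect_equal(nrow(read.delim(out)), 1)
})

test_that("summarize_sweep aggregates by cell and method", {
  gcs <- c(0.45, 0.5, 0.55, 0.6)
  profs <- lapply(seq_along(gcs), function(i)
    toy_profile(gcs[i], n_mc = 1000, seed = 400 + i, id = paste0("m", i)))
  names(profs) <- paste0("m", seq_along(gcs))
  grid <- data.frame(atom_pct = c(100, 50))
  sw <- run_sweep(profs, grid, methods = "heavy1", n_replicates = 2,
                  depth = 1000, pct_incorp = 25, seed = 53)
  sm <- summarize_sweep(sw)
  expect_equal(nrow(sm), 2)
  expect_true(all(c("specificity", "sensitivity", "balanced_accuracy",
                    "sensitivity_sd") %in% names(sm)))
})
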