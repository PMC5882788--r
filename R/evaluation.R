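# Accuracy scoring against simulation truth and orchestration of parameter
# sweeps over (atom % excess, incorporator fraction, sequencing depth,
# beta-diversity, ...) grids.

#' Score a detection result against simulation truth
#'
#' @param result a `detection_result` (logical `call` per taxon; NA counts
#'   as not called).
#' @param truth a `truth_table` over the same taxa (atom % excess; > 0 =
#'   true incorporator).
#' @param balanced `"mean"` (the standard definition,
#'   `(specificity + sensitivity)/2`, default) or `"product"`.
#' @return a one-row data.frame of class `confusion_summary`: `TP`, `FP`,
#'   `TN`, `FN`, `specificity`, `sensitivity`, `balanced_accuracy`,
#'   `precision`.  Sensitivity is NA when there are no true positives,
#'   precision NA when nothing is called.
#' @export
#' @examples
#' truth <- structure(c(a = 50, b = 0, c = 0), class = "truth_table")
#' res <- structure(data.frame(taxon = c("a", "b", "c"),
#'                             call = c(TRUE, TRUE, FALSE)),
#'                  class = c("detection_result", "data.frame"))
#' score(res, truth)
score <- function(result, truth, balanced = c("mean", "product")) {
  balanced <- match.arg(balanced)
  if (!setequal(result$taxon, names(truth)))
    stop("taxon sets of result and truth differ", call. = FALSE)
  call <- result$call[match(names(truth), result$taxon)]
  call[is.na(call)] <- FALSE
  lab <- unclass(truth) > 0
  TP <- sum(call & lab); FP <- sum(call & !lab)
  TN <- sum(!call & !lab); FN <- sum(!call & lab)
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  bal <- if (balanced == "mean") mean(c(spec, sens)) else spec * sens
  prec <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  out <- data.frame(TP = TP, FP = FP, TN = TN, FN = FN,
                    specificity = spec, sensitivity = sens,
                    balanced_accuracy = bal, precision = prec)
  class(out) <- c("confusion_summary", "data.frame")
  out
}

#' Error of atom-%-excess estimates against truth
#'
#' @param est data.frame with `taxon` and `atom_pct_est` (from [qsip()] or
#'   [delta_bd()]).
#' @param truth a `truth_table`.
#' @param labeled_only restrict to truly labeled taxa (default TRUE; the
#'   percent-underestimation aggregate is only defined for them).
#' @return list: `per_taxon` (taxon, truth, estimate, error) and
#'   `aggregate` (mean bias, sd of error, mean percent underestimation
#'   `100 * (truth - est) / truth` over labeled taxa).
#' @export
estimation_error <- function(est, truth, labeled_only = TRUE) {
  common <- intersect(est$taxon, names(truth))
  tr <- unclass(truth)[common]
  e <- est$atom_pct_est[match(common, est$taxon)]
  if (labeled_only) {
    keep <- tr > 0
    tr <- tr[keep]; e <- e[keep]; common <- common[keep]
  }
  err <- e - tr
  pct_under <- ifelse(tr > 0, 100 * (tr - e) / tr, NA_real_)
  list(per_taxon = data.frame(taxon = common, truth = tr, estimate = e,
                              error = err, row.names = NULL,
                              stringsAsFactors = FALSE),
       aggregate = data.frame(mean_bias = mean(err, na.rm = TRUE),
                              sd_error = stats::sd(err[!is.na(err)]),
                              pct_underestimation =
                                mean(pct_under, na.rm = TRUE)))
}

.sweep_methods <- c("heavy1", "heavy2", "heavy3", "heavy4",
                    "hrsip", "mwhrsip", "qsip", "deltabd")

run_detector <- function(method, sim, heavy_window = c(1.71, 1.75),
                         light_window = c(1.68, 1.70), isotope,
                         qsip_seed = NULL) {
  switch(method,
    heavy1 = heavy_sip(sim$table, heavy_window, light_window, method = 1),
    heavy2 = heavy_sip(sim$table, heavy_window, light_window, method = 2),
    heavy3 = heavy_sip(sim$table, heavy_window, light_window, method = 3),
    heavy4 = heavy_sip(sim$table, heavy_window, light_window, method = 4),
    hrsip = hr_sip(sim$table),
    mwhrsip = mw_hr_sip(sim$table),
    qsip = qsip(sim$table, sim$qpcr, isotope = isotope, seed = qsip_seed),
    deltabd = delta_bd(sim$table, isotope = isotope),
    stop("unknown method '", method, "'", call. = FALSE))
}

#' Run a parameter sweep of simulated DNA-SIP experiments
#'
#' For every grid cell and replicate: a fresh truth assignment, a full
#' Stage 1-3 simulation (`n_treatment` + `n_control` gradients), every
#' requested detector, and confusion scoring.  Grid columns beyond the
#' recognized ones are passed through to the output unchanged.
#'
#' @param profiles named list of equilibrium `bd_profile`s (the taxon
#'   universe of the sweep).
#' @param grid data.frame; recognized columns (all optional, defaults in
#'   parentheses): `atom_pct` (100), `pct_incorp` (10), `depth` (1e4),
#'   `pct_shared` (100), `pct_permuted` (0), `frac_mean` (0.004).
#' @param methods subset of `r paste0('"', .sweep_methods, '"', collapse = ", ")`.
#' @param n_replicates replicate simulations per cell (fresh incorporator
#'   draw each).
#' @param isotope an [isotope_spec()].
#' @param spare_profiles extra profiles for replicate-private taxa (only
#'   needed when the grid lowers `pct_shared`).
#' @param keep_estimates also collect per-taxon atom-%% estimates from
#'   qSIP / delta-BD cells.
#' @param out optional path: results are appended to this TSV as they are
#'   produced.
#' @param seed run-level seed; each (cell, replicate) derives its own.
#' @param ... further arguments to [simulate_sip_experiment()] (e.g.
#'   `total_fragments`, `dbl`, `meanlog`).
#' @return list of class `sweep_result`: `scores` (one row per cell x
#'   replicate x method, with confusion counts, specificity, sensitivity,
#'   balanced accuracy under both definitions, precision) and `estimates`
#'   (per-taxon atom-%% estimates, if requested).  Cell failures are
#'   recorded in `failures` and the sweep continues.
#' @export
run_sweep <- function(profiles, grid, methods = c("mwhrsip", "qsip"),
                      n_replicates = 3, isotope = isotope_spec("13C"),
                      spare_profiles = NULL, keep_estimates = FALSE,
                      out = NULL, seed = NULL, ...) {
  stopifnot(all(methods %in% .sweep_methods), nrow(grid) >= 1)
  taxa <- names(profiles)
  defaults <- list(atom_pct = 100, pct_incorp = 10, depth = 1e4,
                   pct_shared = 100, pct_permuted = 0, frac_mean = 0.004)
  dots <- list(...)
  # scalar overrides of cell defaults may also arrive via `...`
  for (k in intersect(names(defaults), names(dots))) {
    if (!k %in% names(grid)) defaults[[k]] <- dots[[k]]
    dots[[k]] <- NULL
  }
  rows <- list(); ests <- list(); fails <- list()
  for (ci in seq_len(nrow(grid))) {
    cell <- as.list(grid[ci, , drop = FALSE])
    for (k in names(defaults))
      if (is.null(cell[[k]])) cell[[k]] <- defaults[[k]]
    for (rep_i in seq_len(n_replicates)) {
      cell_seed <- derive_seed(seed, sprintf("cell%03d_rep%02d", ci, rep_i))
      res <- try({
        truth <- assign_incorporators(taxa, cell$pct_incorp, cell$atom_pct,
                                      seed = derive_seed(cell_seed, "truth"))
        sim <- do.call(simulate_sip_experiment, c(list(
          profiles, truth, isotope = isotope,
          pct_shared = cell$pct_shared, pct_permuted = cell$pct_permuted,
          spare_profiles = spare_profiles, frac_mean = cell$frac_mean,
          depth = cell$depth, seed = cell_seed), dots))
        for (m in methods) {
          det <- run_detector(m, sim, isotope = isotope,
                              qsip_seed = derive_seed(cell_seed, m))
          sc_mean <- score(det, sim$truth, balanced = "mean")
          sc_prod <- score(det, sim$truth, balanced = "product")
          row <- cbind(grid[ci, , drop = FALSE],
                       data.frame(replicate = rep_i, method = m), sc_mean)
          row$balanced_accuracy_product <- sc_prod$balanced_accuracy
          rownames(row) <- NULL
          rows[[length(rows) + 1L]] <- row
          if (!is.null(out))
            utils::write.table(row, out, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = file.exists(out),
                               col.names = !file.exists(out))
          if (keep_estimates && m %in% c("qsip", "deltabd")) {
            ee <- estimation_error(det, sim$truth)$per_taxon
            if (nrow(ee)) {
              ee$method <- m; ee$cell <- ci; ee$replicate <- rep_i
              ee$atom_pct <- cell$atom_pct
              ests[[length(ests) + 1L]] <- ee
            }
          }
        }
        NULL
      }, silent = TRUE)
      if (inherits(res, "try-error"))
        fails[[length(fails) + 1L]] <-
          data.frame(cell = ci, replicate = rep_i,
                     error = conditionMessage(attr(res, "condition")))
    }
  }
  structure(list(scores = do.call(rbind, rows),
                 estimates = if (length(ests)) do.call(rbind, ests),
                 failures = if (length(fails)) do.call(rbind, fails)),
            class = "sweep_result")
}

#' Summarize a sweep: per-cell, per-method means and SDs
#' @param x a `sweep_result`.
#' @param by grouping columns (default the grid columns present).
#' @return data.frame of means/SDs of specificity, sensitivity and
#'   balanced accuracy per group.
#' @export
summarize_sweep <- function(x, by = intersect(c("atom_pct", "pct_incorp",
                                                "depth", "pct_shared",
                                                "pct_permuted", "frac_mean",
                                                "method"),
                                              names(x$scores))) {
  sc <- x$scores
  agg <- function(col, f) stats::aggregate(sc[[col]], sc[by], f,
                                           simplify = TRUE)
  out <- agg("specificity", function(v) mean(v, na.rm = TRUE))
  names(out)[ncol(out)] <- "specificity"
  for (col in c("sensitivity", "balanced_accuracy")) {
    out[[col]] <- agg(col, function(v) mean(v, na.rm = TRUE))$x
    out[[paste0(col, "_sd")]] <- agg(col, function(v)
      stats::sd(v[!is.na(v)]))$x
  }
  out
}
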