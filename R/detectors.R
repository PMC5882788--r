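# The five DNA-SIP incorporator-detection / quantification methods.  All
# operate on a combined `otu_table` (plus a `qpcr_table` for qSIP) whose
# samples carry a logical `treatment` flag.

new_detection_result <- function(method, df) {
  stopifnot(!anyDuplicated(df$taxon))
  attr(df, "method") <- method
  class(df) <- c("detection_result", "data.frame")
  df
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %s: %d / %d taxa called incorporators\n",
              attr(x, "method"), sum(x$call, na.rm = TRUE), nrow(x)))
  invisible(x)
}

# Sample indices whose fraction interval intersects an open BD window.
window_samples <- function(table, window, arm = NULL) {
  s <- table$samples
  hit <- s$bd_high > window[1] & s$bd_low < window[2]
  if (!is.null(arm)) hit <- hit & (s$treatment == arm)
  which(hit)
}

check_table_arms <- function(table, need_control = TRUE) {
  if (is.null(table$samples$treatment))
    stop("otu_table lacks a 'treatment' flag; combine gradients with ",
         "combine_otu_tables()", call. = FALSE)
  if (!any(table$samples$treatment))
    stop("no treatment gradients in table", call. = FALSE)
  if (need_control && !any(!table$samples$treatment))
    stop("method requires >= 1 unlabeled control gradient", call. = FALSE)
}

#' Heavy-SIP: presence/absence in heavy (and light) fractions
#'
#' The classic family of presence-based rules.  "Presence" means a count
#' greater than zero in at least one fraction whose BD interval intersects
#' the window.
#' \itemize{
#'   \item Method 1: present in heavy fractions of the labeled treatment.
#'   \item Method 2: Method 1 AND absent from heavy fractions of the
#'     control.
#'   \item Method 3: Method 1 AND absent from light fractions of the
#'     treatment.
#'   \item Method 4: Methods 2 and 3 combined.
#' }
#'
#' @param table a combined `otu_table` (post-sequencing).
#' @param heavy_window BD window of "heavy" fractions (default
#'   1.71-1.75 g ml^-1).
#' @param light_window BD window of "light" fractions (default
#'   1.68-1.70 g ml^-1; used by methods 3 and 4).
#' @param method 1, 2, 3 or 4.
#' @return a `detection_result` with per-taxon logical `call`.
#' @export
heavy_sip <- function(table, heavy_window = c(1.71, 1.75),
                      light_window = c(1.68, 1.70), method = 1) {
  stopifnot(method %in% 1:4)
  check_table_arms(table, need_control = method %in% c(2, 4))
  th <- window_samples(table, heavy_window, arm = TRUE)
  if (!length(th))
    stop("heavy window intersects no treatment fraction", call. = FALSE)
  present <- function(idx)
    if (length(idx)) rowSums(table$counts[, idx, drop = FALSE] > 0) > 0
    else rep(FALSE, nrow(table$counts))
  call <- present(th)
  if (method %in% c(2, 4))
    call <- call & !present(window_samples(table, heavy_window, arm = FALSE))
  if (method %in% c(3, 4))
    call <- call & !present(window_samples(table, light_window, arm = TRUE))
  new_detection_result(paste0("heavy-sip-m", method),
                       data.frame(taxon = rownames(table$counts),
                                  call = unname(call),
                                  stringsAsFactors = FALSE))
}

# Shared HR-SIP core for a single BD window: sparsity filter then the NB
# Wald test.  With collapse = "gradient" (default) each gradient's window
# fractions are summed into one sample per gradient, so the test compares
# n_treatment vs n_control window totals; collapse = "fraction" treats
# every window fraction as its own sample.  The gradient unit is the
# default because a cleanly shifted incorporator is absent from every
# control window fraction, which under the fraction unit caps its
# prevalence near band-width/window-width/2 and lets the sparsity filter
# discard exactly the strongest true positives.
hr_sip_window <- function(table, window, sparsity, l2fc_null,
                          collapse = c("gradient", "fraction")) {
  collapse <- match.arg(collapse)
  idx_t <- window_samples(table, window, arm = TRUE)
  idx_c <- window_samples(table, window, arm = FALSE)
  if (!length(idx_t) || !length(idx_c))
    stop("BD window [", window[1], ", ", window[2],
         "] intersects no fraction in one arm", call. = FALSE)
  get_counts <- function(idx) {
    m <- table$counts[, idx, drop = FALSE]
    if (collapse == "fraction") return(m)
    s <- table$samples[idx, ]
    # weight edge fractions by their overlap with the window, so window
    # composition does not depend on how fraction boundaries happen to
    # straddle the window edges in each gradient
    ov <- (pmin(s$bd_high, window[2]) - pmax(s$bd_low, window[1])) /
      (s$bd_high - s$bd_low)
    m <- sweep(m, 2, ov, "*")
    g <- s$gradient_id
    round(vapply(unique(g), function(gg)
      rowSums(m[, g == gg, drop = FALSE]), numeric(nrow(m))))
  }
  ct <- get_counts(idx_t); cc <- get_counts(idx_c)
  prevalence <- rowMeans(cbind(ct, cc) > 0)
  tested <- prevalence > sparsity
  res <- data.frame(taxon = rownames(table$counts), tested = tested,
                    log2fc = NA_real_, p = NA_real_, padj = NA_real_,
                    stringsAsFactors = FALSE)
  if (any(tested)) {
    nb <- nb_differential_test(ct[tested, , drop = FALSE],
                               cc[tested, , drop = FALSE],
                               l2fc_null = l2fc_null)
    res$log2fc[tested] <- nb$log2fc
    res$p[tested] <- nb$p
    res$padj[tested] <- stats::p.adjust(nb$p, method = "BH")
  }
  res
}

#' HR-SIP: differential abundance in one heavy BD window
#'
#' Counts in fractions intersecting the heavy window form the samples — by
#' default one summed sample per gradient (edge fractions weighted by
#' window overlap), optionally every window fraction separately.  Taxa
#' present in no more than `sparsity` of those samples are excluded; the
#' remaining taxa are tested for treatment enrichment with the one-sided
#' negative-binomial Wald test ([nb_differential_test()]),
#' Benjamini-Hochberg corrected, and called incorporators at
#' `padj < fdr`.
#'
#' @param table a combined `otu_table` (post-sequencing).
#' @param window heavy BD window (default 1.71-1.75 g ml^-1).
#' @param sparsity prevalence cutoff: taxa must be present in more than
#'   this fraction of window samples (default 0.25).
#' @param l2fc_null log2-fold-change null threshold (default 0.25).
#' @param fdr adjusted-p cutoff (default 0.10).
#' @param collapse sample unit for the test: `"gradient"` (window
#'   fractions summed per gradient; default) or `"fraction"`.
#' @return a `detection_result` with `call`, `log2fc`, `p`, `padj`.
#' @export
hr_sip <- function(table, window = c(1.71, 1.75), sparsity = 0.25,
                   l2fc_null = 0.25, fdr = 0.10,
                   collapse = c("gradient", "fraction")) {
  check_table_arms(table)
  res <- hr_sip_window(table, window, sparsity, l2fc_null, collapse)
  res$call <- !is.na(res$padj) & res$padj < fdr
  new_detection_result("hr-sip", res)
}

#' MW-HR-SIP: HR-SIP over multiple overlapping heavy windows
#'
#' Runs the HR-SIP procedure independently in each window (BH correction
#' within each window); a taxon is called an incorporator when its
#' adjusted p-value is below `fdr` in at least one window.  The minimum
#' adjusted p and the window achieving it are reported.  A `global_bh`
#' mode pools the per-window raw p-values into a single BH correction.
#'
#' @param table a combined `otu_table` (post-sequencing).
#' @param windows list of BD windows (default 1.70-1.73, 1.72-1.75,
#'   1.74-1.77 g ml^-1).
#' @param sparsity,l2fc_null,fdr,collapse as in [hr_sip()].
#' @param global_bh use one BH correction across all windows instead of
#'   per-window correction (default FALSE).
#' @return a `detection_result` with `call`, `padj` (minimum over
#'   windows), `window` (achieving window, "lo-hi").
#' @export
mw_hr_sip <- function(table,
                      windows = list(c(1.70, 1.73), c(1.72, 1.75),
                                     c(1.74, 1.77)),
                      sparsity = 0.25, l2fc_null = 0.25, fdr = 0.10,
                      collapse = c("gradient", "fraction"),
                      global_bh = FALSE) {
  if (!length(windows)) stop("empty window list", call. = FALSE)
  check_table_arms(table)
  per <- lapply(windows, function(w)
    hr_sip_window(table, w, sparsity, l2fc_null, collapse))
  pmat <- vapply(per, `[[`, numeric(nrow(per[[1]])), "p")
  pmat <- matrix(pmat, nrow = nrow(per[[1]]))
  if (global_bh) {
    padjmat <- matrix(stats::p.adjust(pmat, method = "BH"), nrow = nrow(pmat))
  } else {
    padjmat <- vapply(per, `[[`, numeric(nrow(per[[1]])), "padj")
    padjmat <- matrix(padjmat, nrow = nrow(pmat))
  }
  min_padj <- suppressWarnings(apply(padjmat, 1, min, na.rm = TRUE))
  min_padj[!is.finite(min_padj)] <- NA_real_
  which_w <- apply(padjmat, 1, function(r)
    if (all(is.na(r))) NA_integer_ else which.min(r))
  wname <- vapply(windows, function(w) paste(w, collapse = "-"), "")
  res <- data.frame(taxon = per[[1]]$taxon,
                    call = !is.na(min_padj) & min_padj < fdr,
                    padj = min_padj,
                    window = ifelse(is.na(which_w), NA_character_,
                                    wname[which_w]),
                    stringsAsFactors = FALSE)
  new_detection_result("mw-hr-sip", res)
}

# ---- qSIP ----------------------------------------------------------------

# Per-gradient qPCR-scaled weighted-average BD for every taxon.
# Returns taxa x gradients matrix (NA where a taxon has no copies).
qsip_weighted_bd <- function(table, qpcr) {
  s <- table$samples
  stopifnot(identical(s$sample_id, qpcr$sample_id))
  rel <- sweep(table$counts, 2, pmax(colSums(table$counts), 1), "/")
  copies <- sweep(rel, 2, qpcr$copies, "*")
  mids <- (s$bd_low + s$bd_high) / 2
  grads <- unique(s$gradient_id)
  W <- vapply(grads, function(g) {
    j <- which(s$gradient_id == g)
    num <- copies[, j, drop = FALSE] %*% mids[j]
    den <- rowSums(copies[, j, drop = FALSE])
    ifelse(den > 0, num / den, NA_real_)
  }, numeric(nrow(table$counts)))
  W <- matrix(W, nrow = nrow(table$counts),
              dimnames = list(rownames(table$counts), grads))
  W
}

# Atom % excess from observed light/labeled weighted BD, following the
# molecular-weight formulation of the original qSIP method: infer G+C from
# the light-arm BD, convert both arms to average molecular weights, and
# scale by the maximum mass gain at full labeling (natural-abundance
# corrected).
qsip_atom_pct <- function(W_light, Z, isotope) {
  gc <- pmin(pmax((W_light - 1.646057) / 0.083506, 0), 1)
  M_light <- 0.496 * gc + 307.691
  M_lab <- (W_light + Z) / W_light * M_light
  if (isotope$isotope == "15N") {
    dM_max <- 0.5024851 * gc + 3.517396
    nat <- 0.003663
  } else {  # 13C and 13C-like custom isotopes
    dM_max <- 9.974564 - 0.4987282 * gc
    nat <- 0.01111233
  }
  100 * (M_lab - M_light) / dM_max * (1 - nat)
}

#' qSIP: quantitative SIP from qPCR-scaled BD shifts
#'
#' Per fraction, absolute taxon copy numbers are relative abundances
#' scaled by the fraction's total qPCR copy number.  Per gradient, each
#' taxon's abundance-weighted mean BD is computed; the BD shift `Z` is the
#' difference of arm means (treatment minus control).  Bootstrap
#' confidence intervals are obtained by resampling gradients with
#' replacement within each arm; a taxon is called an incorporator when
#' the lower CI bound of `Z` exceeds zero.  Atom % excess is estimated
#' from `Z` either via the G+C-dependent molecular-weight formulation of
#' the original qSIP method (`mode = "mw"`, default) or by direct linear
#' inversion of the isotope shift model (`mode = "linear"`,
#' `100 * Z / I_max`).
#'
#' @param table a combined `otu_table` (post-sequencing).
#' @param qpcr a `qpcr_table` covering every fraction of `table`.
#' @param isotope an [isotope_spec()].
#' @param n_boot bootstrap replicates (default 1000).
#' @param ci confidence level (default 0.90).
#' @param mode atom %% conversion: `"mw"` or `"linear"`.
#' @param require_detection gradient-presence a taxon needs before it is
#'   eligible for an incorporator call: `"treatment"` (reads in every
#'   labeled gradient; default — a replicated design cannot support a
#'   shift claim whose treatment arm has missing replicates),
#'   `"all"` (every gradient of both arms), or `"none"`.  Estimates are
#'   reported regardless, as arm means over the gradients that have data.
#' @param seed integer seed for the bootstrap.
#' @return a `detection_result` with `call`, `Z` (BD shift, g ml^-1),
#'   `ci_low`, `ci_high` (CI of `Z`), and `atom_pct_est`.  Taxa absent
#'   from an arm get `call = FALSE` and NA estimates (`flagged = TRUE`).
#' @export
qsip <- function(table, qpcr, isotope = isotope_spec("13C"), n_boot = 1000,
                 ci = 0.90, mode = c("mw", "linear"),
                 require_detection = c("treatment", "all", "none"),
                 seed = NULL) {
  mode <- match.arg(mode)
  require_detection <- match.arg(require_detection)
  check_table_arms(table)
  W <- qsip_weighted_bd(table, qpcr)
  s <- table$samples
  arm_of <- vapply(colnames(W), function(g)
    s$treatment[match(g, s$gradient_id)], logical(1))
  Wt <- W[, arm_of, drop = FALSE]
  Wc <- W[, !arm_of, drop = FALSE]
  Z <- rowMeans(Wt, na.rm = TRUE) - rowMeans(Wc, na.rm = TRUE)
  W_light <- rowMeans(Wc, na.rm = TRUE)
  boot <- with_seed(seed, {
    nt <- ncol(Wt); nc <- ncol(Wc)
    vapply(seq_len(n_boot), function(b) {
      it <- sample.int(nt, nt, replace = TRUE)
      ic <- sample.int(nc, nc, replace = TRUE)
      rowMeans(Wt[, it, drop = FALSE], na.rm = TRUE) -
        rowMeans(Wc[, ic, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(W)))
  })
  boot <- matrix(boot, nrow = nrow(W))
  a <- (1 - ci) / 2
  qs <- t(apply(boot, 1, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE))
  flagged <- !is.finite(Z)
  est <- ifelse(flagged, NA_real_,
                if (mode == "mw") qsip_atom_pct(W_light, Z, isotope)
                else 100 * Z / isotope$I_max)
  callable <- switch(require_detection,
    treatment = rowSums(is.na(Wt)) == 0,
    all = rowSums(is.na(W)) == 0,
    none = !flagged)
  res <- data.frame(taxon = rownames(table$counts),
                    call = callable & !flagged & is.finite(qs[, 1]) &
                      qs[, 1] > 0,
                    Z = ifelse(flagged, NA_real_, Z),
                    ci_low = qs[, 1], ci_high = qs[, 2],
                    atom_pct_est = est, flagged = flagged,
                    row.names = NULL, stringsAsFactors = FALSE)
  new_detection_result("qsip", res)
}

# ---- delta-BD ------------------------------------------------------------

#' Delta-BD: center-of-mass shift of relative-abundance profiles
#'
#' Per gradient, a taxon's within-fraction relative abundances are linearly
#' interpolated onto `n_interp` evenly spaced BD points spanning the
#' gradient, renormalized, and reduced to a center of mass.  Delta-BD is
#' the mean treatment center of mass minus the mean control center of
#' mass; atom % excess is the linear inversion `100 * dBD / I_max`.
#'
#' @param table a combined `otu_table` (post-sequencing).
#' @param n_interp number of interpolation points (default 20).
#' @param isotope an [isotope_spec()].
#' @return a `detection_result`-like data.frame with `delta_bd` and
#'   `atom_pct_est` (no incorporator call; this is a quantification
#'   method).  Taxa with no reads in an arm get NA.
#' @export
delta_bd <- function(table, n_interp = 20, isotope = isotope_spec("13C")) {
  check_table_arms(table)
  s <- table$samples
  rel <- sweep(table$counts, 2, pmax(colSums(table$counts), 1), "/")
  mids <- (s$bd_low + s$bd_high) / 2
  grads <- unique(s$gradient_id)
  grid_lo <- min(s$bd_low); grid_hi <- max(s$bd_high)
  grid <- seq(grid_lo, grid_hi, length.out = n_interp)
  com <- vapply(grads, function(g) {
    j <- which(s$gradient_id == g)
    ord <- j[order(mids[j])]
    apply(rel[, ord, drop = FALSE], 1, function(y) {
      if (all(y == 0)) return(NA_real_)
      yi <- stats::approx(mids[ord], y, xout = grid, rule = 1)$y
      yi[is.na(yi)] <- 0
      if (sum(yi) == 0) return(NA_real_)
      sum(grid * yi) / sum(yi)
    })
  }, numeric(nrow(rel)))
  com <- matrix(com, nrow = nrow(rel))
  arm_of <- vapply(grads, function(g)
    s$treatment[match(g, s$gradient_id)], logical(1))
  dbd <- rowMeans(com[, arm_of, drop = FALSE], na.rm = TRUE) -
    rowMeans(com[, !arm_of, drop = FALSE], na.rm = TRUE)
  dbd[!is.finite(dbd)] <- NA_real_
  res <- data.frame(taxon = rownames(table$counts),
                    call = NA, delta_bd = dbd,
                    atom_pct_est = 100 * dbd / isotope$I_max,
                    row.names = NULL, stringsAsFactors = FALSE)
  new_detection_result("delta-bd", res)
}
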