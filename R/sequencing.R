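# Stage 3: sampling fragments into gradient fractions, PCR amplification
# bias, sequencing subsampling, and qPCR totals.

new_otu_table <- function(counts, samples, stage) {
  stopifnot(is.matrix(counts), nrow(samples) == ncol(counts))
  colnames(counts) <- samples$sample_id
  structure(list(counts = counts, samples = samples, stage = stage),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> [%s] %d taxa x %d fraction-samples (%d gradients)\n",
              x$stage, nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$gradient_id))))
  invisible(x)
}

# Per-fraction probability masses of a profile for one gradient's
# contiguous fraction scheme.  Exploits the shared boundaries so each
# boundary's Gaussian CDF is evaluated once.
fraction_masses <- function(profile, scheme) {
  bounds <- c(scheme$bd_high[1], scheme$bd_low)  # descending, heavy -> light
  c0 <- profile$centers + profile$shift
  cdf <- colMeans(matrix(
    stats::pnorm(outer(c0, bounds, function(ct, b) (b - ct) / profile$bw)),
    nrow = length(c0)))
  kde_mass <- cdf[-length(cdf)] - cdf[-1]        # mass per [low, high)
  D <- profile$dbl_frac
  w <- profile$span[2] - profile$span[1]
  ov <- pmax(pmin(scheme$bd_high, profile$span[2]) -
               pmax(scheme$bd_low, profile$span[1]), 0)
  (1 - D) * kde_mass + D * ov / w
}

#' Build the fragment-count OTU table for one gradient
#'
#' Taxon `t` contributes `total_fragments * abundance_t` fragments whose BD
#' values follow `t`'s (DBL- and incorporation-adjusted) profile; fragments
#' are binned into the gradient's fractions and fragments falling outside
#' the fractionated span are dropped.  For `total_fragments >=
#' poisson_threshold` each (taxon, fraction) count is drawn Poisson with
#' the cell's expected value (identical expectation, far faster); below it
#' an exact multinomial per taxon is used.
#'
#' @param profiles named list of `bd_profile` objects (stage `"+DBL"` or
#'   later), keyed by taxon id; must cover all community taxa.
#' @param community a `community` vector (relative abundances, sum 1).
#' @param scheme a `fraction_scheme` for a single gradient.
#' @param total_fragments total gDNA fragments in the gradient
#'   (default 1e9).
#' @param poisson_threshold switch-over to the Poisson approximation.
#' @param seed integer seed.
#' @return an `otu_table` with stage `"fragments"` (one gradient).
#' @export
build_otu_table <- function(profiles, community, scheme,
                            total_fragments = 1e9,
                            poisson_threshold = 1e7, seed = NULL) {
  taxa <- names(community)
  missing <- setdiff(taxa, names(profiles))
  if (length(missing))
    stop("no BD profile for taxon: ", paste(missing, collapse = ", "),
         call. = FALSE)
  nf <- nrow(scheme)
  mass <- vapply(taxa, function(t) fraction_masses(profiles[[t]], scheme),
                 numeric(nf))
  # mass: nf x taxa; expected fragments per cell
  lambda <- t(mass) * (total_fragments * as.numeric(community))
  counts <- with_seed(seed, {
    if (total_fragments >= poisson_threshold) {
      matrix(stats::rpois(length(lambda), lambda), nrow = length(taxa))
    } else {
      t(vapply(seq_along(taxa), function(i) {
        n_t <- round(total_fragments * community[i])
        if (n_t == 0) return(integer(nf))
        p <- c(mass[, i], max(1 - sum(mass[, i]), 0))  # last = out-of-span
        stats::rmultinom(1, n_t, p)[seq_len(nf), 1]
      }, integer(nf)))
    }
  })
  rownames(counts) <- taxa
  samples <- data.frame(
    sample_id = sprintf("%s_f%02d", scheme$gradient_id, scheme$fraction_idx),
    gradient_id = scheme$gradient_id, fraction_idx = scheme$fraction_idx,
    bd_low = scheme$bd_low, bd_high = scheme$bd_high,
    stringsAsFactors = FALSE)
  new_otu_table(counts, samples, "fragments")
}

#' Combine per-gradient OTU tables and tag treatment arms
#'
#' @param tables list of single-gradient `otu_table`s (same stage).
#' @param treatment logical vector, one entry per table: is the gradient an
#'   isotope-labeled treatment?
#' @return a combined `otu_table`; taxa are the union (absent = 0 counts).
#' @export
combine_otu_tables <- function(tables, treatment) {
  stopifnot(length(tables) == length(treatment))
  taxa <- unique(unlist(lapply(tables, function(x) rownames(x$counts))))
  counts <- do.call(cbind, lapply(tables, function(x) {
    m <- matrix(0, length(taxa), ncol(x$counts),
                dimnames = list(taxa, colnames(x$counts)))
    m[rownames(x$counts), ] <- x$counts
    m
  }))
  samples <- do.call(rbind, lapply(seq_along(tables), function(i) {
    s <- tables[[i]]$samples
    s$treatment <- treatment[i]
    s
  }))
  new_otu_table(counts, samples, tables[[1]]$stage)
}

#' Apply PCR amplification-efficiency bias
#'
#' Kinetic model of amplification in which a template's per-cycle
#' efficiency declines as its own product accumulates (re-annealing of
#' single-stranded product competes with priming):
#' `e = e_max * K / (K + P)` with `P` the taxon's product copy number in
#' the fraction.  Abundant templates saturate first, compressing
#' abundance ratios toward 1:1.  The default update is the deterministic
#' expected-value recurrence.
#'
#' @param table an `otu_table` at stage `"fragments"`.
#' @param cycles number of PCR cycles (default 30).
#' @param e_max maximum per-cycle efficiency (default 0.95).
#' @param K half-saturation product copy number for the per-template
#'   re-annealing term (default 6e10; the most abundant template species
#'   reach it shortly before the reaction plateau, as in the kinetic
#'   model's calibration experiments).
#' @param total_max reaction plateau: once a fraction's total product
#'   reaches this copy number (primer/dNTP exhaustion) amplification stops
#'   for all templates of that fraction.  The default 2.3e11 makes
#'   saturation begin near cycle 20 for the default template loading
#'   (~3.7e5 molecules).
#' @param template_frac fraction of each gradient fraction's DNA loaded
#'   into the reaction (default 0.01, e.g. 1 ul of a 100 ul fraction).
#'   Template molecule counts are Poisson-subsampled accordingly, so taxa
#'   rarer than ~1 molecule per reaction drop out — the stochastic
#'   template-limitation real amplicon workflows exhibit.  `NULL` skips
#'   subsampling (deterministic expected-value update on the full
#'   fraction).
#' @param seed integer seed (template subsampling only).
#' @return an `otu_table` with stage `"post-PCR"` (real-valued template
#'   proportions; interpret per-fraction columns relatively).
#' @export
apply_pcr_bias <- function(table, cycles = 30, e_max = 0.95, K = 6e10,
                           total_max = 2.3e11, template_frac = 0.01,
                           seed = NULL) {
  if (table$stage != "fragments")
    stop("PCR bias must be applied to a fragment-stage table", call. = FALSE)
  P <- table$counts
  if (!is.null(template_frac)) {
    stopifnot(template_frac > 0, template_frac <= 1)
    P <- with_seed(seed, {
      matrix(stats::rpois(length(P), P * template_frac), nrow = nrow(P),
             dimnames = dimnames(P))
    })
  }
  for (cyc in seq_len(cycles)) {
    e <- e_max * K / (K + P)
    active <- colSums(P) < total_max
    if (!any(active)) break
    P[, active] <- P[, active] * (1 + e[, active, drop = FALSE])
  }
  table$counts <- P
  table$stage <- "post-PCR"
  table
}

#' Subsample sequencing reads per fraction
#'
#' Draws a sequencing depth for every fraction and then a multinomial read
#' sample with probabilities proportional to the fraction's (post-PCR)
#' counts.
#'
#' @param table an `otu_table` at stage `"post-PCR"` or `"fragments"`.
#' @param depth per-fraction depth: a scalar, a vector (one per sample), or
#'   a function `n -> depths`.
#' @param seed integer seed.
#' @return an `otu_table` with stage `"post-sequencing"`; each fraction's
#'   total equals its drawn depth (zero-count fractions get zero reads,
#'   with a warning).
#' @export
subsample_reads <- function(table, depth = 1e4, seed = NULL) {
  if (!table$stage %in% c("post-PCR", "fragments"))
    stop("subsampling expects a fragment- or post-PCR-stage table",
         call. = FALSE)
  ns <- ncol(table$counts)
  with_seed(seed, {
    d <- if (is.function(depth)) depth(ns) else rep_len(depth, ns)
    reads <- matrix(0L, nrow(table$counts), ns,
                    dimnames = dimnames(table$counts))
    empty <- colSums(table$counts) == 0
    if (any(empty))
      warning(sum(empty), " fraction(s) with zero counts produce no reads")
    for (j in which(!empty))
      reads[, j] <- stats::rmultinom(1, d[j], table$counts[, j])[, 1]
    table$counts <- reads
    table$stage <- "post-sequencing"
    table
  })
}

#' Simulate qPCR totals per gradient fraction
#'
#' Total SSU rRNA gene copy numbers per fraction are drawn from a gamma
#' distribution moment-matched to mean `mu` (the fraction's total simulated
#' fragment count) and variance `5889 + mu + 0.714 mu^2`, the empirical
#' mean-variance relation of replicated qPCR counts.  Fractions with
#' `mu = 0` report 0 copies.
#'
#' @param table an `otu_table` at stage `"fragments"`.
#' @param seed integer seed.
#' @return data.frame of class `qpcr_table`: `sample_id`, `gradient_id`,
#'   `fraction_idx`, `copies`.
#' @export
simulate_qpcr <- function(table, seed = NULL) {
  if (table$stage != "fragments")
    stop("qPCR simulation uses the fragment-stage table (pre-PCR totals)",
         call. = FALSE)
  mu <- colSums(table$counts)
  v <- qpcr_variance(mu)
  copies <- with_seed(seed, {
    out <- numeric(length(mu))
    pos <- mu > 0
    out[pos] <- stats::rgamma(sum(pos), shape = mu[pos]^2 / v[pos],
                              rate = mu[pos] / v[pos])
    out
  })
  out <- data.frame(sample_id = table$samples$sample_id,
                    gradient_id = table$samples$gradient_id,
                    fraction_idx = table$samples$fraction_idx,
                    copies = copies, stringsAsFactors = FALSE)
  class(out) <- c("qpcr_table", "data.frame")
  out
}

#' qPCR count variance as a function of the mean
#' @param mu mean copy number (vectorized).
#' @return variance `5889 + mu + 0.714 mu^2`.
#' @export
qpcr_variance <- function(mu) 5889 + mu + 0.714 * mu^2
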