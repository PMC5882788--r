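# Stage 2: gradient fraction layout and pre-fractionation community
# simulation with controlled beta-diversity, plus ground-truth labeling.

#' Simulate the fraction layout of one gradient
#'
#' Fraction BD widths are drawn `Normal(mean_size, sd_size)` truncated at a
#' positive floor and laid end-to-end from the heavy end of the gradient;
#' the last (lightest) fraction is clipped to the span.  Fractions are
#' indexed heavy to light and intervals are `[lower, upper)`
#' (lower-inclusive).
#'
#' @param span gradient BD span `c(low, high)` (g ml^-1).
#' @param mean_size,sd_size fraction width distribution (g ml^-1).
#' @param floor minimum fraction width (g ml^-1).
#' @param gradient_id identifier recorded in the output.
#' @param seed integer seed.
#' @return data.frame of class `fraction_scheme` with columns
#'   `gradient_id`, `fraction_idx`, `bd_low`, `bd_high`.
#' @export
#' @examples
#' fs <- simulate_fractions(seed = 1)
#' nrow(fs)  # ~ 27 fractions for an 0.11 g/ml span and 0.004 mean width
simulate_fractions <- function(span = c(1.67, 1.78), mean_size = 0.004,
                               sd_size = 0.0015, floor = 0.001,
                               gradient_id = "g1", seed = NULL) {
  stopifnot(mean_size > 0, span[2] > span[1])
  with_seed(seed, {
    widths <- numeric(0)
    total <- 0
    while (total < span[2] - span[1]) {
      w <- max(stats::rnorm(1, mean_size, sd_size), floor)
      widths <- c(widths, w)
      total <- total + w
    }
    hi <- span[2] - c(0, cumsum(widths[-length(widths)]))
    lo <- pmax(span[2] - cumsum(widths), span[1])
    out <- data.frame(gradient_id = gradient_id,
                      fraction_idx = seq_along(widths),
                      bd_low = lo, bd_high = hi,
                      stringsAsFactors = FALSE)
    class(out) <- c("fraction_scheme", "data.frame")
    out
  })
}

#' Simulate a lognormal pre-fractionation community
#'
#' Raw abundances are drawn from a lognormal whose underlying normal in log
#' space has the given mean and standard deviation (the convention of
#' classic community-abundance simulators), then normalized to sum to 1.
#'
#' @param taxa character vector of taxon ids (>= 2).
#' @param meanlog,sdlog lognormal parameters (defaults 10 and 2).
#' @param seed integer seed.
#' @return named numeric vector of relative abundances (class
#'   `community`), sorted in the input taxon order.
#' @export
simulate_community <- function(taxa, meanlog = 10, sdlog = 2, seed = NULL) {
  stopifnot(length(taxa) >= 2)
  with_seed(seed, {
    x <- stats::rlnorm(length(taxa), meanlog, sdlog)
    ab <- x / sum(x)
    names(ab) <- taxa
    class(ab) <- "community"
    ab
  })
}

#' Generate replicate communities with controlled beta-diversity
#'
#' Each replicate (i) shares exactly `round(pct_shared/100 * richness)` of
#' the reference's taxa — non-shared taxa are replaced by replicate-private
#' taxa that inherit the abundance of the vacated rank — and (ii) has
#' `round(pct_permuted/100 * richness)` taxa whose rank abundances are
#' permuted among themselves.  Richness and the rank-abundance curve are
#' preserved.
#'
#' @param reference a `community` (named abundance vector).
#' @param pct_shared percent of taxa shared with the reference (0-100).
#' @param pct_permuted percent of taxa with permuted rank abundances.
#' @param n_replicates number of replicate communities.
#' @param seed integer seed.
#' @return list of `community` vectors.
#' @export
apply_beta_diversity <- function(reference, pct_shared = 100,
                                 pct_permuted = 0, n_replicates = 1,
                                 seed = NULL) {
  assert_scalar_in(pct_shared, 0, 100, "pct_shared")
  assert_scalar_in(pct_permuted, 0, 100, "pct_permuted")
  rich <- length(reference)
  n_keep <- round(pct_shared / 100 * rich)
  n_perm <- round(pct_permuted / 100 * rich)
  with_seed(seed, lapply(seq_len(n_replicates), function(r) {
    com <- reference
    if (n_keep < rich) {
      drop <- sample.int(rich, rich - n_keep)
      names(com)[drop] <- sprintf("rep%d_private_%04d", r, seq_along(drop))
    }
    if (n_perm >= 2) {
      idx <- sample.int(rich, n_perm)
      repeat {  # derangement: every selected taxon really changes rank
        newpos <- sample(idx)
        if (!any(newpos == idx)) break
      }
      com[idx] <- com[newpos]
    }
    class(com) <- "community"
    com
  }))
}

#' Mean Bray-Curtis dissimilarity among communities
#'
#' Mean over unordered pairs of `1 - 2 * sum(min(x, y)) / sum(x + y)` on
#' the union taxon set (absent taxa count as 0).
#'
#' @param tables list of >= 2 `community` vectors.
#' @return mean dissimilarity in `[0, 1]`.
#' @export
mean_bray_curtis <- function(tables) {
  stopifnot(length(tables) >= 2)
  taxa <- unique(unlist(lapply(tables, names)))
  mat <- vapply(tables, function(x) {
    v <- stats::setNames(numeric(length(taxa)), taxa)
    v[names(x)] <- x
    v
  }, numeric(length(taxa)))
  pairs <- utils::combn(ncol(mat), 2)
  bc <- apply(pairs, 2, function(p) {
    x <- mat[, p[1]]; y <- mat[, p[2]]
    1 - 2 * sum(pmin(x, y)) / sum(x + y)
  })
  mean(bc)
}

#' Assign ground-truth incorporators
#'
#' Picks exactly `round(pct_incorp/100 * richness)` taxa uniformly at
#' random and assigns them `atom_pct` atom % excess; all other taxa get 0.
#'
#' @param taxa character vector of taxon ids.
#' @param pct_incorp percent of taxa labeled (0-100).
#' @param atom_pct atom % excess of labeled taxa (0-100).
#' @param seed integer seed.
#' @return named numeric vector (class `truth_table`): atom % excess per
#'   taxon.
#' @export
assign_incorporators <- function(taxa, pct_incorp, atom_pct, seed = NULL) {
  assert_scalar_in(pct_incorp, 0, 100, "pct_incorp")
  assert_scalar_in(atom_pct, 0, 100, "atom_pct")
  truth <- stats::setNames(numeric(length(taxa)), taxa)
  n_lab <- round(pct_incorp / 100 * length(taxa))
  if (n_lab > 0)
    truth[with_seed(seed, sample.int(length(taxa), n_lab))] <- atom_pct
  class(truth) <- "truth_table"
  truth
}
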