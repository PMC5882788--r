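# Simulation of the genomic-DNA fragment pool loaded into a gradient
# (lengths + per-fragment G+C), either from an explicit genome sequence or
# from a genome's base composition alone.

#' Fragment size distribution
#'
#' Describes the distribution of gDNA fragment lengths produced by DNA
#' extraction.  The default emulates bead-beating lysis: a left-skewed
#' normal with mean ~12 kb and a 4 kb floor.  For the skewed-normal family
#' `location` is interpreted as the target mean (the skew-normal location
#' parameter is adjusted so the untruncated mean equals `location`).
#'
#' @param family one of `"skewed-normal"`, `"normal"`, `"uniform"`,
#'   `"truncated-normal"`.
#' @param location mean fragment length (bp); for `"uniform"`, the midpoint.
#' @param scale scale (bp): sd for the normal families, half-width for
#'   uniform.
#' @param skew skewness parameter (skew-normal alpha); negative = left
#'   skew.
#' @param min_length lower truncation floor (bp).
#' @return object of class `fragment_size_dist`.
#' @export
fragment_size_dist <- function(family = c("skewed-normal", "normal",
                                          "uniform", "truncated-normal"),
                               location = 12000, scale = 2000, skew = -5,
                               min_length = 4000) {
  family <- match.arg(family)
  stopifnot(location > 0, scale >= 0, min_length >= 1)
  structure(list(family = family, location = location, scale = scale,
                 skew = skew, min_length = min_length),
            class = "fragment_size_dist")
}

# Draw n fragment lengths; resamples below-floor draws so all lengths are
# >= min_length (caller must seed).
sample_fragment_lengths <- function(dist, n) {
  draw <- switch(dist$family,
    "skewed-normal" = function(k) {
      delta <- dist$skew / sqrt(1 + dist$skew^2)
      xi <- dist$location - dist$scale * delta * sqrt(2 / pi)
      u <- abs(stats::rnorm(k)); v <- stats::rnorm(k)
      xi + dist$scale * (delta * u + sqrt(1 - delta^2) * v)
    },
    "normal" = ,
    "truncated-normal" = function(k) stats::rnorm(k, dist$location, dist$scale),
    "uniform" = function(k) stats::runif(k, dist$location - dist$scale,
                                         dist$location + dist$scale))
  x <- draw(n)
  while (any(bad <- x < dist$min_length)) x[bad] <- draw(sum(bad))
  round(x)
}

new_fragment_set <- function(taxon_id, lengths, gc, mode, start = NULL) {
  stopifnot(length(lengths) == length(gc), all(gc >= 0 & gc <= 1))
  structure(list(taxon_id = taxon_id, lengths = as.numeric(lengths),
                 gc = as.numeric(gc), mode = mode, start = start),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> %s: %d %s fragments, mean length %.0f bp, mean G+C %.3f\n",
              x$taxon_id, length(x$lengths), x$mode,
              mean(x$lengths), mean(x$gc)))
  invisible(x)
}

#' Simulate the gDNA fragment pool of one genome
#'
#' Draws `n` fragments from `size_dist` and places them on the genome.  In
#' shotgun mode, start positions are uniform over the genome (with circular
#' wrap-around by default).  In amplicon mode every fragment is placed so
#' that it fully contains one (randomly chosen) amplicon interval,
#' emulating the fact that only fragments encompassing a primer-bound locus
#' template the PCR.  Per-fragment G+C is computed from the actual fragment
#' subsequence (ambiguous bases excluded).
#'
#' @param genome a `genome` object with a sequence.
#' @param size_dist a [fragment_size_dist()].
#' @param n number of fragments (default 1e4 per genome).
#' @param mode `"shotgun"` or `"amplicon"`.
#' @param amplicon_intervals data.frame from [insilico_pcr()]; required in
#'   amplicon mode.
#' @param circular wrap shotgun fragments around the origin (default TRUE).
#' @param seed integer seed.
#' @return a `fragment_set`.
#' @export
simulate_fragments <- function(genome, size_dist = fragment_size_dist(),
                               n = 1e4,
                               mode = c("shotgun", "amplicon"),
                               amplicon_intervals = NULL, circular = TRUE,
                               seed = NULL) {
  mode <- match.arg(mode)
  L <- nchar(genome$sequence)
  with_seed(seed, {
    lens <- pmin(sample_fragment_lengths(size_dist, n), L)
    idx <- gc_cumsum(genome$sequence)
    if (mode == "amplicon") {
      if (is.null(amplicon_intervals) || nrow(amplicon_intervals) == 0)
        stop("no amplicon intervals for taxon '", genome$id,
             "'; run insilico_pcr() first", call. = FALSE)
      a <- amplicon_intervals[sample.int(nrow(amplicon_intervals), n,
                                         replace = TRUE), , drop = FALSE]
      alen <- a$end - a$start
      if (any(lens < alen))
        lens <- pmax(lens, alen)  # fragment must encompass the amplicon
      lo <- pmax(a$end - lens, 0L)
      hi <- pmin(a$start, L - lens)
      start <- floor(lo + stats::runif(n) * (hi - lo + 1))
      start <- pmin(pmax(start, 0), L - lens)
      gc <- gc_interval(idx, start, start + lens)
      gc[is.na(gc)] <- 0
      return(new_fragment_set(genome$id, lens, gc, mode, start = start))
    } else {
      start <- floor(stats::runif(n, 0, L))
      end <- start + lens
      if (circular) {
        over <- end > L
        gc <- numeric(n)
        gc[!over] <- gc_interval(idx, start[!over], end[!over])
        if (any(over)) {
          g1 <- idx$gc[L + 1L] - idx$gc[start[over] + 1L] +
            idx$gc[end[over] - L + 1L]
          t1 <- idx$acgt[L + 1L] - idx$acgt[start[over] + 1L] +
            idx$acgt[end[over] - L + 1L]
          gc[over] <- ifelse(t1 > 0, g1 / t1, NA_real_)
        }
      } else {
        start <- pmin(start, L - lens)
        gc <- gc_interval(idx, start, start + lens)
      }
    }
    gc[is.na(gc)] <- 0
    new_fragment_set(genome$id, lens, gc, mode)
  })
}

#' Simulate a fragment pool from base composition alone
#'
#' Composition-level fast path used for large synthetic genome sets: each
#' fragment's G+C count is drawn `Binomial(length, target_gc)`, the exact
#' marginal distribution of a fragment drawn from an i.i.d. genome of the
#' same composition, without materializing any sequence.
#'
#' @param taxon_id taxon identifier.
#' @param target_gc genome G+C mole fraction.
#' @param size_dist a [fragment_size_dist()].
#' @param n number of fragments.
#' @param seed integer seed.
#' @return a `fragment_set` (mode `"shotgun"`).
#' @export
simulate_fragments_binomial <- function(taxon_id, target_gc,
                                        size_dist = fragment_size_dist(),
                                        n = 1e4, seed = NULL) {
  assert_scalar_in(target_gc, 0, 1, "target_gc")
  with_seed(seed, {
    lens <- sample_fragment_lengths(size_dist, n)
    gc <- stats::rbinom(n, lens, target_gc) / lens
    new_fragment_set(taxon_id, lens, gc, "shotgun")
  })
}
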