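# Shared fixtures and oracles for the sipbench test suite.  Everything is
# generated in code; heavier shared objects are cached for the session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# A small single-taxon equilibrium profile at a given G+C.
toy_profile <- function(gc = 0.5, n_mc = 2000, bandwidth = 0.002,
                        seed = 1, id = "tx") {
  fr <- simulate_fragments_binomial(id, gc, n = 2000, seed = seed)
  build_bd_profile(fit_length_gc_kde(fr), n_mc = n_mc,
                   bandwidth = bandwidth, seed = seed + 1)
}

# Quadrature oracle: integrate a profile's pdf over [lo, hi] with the
# trapezoid rule (independent of profile_mass's closed form).
quad_mass <- function(profile, lo, hi, n = 4001) {
  x <- seq(lo, hi, length.out = n)
  y <- profile_pdf(profile, x)
  sum((y[-1] + y[-n]) / 2) * (x[2] - x[1])
}

# Hand-constructable OTU table: counts is taxa x (#rows of samples).
make_table <- function(counts, samples, stage = "post-sequencing") {
  sipbench:::new_otu_table(counts, samples, stage)
}

# Sample sheet for n_frac fractions per gradient, evenly tiling the span.
even_samples <- function(gradients, treatment, span = c(1.67, 1.78),
                         n_frac = 11) {
  edges <- round(seq(span[2], span[1], length.out = n_frac + 1), 10)
  do.call(rbind, lapply(seq_along(gradients), function(i)
    data.frame(sample_id = sprintf("%s_f%02d", gradients[i], seq_len(n_frac)),
               gradient_id = gradients[i], fraction_idx = seq_len(n_frac),
               bd_low = edges[-1], bd_high = edges[-(n_frac + 1)],
               treatment = treatment[i], stringsAsFactors = FALSE)))
}

# The 200-genome benchmark set used by the acceptance tests (shared).
acceptance_profiles <- function() {
  cached("prof200", {
    fx <- make_fixture(200, seed = 11)
    build_taxon_profiles(manifest = fx$manifest, n_mc = 2000, seed = 12)
  })
}

# Exact one-sided NB likelihood-ratio oracle (MASS::glm.nb, with Poisson
# fallback for degenerate fits); returns raw one-sided p-values for
# enrichment in the treatment arm.
nb_lrt_oracle <- function(treat, ctrl) {
  n_t <- ncol(treat)
  vapply(seq_len(nrow(treat)), function(i) {
    y <- c(treat[i, ], ctrl[i, ])
    if (all(y == 0)) return(1)
    g <- factor(rep(c("t", "c"), c(n_t, ncol(ctrl))), levels = c("c", "t"))
    fit <- try(suppressWarnings(MASS::glm.nb(y ~ g)), silent = TRUE)
    if (inherits(fit, "try-error"))
      fit <- suppressWarnings(stats::glm(y ~ g, family = stats::poisson()))
    fit0 <- suppressWarnings(stats::update(fit, . ~ 1))
    lr <- max(2 * (stats::logLik(fit) - stats::logLik(fit0)), 0)
    p2 <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
    if (stats::coef(fit)[["gt"]] > 0) p2 / 2 else 1 - p2 / 2
  }, numeric(1))
}
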