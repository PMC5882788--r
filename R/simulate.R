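# End-to-end experiment simulation: genome set -> per-taxon equilibrium BD
# profiles -> replicated treatment/control gradients -> post-sequencing
# OTU table + qPCR totals.

#' Build equilibrium BD profiles for a set of taxa
#'
#' Stage 1 for every taxon: simulate the gDNA fragment pool, fit the 2-D
#' (length x G+C) KDE, and integrate it into an equilibrium BD profile.
#' Fragments can come from explicit genome sequences (`genomes`) or, much
#' faster and distributionally equivalent for i.i.d. synthetic genomes,
#' from base composition alone (`manifest`; the default path used by the
#' simulation sweeps).
#'
#' @param manifest data.frame with columns `id` and `target_gc` (see
#'   [make_fixture()]); ignored when `genomes` given.
#' @param genomes optional named list of `genome` objects; fragments are
#'   then cut from the actual sequences (shotgun mode, or amplicon mode if
#'   `primers` is supplied).
#' @param primers optional [primer_pair()] for amplicon-mode fragments.
#' @param size_dist a [fragment_size_dist()].
#' @param n_frags fragments simulated per genome (default 1e4).
#' @param n_mc Monte-Carlo replicates per profile.  The full-scale setting
#'   is 1e5; the default here (2000) is a desk-scale setting that leaves
#'   profile means and fraction masses unchanged within Monte-Carlo error.
#' @param constants a [physics_constants()].
#' @param span gradient BD span (g ml^-1).
#' @param bandwidth 1-D KDE bandwidth (g ml^-1).  The default 0.002 is the
#'   empirical calibration: per-taxon bands then span roughly 2-4 gradient
#'   fractions (the band widths seen in amplicon DNA-SIP data, to which
#'   the upstream tooling tuned its smoothing), rather than the much
#'   narrower bands Scott's rule produces on composition-only synthetic
#'   genomes.  `NA` falls back to Scott's rule.
#' @param seed run-level seed; per-taxon seeds are derived from it.
#' @return named list of equilibrium `bd_profile`s.
#' @export
build_taxon_profiles <- function(manifest = NULL, genomes = NULL,
                                 primers = NULL,
                                 size_dist = fragment_size_dist(),
                                 n_frags = 1e4, n_mc = 2000,
                                 constants = physics_constants(),
                                 span = c(1.67, 1.78), bandwidth = 0.002,
                                 seed = NULL) {
  if (!is.null(bandwidth) && is.na(bandwidth)) bandwidth <- NULL
  if (is.null(manifest) && is.null(genomes))
    stop("supply a manifest or a genome list", call. = FALSE)
  ids <- if (!is.null(genomes)) names(genomes) else manifest$id
  profiles <- lapply(ids, function(id) {
    s_frag <- derive_seed(seed, paste0("frag:", id))
    s_prof <- derive_seed(seed, paste0("prof:", id))
    frags <- if (!is.null(genomes)) {
      g <- genomes[[id]]
      if (!is.null(primers)) {
        amp <- insilico_pcr(g, primers)
        simulate_fragments(g, size_dist, n_frags, mode = "amplicon",
                           amplicon_intervals = amp, seed = s_frag)
      } else {
        simulate_fragments(g, size_dist, n_frags, seed = s_frag)
      }
    } else {
      simulate_fragments_binomial(id,
                                  manifest$target_gc[manifest$id == id],
                                  size_dist, n_frags, seed = s_frag)
    }
    kde <- fit_length_gc_kde(frags)
    build_bd_profile(kde, n_mc = max(n_mc, 1e3), constants = constants,
                     span = span, bandwidth = bandwidth, seed = s_prof)
  })
  names(profiles) <- ids
  profiles
}

#' Simulate a complete replicated DNA-SIP experiment
#'
#' Runs Stages 2 and 3 on top of precomputed equilibrium profiles:
#' simulates pre-fractionation communities (optionally with reduced
#' beta-diversity between replicates), a fraction scheme per gradient,
#' applies DBL smearing (per-taxon, abundance-dependent) and isotope
#' incorporation (treatment gradients only, per the truth table), bins
#' fragments into fractions, simulates qPCR totals, PCR bias, and
#' sequencing subsampling.
#'
#' @param profiles named list of equilibrium `bd_profile`s covering all
#'   community taxa (plus spares for replicate-private taxa when
#'   `pct_shared < 100`).
#' @param truth a `truth_table` from [assign_incorporators()] (atom %
#'   excess per taxon; 0 = unlabeled).  Its names define the community.
#' @param n_treatment,n_control number of gradients per arm (default 3
#'   each).
#' @param isotope an [isotope_spec()].
#' @param dbl a [dbl_params()].
#' @param span gradient BD span (g ml^-1).
#' @param meanlog,sdlog community lognormal parameters.
#' @param pct_shared,pct_permuted beta-diversity controls (see
#'   [apply_beta_diversity()]); 100/0 = identical communities in every
#'   gradient.
#' @param spare_profiles named list of extra profiles used for
#'   replicate-private taxa (required when `pct_shared < 100`).
#' @param total_fragments fragments per gradient (default 1e9).
#' @param frac_mean,frac_sd fraction width distribution (g ml^-1).
#' @param pcr_cycles,pcr_e_max,pcr_K,pcr_total_max,pcr_template_frac PCR
#'   bias model (see
#'   [apply_pcr_bias()]); `pcr_cycles = 0` disables the bias stage.
#' @param depth sequencing depth per fraction (scalar/vector/function).
#' @param seed run-level seed.
#' @return list: `table` (post-sequencing `otu_table`), `fragment_table`
#'   (pre-PCR), `qpcr` (`qpcr_table`), `truth` (extended with 0 for
#'   private taxa), `communities`, `schemes`.
#' @export
simulate_sip_experiment <- function(profiles, truth,
                                    n_treatment = 3, n_control = 3,
                                    isotope = isotope_spec("13C"),
                                    dbl = dbl_params(),
                                    span = c(1.67, 1.78),
                                    meanlog = 10, sdlog = 2,
                                    pct_shared = 100, pct_permuted = 0,
                                    spare_profiles = NULL,
                                    total_fragments = 1e9,
                                    frac_mean = 0.004, frac_sd = 0.0015,
                                    pcr_cycles = 30, pcr_e_max = 0.95,
                                    pcr_K = 6e10, pcr_total_max = 2.3e11,
                                    pcr_template_frac = 0.01,
                                    depth = 1e4,
                                    seed = NULL) {
  taxa <- names(truth)
  missing <- setdiff(taxa, names(profiles))
  if (length(missing))
    stop("profiles missing for taxa: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  n_grad <- n_treatment + n_control
  treatment <- rep(c(TRUE, FALSE), c(n_treatment, n_control))
  grad_ids <- sprintf("%s%d", ifelse(treatment, "T", "C"),
                      c(seq_len(n_treatment), seq_len(n_control)))

  reference <- simulate_community(taxa, meanlog, sdlog,
                                  seed = derive_seed(seed, "community"))
  communities <- apply_beta_diversity(reference, pct_shared, pct_permuted,
                                      n_replicates = n_grad,
                                      seed = derive_seed(seed, "beta"))
  names(communities) <- grad_ids

  # map replicate-private taxa onto spare profiles
  private <- setdiff(unique(unlist(lapply(communities, names))), taxa)
  if (length(private)) {
    if (length(spare_profiles) < length(private))
      stop(length(private), " replicate-private taxa but only ",
           length(spare_profiles), " spare profiles", call. = FALSE)
    spare <- spare_profiles[seq_along(private)]
    names(spare) <- private
    profiles <- c(profiles, spare)
    truth_ext <- stats::setNames(numeric(length(private)), private)
    truth <- c(unclass(truth), truth_ext)
    class(truth) <- "truth_table"
  }

  schemes <- lapply(grad_ids, function(g)
    simulate_fractions(span, frac_mean, frac_sd, gradient_id = g,
                       seed = derive_seed(seed, paste0("frac:", g))))
  names(schemes) <- grad_ids

  per_grad <- lapply(seq_len(n_grad), function(i) {
    g <- grad_ids[i]
    com <- communities[[i]]
    prof_g <- lapply(names(com), function(t) {
      p <- apply_dbl(profiles[[t]], dbl, abundance = com[[t]], span = span)
      if (treatment[i] && truth[[t]] > 0)
        p <- apply_incorporation(p, truth[[t]], isotope)
      p
    })
    names(prof_g) <- names(com)
    build_otu_table(prof_g, com, schemes[[i]],
                    total_fragments = total_fragments,
                    seed = derive_seed(seed, paste0("otu:", g)))
  })
  frag_table <- combine_otu_tables(per_grad, treatment)
  qpcr <- simulate_qpcr(frag_table, seed = derive_seed(seed, "qpcr"))
  tab <- frag_table
  if (pcr_cycles > 0)
    tab <- apply_pcr_bias(tab, cycles = pcr_cycles, e_max = pcr_e_max,
                          K = pcr_K, total_max = pcr_total_max,
                          template_frac = pcr_template_frac,
                          seed = derive_seed(seed, "pcr"))
  tab <- suppressWarnings(
    subsample_reads(tab, depth, seed = derive_seed(seed, "reads")))
  list(table = tab, fragment_table = frag_table, qpcr = qpcr,
       truth = truth, communities = communities, schemes = schemes)
}
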