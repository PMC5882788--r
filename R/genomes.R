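# Genome handling: synthetic genome generation with a target G+C
# composition, FASTA I/O (via Biostrings), and G+C accounting that
# tolerates IUPAC ambiguity codes.

#' Generate a synthetic genome with a target G+C content
#'
#' Bases are drawn i.i.d. with `P(G) + P(C) = target_gc` (split evenly
#' between G and C, and between A and T), so the realized genome-wide G+C
#' concentrates around the target with binomial error.  Deterministic for a
#' given seed.
#'
#' @param target_gc target G+C mole fraction in `[0, 1]`.
#' @param length genome length (bp), >= 1000.
#' @param id genome identifier.
#' @param seed integer seed (optional).
#' @return object of class `genome`: list with `id` and `sequence`
#'   (character scalar over A/C/G/T).
#' @export
#' @examples
#' g <- generate_synthetic_genome(0.5, 10000, seed = 1)
#' gc_content(g$sequence)
generate_synthetic_genome <- function(target_gc, length, id = "synth",
                                      seed = NULL) {
  assert_scalar_in(target_gc, 0, 1, "target_gc")
  stopifnot(length >= 1000)
  p <- c(A = (1 - target_gc) / 2, C = target_gc / 2,
         G = target_gc / 2, T = (1 - target_gc) / 2)
  seq <- with_seed(seed, {
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  })
  structure(list(id = id, sequence = seq), class = "genome")
}

#' G+C mole fraction of a DNA string
#'
#' Ambiguity codes (anything other than A, C, G, T, case-insensitive) are
#' excluded from both numerator and denominator.
#'
#' @param sequence DNA string (character scalar) or vector of strings.
#' @return G+C fraction per input string.
#' @export
gc_content <- function(sequence) {
  vapply(sequence, function(s) {
    b <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
    n_gc <- sum(b == "G" | b == "C")
    n_at <- sum(b == "A" | b == "T")
    if (n_gc + n_at == 0) return(NA_real_)
    n_gc / (n_gc + n_at)
  }, numeric(1), USE.NAMES = FALSE)
}

# Fast G+C via cumulative sums over a raw-coded genome; used for per-fragment
# G+C where millions of substring lookups would be too slow.
gc_cumsum <- function(sequence) {
  b <- charToRaw(toupper(sequence))
  is_gc <- b == charToRaw("G") | b == charToRaw("C")
  is_acgt <- is_gc | b == charToRaw("A") | b == charToRaw("T")
  list(gc = c(0, cumsum(as.integer(is_gc))),
       acgt = c(0, cumsum(as.integer(is_acgt))))
}

# G+C of [start, end) intervals (0-based half-open) from a gc_cumsum index.
gc_interval <- function(idx, start, end) {
  gc <- idx$gc[end + 1L] - idx$gc[start + 1L]
  tot <- idx$acgt[end + 1L] - idx$acgt[start + 1L]
  ifelse(tot > 0, gc / tot, NA_real_)
}

#' Read genomes from a FASTA file
#'
#' Multi-record, wrapped-line FASTA; ambiguity codes are kept in the
#' sequence (they are ignored by G+C accounting).
#'
#' @param path FASTA file path.
#' @return named list of `genome` objects (names = record ids).
#' @export
read_genomes <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate genome ids in ", path, call. = FALSE)
  out <- lapply(seq_along(ss), function(i)
    structure(list(id = ids[i], sequence = as.character(ss[[i]])),
              class = "genome"))
  names(out) <- ids
  out
}

#' Write genomes to a FASTA file
#' @param genomes list of `genome` objects.
#' @param path output FASTA path.
#' @export
write_genomes <- function(genomes, path) {
  ss <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(ss) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Sample genome G+C targets emulating a curated reference set
#'
#' Draws genome-level G+C values from a truncated normal (defaults: mean
#' 0.50, sd 0.12, truncated to `[0.22, 0.75]`, roughly the spread of
#' complete bacterial genomes, which range from ~25 to ~75% G+C) and then
#' caps the proportion of low-G+C
#' genomes (< `low_gc_cutoff`) at `low_gc_cap` by resampling, emulating the
#' down-weighting of endosymbiont-like low-G+C genomes in curated genome
#' sets.
#'
#' @param n number of genomes.
#' @param mean,sd,lo,hi truncated-normal parameters for genome G+C.
#' @param low_gc_cutoff genomes below this G+C are "low G+C" (default 0.30).
#' @param low_gc_cap maximum fraction of low-G+C genomes (default 0.01).
#' @param seed integer seed.
#' @return numeric vector of `n` G+C targets.
#' @export
sample_genome_gc <- function(n, mean = 0.50, sd = 0.12, lo = 0.22, hi = 0.75,
                             low_gc_cutoff = 0.30, low_gc_cap = 0.01,
                             seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, {
    draw <- function(k) {
      x <- stats::rnorm(k, mean, sd)
      while (any(bad <- x < lo | x > hi))
        x[bad] <- stats::rnorm(sum(bad), mean, sd)
      x
    }
    gc <- draw(n)
    max_low <- floor(low_gc_cap * n)
    low <- which(gc < low_gc_cutoff)
    while (length(low) > max_low) {
      gc[low[seq_len(length(low) - max_low)]] <-
        draw(length(low) - max_low)
      low <- which(gc < low_gc_cutoff)
    }
    gc
  })
}

#' Build a synthetic genome set (fixture generator)
#'
#' Generates `n_genomes` synthetic genomes whose G+C targets are drawn by
#' [sample_genome_gc()] (or supplied directly), optionally writing a FASTA
#' file and a tab-separated manifest (`id`, `target_gc`, `length`).
#'
#' @param n_genomes number of genomes (>= 1).
#' @param genome_length length of each genome (bp).
#' @param gc optional numeric vector of G+C targets (length `n_genomes`);
#'   drawn by [sample_genome_gc()] when `NULL`.
#' @param fasta optional output FASTA path.
#' @param manifest optional output manifest TSV path.
#' @param seed integer seed.
#' @param sequences generate actual sequences (`TRUE`, required for FASTA
#'   output and in silico PCR) or only the G+C/length manifest (`FALSE`,
#'   sufficient for composition-level simulation and much faster).
#' @return list with `genomes` (list of `genome` or `NULL`), and `manifest`
#'   (data.frame id, target_gc, length).
#' @export
make_fixture <- function(n_genomes, genome_length = 1e5, gc = NULL,
                         fasta = NULL, manifest = NULL, seed = NULL,
                         sequences = !is.null(fasta)) {
  stopifnot(n_genomes >= 1)
  if (is.null(gc))
    gc <- sample_genome_gc(n_genomes, seed = derive_seed(seed, "gc"))
  stopifnot(length(gc) == n_genomes)
  ids <- sprintf("taxon_%04d", seq_len(n_genomes))
  man <- data.frame(id = ids, target_gc = gc, length = genome_length,
                    stringsAsFactors = FALSE)
  genomes <- NULL
  if (sequences) {
    genomes <- lapply(seq_len(n_genomes), function(i)
      generate_synthetic_genome(gc[i], genome_length, id = ids[i],
                                seed = derive_seed(seed, ids[i])))
    names(genomes) <- ids
    if (!is.null(fasta)) write_genomes(genomes, fasta)
  }
  if (!is.null(manifest))
    utils::write.table(man, manifest, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(genomes = genomes, manifest = man)
}
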