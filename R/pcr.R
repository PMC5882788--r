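# In silico PCR with IUPAC-degenerate primers.  Matching is delegated to
# Biostrings (ambiguity-aware pattern matching with mismatch tolerance);
# the amplicon logic (forward site + downstream reverse-complement site
# within a product-size window) is implemented here.

#' Primer pair for in silico PCR
#'
#' @param forward,reverse primer sequences 5'->3' (IUPAC degenerate codes
#'   allowed); each must be at least 10 nt.
#' @param max_mismatch maximum mismatches tolerated per primer (default 0).
#' @return object of class `primer_pair`.
#' @export
#' @examples
#' default_primers()  # V4-targeting SSU rRNA pair (515F / 927R)
primer_pair <- function(forward, reverse, max_mismatch = 0L) {
  ok <- function(p) nchar(p) >= 10 &&
    grepl("^[ACGTRYSWKMBDHVN]+$", toupper(p))
  if (!ok(forward) || !ok(reverse))
    stop("primers must be IUPAC DNA strings of length >= 10", call. = FALSE)
  structure(list(forward = toupper(forward), reverse = toupper(reverse),
                 max_mismatch = as.integer(max_mismatch)),
            class = "primer_pair")
}

#' Default SSU rRNA V4 primer pair (515F / 927R)
#' @inheritParams primer_pair
#' @return a [primer_pair()].
#' @export
default_primers <- function(max_mismatch = 0L) {
  primer_pair("GTGYCAGCMGCMGCGGTRA", "CCGYCAATTYMTTTRAGTTT", max_mismatch)
}

# All start positions (0-based) where a degenerate primer matches a concrete
# subject with <= max_mismatch mismatches.
match_primer <- function(primer, subject, max_mismatch = 0L) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(primer), subject,
                                max.mismatch = max_mismatch,
                                fixed = "subject")
  Biostrings::start(methods::as(m, "IRanges")) - 1L
}

#' In silico PCR against a genome
#'
#' Finds every locus where the forward primer matches the plus strand and
#' the reverse complement of the reverse primer matches downstream, with the
#' product size inside `size_range`.  Each primer matches under IUPAC
#' degeneracy with at most `max_mismatch` mismatches.  Coordinates are
#' 0-based, half-open, spanning primer to primer inclusive.
#'
#' @param genome a `genome` object (see [read_genomes()]).
#' @param primers a [primer_pair()].
#' @param size_range allowed product length range in bp
#'   (default `c(50, 3000)`).
#' @return data.frame with columns `start`, `end`, `strand`; zero rows when
#'   no site exists.
#' @export
insilico_pcr <- function(genome, primers = default_primers(),
                         size_range = c(50, 3000)) {
  subject <- Biostrings::DNAString(genome$sequence)
  fwd <- match_primer(primers$forward, subject, primers$max_mismatch)
  rev_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(primers$reverse)))
  rev <- match_primer(rev_rc, subject, primers$max_mismatch)
  len_f <- nchar(primers$forward)
  len_r <- nchar(primers$reverse)
  out <- list()
  for (f in fwd) {
    ends <- rev + len_r            # half-open end of the reverse site
    size <- ends - f
    hit <- which(size >= size_range[1] & size <= size_range[2] &
                   rev >= f + len_f)
    for (h in hit)
      out[[length(out) + 1L]] <- c(start = f, end = ends[h])
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  m <- do.call(rbind, out)
  data.frame(start = m[, "start"], end = m[, "end"], strand = "+",
             stringsAsFactors = FALSE)
}
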