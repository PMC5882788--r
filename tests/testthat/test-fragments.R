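test_that("synthetic genomes hit their target composition deterministically", {
  g <- generate_synthetic_genome(0.50, 1e5, seed = 7)
  expect_true(abs(gc_content(g$sequence) - 0.50) < 0.01)
  g2 <- generate_synthetic_genome(0.50, 1e5, seed = 7)
  expect_identical(g$sequence, g2$sequence)
  at <- generate_synthetic_genome(0, 1e4, seed = 1)
  expect_equal(gc_content(at$sequence), 0)
  expect_false(grepl("[GC]", at$sequence))
})

test_that("per-fragment G+C matches a string-counting oracle", {
  g <- generate_synthetic_genome(0.42, 2e4, seed = 3)
  idx <- sipbench:::gc_cumsum(g$sequence)
  set.seed(9)
  for (i in 1:20) {
    s <- sample.int(15000, 1); len <- sample.int(3000, 1) + 10
    sub <- substr(g$sequence, s + 1, s + len)   # 0-based [s, s+len)
    oracle <- gc_content(sub)
    expect_equal(sipbench:::gc_interval(idx, s, s + len), oracle)
  }
})

test_that("fragment pools: size distribution, containment, floor", {
  sd_ <- fragment_size_dist()
  g <- generate_synthetic_genome(0.5, 2e5, seed = 5)
  fr <- simulate_fragments(g, sd_, n = 1e4, seed = 6)
  expect_length(fr$lengths, 1e4)
  expect_true(all(fr$lengths >= sd_$min_length))
  # empirical mean within 2 SE of configured mean (truncation raises the
  # mean slightly above `location`; allow for it via the sample itself)
  se <- sd(fr$lengths) / sqrt(length(fr$lengths))
  expect_lt(abs(mean(fr$lengths) - sd_$location), 4 * se + 200)
  # G+C concentrates near genome G+C, variance shrinking with length
  expect_lt(abs(mean(fr$gc) - 0.5), 0.005)
  v_long <- var(fr$gc[fr$lengths > 14000])
  v_short <- var(fr$gc[fr$lengths < 10000])
  expect_lt(v_long, v_short)
  # binomial fast path agrees in moments
  fb <- simulate_fragments_binomial("t", 0.5, sd_, n = 1e4, seed = 6)
  expect_lt(abs(mean(fb$gc) - mean(fr$gc)), 0.005)
  expect_identical(simulate_fragments_binomial("t", 0.5, sd_, 100, seed = 2)$gc,
                   simulate_fragments_binomial("t", 0.5, sd_, 100, seed = 2)$gc)
})

test_that("in silico PCR finds planted degenerate primer sites", {
  pr <- default_primers()
  set.seed(11)
  # build a genome with one exact amplicon: fwd + 400 bp + revcomp(rev)
  fwd <- gsub("Y", "C", gsub("M", "A", gsub("R", "G", pr$forward)))
  rev <- gsub("Y", "T", gsub("M", "C", gsub("R", "A", pr$reverse)))
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  mid <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  pad <- function(n) paste(sample(c("A", "T"), n, TRUE), collapse = "")
  seqn <- paste0(pad(500), fwd, mid, rc(rev), pad(500))
  g <- structure(list(id = "planted", sequence = seqn), class = "genome")
  amp <- insilico_pcr(g, pr)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$end - amp$start, nchar(fwd) + 400 + nchar(rev))
  expect_equal(amp$start, 500)
  # genome without a site
  empty <- structure(list(id = "e", sequence = strrep("AT", 2000)),
                     class = "genome")
  expect_equal(nrow(insilico_pcr(empty, pr)), 0)
  # IUPAC degeneracy: Y matches C and T with zero mismatches
  subj <- Biostrings::DNAString("AAACGCAAAAAAACGTAAA")
  hits <- sipbench:::match_primer("ACGY", subj, 0)
  expect_equal(hits, c(2L, 12L))
})

test_that("amplicon-mode fragments fully contain an amplicon interval", {
  pr <- default_primers()
  fwd <- gsub("Y", "C", gsub("M", "A", gsub("R", "G", pr$forward)))
  rev <- gsub("Y", "T", gsub("M", "C", gsub("R", "A", pr$reverse)))
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  set.seed(13)
  core <- paste(sample(c("A", "C", "G", "T"), 350, TRUE), collapse = "")
  seqn <- paste0(generate_synthetic_genome(0.5, 3e4, seed = 2)$sequence,
                 fwd, core, rc(rev),
                 generate_synthetic_genome(0.5, 3e4, seed = 3)$sequence)
  g <- structure(list(id = "amp", sequence = seqn), class = "genome")
  amp <- insilico_pcr(g, pr)
  expect_equal(nrow(amp), 1)
  fr <- simulate_fragments(g, fragment_size_dist(), n = 500,
                           mode = "amplicon", amplicon_intervals = amp,
                           seed = 21)
  expect_length(fr$lengths, 500)
  expect_true(all(fr$start <= amp$start & fr$start + fr$lengths >= amp$end))
  expect_error(simulate_fragments(g, mode = "amplicon",
                                  amplicon_intervals = amp[0, ]),
               "amp")
})

test_that("fixture generator caps low-G+C genomes", {
  gc <- sample_genome_gc(400, seed = 31)
  expect_lte(mean(gc < 0.30), 0.01)
  expect_true(all(gc >= 0.22 & gc <= 0.75))
  fx <- make_fixture(5, genome_length = 2000, seed = 1, sequences = TRUE)
  expect_length(fx$genomes, 5)
  realized <- gc_content(vapply(fx$genomes, `[[`, "", "sequence"))
  expect_true(all(abs(realized - fx$manifest$target_gc) < 0.05))
  # FASTA round trip
  fa <- tempfile(fileext = ".fasta")
  write_genomes(fx$genomes, fa)
  back <- read_genomes(fa)
  expect_identical(names(back), fx$manifest$id)
  expect_identical(back[[3]]$sequence, fx$genomes[[3]]$sequence)
})
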