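# Plain-text (TSV) serialization of the core containers, so detectors can
# be run on pre-built tables and simulation outputs can be inspected with
# standard tools.

#' Write / read an OTU table as long-format TSV
#'
#' Columns: `gradient`, `treatment`, `fraction_idx`, `bd_low`, `bd_high`,
#' `taxon`, `count`.  Zero counts are omitted on write and restored on
#' read.
#'
#' @param table an `otu_table`.
#' @param path TSV path.
#' @return `write_otu_table`: the path, invisibly.  `read_otu_table`: an
#'   `otu_table` (stage taken from the `stage` comment line, default
#'   `"post-sequencing"`).
#' @export
write_otu_table <- function(table, path) {
  s <- table$samples
  long <- do.call(rbind, lapply(seq_len(ncol(table$counts)), function(j) {
    nz <- which(table$counts[, j] > 0)
    if (!length(nz)) return(NULL)
    data.frame(gradient = s$gradient_id[j],
               treatment = s$treatment[j] %||% NA,
               fraction_idx = s$fraction_idx[j],
               bd_low = s$bd_low[j], bd_high = s$bd_high[j],
               taxon = rownames(table$counts)[nz],
               count = table$counts[nz, j], stringsAsFactors = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# stage: ", table$stage), con)
  utils::write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(path) {
  first <- readLines(path, n = 1)
  stage <- if (startsWith(first, "# stage:"))
    trimws(sub("# stage:", "", first)) else "post-sequencing"
  long <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
  key <- sprintf("%s_f%02d", long$gradient, long$fraction_idx)
  samples <- unique(data.frame(sample_id = key, gradient_id = long$gradient,
                               fraction_idx = long$fraction_idx,
                               bd_low = long$bd_low, bd_high = long$bd_high,
                               treatment = long$treatment,
                               stringsAsFactors = FALSE))
  samples <- samples[order(samples$gradient_id, samples$fraction_idx), ]
  taxa <- sort(unique(long$taxon))
  counts <- matrix(0, length(taxa), nrow(samples),
                   dimnames = list(taxa, samples$sample_id))
  counts[cbind(match(long$taxon, taxa), match(key, samples$sample_id))] <-
    long$count
  new_otu_table(counts, samples, stage)
}

#' Write / read a fraction scheme TSV
#' @param scheme a `fraction_scheme` (or rbind of several).
#' @param path TSV path.
#' @export
write_fraction_scheme <- function(scheme, path) {
  utils::write.table(as.data.frame(scheme), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fraction_scheme
#' @export
read_fraction_scheme <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("fraction_scheme", "data.frame")
  out
}

#' Write / read qPCR totals TSV
#' @param qpcr a `qpcr_table`.
#' @param path TSV path.
#' @export
write_qpcr_table <- function(qpcr, path) {
  utils::write.table(as.data.frame(qpcr), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_qpcr_table
#' @export
read_qpcr_table <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("qpcr_table", "data.frame")
  out
}

#' Write communities as long-format TSV (gradient, taxon, rel_abund)
#' @param communities named list of `community` vectors.
#' @param path TSV path.
#' @export
write_communities <- function(communities, path) {
  long <- do.call(rbind, lapply(names(communities), function(g)
    data.frame(gradient = g, taxon = names(communities[[g]]),
               rel_abund = as.numeric(communities[[g]]),
               stringsAsFactors = FALSE)))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a detection result TSV
#' @param result a `detection_result`.
#' @param path TSV path.
#' @export
write_detection_result <- function(result, path) {
  df <- as.data.frame(result)
  df$method <- attr(result, "method")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
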