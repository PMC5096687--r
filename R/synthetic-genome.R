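# Synthetic reference genomes: i.i.d. base sequences at a target GC content.
# These stand in for a real multi-chromosome reference so that the calling,
# spectrum and indel stages can be exercised without any download.

#' Specify a synthetic reference genome
#'
#' @param chromosome_lengths integer vector of chromosome lengths (bp),
#'   each at least 1000
#' @param gc_content target G+C fraction in `[0, 1]`
#' @param seed integer seed; generation is deterministic given the spec
#' @return a `genome_spec` object
#' @export
genome_spec <- function(chromosome_lengths, gc_content = 0.42, seed = 1L) {
  assert_that(length(chromosome_lengths) >= 1L, "need at least one chromosome")
  assert_that(all(vapply(chromosome_lengths, is_count, logical(1))) &&
                all(chromosome_lengths >= 1000),
              "chromosome lengths must be integers >= 1000 bp")
  assert_that(is_fraction(gc_content), "gc_content must be in [0, 1]")
  assert_that(is_count(abs(seed)), "seed must be an integer")
  structure(list(chromosome_lengths = as.integer(chromosome_lengths),
                 gc_content = gc_content, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a synthetic reference genome
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2`, one independent stream per chromosome derived
#' from the spec seed, so the same spec always yields byte-identical
#' sequence.
#'
#' @param spec a [genome_spec()]
#' @return a [Biostrings::DNAStringSet] named `chr1`, `chr2`, ...
#' @export
generate_reference <- function(spec) {
  assert_that(inherits(spec, "genome_spec"), "spec must be a genome_spec")
  gc <- spec$gc_content
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_along(spec$chromosome_lengths), function(i) {
    with_seed(derive_seed(spec$seed, "reference", i), {
      paste(sample(BASES, spec$chromosome_lengths[i], replace = TRUE,
                   prob = probs), collapse = "")
    })
  }, character(1))
  names(seqs) <- paste0("chr", seq_along(seqs))
  Biostrings::DNAStringSet(seqs)
}

#' Write a reference genome as FASTA (60-column wrapping)
#'
#' @param reference a [Biostrings::DNAStringSet]
#' @param path output file
#' @export
write_reference_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path, width = 60L)
  invisible(path)
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file
#' @return a [Biostrings::DNAStringSet]
#' @export
read_reference_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

# Character vector view of a genome (one string per chromosome), cached by
# callers that need repeated substring access.
reference_as_strings <- function(reference) {
  stats::setNames(as.character(reference), names(reference))
}
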