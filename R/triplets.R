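# 96-class triplet (trinucleotide) conventions shared by the spectrum,
# signature and simulation code.
#
# Classes are ordered substitution-major in the conventional catalogue order
# (C>A, C>G, C>T, T>A, T>C, T>G), and within each substitution the 16 flank
# pairs are ordered by the 5' base then the 3' base, both alphabetically
# (A, C, G, T). Purine-centred mutations are reverse-complemented into the
# pyrimidine-centred representation before indexing.

SUBSTITUTION_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Labels of the 96 triplet mutation classes
#'
#' @return character vector of length 96, e.g. `"A[C>A]A"`, in catalogue
#'   order (substitution-major, then 5' flank, then 3' flank).
#' @export
triplet_class_labels <- function() {
  out <- character(96)
  i <- 0L
  for (sub in SUBSTITUTION_TYPES) {
    for (f5 in BASES) {
      for (f3 in BASES) {
        i <- i + 1L
        out[i] <- paste0(f5, "[", sub, "]", f3)
      }
    }
  }
  out
}

# The reference triplet (pyrimidine-centred) of each of the 96 classes.
class_triplets <- function() {
  lab <- triplet_class_labels()
  paste0(substr(lab, 1, 1), substr(lab, 3, 3), substr(lab, 7, 7))
}

# The 32 pyrimidine-centred triplets, central C block then central T block,
# flanks alphabetical (5' major). This is the index set of
# genome_triplet_frequencies().
pyrimidine_triplets <- function() {
  out <- character(32)
  i <- 0L
  for (central in c("C", "T")) {
    for (f5 in BASES) {
      for (f3 in BASES) {
        i <- i + 1L
        out[i] <- paste0(f5, central, f3)
      }
    }
  }
  out
}

#' Classify an SNV into one of the 96 triplet mutation classes
#'
#' Purine-centred mutations (central A or G in `ref_triplet`) are
#' reverse-complemented to the pyrimidine-centred convention, so a locus and
#' its reverse complement always map to the same class.
#'
#' @param ref_triplet character vector of reference 3-mers (the mutated base
#'   in the middle)
#' @param alt_base character vector of alternate bases, recycled against
#'   `ref_triplet`
#' @return integer vector of class indices in 1..96
#' @export
classify_snv <- function(ref_triplet, alt_base) {
  n <- max(length(ref_triplet), length(alt_base))
  ref_triplet <- toupper(rep_len(ref_triplet, n))
  alt_base <- toupper(rep_len(alt_base, n))
  assert_that(all(nchar(ref_triplet) == 3L), "ref_triplet must be 3-mers")
  f5 <- substr(ref_triplet, 1, 1)
  ctr <- substr(ref_triplet, 2, 2)
  f3 <- substr(ref_triplet, 3, 3)
  ok <- f5 %in% BASES & ctr %in% BASES & f3 %in% BASES & alt_base %in% BASES
  if (!all(ok)) stopf("ambiguous base in triplet or alt at %d site(s)", sum(!ok))
  if (any(ctr == alt_base)) {
    stopf("alt base equals the reference base at %d site(s)", sum(ctr == alt_base))
  }
  flip <- ctr %in% c("A", "G")
  # reverse complement: new 5' = comp(old 3'), centre and alt complemented
  nf5 <- ifelse(flip, BASE_COMPLEMENT[f3], f5)
  nctr <- ifelse(flip, BASE_COMPLEMENT[ctr], ctr)
  nf3 <- ifelse(flip, BASE_COMPLEMENT[f5], f3)
  nalt <- ifelse(flip, BASE_COMPLEMENT[alt_base], alt_base)
  cls <- match(paste0(nctr, ">", nalt), SUBSTITUTION_TYPES)
  i5 <- match(nf5, BASES)
  i3 <- match(nf3, BASES)
  as.integer((cls - 1L) * 16L + (i5 - 1L) * 4L + i3)
}

#' Construct a 96-component triplet mutation spectrum
#'
#' @param values numeric vector of length 96 in catalogue order
#' @param mode one of `"counts"`, `"rates"`, `"normalized"`
#' @return a `triplet_spectrum` object (named numeric vector)
#' @export
triplet_spectrum <- function(values, mode = c("counts", "rates", "normalized")) {
  mode <- match.arg(mode)
  assert_that(length(values) == 96L, "spectrum must have exactly 96 components")
  values <- as.numeric(values)
  assert_that(all(is.finite(values)) && all(values >= 0),
              "spectrum components must be finite and non-negative")
  if (mode == "normalized") {
    assert_that(abs(sum(values) - 1) <= 1e-9,
                "normalized spectrum must sum to 1 (got %.12g)", sum(values))
  }
  structure(stats::setNames(values, triplet_class_labels()),
            mode = mode, class = "triplet_spectrum")
}

#' @export
print.triplet_spectrum <- function(x, ...) {
  cat(sprintf("triplet_spectrum (%s), total = %g; top classes:\n",
              attr(x, "mode"), sum(x)))
  top <- sort(unclass(x), decreasing = TRUE)[1:5]
  print(round(top, 5))
  invisible(x)
}

spectrum_mode <- function(x) attr(x, "mode")

#' Count pyrimidine-centred triplet occurrences in a genome
#'
#' Counts every overlapping 3-mer on the forward strand and folds
#' purine-centred triplets into their reverse-complement (pyrimidine-centred)
#' bin, i.e. both-strand occurrence counts of the 32 pyrimidine-centred
#' triplets. Windows containing non-ACGT characters are skipped.
#'
#' @param reference a [Biostrings::DNAStringSet] (or object coercible to one)
#' @param label genome label stored on the result
#' @return named integer vector over the 32 pyrimidine-centred triplets,
#'   class `genome_triplet_freqs`
#' @export
genome_triplet_frequencies <- function(reference, label = "genome") {
  if (!methods::is(reference, "DNAStringSet")) {
    reference <- Biostrings::DNAStringSet(reference)
  }
  tf <- Biostrings::trinucleotideFrequency(reference, step = 1L)
  counts64 <- if (is.matrix(tf)) colSums(tf) else tf
  trip64 <- names(counts64)
  pyr <- pyrimidine_triplets()
  out <- stats::setNames(numeric(32), pyr)
  central <- substr(trip64, 2, 2)
  bin <- ifelse(central %in% c("C", "T"), trip64, reverse_complement(trip64))
  for (i in seq_along(counts64)) {
    out[bin[i]] <- out[bin[i]] + counts64[i]
  }
  structure(out, genome = label, class = "genome_triplet_freqs")
}

#' Read / write genome triplet-frequency tables
#'
#' Plain TSV with columns `triplet` and `count`, one row per pyrimidine
#' triplet.
#' @param freqs a `genome_triplet_freqs` vector
#' @param path file path
#' @rdname triplet_freq_io
#' @export
write_triplet_frequencies <- function(freqs, path) {
  utils::write.table(
    data.frame(triplet = names(freqs), count = as.numeric(freqs)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param label genome label for the re-read table
#' @rdname triplet_freq_io
#' @export
read_triplet_frequencies <- function(path, label = "genome") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  assert_that(all(c("triplet", "count") %in% names(df)),
              "triplet frequency table needs columns triplet, count")
  pyr <- pyrimidine_triplets()
  idx <- match(pyr, df$triplet)
  assert_that(!anyNA(idx), "table must contain all 32 pyrimidine triplets")
  structure(stats::setNames(df$count[idx], pyr),
            genome = label, class = "genome_triplet_freqs")
}
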