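# Triplet mutation spectra, genome-frequency normalization, and rainfall
# (intermutation distance) statistics.

#' Build a 96-class triplet spectrum from SNV calls
#'
#' Indels are ignored. Calls at chromosome edges (no flanking base) are
#' excluded with a warning.
#'
#' @param calls data.table/data.frame of calls with columns chrom, pos, ref,
#'   alt, type (only `type == "SNV"` rows are used; a missing type column
#'   means all rows are SNVs)
#' @param reference a [Biostrings::DNAStringSet] covering all call positions
#' @return a [triplet_spectrum()] of counts
#' @export
build_spectrum <- function(calls, reference) {
  refstr <- reference_as_strings(reference)
  calls <- as.data.frame(calls)
  if ("type" %in% names(calls)) calls <- calls[calls$type == "SNV", ]
  vals <- numeric(96)
  if (nrow(calls)) {
    assert_that(all(calls$chrom %in% names(refstr)),
                "call chromosome absent from reference")
    len <- nchar(refstr)[calls$chrom]
    edge <- calls$pos <= 1L | calls$pos >= len
    if (any(edge)) {
      warning(sprintf("%d SNV call(s) at chromosome edges excluded",
                      sum(edge)), call. = FALSE)
      calls <- calls[!edge, ]
    }
  }
  if (nrow(calls)) {
    trip <- substr(refstr[calls$chrom], calls$pos - 1L, calls$pos + 1L)
    cls <- classify_snv(trip, calls$alt)
    tab <- tabulate(cls, nbins = 96)
    vals <- as.numeric(tab)
  }
  triplet_spectrum(vals, mode = "counts")
}

#' Normalize a count spectrum by genome triplet occurrence
#'
#' `rate[i] = count[i] / freq[triplet(i)]`, the per-occurrence mutation rate
#' of each class.
#'
#' @param spectrum a [triplet_spectrum()] of counts
#' @param freqs a [genome_triplet_frequencies()] table (all entries > 0)
#' @return a [triplet_spectrum()] of rates
#' @export
normalize_by_genome <- function(spectrum, freqs) {
  assert_that(inherits(spectrum, "triplet_spectrum"),
              "spectrum must be a triplet_spectrum")
  trip <- class_triplets()
  f <- as.numeric(freqs)[match(trip, names(freqs))]
  f[is.na(f)] <- 0
  v <- as.numeric(spectrum)
  # a zero-frequency triplet is only an error when mutations were observed
  # in it; with zero counts the rate is a well-defined zero
  bad <- f <= 0 & v > 0
  if (any(bad)) {
    stopf("zero or missing genome frequency for triplet %s",
          trip[which(bad)][1])
  }
  rates <- ifelse(f > 0, v / f, 0)
  triplet_spectrum(rates, mode = "rates")
}

#' Rescale a spectrum to sum to one
#'
#' @param spectrum a [triplet_spectrum()] with positive total
#' @return a normalized [triplet_spectrum()]
#' @export
normalize_spectrum <- function(spectrum) {
  s <- sum(spectrum)
  assert_that(s > 0, "cannot normalize an all-zero spectrum")
  triplet_spectrum(as.numeric(spectrum) / s, mode = "normalized")
}

#' Intermutation (rainfall) distances
#'
#' Distance of each SNV to the previous SNV on the same chromosome, computed
#' per sample. The first SNV on each chromosome has no defined distance and
#' is omitted.
#'
#' @param calls data.frame of SNV calls with columns chrom, pos and
#'   optionally sample, ref, alt, type
#' @return data.table with columns sample, chrom, pos, distance, class
#'   (6-class substitution label where ref/alt are available)
#' @export
intermutation_distances <- function(calls) {
  calls <- as.data.frame(calls)
  if ("type" %in% names(calls)) calls <- calls[calls$type == "SNV", ]
  if (!"sample" %in% names(calls)) calls$sample <- "all"
  if (!nrow(calls)) {
    return(data.table::data.table(sample = character(0), chrom = character(0),
                                  pos = integer(0), distance = integer(0),
                                  class = character(0)))
  }
  cls <- if (all(c("ref", "alt") %in% names(calls))) {
    pyr <- calls$ref %in% c("C", "T")
    paste0(ifelse(pyr, calls$ref, BASE_COMPLEMENT[calls$ref]), ">",
           ifelse(pyr, calls$alt, BASE_COMPLEMENT[calls$alt]))
  } else NA_character_
  dt <- data.table::data.table(sample = calls$sample, chrom = calls$chrom,
                               pos = as.integer(calls$pos), class = cls)
  data.table::setorderv(dt, c("sample", "chrom", "pos"))
  dt[, distance := c(NA_integer_, diff(pos)),
     by = c("sample", "chrom")]
  out <- dt[!is.na(dt$distance),
            c("sample", "chrom", "pos", "distance", "class")]
  assert_that(all(out$distance >= 1), "duplicate SNV positions in input")
  out[]
}

#' Fraction of SNVs within a window of the previous SNV
#'
#' @param distances integer distances (>= 1), e.g. the `distance` column of
#'   [intermutation_distances()]
#' @param window clustering window in bp (default 100)
#' @return fraction in `[0, 1]`
#' @export
clustered_fraction <- function(distances, window = 100L) {
  if (is.data.frame(distances)) distances <- distances$distance
  assert_that(length(distances) >= 1, "clustered fraction of an empty set is undefined")
  assert_that(all(distances >= 1), "distances must be >= 1")
  mean(distances <= window)
}

#' Write a spectrum as TSV (class label, value)
#'
#' @param spectrum a [triplet_spectrum()]
#' @param path file path
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  utils::write.table(
    data.frame(class = names(spectrum), value = as.numeric(spectrum)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum TSV written by [write_spectrum_tsv()]
#'
#' @param path file path
#' @param mode spectrum mode of the stored values
#' @return a [triplet_spectrum()]
#' @export
read_spectrum_tsv <- function(path, mode = "counts") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  idx <- match(triplet_class_labels(), df$class)
  assert_that(!anyNA(idx), "spectrum TSV must contain all 96 class labels")
  triplet_spectrum(df$value[idx], mode = mode)
}
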