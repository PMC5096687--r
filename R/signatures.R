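# Signature-catalogue comparison: cross-genome triplet adjustment, Pearson
# correlation against a 30-signature catalogue, baseline subtraction, and
# CpG (NCG>NTG) overrepresentation.

#' Construct a signature catalogue
#'
#' @param mat numeric matrix, 96 rows (catalogue class order) x one column
#'   per signature; each column must be non-negative and sum to 1 within
#'   1e-6
#' @return a `signature_catalog` matrix
#' @export
signature_catalog <- function(mat) {
  mat <- as.matrix(mat)
  assert_that(nrow(mat) == 96L, "catalogue must have 96 rows")
  assert_that(all(mat >= 0), "signature probabilities must be non-negative")
  sums <- colSums(mat)
  assert_that(all(abs(sums - 1) <= 1e-6),
              "each signature must sum to 1 (tolerance 1e-6)")
  rownames(mat) <- triplet_class_labels()
  if (is.null(colnames(mat))) {
    colnames(mat) <- paste0("Signature.", seq_len(ncol(mat)))
  }
  structure(mat, class = c("signature_catalog", "matrix"))
}

#' Deterministic synthetic 30-signature catalogue
#'
#' A stand-in for the published 30-signature table so tests and examples
#' need no download: each synthetic signature concentrates most of its mass
#' on a small random subset of the 96 classes (gamma draws, normalized),
#' giving mutually distinguishable profiles. It is synthetic data, not the
#' published catalogue.
#'
#' @param n_signatures number of signatures (default 30)
#' @param seed integer seed (fixed default so the catalogue is stable)
#' @return a `signature_catalog`
#' @export
synthetic_signature_catalog <- function(n_signatures = 30L, seed = 904L) {
  with_seed(derive_seed(seed, "signature-catalog"), {
    mat <- sapply(seq_len(n_signatures), function(j) {
      w <- stats::rgamma(96, shape = 0.15, rate = 1)
      w / sum(w)
    })
  })
  colnames(mat) <- paste0("Signature.", seq_len(n_signatures))
  signature_catalog(mat)
}

#' Read a signature catalogue TSV (published 30-signature layout)
#'
#' Expects columns `Substitution Type`, `Trinucleotide`, then one numeric
#' column per signature; rows may be in any order.
#'
#' @param path TSV file
#' @return a `signature_catalog`
#' @export
read_signature_catalog <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  assert_that(all(c("Substitution Type", "Trinucleotide") %in% names(df)),
              "catalogue needs 'Substitution Type' and 'Trinucleotide' columns")
  lab <- paste0(substr(df$Trinucleotide, 1, 1), "[", df$`Substitution Type`,
                "]", substr(df$Trinucleotide, 3, 3))
  idx <- match(triplet_class_labels(), lab)
  assert_that(!anyNA(idx), "catalogue must contain all 96 classes")
  valcols <- setdiff(names(df), c("Substitution Type", "Trinucleotide"))
  mat <- as.matrix(df[idx, valcols, drop = FALSE])
  signature_catalog(mat)
}

#' Write a signature catalogue TSV in the published layout
#'
#' @param catalog a `signature_catalog`
#' @param path file path
#' @export
write_signature_catalog <- function(catalog, path) {
  lab <- rownames(catalog)
  df <- data.frame(
    `Substitution Type` = substr(lab, 3, 5),
    Trinucleotide = paste0(substr(lab, 1, 1), substr(lab, 3, 3),
                           substr(lab, 7, 7)),
    check.names = FALSE)
  df <- cbind(df, as.data.frame(unclass(catalog)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Adjust a spectrum for triplet abundance differences between two genomes
#'
#' Each class is reweighted by the ratio of its triplet's occurrence in the
#' target genome to the source genome, then renormalized to sum 1. This
#' makes spectra observed on the source genome comparable with signatures
#' defined on the target genome.
#'
#' @param spectrum a [triplet_spectrum()] (counts or rates)
#' @param source_freqs,target_freqs [genome_triplet_frequencies()] of the
#'   genome the mutations were observed on and the genome of the catalogue
#' @return a normalized [triplet_spectrum()] with attributes `source` and
#'   `target`
#' @export
cross_genome_adjust <- function(spectrum, source_freqs, target_freqs) {
  assert_that(inherits(spectrum, "triplet_spectrum"),
              "spectrum must be a triplet_spectrum")
  trip <- class_triplets()
  src <- as.numeric(source_freqs)[match(trip, names(source_freqs))]
  tgt <- as.numeric(target_freqs)[match(trip, names(target_freqs))]
  if (any(is.na(src)) || any(src <= 0)) {
    stopf("zero or missing source-genome frequency for triplet %s",
          trip[which(is.na(src) | src <= 0)][1])
  }
  assert_that(!anyNA(tgt) && all(tgt >= 0), "invalid target frequencies")
  v <- as.numeric(spectrum) * tgt / src
  out <- normalize_spectrum(triplet_spectrum(v, mode = "rates"))
  attr(out, "source") <- attr(source_freqs, "genome")
  attr(out, "target") <- attr(target_freqs, "genome")
  out
}

#' Pearson correlation of a spectrum with every catalogue signature
#'
#' @param spectrum a [triplet_spectrum()] (any mode; Pearson correlation is
#'   scale-invariant) with non-zero variance
#' @param catalog a `signature_catalog`
#' @return named numeric vector of correlation coefficients, one per
#'   signature
#' @export
correlate_with_catalog <- function(spectrum, catalog) {
  assert_that(inherits(catalog, "signature_catalog"),
              "catalog must be a signature_catalog")
  v <- as.numeric(spectrum)
  assert_that(length(v) == 96L, "spectrum must have 96 components")
  if (stats::sd(v) == 0) stopf("correlation undefined: zero-variance spectrum")
  out <- apply(unclass(catalog), 2, function(s) stats::cor(v, s))
  out
}

#' Subtract a baseline spectrum (e.g. the wild-type mean)
#'
#' Component-wise difference with negative components clipped to zero, then
#' renormalized. The number of clipped components is recorded in the
#' `clipped` attribute.
#'
#' @param spectrum,baseline [triplet_spectrum()] objects of the same mode
#' @return a normalized [triplet_spectrum()]
#' @export
subtract_baseline <- function(spectrum, baseline) {
  assert_that(inherits(spectrum, "triplet_spectrum") &&
                inherits(baseline, "triplet_spectrum"),
              "inputs must be triplet_spectrum objects")
  assert_that(identical(spectrum_mode(spectrum), spectrum_mode(baseline)),
              "spectrum and baseline must share the same mode")
  d <- as.numeric(spectrum) - as.numeric(baseline)
  clipped <- sum(d < 0)
  d[d < 0] <- 0
  if (sum(d) == 0) {
    stopf("baseline subtraction left no positive component")
  }
  out <- normalize_spectrum(triplet_spectrum(d, mode = spectrum_mode(spectrum)))
  attr(out, "clipped") <- clipped
  out
}

#' Fold overrepresentation of NCG>NTG (CpG C>T) mutations
#'
#' Mean rate of the four NCG>NTG classes divided by the mean rate of all 96
#' classes, computed on genome-normalized rates.
#'
#' @param rates a [triplet_spectrum()] of mode `"rates"` (or `"normalized"`)
#' @return fold overrepresentation (1 = no enrichment)
#' @export
cg_tg_overrepresentation <- function(rates) {
  assert_that(inherits(rates, "triplet_spectrum"),
              "rates must be a triplet_spectrum")
  assert_that(spectrum_mode(rates) %in% c("rates", "normalized"),
              "overrepresentation is defined on rates, not raw counts")
  v <- as.numeric(rates)
  if (mean(v) == 0) stopf("undefined: zero mean rate")
  lab <- triplet_class_labels()
  ncg <- substr(lab, 3, 5) == "C>T" & substr(lab, 7, 7) == "G"
  mean(v[ncg]) / mean(v)
}
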