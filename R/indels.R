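# Deletion context classification (tandem repeat / microhomology / other),
# indel length distributions, and category-table comparisons.

#' A deletion with its reference flanks
#'
#' @param chrom chromosome name
#' @param start 1-based position of the first deleted base
#' @param deleted_sequence the deleted bases (1-50 bp)
#' @param flank5,flank3 reference sequence immediately 5' / 3' of the
#'   deletion, each at least `max(5, deletion length)` bp
#' @param sample_id owning sample
#' @return a `deletion_record`
#' @export
deletion_record <- function(chrom, start, deleted_sequence, flank5, flank3,
                            sample_id = NA_character_) {
  deleted_sequence <- toupper(deleted_sequence)
  flank5 <- toupper(flank5); flank3 <- toupper(flank3)
  L <- nchar(deleted_sequence)
  assert_that(L >= 1 && L <= 50, "deletion length must be in 1..50")
  need <- max(5L, L)
  if (nchar(flank5) < need || nchar(flank3) < need) {
    stopf("flanks too short: need >= %d bp on each side", need)
  }
  structure(list(chrom = chrom, start = as.integer(start),
                 deleted_sequence = deleted_sequence,
                 flank5 = flank5, flank3 = flank3,
                 sample_id = sample_id), class = "deletion_record")
}

# longest prefix of `a` equal to a prefix of `b` (compared base by base)
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- strsplit(a, "")[[1]][seq_len(n)]
  bv <- strsplit(b, "")[[1]][seq_len(n)]
  neq <- which(av != bv)
  if (!length(neq)) n else neq[1] - 1L
}

#' Classify a deletion by its breakpoint sequence context
#'
#' Categories:
#' * `repeat` - the deleted sequence is an exact copy of the reference
#'   immediately 3' (or 5') of the deletion: loss of one unit of a tandem
#'   repeat.
#' * `microhomology` - not a repeat, but `k >= 1` bases overlap between the
#'   deletion and its context: `k` is the larger of (longest prefix of the
#'   deleted sequence matching the start of the 3' flank) and (longest
#'   suffix matching the end of the 5' flank), capped at 5.
#' * `other` - no such overlap (`k = 0`).
#'
#' @param rec a [deletion_record()]
#' @return a `deletion_classification`: list with `record`, `category`,
#'   `microhomology_length` and `evidence`
#' @export
classify_deletion <- function(rec) {
  assert_that(inherits(rec, "deletion_record"), "rec must be a deletion_record")
  del <- rec$deleted_sequence
  L <- nchar(del)
  # full adjacent copy 3' or 5' of the breakpoint?
  rep3 <- substr(rec$flank3, 1, L) == del
  rep5 <- substr(rec$flank5, nchar(rec$flank5) - L + 1, nchar(rec$flank5)) == del
  if (rep3 || rep5) {
    return(structure(list(record = rec, category = "repeat",
                          microhomology_length = 0L,
                          evidence = sprintf("full adjacent copy %s",
                                             if (rep3) "3'" else "5'")),
                     class = "deletion_classification"))
  }
  m3 <- common_prefix_len(del, rec$flank3)
  rdel <- paste(rev(strsplit(del, "")[[1]]), collapse = "")
  rf5 <- paste(rev(strsplit(rec$flank5, "")[[1]]), collapse = "")
  m5 <- common_prefix_len(rdel, rf5)
  k <- max(m3, m5)
  note <- if (k > 5L) sprintf("; overlap %d capped at 5", k) else ""
  k <- min(k, 5L)
  if (k >= 1L) {
    structure(list(record = rec, category = "microhomology",
                   microhomology_length = as.integer(k),
                   evidence = sprintf("overlap 3'=%d, 5'=%d%s", m3, m5, note)),
              class = "deletion_classification")
  } else {
    structure(list(record = rec, category = "other",
                   microhomology_length = 0L,
                   evidence = "no terminal overlap"),
              class = "deletion_classification")
  }
}

#' @export
print.deletion_classification <- function(x, ...) {
  cat(sprintf("deletion %s:%d %s -> %s (k=%d; %s)\n", x$record$chrom,
              x$record$start, x$record$deleted_sequence, x$category,
              x$microhomology_length, x$evidence))
  invisible(x)
}

#' Build deletion records from caller output and classify them
#'
#' Flanks are re-read from the reference (never from the alternate allele).
#' Calls use anchored VCF-style alleles: `pos` is the base before the
#' deletion and `ref` is anchor + deleted sequence.
#'
#' @param calls data.frame of calls (columns sample, chrom, pos, ref, alt,
#'   type); only `type == "DEL"` rows are used
#' @param reference a [Biostrings::DNAStringSet]
#' @param flank flank length to extract (>= 10)
#' @return data.table: sample, chrom, start, length, deleted, category, mh_k
#' @export
classify_deletions_in_calls <- function(calls, reference, flank = 10L) {
  assert_that(flank >= 10L, "flank must be at least 10 bp")
  refstr <- reference_as_strings(reference)
  calls <- as.data.frame(calls)
  dels <- calls[calls$type == "DEL", , drop = FALSE]
  out <- vector("list", nrow(dels))
  for (i in seq_len(nrow(dels))) {
    L <- nchar(dels$ref[i]) - nchar(dels$alt[i])
    start <- dels$pos[i] + 1L          # first deleted base
    s <- refstr[[dels$chrom[i]]]
    fl <- max(flank, L, 5L)
    f5 <- substr(s, max(1L, start - fl), start - 1L)
    f3 <- substr(s, start + L, min(nchar(s), start + L + fl - 1L))
    rec <- deletion_record(dels$chrom[i], start,
                           substr(s, start, start + L - 1L), f5, f3,
                           dels$sample[i])
    cl <- classify_deletion(rec)
    out[[i]] <- data.table::data.table(
      sample = dels$sample[i], chrom = dels$chrom[i], start = start,
      length = L, deleted = rec$deleted_sequence, category = cl$category,
      mh_k = cl$microhomology_length)
  }
  if (!length(out)) {
    return(data.table::data.table(sample = character(0), chrom = character(0),
                                  start = integer(0), length = integer(0),
                                  deleted = character(0),
                                  category = character(0), mh_k = integer(0)))
  }
  data.table::rbindlist(out)
}

#' Indel length histogram per group
#'
#' Default bins follow the conventional presentation: 1, 2-5, 6-10, >10 bp.
#'
#' @param lengths integer indel lengths (1..50)
#' @param group grouping factor (e.g. genotype), recycled
#' @param breaks right-closed bin breaks (default `c(0, 1, 5, 10, Inf)`)
#' @return matrix of counts, one row per group, one column per bin
#' @export
length_distribution <- function(lengths, group = "all",
                                breaks = c(0, 1, 5, 10, Inf)) {
  assert_that(all(lengths >= 1 & lengths <= 50) || length(lengths) == 0,
              "indel lengths must be in 1..50")
  labs <- character(length(breaks) - 1)
  for (i in seq_along(labs)) {
    lo <- breaks[i] + 1; hi <- breaks[i + 1]
    labs[i] <- if (is.infinite(hi)) paste0(">", breaks[i]) else
      if (lo == hi) as.character(hi) else paste0(lo, "-", hi)
  }
  group <- rep_len(as.character(group), length(lengths))
  if (!length(lengths)) {
    m <- matrix(0L, 1, length(labs), dimnames = list("all", labs))
    return(m)
  }
  b <- cut(lengths, breaks = breaks, labels = labs)
  tab <- table(factor(group, levels = unique(group)), b)
  m <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}

#' Exact comparison of deletion-category composition between genotypes
#'
#' Fisher's exact test for independence on a category x genotype count
#' table.
#'
#' @param tab non-negative integer matrix, categories x genotypes (at least
#'   2 x 2, no zero margin)
#' @return a test result with the exact two-sided p-value
#' @export
compare_category_tables <- function(tab) {
  fisher_exact(tab)
}
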