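# Unique-mutation calling for isogenic cohorts: all samples are compared at
# each genomic position, and a variant is accepted only when exactly one
# sample carries it (alternate allele fraction >= 0.2 at coverage >= 5)
# while every other sample is essentially pure reference (reference allele
# fraction >= 0.93). Accepted candidates are then scored with -log10 of the
# two-sided Fisher exact p-value between the mutated sample and the other
# sample with the lowest reference fraction.

#' Caller configuration
#'
#' Defaults follow the optimized filter cascade for isogenic cohorts at
#' 20-30x coverage. `base_quality_cutoff` is documentation only: counts are
#' assumed to be already base-quality filtered upstream.
#'
#' @param min_alt_allele_fraction minimum alternate allele fraction in the
#'   mutated sample
#' @param min_mutated_coverage minimum depth of the mutated sample
#' @param min_other_ref_fraction minimum reference-base fraction required of
#'   every other sample
#' @param min_quality_score minimum `-log10` Fisher p against the noisiest
#'   other sample (2.0 means p <= 0.01)
#' @param max_indel_length longest reported indel (bp)
#' @param base_quality_cutoff upstream base-quality filter (documentation)
#' @return a `caller_config` object
#' @export
caller_config <- function(min_alt_allele_fraction = 0.2,
                          min_mutated_coverage = 5L,
                          min_other_ref_fraction = 0.93,
                          min_quality_score = 2.0,
                          max_indel_length = 50L,
                          base_quality_cutoff = 30L) {
  assert_that(is_fraction(min_alt_allele_fraction) &&
                is_fraction(min_other_ref_fraction),
              "allele-fraction thresholds must be in [0, 1]")
  assert_that(is_count(min_mutated_coverage) && min_mutated_coverage >= 1,
              "min_mutated_coverage must be an integer >= 1")
  assert_that(is.numeric(min_quality_score),
              "min_quality_score must be numeric")
  assert_that(is_count(max_indel_length) && max_indel_length >= 1,
              "max_indel_length must be an integer >= 1")
  structure(list(min_alt_allele_fraction = min_alt_allele_fraction,
                 min_mutated_coverage = as.integer(min_mutated_coverage),
                 min_other_ref_fraction = min_other_ref_fraction,
                 min_quality_score = min_quality_score,
                 max_indel_length = as.integer(max_indel_length),
                 base_quality_cutoff = as.integer(base_quality_cutoff)),
            class = "caller_config")
}

#' Probability-based quality score of a candidate mutation
#'
#' `-log10` of the two-sided Fisher exact p-value of independence for the
#' 2x2 table `[[ref_cand, alt_cand], [ref_comp, alt_comp]]` built from the
#' mutated sample and the comparison sample (the other sample with the
#' lowest reference allele fraction). Larger scores mean stronger evidence
#' that the candidate sample differs from the noisiest other sample.
#'
#' @param candidate_counts integer vector `c(ref, alt)` of the mutated sample
#' @param comparison_counts integer vector `c(ref, alt)` of the comparison
#'   sample
#' @return non-negative numeric score
#' @export
quality_score <- function(candidate_counts, comparison_counts) {
  tab <- rbind(candidate_counts, comparison_counts)
  assert_that(all(tab >= 0) && all(tab == floor(tab)),
              "counts must be non-negative integers")
  if (sum(tab) == 0) stopf("quality score undefined for an all-zero table")
  assert_that(sum(tab[1, ]) >= 1 && sum(tab[2, ]) >= 1,
              "each sample needs at least one observation")
  # a margin of zero alternate reads in both samples carries no signal
  if (any(colSums(tab) == 0)) return(0)
  -log10(fisher_2x2_p(tab))
}

# candidate alleles of one sample's rows: SNV alternates plus this sample's
# indel observations. Returns a data.frame (kind, allele, count) or NULL.
sample_alt_alleles <- function(base_row, indel_rows, cfg) {
  counts <- c(A = base_row$A, C = base_row$C, G = base_row$G, T = base_row$T)
  alt <- counts[names(counts) != base_row$ref]
  out <- data.frame(kind = "SNV", allele = names(alt),
                    count = as.numeric(alt), stringsAsFactors = FALSE)
  if (!is.null(indel_rows) && nrow(indel_rows)) {
    len <- ifelse(indel_rows$kind == "DEL", as.integer(indel_rows$allele),
                  nchar(indel_rows$allele))
    keep <- len <= cfg$max_indel_length
    if (any(keep)) {
      out <- rbind(out, data.frame(kind = indel_rows$kind[keep],
                                   allele = indel_rows$allele[keep],
                                   count = as.numeric(indel_rows$count[keep]),
                                   stringsAsFactors = FALSE))
    }
  }
  out[out$count > 0, , drop = FALSE]
}

#' Screen one genomic position across all samples
#'
#' Emits a candidate only when exactly one sample shows an alternate allele
#' at fraction >= `min_alt_allele_fraction` with depth >=
#' `min_mutated_coverage`, every other sample has reference-base fraction >=
#' `min_other_ref_fraction`, and no other sample has zero depth (cleanliness
#' cannot be certified there). The candidate records the comparison sample:
#' the other sample with the lowest reference fraction (first in input order
#' among ties).
#'
#' @param bases data.frame with one row per sample: sample, chrom, pos, ref,
#'   A, C, G, T, depth
#' @param indels optional data.frame (sample, kind, allele, count) of indel
#'   observations at this position
#' @param cfg a [caller_config()]
#' @return a candidate list or `NULL`
#' @export
screen_position <- function(bases, indels = NULL, cfg = caller_config()) {
  assert_that(nrow(bases) >= 2, "need at least two samples at a position")
  assert_that(length(unique(bases$chrom)) == 1L &&
                length(unique(bases$pos)) == 1L,
              "screen_position expects rows of a single position")
  if (length(unique(bases$ref)) != 1L) {
    stopf("inconsistent reference base at %s:%d", bases$chrom[1], bases$pos[1])
  }
  ns <- nrow(bases)
  # column named by the reference base gives each sample's reference count
  refc <- as.numeric(bases[[bases$ref[1]]])
  depth <- as.numeric(bases$depth)
  ref_frac <- ifelse(depth > 0, refc / depth, NA_real_)

  best <- vector("list", ns)
  is_cand <- logical(ns)
  for (i in seq_len(ns)) {
    if (depth[i] < cfg$min_mutated_coverage || depth[i] == 0) next
    irows <- if (!is.null(indels) && nrow(indels)) {
      indels[indels$sample == bases$sample[i], , drop = FALSE]
    } else NULL
    alleles <- sample_alt_alleles(bases[i, , drop = FALSE], irows, cfg)
    if (!nrow(alleles)) next
    frac <- alleles$count / depth[i]
    pass <- frac >= cfg$min_alt_allele_fraction
    if (!any(pass)) next
    alleles <- alleles[pass, , drop = FALSE]
    frac <- frac[pass]
    # deterministic tie-break: highest fraction, then SNV < INS < DEL,
    # then allele string
    ord <- order(-frac, match(alleles$kind, c("SNV", "INS", "DEL")),
                 alleles$allele)
    best[[i]] <- alleles[ord[1], , drop = FALSE]
    is_cand[i] <- TRUE
  }
  if (sum(is_cand) != 1L) return(NULL)
  ci <- which(is_cand)
  others <- setdiff(seq_len(ns), ci)
  if (any(depth[others] == 0)) return(NULL)
  if (any(ref_frac[others] < cfg$min_other_ref_fraction)) return(NULL)
  comp <- others[which.min(ref_frac[others])]
  allele <- best[[ci]]
  comp_alt <- if (allele$kind == "SNV") {
    as.numeric(bases[[allele$allele]][comp])
  } else if (!is.null(indels) && nrow(indels)) {
    hit <- indels$sample == bases$sample[comp] &
      indels$kind == allele$kind & indels$allele == allele$allele
    if (any(hit)) sum(as.numeric(indels$count[hit])) else 0
  } else 0
  list(sample = as.character(bases$sample[ci]),
       chrom = as.character(bases$chrom[1]), pos = bases$pos[1],
       ref_base = bases$ref[1],
       kind = allele$kind, allele = allele$allele,
       alt_count = allele$count, depth = depth[ci],
       ref_count = refc[ci],
       alt_fraction = allele$count / depth[ci],
       comparison_sample = as.character(bases$sample[comp]),
       comp_ref_count = refc[comp], comp_alt_count = comp_alt)
}

#' Call unique mutations across an isogenic cohort
#'
#' Runs the position screen over every represented position and keeps
#' candidates whose quality score reaches `cfg$min_quality_score`. Positions
#' missing one or more samples are skipped with a warning. Output is sorted
#' by (chrom, pos, sample) and is independent of how the input was chunked.
#'
#' @param counts a `position_counts` object (see [simulate_pileup_counts()]
#'   and [read_counts_tsv()])
#' @param cfg a [caller_config()]
#' @param reference optional [Biostrings::DNAStringSet]; when supplied,
#'   anchored VCF-style ref/alt alleles are emitted for indels
#' @return data.table of calls: sample, chrom, pos, ref, alt, type, af,
#'   depth, score, comparison_sample
#' @export
call_unique_mutations <- function(counts, cfg = caller_config(),
                                  reference = NULL) {
  assert_that(inherits(counts, "position_counts"),
              "counts must be a position_counts object")
  bases <- counts$bases
  indels <- counts$indels
  samples <- counts$samples
  ns <- length(samples)
  assert_that(ns >= 2, "need at least two samples")
  empty <- data.table::data.table(
    sample = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), type = character(0),
    af = numeric(0), depth = integer(0), score = numeric(0),
    comparison_sample = character(0))
  if (nrow(bases) == 0) return(empty)
  # enforce position-sorted input per chromosome
  dpos <- diff(bases$pos)
  newchrom <- bases$chrom[-1] != bases$chrom[-nrow(bases)]
  if (any(dpos < 0 & !newchrom)) stopf("input counts are not position-sorted")

  key <- paste(bases$chrom, bases$pos)
  nper <- table(key)
  incomplete <- names(nper)[nper < ns]
  if (length(incomplete)) {
    warning(sprintf("%d position(s) missing one or more samples; skipped",
                    length(incomplete)), call. = FALSE)
  }

  # vectorized prescreen: only positions where some sample could be a
  # candidate are examined in detail
  cmat <- cbind(bases$A, bases$C, bases$G, bases$T)
  refidx <- match(bases$ref, BASES)
  cmat2 <- cmat
  cmat2[cbind(seq_len(nrow(bases)), refidx)] <- -1L
  altmax <- apply(cmat2, 1, max)
  snv_hit <- bases$depth >= cfg$min_mutated_coverage &
    altmax / pmax(bases$depth, 1) >= cfg$min_alt_allele_fraction
  hot <- unique(key[snv_hit])
  if (nrow(indels)) {
    ikey <- paste(indels$chrom, indels$pos)
    dt <- merge(indels,
                bases[, c("sample", "chrom", "pos", "depth")],
                by = c("sample", "chrom", "pos"))
    ihit <- dt$depth >= cfg$min_mutated_coverage &
      dt$count / pmax(dt$depth, 1) >= cfg$min_alt_allele_fraction
    hot <- unique(c(hot, paste(dt$chrom, dt$pos)[ihit]))
  }
  hot <- setdiff(hot, incomplete)
  if (!length(hot)) return(empty)

  bkey <- key
  bsub <- bases[bkey %in% hot, ]
  isub <- if (nrow(indels)) {
    indels[paste(indels$chrom, indels$pos) %in% hot, ]
  } else indels
  refstr <- if (!is.null(reference)) reference_as_strings(reference) else NULL

  bgrp <- split(seq_len(nrow(bsub)), paste(bsub$chrom, bsub$pos))
  igrp <- if (nrow(isub)) {
    split(seq_len(nrow(isub)), paste(isub$chrom, isub$pos))
  } else list()
  out <- list()
  for (k in hot) {
    brows <- bsub[bgrp[[k]], ]
    irows <- if (!is.null(igrp[[k]])) isub[igrp[[k]], ] else NULL
    cand <- screen_position(brows, irows, cfg)
    if (is.null(cand)) next
    score <- quality_score(c(cand$ref_count, cand$alt_count),
                           c(cand$comp_ref_count, cand$comp_alt_count))
    if (score < cfg$min_quality_score) next
    if (cand$kind == "SNV") {
      refa <- cand$ref_base; alta <- cand$allele
    } else if (cand$kind == "INS") {
      refa <- cand$ref_base; alta <- paste0(cand$ref_base, cand$allele)
    } else {
      L <- as.integer(cand$allele)
      if (!is.null(refstr) && !is.null(refstr[[cand$chrom]])) {
        refa <- substr(refstr[[cand$chrom]], cand$pos, cand$pos + L)
        alta <- substr(refstr[[cand$chrom]], cand$pos, cand$pos)
      } else {
        refa <- cand$ref_base
        alta <- sprintf("<DEL:%d>", L)
      }
    }
    out[[length(out) + 1L]] <- data.table::data.table(
      sample = cand$sample, chrom = cand$chrom, pos = as.integer(cand$pos),
      ref = refa, alt = alta, type = cand$kind,
      af = cand$alt_fraction, depth = as.integer(cand$depth),
      score = score, comparison_sample = cand$comparison_sample)
  }
  if (!length(out)) return(empty)
  calls <- data.table::rbindlist(out)
  data.table::setorderv(calls, c("chrom", "pos", "sample"))
  calls
}
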