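# Noisy per-position allele-count simulation. The caller consumes counts,
# not reads: base-quality filtering is modelled as already applied, and the
# per-base error substitutes uniformly among the three non-reference bases.

#' Specify the sequencing noise model
#'
#' Coverage at each site is drawn once per sample from a negative binomial
#' with the given mean and dispersion (Poisson when `coverage_dispersion`
#' is 0). `per_base_error` is the probability that a read reports a wrong
#' base, substituted uniformly among the three non-reference bases.
#'
#' @param mean_coverage mean reads per site (> 0)
#' @param coverage_dispersion negative-binomial dispersion (`size` =
#'   `mean_coverage / coverage_dispersion`); 0 means Poisson
#' @param per_base_error per-read-base error fraction in `[0, 1]`
#' @return a `noise_model` object
#' @export
noise_model <- function(mean_coverage = 25, coverage_dispersion = 0,
                        per_base_error = 0.002) {
  assert_that(is.numeric(mean_coverage) && mean_coverage > 0,
              "mean_coverage must be positive")
  assert_that(is.numeric(coverage_dispersion) && coverage_dispersion >= 0,
              "coverage_dispersion must be >= 0")
  assert_that(is_fraction(per_base_error), "per_base_error must be in [0, 1]")
  structure(list(mean_coverage = mean_coverage,
                 coverage_dispersion = coverage_dispersion,
                 per_base_error = per_base_error), class = "noise_model")
}

draw_coverage <- function(n, noise) {
  if (noise$coverage_dispersion == 0) {
    stats::rpois(n, noise$mean_coverage)
  } else {
    stats::rnbinom(n, mu = noise$mean_coverage,
                   size = noise$mean_coverage / noise$coverage_dispersion)
  }
}

# distribute e error reads among the 3 non-reference bases (uniformly);
# returns an n x 4 count matrix in A,C,G,T order
distribute_errors <- function(err_n, ref_code) {
  n <- length(err_n)
  m <- matrix(0L, n, 4L)
  pos1 <- which(err_n == 1L)
  if (length(pos1)) {
    pick <- sample.int(3L, length(pos1), replace = TRUE)
    for (j in seq_along(pos1)) {
      ob <- (1:4)[-ref_code[pos1[j]]]
      m[pos1[j], ob[pick[j]]] <- 1L
    }
  }
  posm <- which(err_n >= 2L)
  for (j in posm) {
    ob <- (1:4)[-ref_code[j]]
    cnt <- stats::rmultinom(1, err_n[j], rep(1 / 3, 3))
    m[j, ob] <- cnt[, 1]
  }
  m
}

#' Simulate per-position allele counts for every sample
#'
#' Implanted mutations and germline sites are heterozygous: the alternate
#' allele is carried by `Binomial(coverage, 0.5)` reads; sequencing errors
#' are then applied to the remaining reference-allele reads. Positions where
#' no sample shows any non-reference observation are omitted (they can never
#' yield a candidate), but at every emitted position a row is written for
#' every sample so the caller can certify cleanliness.
#'
#' @param reference a [Biostrings::DNAStringSet]
#' @param truth a `cohort_truth` from [implant_mutations()]
#' @param noise a [noise_model()]
#' @param seed integer master seed for the count streams (default: the truth
#'   set's seed)
#' @return a `position_counts` object with `$bases` (data.table: sample,
#'   chrom, pos, ref, A, C, G, T, depth) and `$indels` (sample, chrom, pos,
#'   kind INS/DEL, allele inserted-sequence or deletion-length, count)
#' @export
simulate_pileup_counts <- function(reference, truth, noise,
                                   seed = truth$seed) {
  assert_that(inherits(truth, "cohort_truth"), "truth must be a cohort_truth")
  assert_that(inherits(noise, "noise_model"), "noise must be a noise_model")
  refstr <- reference_as_strings(reference)
  chroms <- names(refstr)
  lens <- nchar(refstr)
  sample_ids <- truth$samples$sample_id
  muts <- truth$mutations
  germ <- truth$germline
  bad <- muts[!muts$chrom %in% chroms | muts$pos < 1 |
                muts$pos > lens[muts$chrom], ]
  assert_that(nrow(bad) == 0, "truth contains positions outside the genome")

  base_rows <- list()
  indel_rows <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    len <- lens[ci]
    ref_codes <- match(strsplit(refstr[[ch]], "")[[1]], BASES)
    cmut <- muts[muts$chrom == ch, ]
    cgerm <- germ[germ$chrom == ch, ]
    cov_l <- list(); err_l <- list()
    interesting <- sort(unique(c(cmut$pos, cgerm$pos)))
    for (s in sample_ids) {
      cov <- with_seed(derive_seed(seed, "coverage", s, ch),
                       draw_coverage(len, noise))
      err <- with_seed(derive_seed(seed, "error", s, ch),
                       stats::rbinom(len, cov, noise$per_base_error))
      cov_l[[s]] <- cov
      err_l[[s]] <- err
      interesting <- c(interesting, which(err > 0L))
    }
    pos <- sort(unique(interesting))
    if (length(pos) == 0L) next
    rcode <- ref_codes[pos]
    for (s in sample_ids) {
      cov <- cov_l[[s]][pos]
      err <- err_l[[s]][pos]
      counts <- matrix(0L, length(pos), 4L)
      alt_reads <- integer(length(pos))

      with_seed(derive_seed(seed, "alleles", s, ch), {
        # sample-private implants
        smut <- cmut[cmut$sample == s, ]
        if (nrow(smut)) {
          mp <- match(smut$pos, pos)
          carriers <- stats::rbinom(nrow(smut), cov[mp], 0.5)
          alt_reads[mp] <- alt_reads[mp] + carriers
          snv <- smut$class == "SNV"
          if (any(snv)) {
            acode <- match(smut$alt[snv], BASES)
            idx <- cbind(mp[snv], acode)
            counts[idx] <- counts[idx] + carriers[snv]
          }
          indel <- which(!snv)
          for (j in indel) {
            if (carriers[j] == 0L) next
            kind <- smut$class[j]
            akey <- if (kind == "DEL") {
              as.character(nchar(smut$ref[j]) - 1L)
            } else {
              substr(smut$alt[j], 2L, nchar(smut$alt[j]))
            }
            indel_rows[[length(indel_rows) + 1L]] <- data.table::data.table(
              sample = s, chrom = ch, pos = smut$pos[j], kind = kind,
              allele = akey, count = carriers[j])
          }
        }
        # shared germline heterozygous sites
        if (nrow(cgerm)) {
          gp <- match(cgerm$pos, pos)
          gcar <- stats::rbinom(nrow(cgerm), cov[gp], 0.5)
          alt_reads[gp] <- alt_reads[gp] + gcar
          gcode <- match(cgerm$alt, BASES)
          idx <- cbind(gp, gcode)
          counts[idx] <- counts[idx] + gcar
        }
        # errors hit the remaining reference reads only; re-draw at carrier
        # sites where the genome-wide draw used the full coverage
        att <- which(alt_reads > 0L)
        if (length(att)) {
          err[att] <- stats::rbinom(length(att), cov[att] - alt_reads[att],
                                    noise$per_base_error)
        }
        emat <- distribute_errors(err, rcode)
      })
      counts <- counts + emat
      refn <- cov - alt_reads - err
      idx <- cbind(seq_along(pos), rcode)
      counts[idx] <- counts[idx] + refn
      base_rows[[paste(ch, s)]] <- data.table::data.table(
        sample = s, chrom = ch, pos = pos, ref = BASES[rcode],
        A = counts[, 1], C = counts[, 2], G = counts[, 3], T = counts[, 4],
        depth = cov)
    }
  }
  bases <- if (length(base_rows)) data.table::rbindlist(base_rows) else
    data.table::data.table(sample = character(0), chrom = character(0),
                           pos = integer(0), ref = character(0),
                           A = integer(0), C = integer(0), G = integer(0),
                           T = integer(0), depth = integer(0))
  indels <- if (length(indel_rows)) data.table::rbindlist(indel_rows) else
    data.table::data.table(sample = character(0), chrom = character(0),
                           pos = integer(0), kind = character(0),
                           allele = character(0), count = integer(0))
  bases$sample <- factor(bases$sample, levels = sample_ids)
  data.table::setorderv(bases, c("chrom", "pos", "sample"))
  bases$sample <- as.character(bases$sample)
  data.table::setorderv(indels, c("chrom", "pos", "sample"))
  structure(list(bases = bases, indels = indels, samples = sample_ids),
            class = "position_counts")
}

#' @export
print.position_counts <- function(x, ...) {
  cat(sprintf("position_counts: %d samples, %d positions, %d indel records\n",
              length(x$samples),
              length(unique(paste(x$bases$chrom, x$bases$pos))),
              nrow(x$indels)))
  invisible(x)
}
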