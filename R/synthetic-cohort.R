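# Synthetic isogenic cohorts: sample-private SNVs and short indels implanted
# on a shared reference, plus shared germline heterozygous sites. The truth
# set records every implant for downstream recovery scoring.

#' Specify a synthetic isogenic cohort
#'
#' Burdens may be a single value (applied to every sample) or one value per
#' sample. Implants are heterozygous and private to one sample; all samples
#' share the germline heterozygous sites. By default no two implanted events
#' lie within `min_spacing` bp of each other, which makes the rainfall
#' clustering null hold by construction and keeps truth/call matching
#' unambiguous; set `min_spacing = 0` to allow clustering.
#'
#' @param samples character vector of unique sample ids, or a data.frame
#'   with columns `sample_id` and `genotype`
#' @param snv_burden,ins_burden,del_burden non-negative integer burdens per
#'   sample (scalar or per-sample vector)
#' @param snv_spectrum a [triplet_spectrum()] used as sampling distribution
#'   over the 96 classes (default uniform)
#' @param deletion_mix fractions for the (repeat, microhomology, other)
#'   deletion context categories; must sum to 1
#' @param deletion_lengths probability weights over deletion/insertion
#'   lengths 1..50 (default: half the events 1 bp, geometric tail)
#' @param mh_k_weights weights over microhomology lengths 1..5
#' @param germline_het_density shared heterozygous sites per bp
#' @param min_spacing minimum distance (bp) between implanted events and
#'   germline sites
#' @param seed integer seed
#' @return a `cohort_spec` object
#' @export
cohort_spec <- function(samples,
                        snv_burden = 0L,
                        ins_burden = 0L,
                        del_burden = 0L,
                        snv_spectrum = NULL,
                        deletion_mix = c(repeat_ = 0.4, microhomology = 0.3,
                                         other = 0.3),
                        deletion_lengths = NULL,
                        mh_k_weights = rep(1, 5),
                        germline_het_density = 1e-4,
                        min_spacing = 100L,
                        seed = 1L) {
  if (is.data.frame(samples)) {
    assert_that(all(c("sample_id", "genotype") %in% names(samples)),
                "samples data.frame needs sample_id and genotype columns")
    meta <- data.frame(sample_id = as.character(samples$sample_id),
                       genotype = as.character(samples$genotype),
                       stringsAsFactors = FALSE)
  } else {
    meta <- data.frame(sample_id = as.character(samples),
                       genotype = "NA", stringsAsFactors = FALSE)
  }
  assert_that(!anyDuplicated(meta$sample_id), "sample ids must be unique")
  ns <- nrow(meta)
  expand <- function(x, what) {
    assert_that(all(vapply(x, is_count, logical(1))),
                "%s burden must be non-negative integers", what)
    assert_that(length(x) %in% c(1L, ns),
                "%s burden must be scalar or one per sample", what)
    as.integer(rep_len(x, ns))
  }
  if (is.null(snv_spectrum)) {
    snv_spectrum <- triplet_spectrum(rep(1 / 96, 96), mode = "normalized")
  }
  assert_that(inherits(snv_spectrum, "triplet_spectrum"),
              "snv_spectrum must be a triplet_spectrum")
  assert_that(sum(snv_spectrum) > 0, "snv_spectrum must have positive mass")
  assert_that(length(deletion_mix) == 3L && all(deletion_mix >= 0),
              "deletion_mix must be 3 non-negative fractions")
  assert_that(abs(sum(deletion_mix) - 1) <= 1e-9, "deletion_mix must sum to 1")
  if (is.null(deletion_lengths)) {
    deletion_lengths <- c(0.5, 0.5 * 0.65 ^ (0:48) * 0.35)
  }
  assert_that(length(deletion_lengths) == 50L && all(deletion_lengths >= 0) &&
                sum(deletion_lengths) > 0,
              "deletion_lengths must be 50 non-negative weights")
  assert_that(length(mh_k_weights) == 5L && all(mh_k_weights >= 0) &&
                sum(mh_k_weights) > 0,
              "mh_k_weights must be 5 non-negative weights")
  assert_that(is.numeric(germline_het_density) && germline_het_density >= 0,
              "germline_het_density must be >= 0")
  structure(list(
    samples = meta,
    snv_burden = expand(snv_burden, "SNV"),
    ins_burden = expand(ins_burden, "insertion"),
    del_burden = expand(del_burden, "deletion"),
    snv_spectrum = snv_spectrum / sum(snv_spectrum),
    deletion_mix = stats::setNames(as.numeric(deletion_mix),
                                   c("repeat", "microhomology", "other")),
    deletion_lengths = deletion_lengths / sum(deletion_lengths),
    mh_k_weights = mh_k_weights / sum(mh_k_weights),
    germline_het_density = germline_het_density,
    min_spacing = as.integer(min_spacing),
    seed = as.integer(seed)), class = "cohort_spec")
}

# ---- internal: interval registry enforcing event spacing -------------------

new_registry <- function(chroms) {
  env <- new.env(parent = emptyenv())
  for (ch in chroms) assign(ch, list(s = numeric(0), e = numeric(0)), env)
  env
}

registry_free <- function(reg, chrom, start, end, spacing) {
  iv <- get(chrom, reg)
  if (length(iv$s) == 0L) return(TRUE)
  !any(start <= iv$e + spacing & end >= iv$s - spacing)
}

registry_reserve <- function(reg, chrom, start, end) {
  iv <- get(chrom, reg)
  iv$s <- c(iv$s, start)
  iv$e <- c(iv$e, end)
  assign(chrom, iv, reg)
}

# ---- internal: deletion context site scanning ------------------------------

# Overlap run-lengths for a deletion of length L whose first deleted base is
# at position p (1-based) of the base-code vector `codes`:
#   m3 = longest prefix of the deleted sequence equal to the sequence
#        immediately 3' of the deletion;
#   m5 = longest suffix of the deleted sequence equal to the sequence
#        immediately 5' of the deletion.
# Comparisons are capped at `cap` bases. Returns a list with integer vectors
# m3 and m5 over all positions (NA outside the valid range).
deletion_overlap_runs <- function(codes, L, cap) {
  n <- length(codes)
  m3 <- integer(n)
  m5 <- integer(n)
  p <- seq_len(n)
  alive3 <- rep(TRUE, n)
  alive5 <- rep(TRUE, n)
  for (i in seq_len(cap)) {
    # prefix vs 3' flank: codes[p + i - 1] == codes[p + L + i - 1]
    i1 <- p + i - 1L
    i2 <- p + L + i - 1L
    okidx <- i2 <= n
    cmp <- rep(FALSE, n)
    cmp[okidx] <- codes[i1[okidx]] == codes[i2[okidx]]
    alive3 <- alive3 & cmp
    m3 <- m3 + alive3
    # suffix vs 5' flank: codes[p + L - i] == codes[p - i]
    j1 <- p + L - i
    j2 <- p - i
    okidx <- j2 >= 1L & j1 <= n
    cmp <- rep(FALSE, n)
    cmp[okidx] <- codes[j1[okidx]] == codes[j2[okidx]]
    alive5 <- alive5 & cmp
    m5 <- m5 + alive5
  }
  list(m3 = m3, m5 = m5)
}

# Candidate first-deleted-base positions for a deletion of length L in a
# given context category (and microhomology length k), leaving `margin` bp of
# clean flank at the chromosome ends.
deletion_site_pool <- function(codes, L, category, k = 0L, margin = 12L) {
  n <- length(codes)
  cap <- max(L, 6L)
  runs <- deletion_overlap_runs(codes, L, cap)
  is_repeat <- runs$m3 >= L | runs$m5 >= L
  k3 <- pmin(runs$m3, 5L)
  k5 <- pmin(runs$m5, 5L)
  # microhomology sites carry the canonical 3' form: the first k deleted
  # bases recur right after the breakpoint, and no longer overlap exists on
  # the 5' side, so the classifier reports exactly k
  sel <- switch(category,
    "repeat" = is_repeat,
    "microhomology" = !is_repeat & k5 <= k3 &
      (if (k < 5L) k3 == k else k3 >= 5L),
    "other" = !is_repeat & k3 == 0L & k5 == 0L,
    stopf("unknown deletion category '%s'", category))
  pos <- which(sel)
  pos[pos > margin & pos + L + margin <= n]
}

# ---- implant_mutations -----------------------------------------------------

#' Implant sample-private mutations and shared germline sites
#'
#' SNV positions are sampled so that their pyrimidine-centred triplet
#' contexts follow `cohort$snv_spectrum`, restricted to triplets present in
#' the reference. Microhomology deletions are placed at loci where exactly
#' `k` bases (1-5) of the deleted sequence recur at the deletion breakpoint
#' (and the deleted sequence is not a full adjacent copy); repeat deletions
#' are full adjacent copies of the deleted sequence.
#'
#' @param reference a [Biostrings::DNAStringSet]
#' @param cohort a [cohort_spec()]
#' @return a `cohort_truth` object: `$mutations` (data.table with columns
#'   sample, chrom, pos, ref, alt, class, category, mh_k, spectrum_class),
#'   `$germline` (chrom, pos, ref, alt) and `$samples`
#' @export
implant_mutations <- function(reference, cohort) {
  assert_that(inherits(cohort, "cohort_spec"), "cohort must be a cohort_spec")
  refstr <- reference_as_strings(reference)
  chroms <- names(refstr)
  lens <- nchar(refstr)
  codes <- lapply(refstr, function(s) {
    match(strsplit(s, "")[[1]], BASES)
  })
  reg <- new_registry(chroms)
  spacing <- cohort$min_spacing
  seed <- cohort$seed

  # per-chromosome pyrimidine-collapsed triplet bin (1..32) of interior sites
  pyr <- pyrimidine_triplets()
  # map 64 forward triplet codes -> 32 bin index; code = 16(a-1)+4(b-1)+c
  trip64 <- apply(expand.grid(f3 = BASES, ctr = BASES, f5 = BASES)[, 3:1],
                  1, paste, collapse = "")
  code_of <- function(t) {
    b <- match(strsplit(t, "")[[1]], BASES)
    16L * (b[1] - 1L) + 4L * (b[2] - 1L) + b[3]
  }
  bin_of_code <- integer(64)
  for (t in trip64) {
    central <- substr(t, 2, 2)
    canon <- if (central %in% c("C", "T")) t else reverse_complement(t)
    bin_of_code[code_of(t)] <- match(canon, pyr)
  }
  # site pools per chromosome per bin (interior positions only)
  pools <- lapply(chroms, function(ch) {
    b <- codes[[ch]]
    n <- length(b)
    if (n < 3L) return(vector("list", 32))
    p <- 2:(n - 1L)
    tc <- 16L * (b[p - 1L] - 1L) + 4L * (b[p] - 1L) + b[p + 1L]
    bins <- bin_of_code[tc]
    keep <- p > 12L & p < n - 12L  # leave flank room at chromosome ends
    split(p[keep], factor(bins[keep], levels = 1:32))
  })
  names(pools) <- chroms
  pool_sizes <- vapply(pools, function(x) vapply(x, length, integer(1)),
                       integer(32))
  if (is.null(dim(pool_sizes))) pool_sizes <- matrix(pool_sizes, nrow = 32)

  reserve_event <- function(chrom, start, end) {
    registry_reserve(reg, chrom, start, end)
  }

  # ---- germline heterozygous sites (shared by all samples) ----
  germ <- data.table::data.table(chrom = character(0), pos = integer(0),
                                 ref = character(0), alt = character(0))
  if (cohort$germline_het_density > 0) {
    rows <- list()
    for (ci in seq_along(chroms)) {
      ch <- chroms[ci]
      with_seed(derive_seed(seed, "germline", ch), {
        ng <- stats::rpois(1, cohort$germline_het_density * lens[ci])
        got <- 0L
        tries <- 0L
        pos_acc <- integer(0)
        while (got < ng && tries < ng * 200 + 200) {
          tries <- tries + 1L
          p <- sample.int(lens[ci] - 24L, 1L) + 12L
          if (registry_free(reg, ch, p, p, spacing)) {
            reserve_event(ch, p, p)
            pos_acc <- c(pos_acc, p)
            got <- got + 1L
          }
        }
        if (got < ng) stopf("capacity: cannot place %d germline sites on %s",
                            ng, ch)
        if (got > 0L) {
          refb <- BASES[codes[[ch]][pos_acc]]
          altb <- vapply(refb, function(r) sample(setdiff(BASES, r), 1L),
                         character(1))
          rows[[ch]] <- data.table::data.table(chrom = ch, pos = pos_acc,
                                               ref = refb, alt = unname(altb))
        }
      })
    }
    if (length(rows)) germ <- data.table::rbindlist(rows)
  }

  # ---- SNVs ----
  cls_trip <- class_triplets()                    # triplet of class 1..96
  cls_alt <- substr(triplet_class_labels(), 5, 5) # alt base of class 1..96
  trip_bin <- match(cls_trip, pyr)                # 32-bin of class 1..96
  avail_bin <- rowSums(pool_sizes) > 0
  class_weights <- as.numeric(cohort$snv_spectrum) * avail_bin[trip_bin]
  mut_rows <- list()
  for (si in seq_len(nrow(cohort$samples))) {
    sid <- cohort$samples$sample_id[si]
    nb <- cohort$snv_burden[si]
    if (nb == 0L) next
    assert_that(sum(class_weights) > 0,
                "no requested SNV triplet context present in the reference")
    with_seed(derive_seed(seed, "snv", sid), {
      ncls <- as.vector(stats::rmultinom(1, nb, class_weights))
      recs <- vector("list", 96)
      for (cl in which(ncls > 0L)) {
        bin <- trip_bin[cl]
        sizes <- pool_sizes[bin, ]
        need <- ncls[cl]
        got <- 0L
        tries <- 0L
        acc_ch <- character(need); acc_p <- integer(need)
        acc_ref <- character(need); acc_alt <- character(need)
        while (got < need && tries < need * 500 + 500) {
          tries <- tries + 1L
          ci <- sample.int(length(chroms), 1L, prob = sizes)
          pool <- pools[[ci]][[bin]]
          p <- pool[sample.int(length(pool), 1L)]
          ch <- chroms[ci]
          if (!registry_free(reg, ch, p, p, spacing)) next
          reserve_event(ch, p, p)
          got <- got + 1L
          ctr <- BASES[codes[[ch]][p]]
          alt <- if (ctr %in% c("C", "T")) cls_alt[cl] else
            unname(BASE_COMPLEMENT[cls_alt[cl]])
          acc_ch[got] <- ch; acc_p[got] <- p
          acc_ref[got] <- ctr; acc_alt[got] <- alt
        }
        if (got < need) {
          stopf("capacity: could not place %d SNVs of class %s for %s",
                need, triplet_class_labels()[cl], sid)
        }
        recs[[cl]] <- data.table::data.table(
          sample = sid, chrom = acc_ch, pos = acc_p, ref = acc_ref,
          alt = acc_alt, class = "SNV", category = NA_character_,
          mh_k = NA_integer_, spectrum_class = cl)
      }
      mut_rows[[paste0("snv.", sid)]] <- data.table::rbindlist(recs)
    })
  }

  # ---- deletions ----
  del_pool_cache <- new.env(parent = emptyenv())
  get_del_pool <- function(category, L, k) {
    key <- paste(category, L, k, sep = ":")
    if (!is.null(del_pool_cache[[key]])) return(del_pool_cache[[key]])
    pl <- lapply(chroms, function(ch) {
      deletion_site_pool(codes[[ch]], L, category, k)
    })
    names(pl) <- chroms
    del_pool_cache[[key]] <- pl
    pl
  }
  for (si in seq_len(nrow(cohort$samples))) {
    sid <- cohort$samples$sample_id[si]
    nd <- cohort$del_burden[si]
    if (nd == 0L) next
    with_seed(derive_seed(seed, "del", sid), {
      recs <- vector("list", nd)
      for (j in seq_len(nd)) {
        placed <- FALSE
        for (attempt in seq_len(500)) {
          category <- sample(names(cohort$deletion_mix), 1L,
                             prob = cohort$deletion_mix)
          lw <- cohort$deletion_lengths
          if (category == "microhomology") {
            # microhomology requires L >= 2 (an L=1 adjacent copy is a repeat)
            lw <- lw * c(0, rep(1, 49))
          }
          L <- sample.int(50L, 1L, prob = lw)
          k <- if (category == "microhomology") {
            kw <- cohort$mh_k_weights * (seq_len(5) <= L - 1L)
            if (sum(kw) == 0) next
            sample.int(5L, 1L, prob = kw)
          } else 0L
          pl <- get_del_pool(category, L, k)
          sizes <- vapply(pl, length, integer(1))
          if (sum(sizes) == 0L) next
          ci <- sample.int(length(chroms), 1L, prob = sizes)
          pool <- pl[[ci]]
          p <- pool[sample.int(length(pool), 1L)]
          ch <- chroms[ci]
          if (!registry_free(reg, ch, p - 1L, p + L - 1L, spacing)) next
          reserve_event(ch, p - 1L, p + L - 1L)
          recs[[j]] <- data.table::data.table(
            sample = sid, chrom = ch, pos = p - 1L,
            ref = substr(refstr[[ch]], p - 1L, p + L - 1L),
            alt = substr(refstr[[ch]], p - 1L, p - 1L),
            class = "DEL", category = category, mh_k = k,
            spectrum_class = NA_integer_)
          placed <- TRUE
          break
        }
        if (!placed) {
          stopf("capacity: could not place deletion %d for sample %s", j, sid)
        }
      }
      mut_rows[[paste0("del.", sid)]] <- data.table::rbindlist(recs)
    })
  }

  # ---- insertions ----
  for (si in seq_len(nrow(cohort$samples))) {
    sid <- cohort$samples$sample_id[si]
    ni <- cohort$ins_burden[si]
    if (ni == 0L) next
    with_seed(derive_seed(seed, "ins", sid), {
      recs <- vector("list", ni)
      for (j in seq_len(ni)) {
        placed <- FALSE
        for (attempt in seq_len(500)) {
          ci <- sample.int(length(chroms), 1L, prob = lens)
          p <- sample.int(lens[ci] - 24L, 1L) + 12L
          ch <- chroms[ci]
          if (!registry_free(reg, ch, p, p, spacing)) next
          L <- sample.int(50L, 1L, prob = cohort$deletion_lengths)
          insseq <- paste(sample(BASES, L, replace = TRUE), collapse = "")
          reserve_event(ch, p, p)
          anchor <- substr(refstr[[ch]], p, p)
          recs[[j]] <- data.table::data.table(
            sample = sid, chrom = ch, pos = p, ref = anchor,
            alt = paste0(anchor, insseq), class = "INS",
            category = NA_character_, mh_k = NA_integer_,
            spectrum_class = NA_integer_)
          placed <- TRUE
          break
        }
        if (!placed) {
          stopf("capacity: could not place insertion %d for sample %s", j, sid)
        }
      }
      mut_rows[[paste0("ins.", sid)]] <- data.table::rbindlist(recs)
    })
  }

  muts <- if (length(mut_rows)) data.table::rbindlist(mut_rows) else
    data.table::data.table(sample = character(0), chrom = character(0),
                           pos = integer(0), ref = character(0),
                           alt = character(0), class = character(0),
                           category = character(0), mh_k = integer(0),
                           spectrum_class = integer(0))
  data.table::setorderv(muts, c("chrom", "pos", "sample"))
  data.table::setorderv(germ, c("chrom", "pos"))
  structure(list(mutations = muts, germline = germ,
                 samples = cohort$samples, seed = seed),
            class = "cohort_truth")
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("cohort_truth: %d samples, %d implanted mutations (%s), %d germline sites\n",
              nrow(x$samples), nrow(x$mutations),
              paste(sprintf("%s=%d", names(table(x$mutations$class)),
                            as.integer(table(x$mutations$class))),
                    collapse = ", "),
              nrow(x$germline)))
  invisible(x)
}

#' Write / read a truth set as a VCF-like TSV
#'
#' Columns: sample, chrom, pos (1-based, anchored VCF-style for indels),
#' ref, alt, class, category, mh_k.
#' @param truth a `cohort_truth`
#' @param path file path
#' @rdname truth_io
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth$mutations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname truth_io
#' @export
read_truth_tsv <- function(path) {
  data.table::fread(path, sep = "\t", colClasses = list(
    character = c("sample", "chrom", "ref", "alt", "class")))
}
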