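# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately re-derive results from first principles (enumeration,
# plain string scans, textbook formulas) and never call the package's own
# code paths.

# exact two-sided Fisher p for a 2x2 table by explicit enumeration of all
# tables with the observed margins, probabilities from factorials
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lp <- function(a) {
    b <- r1 - a; c <- c1 - a; d <- r2 - c
    lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) + lgamma(n - c1 + 1) -
      lgamma(n + 1) - lgamma(a + 1) - lgamma(b + 1) - lgamma(c + 1) -
      lgamma(d + 1)
  }
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- exp(vapply(support, lp, numeric(1)))
  pobs <- exp(lp(tab[1, 1]))
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# exact two-sided Fisher p for a small R x C table by recursive enumeration
# of all tables with the observed margins
oracle_fisher_rxc <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  lfact <- function(x) lgamma(x + 1)
  logprob <- function(m) {
    sum(lfact(rs)) + sum(lfact(cs)) - lfact(sum(m)) - sum(lfact(m))
  }
  pobs <- logprob(tab)
  total <- 0
  enum <- function(partial, rowidx, remaining_cols) {
    if (rowidx == nrow(tab)) {
      m <- rbind(partial, remaining_cols)
      if (all(m >= 0)) {
        lp <- logprob(m)
        if (lp <= pobs + 1e-7) total <<- total + exp(lp)
      }
      return(invisible())
    }
    r <- rs[rowidx]
    cells <- function(filled, colidx, left) {
      if (colidx == ncol(tab)) {
        if (left <= remaining_cols[colidx]) {
          enum(rbind(partial, c(filled, left)), rowidx + 1L,
               remaining_cols - c(filled, left))
        }
        return(invisible())
      }
      for (v in 0:min(left, remaining_cols[colidx])) {
        cells(c(filled, v), colidx + 1L, left - v)
      }
    }
    cells(integer(0), 1L, r)
  }
  enum(matrix(numeric(0), 0, ncol(tab)), 1L, cs)
  total
}

# exact two-sample KS p by full enumeration of group assignments
oracle_ks_perm <- function(x, y) {
  ks_D <- function(a, b) {
    pts <- sort(unique(c(a, b)))
    max(abs(stats::ecdf(a)(pts) - stats::ecdf(b)(pts)))
  }
  pooled <- c(x, y)
  m <- length(x)
  idx <- utils::combn(length(pooled), m)
  D0 <- ks_D(x, y)
  hits <- 0
  for (j in seq_len(ncol(idx))) {
    if (ks_D(pooled[idx[, j]], pooled[-idx[, j]]) >= D0 - 1e-12) {
      hits <- hits + 1
    }
  }
  hits / ncol(idx)
}

# plain string-scan classification of a deletion: returns list(category, k)
oracle_classify_deletion <- function(deleted, flank5, flank3) {
  L <- nchar(deleted)
  if (substr(flank3, 1, L) == deleted ||
      substr(flank5, nchar(flank5) - L + 1, nchar(flank5)) == deleted) {
    return(list(category = "repeat", k = 0L))
  }
  m3 <- 0L
  while (m3 < L && m3 < nchar(flank3) &&
         substr(deleted, m3 + 1, m3 + 1) == substr(flank3, m3 + 1, m3 + 1)) {
    m3 <- m3 + 1L
  }
  m5 <- 0L
  while (m5 < L && m5 < nchar(flank5) &&
         substr(deleted, L - m5, L - m5) ==
         substr(flank5, nchar(flank5) - m5, nchar(flank5) - m5)) {
    m5 <- m5 + 1L
  }
  k <- min(max(m3, m5), 5L)
  if (k >= 1L) list(category = "microhomology", k = k)
  else list(category = "other", k = 0L)
}

# independent re-implementation of the caller's filter cascade on an
# SNV-only count table (data.frame: sample, chrom, pos, ref, A, C, G, T,
# depth), using stats::fisher.test for the score
oracle_call_snvs <- function(bases, cfg) {
  out <- list()
  for (k in unique(paste(bases$chrom, bases$pos))) {
    rows <- bases[paste(bases$chrom, bases$pos) == k, , drop = FALSE]
    if (length(unique(rows$ref)) != 1) stop("inconsistent ref")
    cand <- NULL
    multi <- FALSE
    for (i in seq_len(nrow(rows))) {
      d <- rows$depth[i]
      if (d < cfg$min_mutated_coverage) next
      cnts <- c(A = rows$A[i], C = rows$C[i], G = rows$G[i], T = rows$T[i])
      altb <- setdiff(names(cnts), rows$ref[1])
      fr <- cnts[altb] / d
      if (max(fr) >= cfg$min_alt_allele_fraction) {
        if (!is.null(cand)) multi <- TRUE
        best <- altb[order(-fr, altb)][1]
        cand <- list(i = i, alt = best, altn = cnts[[best]], depth = d,
                     refn = cnts[[rows$ref[1]]])
      }
    }
    if (is.null(cand) || multi) next
    others <- setdiff(seq_len(nrow(rows)), cand$i)
    od <- rows$depth[others]
    if (any(od == 0)) next
    orf <- vapply(others, function(j) {
      rows[[rows$ref[1]]][j] / rows$depth[j]
    }, numeric(1))
    if (any(orf < cfg$min_other_ref_fraction)) next
    comp <- others[which.min(orf)]
    tab <- rbind(c(cand$refn, cand$altn),
                 c(rows[[rows$ref[1]]][comp], rows[[cand$alt]][comp]))
    score <- if (sum(tab[, 2]) == 0) 0 else
      -log10(stats::fisher.test(tab)$p.value)
    if (score < cfg$min_quality_score) next
    out[[length(out) + 1L]] <- data.frame(
      sample = rows$sample[cand$i], chrom = rows$chrom[1],
      pos = rows$pos[1], alt = cand$alt, score = score,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(sample = character(0), chrom = character(0),
                      pos = integer(0), alt = character(0),
                      score = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$pos, res$sample), , drop = FALSE]
}

# random SNV count table for caller/oracle equivalence checks (vectorized:
# the acceptance criterion draws 1000 of these)
random_count_table <- function(npos, nsamp, seed) {
  withr::with_seed(seed, {
    bases4 <- c("A", "C", "G", "T")
    n <- npos * nsamp
    ref <- rep(sample(bases4, npos, replace = TRUE), each = nsamp)
    depth <- sample(0:30, n, replace = TRUE)
    noisy <- stats::runif(n) < 0.3
    nalt <- ifelse(noisy,
                   stats::rbinom(n, depth, stats::runif(n, 0, 0.6)),
                   stats::rbinom(n, depth, 0.01))
    cnt <- matrix(0L, n, 4L, dimnames = list(NULL, bases4))
    shift <- sample.int(3L, n, replace = TRUE)
    refi <- match(ref, bases4)
    alti <- ((refi - 1L + shift) %% 4L) + 1L
    cnt[cbind(seq_len(n), alti)] <- as.integer(nalt)
    cnt[cbind(seq_len(n), refi)] <- as.integer(depth - nalt)
    data.frame(sample = rep(paste0("s", seq_len(nsamp)), times = npos),
               chrom = "chr1", pos = rep(seq_len(npos), each = nsamp),
               ref = ref, A = cnt[, 1], C = cnt[, 2], G = cnt[, 3],
               T = cnt[, 4], depth = depth, stringsAsFactors = FALSE)
  })
}

# wrap a plain SNV count data.frame as a position_counts object
as_position_counts <- function(bases) {
  structure(list(
    bases = data.table::as.data.table(bases),
    indels = data.table::data.table(sample = character(0),
                                    chrom = character(0), pos = integer(0),
                                    kind = character(0),
                                    allele = character(0),
                                    count = integer(0)),
    samples = unique(bases$sample)), class = "position_counts")
}

# small shared fixture: deterministic reference + cohort for reuse
make_test_reference <- function(len = 200000L, nchrom = 2L, seed = 11L,
                                gc = 0.42) {
  generate_reference(genome_spec(rep(len, nchrom), gc, seed))
}
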