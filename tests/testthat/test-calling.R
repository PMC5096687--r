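# Unique-mutation caller: screen, quality score, full cascade.

mk_pos <- function(...) {
  # rows: list of c(A,C,G,T,depth) per sample, shared ref base
  rows <- list(...)
  ref <- attr(rows, "ref")
  do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(sample = paste0("s", i), chrom = "chr1", pos = 100L,
               ref = r$ref, A = r$cnt[1], C = r$cnt[2], G = r$cnt[3],
               T = r$cnt[4], depth = r$depth, stringsAsFactors = FALSE)
  }))
}
row_ct <- function(ref, A = 0, C = 0, G = 0, T = 0, depth = A + C + G + T) {
  list(ref = ref, cnt = c(A, C, G, T), depth = depth)
}

test_that("screen_position applies the three filters", {
  cfg <- caller_config()
  # candidate s1: ref C 6, alt T 4 (af 0.4, depth 10); clean others
  bases <- mk_pos(row_ct("C", C = 6, T = 4),
                  row_ct("C", C = 10),
                  row_ct("C", C = 12))
  cand <- screen_position(bases, NULL, cfg)
  expect_equal(cand$sample, "s1")
  expect_equal(cand$alt_fraction, 0.4)
  expect_equal(cand$kind, "SNV")
  expect_equal(cand$allele, "T")

  # an unclean other sample (ref fraction 0.90 < 0.93) kills the candidate
  bases2 <- mk_pos(row_ct("C", C = 6, T = 4),
                   row_ct("C", C = 9, T = 1),
                   row_ct("C", C = 12))
  expect_null(screen_position(bases2, NULL, cfg))

  # all pure reference: nothing to call
  bases3 <- mk_pos(row_ct("C", C = 20), row_ct("C", C = 25),
                   row_ct("C", C = 30))
  expect_null(screen_position(bases3, NULL, cfg))

  # two candidate samples: not unique, no call
  bases4 <- mk_pos(row_ct("C", C = 6, T = 4), row_ct("C", C = 5, T = 5),
                   row_ct("C", C = 30))
  expect_null(screen_position(bases4, NULL, cfg))

  # a zero-depth other sample: cleanliness cannot be certified
  bases5 <- mk_pos(row_ct("C", C = 6, T = 4), row_ct("C", depth = 0),
                   row_ct("C", C = 30))
  expect_null(screen_position(bases5, NULL, cfg))

  # inconsistent reference bases are a data-integrity error
  bases6 <- mk_pos(row_ct("C", C = 10), row_ct("A", A = 10))
  expect_error(screen_position(bases6, NULL, cfg), "inconsistent")
})

test_that("screen_position picks the noisiest other sample as comparison", {
  cfg <- caller_config()
  bases <- mk_pos(row_ct("C", C = 6, T = 4),
                  row_ct("C", C = 19, G = 1),  # ref fraction 0.95
                  row_ct("C", C = 30))
  cand <- screen_position(bases, NULL, cfg)
  expect_equal(cand$comparison_sample, "s2")
  expect_equal(cand$comp_ref_count, 19)
  expect_equal(cand$comp_alt_count, 0)  # no T reads in s2
})

test_that("quality_score matches exact-test oracles", {
  expect_equal(quality_score(c(6, 4), c(6, 4)), 0)
  # brute-force hypergeometric enumeration oracle
  expect_equal(quality_score(c(6, 4), c(10, 0)),
               -log10(oracle_fisher_2x2(rbind(c(6, 4), c(10, 0)))),
               tolerance = 1e-12)
  expect_gt(quality_score(c(0, 20), c(20, 0)), 5)
  withr::with_seed(77, {
    for (i in 1:50) {
      tab <- matrix(rpois(4, 8), 2)
      if (any(rowSums(tab) == 0) || all(tab[, 2] == 0)) next
      expect_equal(quality_score(tab[1, ], tab[2, ]),
                   -log10(stats::fisher.test(tab)$p.value),
                   tolerance = 1e-9)
    }
  })
  expect_error(quality_score(c(0, 0), c(0, 0)), "all-zero")
})

test_that("an engineered toy table yields exactly its one passing site", {
  cfg <- caller_config()
  rows <- list()
  for (p in 1:10) {
    for (s in c("s1", "s2", "s3")) {
      # position 7 carries a clean het in s2; everything else is reference
      if (p == 7 && s == "s2") {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, chrom = "chr1", pos = p, ref = "G", A = 10L, C = 0L,
          G = 12L, T = 0L, depth = 22L, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, chrom = "chr1", pos = p, ref = "G", A = 0L, C = 0L,
          G = 20L, T = 0L, depth = 20L, stringsAsFactors = FALSE)
      }
    }
  }
  counts <- as_position_counts(do.call(rbind, rows))
  calls <- call_unique_mutations(counts, cfg)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$sample, "s2")
  expect_equal(calls$pos, 7L)
  expect_equal(calls$alt, "A")
  oc <- oracle_call_snvs(counts$bases, cfg)
  expect_equal(nrow(oc), 1L)
  expect_equal(oc$pos, calls$pos)
})

test_that("caller equals the brute-force oracle on random tables", {
  cfg <- caller_config()
  for (seed in 1:60) {
    tab <- random_count_table(npos = 12, nsamp = sample(2:5, 1), seed = seed)
    calls <- call_unique_mutations(as_position_counts(tab), cfg)
    oc <- oracle_call_snvs(tab, cfg)
    expect_equal(nrow(calls), nrow(oc), info = paste("seed", seed))
    if (nrow(oc)) {
      expect_equal(paste(calls$sample, calls$pos, calls$alt),
                   paste(oc$sample, oc$pos, oc$alt), info = paste("seed", seed))
      expect_equal(calls$score, oc$score, tolerance = 1e-9)
    }
  }
})

test_that("raising any threshold never increases the number of calls", {
  base_cfg <- caller_config()
  for (seed in 101:115) {
    tab <- random_count_table(npos = 15, nsamp = 3, seed = seed)
    counts <- as_position_counts(tab)
    n0 <- nrow(call_unique_mutations(counts, base_cfg))
    stricter <- list(
      caller_config(min_alt_allele_fraction = 0.3),
      caller_config(min_mutated_coverage = 10),
      caller_config(min_other_ref_fraction = 0.98),
      caller_config(min_quality_score = 4))
    for (cfg in stricter) {
      expect_lte(nrow(call_unique_mutations(counts, cfg)), n0)
    }
  }
})

test_that("no position is called in two samples", {
  for (seed in 201:210) {
    tab <- random_count_table(npos = 20, nsamp = 4, seed = seed)
    calls <- call_unique_mutations(as_position_counts(tab), caller_config())
    if (nrow(calls)) {
      expect_false(anyDuplicated(paste(calls$chrom, calls$pos)) > 0)
    }
  }
})

test_that("shared heterozygous sites are never called", {
  # all samples het at the site: every non-candidate fails the 0.93 filter
  bases <- mk_pos(row_ct("C", C = 11, T = 9),
                  row_ct("C", C = 10, T = 10),
                  row_ct("C", C = 12, T = 8))
  expect_null(screen_position(bases, NULL, caller_config()))
  ref <- make_test_reference(len = 100000L, nchrom = 1L)
  cs <- cohort_spec(samples = c("a", "b", "c"), germline_het_density = 3e-4,
                    seed = 18)
  truth <- implant_mutations(ref, cs)
  expect_gt(nrow(truth$germline), 10)
  counts <- simulate_pileup_counts(ref, truth, noise_model(25, 0, 0))
  calls <- call_unique_mutations(counts, caller_config())
  expect_equal(nrow(calls), 0L)
})

test_that("indels are called, capped at 50 bp, and privacy is enforced", {
  cfg <- caller_config()
  bases <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(sample = paste0("s", i), chrom = "chr1", pos = 50L,
               ref = "A", A = if (i == 1) 12L else 20L, C = 0L, G = 0L,
               T = 0L, depth = if (i == 1) 22L else 20L,
               stringsAsFactors = FALSE)
  }))
  indels <- data.frame(sample = "s1", chrom = "chr1", pos = 50L,
                       kind = "DEL", allele = "4", count = 10L,
                       stringsAsFactors = FALSE)
  counts <- structure(list(bases = data.table::as.data.table(bases),
                           indels = data.table::as.data.table(indels),
                           samples = paste0("s", 1:3)),
                      class = "position_counts")
  calls <- call_unique_mutations(counts, cfg)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$type, "DEL")
  expect_equal(calls$af, 10 / 22)

  indels$allele <- "60"  # longer than 50 bp: never emitted
  counts$indels <- data.table::as.data.table(indels)
  expect_equal(nrow(call_unique_mutations(counts, cfg)), 0L)
})

test_that("unsorted input errors; missing samples are skipped with warning", {
  tab <- random_count_table(npos = 5, nsamp = 3, seed = 5)
  shuffled <- tab[rev(seq_len(nrow(tab))), ]
  expect_error(call_unique_mutations(as_position_counts(shuffled)),
               "sorted")
  # drop one sample at one position (make it a would-be candidate site)
  tab2 <- tab
  hit <- tab2$pos == 3 & tab2$sample == "s1"
  tab2$C[hit] <- 0L
  tab2$T[hit] <- tab2$depth[hit]
  tab2$A[hit] <- 0L; tab2$G[hit] <- 0L
  tab2$ref[tab2$pos == 3] <- "C"
  cc <- tab2[!(tab2$pos == 3 & tab2$sample == "s2"), ]
  expect_warning(call_unique_mutations(as_position_counts(cc)),
                 "missing")
})

test_that("calls are independent of input chunking", {
  ref <- make_test_reference(len = 150000L, nchrom = 2L, seed = 77)
  cs <- cohort_spec(samples = c("a", "b", "c"), snv_burden = c(30, 10, 0),
                    germline_het_density = 1e-4, seed = 19)
  truth <- implant_mutations(ref, cs)
  counts <- simulate_pileup_counts(ref, truth, noise_model(25, 0, 0.002))
  whole <- call_unique_mutations(counts, caller_config(), ref)
  parts <- lapply(unique(counts$bases$chrom), function(ch) {
    sub <- structure(list(bases = counts$bases[counts$bases$chrom == ch, ],
                          indels = counts$indels[counts$indels$chrom == ch, ],
                          samples = counts$samples),
                     class = "position_counts")
    call_unique_mutations(sub, caller_config(), ref)
  })
  chunked <- data.table::rbindlist(parts)
  data.table::setorderv(chunked, c("chrom", "pos", "sample"))
  expect_equal(as.data.frame(whole), as.data.frame(chunked))
})
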