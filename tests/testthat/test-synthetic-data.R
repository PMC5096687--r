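# Synthetic genome / cohort / count generators.

test_that("generate_reference is deterministic and honours composition", {
  spec <- genome_spec(10000, gc_content = 0.5, seed = 1)
  r1 <- generate_reference(spec)
  r2 <- generate_reference(spec)
  expect_identical(as.character(r1), as.character(r2))
  expect_equal(Biostrings::width(r1), 10000L)
  expect_true(all(strsplit(as.character(r1[[1]]), "")[[1]] %in%
                    c("A", "C", "G", "T")))

  at_only <- generate_reference(genome_spec(100000, gc_content = 0, seed = 2))
  expect_equal(
    sum(Biostrings::letterFrequency(at_only, c("G", "C"))), 0)

  mid <- generate_reference(genome_spec(200000, gc_content = 0.42, seed = 3))
  gc <- sum(Biostrings::letterFrequency(mid, c("G", "C"))) / 200000
  expect_gte(gc, 0.41)
  expect_lte(gc, 0.43)
})

test_that("genome_spec validates its inputs", {
  expect_error(genome_spec(integer(0)), "at least one")
  expect_error(genome_spec(500), ">= 1000")
  expect_error(genome_spec(10000, gc_content = 1.2), "\\[0, 1\\]")
})

test_that("implant_mutations conserves burdens and keeps implants private", {
  ref <- make_test_reference()
  cs <- cohort_spec(samples = paste0("s", 1:4),
                    snv_burden = c(50, 20, 0, 10),
                    ins_burden = 3, del_burden = 4,
                    germline_het_density = 5e-5, seed = 3)
  truth <- implant_mutations(ref, cs)
  m <- truth$mutations
  tab <- table(factor(m$sample, levels = paste0("s", 1:4)), m$class)
  expect_equal(as.vector(tab[, "SNV"]), c(50, 20, 0, 10))
  expect_equal(as.vector(tab[, "INS"]), rep(3L, 4))
  expect_equal(as.vector(tab[, "DEL"]), rep(4L, 4))
  # privacy: one owning sample per locus
  expect_false(anyDuplicated(paste(m$chrom, m$pos)) > 0)
  # determinism
  truth2 <- implant_mutations(ref, cs)
  expect_identical(truth$mutations, truth2$mutations)
  expect_identical(truth$germline, truth2$germline)
})

test_that("implants and germline sites respect the minimum spacing", {
  ref <- make_test_reference()
  cs <- cohort_spec(samples = c("a", "b"), snv_burden = 150, del_burden = 5,
                    germline_het_density = 1e-4, min_spacing = 100, seed = 9)
  truth <- implant_mutations(ref, cs)
  allpos <- rbind(truth$mutations[, c("chrom", "pos")],
                  truth$germline[, c("chrom", "pos")])
  for (ch in unique(allpos$chrom)) {
    p <- sort(allpos$pos[allpos$chrom == ch])
    expect_true(all(diff(p) > 100))
  }
})

test_that("zero burdens give an empty truth set with germline sites only", {
  ref <- make_test_reference(len = 50000L, nchrom = 1L)
  cs <- cohort_spec(samples = c("a", "b"), germline_het_density = 2e-4,
                    seed = 2)
  truth <- implant_mutations(ref, cs)
  expect_equal(nrow(truth$mutations), 0L)
  expect_gt(nrow(truth$germline), 0L)
})

test_that("impossible burdens raise a capacity error", {
  ref <- generate_reference(genome_spec(1000, gc_content = 0.5, seed = 4))
  cs <- cohort_spec(samples = "a", snv_burden = 400, min_spacing = 100,
                    germline_het_density = 0, seed = 5)
  expect_error(implant_mutations(ref, cs), "capacity")
})

test_that("microhomology deletions carry their overlap in the reference", {
  ref <- make_test_reference()
  refstr <- as.character(ref)
  cs <- cohort_spec(samples = "a", del_burden = 25,
                    deletion_mix = c(0, 1, 0),
                    deletion_lengths = c(0, 0, 0, 1, rep(0, 46)), # all 4 bp
                    mh_k_weights = c(0, 1, 0, 0, 0),              # k = 2
                    germline_het_density = 0, seed = 6)
  truth <- implant_mutations(ref, cs)
  dels <- truth$mutations[truth$mutations$class == "DEL", ]
  expect_equal(nrow(dels), 25L)
  expect_true(all(dels$mh_k == 2L))
  for (i in seq_len(nrow(dels))) {
    s <- refstr[[dels$chrom[i]]]
    start <- dels$pos[i] + 1L          # first deleted base
    L <- nchar(dels$ref[i]) - 1L
    expect_equal(L, 4L)
    deleted <- substr(s, start, start + L - 1L)
    after <- substr(s, start + L, start + 2L * L - 1L)
    # first 2 deleted bases repeat right after the deletion, third differs
    expect_equal(substr(deleted, 1, 2), substr(after, 1, 2))
    expect_false(deleted == after)
  }
})

test_that("SNV contexts follow the requested spectrum (chi-square)", {
  ref <- make_test_reference(len = 1500000L, nchrom = 2L, seed = 21)
  w <- rep(1, 96); w[1:16] <- 6; w[81:96] <- 0.25
  spec <- triplet_spectrum(w / sum(w), mode = "normalized")
  cs <- cohort_spec(samples = "a", snv_burden = 5000, snv_spectrum = spec,
                    germline_het_density = 0, seed = 31)
  truth <- implant_mutations(ref, cs)
  obs <- tabulate(truth$mutations$spectrum_class, nbins = 96)
  expect_equal(sum(obs), 5000L)
  p <- as.numeric(spec)
  keep <- p > 0
  chi <- suppressWarnings(
    stats::chisq.test(obs[keep], p = p[keep] / sum(p[keep])))
  expect_gt(chi$p.value, 0.01)
})

test_that("pileup counts are pure reference at unmutated sites when error-free", {
  ref <- make_test_reference(len = 50000L, nchrom = 1L)
  cs <- cohort_spec(samples = c("a", "b", "c"), snv_burden = c(5, 0, 0),
                    germline_het_density = 0, seed = 12)
  truth <- implant_mutations(ref, cs)
  counts <- simulate_pileup_counts(ref, truth, noise_model(30, 0, 0))
  b <- counts$bases
  others <- b[b$sample != "a", ]
  cmat <- cbind(others$A, others$C, others$G, others$T)
  refn <- cmat[cbind(seq_len(nrow(others)), match(others$ref, c("A", "C", "G", "T")))]
  expect_equal(rowSums(cmat), refn)        # only the reference base observed
  expect_equal(refn, others$depth)
})

test_that("implanted het sites follow the binomial allele-fraction model", {
  ref <- make_test_reference(len = 1200000L, nchrom = 2L, seed = 41)
  cs <- cohort_spec(samples = c("a", "b"), snv_burden = c(1000, 0),
                    germline_het_density = 0, seed = 13)
  truth <- implant_mutations(ref, cs)
  nm <- noise_model(mean_coverage = 20, coverage_dispersion = 0,
                    per_base_error = 0)
  counts <- simulate_pileup_counts(ref, truth, nm)
  m <- truth$mutations
  b <- counts$bases[counts$bases$sample == "a", ]
  idx <- match(paste(m$chrom, m$pos), paste(b$chrom, b$pos))
  cmat <- cbind(b$A, b$C, b$G, b$T)
  altn <- cmat[cbind(idx, match(m$alt, c("A", "C", "G", "T")))]
  # alt count ~ Binomial(Poisson(20), 0.5): mean 10, sd sqrt(10)
  expect_lt(abs(mean(altn) - 10), 0.3)
  # determinism of the whole simulation
  counts2 <- simulate_pileup_counts(ref, truth, nm)
  expect_identical(counts$bases, counts2$bases)
})

test_that("germline sites are heterozygous in every sample", {
  ref <- make_test_reference(len = 100000L, nchrom = 1L)
  cs <- cohort_spec(samples = c("a", "b", "c"), germline_het_density = 2e-4,
                    seed = 8)
  truth <- implant_mutations(ref, cs)
  counts <- simulate_pileup_counts(ref, truth, noise_model(30, 0, 0))
  g <- truth$germline
  b <- counts$bases
  cmat <- cbind(b$A, b$C, b$G, b$T)
  for (i in seq_len(min(nrow(g), 20))) {
    rows <- which(b$chrom == g$chrom[i] & b$pos == g$pos[i])
    expect_equal(length(rows), 3L)
    altn <- cmat[cbind(rows, match(g$alt[i], c("A", "C", "G", "T")))]
    refn <- cmat[cbind(rows, match(g$ref[i], c("A", "C", "G", "T")))]
    # both alleles present in essentially every sample at 30x
    expect_true(all(altn + refn == b$depth[rows]))
    expect_true(all(altn > 0))
  }
})
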