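---
title: "Methods: unique-mutation calling and spectrum analysis in isogenic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unique-mutation calling and spectrum analysis in isogenic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutaccum)
```

## The experimental design this package models

A mutation-accumulation experiment starts from a single cell, expands it
for on the order of a hundred divisions, isolates new single-cell clones,
and sequences their whole genomes at moderate coverage (20–30×). All
clones are isogenic, so each genome differs from the shared ancestor only
by the mutations accumulated during the experiment — a variant present in
exactly one clone ("unique" or sample-private) is such a mutation, while a
variant shared by all clones belongs to the common genetic background.
Comparing a DNA-repair-deficient line (the motivating case is loss of
either BRCA1 or BRCA2, the two central homologous-recombination factors)
with its wild-type control in this design measures mutation *rates*
causally rather than correlatively.

The package covers the computational half of the design: unique-mutation
calling from per-position allele counts, triplet spectra and signature
correlation, deletion-breakpoint context classification, and the group
statistics. Read alignment, duplicate removal and realignment happen
upstream; structural variants beyond 50 bp are out of scope.

## The caller

The caller consumes per-position allele-count tables (pileup-derived;
base-quality filtering, conventionally at Q30, is assumed already applied
upstream — the counts are the evidence, not the reads). At every position
all samples are screened jointly:

1. **Candidate filter** — some sample shows an alternate allele (a base,
   an inserted sequence, or a deletion length ≤ 50 bp) at fraction ≥ 0.2
   of its depth, with depth ≥ 5.
2. **Uniqueness** — exactly one sample passes the candidate filter at this
   position.
3. **Cleanliness** — every other sample has reference-base fraction
   ≥ 0.93. A sample with zero depth cannot certify cleanliness, so such
   positions are skipped entirely (this prevents coverage-hole false
   positives at the cost of a little sensitivity).
4. **Quality score** — the candidate's `(ref, alt)` counts are compared
   with those of the *noisiest* other sample (lowest reference fraction;
   first in input order on ties) in a 2×2 two-sided Fisher exact test, and
   the call is kept when `−log10 p ≥ 2` (p ≤ 0.01). The threshold is a
   configurable default: the source experiment reports using a
   probability-based score with optimized parameters but not the numeric
   cutoff, so 2.0 is this package's documented choice, not a published
   value.

The allele-fraction threshold of 0.2 presumes heterozygous variants
(expected fraction 0.5) in diploid-like clones; threshold 0.93 rather than
1.0 tolerates sequencing error in the reference panel. With three samples
at 25× and 0.2% per-base error, the dominant loss mechanisms are binomial
fluctuation of the carrier fraction at low coverage and the score filter
at marginal depth; simulated recovery is ≈ 98%, comfortably above the ~90%
the experimental method reports at this coverage, and false positives are
effectively absent (the score filter removes the single-error-read
candidates that pass the fraction filter at depth 5–10).

Indels are represented VCF-style: left-anchored, `pos` is the base before
the event. Internally coordinates are 1-based throughout the count tables
and call tables.

## Triplet spectra and signatures

SNVs are classified into the standard 96 classes: six pyrimidine-centred
substitutions (C>A, C>G, C>T, T>A, T>C, T>G) × 16 flank combinations,
ordered substitution-major with 5′ then 3′ flank alphabetical, matching
published signature catalogues. Purine-centred mutations are
reverse-complemented first, so a locus and its reverse complement always
land in the same class (a tested invariant).

Per-triplet mutation *rates* divide class counts by the number of
occurrences of the triplet in the genome, counted on overlapping windows
with purine-centred triplets folded into their pyrimidine bins — i.e.
both-strand occurrence counts. Using single-strand counts instead would
rescale every class by the same factor 2 and change nothing downstream;
the both-strand convention is implemented because it matches the
symmetric (strand-collapsed) mutation classes. A zero-frequency triplet is
an error only if mutations were observed in it; with zero counts the rate
is a well-defined zero (this also keeps degenerate toy genomes usable).

To compare spectra observed on one genome against signatures defined on
another (the motivating case: chicken DT40 spectra vs human cancer
signatures), each class is reweighted by the ratio of its triplet's
occurrence in the target genome to the source genome and the spectrum is
renormalized. The reweighting is applied multiplicatively to counts before
normalization; the order is immaterial up to the final normalization,
which is explicit. Comparison uses the Pearson correlation coefficient
across the 96 components against each of the 30 catalogue signatures;
Pearson is scale-invariant, so counts, rates and normalized spectra give
identical coefficients. Subtracting a baseline (e.g. the wild-type mean
spectrum, representing mutational processes common to all lines) is done
component-wise with negative components clipped to zero and
renormalization; the clip count is recorded. Note that subtracting a
*flat* baseline cannot change a Pearson correlation (additive
invariance) — sharpening only occurs for structured baselines, which is
exactly the intended use.

CpG deamination is summarized as the fold overrepresentation of NCG>NTG:
the mean rate of the four C>T-at-CpG classes divided by the mean rate of
all 96 classes (uniform spectra give 1; the theoretical maximum, all
mutations in those four classes, is 96/4 = 24).

The bundled 30-signature catalogue is **synthetic**
(`synthetic_signature_catalog()`, deterministic): sparse random
probability vectors that are mutually distinguishable. It stands in for
the published catalogue so that tests and examples need no download; the
published TSV layout (`Substitution Type` / `Trinucleotide` / one column
per signature) is read and written by
`read_signature_catalog()` / `write_signature_catalog()` for real use.

## Deletion context classification

Each deletion (1–50 bp) is classified from the reference sequence around
its breakpoint, never from the alternate allele:

* **repeat** — the deleted sequence is an exact copy of the reference
  immediately 3′ (or 5′) of the deletion: loss of one unit of a tandem
  repeat, the signature of replication slippage.
* **microhomology** — not a repeat, but k ≥ 1 bases overlap between the
  end of the deletion and its flank: k is the larger of the longest prefix
  of the deleted sequence matching the start of the 3′ flank and the
  longest suffix matching the end of the 5′ flank, capped at 5 (longer
  overlaps still classify as microhomology with k = 5 and a note).
  Terminal microhomology is the hallmark of microhomology-mediated end
  joining.
* **other** — no terminal overlap (k = 0).

Both sides are checked symmetrically because a deletion in a repeat-free
context is the same physical event whichever strand is reported;
classification is invariant under reverse-complementing the whole locus
(deletion plus flanks), a tested property. Repeat and microhomology are
mutually exclusive by construction — the full-copy check runs first.

## Statistics

* `t_test_from_summary()` / `t_test_samples()` — two-sided pooled-variance
  (Student) t-tests, df = n₁ + n₂ − 2, also computable directly from
  published mean ± sd ± n summaries. The pooled rather than Welch form is
  used because it reproduces the printed significance values of the
  motivating experiment's summary table to their printed precision, which
  the Welch form does not; with n = 3 per group this is also the
  conventional choice. Degenerate conventions: both sds zero and equal
  means → p = 1; zero sds with different means → p = 0.
* `fisher_exact()` — two-sided exact test; 2×2 tables by direct
  hypergeometric enumeration (all tables with the observed margins that
  are no more probable than the observed one), larger R×C tables via the
  exact network algorithm. Zero margins are a signalled error.
* `ks_two_sample()` — D is the supremum ECDF difference at the pooled
  points (ties enter through the ECDF jumps); the p-value is exact,
  conditional on the tie pattern, for samples of at most 25 each, and
  uses the asymptotic Kolmogorov series otherwise.
* No multiple-testing adjustment anywhere, matching the experimental
  convention of reporting unadjusted two-sided p-values.

**Type-I calibration.** The test suite verifies, over 10,000 simulated
null replicates each, that the unpaired t (n = 3), paired t (n = 5 pairs)
and KS tests reject at 5% ± 1%. The KS check uses group sizes 25 and 24:
the exact conditional null of D is discrete, and with equal small sizes
the largest attainable level at or below 0.05 is far smaller (0.036 at
25/25, 0.012 at 10/10), so no simulation could show 5% rejection there;
at 25/24 the attainable level is 0.0499. Fisher's exact test is
conservative on discrete tables by construction — its rejection rate is
verified to stay at or below the nominal level, but a 4% lower bound is
mathematically unattainable for it and is not asserted.

## The synthetic-data generator

The generator emulates the stated experimental world: multi-chromosome
references (i.i.d. bases at a target GC content, default 0.42 ≈ a
vertebrate genome), shared germline heterozygous sites (default density
10⁻⁴/bp), sample-private heterozygous implants at configurable burdens,
and noisy counts at 20–30× coverage.

Choices that define the stated world, with rationale:

* **Heterozygous implants (allele fraction 0.5).** The clones are
  diploid-like and the caller's 0.2 fraction threshold presumes
  heterozygous detection. Ploidy is not asserted beyond this.
* **Coverage** — negative binomial with configurable dispersion, Poisson
  at dispersion 0 (the standard overdispersion model for sequencing
  depth); drawn once per sample per site. Default mean 25×.
* **Per-base error 0.002** after base-quality filtering, substituting
  uniformly among the three non-reference bases. Errors apply to
  reference-carrying reads after the carrier draw.
* **Minimum spacing 100 bp** between all implanted events and germline
  sites, so the clustering statistic's null holds by construction and
  truth/call matching is unambiguous. Set `min_spacing = 0` to allow
  clustering.
* **SNV contexts** are sampled in proportion to the requested 96-class
  spectrum, restricted to triplets present in the reference; the implanted
  alternate allele is strand-adjusted so re-classification recovers the
  sampled class exactly (tested by a chi-square goodness-of-fit at burden
  5000).
* **Microhomology deletions** are implanted in the canonical 3′ form: the
  first k deleted bases recur immediately after the breakpoint, the
  deleted sequence is not a full adjacent copy, and the 5′-side overlap
  does not exceed k — so the classifier reports exactly the implanted k
  (a 100% round-trip is an acceptance criterion). Repeat deletions are
  placed at full adjacent copies; "other" deletions at zero-overlap sites.
  Site pools are found by vectorized scans of the reference and cached.
* **Random streams** are separated per purpose and per sample
  (`derive_seed(master, purpose, sample, chromosome)`), so regenerating
  one stage never perturbs another and all outputs are byte-reproducible
  from the spec seeds.
* **Sparse emission.** Positions where no sample shows any non-reference
  observation are omitted from the count tables — they can never yield a
  candidate, so this is exact, not an approximation; at every emitted
  position all samples get a row so the cleanliness filter has its
  evidence.

What the generator does *not* emulate — and therefore what a green test
does not establish: mapping artifacts and reference bias, correlated
(non-independent) errors, copy-number variation and aneuploidy, GC- or
mappability-dependent coverage structure, and indel sequencing errors.
Caller performance numbers from these simulations are idealized relative
to real data in exactly those respects; the published ~90% detection rate
at 20–30× is an empirical figure on real genomes and our simulated ≈ 98%
is consistent with, but not a reproduction of, it.

## Numerical and degenerate-input conventions

* Fisher 2×2 "as or more extreme" uses a relative tolerance of 1e−7 when
  comparing table probabilities, the classical convention for float ties.
* A candidate whose alternate allele is absent from the comparison sample
  *and* from the candidate (all-zero alt margin) carries no signal and
  scores 0; an all-zero 2×2 table is a signalled error.
* Zero-variance spectra cannot be correlated (signalled); baseline
  subtraction that leaves no positive component is signalled.
* Ties in "lowest reference fraction" resolve to the first sample in input
  order; allele tie-breaks order SNV before insertion before deletion,
  then lexicographically — all deterministic.
* Chromosome-edge SNVs (no flanking base) are excluded from spectra with
  a warning, and the spectrum total is documented as calls minus
  exclusions.

## Known limitations

* The caller screens positions independently; multi-nucleotide variants
  are reported as adjacent SNVs (and the default generator never implants
  them closer than the spacing).
* R×C Fisher tests beyond small tables inherit the practical limits of the
  exact network algorithm.
* The synthetic reference has no repeat structure beyond what i.i.d.
  sequence produces, so long-repeat deletion contexts (> ~8 bp units) are
  rare and the generator may refuse (capacity error) rather than silently
  under-deliver.
* Detection-rate and false-positive figures are simulation-based
  idealizations, as discussed above.
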