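---
title: "Rank-specific recognition codes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-specific recognition codes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsrcode)
library(dplyr)
```

## The problem

A C2H2 zinc finger contacts primarily one 3-base DNA subsite, and natural
three-finger domains such as the transcription factor SP1 read a 9-bp site.
Engineered zinc finger nucleases (ZFNs) exploit this modularity, but they are
plagued by off-target binding: a finger does not bind one triplet, it binds
*all* triplets to different degrees. A useful summary of that behaviour is
the **rank-specific recognition (RSR) code**: the complete ordering of all
64 triplets by the strength of complex formation, measured here by
electrophoretic mobility shift assays (EMSA) in which a radiolabelled probe
carrying `GGG<triplet>GGG` is incubated with the protein and the shifted
band quantified by Phosphor Imager counts.

This package implements the full desk-side half of that analysis:

1. deriving an RSR code from a 64-row count table (`compute_rsr_code()`);
2. summary statistics of the code — signal-threshold grouping
   (`stability_grouping()`), G+C composition of the strongest triplets
   (`composition_summary()`), and rank-correlation comparisons between
   proteins (`compare_rank_codes()`, `rank_shift_report()`);
3. genome scanning for candidate and off-target sites — exact k-mer counts
   (`count_exact()`), degenerate `GGGNNNGGG`-style patterns
   (`count_pattern()`, `offtarget_landscape()`), and paired ZFN half-site
   searches with a spacer (`find_dimer_sites()`);
4. composite-site construction for multi-finger design strategies
   (`build_composite_site()`, `enumerate_candidate_sites()`);
5. synthetic-data generators replacing the wet lab and the reference genome
   (`generate_probe_set()`, `simulate_emsa_counts()`, `simulate_genome()`).

The published SP1 screen (counts and HuRef genome occurrences for all 64
triplets), the six rank columns (SP1 and the five second-finger mutants CB1,
MR14, MQ91, MQ135, MQ151), and the mutant helix sequences are shipped as
checksummed plain-text fixtures (`sp1_assay_counts()`, `rank_codes()`,
`mutant_helices()`), so the entire analysis is reproducible offline.

## Deriving a code from counts

```{r}
code <- compute_rsr_code(sp1_assay_counts(), protein = "SP1")
head(tidy(code))
```

Ranking is a sort on `p32_count`, descending. Two choices deserve comment:

* **Tie policy.** Several counts repeat (1850, 300, 225, 188, 110, 50, 10,
  0). The default `"stable"` policy preserves the input-table row order for
  tied triplets; it is the unique simple rule under which the code derived
  from the packaged count table agrees with the published SP1 rank column at
  all 64 positions (verified by `reproduce_paper()` and the test suite). A
  `"lexicographic"` policy is available for order-independent workflows.
* **Threshold semantics.** The strong/weak grouping uses an *inclusive*
  threshold (`count >= 500`) by default. The published strong group of 26
  itself contains a triplet at exactly 500 (CGC), so a strict comparison
  could not reproduce the 26 / 35 / 3 split; `inclusive = FALSE` is
  available.

```{r}
count(stability_grouping(sp1_assay_counts()), group)
composition_summary(code, top_k = 26)
```

"GC-rich" means at least 2 of 3 bases are G or C — a majority rule, which is
the only symmetric rule consistent with the published composition of the top
26 (18 GC-rich of which 6 are pure-GC triplets, 8 AT-rich of which 3 are
pure-AT). With 3 bases no tie is possible, so every triplet has exactly one
richness class.

Cross-protein comparisons use standard rank statistics — Spearman's rho,
Kendall's tau and Spearman's footrule on the two rank vectors — because the
underlying claim ("the mutation reorders binding preferences") is ordinal.
No significance test is attached: the six codes are one realisation each of
a condition-dependent assay, and a p-value against a uniform-permutation
null would not address the scientific question.

## Genome scanning conventions

* Coordinates are 0-based, half-open, on the forward strand (BED
  convention), including for minus-strand hits.
* Overlapping matches are counted by default; occurrence counts of k-mers
  conventionally include overlaps, and a greedy non-overlapping mode is one
  flag away.
* The default strand mode is forward-only, matching a plain string search
  over the reference; `strand = "both"` also matches the reverse complement
  and reports a palindromic query once per strand.
* `N` bases in the genome never match any query position, including pattern
  wildcards (conservative).
* Record boundaries are never crossed.

The half-site pair search takes the left site, a spacer length range
(cleavage happens in the spacer; 6 bp in the HBB worked example), and the
right site under one of two conventions: `"as_written"` (the right site is
the literal forward-strand sequence) or `"opposite_strand"` (the right site
is the second monomer's binding site read 5'-to-3' on the complementary
strand, so its reverse complement is matched). The two are algebraically
interchangeable — `find_dimer_sites(g, L, R, convention =
"opposite_strand")` equals `find_dimer_sites(g, L, dna_revcomp(R))` — and
the tests assert exactly that identity, since informal descriptions of
"the other strand" are a classic source of orientation bugs (a same-
orientation base-wise complement, as sometimes printed next to a site, is
*not* the reverse complement; `dna_complement()` exists for that pairing).

Because reproducing the published HuRef occurrence totals requires a
multi-gigabase assembly download and an unstated strand/overlap convention,
the real-genome path is an optional input mode (`read_genome()` streams any
FASTA); all tests run on synthetic genomes where ground truth is known by
construction.

## Design strategies and candidate sites

Layouts are written as finger-label strings along the site (`"321"` natural
domain, `"321321"` the tandem 2x3 six-finger design, up to `"32113211"`).
Every finger is assumed to span 3 bp, so the composite site length is
`3 * n_fingers` — 18 bp for the 2x3 design. The added "finger 1" copies in
the `3211`-style layouts are believed to act in binding initiation with
relaxed specificity; whether they contact a full triplet is an assumption
this length law makes explicit.

Overlap annotations mark, for fingers labelled 2 and 3, the
complementary-strand base one position 3' of the finger's own subsite (the
"4th base" / target-site overlap); finger 1 does not engage in overlap
binding. The annotation is metadata: it changes neither the site sequence
nor matching, since the overlap base is a converse-strand stabilisation
contact, not an additional matched column.

`enumerate_candidate_sites()` scores each candidate by the *sum* of
per-finger ranks. The per-finger preferences are ordinal, so any monotone
aggregate is defensible; the sum is the simplest and keeps the score an
integer in `[n, 64n]`. The enumeration materialises `r^n` rows (262,144 for
three fingers at the full cutoff, well under a second) and refuses
accidental blow-ups beyond `max_sites`; the count itself is available in
closed form (`n_candidate_sites()`).

## What the synthetic generators emulate

**Probes.** `generate_probe()` fills the `NNN` slot (0-based positions
27-29) of the fixed 58-base EMSA cassette, so every probe carries
`GGG<triplet>GGG` at positions 24-32. Probes are emitted single-stranded;
the assay anneals a complementary strand, which is available as
`dna_revcomp(probe)` when a double-stranded representation is needed.

**Count tables.** `simulate_emsa_counts()` draws a 64-row table whose true
preference order is a supplied code. Mean counts decay geometrically,
`count_scale * decay^(rank - 1)`; the defaults (`count_scale = 4570`,
`decay = 0.90`) were fitted loosely to the printed table's range — 4570 at
rank 1 falling to single digits by rank 64 — and the detection floor
(`detection_limit = 8`) zeroes the means of the bottom three ranks,
mirroring the three undetectable triplets in the published screen. Noise is
a multiplicative lognormal factor (`sigma = 0.3`, a moderate assay-to-assay
variability) followed by Poisson sampling of the signal. This model is
invented plumbing: the study printed a single realised table, so the
generator's only job is to exercise rank recovery under controllable noise.
Its parameters are configuration, not science. At the defaults, the mean
Spearman correlation between recovered and true codes over 100 seeds is
about 0.99; the test suite asserts the repository regression bound of 0.9.
What passing these tests shows is that the *pipeline* recovers ranks under
this noise model — not that real EMSA noise is lognormal-Poisson, nor
anything about condition dependency of real binding.

**Genomes.** `simulate_genome()` draws i.i.d. bases with a requested
composition and plants motifs at random non-overlapping positions; with
`scrub = TRUE` any chance occurrence of a planted motif on the forward
strand is removed by resampling a single base outside the planted windows,
iterating until clean (bounded retries, default 1000). The construction
therefore guarantees `count_exact(motif)` equals the planted copy number —
which is what makes "the composite site occurs exactly once" reproducible
synthetically. An i.i.d. genome has none of the repeat structure, CpG
depletion or isochore composition of a real assembly, so occurrence counts
on it say nothing quantitative about human off-target burdens; the analytic
helper `expected_occurrences()` gives the matching i.i.d. baseline.

## Numerical and degenerate-input choices

* Count tables must cover all 64 triplets exactly once; duplicates,
  missing triplets and negative counts are validation errors.
* An empty scan query, or a query longer than every record, returns an
  empty report rather than an error; invalid characters are always errors
  naming the offending position.
* `simulate_genome(0)` is an empty genome; all counts on it are zero.
* Simulated counts are kept on the continuous scale (no rounding), so a
  noiseless simulation has no accidental ties and recovers its code
  exactly; the detection floor applies to means, deterministically.
* Fixture loaders verify md5 checksums and content invariants (the
  1,261,301 occurrence total, the undetectable set, permutation validity of
  every rank column) on every read.

## Problem sizes used in the checks

The shipped tests run entirely at desk scale: random scan genomes up to a
few hundred bases (at least 200 scanner-versus-oracle instances), planted-
motif genomes of 0.5-5 kb, 50 random scrub configurations, 100 simulation
seeds for the rank-recovery bound, and the full 262,144-site enumeration.
The complete suite runs in well under a minute; `reproduce_paper()` itself
is instantaneous because every published quantity is a 64-row computation.

## Known limitations

* The five mutant codes exist only as rank columns; their raw counts were
  never published, so only the SP1 column can be validated from counts.
  The mutant helix table is metadata — no residue-to-triplet recognition
  model is attempted (the study's own position is that such general rules
  do not exist).
* The published HuRef occurrence numbers (18,279 / 8,676 / 1 and the
  per-9-mer counts) are not reproduced in tests: they depend on an external
  assembly version and an unstated strand/overlap convention. The scanner
  exposes both strand modes and both overlap settings instead of guessing.
* IUPAC ambiguity codes other than `N`, RNA alphabets, mismatch-tolerant
  or PWM scanning, and binding-energy modelling are out of scope.
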