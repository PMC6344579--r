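---
title: "Identifying cancer cell lines from heterogeneous variant profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying cancer cell lines from heterogeneous variant profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cclid)
```

## The problem

Cancer cell lines (CCLs) are identified *in silico* by comparing the small
variants called from their sequencing data against reference collections of
CCL variant profiles. The difficulty is heterogeneity: query and reference
may differ in sequencing scope (whole transcriptome vs. exome vs. a
49-gene panel), caller, and SNP-filtering policy, so the two profiles of
the *same* line can differ by orders of magnitude in size and agree on only
a fraction of calls. `cclid` implements an identification test designed to
stay calibrated under exactly this heterogeneity.

## Model and assumptions

**Variant identity.** A variant is the triple (chromosome, 1-based start,
1-based end); alleles are parsed only to compute the end coordinate
(`end = POS + nchar(REF) − 1`). Ignoring alleles is deliberate: RNA- and
DNA-derived callers frequently disagree on allele representation while
agreeing on position. The package assumes all profiles share one genome
build; no liftover is attempted.

**Null hypothesis.** For a query `q` and a reference profile `l` from
library `L`, the null is that their overlap arises by chance. Libraries are
assumed internally homogeneous (one repository/technology) and mutually
independent; each library is scored on its own.

**Characteristic variants.** Within a library, variant `v` carried by
`f(v)` profiles receives inclusion weight `w(f) = 2^(1−f)`; variants with
`w ≥ θ` are characteristic. At the default `θ = 0.5` a characteristic
variant is carried by at most two profiles — rare enough to be informative.
`θ = 1` keeps library-unique variants only; `θ = 0` disables selection.
(The weight/threshold semantics are fixed by the benchmark behaviour they
must reproduce: the highest threshold must retain library-unique variants
and the zero threshold must retain everything. The legacy reciprocal weight
`w = 1/f` is available via `scoring_params(weight_scheme = "reciprocal")`;
it differs only from `f = 3` on.)

**Scoring.** With `m_l` the characteristic overlap of `q` and `l`, `m_L`
the number of query variants hitting any characteristic variant of `L`, and
`p_l = |char(l)|/|L_char|` (profile's share of the library's *distinct*
characteristic pool), the tail probability is
`P = P(X ≥ m_l), X ~ Binomial(m_L, p_l)` and the confidence score
`CS = −ln P`. The tail is "at least the observed overlap", i.e.
`1 − CDF(m_l − 1)`; `m_l = 0` gives `P = 1`, `CS = 0`.

**Spuriousness filter.** Chance matches between size-mismatched profiles
cluster: a spurious hit tends to recur across many profiles of the library.
The statistic `SP = B(m_max, m_avg)` (beta function of the maximum and mean
per-profile overlap) quantifies this: informative matching gives
`m_max ≫ m_avg` and tiny `SP`; indiscriminate matching gives `SP` near (or
above) 1. The absolute-overlap threshold is
`T = (m_avg + m_max·SP)/(1 − SP)`.

**Decision.** `l` is identified iff

* A: `CS ≥ t` (default `t = 3`, i.e. `P ≤ e⁻³ ≈ 0.0498`),
* B: `CS` ranks among the library's top `k` (default `k = 2`; a query may
  legitimately match a line and its derivative),
* C: `m_l > T`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `weight_threshold` | 0.5 | inclusion weight cutoff; 0.5 keeps `f ≤ 2` variants. Robust: 1.0/0.5/0.25 give near-identical sensitivity on the synthetic benchmark, 0.0 degrades PPV sharply |
| `confidence_t` | 3 | score cutoff of condition A (`P ≤ e⁻³`) |
| `top_k` | 2 | rank cutoff of condition B |
| `include_zero_overlap` | `TRUE` | whether `m_avg` averages over all profiles, including zero-overlap ones |
| `p_floor` | 1e-300 | lower clamp on `P` so self-matches of large profiles keep finite scores |

## Numerical and degenerate-case choices

* The binomial tail uses `pbinom(..., lower.tail = FALSE)`; `CS` is taken
  from the floored probability, so `CS ≤ −ln(1e-300) ≈ 690.8`.
* `SP` is evaluated as `exp(lbeta(m_max, m_avg))`. For large overlaps
  `B(m_max, m_avg)` underflows to exactly 0; `T` then takes its algebraic
  limit `m_avg`.
* When `m_avg < 1` the beta function can exceed 1; any `SP ≥ 1 − 1e-12`
  yields `T = ∞` and condition C fails for every profile. In particular a
  library whose best overlap is a single variant can never support an
  identification.
* A consequence of including zero overlaps in `m_avg`: in a single-profile
  library `m_avg = m_max`, so `T ≥ m_max` and condition C is
  unsatisfiable. Identification needs a library populous enough for the
  true match to stand out from the average.
* Ranks are a total order — `CS` descending, then `m_l` descending, then
  cell line name ascending (C-locale radix order) — so results are
  deterministic and exactly `min(k, n)` profiles satisfy condition B.
* Degenerate inputs are defined outcomes, not errors: empty query or empty
  characteristic pool produce all-negative calls with a warning.

## Open design points, and how they were resolved

* `|L|` in `p_l` is the number of *distinct* characteristic variants of the
  library (the union), consistent with `m_L` counting matches against "any
  profile". The alternative (sum of profile sizes, which would make
  `Σ p_l = 1`) is not used.
* `m_avg` includes zero-overlap profiles (switchable via
  `include_zero_overlap = FALSE`); the condition C reference is the average
  over *all* profiles of the library.
* The tail is `P(X ≥ m_l)` rather than `P(X > m_l)`: the event scored is
  "an overlap at least as large as observed".
* Matching happens strictly after characteristic-variant selection; `m_l`
  and `m_L` never count non-characteristic variants.

## The synthetic data generator

`synth_config()` / `generate_collection()` build a seeded world with the
statistical structure the method assumes, so every pipeline stage is
testable without any external download:

* **Libraries and identity structure.** 3 libraries × 100 cell lines by
  default, each line present in a library with probability 0.8 —
  reproducing the "same line in several repositories" structure that
  identification exploits.
* **Private variants.** Each line owns 500–2000 uniform private variants:
  the informative fingerprint.
* **Background SNPs.** A shared pool of 20 000 variants; each line carries
  a variant with per-variant probability drawn from Beta(0.3, 0.7)
  (mean carriage 30% of the pool, concentration 1). The heavy-tailed
  carrier spectrum mimics a minor-allele-frequency spectrum: most pool
  variants are common (non-informative, down-weighted), but a tail is
  carried by only one or two lines and leaks into the characteristic pool —
  which is what gives the spuriousness filter a realistic, non-zero
  average overlap to calibrate against.
* **Library scope scaling.** Mean profile sizes differ by powers of two
  across libraries (factors 1, 1/2, 1/4), emulating
  transcriptome/exome/hybrid-capture scope differences. Scaling is
  *nested*: each (line, variant) has a coverage quantile `u` and a library
  with factor `s` stores the variants with `u ≤ s`. Real scope differences
  are ordered (panel genes ⊂ exome targets ⊂ transcribed regions), so the
  smaller-scope copy is a subset of the larger-scope one; independent
  per-variant thinning would instead shrink cross-library overlaps with the
  *product* of the two factors, which no technology pair exhibits.
* **Queries.** `derive_query()` keeps each variant with probability
  `retention_rate` (default 0.3) and adds
  `ceiling(noise_rate · |source|)` (default 0.2) novel uniform variants —
  a re-assay of the same line with smaller scope plus caller noise.
* **Genome model.** 24 chromosomes with human-proportional lengths scaled
  to 30 Mb in total — an exome-scale coordinate space, since every
  emulated technology interrogates genic territory. Coordinates only, no
  sequence, SNVs only.
* **Panels.** `generate_panel()` places N non-overlapping 10 kb regions
  uniformly on the genome model (synthetic stand-ins for 151/94/49-gene
  commercial panels, whose region lists are not redistributable).

All randomness flows from the config seed; a fixed seed yields
byte-identical emitted VCFs.

### What the generator does *not* emulate

Uniform variant placement has no mutation hotspots, no recurrent cancer
genes, and no linkage structure. Two consequences matter when reading the
test results. First, a green parameter-recovery test establishes that the
statistical machinery recovers planted identity under realistic size
heterogeneity and noise — not that the method achieves any particular
sensitivity on real repositories. Second, panel degradation is much
sharper than on real data: real panels deliberately target the most
frequently mutated genes, so a 49-gene panel still captures hundreds of
calls, whereas a uniform 49 × 10 kb panel captures ~1.6% of uniform
variants, leaving too few characteristic matches to clear conditions A
and C. The synthetic panel benchmark therefore shows the expected
*ordering* (full ≥ 151 ≥ 94 ≥ 49 regions) with a cliff, rather than the
graceful 96% → 82% → 65% decline reported for real panels.

## Benchmarking harness

`build_gold_standard()` derives identity groups from normalized names
(non-alphanumerics stripped, uppercased) with curated merge/split lists
overriding collisions in either direction; `identity_candidates()` flags
prefix-related names for manual curation rather than auto-merging.
`cross_validate()` scores every query against every reference profile in
every library exactly once per weight threshold; a query derived from a
reference profile counts its own library entry as a gold-related pair.
Sensitivity, specificity, PPV and F1 (harmonic mean of PPV and
sensitivity; undefined ratios are `NA`, never 0) follow the usual
confusion-matrix definitions over these comparisons. Because true
negatives dominate all-vs-all comparison, PPV is the metric to watch.

## Limitations

* No contamination-fraction estimate: the output is identity calls, not
  mixture proportions.
* No multiple-testing correction across libraries (each library is an
  independent test by design).
* Profiles must share a genome build; chromosome dialects (chr-prefix,
  M/MT) are reconciled, coordinates are not.
* The CLI's config files are JSON (no YAML parser among the package's
  dependencies).
* The on-disk library store is this package's own documented TSV format;
  it does not claim compatibility with any other tool's store.
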