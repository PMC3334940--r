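---
title: "Mining high-order SNP-genotype combinations with SupMaxPair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining high-order SNP-genotype combinations with SupMaxPair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Case-control SNP studies usually test one variant at a time, yet a
disease association may exist only for a *combination* of genotypes at
several SNPs while every marginal effect is weak.  Searching for such
combinations is doubly hard: the candidate space grows exponentially
with combination size, and the multiple-testing burden grows with it.
`snpcombine` addresses both with a discriminative-pattern-mining
formulation.

**Binary encoding.**  Each SNP (minor-allele dosage 0/1/2) expands into
three boolean *items* — `mm`, `Mm`, `MM` — exactly one of which is set
per sample when the genotype is observed.  A *pattern* is a conjunction
of items at distinct SNPs; it is *present* in a sample iff all its
items are set.  The encoding is lossless, and a complete matrix always
has bit density exactly 1/3.  Because any pattern reduces to one
present/absent variable, its association with the phenotype is a 2x2
chi-square with a fixed **1 degree of freedom**, whatever the pattern's
size — so statistics of different sizes are directly comparable and no
extra samples are needed for larger combinations.

**SupMaxPair.**  The search objective for a case-enriched pattern P is

    SMP(P) = supp_case(P) - max over size-2 subsets Q of P of supp_ctrl(Q)

(the control-enriched direction swaps the classes; for a size-2 pattern
the only size-2 subset is P itself).  Support is anti-monotone and the
max term is monotone, so SMP is anti-monotone: adding items never
increases it.  Apriori can therefore prune every superset of a failing
candidate without losing any qualifying pattern.  A consequence worth
noting: every reported pattern has support at least the threshold in
its enriched class, so at the default threshold 0.15 no pattern rests
on fewer than 15% of the cases (or controls).

**Jump.**  A high-scoring pattern may still be a trivial extension of a
stronger subset.  The *jump* of P is its chi-square minus the best
chi-square over all its proper subsets (sizes 1..|P|-1, exhaustively).
Positive jump marks genuinely synergistic combinations.  Jump is *not*
anti-monotone, so it is never used for pruning; `jump_filter()` applies
it after mining, and `estimate_fdr()` replays the identical filter
inside every permutation so the correction stays unbiased.

**Size-specific permutation FDR.**  Labels are permuted (class ratio
preserved) and the entire pipeline — same threshold, constraints and
jump filter, asserted by a config digest — is rerun per permutation.
For a real size-k pattern with chi-square c, with m real size-k
patterns at >= c (m >= 1, the pattern counts itself) and n pooled
random size-k patterns at >= c over N permutations, FDR = n/(N·m);
when n = 0 the reported upper bound is 1/(N·m) (e.g. < 0.002 at
N = 500).  Stratifying by size reflects that large combinations are
much rarer under the null; no second-stage correction across sizes is
applied, which we document as a hypothesis-generation choice.

**Gene-set constraints.**  When a SNP-to-gene map and a gene-set
collection are supplied, a candidate survives only if the genes of all
its SNPs are jointly inside at least one retained set.  The predicate
is anti-monotone (a superset's gene set shrinks the eligible sets), so
it prunes at every level of the search.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.15 | SupMaxPair cutoff (fraction). Lower finds more/rarer patterns at rapidly growing cost; 0.1–0.2 is the practical range. |
| `max_size` | 10 | largest pattern size searched. |
| `jump_min` | unset | post-mining jump filter; ±5 are the conventional visualization bounds. |
| `n_perm` | 100 | permutations for FDR (500 for the synthetic protocol). |
| `max_set_size` | Inf | gene sets larger than this are dropped before constraining. |
| `candidate_budget` | 5e6 | guard on the live pattern frontier per level; joined-candidate batches are capped at 20x this value. |
| `cutoff` | 0.5 | functional-network binarization for coherence fractions. |

## The synthetic generator: what it emulates, what it does not

`simulate_dataset()` draws each background SNP independently under
Hardy-Weinberg equilibrium with MAF ~ Uniform(0.05, 0.5), identically
in cases and controls — the background carries no association by
construction.  Ground-truth patterns are embedded by overwriting the
pattern genotypes in an exact number of randomly chosen cases and
controls (nearest integer, ties upward) and perturbing one pattern SNP
in any remaining sample that matches by accident, so realized presence
counts are exact and the truth table is authoritative.

The `paper` preset (70+70 samples, 2172 SNPs) embeds four case-enriched
patterns of sizes 3–6 at class frequencies (f_case, f_ctrl) =
(0.40, 0.05), (0.35, 0.05), (0.30, 0.05), (0.25, 0.05).  These defaults
were fixed once, from two stated properties of the emulated protocol:
every pattern's overall frequency stays below 0.25 — note that
f_case = 0.45 would violate this after ties-up rounding,
(32+4)/140 = 0.257 — and SupMaxPair stays >= 0.15 with margin.
Embedded items use the minor homozygote and their SNPs get a fixed
MAF of 0.2, so the embedded genotype is rare (~4%) in the background
and the pattern's pair supports in the unenriched class stay near
f_ctrl.  Scaling presets (`n280` … `n5600`) grow the sample count at
fixed per-class frequencies.

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure, population stratification, genotyping batch
effects, and realistic MAF spectra.  A green recovery test therefore
establishes correctness of the search and calibration machinery on
independent-SNP data, not robustness to LD-induced redundancy; on real
data, LD will produce families of near-duplicate patterns that this
package reports without deduplication.

## Numerical and algorithmic choices

- **Threshold comparisons** use a 1e-9 absolute tolerance on support
  fractions (counts are exact integers; the tolerance only absorbs
  division rounding).  "More than 5% missing" QC and "greater than c"
  FDR counting follow the conventions stated above (strict >, and >=
  respectively).
- **Degenerate 2x2 tables** (a zero margin) score chi-square 0 and
  p 1 rather than NaN: such patterns are never discriminative.
  Odds ratios with a zero cell get the Haldane–Anscombe +0.5 and are
  flagged in `or_corrected`.
- **Fisher's exact test** is the two-sided hypergeometric sum of all
  tables no more likely than the observed one (the `fisher.test`
  convention, re-implemented vectorised; the suite cross-checks both).
- **Search mechanics.**  Level 2 is evaluated in bulk: pair
  present-counts per class come from one cross-product of the item-bit
  matrix, and the SupMaxPair test is applied as an integer inequality.
  Levels >= 3 join survivors sharing a prefix, count candidate support
  by intersecting the parent's presence column with one item column
  (never re-scanning the matrix), verify all-subsets-survive through
  integer chain keys, and carry the running best-subset chi-square so
  jump costs nothing extra.  Output order is deterministic: direction,
  size, then the global item order (SNP file order, mm < Mm < MM).
- **Budget guard.**  The spec-level idea of a candidate budget is
  implemented on the *live frontier* (survivors stored per level,
  default 5e6) plus a 20x cap on joined candidates per level.  On the
  canonical preset the size-3 join alone evaluates ~28M transient
  candidates while the frontier stays near 1.4e5, so guarding evaluated
  candidates at 5e6 would abort the package's own headline experiment;
  guarding the frontier preserves the intended runaway protection.
- **Seeds.**  Every stochastic step takes an explicit seed;
  per-permutation seeds derive deterministically from the master seed,
  and RNG state is restored after each seeded operation.
- **Rank-sum tests** in the coherence report use the normal
  approximation with tie correction (similarity vectors are heavily
  tied after binarization-scale weighting); two-sided, recorded as such
  in the output.
- **Degree-preserving null**: pair multisets are rewired by shuffling
  gene slots with rejection of self- and duplicate pairs (bounded
  retries); per-gene occurrence counts are preserved exactly.

## Open choices this package made

- Heterozygote/major/minor orientation is taken from the input coding
  (dosage = minor-allele count); no re-polarisation is attempted at
  MAF near 0.5.
- Patterns whose presence vectors coincide (redundant patterns) are all
  reported; deduplication is left to the analyst.
- Ties at jump = 0 are reported signed and unclassified; thresholds
  decide.
- The FDR formula n/(N·m) is the standard empirical estimator
  consistent with the 500-permutation "< 0.002" resolution bound; a
  per-permutation-averaged variant could be added behind the same
  interface if ever needed.

## Limitations

Single-threaded; intended for focused panels (thousands of SNPs), not
GWAS-scale inputs — prioritise or tag-select SNPs first.  Covariates,
population-structure correction, quantitative traits and
information-theoretic epistasis measures are out of scope.  FDRs are
size-stratified only.  The worked numbers shown in the README are
produced by the code paths exercised in `tests/` and
`scripts/acceptance.R`; this vignette states no result they do not
compute.
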