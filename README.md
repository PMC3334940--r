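# snpcombine

Discriminative pattern mining of **high-order SNP-genotype
combinations** in case-control studies.

Univariate SNP tests miss associations that only emerge when several
genotypes co-occur. `snpcombine` searches that combinatorial space for
focused panels (thousands of SNPs) by:

1. **Binary encoding** — each SNP becomes three boolean items
   (`mm`, `Mm`, `MM`), so any combination of genotypes, of any size,
   reduces to one present/absent variable and its phenotype association
   is a 2x2 chi-square with a fixed **1 degree of freedom**.
2. **Apriori under SupMaxPair** — for a case-enriched pattern *P*,

       SMP(P) = supp_case(P) − max_{Q ⊆ P, |Q| = 2} supp_ctrl(Q)

   is anti-monotone, so the level-wise search prunes every superset of
   a failing candidate exactly, and every reported pattern has support
   ≥ threshold in its enriched class.
3. **Jump filtering** — jump(P) = χ²(P) − max over all proper subsets
   of χ²; positive jump separates genuinely synergistic combinations
   from trivial extensions of a strong subset (applied after mining;
   jump is not anti-monotone).
4. **Size-specific permutation FDR** — the whole pipeline (same
   threshold, gene-set constraints, jump filter) is rerun on permuted
   labels; a size-k pattern with χ² = c gets FDR = n/(N·m) from the m
   real and n pooled random size-k patterns at ≥ c, with upper bound
   1/(N·m) when n = 0.
5. **Gene-set constraints** (anti-monotone prune during the search),
   a **Hardy-Weinberg simulator** with embedded ground-truth patterns,
   and **functional-coherence analysis** of within-pattern gene pairs
   against a degree-preserving null.

## Worked example

Simulate a reduced replica of the synthetic benchmark (70 cases, 70
controls, 150 SNPs, four embedded case-enriched patterns of sizes 3-6),
mine at SupMaxPair threshold 0.15, and attach permutation FDRs:

```r
library(snpcombine)

d   <- simulate_dataset(synthetic_spec(70, 70, 150,
         embedded = snpcombine:::default_embedded(), seed = 1))
B   <- encode_binary(d$genotypes)
cfg <- mining_config(threshold = 0.15)
res <- mine(B, d$labels, cfg)
fdr <- estimate_fdr(res, B, d$labels, cfg, n_perm = 100, seed = 17)

fdr[match(d$truth$pattern, fdr$pattern),
    c("pattern", "size", "supp_case", "supp_ctrl", "chi2", "jump",
      "fdr", "fdr_upper")]
```

```
                                                                     pattern
1851                                     snp00001:mm;snp00002:mm;snp00003:mm
2851                         snp00004:mm;snp00005:mm;snp00006:mm;snp00007:mm
3316             snp00008:mm;snp00009:mm;snp00010:mm;snp00011:mm;snp00012:mm
3425 snp00013:mm;snp00014:mm;snp00015:mm;snp00016:mm;snp00017:mm;snp00018:mm
     size supp_case  supp_ctrl     chi2      jump         fdr    fdr_upper
1851    3 0.4000000 0.05714286 23.33333  0.000000 0.001666667 0.0016666667
2851    4 0.3571429 0.05714286 19.17987 -1.625084 0.000000000 0.0003571429
3316    5 0.3000000 0.05714286 14.07304 -1.230600 0.000312500 0.0003125000
3425    6 0.2571429 0.05714286 10.57011 -1.135578 0.003500000 0.0035000000
```

All four embedded patterns are recovered.  Each row is one combination:
`supp_case`/`supp_ctrl` are its presence frequencies per class, `chi2`
its 1-df association statistic (comparable across sizes), `jump` its
gain over the best proper subset (near zero here: each embedded
pattern's subsets ride on almost the same carrier samples, so the full
combination adds little beyond them on this small replica), and `fdr`
its size-specific permutation FDR with `fdr_upper` the resolution
bound `max(n, 1)/(n_perm · m)`.

The same workflow, end to end with output files:

```r
run_pipeline(list(seed = 1, out_dir = "out",
                  simulate = list(preset = "paper"),
                  mine = list(threshold = 0.15),
                  fdr = list(n_perm = 100)))
```

writes `genotypes.tsv`, `phenotypes.tsv`, `truth.tsv`, `patterns.tsv`
and `patterns_fdr.tsv`, each with a provenance header (seed, config and
dataset digests).  The CLI mirrors this:
`Rscript inst/cli/snpcombine.R pipeline --preset paper --threshold 0.15 --out out`.

## Acceptance script

`scripts/acceptance.R` recomputes the package's two headline
quantities from scratch — the exact 1/3 density (in percent) of the
binary encoding of a complete genotype matrix, and the maximum
size-specific permutation FDR bound of the four embedded patterns on a
280-sample, 300-SNP replica of the synthetic protocol mined at
threshold 0.15 with 500 permutations — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
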