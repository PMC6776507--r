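---
title: "Methods: integrating brain allele-specific methylation with GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating brain allele-specific methylation with GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmscan)
```

## The model and its assumptions

`asmscan` operationalizes a common post-GWAS integration design for
disorders whose risk variants are mostly non-coding and sub-threshold:
restrict attention to SNPs with evidence of *cis* allele-specific
methylation (ASM) in brain, reduce that set to LD-independent tagSNPs,
screen the tags against case-control summary statistics, and then demand a
mechanistically coherent chain — risk allele → methylation direction at a
promoter CpG → opposite expression direction of the promoter's gene — before
calling a variant a candidate.

The package assumes:

* **ASM is summarized, not raw.** Inputs are SNP–CpG pairs with a
  per-pair correlation R² produced upstream by array-based meQTL
  regressions. We never touch methylation β-values.
* **Summary statistics suffice.** Association evidence enters only as
  per-variant odds ratios and p-values (daner layout). No genotype-level
  testing is performed or needed.
* **A phased reference panel is an adequate LD oracle.** All r² values are
  exact haplotype-frequency computations on the supplied panel; panel and
  GWAS population are assumed to match.
* **Promoter methylation anti-correlates with expression.** The
  consistency verdict encodes this sign convention; it is a screening
  heuristic, not a causal claim.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_r2_meth` | 0.2 | R², inclusive | conventional floor for array meQTL correlation; below it ASM calls are noise-dominated |
| `tag_r2`, `expand_r2`, `block_r2` | 0.85 | LD r², inclusive | the standard "high LD" threshold for pairwise tagging; used consistently for tagging, expansion and block building |
| `cis_window` | 1 Mb | bp | the field's usual cis definition (TSS-centred eQTL windows use the same span); the source catalogs do not state a cap, so it is configurable |
| `alpha` | 0.05 | — | the level of every multiple-testing regime |
| `promoter_window` | 5000 | bp, strict `<`, upstream only, strand-aware | promoter CpG definition; CpGs in gene bodies deliberately do not map |
| `probe_footprint` | 50 | bp | 27k-array probe length; used only by the probe/variant collision check |
| enrichment ladder | 5e-2 … 5e-8 | p cutoffs | decade steps between the nominal and genome-wide thresholds; only the endpoints are canonical, the interior rungs are a convention |

## The three significance regimes

For the `m` retrieved tags we compute Storey q-values
(π0 by the λ-grid smoother, with a fallback to π0 = 1 below 100 tests,
where the smoother is unstable — q-values then equal Benjamini–Hochberg),
the Bonferroni threshold α/m, and α/Meff with the Li–Ji eigenvalue
estimator `Meff = Σ I(λᵢ ≥ 1) + (λᵢ − ⌊λᵢ⌋)`. Li–Ji is a deliberate
stand-in for proprietary effective-tests calculators: it is published,
reproducible, and testable (M independent variants give Meff = M; M
perfect duplicates give exactly 1; for two variants with any intermediate
correlation the estimator returns 2 — a known, accepted property of the
piecewise form, which discounts only near-complete redundancy). The
reported "FDR p*" is the largest observed p with q ≤ α, which is how an
FDR threshold is conventionally quoted as a p-value.

Fisher enrichment is one-sided ("greater") by default because the
hypothesis is directional — risk variants enriched *in* ASM SNPs; the
two-sided variant is a flag. The sample odds ratio ad/bc is reported as NA
when a margin is empty; the exact p is still computed.

## Allele harmonization

Tags carry panel alleles; summary statistics carry their own effect/other
alleles. We reconcile by identity, swap (OR inverted), strand flip, and
flip+swap, in that order. Strand-ambiguous pairs (A/T, C/G) that fail
identity and swap are dropped rather than frequency-resolved, because a
daner file is not guaranteed to carry allele frequencies; an ambiguous
pair that *does* match by identity or swap is kept, which assumes panel
and GWAS are reported on the same strand (true of modern forward-strand
resources, and of the synthetic world). P-values are never altered by
harmonization — only orientation and OR.

## What the synthetic world emulates, and what it does not

The generator produces every input with known truth, under one
`sim_config()`:

* **Panel** — blocks of LD built by a haplotype-copying mosaic: each block
  has a latent anchor, and every variant copies it per-haplotype with
  probability `within_block_r2^(1/4)`, giving each within-block pair an
  expected r² equal to `within_block_r2` (default 0.9) and cross-block
  r² ≈ 0. One MAF per block (uniform on `maf_range`, default 0.05–0.5):
  unequal frequencies would cap attainable r² below the target, and an
  unattainable request fails loudly rather than clipping. 200 haplotypes
  by default, the size of a CEU-like reference panel. This is *not* a
  coalescent simulation: no recombination gradients, no allele-frequency
  spectrum realism, no population structure — enough LD realism to
  exercise tagging, expansion and blocking, nothing more.
* **Catalog** — two pseudo-studies (one with four brain tissues, one
  cerebellum-only) with overlap probability 0.3 per pair; 15% of pairs get
  R² < 0.2, 2% are placed in trans, 5% on chromosome X — each planted
  defect exercises one filter, and the manifest records exactly which
  pairs must survive.
* **Summary statistics** — null variants draw z ~ N(0,1); ASM SNPs draw a
  non-central z calibrated so the odds of p < 0.05 between ASM and
  non-ASM SNPs equal `enrichment_or` (default 2) in expectation.
  Enrichment is injected through the test statistic because the pipeline
  only ever consumes summary statistics. `n_signal` blocks (default 8,
  the number of significant tags the design anticipates) receive one
  strong planted signal (z centred on 6, comfortably past desk-scale
  Bonferroni); 3.2% of ASM SNPs are omitted from the file, the retrieval
  gap a real summary-statistics join shows. Omission spares planted
  signals: it models platform gaps among null SNPs, and the end-to-end
  manifest comparison needs the planted truth retrievable.
* **Annotations** — per-CpG genes with strand-aware TSS placement (80% of
  CpGs strictly < 5 kb upstream, the rest 6–50 kb); eQTL slope signs
  inverse to the risk-aligned methylation sign with probability
  `consistency_rate` (default 1); histone-mark flags at Bernoulli rate
  0.047 per (region, mark), which makes ~85% of SNPs carry at least one
  of the 40 possible marks; a 7-structure volume GWAS with uniform null
  p-values, planted hits on up to three signal SNPs, and 10% of SNPs
  absent (reported as "?").

A green end-to-end test therefore establishes that the pipeline's
bookkeeping, thresholds, orientation logic and selection rules are exactly
right **on a world that satisfies the model's assumptions**. It does not
establish robustness to population mismatch between panel and GWAS,
imputation artefacts, build/lift-over errors, trans-ASM, or catalog
heterogeneity beyond the planted kinds.

## Numerical and design choices

* **r² routes.** The production path computes r² as the squared Pearson
  correlation of alt-allele indicators (identical algebraically to the
  D²-over-variances formula); tests compare it against an independent
  brute-force haplotype-counting oracle at 1e-12. Monomorphic variants
  are an error, never r² = 0.
* **EM for unphased input** iterates Hill's two-locus scheme to a
  log-likelihood change < 1e-10 (cap 1000); non-convergence raises a
  condition carrying the last estimate, and the all-double-heterozygote
  degeneracy (likelihood cannot separate coupling from repulsion) is
  flagged `ambiguous` rather than silently returned.
* **Greedy tagging** picks, per CpG, the candidate covering the most
  untagged candidates at r² ≥ `tag_r2`; ties break by smaller GWAS p
  (favouring analyzable tags), then leftmost position, so output is
  deterministic. This is pairwise tagging; aggressive multi-marker
  tagging is out of scope.
* **LD blocks** are connected components of the r² ≥ 0.85 graph restricted
  to same-chromosome edges, labelled in leftmost-coordinate order.
  Gabriel-style confidence-interval blocks were rejected as unnecessary
  complexity for grouping an already-selected variant set.
* **Eigenvalue hygiene.** Meff snaps near-integer eigenvalues (|λ −
  round(λ)| < 1e-9) before flooring — a block of perfect duplicates yields
  λ = M only up to rounding error, and the floor is discontinuous there.
* **Merging** keeps, for a pair reported by several sources, the
  coordinates/R²/direction of the source with the largest R² (strongest
  evidence); provenance keeps every source. Merge is idempotent, and
  filter membership is order-independent (audit counts are not, and say
  so).
* **Prioritization score** is the unweighted sum of enhancer marks,
  promoter marks, eQTL gene count and volume-hit count; the weights are
  exposed because "number of functional annotations" has no canonical
  operational definition. Ties break by smaller p, then position;
  variants absent from the summary statistics rank last.
* **Volume Bonferroni denominator** is the number of queried SNPs present
  in the volume table, recomputed per run.

## Known limitations

* π0 estimation below 100 tests silently becomes BH; that is intended but
  means small screens never benefit from π0 < 1.
* The Li–Ji Meff is one member of a family of eigenvalue estimators;
  other calculators will give somewhat different thresholds on the same
  panel.
* Strand-ambiguous SNPs that match by identity/swap are trusted, as
  discussed above; supply frequency-checked input if palindromic SNPs
  worry you.
* The consistency verdict uses eQTL sign agreement across tissues;
  tissue-discordant genes get their own verdict
  (`discordant-across-tissues`) and are never silently called consistent.
* Predicted-expression (TWAS-style) association is out of scope; the
  expression column of the report derives from the eQTL table only.

## Reproducing the analysis shape

```{r demo, eval = FALSE}
run <- run_demo(seed = 42)
run$flow        # Fig.-1-style flow counts
run$report      # one putative causal SNP per LD block
```

Every number printed by the demo is written to `flow_summary.json`,
`screen_thresholds.json` and the stage TSVs in the run directory, with the
thresholds used logged in `run_log.txt`.
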