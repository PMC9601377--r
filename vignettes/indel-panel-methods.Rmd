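---
title: "Methods: forensic population genetics of biallelic InDel panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forensic population genetics of biallelic InDel panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelpop)
```

`indelpop` implements the complete statistical battery used to characterise
a panel of biallelic insertion-deletion (DIP) markers in a reference
population: per-locus diversity and forensic efficiency parameters,
Hardy-Weinberg (HWE) and linkage-disequilibrium (LD) testing, combined
identification indexes, bias-corrected FST with neighbor-joining trees and
SMACOF ordination, and locus-by-locus AMOVA. This vignette documents the
models, the numerical choices, and what the synthetic-data generators do and
do not emulate.

## Data model

Three tidy tables carry everything:

- a **genotype table**: one row per sample (`sample_id`, optional
  `population`), one character column per locus with unordered calls
  `"D/I"`; the missing token defaults to `"./."`. Calls are normalised on
  read, so `"I/D"` and `"D/I"` are the same genotype.
- **genotype counts** per biallelic locus, `(n_dd, n_di, n_ii, n)` — the
  sufficient statistic for all single-locus computations. Missing calls are
  excluded per locus (complete-case `n`); a locus with no calls at all is an
  error rather than a silent drop.
- a **population frequency table** in long format (`population`, `locus`,
  `allele`, `freq`, `n`) for the between-population machinery. Frequencies
  are stored at full precision; rounding to 4 decimals happens only in
  report writers.

## Reconstructing counts from published summaries

A published per-locus row — allele frequencies and observed heterozygosity
to 4 decimals, with the sample size — pins the integer genotype counts
essentially uniquely: `n_di` is the nearest integer to `het_obs * n` and the
insertion-allele count the nearest integer to `freq_ins * 2n` (rounding
error at 4 decimals is at most 0.5 of a unit when `2n <= 2000`), and the
homozygote counts follow by subtraction. `reconstruct_counts()` applies this
rule and then verifies the inverse map: recomputed proportions must match
the inputs within `5e-5`, half of one unit in the fourth decimal. Rows with
no integer solution raise an error that reports the closest candidate and
its residual rather than guessing silently.

The bundled reference table (`load_dipplex_panel()`) has one quirk the
loader resolves numerically at load time: its two heterozygosity columns are
swapped relative to their printed legend. The column labelled as observed
heterozygosity equals Nei's unbiased expected heterozygosity
`2pq * 2n/(2n-1)` at every locus to 4 decimals, while the column labelled
as expected contains values above the biallelic expected-heterozygosity
maximum attainable at the stated sample size (about 0.5004 at n = 631),
which only an observed proportion can reach. Internal consistency of the
numbers outranks the legend, so the loader maps the columns accordingly,
re-derives both facts before returning, and informs once per session. The
same inconsistency propagates to the source's quoted column averages, which
are cross-assigned; the package reports the averages as computed from the
reconstructed counts.

## Forensic efficiency parameters

With `p`, `q = 1 - p` the allele frequencies, `h` the observed heterozygote
proportion and `H = 1 - h`:

- expected heterozygosity uses Nei's small-sample correction
  `(2n/(2n-1)) (1 - sum p_i^2)`; this choice reproduces the reference
  table's expected-heterozygosity column exactly.
- PIC is Botstein's `1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2`.
- match probability is computed from **observed** genotype proportions, not
  HWE-expected ones (`PM = sum g_k^2`, `PD = 1 - PM`), matching the
  convention of the STRAF-family tools; the observed convention reproduces
  the reference PD column at every locus.
- PE uses the Brenner/Fisher form `h^2 (1 - 2 h H^2)` and TPI is `1/(2H)`;
  both are functions of observed heterozygosity alone and are strictly
  increasing in it. TPI is an error, not infinity, at `h = 1`.
- combined indexes multiply per-locus values: `cPM = prod(PM)`,
  `cPD = 1 - cPM`, `cPE = 1 - prod(1 - PE)`.

`summarize_counts()` / `summarize_panel()` return a fitted-object-style
`indel_panel` with `tidy()` (per-locus table), `glance()` (combined
indexes), `autoplot()` and a published-style report writer that rounds to 4
decimals at write time.

## Hardy-Weinberg testing

The exact test conditions on the allele counts: under HWE the heterozygote
count follows the Levene/Haldane distribution, and the two-sided p-value is
the probability-ordering tail — the sum of conditional probabilities of all
heterozygote counts no more probable than the one observed. Monomorphic
loci return p = 1 (a single admissible outcome). The Monte-Carlo test
re-pairs the pooled `2n` alleles uniformly at random (a genuine permutation
of gametes rather than a draw from the enumerated distribution), scores each
re-pairing by its Levene probability, and uses the add-one estimator
`(k + 1)/(n_perm + 1)`, which never returns zero. The default
`n_perm = 10000` mirrors the conventional setting for forensic panels.
Per-locus streams derive from one master seed by a fixed counter scheme, so
panel-level results do not depend on evaluation order.

## Linkage disequilibrium

Unphased two-locus data leave the gametic phase of double heterozygotes
ambiguous. `em_haplotypes()` maximises the random-union-of-gametes
likelihood by EM over that ambiguity (Excoffier-Slatkin), for any allele
counts at either locus; the log-likelihood is asserted non-decreasing at
every iteration, convergence is a log-likelihood gain below `1e-8` with a
1000-iteration cap, and multiallelic pairs use 3 seeded restarts (the first
start is always the linkage-equilibrium configuration) to dodge local
optima. The LD statistic is `-2 (logL_null - logL_full)` with the null
fixing haplotype frequencies at allele-frequency products. Significance
comes from permuting one locus's genotype column across samples — which
preserves both single-locus genotype distributions exactly — and recomputing
the statistic, again with the add-one estimator. `ld_all_pairs()` runs all
`C(L, 2)` pairs (435 for a 30-locus panel) with per-pair derived seeds and
flags significance after Bonferroni correction (`alpha/m`; 0.05/30 = 0.00167
for per-locus HWE, 0.05/435 for all pairs).

## FST, trees, ordination, AMOVA

**FST.** Per locus, the package uses the Nei-Chesser (1983) bias-corrected
estimators of within- and total heterozygosity with the harmonic mean
sample size, with observed heterozygosity entering at its HWE expectation
(appropriate for allele-frequency-only inputs); `fst = 1 - Hs/Ht` per locus
and `1 - mean(Hs)/mean(Ht)` multilocus. Negative estimates are legitimate
sampling outcomes and are preserved in results; they are clamped to zero
only when a matrix is used as a distance. Loci monomorphic for the same
allele in all populations have `Ht = 0` and are excluded from the ratio.

One property of this estimator family matters for interpretation: its
"total" heterozygosity refers to the pooled mixture of the compared
populations. With only two populations the estimator therefore converges to
`F/(2 - F)` rather than `F` when each population sits at coancestry `F`
from a common ancestor — an intrinsic property of Gst-type measures, not a
bug. With many populations the deme-number factor `(1 - 1/s)/(1 - F/s)`
approaches 1; the package's parameter-recovery checks therefore run at the
20-population scale of the worldwide comparison, where recovery is within
±0.03 across `F` from 0.02 to 0.20, and the two-population case is checked
against its `F/(2 - F)` expectation.

**Neighbor joining** follows Saitou-Nei exactly: join the pair minimising
`Q_ij = (m-2) d_ij - r_i - r_j`, with ties broken by the lowest index pair
in current matrix order (original label order first, created nodes
appended). Negative branch lengths — routine with FST distances — are set to
zero with the deficit transferred to the sister branch so the joined pair's
path length is preserved (Kuhner-Felsenstein); the terminal three-way join
clamps at zero. Additive matrices are recovered exactly (verified against
the reference implementation in ape on random trees of 4-12 taxa). Trees
are unrooted, serialised to Newick at 6 decimals with children ordered by
smallest descendant label so output is deterministic.

**SMACOF.** Metric MDS by stress majorization: Torgerson (classical
scaling) initialisation, Guttman-transform updates, stop when the raw-stress
decrease falls below `1e-8` or after 10000 iterations. The deterministic
initialisation makes results reproducible without a seed; majorization
guarantees a non-increasing stress sequence, which the implementation
asserts at every step. Reported stress is normalised stress-1. Degenerate
all-zero matrices return all points at the origin with zero stress.

**AMOVA.** One-level analysis on the allele identity/non-identity distance:
sums of squares over the `2n` alleles partition variance into among- and
within-population components, `phi_ST = among/(among + within)`, with
significance from permuting individuals (keeping their two alleles
together) across populations. The among-component estimator is unbiased and
may go negative under panmixia. For unlinked biallelic loci this allelic
AMOVA is equivalent to an FST-based analysis; with two weakly
differentiated populations the multi-locus `phi_ST` and pairwise FST agree
closely (the package checks agreement within 0.02 at `F = 0.02`, the
homogeneity regime relevant to comparing regions of one country — at strong
differentiation the two estimators diverge by construction, as above).

## Synthetic data: what it does and does not emulate

The generators produce the statistical structure the analysis assumes,
so every stage is testable without external data:

- `simulate_hwe_genotypes()`: independent loci, genotypes
  `(p^2, 2pq, q^2)` — the HWE null.
- `simulate_inbred_genotypes()`: heterozygote deficit
  `(p^2 + F_IS pq, 2pq(1 - F_IS), q^2 + F_IS pq)` — the alternative used
  for HWE power checks.
- `simulate_balding_nichols()`: population frequencies drawn from
  `Beta(p(1-F)/F, (1-p)(1-F)/F)` around an ancestral `p`, genotypes HWE
  within populations — ground truth for FST recovery, with the Beta moment
  identity (across-population heterozygosity reduced by `1 - F`) as an
  analytic check.
- `simulate_multiallelic_locus()`: HWE genotypes over `k` alleles, for
  mixed STR-by-InDel LD tests.

The default study-like panel (`simulate_reference_panel()`) mirrors the
reference design: 30 loci at the published frequencies, 631 individuals,
three region labels. The regional sample sizes were not published, so the
default splits the sample as evenly as possible (211/210/210) — a package
choice, stated here once.

All generators derive per-locus and per-population streams from one master
seed via a fixed integer counter scheme, making outputs bit-reproducible
and order-independent. What they do **not** emulate: genotyping error and
allelic dropout, missing-data patterns, mutation, physical linkage between
loci on the same chromosome, and real multi-locus phase structure. Passing
the synthetic checks therefore demonstrates correctness of the estimators
under their stated models, not robustness to laboratory artefacts.
Similarly, `counts_to_genotypes()` re-pairs loci arbitrarily across
samples: single-locus statistics are exact, but its tables carry no real
multi-locus signal, which is precisely why LD calibration uses the
simulators instead.

## Problem sizes and numerical conventions

The test suite exercises the stochastic machinery at sizes chosen to make
Monte-Carlo error small relative to the tolerances checked: 1000 simulated
loci (n = 631) for HWE size, 300 panels for the Bonferroni gate, 200
simulated locus pairs (n = 631, 99 permutations) for LD size, 20
populations of 500 for FST recovery, and 200 replicates for AMOVA
calibration; assertions on Monte-Carlo quantities use binomial error bands
(typically 3 standard errors) rather than point equalities. Other
conventions: EM tolerance `1e-8` on the log-likelihood; SMACOF tolerance
`1e-8` on raw stress; frequency vectors validated to sum to 1 within
`1e-6` (tiny deviations renormalised, larger ones rejected); distance
matrices validated symmetric within `1e-12`; reconstruction consistency at
`5e-5`. p-value estimators are add-one throughout, so permutation p-values
are never zero.

## Known limitations

- Match probabilities are uncorrected for population substructure (no
  theta/NRC-II adjustment); TPI is the only kinship index.
- The exact HWE path is biallelic (sufficient for DIP panels); multiallelic
  loci go through the Monte-Carlo machinery only via LD.
- Pairwise Gst-type FST compresses strong differentiation (see above);
  for two-deme absolute coancestry a variance-components estimator would be
  needed.
- AMOVA is single-level (populations within total); no region/population
  hierarchy.
- Newick serialisation assumes unique tip labels.
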