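---
title: "Calling tissue-specific differential methylation from methyl-sensitive cut counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling tissue-specific differential methylation from methyl-sensitive cut counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msccdm)
```

## The measurement and the model

Methyl-sensitive cut counting profiles DNA methylation by sequencing
tags adjacent to the recognition sites of methylation-sensitive
restriction enzymes (motifs CCGG, ACGT, GCGC, CCGC, GGCG — each
containing one CpG). An unmethylated CpG is cut efficiently and yields
many tags; a methylated CpG yields few. After scaling each library by a
factor proportional to the inverse of its total read count, the
normalized tag count at a site — its *digestion frequency* (df) — is a
monotone proxy for unmethylation. Across sites the df distribution is
bimodal: a methylated mode near zero and an unmethylated mode around
25–30.

The pipeline asks, for a multi-tissue design (canonically 4 tissues
× 3 replicate libraries): at which sites does methylation differ
between tissues (DMS), and at which is it unusually high or low in
exactly one tissue (TS-DMS)?

## The procedure, stage by stage

1. **Normalization** (`normalize_libraries`). Factor
   `target_depth / library_total` per library; the default target is
   the mean library total, so the scale of df values is preserved.
   Normalization is applied to the whole experiment at once, spike-in
   rows included, matching the equimolar spike-in design.

2. **Cutoff** (`cgi_mean_df`, `find_valley_cutoff`). The per-CGI mean
   df scores form a bimodal histogram; the cutoff separating
   methylated from unmethylated is the minimum of a kernel-density
   smoothing between the two largest modes. Two numerical guards make
   the valley search robust: a mode must reach at least 5% of the peak
   density (kernel wiggles in the tails are not modes), and the valley
   must dip below 80% of the smaller mode. If no such valley exists the
   operative fixed cutoff of 10 is used, with a warning. Sites not
   reaching the cutoff in any library are presumed methylated
   everywhere and excluded (`prefilter_sites`; inclusive `>=`, and a
   stricter per-group variant is available).

3. **Pairwise Welch tests** (`welch_pairs`). All `choose(k, 2)` group
   pairs are tested per site with the unequal-variance t statistic and
   Welch–Satterthwaite degrees of freedom. A variance floor of `1e-8`
   on the squared standard error handles zero-variance replicate
   triplets (two constant groups with equal means give p = 1, with
   different means a decisive p). Standardized residuals
   (`standardized_residuals`, `qq_normality`) give an advisory normal
   QQ diagnostic — the caller warns below correlation 0.95, never
   blocks.

4. **mdFDR selection** (`mdfdr_select`). The mixed-directional FDR —
   false site selections plus wrong-direction pair claims — is
   controlled by a two-stage procedure: per-site screening p-value
   `p* = min(m * min_j p_ij, 1)` (Bonferroni over the m pairs),
   Benjamini–Hochberg on the p* at level α selecting R sites, then
   within each selected site a pair is significant iff
   `p_ij <= R * alpha / (N * m)`, its direction the sign of its t
   statistic.

5. **Minimum difference and classification** (`min_diff_filter`,
   `classify_ts`). Significant pairs whose group means differ by less
   than δ (default: the stage-2 cutoff, operative value 10) are
   dropped, so statistical significance also implies a different
   methylation state. A site is `ts_unmeth(g)` iff exactly the k−1
   pairs involving g are significant with g's mean higher in each, and
   no other pair is significant (strict mode; a lenient mode ignoring
   the complementary pairs sits behind `strict = FALSE`); `ts_meth(g)`
   symmetrically.

## Spike-in calibration and what "10%" can mean

Unmethylated lambda DNA spiked equimolarly into every library
contributes ~1,202 sites that are genuinely unmethylated everywhere: a
built-in global null. `empirical_fdr` reruns the identical machinery on
those rows and reports the flagged fraction.

The stage-1 multiplicity treatment matters enormously here, and the
package makes the choice explicit:

* `screening = "bh"` runs the BH screening across the spike-in rows
  alone. On a complete null BH's expected rejection count is below one
  per thousand sites, so the flagged fraction is ~0% regardless of α —
  it measures the procedure's conservatism, not a per-site error rate.
* `screening = "saturated"` (default) screens each site at level α
  with Bonferroni follow-up at α/m. This is the limiting behaviour of
  the BH stage when the null rows are embedded in a signal-dense
  genome-wide analysis whose data-driven selection threshold approaches
  α — which is how a spike-in travels through a real experiment, and
  the only reading under which "fraction of null sites flagged ≈ α" is
  even approximately expected.

Even in saturated mode, an iid simulated null flags about 5%, not 10%,
at α = 0.10: the ×m Bonferroni on six positively dependent pairwise
tests is conservative by roughly a factor of two (independence would
give `1 − (1 − α/6)^6 ≈ 0.096`; the shared group means push it down
further). The rate is insensitive to the count dispersion. An observed
flagged fraction *equal* to the nominal level on real spike-in data
therefore implies some genuine between-library variation in the
spike-in block (batch or spike-ratio effects) rather than an iid null —
a useful diagnostic reading, and the reason the calibration script
reports the Monte-Carlo band alongside the single-run value.

## The synthetic methylome: what it emulates and what it cannot

`simulate_methylome` draws negative-binomial counts with mean
`state mean × library factor`:

* `mu_unmeth = 30`, `mu_meth = 2` — the two df modes;
* `frac_methylated_everywhere = 0.75` — mammalian genomes run at
  roughly 70–80% methylated CpGs;
* `frac_ts_unmeth = 0.01`, `frac_ts_meth = 0.001` per group — planted
  tissue-specific sites, hypermethylated ones 10× rarer, mirroring the
  observed dominance of hypomethylated TS-DMS (~94%);
* `dispersion = 50` (NB size; CV ≈ 23% at the unmethylated mean) —
  isogenic-mouse triplicates: counting noise plus mild biological
  overdispersion. `Inf` gives the Poisson limit, making the
  pure-counting regime testable;
* library factors ~ Uniform(0.7, 1.3); a 1,202-site spike-in block,
  unmethylated in every library.

`simulate_toy_genome` adds the genomic side: a random genome whose
enumerated recognition sites carry the planted states, CGIs with
coherent methylation (so their mean-df histogram is genuinely bimodal
and the valley cutoff is derivable), per-tissue enhancer sets with a
configurable planted fold enrichment of TS sites, and gene models with
an expression-call table whose unique-expression calls track TS
association.

**Known limitation — detection power.** Count-level noise has a floor:
a negative binomial at mean 30 cannot have CV below the Poisson 18%.
With triplicates, a 30-vs-2 contrast then yields Welch t around 9 on
~2.3 degrees of freedom, whose heavy tail keeps per-pair p-values above
~10⁻³, while BH screening with ~4% planted signal demands p* in the
10⁻³–10⁻⁴ range. The consequence is honest but stark: on the default
simulation the caller recovers only a few percent of planted TS sites
(every recovered label correct, empirical FDR ≈ 0). Real experiments of
this design detect vastly more, which implies their replicate
variability at df ≈ 30 is effectively sub-Poisson on this scale —
a regime a count-level simulator cannot reach at these means. Passing
tests on this generator therefore validate error control, direction
assignment, classification logic and the downstream stages; they do
not certify the sensitivity attainable on tighter real data.

What survives the power limitation is instructive: the recovered
TS-DMS, few as they are, reconstruct the tissue structure — Pearson
correlation-distance, average-linkage clustering of the 12 samples on
the called TS-DMS signature is pure at k = 4, and a held-out library
simulated from one tissue's profile joins that tissue's subtree.

## Annotation, enrichment, clustering choices

* Coordinates are 0-based half-open throughout; BED is the interval
  dialect. The motif scan is forward-strand with the five literal
  motifs (the list is configurable since GGCG/CCGC form a strand
  pair); coincident motifs at one CpG collapse to a single record,
  first configured motif winning.
* Gene windows are strand-aware: TSS region −3 kb/+2 kb, gene body,
  3′ region 3 kb past the downstream edge, with precedence
  TSS > body > 3′ when genes overlap. CGI shores extend 2 kb; island
  membership excludes shore. Gene association is strong within the
  gene span ±3 kb, else weak to the nearest TSS; ties break to the
  lexicographically smaller gene id, deterministically.
* The expression odds ratio is `(a/c)/(b/d)` with a Wald test on the
  log scale (`sqrt(1/a + 1/b + 1/c + 1/d)`), Haldane–Anscombe +0.5 on
  zero cells; the gene universe is an explicit input because published
  counts alone do not determine it.
* Fold enrichment is the ratio of the TS-DMS overlap fraction to the
  all-sites overlap fraction; its permutation p-value places
  length-matched random regions (chromosome chosen ∝ length among
  those the region fits, start uniform), allows placed regions to
  overlap, and uses the add-one estimator `(1 + #{>= obs}) / (B + 1)`,
  so p is never 0 and bottoms out at `1/(B+1)`.
* Signatures are `log2(df + 1)` (the pseudocount pins df 0 to 0);
  heatmap colour anchors black at df 0 and saturated red at df ≥ 50.
  Linkage is average by default (complete and single available);
  the "first 40 rows" restriction is display-only. Cluster purity cuts
  the tree at k and scores majority-label agreement.

## Problem sizes used

The bundled analysis scripts and the test suite run the generator at
5–10 thousand genomic sites with the 1,202-site spike-in block, 50
Monte-Carlo replicates for calibration summaries, and 1,000–2,000
permutation iterations — sizes chosen so a complete run takes minutes
on a laptop while keeping Monte-Carlo standard errors around 0.1% for
calibration rates. All stages scale linearly in sites × samples and
accept larger inputs unchanged.
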