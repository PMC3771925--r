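# msccdm

Differential DNA methylation from methyl-sensitive cut counting.

Methyl-sensitive restriction enzymes cut unmethylated CpGs; counting
sequencing tags at each recognition site (motifs CCGG, ACGT, GCGC,
CCGC, GGCG) gives a per-site *digestion frequency* (df) that is high at
unmethylated CpGs and near zero at methylated ones. For a multi-tissue
design (4 tissues × 3 replicate libraries), `msccdm` implements the
full analysis:

1. library normalization to a common depth;
2. a methylated/unmethylated df cutoff read off the valley of the
   bimodal per-CpG-island score distribution (fixed fallback 10), and
   exclusion of sites below the cutoff in every library;
3. all six pairwise Welch t tests per site,
   `t = (x̄_a − x̄_b) / sqrt(s²_a/n_a + s²_b/n_b)` with
   Welch–Satterthwaite df;
4. mixed-directional FDR control (two-stage: Bonferroni-combined
   screening p\* per site, Benjamini–Hochberg across sites at level α,
   then per-pair follow-up at `R·α/(N·m)` with sign-based directions);
5. a minimum group-mean-difference filter (δ = the cutoff) and
   classification of **TS-DMS**: sites significantly un- or
   hyper-methylated in exactly one tissue;
6. empirical false-discovery calibration on the 1,202-site unmethylated
   lambda spike-in block carried by every library;
7. genomic annotation (TSS −3/+2 kb, gene body, 3′ 3 kb, intergenic;
   CGI island/shore/outside), gene association (±3 kb strong, nearest
   TSS weak), expression odds ratios `(a/c)/(b/d)`, and fold
   enrichment of TS-DMS in enhancer sets with a length-matched
   random-placement permutation p-value;
8. epigenetic-signature clustering: Pearson correlation distance on
   `log2(df + 1)` profiles, average linkage, tissue purity, Newick and
   heatmap output.

A negative-binomial synthetic-methylome generator with planted
tissue-specific sites, a toy genome with annotations, and ground-truth
tables makes every stage testable end to end. See
`vignettes/methylome-differential-analysis.Rmd` for the model,
parameter defaults, numerical choices, and known limitations.

## Worked example

```r
library(msccdm)

sim <- simulate_methylome(sim_config(seed = 7))   # 10,000 sites + spike-in
x   <- normalize_libraries(sim$set)
call <- call_dms(genomic_rows(x), alpha = 0.10, cutoff = 10)
print(call)
#> DMS call at mdFDR 0.1
#>   surveyed 10000 -> retained 2465 (df cutoff 10)
#>   selected 93; DMS after min-diff 10: 89; TS-DMS: 29
#>   hypomethylated (ts_unmeth): brain=7 kidney=8 liver=10 testis=4
#>   hypermethylated (ts_meth): brain=0 kidney=0 liver=0 testis=0

print(empirical_fdr(x, alpha = 0.10))
#> spike-in calibration (saturated screening): 48/1202 flagged = 3.99% at nominal 10%

ts <- ts_dms(call)
hc <- hierarchical_cluster(correlation_distance(
        signature_matrix(x, ts$site_id)))
cluster_purity(hc, x$samples$group, k = 4)
#> [1] 1
```

Reading: of 10,000 simulated CpGs, 2,465 reach the unmethylation
cutoff in at least one library; 93 are selected at mdFDR 10%, 89
survive the minimum-difference filter, and 29 are tissue-specific, all
hypomethylated — and the 12
libraries cluster perfectly by tissue on that TS-DMS signature. The
spike-in block, a built-in global null, shows the empirical per-site
flagging rate of the selection procedure (about half the nominal level
on an iid null; the vignette explains why).

The numbered scripts under `analysis/` run the same stages as a
narrative workflow (simulate → normalize/cutoff → call → calibrate →
annotate → enrich → cluster), writing tables under `results/`.

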