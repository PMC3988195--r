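# rvcluster

Region-based association testing of **clustered rare variants** in
case-control studies.

Rare variants (MAF ≤ 5%) are too sparse to test one at a time, and causal
ones tend to cluster physically — variants hitting the same protein domain
or regulatory element sit close together on the sequence.  `rvcluster`
implements a region test that exploits both facts: per-site evidence is
truncated adaptively (sites with weak P-values are dropped), and the
surviving signals are combined through a spatial proximity kernel so nearby
significant sites reinforce each other.

For a region with K rare sites, each site i contributes a Fisher mid-P
value p_i (or a logistic-regression P-value under covariate adjustment), a
direction class (deleterious- vs protective-inclined, from the sign of the
case–control frequency difference), and a Madsen–Browning weight
w_i = 1/√(n q_i(1−q_i)) with q_i the smoothed control minor-allele
frequency.  At truncation threshold τ, the direction-split signal vectors
u_del and u_pro hold w_i · 1[p_i < τ] for sites in the matching class, and
the statistic is the quadratic form

    S(τ) = u_del' C u_del + u_pro' C u_pro,

with tri-weight spatial kernel c_ij = (1 − (d_ij/d_max)²)³ for inter-site
distance d_ij < d_max (default 20 kb), 0 beyond.  A grid of thresholds
(0.10–0.20) is scanned and significance comes from a permutation minimum-P
procedure: B case/control shuffles, full recomputation of P-values,
directions and weights under each, and ranking of the observed minimum
per-threshold P-value against the permuted minima.  With the identity
kernel the procedure is exactly the adaptive combination of P-values (ADA)
test.  A Madsen–Browning weighted-sum burden test (`ws_test()`) runs under
the same permutation engine as a baseline, and a built-in simulator
generates case-control data from a rare-skewed haplotype pool with a
PAR→GRR multiplicative penetrance model for calibration and power studies.

## Worked example

Simulate a 20 kb region with 20 clustered deleterious causal variants
(PAR 1% each), filter to rare sites, and test:

```r
library(rvcluster)

cfg <- sim_config(H = 2000, n_sites = 120, n_causal = 20, cluster_span = 6000,
                  n_protective = 0, n_deleterious = 20, par = 0.01,
                  n_cases = 500, n_controls = 500, seed = 42)
dat   <- simulate_case_control(cfg)
panel <- maf_filter(dat$panel, dat$pheno)   # drop MAF > 5% and monomorphic
panel
#> genotype_panel: 1000 subjects x 98 sites, positions 16..19971 bp

res <- cluster_test(panel, dat$pheno, B = 1000, seed = 7)
res
#> CLUSTER test: adjusted P = 0.000999 (B = 1000 permutations)
#>   min per-threshold P = 0 over 11 thresholds [0.1..0.2]
#>   500 cases / 500 controls, 98 sites, statistic=split, g(p)=indicator

ws_test(panel, dat$pheno, B = 1000, seed = 7)
#> WS burden test: rank-sum = 279119.50, P = 0.000999 (B = 1000)
#>   500 cases / 500 controls, 98 sites
```

The adjusted P of 0.000999 = 1/(B+1) is the smallest value B = 1000
permutations can report: no permuted dataset produced a minimum
per-threshold P-value as small as the observed one, i.e. the clustered
signal is detected decisively.  The per-site table shows what drove it —
the strongest sites are deleterious-inclined and sit within the causal
window:

```r
head(res$site_summaries[order(res$site_summaries$p_value), ], 3)
#>    site_id position      p_value            direction   weight maf_combined
#> 79  site96    15878 5.830224e-05 deleterious_inclined 1.001499       0.0070
#> 74  site90    15316 4.749675e-04 deleterious_inclined 1.001499       0.0055
#> 76  site93    15572 4.749675e-04 deleterious_inclined 1.001499       0.0055
```

Real data come in through `read_vcf()` (biallelic SNVs, minor-allele
dosages, subjects with missing genotypes dropped) or
`read_genotype_matrix()` (plain TSV).  A command-line front end with
`cluster-test`, `ada-test`, `ws-test`, `simulate`, `type1` and `power`
subcommands lives at `inst/cli/rvcluster.R`.

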