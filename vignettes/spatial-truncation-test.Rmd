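---
title: "Region testing of clustered rare variants: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region testing of clustered rare variants: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The testing problem

Individually, rare variants (minor allele frequency of a few percent or
less) carry too few observations to be tested one at a time with useful
power, so case-control association testing proceeds region by region: all
rare sites in a gene or window are combined into one statistic.  Causal
variants, however, are often not spread evenly over a region — variants
disrupting the same protein domain or regulatory element sit close together
on the sequence.  `rvcluster` implements a region test built around that
observation: association evidence is accumulated per site, weak sites are
truncated away adaptively, and the surviving signals are combined through a
spatial proximity kernel so that nearby significant sites reinforce each
other.

## The statistic

For a region with $K$ rare variant sites, each site $i$ gets

* a per-site P-value $p_i$, by default the two-sided **mid-P** of Fisher's
  exact test on the 2×2 table of minor/major allele counts by case/control
  status (each diploid subject contributes two alleles), or a logistic-
  regression Wald P-value when covariate adjustment is needed;
* a direction class: *deleterious-inclined* if the case minor-allele
  frequency strictly exceeds the control frequency, *protective-inclined*
  if strictly smaller, *tied* otherwise (tied sites join neither class);
* a **Madsen–Browning weight** $w_i = 1/\sqrt{n\,q_i(1-q_i)}$, where
  $q_i = (m_i^U + 1)/(2n_U + 2)$ is the smoothed control minor-allele
  frequency, $n_U$ the number of controls, and $n$ the total sample size.
  Rare-in-controls sites are upweighted.

Given a truncation threshold $\tau$, the deleterious signal vector has
entries $u_i = \delta_i^{del}\, w_i\, g(p_i)\, \mathbf{1}[p_i < \tau]$, and
analogously for the protective vector.  The per-site magnitude $g$ is the
pure indicator $g(p)=1$ by default, with $g(p) = -\log_{10} p$ available
(`transform = "neglog10"`); under the identity kernel both reduce to an
adaptive-combination-of-P-values statistic, and the permutation calibration
below holds for either, so neither is privileged by the machinery.  The
threshold statistic is the direction-split quadratic form

$$S(\tau) = u_{del}' C\, u_{del} + u_{pro}' C\, u_{pro},$$

where $C$ is the spatial kernel: $c_{ij} = (1 - (d_{ij}/d_{max})^2)^3$ for
inter-site distance $d_{ij} < d_{max}$ and 0 beyond (the compactly
supported tri-weight decay), $c_{ii}=1$.  The two direction classes are
never cross-multiplied: deleterious and protective variants are assumed to
form their own clusters, and mixing them would inject the distance between
opposite-effect sites into the statistic.  A pooled variant that mixes the
classes first (`variant = "pooled"`) is provided for comparison; it gains
power when roughly half the causal variants act in each direction and loses
power when effects share one direction.

Because $\tau$ is not known in advance, a grid
$\tau \in \{0.10, 0.11, \ldots, 0.20\}$ is scanned.  Significance is
assessed by a permutation minimum-P procedure with $B$ label shuffles that
preserve the case/control totals.  Under each shuffle the *entire*
construction is recomputed — P-values, direction classes, and weights —
because the weights depend on which subjects are labelled controls;
re-using observed weights would break the exchangeability the permutation
argument needs.  Each threshold's statistic becomes a permutation P-value,
the minimum over thresholds is taken for the observed and for every
permuted sample (self-inclusively for the permuted ones, so both sides of
the comparison are built from $B$ comparisons), and the reported adjusted
P-value is the add-one estimator
$(1 + \#\{b : \min_j \hat p_j^{(b)} \le \min_j \hat p_j^{obs}\})/(B+1)$.
The add-one form can never report 0 and is never anti-conservative; its
granularity is $1/(B+1)$, so $B$ bounds the smallest attainable P-value.

With the identity kernel ($c_{ij} = 0$ for $i \ne j$) positions are ignored
and the procedure is exactly the ADA test (`ada_test()`); with $d_{max}$
below the smallest inter-site gap the tri-weight kernel degenerates to the
identity, so the spatial test approaches ADA continuously.  The kernel is
not forced to be positive semi-definite: the statistic enters only through
permutation ranks, so indefiniteness cannot invalidate the P-value.

The Madsen–Browning weighted-sum burden test (`ws_test()`) is included as a
baseline under the same permutation engine: subjects are scored by
$\sum_i x_i / \sqrt{n\,q_i(1-q_i)}$, the statistic is the sum of case ranks
(midranks for ties), one-sided for excess burden in cases.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `thresholds` | 0.10–0.20 by 0.01 | truncation grid; suitable for rare-variant per-site P-values, which are discrete and rarely very small |
| `d_max` | 20,000 bp | tri-weight support; sites further apart never interact |
| `B` | 1,000 | permutations; smallest reportable P is $1/(B+1)$ |
| `max_maf` | 0.05 | pooled-MAF cutoff defining "rare"; sites at exactly 5% are retained, monomorphic sites removed |
| `transform` | `"indicator"` | per-site magnitude $g(p)$ |
| `variant` | `"split"` | direction-split vs pooled quadratic form |

## Numerical and edge-case conventions

* The mid-P uses the probability-based two-sided rule — outcomes strictly
  less probable than the observed count contribute fully, equally probable
  outcomes half — with a $1 + 10^{-7}$ relative tie tolerance for floating
  comparisons.  A degenerate table (no minor alleles, or nothing but minor
  alleles) is defined to have $p = 1$: it carries no information.
* Truncation uses strict $p < \tau$; a P-value exactly at the threshold is
  excluded.
* Under label permutation each site's total minor-allele count is fixed, so
  the mid-P depends only on the case minor-allele count; the implementation
  tabulates the hypergeometric mid-P once per distinct site total and looks
  permuted values up, which is what makes $B$ in the hundreds per replicate
  affordable in the calibration experiments.
* Weight smoothing ($+1$ in $q_i$) keeps $0 < q_i < 1$ even when a shuffled
  labelling leaves a site with no control minor alleles, so weights are
  always finite.
* Panels with every site tied (identical case and control frequencies)
  yield an adjusted P of exactly 1, with a warning.
* Missing genotypes are handled by dropping the subject at load time; no
  imputation.  Per-site tables use allele counts (two per subject), the
  conventional coding for rare-variant exact tests; carrier coding is not
  offered.

## The simulator

`simulate_case_control()` provides the synthetic study conditions for
calibration and power experiments.  A pool of $H$ haplotypes over a region
(default 20 kb, ~330 sites, emulating deep resequencing of a gene-sized
region) is generated with per-site pool frequencies drawn from a
$1/x$-shaped spectrum on $[1/H, 0.05]$ — the rare-skewed site-frequency
spectrum characteristic of resequencing data — plus a 15% admixture of
common sites (frequency 0.05–0.5) so that the MAF filter is exercised.
Alleles are independent across sites by default, reflecting the low linkage
disequilibrium typical of rare variants; an optional founder-mosaic step
(`ld_founders`) induces local LD for sensitivity checks.

Causal variants are placed either clustered (all inside a random window,
default 6 kb) or approximately equally spaced across the region, split into
protective and deleterious sets.  Effect sizes come from the population
attributable risk: $GRR = PAR/(MAF(1-PAR)) + 1$ per deleterious allele,
the reciprocal for protective alleles, with MAF taken from the pool (PAR is
a population quantity).  Disease status is Bernoulli at the multiplicative
penetrance $f_0 \prod_j GRR_j^{g_j}$ (baseline $f_0 = 1\%$), and subjects
are drawn with replacement until the case and control quotas (default
500 + 500) are filled.

What the simulator deliberately does **not** emulate: coalescent gene
genealogies, demographic history, recombination maps, or realistic LD
structure.  Test calibration (type-I error) does not depend on those
features — it only requires genotypes independent of phenotype — but power
on real data does: surrounding variants in LD with causal ones contribute
signal that this generator's independent sites cannot, so absolute power
levels here understate what correlated real data can provide, and passing
power checks demonstrate orderings, not field performance.

## Experiment scale

The calibration driver `run_type1()` defaults to a reduced but
statistically meaningful scale chosen so a full run completes in minutes on
one CPU: 2,000 replicates, 200 cases + 200 controls, a pool of 2,000
haplotypes with 70 sites (~60 rare after filtering), $B = 500$.  At this
site density a 6 kb window reliably holds about 18 rare sites, so the
reduced design places 10 causal variants (the full design's 20 would not
fit); the power experiments that need 20 clustered causal variants use a
denser 120-site map instead.  Power runs use $B = 200$ and 150–300
replicates per scenario, echoing the usual practice of spending fewer
permutations on power than on type-I estimation.  Rejection rates are
reported with binomial standard errors; at 2,000 replicates the 99%
envelope around a nominal 0.05 is about ±0.013.

## Known limitations

* The adjusted P-value's resolution is $1/(B+1)$; genome-wide significance
  claims need $B$ in the $10^5$ range, which the current engine supports
  but at proportional cost.  No adaptive early stopping is implemented.
* Control-based weighting targets alleles rare in controls, so evidence
  from protective variants — whose minor alleles are *enriched* in controls
  — is systematically downweighted relative to an equally strong
  deleterious configuration.  With weak protective effects and small
  samples this can depress power toward (or below) the nominal level even
  though calibration under the null remains exact; the direction-split
  statistic recovers protective signal as samples or effect sizes grow.
* Only two kernel measures ship (tri-weight, identity); other decay shapes
  would slot into the same seam but are not exposed.
* Single-region, single-chromosome analysis; no covariates outside the
  logistic per-site engine; no multi-gene batch orchestration.
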