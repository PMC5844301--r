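---
title: "Genotype-likelihood sweep scans and domestication topology tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-likelihood sweep scans and domestication topology tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The inference problem

Asian rice (*Oryza sativa*) comprises three major domesticated
subpopulations — aus, indica and japonica — each phylogenetically closest to
a distinct wild (*O. rufipogon/nivara*) subpopulation: japonica to Or-III,
aus and indica to different subsets of Or-I, with Or-II the most distant
wild group. Two domestication histories are compatible with that
genome-wide picture:

* **single de novo domestication with introgression** — the domestication
  alleles arose once (on the japonica lineage) and moved into the ancestors
  of aus and indica by gene flow. At a true domestication locus all
  domesticated samples then share one recent haplotype, so the local gene
  tree shows the *domesticates as one clade*, unlike the genome-wide tree;
* **multiple independent domestications** — each subpopulation fixed its own
  sweep on its own background, so domestication-locus trees look like the
  genome-wide tree (each domesticate sister to its own wild progenitor).

The discriminating evidence therefore comes from (i) finding candidate
domestication sweeps as windows where domesticated diversity collapses
relative to wild diversity, and (ii) classifying the local tree topology at
those windows against the genome-wide topology. Both steps must work on
low-coverage (1–2×) resequencing data, where hard genotype calls are
unreliable; the whole pipeline therefore runs on genotype *likelihoods*.

This package implements the full chain and a synthetic-data generator that
emulates the assumed demography, so every stage can be calibrated against
known truth.

## The probabilistic machinery

**Genotype likelihoods.** At a biallelic site, an individual with `k0`
reads of allele 0 and `k1` of allele 1 under miscall probability `e` has

    L(0) = (1-e)^k0 e^k1,  L(1) = (1/2)^(k0+k1),  L(2) = e^k0 (1-e)^k1,

kept unnormalized in log space. Sites are filtered by the canonical
low-coverage rule: at least one-third of individuals with data, total depth
between one-third and five times the number of individuals. Those ratios
presume roughly 1× coverage, so `site_filter_preset(n, mean_depth)` scales
the two depth bounds by the expected coverage; at `mean_depth = 1` it
reproduces the rule verbatim. A single shared error rate stands in for
per-read base qualities; data emulating quality-filtered reads should use
`e <= 0.001`.

**SAF and SFS.** The site allele frequency (SAF) vector gives the
likelihood of the site's reads for each possible derived-allele count
`j = 0..2n`, computed by the standard dynamic program over individuals with
hypergeometric assignment weights. The population site frequency spectrum
is estimated from the SAF matrix by EM (uniform start, tolerance `1e-8` on
the spectrum, 500-iteration cap; the log-likelihood trajectory is returned
and is non-decreasing). The spectrum then acts as an empirical prior:
per-site posteriors are `P(j | data) ∝ p_j L_s(j)`.

The spectrum is *unfolded*, with the simulator's state 0 as ancestral
(playing the role of the reference genome used as outgroup). This is safe
because the downstream estimators only need to know whether a site is
polymorphic, not whether the variant is high- or low-frequency: both theta
estimators below are invariant to exchanging `j` and `m - j`.

**Theta and windows.** Per site, with `m = 2n`:

    theta_pi = sum_j P(j|data) j(m-j)/C(m,2)
    theta_W  = P(0 < j < m) / a_m,  a_m = sum_{i=1}^{m-1} 1/i.

Windows are nonoverlapping tilings (20, 100, 500, 1000 kbp; 20 kbp is the
default scan resolution), `theta_pi` per site is the window sum divided by
the number of sites with data, and windows with under 25% of sites with
data are discarded. "Sites with data" means sites passing the coverage
filters (the filter implies at least one covered individual), counted
against the window span; the alternative reading (all reference bases) is
the `min_frac` denominator and is fixed by the window span here — the
choice is exposed through the filter configuration rather than a separate
flag.

**Sweep scan.** The wild reference for `pi_w` is Or-II (most distant from
all domesticates, hence least distorted by shared history or gene flow).
Ratios `pi_w/pi_d` are computed per domesticated subpopulation on the
common window grid; each subpopulation's 97.5th percentile (type-7 linear
interpolation — the convention is not dictated by the method, so it is
config-exposed) is computed over its *finite* ratios, and the smallest of
the three percentiles is the shared significance threshold. Windows
exceeding the threshold in aus AND indica AND japonica are colocated
low-diversity genomic regions (CLDGRs). Infinite ratios (`pi_d = 0`) are
excluded from percentiles — they would otherwise make the empirical
distribution undefined — but count as exceedances, since a zero-diversity
domesticated window is the strongest possible sweep evidence. CLDGRs are
reported both as individual windows and merged into maximal adjacent runs;
gene annotation is half-open interval intersection with a BED file.

**Distances and trees.** At SNP sites (likelihood-ratio test of minor
allele frequency zero versus the ML frequency, 1 df, `p < 1e-3`; the ML
frequency comes from a golden-section search on [0, 0.5] after orienting
the site by its major allele), per-individual genotype posteriors are
computed under a Hardy–Weinberg prior at the ML frequency (uniform prior
available). The distance between individuals is the mean over co-covered
SNPs of the expected allelic difference `E|g_a - g_b|/2`; pairs sharing
fewer than 20 SNPs are unreliable and dropped from region trees. Trees are
built with a fully specified neighbor-joining implementation (ties broken
by smallest index pair, negative branch lengths clamped to zero and
counted) rather than balanced minimum evolution: for topology-level claims
the two agree on clean signal, and plain NJ is exact on additive matrices,
which makes it independently testable.

**Topology classification.** Trees are rooted on the Or-II clade (if Or-II
is scrambled — which happens on noisy low-coverage trees — the root falls
back to the edge above the first Or-II leaf, and the fallback is recorded).
A tree is `domesticate_monophyletic` when all domesticated leaves form one
clade; otherwise it is `subpop_concordant` when every domesticated
subpopulation forms a clade whose sister region contains its designated
progenitor's wild leaves (japonica–OrIII, aus–OrI, indica–OrI) and no other
domesticate's leaves; otherwise `other`. "Clustering with the same
subpopulation type" is not a formalized test in the rice domestication
literature; the definition here is this package's operationalization of
it.

## The synthetic world

`demography_config()` states the world once; the defaults are the
conditions the analysis is calibrated against, not tuning knobs:

| parameter | default | why |
|---|---|---|
| `n_per_subpop` | 10 diploids | enough for 21-bin spectra and clean clades at desk scale |
| `L` | 1.2 Mbp | 60 scan windows: enough for a 97.5th percentile and for concatenating 50 neutral windows |
| `theta_neutral` | 0.005/site | wild rice nucleotide diversity is a few per mille |
| `mu` | 7e-9 | plant nuclear point-mutation scale; only its positivity matters on the coalescent scale |
| `split_or2 / or13 / or1ab` | 1.0 / 0.6 / 0.4 | deep Or-II outgroup; deep japonica–indica genome-wide divergence; Or-I internal structure for the two progenitor demes |
| `split_dom` | 0.1 each | domestication is recent relative to wild splits |
| `bottleneck_factor` | 0.2 | gives domesticated diversity ~0.7× wild, the observed regime |
| `sweep_interval` | [480, 540) kbp | three full 20 kbp scan windows: wide enough that a gene ± 20 kbp region lies entirely inside the swept haplotype (the regime in which gene-region trees reflect the domestication history — real rice domestication sweeps extend well beyond the gene body), yet only 5% of the chromosome |
| `post_sweep_time` | 0.01 | haplotypes near-identical after the transfer |
| `block_length` | 5 kbp | recombination as independent blocks (below) |
| read model | depth 2×, `e = 0.001` | the study regime: low coverage, quality-filtered bases |

Times are coalescent units of `2 N_ref` generations with
`theta_neutral = 4 N_ref mu`; the neutral mutation intensity per unit
branch per site is `theta_neutral/2`.

Deliberate simplifications, and what they imply for a green test:

* **Recombination** is modeled as independent non-recombining 5 kbp blocks,
  not an ancestral recombination graph. Windows get quasi-independent
  genealogies, which is all the scan statistics need, but linkage decay
  *within* blocks and across block boundaries is not realistic.
* **The sweep** is a haplotype transplant: one japonica-ancestor haplotype
  is copied over the sweep interval onto all domesticated haplotypes, then
  each copy mutates independently for `post_sweep_time`. This produces
  exactly the signature under test (near-zero domesticated diversity and
  domesticate monophyly at the locus) at O(1) cost, but it has no partial
  sweeps, no hitchhiking gradient at the locus edges, and no soft-sweep
  alternative. Columns made monomorphic by the transplant are dropped.
* **Or-I substructure**: because aus and indica need distinct progenitor
  demes, Or-I is internally split (OrI-a/OrI-b, merging at `split_or1ab`).
  Its sampled diversity is therefore *by design* above `theta_neutral`;
  diversity-calibration checks use the panmictic Or-II/Or-III.
* No indels, no more than two alleles, no mapping artifacts, no per-read
  quality variation. A green suite establishes that the inference machinery
  is correct and well calibrated *in this world*; it does not establish
  robustness to alignment error or reference bias.

## Numerical choices

* SAF dynamic program in linear space with per-individual renormalization;
  returned normalized to per-site maximum 1 (the only scale consumers use).
* EM stops at `max_j |Δp_j| < 1e-8` or 500 iterations; both exposed. The
  fused pipeline (`subpop_theta()`) deduplicates sites by their sorted
  per-individual `(depth, k1)` pattern before the SAF/EM stage — exact, by
  exchangeability of the SAF over individuals — and is tested equal to the
  modular route.
* Golden-section search for the ML allele frequency, tolerance `1e-6`.
* NJ ties broken by smallest (row, column) pair; negative branch lengths
  clamped at zero with a count attribute.
* All randomness flows from one master seed through counter-based child
  seeds (`child_seed()`), so every output is bit-reproducible and
  replicates are independent.
* Read simulation draws depth and background error counts by inverse-CDF
  lookup from single uniforms (exact distributions, fixed draw order);
  heterozygous and derived-carrying cells use binomial draws directly.

## Limitations

* The percentile convention, the identical-grid (rather than
  overlapping-interval) CLDGR intersection, and the "sites with data"
  denominator are all places where the canonical procedure is
  underspecified;
  each choice here is documented above and, where meaningful, exposed as a
  parameter.
* The constant-error genotype likelihood is the same *inferential role* as,
  not an equivalence to, quality-aware likelihood models.
* With 60 windows per chromosome, per-replicate thresholds at the 500 kbp
  and 1000 kbp window sizes are undefined (fewer than 40 finite ratios);
  the window-size sensitivity experiment pools ratio distributions across
  replicates instead.
* Tree confidence (bootstrap) and model-based sweep statistics are out of
  scope; the scan is intentionally the simple diversity-ratio method so
  that its false-positive behavior (bottleneck-driven lineage sorting
  mimicking concordance) can be studied rather than hidden.
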