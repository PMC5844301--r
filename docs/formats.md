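# File formats

All interchange files are plain text, tab-separated unless noted. Coordinates
are 0-based half-open `[start, end)` throughout.

## Demography configuration (YAML)

Fields mirror `demography_config()`:

```yaml
n_per_subpop: 10
L: 1200000
mu: 7.0e-9
theta_neutral: 0.005
split_or2: 1.0
split_or13: 0.6
split_or1ab: 0.4
split_dom: {aus: 0.1, indica: 0.1, japonica: 0.1}
bottleneck_factor: 0.2
sweep_interval: [480000, 540000]
post_sweep_time: 0.01
block_length: 5000
seed: 1
```

Times are in coalescent units of `2 N_ref` generations, with `N_ref` implied
by `theta_neutral = 4 N_ref mu`.

## Haplotypes (`positions.tsv`, `haplotypes.tsv`)

`positions.tsv`: single column `pos`, the 0-based bp coordinate of each
segregating column, strictly increasing. `haplotypes.tsv`: columns
`haplotype` (individual id, two rows per diploid) and `alleles` (a 0/1
string, one character per segregating site, allele 0 = ancestral/reference).

## Read pile (`reads.tsv`)

Sparse: one row per (site, individual) with depth > 0. Columns `pos` (0-based
bp), `id`, `depth`, `k1` (reads supporting allele 1; `k0 = depth - k1`).

## Genotype likelihoods (GL text format)

Written by `write_gl()`, a minimal Beagle-GL-like dialect: column `pos`, then
per individual three columns `<id>.ll0`, `<id>.ll1`, `<id>.ll2` holding
unnormalized log-likelihoods of genotypes 0/1/2 (copies of allele 1). A
site-individual with no reads has all three equal to 0.

## SFS (`sfs_<subpop>.tsv`)

Columns `j` (derived-allele count, `0..2n`) and `p` (probability; sums to 1).

## Per-site theta (`theta_<subpop>.tsv`)

Columns `pos`, `theta_pi`, `theta_w` for every site passing the coverage
filters.

## Window table (`windows_<subpop>_<size>.tsv`)

Columns `chrom`, `start`, `end`, `sum_theta_pi`, `sum_theta_w`,
`n_sites_with_data`, `theta_pi_per_site`, `theta_w_per_site`, `pass`
(data fraction >= 25%). First three columns are BED-compatible.

## Ratio table (`ratios_<subpop>.tsv`)

Columns `chrom`, `start`, `end`, `pi_w`, `pi_d`, `ratio`, `finite`. Only
windows passing the data filter in both populations appear; `ratio` is `Inf`
when `pi_d = 0` (flagged `finite = FALSE`).

## CLDGR output (`cldgr.bed`, `cldgr_merged.bed`)

`cldgr.bed`: windows exceeding the common threshold in all three domesticated
subpopulations, with per-subpopulation ratios and (optionally) comma-joined
overlapping gene names. `cldgr_merged.bed`: maximal runs of adjacent CLDGR
windows with `n_windows`.

## Gene intervals (BED)

Standard BED3/BED4: `chrom`, `start`, `end`, optional `name`.
`inst/extdata/domestication_genes.bed` carries the three rice domestication
genes (LABA1, sh4, PROG1) with their published coordinates converted to
0-based half-open.

## Trees

Newick with branch lengths, via `ape::write.tree()`. Tip labels are sample
ids `<subpop>_<nn>`, from which subpopulation and wild/domesticated status
are recovered.
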