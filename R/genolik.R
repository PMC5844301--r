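# Per-site diploid genotype likelihoods from biallelic read counts, with the
# site/depth/individual filters used throughout the pipeline. A single shared
# error rate per run stands in for per-read qualities: data emulating
# quality-filtered reads should use e <= 0.001.

#' Genotype likelihoods from allele counts
#'
#' For a biallelic site with `k0` reads of allele 0 and `k1` reads of allele
#' 1 and miscall probability `e`, the likelihood of genotype `g` (copies of
#' allele 1) is the product over reads of the per-read base probability:
#' homozygotes emit the other allele with probability `e`, heterozygotes emit
#' either allele with probability 1/2. Likelihoods are returned in log space,
#' unnormalized; a site-individual with no reads carries no information
#' (all three log-likelihoods are 0).
#'
#' @param pile a `read_pile`, or an integer matrix/vector of depths if `k1`
#'   is given separately.
#' @param k1 allele-1 read counts (when `pile` is a depth matrix).
#' @param e per-base miscall probability; defaults to the pile's.
#' @return An object of class `gl_matrix`: list of `ll0`, `ll1`, `ll2`
#'   (log-likelihood matrices, sites x individuals) and `covered`
#'   (depth > 0).
#' @export
genotype_likelihoods <- function(pile, k1 = NULL, e = NULL) {
  if (inherits(pile, "read_pile")) {
    depth <- pile$depth; k1 <- pile$k1
    if (is.null(e)) e <- pile$error_rate
  } else {
    depth <- as.matrix(pile); k1 <- as.matrix(k1)
    if (is.null(e)) stop("e must be given for raw count input")
  }
  stopifnot(e >= 0, e < 0.5)
  k0 <- depth - k1
  l1e <- log1p(-e)
  if (e > 0) {
    le <- log(e)
    ll0 <- k0 * l1e + k1 * le
    ll2 <- k0 * le + k1 * l1e
  } else {  # e = 0: impossible-genotype reads give -Inf (0 * -Inf guarded)
    ll0 <- k0 * l1e + ifelse(k1 > 0, -Inf, 0)
    ll2 <- ifelse(k0 > 0, -Inf, 0) + k1 * l1e
  }
  ll1 <- (k0 + k1) * log(0.5)
  structure(list(ll0 = ll0, ll1 = ll1, ll2 = ll2, covered = depth > 0,
                 e = e), class = "gl_matrix")
}

#' Site filter preset scaled from the subpopulation size and coverage
#'
#' The canonical low-coverage filter rule sets the minimum number of
#' individuals with data and the minimum total site depth to one-third of
#' the number of individuals, and the maximum total depth to five times the
#' number of individuals. Those ratios are calibrated to roughly 1x data;
#' this preset generalizes them by the expected per-individual coverage so
#' the same relative stringency applies at any depth (at `mean_depth = 1` it
#' reduces exactly to the one-third / five-times rule).
#'
#' @param n_ind number of individuals in the (sub)population.
#' @param mean_depth expected per-individual coverage.
#' @return list with `min_ind`, `min_depth`, `max_depth`.
#' @export
site_filter_preset <- function(n_ind, mean_depth = 1) {
  list(min_ind = ceiling(n_ind / 3),
       min_depth = ceiling(n_ind * mean_depth / 3),
       max_depth = 5 * n_ind * mean_depth)
}

#' Apply per-site coverage filters
#'
#' A site passes when at least `min_ind` individuals have data and the total
#' depth lies within `[min_depth, max_depth]`.
#'
#' @param pile a `read_pile`.
#' @param filters list with `min_ind`, `min_depth`, `max_depth` (see
#'   [site_filter_preset()]).
#' @return Logical vector of per-site pass flags.
#' @export
apply_site_filters <- function(pile, filters) {
  stopifnot(filters$min_ind >= 1, filters$min_depth <= filters$max_depth)
  ncov <- rowSums(pile$depth > 0)
  tot <- rowSums(pile$depth)
  ncov >= filters$min_ind & tot >= filters$min_depth &
    tot <= filters$max_depth
}

#' SNP calling by likelihood-ratio test on the pooled sample
#'
#' Tests minor allele frequency = 0 against the maximum-likelihood frequency
#' (1 df chi-square). Each site is oriented by its major allele (the
#' monomorphic state with the higher likelihood), and the ML minor-allele
#' frequency is found by golden-section search on `[0, 0.5]` under
#' Hardy-Weinberg genotype proportions. A site is a SNP when the test
#' p-value is below `p_threshold`.
#'
#' @param gl a `gl_matrix` over the pooled individuals.
#' @param p_threshold significance threshold (default `1e-3`).
#' @param tol golden-section tolerance on the frequency.
#' @return data.frame with `fhat` (ML allele-1 frequency), `lrt`, `p`,
#'   `is_snp`.
#' @export
snp_call <- function(gl, p_threshold = 1e-3, tol = 1e-6) {
  res <- cpp_snp_lrt(gl$ll0, gl$ll1, gl$ll2, tol)
  p <- pchisq(res$lrt, df = 1, lower.tail = FALSE)
  data.frame(fhat = res$fhat, lrt = res$lrt, p = p,
             is_snp = p < p_threshold)
}
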