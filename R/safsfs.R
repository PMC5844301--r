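# Sample allele frequency (SAF) likelihoods, EM estimation of the site
# frequency spectrum, and per-site allele-frequency posteriors — the
# SFS-as-prior machinery that lets theta be estimated without hard genotype
# calls. The spectrum is unfolded with allele 0 as the ancestral state; the
# downstream theta estimators are invariant to folding.

#' Site allele frequency likelihoods
#'
#' For each site, the likelihood of the read data given `j` derived alleles
#' among the `m = 2n` sampled chromosomes, `j = 0..m`, computed by the
#' standard dynamic program over individuals with hypergeometric assignment
#' weights:
#' `h_k(j) = sum_g h_{k-1}(j-g) GL_k(g) C(2,g) C(2k-2, j-g) / C(2k, j)`.
#'
#' @param gl a `gl_matrix` for the `n` individuals of one subpopulation.
#' @return Numeric matrix, sites x (2n+1), of log SAF values normalized so
#'   the per-site maximum is 0.
#' @export
saf <- function(gl) {
  stopifnot(inherits(gl, "gl_matrix"))
  cpp_saf(gl$ll0, gl$ll1, gl$ll2)
}

#' Estimate the site frequency spectrum by EM
#'
#' Maximizes the product over sites of `sum_j p_j L_s(j)` in the spectrum
#' `p`, starting from uniform:
#' `p_j <- (1/S) sum_s p_j L_s(j) / sum_k p_k L_s(k)`.
#' Iteration stops when `max_j |delta p_j| < tol` or after `max_iter`
#' rounds. Rows may carry integer weights (collapsed duplicate sites).
#'
#' @param saf_mat log SAF matrix from [saf()] (or linear if
#'   `log_input = FALSE`).
#' @param weights optional per-row multiplicities.
#' @param tol convergence tolerance on the spectrum (default `1e-8`).
#' @param max_iter iteration cap (default 500).
#' @param log_input whether `saf_mat` is in log space (default TRUE).
#' @return An object of class `sfs`: list with `p` (the normalized
#'   spectrum), `loglik` (per-iteration trajectory, non-decreasing),
#'   `iterations`, `converged`.
#' @export
estimate_sfs <- function(saf_mat, weights = NULL, tol = 1e-8,
                         max_iter = 500, log_input = TRUE) {
  saf_mat <- as.matrix(saf_mat)
  if (nrow(saf_mat) < 1) stop("need at least one covered site")
  lin <- if (log_input) exp(saf_mat - apply(saf_mat, 1, max)) else saf_mat
  if (any(rowSums(lin) <= 0)) stop("site with zero total SAF mass")
  if (is.null(weights)) weights <- rep(1, nrow(lin))
  res <- cpp_sfs_em(lin, as.numeric(weights), tol, as.integer(max_iter))
  structure(list(p = as.numeric(res$p), loglik = as.numeric(res$loglik),
                 iterations = res$iterations, converged = res$converged),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat("SFS over", length(x$p) - 1, "chromosomes;",
      x$iterations, "EM iterations",
      if (x$converged) "(converged)" else "(iteration cap)", "\n")
  print(signif(x$p, 4))
  invisible(x)
}

#' Per-site allele-frequency posterior with the SFS as prior
#'
#' `P(j | data) ∝ p_j L_s(j)`, normalized to sum 1 per site.
#'
#' @param saf_mat log SAF matrix (sites x m+1), as from [saf()].
#' @param sfs an `sfs` object or a bare probability vector of length m+1.
#' @return Matrix of posterior probabilities, rows summing to 1.
#' @export
posterior_freq <- function(saf_mat, sfs) {
  p <- if (inherits(sfs, "sfs")) sfs$p else as.numeric(sfs)
  saf_mat <- rbind(saf_mat)
  stopifnot(ncol(saf_mat) == length(p))
  lin <- exp(saf_mat - apply(saf_mat, 1, max))
  post <- sweep(lin, 2, p, "*")
  tot <- rowSums(post)
  if (any(tot <= 0)) stop("posterior with zero total mass")
  post / tot
}
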