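# Per-site theta estimators from allele-frequency posteriors, and
# nonoverlapping window aggregation with the 25% data-fraction filter.

#' Per-site Watterson and Tajima theta from frequency posteriors
#'
#' `theta_pi = sum_j P(j|data) j(m-j) / C(m,2)` and
#' `theta_W = P(0 < j < m) / a_m` with `a_m = sum_{i=1}^{m-1} 1/i`.
#' Both are zero when the posterior concentrates on `j = 0` or `j = m`, so
#' they are invariant to whether a variant is labelled high- or
#' low-frequency (folding does not matter).
#'
#' @param post posterior matrix (sites x m+1), rows summing to 1, as from
#'   [posterior_freq()].
#' @return data.frame with `theta_pi` and `theta_w` per site.
#' @export
theta_per_site <- function(post) {
  post <- rbind(post)
  m <- ncol(post) - 1L
  j <- 0:m
  a_m <- sum(1 / seq_len(m - 1))
  cm2 <- m * (m - 1) / 2
  theta_pi <- as.numeric(post %*% (j * (m - j) / cm2))
  theta_w <- (1 - post[, 1] - post[, m + 1]) / a_m
  data.frame(theta_pi = theta_pi, theta_w = theta_w)
}

#' Nonoverlapping window scan of per-site theta
#'
#' Tiles `[0, L)` into nonoverlapping windows of `window_bp` (the last,
#' possibly partial, window is kept and judged against its own span), sums
#' per-site `theta_pi` over the sites with data, divides by the number of
#' such sites, and flags windows where the data fraction is below
#' `min_frac` (default 0.25) as discarded.
#'
#' "Sites with data" are the sites that passed the coverage filters (which
#' imply at least one covered individual), counted against the window span.
#'
#' @param positions 0-based bp coordinates of the sites with data, sorted.
#' @param theta data.frame from [theta_per_site()] for those sites (same
#'   order).
#' @param L chromosome length in bp.
#' @param window_bp window (and step) length in bp; the canonical sizes are
#'   20, 100, 500 and 1000 kbp.
#' @param min_frac minimum fraction of sites with data per window.
#' @param chrom chromosome name for the output table.
#' @return data.frame (class `window_table`) with `chrom`, `start`, `end`
#'   (0-based half-open), `sum_theta_pi`, `sum_theta_w`,
#'   `n_sites_with_data`, `theta_pi_per_site`, `theta_w_per_site`, `pass`.
#' @export
window_scan <- function(positions, theta, L, window_bp = 20000,
                        min_frac = 0.25, chrom = "chr1") {
  if (is.unsorted(positions)) stop("positions must be sorted")
  stopifnot(length(positions) == nrow(theta))
  starts <- seq.int(0L, max(L - 1L, 0L), by = window_bp)
  ends <- pmin(starts + window_bp, L)
  w <- findInterval(positions, starts)
  n <- tabulate(w, nbins = length(starts))
  sum_tp <- vapply(seq_along(starts), function(i)
    sum(theta$theta_pi[w == i]), numeric(1))
  sum_tw <- vapply(seq_along(starts), function(i)
    sum(theta$theta_w[w == i]), numeric(1))
  span <- ends - starts
  out <- data.frame(chrom = chrom, start = starts, end = ends,
                    sum_theta_pi = sum_tp, sum_theta_w = sum_tw,
                    n_sites_with_data = n,
                    theta_pi_per_site = ifelse(n > 0, sum_tp / n, NA_real_),
                    theta_w_per_site = ifelse(n > 0, sum_tw / n, NA_real_),
                    pass = n / span >= min_frac,
                    stringsAsFactors = FALSE)
  class(out) <- c("window_table", "data.frame")
  out
}

#' Fused per-subpopulation theta pipeline
#'
#' Runs the whole chain read counts -> genotype likelihoods -> site filters
#' -> SAF -> EM SFS -> posterior -> per-site theta for one subpopulation in
#' a single compiled pass. Sites are collapsed by their (sorted)
#' per-individual count pattern before the SAF dynamic program, which is
#' exact because the SAF is exchangeable over individuals; the result is
#' identical, site for site, to the modular route through [saf()],
#' [estimate_sfs()], [posterior_freq()] and [theta_per_site()].
#'
#' @param pile a `read_pile` for the subpopulation's individuals.
#' @param filters coverage filters; defaults to
#'   [site_filter_preset()] at the pile's mean depth.
#' @param tol,max_iter EM controls (see [estimate_sfs()]).
#' @return list with `sfs` (an `sfs` object), `site_pass` (length-L
#'   logical), `positions` (0-based coordinates of passing sites),
#'   `theta` (data.frame of per-site `theta_pi`, `theta_w` for those
#'   sites), and `n_unique_patterns`.
#' @export
subpop_theta <- function(pile, filters = NULL, tol = 1e-8, max_iter = 500) {
  stopifnot(inherits(pile, "read_pile"))
  n <- ncol(pile$depth)
  if (is.null(filters))
    filters <- site_filter_preset(n, max(pile$mean_depth, 1))
  res <- cpp_subpop_theta(pile$depth, pile$k1, max(pile$error_rate, 1e-12),
                          as.integer(filters$min_ind),
                          as.numeric(filters$min_depth),
                          as.numeric(filters$max_depth), tol,
                          as.integer(max_iter))
  pass <- as.logical(res$pass)
  pat <- res$pattern[pass]
  sfs <- structure(list(p = as.numeric(res$sfs),
                        loglik = as.numeric(res$loglik),
                        iterations = res$iterations,
                        converged = res$converged), class = "sfs")
  list(sfs = sfs, site_pass = pass, positions = which(pass) - 1L,
       theta = data.frame(theta_pi = res$theta_pi_u[pat],
                          theta_w = res$theta_w_u[pat]),
       n_unique_patterns = res$n_unique)
}
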