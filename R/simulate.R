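# Coalescent-style synthetic data: haplotypes under the structured
# wild/domesticated demography, the haplotype-transplant sweep, and
# low-coverage reads. Recombination is approximated by independent
# non-recombining blocks (default 5 kbp), which is enough to give windows
# quasi-independent genealogies.

# Structured coalescent for one non-recombining block.
# Populations are keyed by deme label; sizes are relative to the wild
# reference size (domesticates get bottleneck_factor). Returns the genealogy
# as parent pointers plus node times and per-node leaf sets.
coalesce_block <- function(cfg) {
  labels <- sample_sheet(cfg$n_per_subpop)
  n_hap <- 2L * nrow(labels)
  # integer deme codes: 1 OrIa, 2 OrIb, 3 OrII, 4 OrIII, 5 aus, 6 indica,
  # 7 japonica
  deme_code <- c(OrIa = 1L, OrIb = 2L, OrII = 3L, OrIII = 4L, aus = 5L,
                 indica = 6L, japonica = 7L)
  hap_deme <- deme_code[rep(labels$deme, each = 2)]
  sizes <- c(1, 1, 1, 1, cfg$bottleneck_factor, cfg$bottleneck_factor,
             cfg$bottleneck_factor)
  # backward-time population merge events
  ev_time <- c(cfg$split_dom[["aus"]], cfg$split_dom[["indica"]],
               cfg$split_dom[["japonica"]], cfg$split_or1ab, cfg$split_or13,
               cfg$split_or2)
  ev_from <- c(5L, 6L, 7L, 2L, 4L, 3L)
  ev_to <- c(1L, 2L, 4L, 1L, 1L, 1L)
  o <- order(ev_time)
  ev_time <- ev_time[o]; ev_from <- ev_from[o]; ev_to <- ev_to[o]

  max_nodes <- 2L * n_hap - 1L
  parent <- integer(max_nodes)
  node_time <- numeric(max_nodes)
  leafset <- vector("list", max_nodes)
  for (i in seq_len(n_hap)) leafset[[i]] <- i

  active <- seq_len(n_hap)
  act_deme <- hap_deme
  nxt <- n_hap + 1L
  t <- 0
  ev <- 1L
  repeat {
    if (length(active) == 1L && ev > length(ev_time)) break
    k_p <- tabulate(act_deme, 7L)
    rate <- k_p * (k_p - 1) / 2 / sizes
    R <- sum(rate)
    dt <- if (R > 0) rexp(1, R) else Inf
    if (ev <= length(ev_time) && t + dt >= ev_time[ev]) {
      t <- ev_time[ev]
      act_deme[act_deme == ev_from[ev]] <- ev_to[ev]
      ev <- ev + 1L
      next
    }
    t <- t + dt
    d <- sample.int(7L, 1L, prob = rate)
    members <- which(act_deme == d)
    pick <- members[sample.int(length(members), 2L)]
    i <- active[pick[1]]; j <- active[pick[2]]
    parent[c(i, j)] <- nxt
    node_time[nxt] <- t
    leafset[[nxt]] <- c(leafset[[i]], leafset[[j]])
    active <- c(active[-pick], nxt)
    act_deme <- c(act_deme[-pick], d)
    nxt <- nxt + 1L
  }
  list(parent = parent[seq_len(nxt - 1L)],
       node_time = node_time[seq_len(nxt - 1L)],
       leafset = leafset[seq_len(nxt - 1L)],
       n_hap = n_hap, root = nxt - 1L)
}

#' Simulate haplotypes under the six-subpopulation rice demography
#'
#' Generates coalescent genealogies independently per non-recombining block,
#' drops Poisson mutations on branches (infinite-sites within a discrete bp
#' grid), and returns the resulting 0/1 haplotype matrix. Allele 0 is the
#' ancestral state everywhere, playing the role of the reference genome used
#' as outgroup.
#'
#' @param cfg a [demography_config()].
#' @return An object of class `haplotype_set`: list with `haplotypes`
#'   (`2 * n_total` rows x S segregating columns, 0/1 integer), `positions`
#'   (0-based bp, strictly increasing), `labels` (per-individual sample
#'   sheet), `L`, and the originating `cfg`.
#' @export
simulate_haplotypes <- function(cfg) {
  stopifnot(inherits(cfg, "demography_config"))
  set.seed(child_seed(cfg$seed, 1L))
  labels <- sample_sheet(cfg$n_per_subpop)
  n_hap <- 2L * nrow(labels)
  rate <- if (cfg$mu > 0) cfg$theta_neutral / 2 else 0

  starts <- seq.int(0L, cfg$L - 1L, by = cfg$block_length)
  cols <- vector("list", length(starts))
  poss <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    blen <- min(cfg$block_length, cfg$L - starts[b])
    gen <- coalesce_block(cfg)
    has_parent <- which(gen$parent > 0L)
    elen <- gen$node_time[gen$parent[has_parent]] - gen$node_time[has_parent]
    total <- sum(elen)
    n_mut <- if (rate > 0) rpois(1, rate * total * blen) else 0L
    n_mut <- min(n_mut, blen)  # discrete grid saturation (never in practice)
    if (n_mut == 0L) { cols[[b]] <- NULL; next }
    edge_of <- sample.int(length(has_parent), n_mut, replace = TRUE,
                          prob = elen / total)
    pos <- starts[b] + sort(sample.int(blen, n_mut)) - 1L
    m <- matrix(0L, nrow = n_hap, ncol = n_mut)
    for (k in seq_len(n_mut)) {
      m[gen$leafset[[has_parent[edge_of[k]]]], k] <- 1L
    }
    cols[[b]] <- m
    poss[[b]] <- pos
  }
  keep <- !vapply(cols, is.null, logical(1))
  hap <- if (any(keep)) do.call(cbind, cols[keep]) else
    matrix(0L, nrow = n_hap, ncol = 0L)
  positions <- if (any(keep)) unlist(poss[keep]) else integer(0)
  structure(list(haplotypes = hap, positions = as.integer(positions),
                 labels = labels, L = cfg$L, cfg = cfg),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("Haplotype set:", nrow(x$haplotypes), "haplotypes x",
      ncol(x$haplotypes), "segregating sites on", x$L, "bp\n")
  invisible(x)
}

#' Transplant the domestication sweep haplotype with introgression
#'
#' Models the hard domestication sweep plus its introgression from japonica
#' into aus and indica by copying one japonica haplotype over the sweep
#' interval onto every domesticated haplotype, then letting each copy
#' accumulate independent mutations for `post_sweep_time` (coalescent units).
#' Sites outside the sweep interval are untouched; columns that become
#' monomorphic across the whole sample are dropped.
#'
#' @param h a `haplotype_set`.
#' @param cfg the [demography_config()] (supplies `sweep_interval`,
#'   `post_sweep_time` and the mutation intensity).
#' @return A modified `haplotype_set`.
#' @export
apply_sweep_introgression <- function(h, cfg = h$cfg) {
  stopifnot(inherits(h, "haplotype_set"))
  if (is.null(cfg$sweep_interval)) stop("sweep_interval is not set")
  sw <- cfg$sweep_interval
  if (sw[1] < 0 || sw[2] > h$L) stop("sweep_interval outside [0, L)")
  set.seed(child_seed(cfg$seed, 2L))

  dom_ind <- which(h$labels$status == "domesticated")
  dom_rows <- as.vector(rbind(2L * dom_ind - 1L, 2L * dom_ind))
  donor_row <- 2L * which(h$labels$subpop == "japonica")[1] - 1L
  in_sw <- which(h$positions >= sw[1] & h$positions < sw[2])
  hap <- h$haplotypes
  if (length(in_sw))
    hap[dom_rows, in_sw] <- rep(hap[donor_row, in_sw], each = length(dom_rows))

  # independent post-sweep mutations, one new private site per mutation
  rate <- if (cfg$mu > 0) cfg$theta_neutral / 2 else 0
  lam <- rate * cfg$post_sweep_time * (sw[2] - sw[1])
  n_new <- rpois(length(dom_rows), lam)
  tot_new <- sum(n_new)
  if (tot_new > 0) {
    avail <- setdiff(seq.int(sw[1], sw[2] - 1L), h$positions)
    tot_new <- min(tot_new, length(avail))
    new_pos <- sort(sample(avail, tot_new))
    owner <- rep(dom_rows, n_new)[seq_len(tot_new)]
    new_cols <- matrix(0L, nrow = nrow(hap), ncol = tot_new)
    new_cols[cbind(owner, seq_len(tot_new))] <- 1L
    hap <- cbind(hap, new_cols)
    positions <- c(h$positions, new_pos)
    o <- order(positions)
    hap <- hap[, o, drop = FALSE]
    positions <- positions[o]
  } else positions <- h$positions

  cs <- colSums(hap)
  keep <- cs > 0L & cs < nrow(hap)
  h$haplotypes <- hap[, keep, drop = FALSE]
  h$positions <- as.integer(positions[keep])
  h$cfg <- cfg
  h
}

#' Simulate low-coverage sequencing reads
#'
#' Per (site, individual) the read depth is Poisson(`mean_depth`); each read
#' is drawn from the individual's two alleles with equal probability and
#' miscalled (flipped to the other allele) with probability `e`. Draws are
#' site-major then individual-major, so output is deterministic given
#' `seed`.
#'
#' @param h a `haplotype_set`.
#' @param mean_depth mean sequencing depth per site per individual.
#' @param e per-base miscall probability, `0 <= e < 0.5`.
#' @param seed integer RNG seed.
#' @param individuals optional integer vector of individual indices (rows of
#'   `sample_labels(h)`) to simulate; default all.
#' @return An object of class `read_pile`: `depth` and `k1` (allele-1 read
#'   count) matrices of dimension `L x n_individuals`, plus `error_rate`,
#'   `labels`, `L`.
#' @export
simulate_reads <- function(h, mean_depth = 2, e = 0.001, seed = 1L,
                           individuals = NULL) {
  stopifnot(inherits(h, "haplotype_set"), mean_depth > 0, e >= 0, e < 0.5)
  if (is.null(individuals)) individuals <- seq_len(nrow(h$labels))
  set.seed(as.integer(seed))
  res <- cpp_simulate_reads(h$haplotypes, h$positions, h$L, mean_depth, e,
                            as.integer(individuals))
  labels <- h$labels[individuals, , drop = FALSE]
  colnames(res$depth) <- labels$id
  colnames(res$k1) <- labels$id
  structure(list(depth = res$depth, k1 = res$k1, error_rate = e,
                 labels = labels, L = h$L, mean_depth = mean_depth),
            class = "read_pile")
}

#' Construct a read pile from explicit count matrices
#'
#' Mostly useful for tests and small worked examples; the matrices are
#' sites x individuals.
#'
#' @param depth integer matrix of read depths.
#' @param k1 integer matrix of allele-1 read counts (`k1 <= depth`).
#' @param e per-base miscall probability.
#' @param labels optional sample sheet (data.frame with at least `id`).
#' @return A `read_pile`.
#' @export
read_pile <- function(depth, k1, e = 0.001, labels = NULL) {
  depth <- as.matrix(depth); k1 <- as.matrix(k1)
  stopifnot(all(dim(depth) == dim(k1)), all(k1 <= depth), all(depth >= 0),
            e >= 0, e < 0.5)
  if (is.null(labels))
    labels <- data.frame(id = sprintf("ind_%02d", seq_len(ncol(depth))),
                         subpop = NA_character_, status = NA_character_,
                         deme = NA_character_, stringsAsFactors = FALSE)
  structure(list(depth = depth, k1 = k1, error_rate = e, labels = labels,
                 L = nrow(depth), mean_depth = mean(depth)),
            class = "read_pile")
}

#' @export
print.read_pile <- function(x, ...) {
  cat("Read pile:", nrow(x$depth), "sites x", ncol(x$depth),
      "individuals, mean depth", signif(mean(x$depth), 3),
      "error", x$error_rate, "\n")
  invisible(x)
}

#' Subset a read pile to a set of individuals
#'
#' @param pile a `read_pile`.
#' @param individuals integer indices or individual ids.
#' @return A `read_pile` restricted to those columns.
#' @export
pile_subset <- function(pile, individuals) {
  if (is.character(individuals))
    individuals <- match(individuals, pile$labels$id)
  stopifnot(!anyNA(individuals))
  pile$depth <- pile$depth[, individuals, drop = FALSE]
  pile$k1 <- pile$k1[, individuals, drop = FALSE]
  pile$labels <- pile$labels[individuals, , drop = FALSE]
  pile
}

#' True per-window diversity from simulated haplotypes
#'
#' Computes the realized average pairwise difference per site (sample
#' heterozygosity) for one subpopulation in nonoverlapping windows, directly
#' from the haplotype matrix. This is the ground truth the
#' genotype-likelihood estimators are calibrated against.
#'
#' @param h a `haplotype_set`.
#' @param subpop subpopulation label (e.g. `"OrII"`).
#' @param window_bp window length in bp.
#' @return data.frame with `start`, `end` (0-based half-open) and `pi_true`
#'   (per-site average pairwise difference within the window).
#' @export
truth_windows <- function(h, subpop, window_bp) {
  idx <- which(h$labels$subpop == subpop)
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  m <- length(rows)
  j <- colSums(h$haplotypes[rows, , drop = FALSE])
  persite <- 2 * j * (m - j) / (m * (m - 1))
  starts <- seq.int(0L, h$L - 1L, by = window_bp)
  ends <- pmin(starts + window_bp, h$L)
  win <- findInterval(h$positions, starts)
  pi_sum <- vapply(seq_along(starts), function(w)
    sum(persite[win == w]), numeric(1))
  data.frame(start = starts, end = ends,
             pi_true = pi_sum / (ends - starts))
}
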