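# Genotype-posterior pairwise distances, neighbor-joining trees, and the
# topology classifier that separates the two domestication models: a single
# de novo domestication with introgression leaves the domesticated samples
# monophyletic at the sweep locus but not genome-wide, whereas independent
# domestications leave every locus concordant with the subpopulation tree.

#' Per-individual genotype posteriors at SNP sites
#'
#' Runs the pooled SNP pipeline: coverage filters on the pooled sample,
#' the likelihood-ratio SNP test (see [snp_call()]), and per-individual
#' genotype posteriors at the retained SNPs under a Hardy-Weinberg prior at
#' the ML allele frequency (or a uniform prior).
#'
#' @param pile a `read_pile` over all individuals entering the trees.
#' @param filters pooled coverage filters; default
#'   [site_filter_preset()] at the pile's mean depth.
#' @param snp_p SNP p-value threshold (default `1e-3`).
#' @param prior `"hwe"` (default) or `"uniform"`.
#' @return An object of class `geno_post`: `positions` (0-based SNP
#'   coordinates), `p0`, `p1`, `p2` (posterior matrices, SNPs x
#'   individuals), `covered` (0/1 matrix), `fhat`, `labels`.
#' @export
genotype_posteriors <- function(pile, filters = NULL, snp_p = 1e-3,
                                prior = c("hwe", "uniform")) {
  prior <- match.arg(prior)
  n <- ncol(pile$depth)
  if (is.null(filters))
    filters <- site_filter_preset(n, max(pile$mean_depth, 1))
  pass <- apply_site_filters(pile, filters)
  cand <- which(pass & rowSums(pile$k1) > 0)
  if (length(cand) == 0)
    return(structure(list(positions = integer(0)), class = "geno_post"))
  gl <- genotype_likelihoods(pile$depth[cand, , drop = FALSE],
                             pile$k1[cand, , drop = FALSE],
                             e = max(pile$error_rate, 1e-12))
  snp <- snp_call(gl, p_threshold = snp_p)
  keep <- which(snp$is_snp)
  f <- snp$fhat[keep]
  pri <- if (prior == "hwe")
    cbind((1 - f)^2, 2 * f * (1 - f), f^2)
  else matrix(1 / 3, length(keep), 3)
  post_g <- function(llg, col) exp(llg[keep, , drop = FALSE]) * pri[, col]
  p0 <- post_g(gl$ll0, 1); p1 <- post_g(gl$ll1, 2); p2 <- post_g(gl$ll2, 3)
  tot <- p0 + p1 + p2
  structure(list(positions = cand[keep] - 1L, p0 = p0 / tot, p1 = p1 / tot,
                 p2 = p2 / tot,
                 covered = (pile$depth[cand, , drop = FALSE] > 0)[keep, ,
                                                                  drop = FALSE] * 1,
                 fhat = f, labels = pile$labels),
            class = "geno_post")
}

#' @export
print.geno_post <- function(x, ...) {
  cat("Genotype posteriors:", length(x$positions), "SNP sites x",
      nrow(x$labels), "individuals\n")
  invisible(x)
}

#' Pairwise genetic distances from genotype posteriors
#'
#' `d(a,b)` is the mean over co-covered SNPs of the expected allelic
#' difference `sum_{g1,g2} P(g1|a) P(g2|b) |g1-g2| / 2`, which lies in
#' `[0, 1]`. Pairs with fewer than `min_overlap` co-covered SNPs are flagged
#' unreliable.
#'
#' @param gp a `geno_post`, optionally restricted with `sites`.
#' @param sites optional integer index vector into the SNP rows.
#' @param min_overlap minimum co-covered SNPs per pair (default 20).
#' @return list with `d` (n x n symmetric matrix, zero diagonal),
#'   `n_overlap`, and `unreliable` (logical matrix).
#' @export
pairwise_distances <- function(gp, sites = NULL, min_overlap = 20) {
  if (is.null(sites)) sites <- seq_along(gp$positions)
  if (length(sites) == 0) stop("no SNP sites in the requested region")
  C <- gp$covered[sites, , drop = FALSE]
  P0 <- gp$p0[sites, , drop = FALSE] * C
  P1 <- gp$p1[sites, , drop = FALSE] * C
  P2 <- gp$p2[sites, , drop = FALSE] * C
  num <- crossprod(P0, P1) + crossprod(P1, P0) +
    crossprod(P1, P2) + crossprod(P2, P1) +
    2 * (crossprod(P0, P2) + crossprod(P2, P0))
  n_overlap <- crossprod(C)
  d <- num / 2 / pmax(n_overlap, 1)
  diag(d) <- 0
  d <- (d + t(d)) / 2
  rownames(d) <- colnames(d) <- gp$labels$id
  list(d = d, n_overlap = n_overlap,
       unreliable = n_overlap < min_overlap & upper.tri(n_overlap))
}

#' Neighbor joining
#'
#' The classic Saitou-Nei agglomeration, implemented directly so that the
#' behavior is fully specified: at each step the pair minimizing
#' `Q(i,j) = (m-2) d(i,j) - r_i - r_j` is joined, ties broken by the
#' smallest (row, column) index pair; negative branch lengths are clamped to
#' zero (count recorded in attribute `n_clamped`). Exact on additive
#' distance matrices, including branch lengths.
#'
#' @param D symmetric distance matrix with at least 3 taxa; dimnames are
#'   used as tip labels.
#' @param labels optional tip labels overriding `rownames(D)`.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(D, labels = NULL) {
  D <- as.matrix(D)
  if (any(!is.finite(D))) stop("non-finite distances")
  N <- nrow(D)
  if (N < 3) stop("need at least 3 taxa")
  if (is.null(labels)) labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(N))
  # each active node carries its own Newick fragment
  frag <- labels
  n_clamped <- 0L
  bl <- function(x) {
    if (x < 0) n_clamped <<- n_clamped + 1L
    sprintf("%.17g", max(x, 0))
  }
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # smallest (row, col) tie-break: scan upper triangle in row-major order
    best <- c(Inf, 0L, 0L)
    for (i in 1:(m - 1)) for (j in (i + 1):m)
      if (Q[i, j] < best[1]) best <- c(Q[i, j], i, j)
    i <- best[2]; j <- best[3]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    newfrag <- paste0("(", frag[i], ":", bl(vi), ",", frag[j], ":", bl(vj),
                      ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    D <- D2
  }
  # final three-point resolution
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", frag[1], ":", bl(v1), ",", frag[2], ":", bl(v2), ",",
                frag[3], ":", bl(v3), ");")
  tr <- ape::read.tree(text = nwk)
  attr(tr, "n_clamped") <- n_clamped
  tr
}

# tip index sets per node of a rooted tree, postorder
node_tipsets <- function(tr) {
  nt <- length(tr$tip.label)
  res <- vector("list", nt + tr$Nnode)
  for (i in seq_len(nt)) res[[i]] <- i
  eo <- ape::reorder.phylo(tr, "postorder")$edge
  for (k in seq_len(nrow(eo)))
    res[[eo[k, 1]]] <- c(res[[eo[k, 1]]], res[[eo[k, 2]]])
  res
}

#' Classify a labelled tree against the two domestication models
#'
#' Roots the tree on the Or-II clade (Or-II is the wild outgroup most
#' distant from all domesticates); if Or-II is not monophyletic the tree is
#' rooted on the edge above its first leaf instead (recorded in attribute
#' `rooting`). Classification:
#' \describe{
#'   \item{`domesticate_monophyletic`}{all domesticated leaves form one
#'     clade — the single-domestication-with-introgression signature.}
#'   \item{`subpop_concordant`}{each domesticated subpopulation forms a
#'     clade whose sister region contains leaves of its designated wild
#'     progenitor and no leaves of another domesticated subpopulation — the
#'     genome-wide / multiple-domestication signature.}
#'   \item{`other`}{anything else.}
#' }
#'
#' @param tree an `ape::phylo` tree.
#' @param subpop named character vector: subpopulation per tip label.
#' @param progenitors named character vector mapping each domesticated
#'   subpopulation to its wild progenitor.
#' @return One of `"domesticate_monophyletic"`, `"subpop_concordant"`,
#'   `"other"`, with attribute `rooting`.
#' @export
classify_topology <- function(tree, subpop,
                              progenitors = c(aus = "OrI", indica = "OrI",
                                              japonica = "OrIII")) {
  sp <- subpop[tree$tip.label]
  if (anyNA(sp)) stop("every tip needs a subpopulation label")
  out_tips <- tree$tip.label[sp == "OrII"]
  if (length(out_tips) == 0) stop("missing OrII outgroup leaves")
  dom_pops <- names(progenitors)
  if (sum(unique(sp) %in% dom_pops) < 2)
    stop("need leaves from at least two domesticated subpopulations")
  rooted <- tryCatch({
    r <- ape::root(tree, outgroup = out_tips, resolve.root = TRUE)
    attr(r, "how") <- "outgroup_clade"; r
  }, error = function(e) {
    r <- ape::root(tree, outgroup = out_tips[1], resolve.root = TRUE)
    attr(r, "how") <- "first_outgroup_leaf"; r
  })
  rooting <- attr(rooted, "how")
  sp <- subpop[rooted$tip.label]
  tipsets <- node_tipsets(rooted)
  setkey <- vapply(tipsets, function(s) paste(sort(s), collapse = ","),
                   character(1))
  has_clade <- function(tips) {
    paste(sort(tips), collapse = ",") %in% setkey
  }
  dom_tips <- which(sp %in% dom_pops)
  cls <- "other"
  if (has_clade(dom_tips)) cls <- "domesticate_monophyletic"
  else {
    ok <- TRUE
    for (d in intersect(dom_pops, unique(sp))) {
      tips_d <- which(sp == d)
      key <- paste(sort(tips_d), collapse = ",")
      node <- match(key, setkey)
      if (is.na(node)) { ok <- FALSE; break }
      par <- rooted$edge[rooted$edge[, 2] == node, 1]
      if (length(par) == 0) { ok <- FALSE; break }  # clade is the root
      sister <- setdiff(tipsets[[par]], tips_d)
      ssp <- sp[sister]
      if (!any(ssp == progenitors[[d]]) ||
          any(ssp %in% setdiff(dom_pops, d))) { ok <- FALSE; break }
    }
    if (ok) cls <- "subpop_concordant"
  }
  attr(cls, "rooting") <- rooting
  cls
}

#' Neighbor-joining tree for a genomic region
#'
#' Restricts the genotype-posterior distances to the SNPs inside
#' `[region[1], region[2])`, builds the NJ tree, and attaches the topology
#' classification. Individuals with unreliable distances (fewer than
#' `min_overlap` co-covered SNPs against any partner) are dropped, greedily
#' removing the worst individual until all remaining pairs are reliable.
#'
#' @param gp a `geno_post`.
#' @param region numeric `[start, end)` in bp; `NULL` means all SNPs.
#' @param min_snps minimum SNPs required in the region (default 20).
#' @param min_overlap minimum co-covered SNPs per retained pair.
#' @param subpop,progenitors passed to [classify_topology()]; `subpop`
#'   defaults to the labels carried by `gp`.
#' @return list with `tree`, `n_snps`, `classification`.
#' @export
region_tree <- function(gp, region = NULL, min_snps = 20, min_overlap = 20,
                        subpop = NULL, progenitors = c(aus = "OrI",
                                                       indica = "OrI",
                                                       japonica = "OrIII")) {
  sites <- if (is.null(region)) seq_along(gp$positions)
  else which(gp$positions >= region[1] & gp$positions < region[2])
  if (length(sites) < min_snps)
    stop("too few SNPs in region (", length(sites), " < ", min_snps, ")")
  pd <- pairwise_distances(gp, sites, min_overlap)
  d <- pd$d; no <- pd$n_overlap
  while (nrow(d) > 3 && any(no[upper.tri(no)] < min_overlap)) {
    bad <- which.max(colSums(no < min_overlap))
    d <- d[-bad, -bad, drop = FALSE]
    no <- no[-bad, -bad, drop = FALSE]
  }
  tr <- nj_tree(d)
  if (is.null(subpop))
    subpop <- setNames(gp$labels$subpop, gp$labels$id)
  cls <- classify_topology(tr, subpop, progenitors)
  list(tree = tr, n_snps = length(sites), classification = cls)
}

#' Concatenation-dilution experiment
#'
#' Recomputes the tree over the union of the sweep-region SNPs and the
#' first `k` neutral regions for growing `k`, recording the classification
#' each time. Concatenating enough neutral sequence lets the genome-wide
#' signal overwhelm the sweep's phylogenetic signature; the smallest `k`
#' at which the classification leaves `domesticate_monophyletic` is
#' reported.
#'
#' @param gp a `geno_post`.
#' @param sweep_region `[start, end)` of the sweep window.
#' @param neutral_regions list of `[start, end)` vectors, disjoint from the
#'   sweep region.
#' @param ks integer vector of neutral-region counts to evaluate (always
#'   includes 0).
#' @param ... passed to [region_tree()]'s distance/classification controls.
#' @return data.frame with `k`, `n_snps`, `classification`; attribute
#'   `flip_k` is the smallest evaluated `k` whose classification is not
#'   `domesticate_monophyletic` (NA if never).
#' @export
concatenation_experiment <- function(gp, sweep_region, neutral_regions,
                                     ks = c(0, 1, 2, 5, 10, 25, 50), ...) {
  ks <- sort(unique(c(0L, as.integer(ks))))
  ks <- ks[ks <= length(neutral_regions)]
  site_idx <- function(region)
    which(gp$positions >= region[1] & gp$positions < region[2])
  sweep_sites <- site_idx(sweep_region)
  neutral_sites <- lapply(neutral_regions, site_idx)
  subpop <- setNames(gp$labels$subpop, gp$labels$id)
  res <- lapply(ks, function(k) {
    sites <- sort(unique(c(sweep_sites,
                           unlist(neutral_sites[seq_len(k)]))))
    pd <- pairwise_distances(gp, sites)
    tr <- nj_tree(pd$d)
    data.frame(k = k, n_snps = length(sites),
               classification = as.character(classify_topology(tr, subpop)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  flip <- out$k[out$classification != "domesticate_monophyletic"]
  attr(out, "flip_k") <- if (length(flip)) min(flip) else NA_integer_
  out
}
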