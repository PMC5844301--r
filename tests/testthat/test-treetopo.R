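# Distances from genotype posteriors, neighbor joining, topology classes.

mk_gp <- function(p0, p1, p2, covered = NULL, subpop = NULL) {
  n <- ncol(p0)
  if (is.null(covered)) covered <- matrix(1, nrow(p0), n)
  ids <- sprintf("ind_%02d", seq_len(n))
  if (is.null(subpop)) subpop <- rep("OrII", n)
  structure(list(positions = seq_len(nrow(p0)) - 1L, p0 = p0, p1 = p1,
                 p2 = p2, covered = covered,
                 labels = data.frame(id = ids, subpop = subpop,
                                     status = ifelse(subpop %in%
                                       c("aus", "indica", "japonica"),
                                       "domesticated", "wild"),
                                     stringsAsFactors = FALSE)),
            class = "geno_post")
}

test_that("pairwise distances follow the expected mismatch formula", {
  # identical point-mass genotypes: distance 0
  gp <- mk_gp(p0 = cbind(c(1, 0), c(1, 0)), p1 = cbind(c(0, 0), c(0, 0)),
              p2 = cbind(c(0, 1), c(0, 1)))
  expect_equal(pairwise_distances(gp, min_overlap = 1)$d[1, 2], 0)
  # opposite homozygotes at one site: distance 1
  gp2 <- mk_gp(p0 = cbind(1, 0), p1 = cbind(0, 0), p2 = cbind(0, 1))
  expect_equal(pairwise_distances(gp2, min_overlap = 1)$d[1, 2], 1)
  # mixed posterior case, by hand:
  # P(a) = (.5,.5,0), P(b) = (0,0,1): E|g1-g2|/2 = (.5*2 + .5*1)/2 = 0.75
  gp3 <- mk_gp(p0 = cbind(0.5, 0), p1 = cbind(0.5, 0), p2 = cbind(0, 1))
  expect_equal(pairwise_distances(gp3, min_overlap = 1)$d[1, 2], 0.75)
  # co-coverage masking: uncovered sites are excluded pair by pair
  gp4 <- mk_gp(p0 = cbind(c(1, 1), c(0, 1)), p1 = cbind(c(0, 0), c(0, 0)),
               p2 = cbind(c(0, 0), c(1, 0)),
               covered = cbind(c(1, 1), c(1, 0)))
  pd <- pairwise_distances(gp4, min_overlap = 1)
  expect_equal(pd$d[1, 2], 1)  # only site 1 co-covered
  expect_equal(pd$n_overlap[1, 2], 1)
  expect_true(pairwise_distances(gp4, min_overlap = 2)$unreliable[1, 2])
})

test_that("distances at depth 30 track the true genotype mismatch", {
  fx <- deep_sim()
  gp <- genotype_posteriors(fx$pile)
  a <- which(fx$pile$labels$subpop == "OrII")[1]
  b <- which(fx$pile$labels$subpop == "OrI")[1]
  d <- pairwise_distances(gp)$d[a, b]
  dos <- function(i) fx$h$haplotypes[2 * i - 1, ] + fx$h$haplotypes[2 * i, ]
  snp_cols <- match(gp$positions, fx$h$positions)
  truth <- mean(abs(dos(a)[snp_cols] - dos(b)[snp_cols]) / 2, na.rm = TRUE)
  expect_lt(abs(d / truth - 1), 0.05)
})

test_that("neighbor joining is exact on additive matrices", {
  for (seed in 1:30) {
    ntaxa <- sample(4:12, 1)
    ref <- random_additive(ntaxa, seed)
    est <- nj_tree(ref$D)
    expect_true(same_topology(est, ref$tree))
    # additivity: path distances on the estimate reproduce the input
    expect_equal(ape::cophenetic.phylo(est)[rownames(ref$D), colnames(ref$D)],
                 ref$D, tolerance = 1e-9)
  }
})

test_that("three taxa resolve by the three-point formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))
  expect_error(nj_tree(D[1:2, 1:2]), "3 taxa")
  D2 <- D; D2[1, 2] <- NA
  expect_error(nj_tree(D2), "finite")
})

test_that("small perturbations of an additive metric keep the topology", {
  ref <- random_additive(8, 99)
  set.seed(1)
  for (i in 1:5) {
    E <- matrix(runif(64, -5e-3, 5e-3), 8)
    E <- (E + t(E)) / 2
    diag(E) <- 0
    expect_true(same_topology(nj_tree(ref$D + E), ref$tree))
  }
})

# helper: subpop vector from tip prefixes
subpop_of <- function(tr) setNames(sub("_.*$", "", tr$tip.label),
                                   tr$tip.label)

test_that("topology classes match their defining examples", {
  mono <- ape::read.tree(text = paste0(
    "((((aus_1,aus_2),(indica_1,indica_2)),(japonica_1,japonica_2)),",
    "((OrIII_1,OrIII_2),((OrI_1,OrI_2),(OrII_1,OrII_2))));"))
  expect_equal(as.character(classify_topology(mono, subpop_of(mono))),
               "domesticate_monophyletic")
  conc <- ape::read.tree(text = paste0(
    "((((aus_1,aus_2),(OrI_1,OrI_2)),((indica_1,indica_2),(OrI_3,OrI_4))),",
    "((japonica_1,japonica_2),(OrIII_1,OrIII_2)),(OrII_1,OrII_2));"))
  expect_equal(as.character(classify_topology(conc, subpop_of(conc))),
               "subpop_concordant")
  # progenitor mismatch (japonica sister to OrI) is 'other'
  wrong <- ape::read.tree(text = paste0(
    "((((aus_1,aus_2),(OrIII_1,OrIII_2)),((indica_1,indica_2),",
    "(OrI_3,OrI_4))),((japonica_1,japonica_2),(OrI_1,OrI_2)),",
    "(OrII_1,OrII_2));"))
  expect_equal(as.character(classify_topology(wrong, subpop_of(wrong))),
               "other")
  # non-monophyletic domesticated subpop is 'other'
  broken <- ape::read.tree(text = paste0(
    "(((aus_1,(OrI_1,aus_2)),((indica_1,indica_2),(OrI_3,OrI_4))),",
    "((japonica_1,japonica_2),(OrIII_1,OrIII_2)),(OrII_1,OrII_2));"))
  expect_equal(as.character(classify_topology(broken, subpop_of(broken))),
               "other")
  expect_error(classify_topology(ape::read.tree(text = "((aus_1,indica_1),japonica_1);"),
                                 c(aus_1 = "aus", indica_1 = "indica",
                                   japonica_1 = "japonica")),
               "OrII")
})

test_that("classification is invariant to leaf order and rotation", {
  conc <- ape::read.tree(text = paste0(
    "((((aus_1,aus_2),(OrI_1,OrI_2)),((indica_1,indica_2),(OrI_3,OrI_4))),",
    "((japonica_1,japonica_2),(OrIII_1,OrIII_2)),(OrII_1,OrII_2));"))
  base <- as.character(classify_topology(conc, subpop_of(conc)))
  set.seed(8)
  for (i in 1:5) {
    tr <- conc
    for (node in sample((length(tr$tip.label) + 1):(length(tr$tip.label) +
                                                      tr$Nnode), 3))
      tr <- tryCatch(ape::rotate(tr, node), error = function(e) tr)
    tr <- ape::read.tree(text = ape::write.tree(tr))
    expect_equal(as.character(classify_topology(tr, subpop_of(tr))), base)
  }
})

test_that("region trees enforce the SNP minimum and match genome-wide", {
  fx <- small_sim()
  gp <- genotype_posteriors(fx$pile)
  expect_error(region_tree(gp, c(0, 50)), "too few")
  whole <- region_tree(gp, c(0, fx$cfg$L))
  genome <- region_tree(gp, NULL)
  expect_equal(as.character(whole$classification),
               as.character(genome$classification))
  locus <- region_tree(gp, fx$cfg$sweep_interval)
  expect_equal(as.character(locus$classification),
               "domesticate_monophyletic")
})

test_that("concatenation with k = 0 reduces to the region tree", {
  fx <- small_sim()
  gp <- genotype_posteriors(fx$pile)
  sw <- fx$cfg$sweep_interval
  neutral <- list(c(0, 20000), c(20000, 40000), c(120000, 140000))
  cc <- concatenation_experiment(gp, sw, neutral, ks = c(0, 3))
  expect_equal(cc$classification[cc$k == 0],
               as.character(region_tree(gp, sw)$classification))
  expect_equal(nrow(cc), 2L)
})
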