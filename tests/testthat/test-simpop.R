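# Synthetic-data generator: demography, sweep transplant, read model.

test_that("configuration validation rejects inconsistent histories", {
  expect_error(demography_config(bottleneck_factor = 0), "bottleneck")
  expect_error(demography_config(bottleneck_factor = 1.2), "bottleneck")
  expect_error(demography_config(sweep_interval = c(-1, 100)), "sweep")
  expect_error(demography_config(sweep_interval = c(0, 2e6)), "sweep")
  expect_error(demography_config(split_dom = c(aus = 0.1, indica = 0.1)),
               "progenitor")
  expect_error(demography_config(split_or13 = 1.5), "nested")
  expect_error(demography_config(split_dom = c(aus = 0.5, indica = 0.1,
                                               japonica = 0.1)),
               "predate")
})

test_that("haplotype simulation is deterministic and well formed", {
  cfg <- small_cfg(seed = 11)
  h1 <- simulate_haplotypes(cfg)
  h2 <- simulate_haplotypes(cfg)
  expect_identical(h1$haplotypes, h2$haplotypes)
  expect_identical(h1$positions, h2$positions)
  # positions strictly increasing within [0, L)
  expect_true(all(diff(h1$positions) > 0))
  expect_true(all(h1$positions >= 0 & h1$positions < cfg$L))
  # every column segregating
  cs <- colSums(h1$haplotypes)
  expect_true(all(cs > 0 & cs < nrow(h1$haplotypes)))
  expect_identical(nrow(h1$haplotypes), 2L * 6L * 6L)
})

test_that("mu = 0 yields zero segregating sites", {
  cfg <- small_cfg(seed = 5)
  cfg$mu <- 0
  h <- simulate_haplotypes(cfg)
  expect_identical(ncol(h$haplotypes), 0L)
})

test_that("wild diversity matches theta_neutral; bottleneck reduces it", {
  # 50 tiny replicates; OrII/OrIII are panmictic so E[pi] = theta exactly.
  # OrI mixes the OrI-a/OrI-b demes and is expected to run higher.
  n_rep <- 50
  theta <- 0.005
  pis <- t(vapply(seq_len(n_rep), function(r) {
    cfg <- demography_config(n_per_subpop = 5, L = 50000,
                             sweep_interval = c(20000, 30000),
                             theta_neutral = theta, seed = 1000 + r)
    h <- simulate_haplotypes(cfg)
    vapply(c("OrII", "OrIII", "OrI", "aus", "indica", "japonica"),
           function(sp) truth_windows(h, sp, cfg$L)$pi_true, numeric(1))
  }, numeric(6)))
  colnames(pis) <- c("OrII", "OrIII", "OrI", "aus", "indica", "japonica")
  for (sp in c("OrII", "OrIII")) {
    se <- sd(pis[, sp]) / sqrt(n_rep)
    expect_lt(abs(mean(pis[, sp]) - theta), 3 * se)
  }
  expect_gt(mean(pis[, "OrI"]), theta)        # deme structure inflates OrI
  expect_lt(mean(pis[, "OrI"]), 1.5 * theta)
  # strict wild > domesticated diversity, averaged over replicates
  for (sp in c("aus", "indica", "japonica"))
    expect_lt(mean(pis[, sp]), mean(pis[, "OrII"]))
})

test_that("degenerate history makes domesticates exchangeable with wilds", {
  n_rep <- 20
  diffs <- vapply(seq_len(n_rep), function(r) {
    cfg <- demography_config(n_per_subpop = 5, L = 50000,
                             sweep_interval = c(20000, 30000),
                             bottleneck_factor = 1,
                             split_dom = c(aus = 1e-9, indica = 1e-9,
                                           japonica = 1e-9),
                             seed = 3000 + r)
    h <- simulate_haplotypes(cfg)
    truth_windows(h, "japonica", cfg$L)$pi_true -
      truth_windows(h, "OrIII", cfg$L)$pi_true
  }, numeric(1))
  se <- sd(diffs) / sqrt(n_rep)
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("sweep transplant homogenizes the locus and nothing else", {
  cfg <- small_cfg(seed = 21)
  cfg$post_sweep_time <- 0
  h <- simulate_haplotypes(cfg)
  hs <- apply_sweep_introgression(h, cfg)
  sw <- cfg$sweep_interval
  labs <- sample_labels(hs)
  dom <- which(labs$status == "domesticated")
  dom_rows <- as.vector(rbind(2L * dom - 1L, 2L * dom))
  in_sw <- hs$positions >= sw[1] & hs$positions < sw[2]
  # post_sweep_time = 0: all domesticated haplotypes identical at the locus
  block <- hs$haplotypes[dom_rows, in_sw, drop = FALSE]
  expect_true(all(block == rep(block[1, ], each = nrow(block))))
  expect_equal(truth_windows(hs, "aus", sw[2] - sw[1])$pi_true[
    sw[1] / (sw[2] - sw[1]) + 1], 0)
  # outside the locus the columns are untouched (match by position)
  out_new <- which(!(hs$positions >= sw[1] & hs$positions < sw[2]))
  out_old <- match(hs$positions[out_new], h$positions)
  expect_identical(hs$haplotypes[, out_new], h$haplotypes[, out_old])
})

test_that("sweep-window domesticated diversity collapses below flanks", {
  fx <- small_sim()
  sw <- fx$cfg$sweep_interval
  tw <- truth_windows(fx$h, "indica", 20000)
  i_sw <- which(tw$start == sw[1])
  flank <- mean(tw$pi_true[c(i_sw - 1, i_sw + 1)])
  expect_lt(tw$pi_true[i_sw], 0.1 * flank)
})

test_that("read simulation honors depth, error and determinism", {
  # >= 1e5 site-individual draws: empirical mean depth within 2%
  set.seed(1)
  hapm <- matrix(rbinom(12 * 400, 1, 0.3), nrow = 12)
  h <- manual_haps(hapm, seq(0, 399) * 25, 10000)
  p1 <- simulate_reads(h, 2, 0.01, seed = 8)
  p2 <- simulate_reads(h, 2, 0.01, seed = 8)
  expect_identical(p1$depth, p2$depth)
  expect_identical(p1$k1, p2$k1)
  expect_gt(length(p1$depth), 1e4)
  big <- simulate_reads(manual_haps(hapm[, 0, drop = FALSE], integer(0),
                                    20000), 2, 0.01, seed = 9)
  expect_gt(length(big$depth), 1e5)
  expect_lt(abs(mean(big$depth) / 2 - 1), 0.02)
  expect_true(all(big$k1 <= big$depth))
  # e = 0, homozygous-ancestral individuals: no allele-1 reads off-locus
  clean <- simulate_reads(h, 5, 0, seed = 10)
  inv <- setdiff(seq_len(h$L), h$positions + 1L)
  expect_true(all(clean$k1[inv, ] == 0))
  # e = 0 at a fixed-derived column: all reads carry allele 1
  hfix <- manual_haps(matrix(1L, nrow = 12, ncol = 1), 0L, 100)
  pfix <- simulate_reads(hfix, 5, 0, seed = 11)
  expect_identical(pfix$k1[1, ], pfix$depth[1, ])
  # vanishing depth: essentially everything missing
  p0 <- simulate_reads(h, 1e-9, 0.01, seed = 12)
  expect_true(all(p0$depth == 0))
})
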