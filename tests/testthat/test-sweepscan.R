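# pi_w/pi_d ratios, the common threshold, CLDGR calling, gene annotation.

mk_wt <- function(tp, pass = TRUE, start = NULL, window = 20000) {
  n <- length(tp)
  if (is.null(start)) start <- seq(0, by = window, length.out = n)
  out <- data.frame(chrom = "chr1", start = start, end = start + window,
                    sum_theta_pi = tp * window, sum_theta_w = tp * window,
                    n_sites_with_data = window,
                    theta_pi_per_site = tp, theta_w_per_site = tp,
                    pass = rep(pass, length.out = n))
  class(out) <- c("window_table", "data.frame")
  out
}

test_that("pi_ratio joins grids and flags infinities", {
  r <- pi_ratio(mk_wt(c(0.004, 0.002)), mk_wt(c(0.001, 0)))
  expect_equal(r$ratio[1], 4)
  expect_identical(r$ratio[2], Inf)
  expect_false(r$finite[2])
  # windows failing the data filter in either population are excluded
  r2 <- pi_ratio(mk_wt(c(0.004, 0.002), pass = c(TRUE, FALSE)),
                 mk_wt(c(0.001, 0.001)))
  expect_equal(nrow(r2), 1L)
  expect_error(pi_ratio(mk_wt(c(1, 2)), mk_wt(c(1, 2), start = c(0, 40000))),
               "grids")
})

test_that("common threshold is the minimum of the per-subpop percentiles", {
  rl <- list(aus = rep(8.1, 50), indica = rep(5.2, 50),
             japonica = rep(12.0, 50))
  thr <- common_threshold(rl)
  expect_equal(as.numeric(thr), 5.2)
  expect_equal(sort(names(attr(thr, "per_subpop"))),
               c("aus", "indica", "japonica"))
  # identical distributions: threshold equals the common percentile
  set.seed(2)
  v <- rexp(200)
  same <- common_threshold(list(a = v, b = v, c = v))
  expect_equal(as.numeric(same), pct7(v, 97.5))
  # 1000-value vectors match the independent sort-and-interpolate oracle
  vv <- lapply(1:3, function(i) { set.seed(i); rexp(1000, 0.5) })
  thr2 <- common_threshold(vv)
  expect_equal(as.numeric(thr2), min(vapply(vv, pct7, numeric(1), p = 97.5)))
  # infinite ratios are excluded from the percentile computation
  with_inf <- common_threshold(list(a = c(v, rep(Inf, 20)), b = v, c = v))
  expect_equal(as.numeric(with_inf), pct7(v, 97.5))
  expect_error(common_threshold(list(a = rexp(30), b = v, c = v)),
               "too few")
})

test_that("CLDGR calling intersects exceedances across the three subpops", {
  set.seed(5)
  wild <- mk_wt(runif(60, 0.004, 0.006))
  doms <- lapply(1:3, function(i) mk_wt(runif(60, 0.002, 0.005)))
  names(doms) <- c("aus", "indica", "japonica")
  # plant a shared sweep window with near-zero domesticated diversity
  for (nm in names(doms)) doms[[nm]]$theta_pi_per_site[25] <- 1e-6
  ratios <- lapply(doms, function(d) pi_ratio(wild, d))
  thr <- common_threshold(ratios)
  cl <- find_cldgr(ratios, thr)
  expect_true(25 %in% (cl$windows$start / 20000 + 1))
  # intersection property: every member exceeds in every subpop
  for (nm in names(ratios)) {
    r <- ratios[[nm]]
    idx <- match(cl$windows$start, r$start)
    expect_true(all(r$ratio[idx] > thr))
  }
  # monotone decreasing in the threshold
  sizes <- vapply(c(thr, thr * 2, thr * 5), function(t)
    nrow(find_cldgr(ratios, t)$windows), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # one subpop below threshold everywhere: empty set
  ratios2 <- ratios
  ratios2$aus$ratio <- rep(0, nrow(ratios2$aus))
  expect_equal(nrow(find_cldgr(ratios2, thr)$windows), 0L)
  # infinite ratios count as exceeding
  ratios3 <- ratios
  for (nm in names(ratios3)) ratios3[[nm]]$ratio[10] <- Inf
  expect_true(180000 %in% find_cldgr(ratios3, thr)$windows$start)
})

test_that("adjacent CLDGR windows merge into maximal runs", {
  win <- data.frame(chrom = "chr1", start = c(0, 20000, 40000, 100000),
                    end = c(20000, 40000, 60000, 120000))
  m <- merge_windows(win)
  expect_equal(nrow(m), 2L)
  expect_equal(m$end[1], 60000)
  expect_equal(m$n_windows, c(3L, 1L))
})

test_that("gene annotation uses half-open overlap on real coordinates", {
  genes <- data.frame(
    chrom = c("chr4", "chr4", "chr7"),
    start = c(34231186, 25959399, 2839194),
    end = c(34233221, 25963504, 2840089),
    name = c("sh4", "LABA1", "PROG1"))
  win <- data.frame(chrom = c("chr4", "chr4", "chr4", "chr7"),
                    start = c(34220000, 25940000, 25960000, 2820000),
                    end = c(34240000, 25960000, 25980000, 2840000))
  ann <- annotate_genes(win, genes)
  expect_equal(ann$genes, c("sh4", "LABA1", "LABA1", "PROG1"))
  # LABA1 spans two adjacent 20 kbp windows and annotates both
  expect_equal(sum(ann$genes == "LABA1"), 2L)
  # gene abutting the window end exactly: half-open, no overlap
  abut <- annotate_genes(data.frame(chrom = "chr1", start = 0, end = 200),
                         data.frame(chrom = "chr1", start = 200, end = 300,
                                    name = "g"))
  expect_equal(abut$genes, "")
  expect_error(annotate_genes(win, data.frame(chrom = "chr1", start = 5,
                                              end = 2, name = "bad")),
               "malformed")
})
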