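# Orchestration: one replicate of the full inference chain
# (simulate -> reads -> GL -> SFS -> theta -> windows -> pi_w/pi_d scan ->
# CLDGRs -> trees -> topology classes), and the replication experiment that
# tabulates sweep recall, topology class frequencies, and the
# flank/concatenation dilution curves.

#' Run configuration for the replication experiment
#'
#' @param demography a [demography_config()].
#' @param mean_depth mean sequencing coverage (the study regime is 1-2x).
#' @param error_rate per-base miscall probability after quality filtering.
#' @param window_bp window sizes (bp) for the scan; first entry drives the
#'   CLDGR calls.
#' @param percentile sweep-threshold percentile (default 97.5).
#' @param min_frac window data-fraction filter (default 0.25).
#' @param min_ratio_windows minimum finite ratio windows per subpopulation
#'   for a valid threshold (default 40; lower it for toy chromosomes).
#' @param flank_totals total region extents (bp, gene + both flanks) for the
#'   flank-dilution curve.
#' @param concat_ks neutral-window counts for the concatenation experiment.
#' @param n_replicates number of replicates.
#' @param seed master seed; every stage/replicate derives its own stream.
#' @return list of class `run_config`.
#' @export
run_config <- function(demography = demography_config(),
                       mean_depth = 2, error_rate = 0.001,
                       window_bp = c(20000, 100000, 500000, 1000000),
                       percentile = 97.5, min_frac = 0.25,
                       min_ratio_windows = 40,
                       flank_totals = c(40000, 100000, 500000, 1000000),
                       concat_ks = c(0, 1, 2, 5, 10, 25, 50),
                       n_replicates = 20, seed = 1L) {
  if (n_replicates < 1) stop("n_replicates must be at least 1")
  structure(list(demography = demography, mean_depth = mean_depth,
                 error_rate = error_rate, window_bp = window_bp,
                 percentile = percentile, min_frac = min_frac,
                 min_ratio_windows = min_ratio_windows,
                 flank_totals = flank_totals, concat_ks = concat_ks,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "run_config")
}

# window tables for one subpopulation at each requested size
subpop_windows <- function(pile, subpop_ids, window_bp, min_frac,
                           mean_depth) {
  sub <- pile_subset(pile, subpop_ids)
  th <- subpop_theta(sub,
                     filters = site_filter_preset(ncol(sub$depth),
                                                  mean_depth))
  lapply(setNames(window_bp, paste0("w", window_bp)), function(wbp)
    window_scan(th$positions, th$theta, sub$L, wbp, min_frac))
}

#' Run one replicate of the full pipeline
#'
#' @param cfg a [run_config()].
#' @param replicate replicate counter (drives the derived seeds).
#' @param sweep simulate the domestication sweep (`TRUE`) or a fully
#'   neutral genome (`FALSE`).
#' @param trees build the genome-wide/sweep-locus trees and dilution curves
#'   (slower; not needed for pure scan experiments).
#' @param subpops subpopulations to run the theta pipeline on.
#' @return list with the haplotype truth, window tables per subpopulation
#'   and window size, ratio tables, threshold, `cldgr`, and (when `trees`)
#'   the genome/sweep classifications, flank curve and concatenation curve.
#' @export
run_replicate <- function(cfg, replicate = 1L, sweep = TRUE, trees = TRUE,
                          subpops = c("OrII", "aus", "indica", "japonica")) {
  demo <- cfg$demography
  demo$seed <- child_seed(cfg$seed, 101L, replicate)
  h <- simulate_haplotypes(demo)
  if (sweep) h <- apply_sweep_introgression(h, demo)
  labs <- sample_labels(h)
  ind <- if (trees) seq_len(nrow(labs)) else which(labs$subpop %in% subpops)
  pile <- simulate_reads(h, cfg$mean_depth, cfg$error_rate,
                         seed = child_seed(cfg$seed, 102L, replicate),
                         individuals = ind)

  win <- lapply(setNames(nm = subpops), function(sp)
    subpop_windows(pile, pile$labels$id[pile$labels$subpop == sp],
                   cfg$window_bp, cfg$min_frac, cfg$mean_depth))

  doms <- intersect(c("aus", "indica", "japonica"), subpops)
  scan <- lapply(setNames(nm = paste0("w", cfg$window_bp)), function(wn) {
    ratios <- lapply(setNames(nm = doms), function(d)
      pi_ratio(win$OrII[[wn]], win[[d]][[wn]]))
    thr <- tryCatch(common_threshold(ratios, cfg$percentile,
                                     cfg$min_ratio_windows),
                    error = function(e) NA_real_)
    cl <- if (is.na(thr)) NULL else find_cldgr(ratios, thr)
    list(ratios = ratios, threshold = thr, cldgr = cl)
  })

  out <- list(replicate = replicate, sweep = sweep, windows = win,
              scan = scan, L = h$L,
              sweep_interval = if (sweep) demo$sweep_interval else NULL)

  if (trees) {
    gp <- genotype_posteriors(pile)
    subpop <- setNames(pile$labels$subpop, pile$labels$id)
    genome <- region_tree(gp, NULL, subpop = subpop)
    out$genome_class <- as.character(genome$classification)
    if (sweep) {
      sw <- demo$sweep_interval
      locus <- region_tree(gp, sw, subpop = subpop)
      out$sweep_class <- as.character(locus$classification)
      # flank dilution around a nominal 2 kbp gene at the locus centre
      gene <- c(mean(sw) - 1000, mean(sw) + 1000)
      out$flank <- data.frame(total_bp = cfg$flank_totals, classification =
        vapply(cfg$flank_totals, function(tot) {
          fl <- (tot - (gene[2] - gene[1])) / 2
          reg <- c(max(0, gene[1] - fl), min(h$L, gene[2] + fl))
          as.character(region_tree(gp, reg, subpop = subpop)$classification)
        }, character(1)))
      neutral <- neutral_windows(h$L, sw, 20000)
      out$concat <- concatenation_experiment(gp, sw, neutral,
                                             ks = cfg$concat_ks)
    }
  }
  out
}

# 20 kbp windows at least one window away from the sweep interval
neutral_windows <- function(L, sweep_interval, window_bp = 20000,
                            buffer = 20000) {
  starts <- seq.int(0L, L - 1L, by = window_bp)
  ends <- pmin(starts + window_bp, L)
  keep <- ends <= sweep_interval[1] - buffer |
    starts >= sweep_interval[2] + buffer
  lapply(which(keep), function(i) c(starts[i], ends[i]))
}

#' Run the replication experiment
#'
#' Repeats [run_replicate()] `cfg$n_replicates` times and tabulates
#' (i) sweep-window CLDGR recall, (ii) topology class frequencies at the
#' sweep locus versus genome-wide, and (iii) the flank-size and
#' concatenation dilution curves. All output is a deterministic function of
#' the configuration.
#'
#' @param cfg a [run_config()].
#' @param sweep simulate the sweep (default TRUE).
#' @param trees build trees per replicate (default TRUE).
#' @param progress print a line per replicate to stderr.
#' @return list of class `replication_report` with `replicates` (raw per
#'   replicate results), `recall`, `class_freq`, `flank_curve`,
#'   `concat_curve`.
#' @export
run_replication <- function(cfg, sweep = TRUE, trees = TRUE,
                            progress = FALSE) {
  reps <- lapply(seq_len(cfg$n_replicates), function(r) {
    t0 <- proc.time()[3]
    res <- run_replicate(cfg, r, sweep = sweep, trees = trees)
    if (progress)
      message(sprintf("[replicate %d/%d] %s %.1fs", r, cfg$n_replicates,
                      if (sweep) "sweep" else "neutral",
                      proc.time()[3] - t0))
    res
  })
  wn <- paste0("w", cfg$window_bp[1])
  hit <- vapply(reps, function(r) {
    if (!sweep || is.null(r$scan[[wn]]$cldgr)) return(NA)
    sw <- r$sweep_interval
    any(r$scan[[wn]]$cldgr$windows$start < sw[2] &
          r$scan[[wn]]$cldgr$windows$end > sw[1])
  }, logical(1))
  report <- list(cfg = cfg, sweep = sweep, replicates = reps,
                 recall = mean(hit, na.rm = TRUE))
  if (trees) {
    report$class_freq <- list(
      genome = table(vapply(reps, `[[`, character(1), "genome_class")))
    if (sweep) {
      report$class_freq$sweep_locus <-
        table(vapply(reps, `[[`, character(1), "sweep_class"))
      report$flank_curve <- do.call(rbind, lapply(seq_along(reps),
        function(i) cbind(replicate = i, reps[[i]]$flank)))
      report$concat_curve <- do.call(rbind, lapply(seq_along(reps),
        function(i) cbind(replicate = i,
                          as.data.frame(reps[[i]]$concat))))
    }
  }
  class(report) <- "replication_report"
  report
}

#' @export
print.replication_report <- function(x, ...) {
  cat("Replication report:", length(x$replicates), "replicates,",
      if (x$sweep) "sweep" else "neutral", "demography\n")
  if (x$sweep) cat("  sweep-window CLDGR recall:", signif(x$recall, 3), "\n")
  if (!is.null(x$class_freq)) {
    cat("  genome-wide classes:\n"); print(x$class_freq$genome)
    if (!is.null(x$class_freq$sweep_locus)) {
      cat("  sweep-locus classes:\n"); print(x$class_freq$sweep_locus)
    }
  }
  invisible(x)
}

#' Window-size sensitivity experiment
#'
#' Pools pi_w/pi_d ratio values across replicates separately for each
#' window size (small chromosomes do not give enough windows per replicate
#' for a per-replicate percentile at the larger sizes), derives the common
#' threshold per size from the pooled empirical distributions, and counts
#' CLDGR windows. Larger windows tile the chromosome into fewer windows, so
#' the CLDGR count tends to shrink as the window size grows.
#'
#' @param cfg a [run_config()] (its `window_bp` vector defines the sizes).
#' @param n_replicates replicates to pool (default `cfg$n_replicates`).
#' @return data.frame with `window_bp`, `n_windows` (pooled, passing),
#'   `threshold`, `n_cldgr`.
#' @export
window_size_experiment <- function(cfg, n_replicates = cfg$n_replicates) {
  reps <- lapply(seq_len(n_replicates), function(r)
    run_replicate(cfg, r, sweep = TRUE, trees = FALSE))
  doms <- c("aus", "indica", "japonica")
  do.call(rbind, lapply(cfg$window_bp, function(wbp) {
    wn <- paste0("w", wbp)
    pooled <- lapply(setNames(nm = doms), function(d)
      do.call(rbind, lapply(seq_along(reps), function(i) {
        r <- reps[[i]]$scan[[wn]]$ratios[[d]]
        r$chrom <- sprintf("rep%d", i)
        r
      })))
    thr <- tryCatch(common_threshold(pooled, cfg$percentile,
                                     min_windows = 10),
                    error = function(e) NA_real_)
    ncl <- if (is.na(thr)) NA_integer_ else
      nrow(find_cldgr(pooled, thr)$windows)
    data.frame(window_bp = wbp, n_windows = nrow(pooled[[1]]),
               threshold = thr, n_cldgr = ncl)
  }))
}
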