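#' Demography configuration for the synthetic rice population generator
#'
#' Describes the six-subpopulation demography that the generator emulates:
#' three wild subpopulations (OrI, OrII, OrIII) and three domesticated ones
#' (aus, indica, japonica), each domesticate descending from its own wild
#' progenitor (japonica from OrIII, aus from the OrI-a deme, indica from the
#' OrI-b deme), with a diversity-reducing bottleneck on every domesticated
#' branch and one hard-sweep haplotype that originates on the japonica lineage
#' and is introgressed into aus and indica.
#'
#' Times are in coalescent units of `2 * N_ref` generations, where `N_ref` is
#' the wild effective size implied by `theta_neutral = 4 * N_ref * mu`. On
#' that scale the neutral mutation intensity per unit branch length per site
#' is `theta_neutral / 2`; setting `mu = 0` switches mutation off entirely.
#'
#' @param n_per_subpop diploid individuals per subpopulation.
#' @param L sequence length in bp.
#' @param mu per-site per-generation mutation rate (only its positivity and
#'   the ratio `theta_neutral / mu` matter on the coalescent scale).
#' @param theta_neutral scaled diversity `4 * N_e * mu` per site for the wild
#'   populations.
#' @param split_or2 divergence of OrII from everything else (deepest split).
#' @param split_or13 divergence of OrIII (+japonica ancestor) from OrI.
#' @param split_or1ab divergence of the OrI-a and OrI-b demes within OrI.
#' @param split_dom named numeric: domestication split times for `aus`
#'   (from OrI-a), `indica` (from OrI-b) and `japonica` (from OrIII).
#' @param bottleneck_factor multiplier (0, 1] applied to N_e on each
#'   domesticated branch.
#' @param sweep_interval `[start, end)` 0-based bp coordinates of the
#'   domestication locus.
#' @param post_sweep_time coalescent time over which each transplanted sweep
#'   haplotype accumulates independent mutations after the transfer.
#' @param block_length length in bp of the independent non-recombining blocks
#'   used in place of a full recombination model.
#' @param seed integer RNG seed; all generator output is a deterministic
#'   function of the configuration including this seed.
#'
#' @return An object of class `demography_config`.
#' @export
demography_config <- function(n_per_subpop = 10,
                              L = 1200000,
                              mu = 7e-9,
                              theta_neutral = 0.005,
                              split_or2 = 1.0,
                              split_or13 = 0.6,
                              split_or1ab = 0.4,
                              split_dom = c(aus = 0.1, indica = 0.1,
                                            japonica = 0.1),
                              bottleneck_factor = 0.2,
                              sweep_interval = c(480000, 540000),
                              post_sweep_time = 0.01,
                              block_length = 5000,
                              seed = 1L) {
  stopifnot(n_per_subpop >= 1, L >= 1, mu >= 0, theta_neutral >= 0,
            block_length >= 1)
  if (!(bottleneck_factor > 0 && bottleneck_factor <= 1))
    stop("bottleneck_factor must be in (0, 1]")
  need <- c("aus", "indica", "japonica")
  if (!all(need %in% names(split_dom)))
    stop("every domesticated subpopulation needs a progenitor split time: ",
         paste(setdiff(need, names(split_dom)), collapse = ", "))
  split_dom <- split_dom[need]
  if (any(split_dom < 0)) stop("split times must be non-negative")
  if (!(split_or1ab < split_or13 && split_or13 < split_or2))
    stop("splits must be nested: or1ab < or13 < or2")
  if (split_dom[["aus"]] > split_or1ab || split_dom[["indica"]] > split_or1ab)
    stop("aus/indica domestication splits must predate the OrI-a/OrI-b merge")
  if (split_dom[["japonica"]] > split_or13)
    stop("japonica domestication split must predate the OrI/OrIII merge")
  if (!is.null(sweep_interval)) {
    stopifnot(length(sweep_interval) == 2)
    if (sweep_interval[1] < 0 || sweep_interval[2] > L ||
        sweep_interval[1] >= sweep_interval[2])
      stop("sweep_interval must be a non-empty [start, end) within [0, L)")
  }
  structure(list(
    n_per_subpop = as.integer(n_per_subpop), L = as.integer(L), mu = mu,
    theta_neutral = theta_neutral, split_or2 = split_or2,
    split_or13 = split_or13, split_or1ab = split_or1ab,
    split_dom = split_dom, bottleneck_factor = bottleneck_factor,
    sweep_interval = sweep_interval, post_sweep_time = post_sweep_time,
    block_length = as.integer(block_length), seed = as.integer(seed)
  ), class = "demography_config")
}

#' @export
print.demography_config <- function(x, ...) {
  cat("Demography: 6 subpopulations x", x$n_per_subpop, "diploids, L =",
      x$L, "bp\n")
  cat("  theta_neutral =", x$theta_neutral, " bottleneck =",
      x$bottleneck_factor, "\n")
  cat("  splits: dom", paste(signif(x$split_dom, 3), collapse = "/"),
      "| OrI a/b", x$split_or1ab, "| OrI/OrIII", x$split_or13,
      "| OrII", x$split_or2, "\n")
  if (!is.null(x$sweep_interval))
    cat("  sweep locus: [", x$sweep_interval[1], ",", x$sweep_interval[2],
        ") post-sweep time", x$post_sweep_time, "\n")
  invisible(x)
}

# Sample sheet: individuals in fixed order, with the internal deme used for
# the coalescent (OrI is split into demes a and b; aus/indica descend from
# them respectively).
sample_sheet <- function(n_per_subpop) {
  subpops <- c("OrI", "OrII", "OrIII", "aus", "indica", "japonica")
  status <- c(OrI = "wild", OrII = "wild", OrIII = "wild",
              aus = "domesticated", indica = "domesticated",
              japonica = "domesticated")
  n <- n_per_subpop
  df <- do.call(rbind, lapply(subpops, function(sp) {
    data.frame(id = sprintf("%s_%02d", sp, seq_len(n)), subpop = sp,
               status = status[[sp]], stringsAsFactors = FALSE)
  }))
  deme <- df$subpop
  ori <- which(df$subpop == "OrI")
  half <- ceiling(length(ori) / 2)
  deme[ori[seq_len(half)]] <- "OrIa"
  deme[ori[-seq_len(half)]] <- "OrIb"
  df$deme <- deme
  rownames(df) <- NULL
  df
}

#' Subpopulation labels of a haplotype set or sample sheet
#'
#' @param x a `haplotype_set` or `read_pile` object.
#' @return data.frame with columns `id`, `subpop`, `status`, `deme`.
#' @export
sample_labels <- function(x) x$labels
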