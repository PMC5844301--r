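# The pi_w/pi_d sweep scan: wild-to-domesticate diversity ratios per window,
# the empirical common threshold (lowest of the three 97.5th percentiles),
# colocated low-diversity genomic region (CLDGR) calling across the three
# domesticated subpopulations, and gene-overlap annotation.

#' Wild/domesticate diversity ratio per window
#'
#' Joins two window tables on the same grid and returns
#' `ratio = pi_w / pi_d` for the windows passing the data-fraction filter in
#' both populations. Windows where `pi_d = 0` get ratio `+Inf` with
#' `finite = FALSE`: a zero-diversity domesticated window is the strongest
#' sweep evidence but must not enter percentile computations.
#'
#' @param wild window table (typically Or-II, the wild diversity reference).
#' @param dom window table for one domesticated subpopulation.
#' @return data.frame (class `ratio_table`) with the window coordinates,
#'   `pi_w`, `pi_d`, `ratio`, `finite`.
#' @export
pi_ratio <- function(wild, dom) {
  if (nrow(wild) != nrow(dom) || any(wild$start != dom$start) ||
      any(wild$end != dom$end) || any(wild$chrom != dom$chrom))
    stop("window grids do not match")
  keep <- wild$pass & dom$pass
  pi_w <- wild$theta_pi_per_site[keep]
  pi_d <- dom$theta_pi_per_site[keep]
  ratio <- ifelse(pi_d > 0, pi_w / pi_d, ifelse(pi_w > 0, Inf, NaN))
  out <- data.frame(chrom = wild$chrom[keep], start = wild$start[keep],
                    end = wild$end[keep], pi_w = pi_w, pi_d = pi_d,
                    ratio = ratio, finite = is.finite(ratio),
                    stringsAsFactors = FALSE)
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' Common sweep-significance threshold across domesticated subpopulations
#'
#' Computes the `percentile`-th percentile (type 7, linear interpolation
#' between order statistics) of the finite ratios for each domesticated
#' subpopulation and returns the smallest of them: the subpopulation with
#' the lowest 97.5th percentile sets the significance threshold shared by
#' all three.
#'
#' @param ratios named list of `ratio_table`s (or bare ratio vectors), one
#'   per domesticated subpopulation.
#' @param percentile percentile in (0, 100); default 97.5.
#' @param min_windows minimum number of finite ratios required per
#'   subpopulation (default 40).
#' @return The threshold (numeric scalar) with attribute `per_subpop`.
#' @export
common_threshold <- function(ratios, percentile = 97.5, min_windows = 40) {
  qs <- vapply(ratios, function(r) {
    v <- if (is.data.frame(r)) r$ratio[r$finite] else r[is.finite(r)]
    if (length(v) < min_windows)
      stop("too few finite ratio windows (", length(v), " < ", min_windows,
           ")")
    unname(quantile(v, percentile / 100, type = 7))
  }, numeric(1))
  structure(min(qs), per_subpop = qs)
}

#' Call colocated low-diversity genomic regions (CLDGRs)
#'
#' A window is a CLDGR when its pi_w/pi_d ratio exceeds the common threshold
#' in aus AND indica AND japonica simultaneously. Infinite ratios (zero
#' domesticated diversity) count as exceedances. Only windows present
#' (i.e. passing the data filter) in all three ratio tables are eligible.
#'
#' @param ratios named list of three `ratio_table`s (aus, indica, japonica).
#' @param threshold common threshold from [common_threshold()].
#' @return list (class `cldgr_set`) with `windows` (data.frame of CLDGR
#'   windows with the three ratios), `merged` (BED-like data.frame of
#'   maximal runs of adjacent CLDGR windows) and `threshold`.
#' @export
find_cldgr <- function(ratios, threshold) {
  stopifnot(length(ratios) >= 3)
  key <- function(r) paste(r$chrom, r$start, r$end)
  common <- Reduce(intersect, lapply(ratios, key))
  per <- lapply(ratios, function(r) r[match(common, key(r)), , drop = FALSE])
  exceed <- Reduce(`&`, lapply(per, function(r) r$ratio > threshold))
  base <- per[[1]][exceed, c("chrom", "start", "end"), drop = FALSE]
  for (nm in names(per)) base[[paste0("ratio_", nm)]] <- per[[nm]]$ratio[exceed]
  base <- base[order(base$chrom, base$start), , drop = FALSE]
  rownames(base) <- NULL
  merged <- merge_windows(base)
  structure(list(windows = base, merged = merged, threshold = threshold),
            class = "cldgr_set")
}

#' @export
print.cldgr_set <- function(x, ...) {
  cat("CLDGR set:", nrow(x$windows), "windows (",
      nrow(x$merged), "merged regions ) at threshold",
      signif(x$threshold, 4), "\n")
  invisible(x)
}

#' Merge adjacent or overlapping windows into maximal runs
#'
#' @param windows data.frame with `chrom`, `start`, `end` (half-open).
#' @return data.frame of merged regions with `n_windows` per run.
#' @export
merge_windows <- function(windows) {
  if (nrow(windows) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0)))
  windows <- windows[order(windows$chrom, windows$start), , drop = FALSE]
  out <- windows[1, c("chrom", "start", "end")]
  out$n_windows <- 1L
  for (i in seq_len(nrow(windows))[-1]) {
    k <- nrow(out)
    if (windows$chrom[i] == out$chrom[k] && windows$start[i] <= out$end[k]) {
      out$end[k] <- max(out$end[k], windows$end[i])
      out$n_windows[k] <- out$n_windows[k] + 1L
    } else out <- rbind(out, cbind(windows[i, c("chrom", "start", "end")],
                                   n_windows = 1L))
  }
  rownames(out) <- NULL
  out
}

#' Annotate CLDGR windows with overlapping genes
#'
#' Half-open interval intersection: a gene overlaps a window when the two
#' intervals share at least one bp (a gene abutting the window end exactly
#' does not overlap).
#'
#' @param cldgr a `cldgr_set` (or plain data.frame of windows).
#' @param genes data.frame of gene intervals with `chrom`, `start`, `end`
#'   (0-based half-open, as read by [read_bed()]) and `name`.
#' @return The `cldgr_set` with a `genes` column (comma-separated ids) on
#'   its `windows` table.
#' @export
annotate_genes <- function(cldgr, genes) {
  win <- if (inherits(cldgr, "cldgr_set")) cldgr$windows else cldgr
  if (!all(c("chrom", "start", "end", "name") %in% names(genes)))
    stop("malformed gene table: need chrom, start, end, name")
  if (any(genes$start >= genes$end)) stop("malformed gene interval")
  ann <- vapply(seq_len(nrow(win)), function(i) {
    hit <- genes$chrom == win$chrom[i] & genes$start < win$end[i] &
      win$start[i] < genes$end
    paste(genes$name[hit], collapse = ",")
  }, character(1))
  win$genes <- ann
  if (inherits(cldgr, "cldgr_set")) { cldgr$windows <- win; cldgr }
  else win
}
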