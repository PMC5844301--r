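# Plain-text readers/writers for the pipeline's interchange formats.
# Schemas are documented in docs/formats.md at the repository root.

#' Write genotype likelihoods in the text GL format
#'
#' A minimal Beagle-GL-like dialect: one row per site, columns `pos`
#' (0-based) then three log-likelihood columns (`<id>.ll0`, `.ll1`, `.ll2`)
#' per individual.
#'
#' @param gl a `gl_matrix`.
#' @param positions 0-based site coordinates.
#' @param ids individual ids.
#' @param path output file.
#' @export
write_gl <- function(gl, positions, ids, path) {
  n <- ncol(gl$ll0)
  stopifnot(length(ids) == n)
  out <- data.frame(pos = positions)
  for (i in seq_len(n)) {
    out[[paste0(ids[i], ".ll0")]] <- gl$ll0[, i]
    out[[paste0(ids[i], ".ll1")]] <- gl$ll1[, i]
    out[[paste0(ids[i], ".ll2")]] <- gl$ll2[, i]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read the text GL format written by [write_gl()]
#'
#' @param path input file.
#' @return list with `positions`, `ids` and a `gl_matrix`.
#' @export
read_gl <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  positions <- tab$pos
  cols <- setdiff(names(tab), "pos")
  ids <- unique(sub("\\.ll[012]$", "", cols))
  pick <- function(suffix)
    as.matrix(tab[, paste0(ids, suffix), drop = FALSE])
  ll0 <- pick(".ll0"); ll1 <- pick(".ll1"); ll2 <- pick(".ll2")
  covered <- !(ll0 == 0 & ll1 == 0 & ll2 == 0)
  list(positions = positions, ids = ids,
       gl = structure(list(ll0 = ll0, ll1 = ll1, ll2 = ll2,
                           covered = covered, e = NA_real_),
                      class = "gl_matrix"))
}

#' Read a BED file of gene (or region) intervals
#'
#' Standard BED: 0-based half-open, tab-separated `chrom start end [name]`.
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("malformed BED: fewer than 3 columns")
  names(tab)[1:3] <- c("chrom", "start", "end")
  tab$name <- if (ncol(tab) >= 4) as.character(tab[[4]])
  else sprintf("region_%d", seq_len(nrow(tab)))
  if (any(tab$start >= tab$end)) stop("malformed BED interval")
  tab[, c("chrom", "start", "end", "name")]
}

#' Write a BED-like table
#'
#' @param tab data.frame whose first three columns are `chrom`, `start`,
#'   `end`.
#' @param path output file.
#' @param header write a commented header line (default FALSE, plain BED).
#' @export
write_bed <- function(tab, path, header = FALSE) {
  if (header)
    cat("#", paste(names(tab), collapse = "\t"), "\n", sep = "",
        file = path)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, append = header)
}

#' Write a window (or ratio) table as TSV
#'
#' @param tab data.frame (e.g. from [window_scan()] or [pi_ratio()]).
#' @param path output file.
#' @export
write_window_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a demography configuration from YAML
#'
#' The YAML fields mirror the arguments of [demography_config()];
#' `split_dom` is a mapping with keys `aus`, `indica`, `japonica`.
#'
#' @param path YAML file.
#' @return A `demography_config`.
#' @export
read_demography_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$split_dom)) y$split_dom <- unlist(y$split_dom)
  if (!is.null(y$sweep_interval)) y$sweep_interval <- unlist(y$sweep_interval)
  do.call(demography_config, y)
}
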