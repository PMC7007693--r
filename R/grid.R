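#' Genome-wide 1-kb window grid
#'
#' A `genome_grid` indexes the genome as a sequence of fixed-width windows
#' (1 kb by default), shared by binned signal tracks, cistrome occupancy
#' vectors and motif hits. Coordinates are 0-based, half-open (BED
#' convention); window indices are global and 0-based, with chromosomes laid
#' out in the order given. The last window of each chromosome may be shorter
#' than `window_size` and is kept with its actual span.
#'
#' @param chrom_names character vector of chromosome identifiers.
#' @param chrom_lengths integer vector of chromosome lengths in bp.
#' @param window_size window width in bp (default 1000).
#' @return An object of class `genome_grid` with fields `chrom_names`,
#'   `chrom_lengths`, `window_size`, `windows_per_chrom`, `window_count`
#'   and `offset_index` (global index of each chromosome's first window).
#' @examples
#' g <- genome_grid(c("chr1", "chr2"), c(5000, 2500), window_size = 1000)
#' g$window_count  # 5 + 3
#' @export
genome_grid <- function(chrom_names, chrom_lengths, window_size = 1000L) {
  stopifnot(length(chrom_names) == length(chrom_lengths),
            length(chrom_names) >= 1L,
            !anyDuplicated(chrom_names),
            all(chrom_lengths > 0), window_size >= 1)
  chrom_lengths <- as.numeric(chrom_lengths)
  wpc <- as.integer(ceiling(chrom_lengths / window_size))
  offs <- c(0L, cumsum(wpc))
  structure(list(
    chrom_names   = as.character(chrom_names),
    chrom_lengths = chrom_lengths,
    window_size   = as.integer(window_size),
    windows_per_chrom = wpc,
    window_count  = sum(wpc),
    offset_index  = stats::setNames(offs[-length(offs)], chrom_names)
  ), class = "genome_grid")
}

#' @export
print.genome_grid <- function(x, ...) {
  cat(sprintf("genome_grid: %d chromosomes, %d windows of %d bp\n",
              length(x$chrom_names), x$window_count, x$window_size))
  invisible(x)
}

chrom_index <- function(grid, chrom) {
  i <- match(chrom, grid$chrom_names)
  if (anyNA(i)) {
    stop("unknown chromosome(s): ",
         paste(unique(chrom[is.na(i)]), collapse = ", "))
  }
  i
}

#' Map genomic positions to global window indices
#'
#' @param grid a [genome_grid()].
#' @param chrom chromosome name(s), recycled against `pos`.
#' @param pos 0-based base-pair position(s).
#' @return 0-based global window indices.
#' @export
window_of <- function(grid, chrom, pos) {
  ci <- chrom_index(grid, chrom)
  if (any(pos < 0) || any(pos >= grid$chrom_lengths[ci]))
    stop("position outside chromosome bounds")
  as.integer(grid$offset_index[ci] + pos %/% grid$window_size)
}

# Start (bp, 0-based) and actual span of each global window on one chromosome.
window_coords <- function(grid, ci) {
  n  <- grid$windows_per_chrom[ci]
  st <- (seq_len(n) - 1) * as.numeric(grid$window_size)
  en <- pmin(st + grid$window_size, grid$chrom_lengths[ci])
  list(start = st, end = en, mid = (st + en) / 2,
       global = grid$offset_index[ci] + seq_len(n) - 1L)
}

#' Decompose global window indices into (chromosome, local window)
#'
#' Inverse of the global layout: every index in `[0, window_count)` maps to
#' exactly one (chromosome, local index) pair.
#'
#' @param grid a [genome_grid()].
#' @param index 0-based global window indices.
#' @return data.frame with columns `chrom`, `local` (0-based), `start`, `end`.
#' @export
window_location <- function(grid, index) {
  index <- as.integer(index)
  if (any(index < 0 | index >= grid$window_count))
    stop("window index out of range")
  bounds <- c(grid$offset_index, grid$window_count)
  ci <- findInterval(index, bounds, left.open = FALSE)
  local <- index - grid$offset_index[ci]
  st <- local * as.numeric(grid$window_size)
  data.frame(chrom = grid$chrom_names[ci], local = local,
             start = st,
             end = pmin(st + grid$window_size, grid$chrom_lengths[ci]),
             stringsAsFactors = FALSE)
}
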