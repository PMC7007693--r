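#' Construct a cistrome from occupied windows
#'
#' A cistrome is the genome-wide binding-site set of one transcriptional
#' regulator, represented as the set of 1-kb windows containing at least one
#' peak summit (or motif hit). Occupancy is binary: summit multiplicity
#' within a window is not retained. Summit base-pair positions, when known,
#' are kept alongside for promoter-count baselines.
#'
#' @param cistrome_id unique identifier for this peak set.
#' @param tr_name the regulator the peaks belong to.
#' @param windows 0-based global window indices (deduplicated, sorted).
#' @param grid a [genome_grid()].
#' @param source `"chipseq_peaks"` or `"motif_hits"`.
#' @param summits optional data.frame (`chrom`, `pos`) of summit positions.
#' @return list of class `cistrome`.
#' @export
cistrome <- function(cistrome_id, tr_name, windows, grid,
                     source = c("chipseq_peaks", "motif_hits"),
                     summits = NULL) {
  source <- match.arg(source)
  windows <- sort(unique(as.integer(windows)))
  if (length(windows) && (windows[1] < 0 ||
                          windows[length(windows)] >= grid$window_count))
    stop("occupied window index outside the grid")
  structure(list(cistrome_id = as.character(cistrome_id),
                 tr_name = as.character(tr_name),
                 source = source, windows = windows, summits = summits),
            class = "cistrome")
}

#' Build a cistrome from peak records
#'
#' Each peak contributes its summit: `start + summit_offset` when a summit
#' offset is given, else the interval midpoint `floor((start + end) / 2)`.
#' The occupied windows are the 1-kb windows containing a summit — a peak
#' spanning a window boundary occupies only the summit's window.
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open) and optionally `summit_offset` (offset from `start`,
#'   `NA` for midpoint).
#' @param grid a [genome_grid()].
#' @inheritParams cistrome
#' @return a [cistrome()].
#' @export
load_peaks <- function(peaks, grid, cistrome_id = "peaks",
                       tr_name = cistrome_id,
                       source = c("chipseq_peaks", "motif_hits")) {
  source <- match.arg(source)
  if (nrow(peaks) == 0)
    return(cistrome(cistrome_id, tr_name, integer(), grid, source,
                    summits = data.frame(chrom = character(),
                                         pos = numeric())))
  chrom <- as.character(peaks$chrom)
  start <- as.numeric(peaks$start)
  end   <- as.numeric(peaks$end)
  off   <- if ("summit_offset" %in% names(peaks))
    as.numeric(peaks$summit_offset) else rep(NA_real_, nrow(peaks))
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 |
                 start >= end)
  if (length(bad))
    stop(sprintf("malformed peak record at line %d: %s:%s-%s", bad[1],
                 chrom[bad[1]], start[bad[1]], end[bad[1]]))
  bad <- which(!is.na(off) & (off < 0 | off >= end - start))
  if (length(bad))
    stop(sprintf("summit offset out of peak bounds at line %d", bad[1]))
  summit <- ifelse(is.na(off), (start + end) %/% 2, start + off)
  ci <- match(chrom, grid$chrom_names)
  if (anyNA(ci)) {
    bad <- which(is.na(ci))[1]
    stop(sprintf("peak record %d on unknown chromosome '%s'", bad, chrom[bad]))
  }
  bad <- which(summit >= grid$chrom_lengths[ci])
  if (length(bad))
    stop(sprintf("peak record %d extends beyond chromosome end", bad[1]))
  cistrome(cistrome_id, tr_name,
           window_of(grid, chrom, summit), grid, source,
           summits = data.frame(chrom = chrom, pos = summit,
                                stringsAsFactors = FALSE))
}

#' Read peaks from a BED-like file
#'
#' Columns: `chrom`, `start`, `end`, then optionally `name` and
#' `summit_offset` (offset of the summit from `start`, as in narrowPeak's
#' point-source column). Three-column files use interval midpoints.
#'
#' @param path file path.
#' @inheritParams load_peaks
#' @return a [cistrome()].
#' @export
read_bed_peaks <- function(path, grid, cistrome_id = NULL,
                           tr_name = NULL,
                           source = c("chipseq_peaks", "motif_hits")) {
  source <- match.arg(source)
  if (is.null(cistrome_id))
    cistrome_id <- sub("\\.bed$", "", basename(path), ignore.case = TRUE)
  x <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse BED file ", path, ": ",
                             conditionMessage(e)))
  peaks <- data.frame(chrom = x[[1]], start = x[[2]], end = x[[3]],
                      stringsAsFactors = FALSE)
  if (ncol(x) >= 5 && is.numeric(x[[5]])) peaks$summit_offset <- x[[5]]
  if (is.null(tr_name))
    tr_name <- if (ncol(x) >= 4 && is.character(x[[4]]) &&
                   length(unique(x[[4]])) == 1L) x[1, 4] else cistrome_id
  load_peaks(peaks, grid, cistrome_id = cistrome_id, tr_name = tr_name,
             source = source)
}

#' Write a cistrome as BED
#'
#' Summit positions are written as 1-bp intervals when available, otherwise
#' each occupied window's full span is written.
#'
#' @param cis a [cistrome()].
#' @param grid the matching [genome_grid()].
#' @param path output path.
#' @export
write_cistrome_bed <- function(cis, grid, path) {
  if (!is.null(cis$summits) && nrow(cis$summits)) {
    df <- data.frame(cis$summits$chrom,
                     format(cis$summits$pos, scientific = FALSE, trim = TRUE),
                     format(cis$summits$pos + 1, scientific = FALSE,
                            trim = TRUE),
                     cis$tr_name)
  } else if (length(cis$windows)) {
    loc <- window_location(grid, cis$windows)
    df <- data.frame(loc$chrom,
                     format(loc$start, scientific = FALSE, trim = TRUE),
                     format(loc$end, scientific = FALSE, trim = TRUE),
                     cis$tr_name)
  } else df <- data.frame(character(), character(), character(), character())
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
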