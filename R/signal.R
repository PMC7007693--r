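#' Bin interval signal into the genome grid
#'
#' Summarizes a coverage-style track (bedGraph intervals or any set of
#' scored intervals) into per-window values. Each window's value is the
#' length-weighted mean of the overlapping interval values over the window's
#' actual span, with uncovered bases contributing 0 — so signal mass
#' (value times covered length) is conserved.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (0-based, half-open) and `value` (finite, non-negative).
#' @param grid a [genome_grid()].
#' @param profile_id identifier for the resulting track.
#' @param assay_kind `"dnase"` or `"h3k27ac"`.
#' @return A `binned_track`: list with `profile_id`, `assay_kind` and
#'   `values`, a numeric vector of length `grid$window_count`.
#' @export
bin_signal <- function(intervals, grid, profile_id = "track",
                       assay_kind = c("dnase", "h3k27ac")) {
  assay_kind <- match.arg(assay_kind)
  vals <- numeric(grid$window_count)
  if (nrow(intervals) > 0) {
    chrom <- as.character(intervals$chrom)
    start <- as.numeric(intervals$start)
    end   <- as.numeric(intervals$end)
    value <- as.numeric(intervals$value)
    ci <- match(chrom, grid$chrom_names)
    if (anyNA(ci)) {
      bad <- which(is.na(ci))[1]
      stop(sprintf("interval %d on unknown chromosome '%s'", bad, chrom[bad]))
    }
    bad <- which(!is.finite(start) | !is.finite(end) | start < 0 |
                   end > grid$chrom_lengths[ci] | start >= end)
    if (length(bad))
      stop(sprintf("interval %d (%s:%g-%g) outside chromosome bounds or empty",
                   bad[1], chrom[bad[1]], start[bad[1]], end[bad[1]]))
    bad <- which(!is.finite(value) | value < 0)
    if (length(bad))
      stop(sprintf("interval %d has negative or non-finite value %g",
                   bad[1], value[bad[1]]))
    ws <- as.numeric(grid$window_size)
    w0 <- start %/% ws
    w1 <- (end - 1) %/% ws
    reps <- as.integer(w1 - w0 + 1)
    i <- rep.int(seq_along(start), reps)
    piece_win <- w0[i] + sequence(reps) - 1
    ps <- pmax(start[i], piece_win * ws)
    pe <- pmin(end[i], (piece_win + 1) * ws)
    gidx <- as.integer(grid$offset_index[ci[i]] + piece_win + 1)  # 1-based into vals
    mass <- rowsum((pe - ps) * value[i], gidx)
    at <- as.integer(rownames(mass))
    span <- window_location(grid, at - 1L)
    vals[at] <- mass[, 1] / (span$end - span$start)
  }
  structure(list(profile_id = as.character(profile_id),
                 assay_kind = assay_kind, values = vals),
            class = "binned_track")
}

#' Read a signal track file and bin it
#'
#' bedGraph and bigWig go through `rtracklayer::import()`; the resulting
#' ranges are converted back to the grid's 0-based, half-open convention
#' before binning.
#'
#' @param path path to a bedGraph (`.bedgraph`/`.bg`) or bigWig
#'   (`.bw`/`.bigwig`) file.
#' @param grid a [genome_grid()].
#' @inheritParams bin_signal
#' @return a `binned_track` (see [bin_signal()]).
#' @export
read_signal_track <- function(path, grid, profile_id = NULL,
                              assay_kind = c("dnase", "h3k27ac")) {
  assay_kind <- match.arg(assay_kind)
  if (is.null(profile_id))
    profile_id <- sub("\\.(bedgraph|bg|bw|bigwig)$", "", basename(path),
                      ignore.case = TRUE)
  ext <- tolower(tools::file_ext(path))
  fmt <- switch(ext, bedgraph = "bedGraph", bg = "bedGraph",
                bw = "BigWig", bigwig = "BigWig",
                stop("unrecognized signal format: ", path))
  gr <- rtracklayer::import(path, format = fmt)
  intervals <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end   = GenomicRanges::end(gr),
    value = S4Vectors::mcols(gr)$score,
    stringsAsFactors = FALSE)
  intervals <- intervals[intervals$value != 0, , drop = FALSE]
  bin_signal(intervals, grid, profile_id = profile_id,
             assay_kind = assay_kind)
}

#' Write a binned track as bedGraph
#'
#' Emits one record per non-zero window (0-based, half-open coordinates).
#'
#' @param track a `binned_track`.
#' @param grid the [genome_grid()] the track was binned on.
#' @param path output file path.
#' @export
write_bedgraph <- function(track, grid, path) {
  nz <- which(track$values != 0)
  if (length(nz)) {
    loc <- window_location(grid, nz - 1L)
    df <- data.frame(loc$chrom, format(loc$start, scientific = FALSE,
                                       trim = TRUE),
                     format(loc$end, scientific = FALSE, trim = TRUE),
                     track$values[nz])
  } else df <- data.frame(character(), character(), character(), numeric())
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
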