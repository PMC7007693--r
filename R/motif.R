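#' Position weight matrices and genome scanning
#'
#' PWMs are scored as log-odds against a background base composition, with
#' a small pseudocount mixed in before the log so zero-probability entries
#' stay finite. The genome is tiled into non-overlapping 100-bp windows;
#' each window's score is the best placement (both strands, every offset
#' that fits entirely inside the window). Hits are windows whose score
#' strictly exceeds the per-motif genome-wide percentile threshold (99th by
#' default), then mapped to the 1-kb windows containing their midpoints.
#'
#' @name motif_scan
NULL

DNA_CODE <- {
  z <- rep(5L, 256)
  z[utf8ToInt("A")] <- 1L; z[utf8ToInt("a")] <- 1L
  z[utf8ToInt("C")] <- 2L; z[utf8ToInt("c")] <- 2L
  z[utf8ToInt("G")] <- 3L; z[utf8ToInt("g")] <- 3L
  z[utf8ToInt("T")] <- 4L; z[utf8ToInt("t")] <- 4L
  z
}

#' Construct a PWM
#'
#' @param motif_id motif identifier.
#' @param tr_name name of the factor the motif belongs to.
#' @param matrix positions-by-4 matrix of base probabilities (columns
#'   A, C, G, T), each row summing to 1.
#' @param background base frequencies (strictly positive, summing to 1).
#' @param pseudocount fraction of background mixed into each position
#'   before the log-odds (default 0.001).
#' @return list of class `pwm`.
#' @export
pwm <- function(motif_id, tr_name, matrix,
                background = rep(0.25, 4), pseudocount = 0.001) {
  matrix <- as.matrix(matrix)
  stopifnot(ncol(matrix) == 4, nrow(matrix) >= 1,
            all(matrix >= 0), all(background > 0),
            abs(sum(background) - 1) < 1e-6, pseudocount > 0)
  if (any(abs(rowSums(matrix) - 1) > 1e-6))
    stop("PWM rows must sum to 1")
  colnames(matrix) <- c("A", "C", "G", "T")
  structure(list(motif_id = as.character(motif_id),
                 tr_name = as.character(tr_name),
                 matrix = matrix, background = background,
                 pseudocount = pseudocount),
            class = "pwm")
}

# Log-odds lookup, rows A,C,G,T plus an N row of -Inf: any placement
# covering an N scores -Inf so only N-free placements count.
pwm_logodds <- function(p) {
  m <- p$matrix
  padded <- sweep(m, 2, p$pseudocount * p$background, `+`)
  padded <- padded / rowSums(padded)
  lo <- log(sweep(padded, 2, p$background, `/`))
  rbind(t(lo), N = rep(-Inf, nrow(m)))
}

reverse_complement_pwm <- function(p) {
  m <- p$matrix[rev(seq_len(nrow(p$matrix))), c("T", "G", "C", "A"),
                drop = FALSE]
  colnames(m) <- c("A", "C", "G", "T")
  p$matrix <- m
  p
}

#' Read PWMs from JASPAR-format text
#'
#' Accepts the standard four-line count blocks, either bracketed
#' (`A [ 1 2 3 ]`) or bare rows, headed by `>motif_id name`. Counts are
#' converted to per-position probabilities.
#'
#' @param path file path.
#' @param background,pseudocount passed to [pwm()].
#' @return named list of [pwm()] objects (possibly empty).
#' @export
read_jaspar <- function(path, background = rep(0.25, 4),
                        pseudocount = 0.001) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  out <- list()
  for (h in seq_along(heads)) {
    hdr <- strsplit(sub("^>\\s*", "", lines[heads[h]]), "\\s+")[[1]]
    motif_id <- hdr[1]
    tr_name <- if (length(hdr) >= 2) hdr[2] else hdr[1]
    to <- if (h < length(heads)) heads[h + 1] - 1 else length(lines)
    block <- lines[(heads[h] + 1):to]
    if (length(block) < 4)
      stop("motif '", motif_id, "': expected 4 base rows, got ",
           length(block))
    rows <- lapply(block[1:4], function(ln) {
      ln <- gsub("^[ACGTacgt]\\s*|\\[|\\]", " ", ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1)
      stop("motif '", motif_id, "': ragged count rows")
    counts <- do.call(cbind, rows)  # positions x 4 (A,C,G,T)
    tot <- rowSums(counts)
    if (any(tot <= 0)) stop("motif '", motif_id, "': empty count column")
    out[[motif_id]] <- pwm(motif_id, tr_name, counts / tot,
                           background = background,
                           pseudocount = pseudocount)
  }
  out
}

# Best-placement score per scan-window tile for one chromosome sequence.
# Placements must sit entirely inside their tile; tiles are non-overlapping.
score_one_strand <- function(code, lut, m, scan_window) {
  len <- length(code)
  ntile <- as.integer(ceiling(len / scan_window))
  npos <- len - m + 1L
  if (npos < 1L) return(rep(-Inf, ntile))
  sc <- numeric(npos)
  for (k in seq_len(m)) sc <- sc + lut[code[k:(k + npos - 1L)], k]
  # pad to the tile lattice, then max over the in-tile start offsets
  padded <- rep(-Inf, ntile * scan_window)
  padded[seq_len(npos)] <- sc
  tilemat <- matrix(padded, nrow = scan_window)
  best <- tilemat[1L, ]
  for (r in seq_len(scan_window - m + 1L)[-1L])
    best <- pmax(best, tilemat[r, ])
  best
}

#' Score genome tiles against a PWM
#'
#' @param sequences a named `Biostrings::DNAStringSet` (or named character
#'   vector) covering the grid's chromosomes.
#' @param p a [pwm()].
#' @param grid a [genome_grid()].
#' @param scan_window tile width in bp (default 100, non-overlapping).
#' @return list of class `motif_scores`: per-tile max log-odds `scores`,
#'   tile `chrom` and `mid` (midpoint, bp), plus the scan geometry.
#' @export
score_windows <- function(sequences, p, grid, scan_window = 100L) {
  m <- nrow(p$matrix)
  if (m > scan_window)
    stop("PWM longer than the scan window (", m, " > ", scan_window, ")")
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (!all(grid$chrom_names %in% names(sequences)))
    stop("sequences do not cover the grid's chromosomes")
  lut_f <- pwm_logodds(p)
  lut_r <- pwm_logodds(reverse_complement_pwm(p))
  res_sc <- list(); res_ch <- list(); res_mid <- list()
  for (ch in grid$chrom_names) {
    s <- as.character(sequences[[ch]])
    clen <- grid$chrom_lengths[chrom_index(grid, ch)]
    if (nchar(s) < clen)
      stop("sequence for ", ch, " shorter than the grid chromosome")
    code <- DNA_CODE[utf8ToInt(substr(s, 1L, clen))]
    fw <- score_one_strand(code, lut_f, m, scan_window)
    rv <- score_one_strand(code, lut_r, m, scan_window)
    sc <- pmax(fw, rv)
    ntile <- length(sc)
    st <- (seq_len(ntile) - 1) * as.numeric(scan_window)
    res_sc[[ch]] <- sc
    res_ch[[ch]] <- rep(ch, ntile)
    res_mid[[ch]] <- (st + pmin(st + scan_window, clen)) / 2
  }
  structure(list(motif_id = p$motif_id, tr_name = p$tr_name,
                 scan_window = as.integer(scan_window),
                 scores = unlist(res_sc, use.names = FALSE),
                 chrom = unlist(res_ch, use.names = FALSE),
                 mid = unlist(res_mid, use.names = FALSE)),
            class = "motif_scores")
}

#' Call motif hits by percentile thresholding
#'
#' The threshold is the given percentile (linear interpolation) of the
#' finite tile scores; a tile is a hit iff its score is strictly greater,
#' which keeps the hit fraction at or below `1 - percentile/100` under
#' ties. Hits are mapped to the 1-kb window containing the tile midpoint.
#'
#' @param scores a `motif_scores` object from [score_windows()].
#' @param grid a [genome_grid()].
#' @param threshold_percentile percentile in (0, 100) (default 99).
#' @return list of class `motif_hits`: `motif_id`, `tr_name`,
#'   `scan_window`, `threshold_percentile`, `threshold`, `hits` (0-based
#'   1-kb window indices) and `hit_pos` (`chrom`, `pos` tile midpoints).
#' @export
call_hits <- function(scores, grid, threshold_percentile = 99) {
  stopifnot(threshold_percentile > 0, threshold_percentile < 100)
  fin <- is.finite(scores$scores)
  if (!any(fin)) {
    warning("all tile scores are -Inf; empty hit set for ",
            scores$motif_id)
    return(structure(list(motif_id = scores$motif_id,
                          tr_name = scores$tr_name,
                          scan_window = scores$scan_window,
                          threshold_percentile = threshold_percentile,
                          threshold = Inf, hits = integer(),
                          hit_pos = data.frame(chrom = character(),
                                               pos = numeric())),
                     class = "motif_hits"))
  }
  if (sum(fin) < 100)
    stop("need at least 100 finite tile scores to set a percentile ",
         "threshold (got ", sum(fin), ")")
  thr <- unname(stats::quantile(scores$scores[fin],
                                threshold_percentile / 100, type = 7))
  sel <- which(fin & scores$scores > thr)
  hits <- if (length(sel))
    sort(unique(window_of(grid, scores$chrom[sel],
                          pmin(scores$mid[sel],
                               grid$chrom_lengths[chrom_index(
                                 grid, scores$chrom[sel])] - 1))))
  else integer()
  structure(list(motif_id = scores$motif_id, tr_name = scores$tr_name,
                 scan_window = scores$scan_window,
                 threshold_percentile = threshold_percentile,
                 threshold = thr, hits = hits,
                 hit_pos = data.frame(chrom = scores$chrom[sel],
                                      pos = scores$mid[sel],
                                      stringsAsFactors = FALSE)),
            class = "motif_hits")
}

#' Convert motif hits to a cistrome
#'
#' @param hits a `motif_hits` object.
#' @param grid the matching [genome_grid()].
#' @param cistrome_id identifier (default the motif id).
#' @return a [cistrome()] with `source = "motif_hits"`.
#' @export
hits_as_cistrome <- function(hits, grid, cistrome_id = hits$motif_id) {
  cistrome(cistrome_id, hits$tr_name, hits$hits, grid,
           source = "motif_hits",
           summits = data.frame(chrom = hits$hit_pos$chrom,
                                pos = floor(hits$hit_pos$pos),
                                stringsAsFactors = FALSE))
}

#' Build a sharply peaked PWM from a consensus sequence
#'
#' @param consensus DNA string over ACGT.
#' @param motif_id,tr_name identifiers.
#' @param p probability of the consensus base at each position
#'   (default 0.97; the rest is split over the other bases).
#' @return a [pwm()].
#' @export
consensus_pwm <- function(consensus, motif_id = "consensus",
                          tr_name = motif_id, p = 0.97) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(bases %in% c("A", "C", "G", "T")), p > 0.25, p < 1)
  m <- matrix((1 - p) / 3, length(bases), 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(bases), match(bases, colnames(m)))] <- p
  pwm(motif_id, tr_name, m)
}
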