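#' Regulatory-potential parameters
#'
#' The decay weight at genomic distance `d` from the TSS is
#' `w(d) = 2 exp(-mu d/L) / (1 + exp(-mu d/L))`, a logistic-tailed kernel
#' equal to 1 at the TSS. `mu = ln(3) * L / delta` so that the weight falls
#' to exactly 1/2 at the decay distance `delta` (`exp(-mu*delta/L) = 1/3`).
#' Signal is integrated over the `[tss - L, tss + L]` interval.
#'
#' @param L half-interval around the TSS in bp (default 100 kb).
#' @param delta half-weight decay distance in bp (default 10 kb).
#' @param window_size signal window width in bp (default 1 kb).
#' @return list of class `rp_params` with fields `L`, `delta`, `mu`,
#'   `window_size`.
#' @examples
#' p <- rp_params()
#' decay_weight(0, p)        # 1
#' decay_weight(p$delta, p)  # 0.5
#' @export
rp_params <- function(L = 1e5, delta = 1e4, window_size = 1000L) {
  stopifnot(L > 0, delta > 0, delta < L, window_size >= 1)
  structure(list(L = as.numeric(L), delta = as.numeric(delta),
                 mu = log(3) * L / delta,
                 window_size = as.integer(window_size)),
            class = "rp_params")
}

#' Distance-decay weight of regulatory influence
#'
#' @param distance_bp non-negative genomic distance(s) from the TSS in bp.
#' @param params an [rp_params()].
#' @return weight(s) in (0, 1]; strictly decreasing in distance.
#' @export
decay_weight <- function(distance_bp, params = rp_params()) {
  stopifnot(all(distance_bp >= 0))
  x <- exp(-params$mu * distance_bp / params$L)
  2 * x / (1 + x)
}

# Per-gene window context: global window indices (0-based) whose midpoints
# fall within [tss - L, tss + L], plus their decay weights. Shared by the
# chrom-RP, peak-RP and in-silico-deletion computations.
gene_window_context <- function(grid, genes, params = rp_params()) {
  ci <- chrom_index(grid, genes$chrom)
  wc_cache <- lapply(unique(ci), function(cc) window_coords(grid, cc))
  names(wc_cache) <- as.character(unique(ci))
  lapply(seq_len(nrow(genes)), function(k) {
    wc <- wc_cache[[as.character(ci[k])]]
    keep <- which(wc$mid >= genes$tss[k] - params$L &
                    wc$mid <= genes$tss[k] + params$L)
    list(windows = wc$global[keep],
         weights = decay_weight(abs(wc$mid[keep] - genes$tss[k]), params))
  })
}

#' Chromatin regulatory potential of one gene
#'
#' `R = sum_m w(|mid_m - tss|) * s_m` over the 1-kb windows `m` whose
#' midpoints fall within `[tss - L, tss + L]` (truncated at chromosome
#' ends), where `s_m` is the window-mean signal.
#'
#' @param track a `binned_track`.
#' @param gene one row of a [gene_annotation()] table.
#' @param grid a [genome_grid()].
#' @param params an [rp_params()].
#' @return raw (unnormalized) chrom-RP, a non-negative scalar.
#' @export
chrom_rp <- function(track, gene, grid, params = rp_params()) {
  ctx <- gene_window_context(grid, gene, params)[[1]]
  sum(ctx$weights * track$values[ctx$windows + 1L])
}

#' Peak regulatory potential of one gene
#'
#' Same weighted sum as [chrom_rp()] with binary occupancy in place of
#' signal: each occupied window within `[tss - L, tss + L]` contributes its
#' decay weight.
#'
#' @param cis a [cistrome()].
#' @inheritParams chrom_rp
#' @return raw peak-RP, a non-negative dimensionless scalar.
#' @export
peak_rp <- function(cis, gene, grid, params = rp_params()) {
  ctx <- gene_window_context(grid, gene, params)[[1]]
  sum(ctx$weights[ctx$windows %in% cis$windows])
}

#' Raw chrom-RP matrix for all genes and tracks
#'
#' @param store a [compendium_store()], or a list of tracks plus explicit
#'   `genes`/`grid`.
#' @param params an [rp_params()].
#' @param normalize normalize per profile (see [normalize_rp()])?
#' @return an `rp_matrix` (see [normalize_rp()]); with `normalize = FALSE`,
#'   the raw genes-by-profiles matrix.
#' @export
compute_rp_matrix <- function(store, params = rp_params(), normalize = TRUE) {
  genes <- store$genes
  ctx <- gene_window_context(store$grid, genes, params)
  raw <- matrix(0, nrow(genes), length(store$tracks),
                dimnames = list(genes$gene_id,
                                unname(vapply(store$tracks, `[[`, "",
                                              "profile_id"))))
  for (j in seq_along(store$tracks)) {
    v <- store$tracks[[j]]$values
    raw[, j] <- vapply(ctx, function(cc)
      sum(cc$weights * v[cc$windows + 1L]), numeric(1))
  }
  if (normalize) normalize_rp(raw) else raw
}

#' Per-profile normalization of a raw RP matrix
#'
#' Within each profile, raw RPs are mapped to
#' `R' = log(R + 1) - c_j`, where the offset `c_j` is the mean of
#' `log(R + 1)` over all genes — so each profile's normalized column has
#' mean zero and profiles are comparable despite depth differences.
#' Natural log throughout.
#'
#' @param raw genes-by-profiles matrix of raw RPs (non-negative, finite),
#'   with dimnames.
#' @return list of class `rp_matrix`: `gene_ids`, `profile_ids`, `raw`,
#'   `norm_offset` (per-profile `c_j`), `normalized`.
#' @export
normalize_rp <- function(raw) {
  raw <- as.matrix(raw)
  if (nrow(raw) < 2) stop("need at least 2 genes to normalize")
  if (any(!is.finite(raw)) || any(raw < 0))
    stop("raw RPs must be finite and non-negative")
  lg <- log1p(raw)
  offs <- colMeans(lg)
  structure(list(gene_ids = rownames(raw), profile_ids = colnames(raw),
                 raw = raw, norm_offset = offs,
                 normalized = sweep(lg, 2, offs)),
            class = "rp_matrix")
}

#' Peak-RP vectors for a set of cistromes
#'
#' @param store a [compendium_store()].
#' @param cistromes list of [cistrome()]s (default: the store's).
#' @param params an [rp_params()].
#' @return genes-by-cistromes matrix of raw peak-RPs.
#' @export
compute_peak_rp <- function(store, cistromes = store$cistromes,
                            params = rp_params()) {
  ctx <- gene_window_context(store$grid, store$genes, params)
  out <- matrix(0, nrow(store$genes), length(cistromes),
                dimnames = list(store$genes$gene_id,
                                unname(vapply(cistromes, `[[`, "",
                                              "cistrome_id"))))
  for (j in seq_along(cistromes)) {
    win <- cistromes[[j]]$windows
    out[, j] <- vapply(ctx, function(cc)
      sum(cc$weights[cc$windows %in% win]), numeric(1))
  }
  out
}

#' Average-rank percentile transform
#'
#' Maps values to `rank / n` with ties sharing their mean rank, so the
#' largest value maps to 1 and percentiles are comparable across cistromes
#' of very different peak counts.
#'
#' @param values numeric vector (length >= 1).
#' @return percentiles in (0, 1].
#' @export
rp_percentile <- function(values) {
  stopifnot(length(values) >= 1)
  rank(values, ties.method = "average") / length(values)
}
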