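#' One-sided Wilcoxon rank-sum test
#'
#' Tests whether the query values are stochastically greater than the
#' background values. Uses the exact rank-sum distribution when the smaller
#' sample has at most 8 observations and there are no ties, otherwise the
#' normal approximation with tie and continuity corrections.
#'
#' @param query_values,background_values numeric vectors (non-empty).
#' @return one-sided p-value in (0, 1].
#' @export
wilcoxon_one_sided <- function(query_values, background_values) {
  stopifnot(length(query_values) > 0, length(background_values) > 0)
  ties <- anyDuplicated(c(query_values, background_values)) > 0
  exact <- !ties && min(length(query_values),
                        length(background_values)) <= 8
  suppressWarnings(
    stats::wilcox.test(query_values, background_values,
                       alternative = "greater", exact = exact,
                       correct = TRUE)$p.value)
}

#' Cauchy combination of p-values
#'
#' `t = sum_i w_i tan((0.5 - p_i) pi)` and `p = 1/2 - arctan(t)/pi`.
#' Robust to dependence among the component tests; the identity
#' `combine(p, ..., p) = p` holds for equal weights. Components are clamped
#' to `[1e-15, 1 - 1e-15]` before the tangent transform.
#'
#' @param p_values vector of p-values in (0, 1).
#' @param weights combination weights (default uniform `1/d`).
#' @return combined p-value in (0, 1).
#' @export
cauchy_combine <- function(p_values, weights = NULL) {
  d <- length(p_values)
  if (d == 0) stop("no p-values to combine")
  if (is.null(weights)) weights <- rep(1 / d, d)
  stopifnot(length(weights) == d, all(weights >= 0))
  p <- pmin(pmax(p_values, 1e-15), 1 - 1e-15)
  t_stat <- sum(weights * tan((0.5 - p) * pi))
  0.5 - atan(t_stat) / pi
}

#' Combine evidence channels into a ranked regulator table
#'
#' Each cistrome carries up to three one-sided p-values: the peak-RP
#' channel and the two in-silico-deletion channels (DNase and H3K27ac).
#' ChIP-seq-derived cistromes combine all three (`d = 3`); motif-imputed
#' cistromes combine only the two deletion channels (`d = 2`), ignoring a
#' peak-RP p-value even if present. Combination uses uniform Cauchy
#' weights; cistromes missing a required channel are skipped with a
#' warning. Ties on the combined p are broken by the smaller mean deletion
#' p, then lexicographically by cistrome id.
#'
#' @param channels data.frame with columns `cistrome_id`, `tr_name`,
#'   `p_peak_rp`, `p_isd_dnase`, `p_isd_h3k27ac` (NA where unavailable).
#' @param mode `"chipseq"` or `"motif"`.
#' @return data.frame of class `tr_rank_table`, sorted by rank, with
#'   columns `cistrome_id`, `tr_name`, the channel p-values, `t_cauchy`,
#'   `p_combined`, `rank`; per-TR best combined p in
#'   `attr(, "tr_summary")`.
#' @export
combine_channels <- function(channels, mode = c("chipseq", "motif")) {
  mode <- match.arg(mode)
  need <- if (mode == "chipseq")
    c("p_peak_rp", "p_isd_dnase", "p_isd_h3k27ac")
  else c("p_isd_dnase", "p_isd_h3k27ac")
  stopifnot(all(c("cistrome_id", "tr_name") %in% names(channels)))
  for (ch in setdiff(c("p_peak_rp", "p_isd_dnase", "p_isd_h3k27ac"),
                     names(channels)))
    channels[[ch]] <- NA_real_
  ok <- stats::complete.cases(channels[need])
  if (any(!ok))
    warning("skipping ", sum(!ok),
            " cistrome(s) with a missing evidence channel: ",
            paste(utils::head(channels$cistrome_id[!ok], 5),
                  collapse = ", "))
  x <- channels[ok, , drop = FALSE]
  if (nrow(x) == 0) stop("no cistrome has all required channels")
  comb <- t(vapply(seq_len(nrow(x)), function(i) {
    p <- pmin(pmax(as.numeric(x[i, need]), 1e-15), 1 - 1e-15)
    t_stat <- mean(tan((0.5 - p) * pi))
    c(t_stat, 0.5 - atan(t_stat) / pi)
  }, numeric(2)))
  x$t_cauchy <- comb[, 1]
  x$p_combined <- comb[, 2]
  isd_mean <- rowMeans(x[, c("p_isd_dnase", "p_isd_h3k27ac")])
  ord <- order(x$p_combined, isd_mean, x$cistrome_id)
  x <- x[ord, , drop = FALSE]
  x$rank <- seq_len(nrow(x))
  rownames(x) <- NULL
  tr_summary <- stats::aggregate(p_combined ~ tr_name, data = x, FUN = min)
  tr_summary <- tr_summary[order(tr_summary$p_combined), , drop = FALSE]
  rownames(tr_summary) <- NULL
  structure(x, tr_summary = tr_summary,
            class = c("tr_rank_table", "data.frame"))
}

#' Promoter-count baseline test
#'
#' The simple baseline: count peak summits (or motif hits) in the promoter
#' interval `[tss - half_width, tss + half_width]` (closed on both ends)
#' and compare query against background counts with the one-sided Wilcoxon
#' rank-sum test.
#'
#' @param cis a [cistrome()] with summit positions, or a `motif_hits`
#'   object.
#' @param genes a [gene_annotation()] table.
#' @param sets a `gene_set_pair`.
#' @param half_width promoter half-width in bp (default 5000).
#' @return list: `p` (one-sided p-value), `counts` (named per-gene summit
#'   counts over query and background genes).
#' @export
baseline_promoter_count <- function(cis, genes, sets, half_width = 5000) {
  pos <- if (inherits(cis, "motif_hits")) cis$hit_pos else cis$summits
  if (is.null(pos)) stop("cistrome carries no summit positions")
  ids <- c(sets$query, sets$background)
  gi <- match(ids, genes$gene_id)
  if (anyNA(gi)) stop("gene set contains ids absent from the annotation")
  counts <- vapply(gi, function(k) {
    sum(pos$chrom == genes$chrom[k] &
          pos$pos >= genes$tss[k] - half_width &
          pos$pos <= genes$tss[k] + half_width)
  }, numeric(1))
  names(counts) <- ids
  nq <- length(sets$query)
  list(p = wilcoxon_one_sided(counts[seq_len(nq)], counts[-seq_len(nq)]),
       counts = counts)
}

#' Partition a cistrome into direct and indirect binding sites
#'
#' Direct sites are the occupied windows that carry the regulator's own
#' motif (intersection with the motif-hit windows); indirect sites are the
#' rest. Summit positions are carried into the half whose window they fall
#' in. Peak-RPs of the two halves are typically percentile-normalized
#' ([rp_percentile()]) before rank testing, so halves of very different
#' sizes remain comparable.
#'
#' @param cis a [cistrome()].
#' @param hits a `motif_hits` object for the same regulator, on the same
#'   grid.
#' @param grid the shared [genome_grid()].
#' @return list with [cistrome()]s `direct` and `indirect` (ids suffixed
#'   `.direct` / `.indirect`).
#' @export
split_direct_indirect <- function(cis, hits, grid) {
  if (length(hits$hits) == 0)
    warning("empty motif hit set: all binding sites classed as indirect")
  direct_w <- intersect(cis$windows, hits$hits)
  indirect_w <- setdiff(cis$windows, hits$hits)
  split_summits <- function(target) {
    if (is.null(cis$summits) || nrow(cis$summits) == 0) return(NULL)
    w <- window_of(grid, cis$summits$chrom, cis$summits$pos)
    cis$summits[w %in% target, , drop = FALSE]
  }
  list(direct = cistrome(paste0(cis$cistrome_id, ".direct"), cis$tr_name,
                         direct_w, grid, cis$source,
                         summits = split_summits(direct_w)),
       indirect = cistrome(paste0(cis$cistrome_id, ".indirect"),
                           cis$tr_name, indirect_w, grid, cis$source,
                           summits = split_summits(indirect_w)))
}
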