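#' Regulatory potential after in silico deletion
#'
#' Deleting a cistrome zeroes the chromatin signal in every 1-kb window the
#' cistrome occupies. Because the chrom-RP is a weighted sum over windows,
#' the deleted RP is the original RP minus the deleted windows'
#' contributions: `Rtilde = R - sum_{m in M} w_m s_m` over the occupied
#' windows `m` within the gene's `[tss - L, tss + L]` interval. Clamped at
#' zero against rounding.
#'
#' @param track a `binned_track`.
#' @param cis a [cistrome()].
#' @param gene one row of a [gene_annotation()] table.
#' @param grid a [genome_grid()].
#' @param params an [rp_params()].
#' @return the post-deletion raw RP (non-negative scalar).
#' @export
deleted_rp <- function(track, cis, gene, grid, params = rp_params()) {
  r <- chrom_rp(track, gene, grid, params)
  ctx <- gene_window_context(grid, gene, params)[[1]]
  hit <- ctx$windows %in% cis$windows
  max(r - sum(ctx$weights[hit] * track$values[ctx$windows[hit] + 1L]), 0)
}

#' Renormalize deleted RPs with the original offsets
#'
#' Post-deletion RPs are put on the same normalized scale as the
#' pre-deletion matrix: `Rtilde' = log(Rtilde + 1) - c_j`, reusing the
#' profile's original offset `c_j` (the offset is never recomputed after a
#' deletion, so deletions are comparable across cistromes).
#'
#' @param r_tilde raw post-deletion RP value(s).
#' @param norm_offset the profile's original normalization offset `c_j`.
#' @return normalized post-deletion RP(s).
#' @export
renormalize_deleted <- function(r_tilde, norm_offset) {
  log1p(pmax(r_tilde, 0)) - norm_offset
}

#' Per-gene drop in model regulatory potential under cistrome deletion
#'
#' For each gene, `deltaRP = sum_j alpha_j (R'_jk - Rtilde'_jk)` over the
#' model's selected profiles, with the coefficients frozen (no refitting).
#' Only genes with at least one occupied window inside their `[tss-L,
#' tss+L]` interval are touched; all other genes get an exact zero, since
#' deleting an unrelated cistrome leaves their chromatin landscape
#' unchanged.
#'
#' @param model a `chrom_model` from [fit_final_model()].
#' @param store a [compendium_store()] holding the model's tracks.
#' @param cis a [cistrome()] present in (or compatible with) the store.
#' @param gene_ids genes to evaluate (typically query plus background).
#' @param rp an `rp_matrix` of the store's raw chrom-RPs (computed if
#'   missing from the store's cache).
#' @param params an [rp_params()].
#' @param ctx precomputed per-gene window context for `gene_ids` (internal
#'   reuse across cistromes; leave `NULL` to compute).
#' @return list of class `delta_rp_result`: `cistrome_id`, `assay_kind`,
#'   `delta_rp` (named per-gene vector), `deleted_window_count`.
#' @export
delta_rp <- function(model, store, cis, gene_ids,
                     rp = store$rp_cache, params = rp_params(),
                     ctx = NULL) {
  if (is.null(rp)) rp <- compute_rp_matrix(store, params)
  if (!all(model$selected_profiles %in% rp$profile_ids))
    stop("model profiles missing from the RP matrix")
  if (!all(gene_ids %in% rp$gene_ids))
    stop("unknown gene id(s) in delta_rp")
  genes <- store$genes[match(gene_ids, store$genes$gene_id), , drop = FALSE]
  if (is.null(ctx)) ctx <- gene_window_context(store$grid, genes, params)
  delta <- stats::setNames(numeric(length(gene_ids)), gene_ids)
  ndel <- 0L
  win <- cis$windows
  if (length(win)) {
    touched_windows <- integer()
    for (k in seq_along(ctx)) {
      hit <- which(ctx[[k]]$windows %in% win)
      if (!length(hit)) next
      touched_windows <- c(touched_windows, ctx[[k]]$windows[hit])
      w <- ctx[[k]]$weights[hit]
      vidx <- ctx[[k]]$windows[hit] + 1L
      d <- 0
      for (j in model$selected_profiles) {
        r <- rp$raw[gene_ids[k], j]
        rt <- max(r - sum(w * store$tracks[[j]]$values[vidx]), 0)
        d <- d + model$alpha[[j]] * (log1p(r) - log1p(rt))
      }
      delta[k] <- d
    }
    ndel <- length(unique(touched_windows))
  }
  structure(list(cistrome_id = cis$cistrome_id,
                 assay_kind = model$assay_kind,
                 delta_rp = delta, deleted_window_count = ndel),
            class = "delta_rp_result")
}
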