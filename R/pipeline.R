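#' Run configuration for the ranking pipeline
#'
#' @param background_size background gene-set size (default 3000).
#' @param bins covariate strata for background sampling (default 10).
#' @param max_profiles cap on selected profiles per assay (default 10).
#' @param mode which cistrome families to rank: `"chipseq"`, `"motif"` or
#'   `"both"`.
#' @param seed integer seed for the (only) stochastic step, background
#'   sampling.
#' @param params an [rp_params()].
#' @param verbose log progress to stderr?
#' @return list of class `run_config`.
#' @export
run_config <- function(background_size = 3000L, bins = 10L,
                       max_profiles = 10L,
                       mode = c("both", "chipseq", "motif"),
                       seed = 0L, params = rp_params(), verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(background_size >= 1, bins >= 1, max_profiles >= 1)
  structure(list(background_size = as.integer(background_size),
                 bins = as.integer(bins),
                 max_profiles = as.integer(max_profiles),
                 mode = mode, seed = as.integer(seed), params = params,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

log_msg <- function(config, fmt, ...) {
  msg <- sprintf(fmt, ...)
  if (isTRUE(config$verbose)) message(msg)
  msg
}

#' Resolve query gene identifiers against the store
#'
#' Exact matches first, then a case-insensitive fallback; unmatched
#' identifiers are reported back for the sidecar file.
#'
#' @param ids character vector of query identifiers.
#' @param genes a [gene_annotation()] table.
#' @return list: `matched` (store gene ids), `n_fallback`
#'   (case-insensitive matches), `unmatched` (input ids with no match).
#' @export
resolve_gene_ids <- function(ids, genes) {
  ids <- unique(trimws(ids))
  ids <- ids[nzchar(ids)]
  exact <- ids %in% genes$gene_id
  rest <- ids[!exact]
  fb <- match(tolower(rest), tolower(genes$gene_id))
  list(matched = unique(c(ids[exact], genes$gene_id[fb[!is.na(fb)]])),
       n_fallback = sum(!is.na(fb)),
       unmatched = rest[is.na(fb)])
}

#' Build a compendium store from standard-format inputs
#'
#' Reads the chromosome sizes, gene annotation, covariates, signal tracks
#' and peak files; bins every track on the 1-kb grid; precomputes the
#' normalized chrom-RP matrix; and writes the store to `out_store`.
#'
#' @param annotation path to the gene annotation (TSV or BED6).
#' @param chrom_sizes path to a two-column chrom.sizes file.
#' @param track_paths named character vector of bedGraph/bigWig paths;
#'   names are profile ids.
#' @param track_assays assay kind (`"dnase"`/`"h3k27ac"`) per track;
#'   default guesses from the profile id prefix.
#' @param peak_paths character vector of peak BED paths (one cistrome
#'   each).
#' @param covariates optional path to a two-column TSV (`gene_id`,
#'   `covariate`) of promoter activities for background stratification.
#' @param out_store output store path (`NULL` to skip writing).
#' @param params an [rp_params()].
#' @param verbose log progress?
#' @return the [compendium_store()], invisibly when written.
#' @export
cmd_build <- function(annotation, chrom_sizes, track_paths,
                      track_assays = NULL, peak_paths = character(),
                      covariates = NULL, out_store = NULL,
                      params = rp_params(), verbose = FALSE) {
  grid <- read_chrom_sizes(chrom_sizes, window_size = params$window_size)
  genes <- read_gene_annotation(annotation, grid = grid)
  if (is.null(names(track_paths)))
    names(track_paths) <- sub("\\.[^.]+$", "", basename(track_paths))
  if (is.null(track_assays))
    track_assays <- ifelse(grepl("h3k27ac", names(track_paths),
                                 ignore.case = TRUE), "h3k27ac", "dnase")
  tracks <- lapply(seq_along(track_paths), function(i) {
    if (verbose) message("binning ", track_paths[i])
    read_signal_track(track_paths[i], grid,
                      profile_id = names(track_paths)[i],
                      assay_kind = track_assays[i])
  })
  cistromes <- lapply(peak_paths, function(p) {
    if (verbose) message("loading peaks ", p)
    read_bed_peaks(p, grid)
  })
  cov <- NULL
  if (!is.null(covariates)) {
    cv <- utils::read.table(covariates, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    cov <- stats::setNames(cv[[2]], cv[[1]])
  }
  store <- compendium_store(grid, genes, tracks, cistromes,
                            covariates = cov)
  store$rp_cache <- compute_rp_matrix(store, params)
  if (!is.null(out_store)) {
    save_store(store, out_store)
    if (verbose) message("store written to ", out_store)
    return(invisible(store))
  }
  store
}

#' Scan a genome for motif-imputed cistromes and add them to a store
#'
#' One cistrome (source `"motif_hits"`) is added per PWM; rescanning a
#' motif already in the store replaces its cistrome rather than
#' duplicating it.
#'
#' @param store a [compendium_store()] or a store file path.
#' @param fasta genome FASTA path, or a named `DNAStringSet`.
#' @param pwm_file JASPAR-format PWM text path, or a list of [pwm()]s.
#' @param scan_window scan tile width in bp (default 100).
#' @param threshold_percentile hit-calling percentile (default 99).
#' @param out_store optional path to rewrite the store.
#' @param verbose log progress?
#' @return the updated store.
#' @export
cmd_scan <- function(store, fasta, pwm_file, scan_window = 100L,
                     threshold_percentile = 99, out_store = NULL,
                     verbose = FALSE) {
  if (is.character(store)) store <- load_store(store)
  seqs <- if (is.character(fasta))
    Biostrings::readDNAStringSet(fasta) else fasta
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  pwms <- if (is.character(pwm_file)) read_jaspar(pwm_file) else pwm_file
  if (length(pwms) == 0) {
    warning("no PWMs to scan; store unchanged")
    return(store)
  }
  for (p in pwms) {
    if (verbose) message("scanning ", p$motif_id)
    sc <- score_windows(seqs, p, store$grid, scan_window = scan_window)
    hits <- call_hits(sc, store$grid,
                      threshold_percentile = threshold_percentile)
    cis <- hits_as_cistrome(hits, store$grid)
    store$cistromes[[cis$cistrome_id]] <- cis
  }
  if (!is.null(out_store)) save_store(store, out_store)
  store
}

# Wilcoxon channel p-value from per-gene statistics; an all-zero channel
# (cistrome never touches these genes) is "no evidence": p = 1.
channel_p <- function(values, sets) {
  if (all(values == 0)) return(1)
  wilcoxon_one_sided(values[sets$query], values[sets$background])
}

#' Rank candidate regulators for a query gene set
#'
#' The full inference: resolve the query against the store, sample a
#' stratified background, fit one chromatin landscape model per assay
#' (L1 profile selection then a final logistic fit), delete each cistrome
#' in silico from each model, test query-vs-background differences per
#' evidence channel, and Cauchy-combine the channels into a ranked table.
#' ChIP-seq and motif cistromes are ranked in separate tables.
#'
#' @param store a [compendium_store()] or store file path.
#' @param gene_list character vector of query gene ids, or a path to a
#'   one-id-per-line text file.
#' @param config a [run_config()].
#' @param out_dir optional output directory; when given, the ranked
#'   table(s), model summary, config echo, unmatched-gene report and log
#'   are written there.
#' @return list of class `tr_ranking`: `tables` (per-mode
#'   `tr_rank_table`s), `models` (per-assay `chrom_model`s), `channels`
#'   (the per-cistrome channel p-values), `sets`, `resolution`, `config`.
#' @export
cmd_rank <- function(store, gene_list, config = run_config(),
                     out_dir = NULL) {
  if (is.character(store) && length(store) == 1) store <- load_store(store)
  if (length(gene_list) == 1 && file.exists(gene_list))
    gene_list <- readLines(gene_list)
  logs <- character()
  res <- resolve_gene_ids(gene_list, store$genes)
  if (length(res$matched) == 0)
    stop("no query gene resolvable in the store; unmatched: ",
         paste(utils::head(res$unmatched, 20), collapse = ", "))
  if (res$n_fallback > 0)
    logs <- c(logs, log_msg(config, "%d identifier(s) matched case-%s",
                            res$n_fallback, "insensitively"))
  if (length(res$matched) < 20)
    warning("only ", length(res$matched), " query genes resolved; ",
            "rankings may be unstable")
  logs <- c(logs, log_msg(config, "query: %d genes resolved, %d unmatched",
                          length(res$matched), length(res$unmatched)))

  sets <- select_background(res$matched, store,
                            n = config$background_size,
                            bins = config$bins, seed = config$seed)
  logs <- c(logs, log_msg(config, "background: %d genes (seed %d)",
                          length(sets$background), config$seed))
  rp <- store$rp_cache
  if (is.null(rp)) rp <- compute_rp_matrix(store, config$params)

  assays <- vapply(store$tracks, `[[`, "", "assay_kind")
  models <- list()
  for (assay in intersect(c("dnase", "h3k27ac"), unique(assays))) {
    cols <- names(store$tracks)[assays == assay]
    path <- fit_l1_path(rp$normalized[, cols, drop = FALSE], sets,
                        max_profiles = config$max_profiles)
    models[[assay]] <- fit_final_model(
      rp$normalized, sets, path$selected_profiles, assay_kind = assay,
      penalty = path$penalty)
    logs <- c(logs, log_msg(config,
                            "%s model: %d profiles selected, AUC %.3f",
                            assay, path$n_selected, models[[assay]]$auc))
  }
  if (length(models) == 0) stop("store has no chromatin signal tracks")

  all_genes <- c(sets$query, sets$background)
  gsub_genes <- store$genes[match(all_genes, store$genes$gene_id), ,
                            drop = FALSE]
  ctx <- gene_window_context(store$grid, gsub_genes, config$params)
  prp <- compute_peak_rp(store, params = config$params)[all_genes, ,
                                                        drop = FALSE]
  channels <- data.frame(
    cistrome_id = vapply(store$cistromes, `[[`, "", "cistrome_id"),
    tr_name = vapply(store$cistromes, `[[`, "", "tr_name"),
    source = vapply(store$cistromes, `[[`, "", "source"),
    p_peak_rp = NA_real_, p_isd_dnase = NA_real_,
    p_isd_h3k27ac = NA_real_, stringsAsFactors = FALSE)
  rownames(channels) <- NULL
  for (i in seq_len(nrow(channels))) {
    cis <- store$cistromes[[channels$cistrome_id[i]]]
    channels$p_peak_rp[i] <- channel_p(prp[, cis$cistrome_id], sets)
    for (assay in names(models)) {
      d <- delta_rp(models[[assay]], store, cis, all_genes, rp = rp,
                    params = config$params, ctx = ctx)
      channels[[paste0("p_isd_", assay)]][i] <- channel_p(d$delta_rp, sets)
    }
  }

  tables <- list()
  if (config$mode %in% c("both", "chipseq")) {
    sel <- channels$source == "chipseq_peaks"
    if (any(sel))
      tables$chipseq <- combine_channels(channels[sel, , drop = FALSE],
                                         mode = "chipseq")
  }
  if (config$mode %in% c("both", "motif")) {
    sel <- channels$source == "motif_hits"
    if (any(sel))
      tables$motif <- combine_channels(channels[sel, , drop = FALSE],
                                       mode = "motif")
  }
  if (length(tables) == 0)
    stop("no cistromes of the requested kind in the store")

  out <- structure(list(tables = tables, models = models,
                        channels = channels, sets = sets,
                        resolution = res, config = config, log = logs),
                   class = "tr_ranking")
  if (!is.null(out_dir)) write_ranking_outputs(out, out_dir)
  out
}

write_ranking_outputs <- function(ranking, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (mode in names(ranking$tables))
    utils::write.table(as.data.frame(ranking$tables[[mode]]),
                       file.path(out_dir,
                                 sprintf("%s_ranking.tsv", mode)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  ms <- do.call(rbind, lapply(ranking$models, function(m)
    data.frame(profile_id = m$selected_profiles,
               assay_kind = m$assay_kind, alpha = unname(m$alpha),
               auc = m$auc, penalty = m$penalty,
               stringsAsFactors = FALSE)))
  utils::write.table(ms, file.path(out_dir, "model_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- ranking$config
  writeLines(c(sprintf("background_size=%d", cfg$background_size),
               sprintf("bins=%d", cfg$bins),
               sprintf("max_profiles=%d", cfg$max_profiles),
               sprintf("mode=%s", cfg$mode),
               sprintf("seed=%d", cfg$seed),
               sprintf("L=%g", cfg$params$L),
               sprintf("delta=%g", cfg$params$delta),
               sprintf("window_size=%d", cfg$params$window_size)),
             file.path(out_dir, "config.txt"))
  writeLines(ranking$resolution$unmatched,
             file.path(out_dir, "unmatched_genes.txt"))
  writeLines(ranking$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Emit a synthetic fixture bundle
#'
#' Generates the synthetic compendium for a [fixture_spec()] and writes it
#' as standard-format files ([write_fixture_bundle()]), ready for
#' [cmd_build()].
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory.
#' @param params an [rp_params()].
#' @return the `fixture_bundle`, invisibly.
#' @export
cmd_simulate <- function(spec = fixture_spec(), out_dir,
                         params = rp_params()) {
  fx <- generate_fixtures(spec, params)
  write_fixture_bundle(fx, out_dir)
  echo <- vapply(spec, function(v) as.character(v)[1], "")
  writeLines(paste0(names(echo), "=", echo),
             file.path(out_dir, "fixture_spec.txt"))
  invisible(fx)
}
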